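#' Single-generation moments of allele frequency change
#'
#' First two moments of the change in frequency of an allele with (signed)
#' effect `a` when the population mean is at distance `D` from the optimum
#' (internal \eqn{\delta} units, so `VS = 2N`):
#' \deqn{E(\Delta x) = \left(\frac{aD}{V_S} - \frac{a^2}{V_S}
#'   \left(\tfrac{1}{2}-x\right)\right) x(1-x), \qquad
#'   V(\Delta x) = \frac{x(1-x)}{2N}.}
#' The first term is directional selection (semi-dominant, favoring alleles
#' whose effects reduce `D`), the second stabilizing selection
#' (under-dominant, against the minor allele). For a rare allele the expected
#' change is positive exactly when `D > a/2`.
#'
#' @param a Signed allele effect (orientation times magnitude), \eqn{\delta}
#'   units.
#' @param x Current frequency in `[0, 1]`.
#' @param D Distance of the mean phenotype from the new optimum
#'   (\eqn{\delta} units).
#' @param scale A [trait_scale()].
#' @return A list with vectors `expected` and `variance`.
#' @examples
#' sc <- trait_scale(5000)
#' delta_x_moments(sqrt(200), 0.0025, 50, sc)$expected  # ~1.515e-4
#' @export
delta_x_moments <- function(a, x, D, scale) {
  stopifnot(inherits(scale, "trait_scale"))
  if (any(x < 0 | x > 1)) stop("`x` must lie in [0, 1]", call. = FALSE)
  VS <- 2 * scale$N
  list(expected = (a * D / VS - (a^2 / VS) * (0.5 - x)) * x * (1 - x),
       variance = x * (1 - x) / (2 * scale$N))
}

# --- internal population state -------------------------------------------
# Vectors indexed by allele; `seg` holds indices of segregating alleles.
# fate codes: 0 segregating, 1 fixed, 2 lost.
new_population_state <- function(scenario, standing) {
  n <- nrow(standing)
  cap <- max(64L, 2L * n)
  st <- list(
    t = 0L, Lambda = scenario$Lambda, mean_bg = 0, shift_large = 0,
    n = n, cap = cap, next_id = n + 1L, archive = list(),
    id = c(seq_len(n), integer(cap - n)),
    a = c(standing$a, numeric(cap - n)),
    ori = c(as.integer(standing$orientation), integer(cap - n)),
    x = c(standing$x0, numeric(cap - n)),
    x0eff = c(standing$x0, numeric(cap - n)),
    x0 = c(standing$x0, numeric(cap - n)),
    xmax = c(standing$x0, numeric(cap - n)),
    origin = c(rep(1L, n), integer(cap - n)),  # 1 standing, 2 new
    birth = integer(cap),
    fate = integer(cap),
    fate_gen = rep(NA_integer_, cap),
    seg = seq_len(n))
  st$D <- scenario$Lambda
  st$VA_large <- if (n) sum(2 * st$a[st$seg]^2 * st$x[st$seg] *
                              (1 - st$x[st$seg])) else 0
  st
}

# Move finished (fixed/lost) alleles out of the hot per-allele vectors into
# an archive of data-frame chunks, so per-generation vector operations stay
# proportional to the number of segregating alleles. Bookkeeping scalars
# (shift_large, mean_bg) already carry the permanent contributions of
# finished alleles, so compaction does not affect the dynamics.
compact_state <- function(st) {
  live <- seq_len(st$n)
  done <- live[st$fate[live] != 0L]
  if (length(done) == 0L) return(st)
  st$archive[[length(st$archive) + 1L]] <- alleles_chunk(st, done)
  keep <- live[st$fate[live] == 0L]
  nk <- length(keep)
  cap <- max(64L, 2L * nk)
  pad_d <- numeric(cap - nk)
  pad_i <- integer(cap - nk)
  st$id <- c(st$id[keep], pad_i)
  st$a <- c(st$a[keep], pad_d)
  st$ori <- c(st$ori[keep], pad_i)
  st$x <- c(st$x[keep], pad_d)
  st$x0eff <- c(st$x0eff[keep], pad_d)
  st$x0 <- c(st$x0[keep], pad_d)
  st$xmax <- c(st$xmax[keep], pad_d)
  st$origin <- c(st$origin[keep], pad_i)
  st$birth <- c(st$birth[keep], pad_i)
  st$fate <- c(st$fate[keep], pad_i)
  st$fate_gen <- c(st$fate_gen[keep], rep(NA_integer_, cap - nk))
  st$n <- nk
  st$cap <- cap
  st$seg <- seq_len(nk)
  st
}

alleles_chunk <- function(st, i) {
  data.frame(
    allele_id = st$id[i], Se = st$a[i]^2, a = st$a[i],
    orientation = st$ori[i],
    origin = c("standing", "new")[st$origin[i]],
    birth_generation = st$birth[i],
    fate = c("segregating", "fixed", "lost")[st$fate[i] + 1L],
    fate_generation = st$fate_gen[i],
    x0 = st$x0[i], x_max = st$xmax[i], x_final = st$x[i])
}

grow_state <- function(st, need) {
  newcap <- st$cap
  while (newcap < need) newcap <- 2L * newcap
  pad <- newcap - st$cap
  for (f in c("a", "x", "x0eff", "x0", "xmax"))
    st[[f]] <- c(st[[f]], numeric(pad))
  for (f in c("id", "ori", "origin", "birth", "fate"))
    st[[f]] <- c(st[[f]], integer(pad))
  st$fate_gen <- c(st$fate_gen, rep(NA_integer_, pad))
  st$cap <- newcap
  st
}

# One generation of the hybrid engine, operating on the internal state.
# Order within a generation: (i) binomial update of segregating alleles at
# the current D; (ii) deterministic background advance by D*(1-exp(-s2/VS)),
# the one-generation solution of Lande's equation; (iii) Poisson(2NU) new
# mutations at 1/2N; (iv) D recomputed from the bookkeeping identity;
# (v) fates updated.
step_state <- function(st, scenario) {
  N <- scenario$N
  twoN <- 2 * N
  VS <- 2 * N
  D <- st$D
  seg <- st$seg
  if (length(seg)) {
    a <- st$a[seg] * st$ori[seg]
    x <- st$x[seg]
    ex <- x + (a * D / VS - (a^2 / VS) * (0.5 - x)) * x * (1 - x)
    xn <- stats::rbinom(length(seg), twoN, pmin(pmax(ex, 0), 1)) / twoN
    st$shift_large <- st$shift_large + sum(st$ori[seg] * 2 * st$a[seg] *
                                             (xn - x))
    st$x[seg] <- xn
    st$xmax[seg] <- pmax(st$xmax[seg], xn)
    fixed <- xn == 1
    lost <- xn == 0
    if (any(fixed | lost)) {
      st$fate[seg[fixed]] <- 1L
      st$fate[seg[lost]] <- 2L
      st$fate_gen[seg[fixed | lost]] <- st$t + 1L
      st$seg <- seg[!(fixed | lost)]
    }
  }
  st$mean_bg <- st$mean_bg + D * (1 - exp(-scenario$sigma2 / VS))
  if (scenario$twoNU > 0) {
    k <- stats::rpois(1, scenario$twoNU)
    if (k > 0) {
      if (st$n + k > st$cap) st <- grow_state(st, st$n + k)
      idx <- st$n + seq_len(k)
      st$id[idx] <- st$next_id + seq_len(k) - 1L
      st$next_id <- st$next_id + k
      Se_new <- scenario$effect_dist$sample(k)
      st$a[idx] <- sqrt(Se_new)
      st$ori[idx] <- sample(c(-1L, 1L), k, replace = TRUE)
      st$x[idx] <- 1 / twoN
      st$x0eff[idx] <- 0
      st$x0[idx] <- 1 / twoN
      st$xmax[idx] <- 1 / twoN
      st$origin[idx] <- 2L
      st$birth[idx] <- st$t + 1L
      st$fate[idx] <- 0L
      st$n <- st$n + k
      st$seg <- c(st$seg, idx)
      st$shift_large <- st$shift_large + sum(st$ori[idx] * 2 * st$a[idx] /
                                               twoN)
    }
  }
  st$t <- st$t + 1L
  st$D <- st$Lambda - st$mean_bg - st$shift_large
  seg <- st$seg
  st$VA_large <- if (length(seg)) sum(2 * st$a[seg]^2 * st$x[seg] *
                                        (1 - st$x[seg])) else 0
  # keep hot vectors proportional to the segregating count
  if (st$n - length(seg) > pmax(1024L, length(seg)))
    st <- compact_state(st)
  st
}

state_alleles_df <- function(st) {
  chunks <- c(st$archive, list(alleles_chunk(st, seq_len(st$n))))
  out <- do.call(rbind, chunks)
  if (nrow(out)) out <- out[order(out$allele_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Advance the hybrid engine by one generation
#'
#' Functional single-step interface to the hybrid engine used by
#' [run_hybrid()]: each segregating large-effect allele receives a binomial
#' update around its expected frequency change ([delta_x_moments()] at the
#' current distance `D`), the infinitesimal background mean advances
#' deterministically by `D * (1 - exp(-sigma2/VS))` (the one-generation
#' solution of Lande's equation), `Poisson(2NU)` new mutations enter at
#' frequency \eqn{1/2N}, and `D` is recomputed from the bookkeeping identity
#' \deqn{D = \Lambda - \Delta\bar{z}_{bg} - \sum_i o_i\, 2 a_i (x_i -
#'   x_i(0^-)),}
#' where \eqn{x_i(0^-)} is the pre-shift frequency (`x0` for standing
#' alleles, 0 for new mutations).
#'
#' @param state A population state created by [population_state()] or
#'   returned by a previous `step_hybrid()` call.
#' @param scenario A [scenario()].
#' @return The updated state.
#' @seealso [run_hybrid()]
#' @export
step_hybrid <- function(state, scenario) {
  stopifnot(inherits(scenario, "scenario"))
  step_state(state, scenario)
}

#' Create a population state at the moment of the shift
#'
#' @param scenario A [scenario()].
#' @param standing A `standing_architecture` (defaults to an empty one).
#' @return A population state list with fields `t`, `D`, `mean_bg`,
#'   `VA_large` and per-allele vectors, for use with [step_hybrid()].
#' @export
population_state <- function(scenario, standing = NULL) {
  if (is.null(standing))
    standing <- new_standing_architecture(numeric(0), integer(0), numeric(0),
                                          N = scenario$N)
  new_population_state(scenario, standing)
}

#' Run the hybrid engine: tracked large-effect alleles over a Lande background
#'
#' Stochastic forward simulation after a sudden optimum shift. Large-effect
#' alleles (standing ones from `standing`, new ones arising at rate `2NU`
#' per generation) are tracked individually with per-locus binomial updates
#' under the signed single-generation moments; small- and intermediate-effect
#' variation is summarized by a normally distributed "Fisherian" background
#' of constant variance `sigma2` whose mean advances by Lande's
#' approximation. Deterministic given the RNG state.
#'
#' The run stops early (unless `full_horizon = TRUE`) once no large-effect
#' allele segregates, the distance has decayed below `stop_D`, and the
#' new-mutation window `T_end` ([adaptation_window()]) has closed; with
#' `twoNU = 0` the distance condition alone applies since no further alleles
#' can arise.
#'
#' @param scenario A [scenario()].
#' @param standing Standing architecture at the shift; defaults to
#'   [sample_standing()] drawn from the current RNG stream.
#' @param generations Maximum number of generations (default: the
#'   new-mutation window plus `2N`, long enough for borderline trajectories
#'   near frequency 1/2 to resolve by drift).
#' @param thin Stride for recording the per-generation series.
#' @param full_horizon If `TRUE`, ignore the early-stopping rule.
#' @param record_freqs If `TRUE`, also record thinned per-allele frequency
#'   series (long format) in `$freqs`.
#' @param stop_D Distance threshold of the early-stopping rule, in
#'   \eqn{\delta} units.
#' @param max_alleles Memory guard: abort if the segregating count exceeds
#'   this cap.
#' @return An object of class `"shift_trajectory"`: a list with `series`
#'   (data frame `t`, `D`, `VA_large`, `sigma2`, `n_segregating`), `alleles`
#'   (terminal table of every allele ever born, with fates, `x0` and
#'   `x_max`), optionally `freqs`, and the `scenario`.
#' @examples
#' sc <- scenario(N = 1000, Lambda = 30, sigma2 = 40, twoNU = 0)
#' set.seed(1)
#' tr <- run_hybrid(sc, generations = 200)
#' head(tr$series)
#' @export
run_hybrid <- function(scenario, standing = NULL, generations = NULL,
                       thin = 1L, full_horizon = FALSE, record_freqs = FALSE,
                       stop_D = 1e-3, max_alleles = Inf) {
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(standing)) standing <- sample_standing(scenario)
  t_end <- adaptation_window(scenario$Lambda, scenario$sigma2, scenario$scale)
  if (is.null(generations))
    generations <- ceiling(min(t_end, 10 * scenario$N)) + 2L * scenario$N
  if (generations < 1) stop("`generations` must be >= 1", call. = FALSE)
  st <- new_population_state(scenario, standing)
  nrec <- generations %/% thin + 2L
  rec_t <- integer(nrec); rec_D <- numeric(nrec); rec_VA <- numeric(nrec)
  rec_ns <- integer(nrec)
  freqs <- if (record_freqs) vector("list", nrec) else NULL
  ri <- 0L
  record <- function() {
    ri <<- ri + 1L
    rec_t[ri] <<- st$t; rec_D[ri] <<- st$D; rec_VA[ri] <<- st$VA_large
    rec_ns[ri] <<- length(st$seg)
    if (record_freqs && length(st$seg))
      freqs[[ri]] <<- data.frame(t = st$t, allele_id = st$id[st$seg],
                                 x = st$x[st$seg])
  }
  record()
  for (g in seq_len(generations)) {
    st <- step_state(st, scenario)
    if (length(st$seg) > max_alleles)
      stop("segregating allele count exceeded `max_alleles`", call. = FALSE)
    if (st$t %% thin == 0L) record()
    if (!full_horizon && length(st$seg) == 0L && st$D < stop_D &&
        (scenario$twoNU == 0 || st$t >= t_end))
      break
  }
  if (st$t %% thin != 0L) record()
  series <- data.frame(t = rec_t[seq_len(ri)], D = rec_D[seq_len(ri)],
                       VA_large = rec_VA[seq_len(ri)],
                       sigma2 = scenario$sigma2,
                       n_segregating = rec_ns[seq_len(ri)])
  out <- list(series = series, alleles = state_alleles_df(st),
              freqs = if (record_freqs) do.call(rbind, freqs[seq_len(ri)]),
              scenario = scenario, T_end = t_end, generations_run = st$t,
              final_state = st)
  class(out) <- "shift_trajectory"
  out
}

#' @export
print.shift_trajectory <- function(x, ...) {
  n_fix <- sum(x$alleles$fate == "fixed")
  cat("Optimum-shift trajectory: ", x$generations_run, " generations, ",
      nrow(x$alleles), " large-effect alleles ever born, ", n_fix,
      " fixed\n", sep = "")
  cat("  final D = ", format(x$series$D[nrow(x$series)]),
      " (Lambda = ", format(x$scenario$Lambda), ")\n", sep = "")
  invisible(x)
}

#' Run the fully polygenic engine
#'
#' Every allele affecting the trait, across the whole effect-size range, is
#' tracked individually with binomial updates under the signed
#' single-generation moments; there is no deterministic background, and the
#' distance `D` is computed from the bookkeeping identity over all loci.
#' Recurrent mutation continues throughout. The initial segregating set is
#' drawn from the MSDB sojourn distribution over the full effect
#' distribution unless `standing` is supplied.
#'
#' @param N Diploid population size.
#' @param Lambda Shift size (\eqn{\delta} units).
#' @param twoNU Population-scaled mutational input across the full effect
#'   distribution.
#' @param effect_dist An [effect_dist] over all effect sizes (construct with
#'   `large_cutoff = 0` to admit small effects).
#' @param generations Number of generations to run (no early stopping).
#' @param standing Optional initial `standing_architecture`.
#' @param thin Recording stride.
#' @param record_freqs Record thinned per-allele frequencies.
#' @param max_alleles Memory guard: abort if the segregating count exceeds
#'   this cap.
#' @return A `"shift_trajectory"` (see [run_hybrid()]).
#' @export
run_polygenic <- function(N, Lambda, twoNU, effect_dist, generations,
                          standing = NULL, thin = 1L, record_freqs = FALSE,
                          max_alleles = 2e5) {
  sc <- scenario(N = N, Lambda = Lambda, sigma2 = 0, twoNU = twoNU,
                 effect_dist = effect_dist, large_cutoff = 0)
  # warn when the trait is not highly polygenic: MSDB variance should dwarf
  # the typical squared effect for the per-locus diffusion to describe a
  # polygenic response
  nodes <- effect_dist_nodes(effect_dist)
  va_msdb <- twoNU * sum(nodes$w * vapply(nodes$Se, sojourn_variance_per_input,
                                          numeric(1), scale = sc$scale))
  mean_se <- sum(nodes$w * nodes$Se)
  if (va_msdb < 10 * mean_se)
    warning("MSDB variance (", format(va_msdb, digits = 3),
            ") is not much larger than the typical squared effect (",
            format(mean_se, digits = 3),
            "): the trait is not highly polygenic", call. = FALSE)
  if (is.null(standing)) standing <- sample_standing(sc)
  run_hybrid(sc, standing = standing, generations = generations,
             thin = thin, full_horizon = TRUE, record_freqs = record_freqs,
             max_alleles = max_alleles)
}
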