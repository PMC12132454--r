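#' @keywords internal
logspace_add <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))

# package-local cache of sojourn grids, keyed by (Se, N)
.sojourn_cache <- new.env(parent = emptyenv())

# Sojourn-time grid for an allele under stabilizing selection at MSDB.
#
# Diffusion with drift m(x) = -(Se/2N)(1/2 - x)x(1-x) (internal units, so
# a^2/VS = Se/2N) and variance v(x) = x(1-x)/2N; a new mutant enters at
# p = 1/2N. With psi(y) = exp(-int 2m/v) = exp(Se*y*(1-y)) and
# Psi(x) = int_0^x psi, the standard sojourn-time density is
#   t(x) = 2 Psi(p) (Psi(1)-Psi(x)) / (Psi(1) v(x) psi(x))   for x >= p,
#   t(x) = 2 Psi(x) (Psi(1)-Psi(p)) / (Psi(1) v(x) psi(x))   for x <  p.
# psi reaches exp(Se/4), so everything is assembled in log space.
sojourn_grid <- function(Se, N, n = 1200) {
  key <- paste0(format(Se, digits = 12), "_", N)
  hit <- get0(key, envir = .sojourn_cache)
  if (!is.null(hit)) return(hit)
  if (!is.finite(Se) || Se < 0) stop("`Se` must be >= 0", call. = FALSE)
  p <- 1 / (2 * N)
  xmin <- 1 / (100 * N)
  half <- exp(seq(log(xmin), log(0.5), length.out = ceiling(n / 2)))
  x <- sort(unique(c(p, half, 1 - half)))
  m <- length(x)
  logpsi <- Se * x * (1 - x)
  dx <- diff(x)
  # log of trapezoid segment masses of psi
  lseg <- log(dx / 2) + logspace_add(logpsi[-1], logpsi[-m])
  # end slivers [0, xmin] and [1 - xmin, 1]: psi ~ exp(Se*y) near 0
  lm0 <- if (Se > 0) log(expm1(Se * xmin)) - log(Se) else log(xmin)
  # cumulative log-sum-exp
  lcum <- function(v, init) {
    out <- numeric(length(v) + 1L)
    s <- init
    out[1L] <- s
    for (i in seq_along(v)) {
      s <- logspace_add(s, v[i])
      out[i + 1L] <- s
    }
    out
  }
  logPsi <- lcum(lseg, lm0)              # Psi at grid points
  logPsiT <- rev(lcum(rev(lseg), lm0))   # Psi(1) - Psi(x) at grid points
  logPsi1 <- logspace_add(logPsi[m], lm0)
  logv <- log(x) + log1p(-x) - log(2 * N)
  ip <- match(p, x)
  logtau <- ifelse(
    x >= p,
    log(2) + logPsi[ip] + logPsiT - logPsi1 - logv - logpsi,
    log(2) + logPsi + logPsiT[ip] - logPsi1 - logv - logpsi)
  tau <- exp(logtau)
  # total sojourn mass over (0,1), including the end slivers where tau is flat
  mass <- sum(diff(x) * (tau[-1] + tau[-m]) / 2) + xmin * (tau[1] + tau[m])
  # segregating mass: integral over the frequency cells of the Wright-Fisher
  # states k/2N, k = 1..2N-1, i.e. (1/4N, 1 - 1/4N); the sliver below 1/4N
  # has no segregating-state counterpart (it reflects sub-entry boundary
  # layers of the diffusion)
  lo <- 1 / (4 * N)
  seg <- x >= lo & x <= 1 - lo
  xs <- x[seg]; ts <- tau[seg]
  ms <- length(xs)
  mass_seg <- sum(diff(xs) * (ts[-1] + ts[-ms]) / 2)
  cdf_seg <- c(0, cumsum(diff(xs) * (ts[-1] + ts[-ms]) / 2)) / mass_seg
  res <- list(Se = Se, N = N, x = x, tau = tau, mass = mass,
              mass_seg = mass_seg, x_seg = xs, cdf_seg = cdf_seg)
  assign(key, res, envir = .sojourn_cache)
  res
}

#' Sojourn-time density at mutation-selection-drift balance
#'
#' Before the shift the population mean sits at the optimum, so an allele of
#' squared effect \eqn{S_e = a^2} experiences only the under-dominant
#' stabilizing-selection term and genetic drift. `sojourn_density` returns the
#' (unnormalized) diffusion sojourn-time density over frequency for a new
#' mutant entering at frequency \eqn{1/2N}: `2NU` times its integral is the
#' expected number of such alleles segregating at stationarity, and its
#' normalized form is the frequency distribution of a segregating allele.
#'
#' @param Se Squared allele effect in internal units (>= 0; 0 gives the
#'   neutral limit).
#' @param scale A [trait_scale()] (only `N` is used; internal units assumed).
#' @return A vectorized function of frequency `x` in (0,1), with the
#'   quadrature grid attached as attribute `"grid"`.
#' @seealso [sojourn_mass()], [r_sojourn()], [sample_standing()]
#' @examples
#' sc <- trait_scale(1000)
#' f <- sojourn_density(0, sc)     # neutral: ~ 2/x for x above 1/2N
#' f(0.01) / f(0.02)               # ~ 2
#' @export
sojourn_density <- function(Se, scale) {
  stopifnot(inherits(scale, "trait_scale"))
  g <- sojourn_grid(Se, scale$N)
  f <- function(x) {
    if (any(x <= 0 | x >= 1)) stop("`x` must lie strictly in (0,1)",
                                   call. = FALSE)
    exp(stats::approx(g$x, log(g$tau), xout = pmin(pmax(x, g$x[1]),
                                                   g$x[length(g$x)]),
                      rule = 2)$y)
  }
  attr(f, "grid") <- g
  class(f) <- c("sojourn_density", "function")
  f
}

#' Expected sojourn mass per unit mutational input
#'
#' Integral of the sojourn-time density of [sojourn_density()] over the
#' frequency cells of the segregating Wright-Fisher states
#' (`(1/4N, 1 - 1/4N)` by default); multiplied by `2NU` it gives the
#' expected number of segregating alleles of squared effect `Se` at MSDB.
#' With `full = TRUE` the integral runs over all of (0,1), which also counts
#' the sub-entry boundary layer of the diffusion below frequency `1/4N`.
#'
#' @inheritParams sojourn_density
#' @param full Integrate over all of (0,1) instead of the segregating cells.
#' @return A single number.
#' @export
sojourn_mass <- function(Se, scale, full = FALSE) {
  stopifnot(inherits(scale, "trait_scale"))
  g <- sojourn_grid(Se, scale$N)
  if (full) g$mass else g$mass_seg
}

#' Draw standing frequencies from the MSDB sojourn distribution
#'
#' Inverse-CDF sampling from the normalized sojourn-time density of a
#' segregating allele with squared effect `Se`, restricted to the
#' segregating-state cells `(1/4N, 1 - 1/4N)`. By default draws are rounded
#' to the nearest Wright-Fisher state `k/2N` (`k = 1, ..., 2N-1`), matching
#' the discrete frequencies of the forward engines; set `discrete = FALSE`
#' for raw continuum draws.
#'
#' @param n Number of draws.
#' @inheritParams sojourn_density
#' @param discrete Round draws to Wright-Fisher states (default `TRUE`).
#' @return Numeric vector of frequencies in (0,1).
#' @export
r_sojourn <- function(n, Se, scale, discrete = TRUE) {
  stopifnot(inherits(scale, "trait_scale"))
  g <- sojourn_grid(Se, scale$N)
  u <- stats::runif(n)
  x <- stats::approx(g$cdf_seg, g$x_seg, xout = u, rule = 2,
                     ties = "ordered")$y
  if (discrete) {
    twoN <- 2 * scale$N
    x <- pmin(pmax(round(x * twoN), 1), twoN - 1) / twoN
  }
  x
}

# expected contribution to genetic variance per unit mutational input:
# int 2 Se x (1-x) tau(x) dx  (a^2 = Se in internal units)
sojourn_variance_per_input <- function(Se, scale) {
  g <- sojourn_grid(Se, scale$N)
  integrand <- 2 * Se * g$x * (1 - g$x) * g$tau
  m <- length(g$x)
  sum(diff(g$x) * (integrand[-1] + integrand[-m]) / 2)
}

#' Construct a standing architecture by hand
#'
#' Assembles the set of large-effect alleles segregating at the moment of
#' the shift from explicit vectors, e.g. to run single-allele experiments
#' with a chosen initial frequency. [sample_standing()] draws such
#' architectures from MSDB instead.
#'
#' @param Se Squared effects (internal units).
#' @param orientation +1 (aligned with the shift) or -1, recycled.
#' @param x0 Initial frequencies in (0, 1).
#' @param N Population size the frequencies refer to.
#' @return A `standing_architecture` data frame.
#' @examples
#' standing_architecture(Se = 200, orientation = 1, x0 = 1/400, N = 1000)
#' @export
standing_architecture <- function(Se, orientation, x0, N) {
  stopifnot(length(Se) == length(x0), all(x0 > 0 & x0 < 1),
            all(orientation %in% c(-1, 1)))
  new_standing_architecture(Se, rep_len(orientation, length(Se)), x0, N = N)
}

new_standing_architecture <- function(Se, orientation, x0, origin = "standing",
                                      N = NULL) {
  df <- data.frame(
    allele_id = seq_along(Se),
    Se = as.numeric(Se),
    a = sqrt(as.numeric(Se)),
    orientation = as.integer(orientation),
    x0 = as.numeric(x0),
    origin = rep_len(origin, length(Se)))
  class(df) <- c("standing_architecture", "data.frame")
  attr(df, "N") <- N
  df
}

#' Total large-effect genetic variance of a standing architecture
#'
#' \eqn{\sum_i 2 a_i^2 x_i (1 - x_i)} in \eqn{\delta^2} units.
#'
#' @param arch A `standing_architecture` as returned by [sample_standing()]
#'   or [burnin_engine()].
#' @return A single number.
#' @export
total_large_variance <- function(arch) {
  if (nrow(arch) == 0) return(0)
  sum(2 * arch$Se * arch$x0 * (1 - arch$x0))
}

#' Sample the standing large-effect architecture at the shift
#'
#' The number of large-effect alleles segregating at the moment of the shift
#' is Poisson with mean `2NU` times the expected sojourn mass integrated over
#' the mutational distribution of effects; each allele's `(Se, x0)` pair is
#' drawn from the joint density `effect_dist(Se) * sojourn(x | Se)` and its
#' orientation is +1/-1 with probability 1/2. Replicates with zero standing
#' alleles are retained (the Poisson number is not conditioned).
#'
#' @param scenario A [scenario()].
#' @return A `standing_architecture` data frame (columns `allele_id`, `Se`,
#'   `a`, `orientation`, `x0`, `origin`), possibly with zero rows.
#' @examples
#' sc <- scenario(N = 1000, Lambda = 30, sigma2 = 40, twoNU = 5,
#'                effect_dist = effect_dist_point(200))
#' set.seed(1)
#' arch <- sample_standing(sc)
#' total_large_variance(arch)
#' @export
sample_standing <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  if (scenario$twoNU == 0)
    return(new_standing_architecture(numeric(0), integer(0), numeric(0),
                                     N = scenario$N))
  nodes <- effect_dist_nodes(scenario$effect_dist)
  mass <- vapply(nodes$Se, sojourn_mass, numeric(1), scale = scenario$scale)
  lambda <- scenario$twoNU * sum(nodes$w * mass)
  n <- stats::rpois(1, lambda)
  if (n == 0)
    return(new_standing_architecture(numeric(0), integer(0), numeric(0),
                                     N = scenario$N))
  pr <- nodes$w * mass
  idx <- sample.int(length(nodes$Se), n, replace = TRUE, prob = pr)
  x0 <- numeric(n)
  for (k in unique(idx)) {
    sel <- idx == k
    x0[sel] <- r_sojourn(sum(sel), nodes$Se[k], scenario$scale)
  }
  ori <- sample(c(-1L, 1L), n, replace = TRUE)
  new_standing_architecture(nodes$Se[idx], ori, x0, N = scenario$N)
}

#' Wright-Fisher burn-in to mutation-selection-drift balance
#'
#' Forward simulation of the pre-shift equilibrium, used as an independent
#' cross-check of [sample_standing()]: `Poisson(2NU)` new alleles enter at
#' frequency \eqn{1/2N} each generation, every segregating allele is updated
#' by a binomial draw around its stabilizing-selection expectation (the
#' population mean is held at the optimum, `D = 0`), and fixed or lost
#' alleles are discarded.
#'
#' @param scenario A [scenario()].
#' @param generations Number of generations to simulate; at least `20 N` is
#'   recommended (a warning is issued below that), the default is `40 N` with
#'   a convergence check on the running mean of the total large-effect
#'   variance.
#' @param snapshot_every If positive, also collect the segregating set every
#'   `snapshot_every` generations after half the burn-in; the snapshots are
#'   returned in attribute `"snapshots"` (a list of data frames), giving
#'   near-independent draws from the equilibrium for distributional tests.
#' @return A `standing_architecture` data frame of the segregating set at the
#'   final generation.
#' @export
burnin_engine <- function(scenario, generations = 40 * scenario$N,
                          snapshot_every = 0) {
  stopifnot(inherits(scenario, "scenario"))
  N <- scenario$N
  twoN <- 2 * N
  if (generations < 20 * N)
    warning("burn-in shorter than 20 N generations may not reach MSDB",
            call. = FALSE)
  x <- numeric(0)
  Se <- numeric(0)
  ori <- integer(0)
  snapshots <- list()
  vl_track <- numeric(0)
  track_every <- max(1L, N %/% 10L)
  for (g in seq_len(generations)) {
    if (length(x)) {
      ex <- x - (Se / twoN) * (0.5 - x) * x * (1 - x)
      x <- stats::rbinom(length(x), twoN, pmin(pmax(ex, 0), 1)) / twoN
      keep <- x > 0 & x < 1
      if (!all(keep)) {
        x <- x[keep]; Se <- Se[keep]; ori <- ori[keep]
      }
    }
    k <- stats::rpois(1, scenario$twoNU)
    if (k > 0) {
      x <- c(x, rep(1 / twoN, k))
      Se <- c(Se, scenario$effect_dist$sample(k))
      ori <- c(ori, sample(c(-1L, 1L), k, replace = TRUE))
    }
    if (g %% track_every == 0)
      vl_track <- c(vl_track, sum(2 * Se * x * (1 - x)))
    if (snapshot_every > 0 && g > generations / 2 &&
        g %% snapshot_every == 0)
      snapshots[[length(snapshots) + 1L]] <-
        data.frame(Se = Se, orientation = ori, x0 = x)
  }
  # convergence: the running mean of total large-effect variance over the
  # last quarter vs the quarter before should agree within 5%, judged
  # against the sampling noise of the equilibrium series (chunk means)
  nk <- length(vl_track)
  if (nk >= 16) {
    half <- vl_track[seq(floor(nk / 2) + 1, nk)]
    q4 <- mean(half[seq(length(half) %/% 2 + 1, length(half))])
    q3 <- mean(half[seq_len(length(half) %/% 2)])
    chunks <- split(half, cut(seq_along(half), 8, labels = FALSE))
    se_diff <- stats::sd(vapply(chunks, mean, numeric(1))) / sqrt(2)
    if (q4 > 0 && abs(q4 - q3) / q4 > 0.05 && abs(q4 - q3) > 3 * se_diff)
      warning("burn-in may not have converged: running mean of large-effect ",
              "variance still drifting by ",
              sprintf("%.1f%%", 100 * abs(q4 - q3) / q4), call. = FALSE)
  }
  out <- new_standing_architecture(Se, ori, x, N = N)
  if (snapshot_every > 0) attr(out, "snapshots") <- snapshots
  out
}
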