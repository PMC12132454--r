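#' Derived per-replicate seeds
#'
#' Counter-based derivation of independent replicate seeds from one master
#' seed: `seed_i = (base_seed + i * 1000003) mod (2^31 - 1)`, with 0 mapped
#' to 1. The multiplier is prime and the map is injective for any replicate
#' count below 2^31 - 1, so replicate `i` can be reproduced in isolation.
#'
#' @param base_seed Master integer seed.
#' @param i Replicate index (1-based, vectorized).
#' @return Integer vector of seeds.
#' @export
derive_seed <- function(base_seed, i) {
  s <- (as.double(base_seed) + as.double(i) * 1000003) %% 2147483647
  as.integer(ifelse(s == 0, 1, s))
}

#' Long-term contribution of large-effect fixations to the shift
#'
#' Fraction of the optimum shift accounted for by fixed large-effect
#' alleles: \eqn{\sum_{\mathrm{fixed}} o_i\, 2 a_i (1 - x_{0,i}^{eff}) /
#' \Lambda}, where the effective initial frequency is the pre-shift
#' frequency for standing alleles and 0 for new mutations (a fixation moves
#' the mean by twice its effect times the frequency change it causes). The
#' remainder of the shift is absorbed by the polygenic background.
#'
#' @param trajectory A `"shift_trajectory"` from [run_hybrid()].
#' @return A single number (can exceed 1 or be negative in individual
#'   replicates; non-negative in expectation summaries).
#' @export
contribution_fraction <- function(trajectory) {
  al <- trajectory$alleles
  fixed <- al[al$fate == "fixed", , drop = FALSE]
  if (nrow(fixed) == 0) return(0)
  x0eff <- ifelse(fixed$origin == "standing", fixed$x0, 0)
  sum(fixed$orientation * 2 * fixed$a * (1 - x0eff)) /
    trajectory$scenario$Lambda
}

#' Replicate runner for the hybrid engine
#'
#' Runs [sample_standing()] + [run_hybrid()] `n_reps` times with independent
#' seeds derived from `base_seed` ([derive_seed()]), and aggregates the
#' headline summaries: number of large-effect fixations, their contribution
#' to the shift ([contribution_fraction()]), and the time for the distance
#' to first fall below the MSDB fluctuation scale \eqn{\delta}. Fully
#' reproducible from `base_seed`.
#'
#' @param scenario A [scenario()].
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Master seed.
#' @param ... Passed to [run_hybrid()] (e.g. `generations`).
#' @return An object of class `"replicate_summary"`: list with `replicates`
#'   (one row per replicate: `seed`, `n_fixed_large`,
#'   `contribution_fraction`, `time_to_D_below_delta`) and `summary`
#'   (means, SDs and Monte-Carlo standard errors).
#' @examples
#' sc <- scenario(N = 200, Lambda = 20, sigma2 = 10, twoNU = 0.5,
#'                effect_dist = effect_dist_point(50))
#' rs <- run_replicates(sc, n_reps = 5, base_seed = 1)
#' rs$summary
#' @export
run_replicates <- function(scenario, n_reps, base_seed, ...) {
  stopifnot(inherits(scenario, "scenario"), n_reps >= 1)
  seeds <- derive_seed(base_seed, seq_len(n_reps))
  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(seeds[i])
    standing <- sample_standing(scenario)
    tr <- run_hybrid(scenario, standing = standing, ...)
    below <- tr$series$t[tr$series$D < 1]
    reps[[i]] <- data.frame(
      seed = seeds[i],
      n_fixed_large = sum(tr$alleles$fate == "fixed"),
      contribution_fraction = contribution_fraction(tr),
      time_to_D_below_delta = if (length(below)) min(below) else NA_integer_)
  }
  reps <- do.call(rbind, reps)
  agg <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), sd = stats::sd(v),
      se = stats::sd(v) / sqrt(length(v)))
  }
  summary <- rbind(
    n_fixed_large = agg(reps$n_fixed_large),
    contribution_fraction = agg(reps$contribution_fraction),
    time_to_D_below_delta = agg(reps$time_to_D_below_delta),
    p_any_fixation = agg(as.numeric(reps$n_fixed_large > 0)))
  structure(list(replicates = reps, summary = as.data.frame(summary),
                 scenario = scenario, base_seed = base_seed),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("Replicate summary (", nrow(x$replicates), " replicates, base seed ",
      x$base_seed, "):\n", sep = "")
  print(round(x$summary, 5))
  invisible(x)
}

#' Convert (total variance, large-effect share) to model parameters
#'
#' Re-parameterizes the trait genetics by the total MSDB genetic variance
#' `VA0` and the proportion `p_large` of it arising from large-effect
#' alleles: the background takes `sigma2 = (1 - p_large) * VA0`, and `twoNU`
#' is solved so that the expected MSDB large-effect variance
#' (`2NU` times the per-unit-input sojourn variance integrated over the
#' effect distribution) equals `p_large * VA0`.
#'
#' @param VA0 Total genetic variance at MSDB (\eqn{\delta^2} units).
#' @param p_large Proportion from large-effect alleles in `[0, 1]`.
#' @param effect_dist An [effect_dist].
#' @param scale A [trait_scale()].
#' @return List with `sigma2` and `twoNU`; `twoNU` is `NA` (infeasible) when
#'   the effect distribution contributes no variance but `p_large > 0`.
#' @export
va0_p_to_params <- function(VA0, p_large, effect_dist, scale) {
  stopifnot(inherits(scale, "trait_scale"))
  if (p_large < 0 || p_large > 1) stop("`p_large` must lie in [0,1]",
                                       call. = FALSE)
  sigma2 <- (1 - p_large) * VA0
  if (p_large == 0) return(list(sigma2 = sigma2, twoNU = 0))
  nodes <- effect_dist_nodes(effect_dist)
  v1 <- sum(nodes$w * vapply(nodes$Se, sojourn_variance_per_input,
                             numeric(1), scale = scale))
  if (v1 <= 0) return(list(sigma2 = sigma2, twoNU = NA_real_))
  list(sigma2 = sigma2, twoNU = p_large * VA0 / v1)
}

#' Monte-Carlo scan over a two-parameter grid
#'
#' Fills a grid over two of `twoNU`, `Lambda`, `sigma2` — or over
#' `(VA0, p_large)`, converted cell-wise by [va0_p_to_params()] — with the
#' Monte-Carlo probability that at least one large-effect allele fixes
#' (`statistic = "p_fix"`) or the mean contribution fraction
#' (`statistic = "contribution"`), using `n_reps` hybrid-engine replicates
#' per cell with seeds derived from `base_seed`. Deterministic given
#' `base_seed`.
#'
#' @param axes Named list of exactly two numeric vectors; names from
#'   `twoNU`, `Lambda`, `sigma2`, `VA0`, `p_large`.
#' @param scenario Template [scenario()] supplying the parameters not on the
#'   axes.
#' @param n_reps Replicates per cell.
#' @param base_seed Master seed.
#' @param statistic `"p_fix"` or `"contribution"`.
#' @param ... Passed to [run_hybrid()].
#' @return An object of class `"param_grid"`: list with `cells` (long data
#'   frame `axis1`, `axis2`, `value`, `se`, `n_reps`, `valid`), `values` (a
#'   matrix, axis1 in rows), axis definitions, and the statistic.
#' @seealso [smooth_grid()]
#' @export
grid_scan <- function(axes, scenario, n_reps = 100, base_seed = 1,
                      statistic = c("p_fix", "contribution"), ...) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(scenario, "scenario"))
  if (length(axes) != 2 || is.null(names(axes)))
    stop("`axes` must be a named list of two numeric vectors", call. = FALSE)
  nm <- names(axes)
  allowed <- c("twoNU", "Lambda", "sigma2", "VA0", "p_large")
  if (!all(nm %in% allowed))
    stop("axis names must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  va_mode <- all(c("VA0", "p_large") %in% nm)
  if (any(nm %in% c("VA0", "p_large")) && !va_mode)
    stop("`VA0` and `p_large` must be used together", call. = FALSE)
  n1 <- length(axes[[1]]); n2 <- length(axes[[2]])
  vals <- matrix(NA_real_, n1, n2)
  ses <- matrix(NA_real_, n1, n2)
  valid <- matrix(TRUE, n1, n2)
  cell <- 0L
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    cell <- cell + 1L
    sc <- scenario
    if (va_mode) {
      par <- list(); par[[nm[1]]] <- axes[[1]][i]; par[[nm[2]]] <- axes[[2]][j]
      conv <- va0_p_to_params(par$VA0, par$p_large, scenario$effect_dist,
                              scenario$scale)
      if (is.na(conv$twoNU)) { valid[i, j] <- FALSE; next }
      sc$sigma2 <- conv$sigma2
      sc$twoNU <- conv$twoNU
    } else {
      sc[[nm[1]]] <- axes[[1]][i]
      sc[[nm[2]]] <- axes[[2]][j]
    }
    rs <- run_replicates(sc, n_reps,
                         base_seed = derive_seed(base_seed, cell), ...)
    row <- if (statistic == "p_fix") "p_any_fixation" else
      "contribution_fraction"
    vals[i, j] <- rs$summary[row, "mean"]
    ses[i, j] <- rs$summary[row, "se"]
  }
  cells <- data.frame(
    axis1 = rep(axes[[1]], times = n2), axis2 = rep(axes[[2]], each = n1),
    value = as.vector(vals), se = as.vector(ses), n_reps = n_reps,
    valid = as.vector(valid))
  names(cells)[1:2] <- nm
  structure(list(cells = cells, values = vals, se = ses, axes = axes,
                 statistic = statistic, base_seed = base_seed),
            class = "param_grid")
}

#' Gaussian smoothing of a scanned grid
#'
#' Separable Gaussian convolution with reflecting (mirror) boundaries, as
#' used to draw contour maps from noisy Monte-Carlo grids. The kernel is
#' normalized, so a constant grid is unchanged and total mass is preserved;
#' `bandwidth = 0` returns the input exactly.
#'
#' @param grid A `"param_grid"` from [grid_scan()], or a plain numeric
#'   matrix.
#' @param bandwidth Kernel standard deviation in grid cells (>= 0).
#' @return Same type as the input; a `"param_grid"` gains a `smoothed`
#'   matrix and a `smoothed` column in `$cells`.
#' @export
smooth_grid <- function(grid, bandwidth) {
  if (bandwidth < 0) stop("`bandwidth` must be >= 0", call. = FALSE)
  mat <- if (inherits(grid, "param_grid")) grid$values else grid
  sm <- gaussian_smooth_matrix(mat, bandwidth)
  if (!inherits(grid, "param_grid")) return(sm)
  grid$smoothed <- sm
  grid$cells$smoothed <- as.vector(sm)
  grid$bandwidth <- bandwidth
  grid
}

gaussian_smooth_matrix <- function(mat, bandwidth) {
  if (bandwidth == 0) return(mat)
  r <- max(1L, ceiling(3 * bandwidth))
  k <- stats::dnorm(seq(-r, r), sd = bandwidth)
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    if (n == 1) return(v)
    # mirror padding (edge value repeated): conserves total mass for a
    # symmetric normalized kernel
    idx <- c(pmin(r:1, n), 1:n, pmax(n - (1:r) + 1, 1))
    vp <- v[idx]
    stats::convolve(vp, rev(k), type = "filter")
  }
  out <- apply(mat, 2, smooth1)
  out <- t(apply(out, 1, smooth1))
  out
}
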