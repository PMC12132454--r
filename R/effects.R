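#' Mutational distributions of large-effect alleles
#'
#' Distributions over the squared effect \eqn{S_e = a^2} of newly arising
#' alleles. Effect orientation (aligned with or opposing the eventual shift)
#' is not part of the distribution: every mutation is assigned orientation
#' +1 or -1 with probability 1/2 each, independent of magnitude, reflecting a
#' trait that is symmetric around its optimum.
#'
#' Two families are provided:
#' \describe{
#'   \item{`effect_dist_point(Se)`}{all mutations share one squared effect;
#'     used for single-effect experiments.}
#'   \item{`effect_dist_exponential(mean_Se, Se_min, Se_max)`}{density
#'     proportional to \eqn{\exp(-S_e/\mathrm{mean\_Se})} truncated to
#'     `[Se_min, Se_max]`.}
#' }
#' Both are objects of class `"effect_dist"` exposing a density `$density(Se)`
#' (normalized over the support, checked by quadrature to 1e-6), a sampler
#' `$sample(n)` using the current RNG stream, and `$support`. Any list with
#' those fields can be substituted by users.
#'
#' @param Se,mean_Se Squared effects in internal units (\eqn{S_e = a^2}).
#' @param Se_min,Se_max Support bounds of the truncated family. `Se_min` must
#'   not be below `large_cutoff` unless the distribution is explicitly meant
#'   for a fully polygenic run (set `large_cutoff = 0`).
#' @param large_cutoff Smallest squared effect admitted as "large"
#'   (default 20, safely above the \eqn{S_e \approx 5} nearly neutral band).
#' @return An object of class `"effect_dist"`.
#' @examples
#' d <- effect_dist_exponential(mean_Se = 100, Se_min = 20, Se_max = 1000)
#' integrate(d$density, 20, 1000)$value  # 1
#' @name effect_dist
NULL

new_effect_dist <- function(family, params, support, density, sample_fn,
                            is_point = FALSE) {
  structure(list(family = family, params = params, support = support,
                 density = density, sample = sample_fn, is_point = is_point),
            class = "effect_dist")
}

#' @rdname effect_dist
#' @export
effect_dist_point <- function(Se, large_cutoff = 20) {
  if (length(Se) != 1L || !is.finite(Se) || Se <= 0)
    stop("`Se` must be a single positive number", call. = FALSE)
  if (Se < large_cutoff)
    stop("point-mass `Se` below the large-effect cutoff (", large_cutoff,
         "); lower `large_cutoff` explicitly for small-effect experiments",
         call. = FALSE)
  new_effect_dist(
    family = "point", params = list(Se = Se), support = c(Se, Se),
    density = function(x) ifelse(x == Se, Inf, 0),
    sample_fn = function(n) rep(Se, n),
    is_point = TRUE)
}

#' @rdname effect_dist
#' @export
effect_dist_exponential <- function(mean_Se, Se_min = 20, Se_max = 2000,
                                    large_cutoff = 20) {
  if (!is.finite(mean_Se) || mean_Se <= 0)
    stop("`mean_Se` must be positive", call. = FALSE)
  if (!is.finite(Se_min) || !is.finite(Se_max) || Se_min < 0 ||
      Se_max <= Se_min)
    stop("need 0 <= Se_min < Se_max", call. = FALSE)
  if (Se_min < large_cutoff)
    stop("`Se_min` below the large-effect cutoff (", large_cutoff,
         "); lower `large_cutoff` explicitly for small-effect experiments",
         call. = FALSE)
  rate <- 1 / mean_Se
  # normalizing constant of the truncated exponential
  z <- exp(-rate * Se_min) - exp(-rate * Se_max)
  dens <- function(x) ifelse(x >= Se_min & x <= Se_max,
                             rate * exp(-rate * x) / z, 0)
  qf <- function(u) -log(exp(-rate * Se_min) - u * z) / rate
  d <- new_effect_dist(
    family = "exponential",
    params = list(mean_Se = mean_Se, Se_min = Se_min, Se_max = Se_max),
    support = c(Se_min, Se_max),
    density = dens,
    sample_fn = function(n) qf(stats::runif(n)))
  chk <- stats::integrate(d$density, Se_min, Se_max, rel.tol = 1e-9)
  if (abs(chk$value - 1) > 1e-6)
    stop("effect distribution density does not integrate to 1 (got ",
         format(chk$value), ")", call. = FALSE)
  d
}

#' @export
print.effect_dist <- function(x, ...) {
  cat("Effect-size distribution (", x$family, ") over Se in [",
      format(x$support[1]), ", ", format(x$support[2]), "]\n", sep = "")
  invisible(x)
}

# Quadrature nodes/weights over the support of an effect distribution.
# Point masses get a single node; continuous families a log-spaced grid.
effect_dist_nodes <- function(effect_dist, n = 33) {
  if (isTRUE(effect_dist$is_point))
    return(list(Se = effect_dist$support[1], w = 1))
  lo <- effect_dist$support[1]; hi <- effect_dist$support[2]
  grid <- exp(seq(log(lo), log(hi), length.out = n))
  mid <- c(lo, (grid[-1] + grid[-n]) / 2, hi)
  w <- effect_dist$density(grid) * diff(mid)
  w <- w / sum(w)  # renormalize the discretization
  list(Se = grid, w = w)
}
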