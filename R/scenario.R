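#' Shift scenario: ecology and genetics of the trait
#'
#' Bundles the parameters of a sudden-optimum-shift experiment, all in
#' internal \eqn{\delta} units (see [trait_scale()]): the shift size `Lambda`,
#' the variance `sigma2` of the infinitesimal ("Fisherian") genetic
#' background, the population-scaled mutational input `twoNU` of large-effect
#' alleles (expected number of new large-effect mutations per generation), and
#' the mutational distribution of their squared effects.
#'
#' A warning (not an error) is issued when `Lambda` exceeds \eqn{\sqrt{V_S}}:
#' beyond that the Gaussian form of the fitness function can no longer be
#' trusted as a local approximation, so results are extrapolations.
#'
#' @param N Diploid population size. Internally `VS = 2N` and `delta = 1`.
#' @param Lambda Shift in the optimum, in \eqn{\delta} units (>= 0).
#' @param sigma2 Background genetic variance, in \eqn{\delta^2} units (>= 0).
#' @param twoNU Population-scaled mutation rate to large-effect alleles per
#'   generation (>= 0).
#' @param effect_dist An [effect_dist] object (defaults to a point mass at
#'   `Se = 100`).
#' @param large_cutoff Smallest squared effect treated as "large" (default 20).
#' @return An object of class `"scenario"` with fields `N`, `VS`, `Lambda`,
#'   `sigma2`, `twoNU`, `effect_dist`, `large_cutoff` and `scale`.
#' @examples
#' sc <- scenario(N = 1000, Lambda = 30, sigma2 = 40, twoNU = 0.1,
#'                effect_dist = effect_dist_point(200))
#' @export
scenario <- function(N, Lambda, sigma2, twoNU,
                     effect_dist = effect_dist_point(100),
                     large_cutoff = 20) {
  scale <- trait_scale(N)  # internal units: VS = 2N, delta = 1
  if (length(Lambda) != 1L || !is.finite(Lambda) || Lambda < 0)
    stop("`Lambda` must be a single number >= 0", call. = FALSE)
  if (length(sigma2) != 1L || !is.finite(sigma2) || sigma2 < 0)
    stop("`sigma2` must be a single number >= 0", call. = FALSE)
  if (length(twoNU) != 1L || !is.finite(twoNU) || twoNU < 0)
    stop("`twoNU` must be a single number >= 0", call. = FALSE)
  if (!inherits(effect_dist, "effect_dist") &&
      !all(c("density", "sample", "support") %in% names(effect_dist)))
    stop("`effect_dist` must be an effect_dist object", call. = FALSE)
  VS <- 2 * N
  if (Lambda > sqrt(VS))
    warning("Lambda exceeds sqrt(VS): the shift is larger than the width of ",
            "the fitness function; results are extrapolations",
            call. = FALSE)
  structure(list(N = as.integer(N), VS = VS, Lambda = Lambda,
                 sigma2 = sigma2, twoNU = twoNU, effect_dist = effect_dist,
                 large_cutoff = large_cutoff, scale = scale),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Optimum-shift scenario (internal delta units):\n",
      "  N = ", x$N, "  (VS = 2N = ", x$VS, ")\n",
      "  Lambda = ", format(x$Lambda),
      "   sigma2 = ", format(x$sigma2),
      "   2NU = ", format(x$twoNU), "\n", sep = "")
  print(x$effect_dist)
  invisible(x)
}
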