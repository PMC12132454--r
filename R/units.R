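#' Trait unit system
#'
#' The natural unit for a trait under Gaussian stabilizing selection of squared
#' width `VS` in a diploid population of size `N` is
#' \eqn{\delta = \sqrt{V_S / 2N}}, the magnitude of fluctuations of the mean
#' phenotype at mutation-selection-drift balance (MSDB). Measuring allele
#' effects `a` in units of \eqn{\delta} makes the population-scaled selection
#' coefficient of an allele at MSDB equal to \eqn{S_e = a^2}
#' (equivalently \eqn{S_e = 2N a^2 / V_S} in raw units).
#'
#' All other functions in the package work in internal \eqn{\delta} units, in
#' which `delta = 1` and `VS = 2N`; `trait_scale` records the mapping between
#' raw trait units and internal units.
#'
#' @param N Diploid population size (integer >= 2).
#' @param VS Squared width of the Gaussian fitness function, in raw
#'   trait-units squared. Defaults to `2 * N`, i.e. raw units already are
#'   internal \eqn{\delta} units.
#' @return An object of class `"trait_scale"` with fields `N`, `VS` and
#'   `delta`, satisfying `delta^2 * 2 * N == VS` by construction.
#' @examples
#' sc <- trait_scale(N = 5000, VS = 1)
#' sc$delta           # 0.01
#' to_internal(0.1, sc)  # 10 delta units
#' @export
trait_scale <- function(N, VS = 2 * N) {
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N))
    stop("`N` must be a single integer >= 2", call. = FALSE)
  if (length(VS) != 1L || !is.finite(VS) || VS <= 0)
    stop("`VS` must be a single positive number", call. = FALSE)
  structure(list(N = as.integer(N), VS = VS, delta = sqrt(VS / (2 * N))),
            class = "trait_scale")
}

#' @export
print.trait_scale <- function(x, ...) {
  cat("Trait scale: N =", x$N, ", VS =", format(x$VS),
      ", delta =", format(x$delta), "\n")
  invisible(x)
}

#' Convert between raw trait units and internal delta units
#'
#' Internal units measure trait values and allele effects in units of
#' \eqn{\delta = \sqrt{V_S/2N}} (`power = 1`) and variances in \eqn{\delta^2}
#' (`power = 2`). The two functions are exact inverses.
#'
#' @param value Numeric vector in raw units (`to_internal`) or internal units
#'   (`from_internal`).
#' @param scale A [trait_scale()].
#' @param power Exponent of the trait dimension: 1 for trait values and allele
#'   effects, 2 for variances.
#' @return Numeric vector of the same length as `value`.
#' @examples
#' sc <- trait_scale(N = 5000, VS = 1)
#' to_internal(sc$VS, sc, power = 2)   # 2N = 10000
#' from_internal(to_internal(0.37, sc), sc)  # 0.37
#' @export
to_internal <- function(value, scale, power = 1) {
  stopifnot(inherits(scale, "trait_scale"))
  if (!(length(power) == 1L && power %in% c(1, 2)))
    stop("`power` must be 1 (trait values/effects) or 2 (variances)",
         call. = FALSE)
  if (any(!is.finite(value)))
    stop("non-finite `value`: invalid parameterization", call. = FALSE)
  value / scale$delta^power
}

#' @rdname to_internal
#' @export
from_internal <- function(value, scale, power = 1) {
  stopifnot(inherits(scale, "trait_scale"))
  if (!(length(power) == 1L && power %in% c(1, 2)))
    stop("`power` must be 1 (trait values/effects) or 2 (variances)",
         call. = FALSE)
  if (any(!is.finite(value)))
    stop("non-finite `value`: invalid parameterization", call. = FALSE)
  value * scale$delta^power
}

#' Allele effect sizes and population-scaled selection coefficients
#'
#' In internal \eqn{\delta} units the population-scaled selection coefficient
#' of an allele at MSDB is \eqn{S_e = a^2}. `se_from_effect` and
#' `effect_from_se` convert between the two parameterizations. The boundary
#' between (nearly) neutral and strongly selected stabilizing-selection
#' dynamics sits at \eqn{S_e \approx 5}; "large effect" in this package means
#' \eqn{S_e} well above that, bounded below by the configurable cutoff
#' `Se_min` of the mutational distribution (default 20).
#'
#' @param a Allele effect on the trait, in \eqn{\delta} units (> 0).
#' @param Se Population-scaled selection coefficient (> 0).
#' @return Numeric vector.
#' @examples
#' se_from_effect(sqrt(200))  # 200
#' effect_from_se(200)        # 14.142...
#' @export
se_from_effect <- function(a) {
  if (any(!is.finite(a) | a < 0)) stop("`a` must be finite and >= 0",
                                       call. = FALSE)
  a^2
}

#' @rdname se_from_effect
#' @export
effect_from_se <- function(Se) {
  if (any(!is.finite(Se) | Se < 0)) stop("`Se` must be finite and >= 0",
                                         call. = FALSE)
  sqrt(Se)
}
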