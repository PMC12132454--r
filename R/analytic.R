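#' Lande's approximation for the mean distance from the optimum
#'
#' For a highly polygenic trait the distance of the mean phenotype from the
#' new optimum decays as \eqn{dD/dt = -(V_A/V_S) D}, i.e.
#' \eqn{D(t) = \Lambda e^{-V_A t / V_S}}.
#'
#' @param t Generations since the shift (>= 0, vectorized).
#' @param Lambda Shift size (\eqn{\delta} units).
#' @param VA Genetic variance in the trait (\eqn{\delta^2} units, >= 0).
#' @param scale A [trait_scale()] (supplies `VS = 2N` in internal units).
#' @return Distance in \eqn{\delta} units.
#' @examples
#' lande_distance(25, 80, 400, trait_scale(5000))  # 80 * exp(-1)
#' @export
lande_distance <- function(t, Lambda, VA, scale) {
  stopifnot(inherits(scale, "trait_scale"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (any(VA < 0)) stop("`VA` must be >= 0", call. = FALSE)
  Lambda * exp(-VA * t / (2 * scale$N))
}

#' Distance at which selection on a rare allele reverses sign
#'
#' For a rare allele of effect `a` the expected frequency change is positive
#' exactly while the distance from the optimum exceeds `a/2`; once `D` drops
#' below `a/2` stabilizing selection outweighs directional selection and the
#' allele is selected against.
#'
#' @param a Allele effect (\eqn{\delta} units, > 0).
#' @return `a / 2`.
#' @export
sign_reversal_distance <- function(a) {
  if (any(!is.finite(a) | a < 0)) stop("`a` must be >= 0", call. = FALSE)
  a / 2
}

#' Instantaneous mean-fitness reduction after a shift
#'
#' Under the Gaussian fitness function of squared width `VS`, a population
#' with mean at distance `Lambda` from the optimum and phenotypic variance
#' `VA` has mean fitness \eqn{\sqrt{V_S/(V_S+V_A)}\,
#' e^{-\Lambda^2/2(V_S+V_A)}} relative to a population centered at the
#' optimum with the same variance. The returned reduction is one minus that
#' ratio; with `VA = 0` it reduces to \eqn{1 - e^{-\Lambda^2/2V_S}}.
#'
#' @param Lambda Shift size (\eqn{\delta} units, >= 0).
#' @param scale A [trait_scale()].
#' @param VA Phenotypic variance (\eqn{\delta^2} units, default 0).
#' @return A fraction in `[0, 1)`.
#' @examples
#' sc <- trait_scale(5000)
#' mean_fitness_reduction(0.8 * sqrt(2 * 5000), sc)  # ~0.274
#' @export
mean_fitness_reduction <- function(Lambda, scale, VA = 0) {
  stopifnot(inherits(scale, "trait_scale"))
  if (any(Lambda < 0)) stop("`Lambda` must be >= 0", call. = FALSE)
  if (any(VA < 0)) stop("`VA` must be >= 0", call. = FALSE)
  VS <- 2 * scale$N
  1 - exp(-Lambda^2 / (2 * (VS + VA)))
}

#' Duration of the new-mutation window
#'
#' Time until the background-only Lande trajectory decays to the MSDB
#' fluctuation scale \eqn{\delta}: the solution of
#' \eqn{\Lambda e^{-\sigma^2 t / V_S} = \delta}, i.e.
#' \eqn{T_{end} = (V_S/\sigma^2) \ln(\Lambda/\delta)}. New mutations arising
#' after `T_end` see essentially no directional selection; the window closes
#' the new-allele fixation integral and the hybrid engine's stopping rule.
#' A window of length 0 is returned when `Lambda <= delta`.
#'
#' @param Lambda Shift size (\eqn{\delta} units).
#' @param sigma2 Background variance (\eqn{\delta^2} units, > 0 for a finite
#'   window).
#' @param scale A [trait_scale()].
#' @param delta Distance defining window closure (default 1, the MSDB
#'   fluctuation scale in internal units); override to use a different
#'   window definition.
#' @return Window length in generations (`Inf` when `sigma2 = 0` and
#'   `Lambda > delta`).
#' @examples
#' adaptation_window(100, 40, trait_scale(5000))  # 250 * log(100)
#' @export
adaptation_window <- function(Lambda, sigma2, scale, delta = 1) {
  stopifnot(inherits(scale, "trait_scale"))
  if (Lambda <= delta) return(0)
  if (sigma2 == 0) return(Inf)
  (2 * scale$N / sigma2) * log(Lambda / delta)
}

# replace the shift size of a scenario without re-triggering validation
set_lambda <- function(scenario, Lambda) {
  scenario$Lambda <- Lambda
  scenario
}

# Backward-in-time survival profile of a single copy under the
# time-inhomogeneous branching approximation.
#
# A rare aligned allele of effect a sees per-copy selective advantage
# s(t) = (a/VS) (D_bg(t) - a/2) with D_bg(t) = Lambda e^{-sigma2 t/VS}.
# With Poisson(w_t) offspring per copy, w_t = 1 + s(t) (the branching limit
# of binomial Wright-Fisher resampling of a rare allele), the probability
# that a copy present at generation t still has surviving descendants when
# the favorable window closes solves the survival recursion
#   p(t) = 1 - exp(-w_t p(t+1)),
# integrated backward from p(T*) = 1 at the time T* where s crosses 0
# (beyond it a low-copy lineage cannot establish). In the constant-s limit
# the recursion relaxes to its interior fixed point, the classic eventual
# branching survival probability (~2s for small s). Returns p1(t) on
# t = 0, ..., T*.
establishment_profile <- function(a, scenario) {
  VS <- 2 * scenario$N
  Lam <- scenario$Lambda
  s2 <- scenario$sigma2
  if (Lam <= a / 2) return(numeric(0))
  if (s2 > 0) {
    tstar <- floor((VS / s2) * log(Lam / (a / 2)))
  } else {
    s0 <- (a / VS) * (Lam - a / 2)
    tstar <- min(ceiling(400 / max(s0, 1e-5)), 5e5)
  }
  p <- 1
  p1 <- numeric(tstar + 1L)
  for (t in tstar:0) {
    s <- (a / VS) * (Lam * exp(-s2 * t / VS) - a / 2)
    p <- 1 - exp(-(1 + max(s, 0)) * p)
    p1[t + 1L] <- p
  }
  p1
}

#' Establishment probability of a large-effect allele after the shift
#'
#' Probability that an allele with aligned effect `a`, present at frequency
#' `x0` at time `t0` after the shift, escapes stochastic loss. Computed from
#' a time-inhomogeneous branching approximation for the `2N x0` initial
#' copies, each with per-copy selective advantage
#' \eqn{s(t) = (a/V_S)(D_{bg}(t) - a/2)} along the background-only Lande
#' trajectory \eqn{D_{bg}(t) = \Lambda e^{-\sigma^2 t/V_S}}:
#' \eqn{P = 1 - (1 - p_1)^{2N x_0}} (independent copies), where the
#' per-copy survival probability `p1` solves the time-varying branching
#' survival recursion by backward numerical integration. Returns 0 when the
#' allele is never favored (\eqn{\Lambda \le a/2}).
#'
#' @param a Aligned allele effect (\eqn{\delta} units, > 0).
#' @param x0 Initial frequency in (0, 1).
#' @param scenario A [scenario()].
#' @param t0 Generation (after the shift) at which the `2N x0` copies are
#'   present; 0 for standing alleles.
#' @return A probability in `[0, 1]`.
#' @examples
#' sc <- scenario(N = 5000, Lambda = 100, sigma2 = 40, twoNU = 0,
#'                effect_dist = effect_dist_point(200))
#' establishment_probability(sqrt(200), 1/400, sc)
#' @export
establishment_probability <- function(a, x0, scenario, t0 = 0) {
  stopifnot(inherits(scenario, "scenario"))
  if (any(x0 <= 0 | x0 >= 1)) stop("`x0` must lie in (0,1)", call. = FALSE)
  p1 <- establishment_profile(a, scenario)
  if (length(p1) == 0) return(0 * x0)
  t0 <- round(t0)
  p1t <- ifelse(t0 + 1L <= length(p1), p1[pmin(t0 + 1L, length(p1))], 0)
  1 - exp(2 * scenario$N * x0 * log1p(-p1t))
}

#' Deterministic reach-one-half indicator
#'
#' Joint deterministic integration of the allele frequency (expected
#' single-generation change, aligned) and the distance from the optimum
#' (background Lande decay plus the allele's own contribution,
#' \eqn{D_{t+1} = D_t e^{-\sigma^2/V_S} - 2a\,\Delta x_t}) starting from
#' `(x_start, D0)`. Returns whether the frequency reaches 1/2 while the
#' expected change is still positive — past that point stabilizing selection
#' favors the allele and fixation is nearly assured — and the first-crossing
#' time. A pure function of its inputs.
#'
#' @param a Aligned allele effect (> 0).
#' @param x_start Starting frequency in (0, 1).
#' @param scenario A [scenario()].
#' @param D0 Starting distance (defaults to the scenario's `Lambda`).
#' @param max_gen Iteration guard.
#' @return A list with `reaches` (logical) and `time` (first-crossing
#'   generation, `NA` if never).
#' @export
reaches_half <- function(a, x_start, scenario, D0 = scenario$Lambda,
                         max_gen = 5e5) {
  stopifnot(inherits(scenario, "scenario"))
  if (x_start <= 0 || x_start >= 1) stop("`x_start` must lie in (0,1)",
                                         call. = FALSE)
  VS <- 2 * scenario$N
  decay <- exp(-scenario$sigma2 / VS)
  x <- x_start
  D <- D0
  t <- 0L
  repeat {
    if (x >= 0.5) return(list(reaches = TRUE, time = t))
    dx <- (a * D / VS - (a^2 / VS) * (0.5 - x)) * x * (1 - x)
    if (dx <= 0) return(list(reaches = FALSE, time = NA_integer_))
    D <- D * decay - 2 * a * dx
    x <- x + dx
    t <- t + 1L
    if (t > max_gen) return(list(reaches = FALSE, time = NA_integer_))
  }
}

# Establishment frequency seeding the deterministic reach-1/2 integration:
# the standard drift-selection boundary c/(2N s), bounded below by the
# actual starting frequency. When that boundary exceeds 1/4 (2N s0 < 4 c)
# selection is too weak relative to drift for a quasi-deterministic ascent
# to exist at all, and NA is returned (no establishment in the
# deterministic sense).
establishment_frequency <- function(a, x0, scenario, t0 = 0, c_est = 1) {
  VS <- 2 * scenario$N
  s0 <- (a / VS) * (scenario$Lambda * exp(-scenario$sigma2 * t0 / VS) - a / 2)
  if (s0 <= 0) return(NA_real_)
  xdrift <- c_est / (2 * scenario$N * s0)
  if (xdrift > 0.25) return(NA_real_)
  min(max(x0, xdrift), 0.5)
}

# Critical starting distance for a deterministic reach-1/2 crossing.
#
# reaches_half(a, x_start, sc, D0) is monotone in D0; this returns the
# smallest D0 from which a trajectory started at x_start still crosses 1/2
# (Inf if it cannot even from far away, reflecting that the allele's own
# pull on the mean closes the window too fast).
critical_D0 <- function(a, x_start, scenario, rel_tol = 0.02) {
  hi <- 4 * sqrt(2 * scenario$N)
  if (!reaches_half(a, x_start, scenario, D0 = hi)$reaches) return(Inf)
  lo <- a / 2 * 1e-3
  if (reaches_half(a, x_start, scenario, D0 = lo)$reaches) return(lo)
  while (hi / lo > 1 + rel_tol) {
    mid <- sqrt(lo * hi)
    if (reaches_half(a, x_start, scenario, D0 = mid)$reaches) hi <- mid
    else lo <- mid
  }
  hi
}

# Interpolator of log critical_D0 over start frequencies in [x_lo, 0.5).
critical_D0_interp <- function(a, scenario, x_lo, n_knots = 8) {
  xk <- exp(seq(log(x_lo), log(0.499), length.out = n_knots))
  dk <- vapply(xk, function(x) critical_D0(a, x, scenario), numeric(1))
  function(x) {
    x <- pmin(pmax(x, xk[1]), xk[n_knots])
    if (all(is.infinite(dk))) return(rep(Inf, length(x)))
    fin <- is.finite(dk)
    if (!all(fin)) {
      # Inf knots (if any) sit at the low-frequency end; treat them as a
      # very large finite value for interpolation
      dk[!fin] <- max(dk[fin]) * 1e3
    }
    exp(stats::approx(log(xk), log(dk), xout = log(x), rule = 2)$y)
  }
}

# Probability that an establishing lineage crosses 1/2 before selection
# reverses, averaged over the random establishment delay.
#
# Conditional on establishment, the lineage size behaves as W (1+s0)^t,
# where W is the limiting size factor of the branching process: each of the
# k0 initial copies contributes 0 with probability 1-p1 or an
# exponentially distributed factor with mean 1/p1, so conditional on at
# least one survivor W is approximately Gamma with shape
# kappa = k0 p1 / (1 - (1-p1)^k0) (the mean number of surviving copies)
# and scale 1/p1. The crossing succeeds iff the lineage reaches the
# drift-selection boundary n_c = 2N x_e early enough that the remaining
# distance still exceeds the critical value D0* for a deterministic
# crossing from x_e, i.e. within T_allow = (VS/sigma2) log(D_start/D0*)
# generations, which requires W > n_c e^{-lambda T_allow},
# lambda = log(1+s0). With sigma2 = 0 timing is irrelevant and the
# deterministic indicator is returned.
reach_probability <- function(k0, xe, p1, s0, D_start, D0star, scenario) {
  if (!is.finite(D0star)) return(0)
  lam <- log1p(s0)
  nc <- 2 * scenario$N * xe
  if (scenario$sigma2 == 0)
    return(as.numeric(D_start > D0star || k0 >= nc))
  T_allow <- (2 * scenario$N / scenario$sigma2) * log(D_start / D0star)
  wstar <- nc * exp(-pmax(pmin(lam * T_allow, 700), -700))
  psurv <- -expm1(k0 * log1p(-p1))  # 1 - (1-p1)^k0
  kappa <- max(k0 * p1 / psurv, 1e-12)
  stats::pgamma(wstar, shape = kappa, scale = 1 / p1, lower.tail = FALSE)
}

#' Fixation probability of a large-effect allele
#'
#' The composite approximation: the probability that the allele establishes
#' ([establishment_probability()]) multiplied by the probability that, once
#' established, it reaches frequency 1/2 before selection on it reverses;
#' fixation after crossing 1/2 is treated as certain. The crossing
#' probability combines the deterministic joint integration of
#' [reaches_half()] (through the critical starting distance from which a
#' crossing is still possible) with the random establishment delay of the
#' surviving lineage, whose exponentially distributed size factor smears
#' the deterministic threshold over shift sizes.
#'
#' For a standing allele the product is averaged over the MSDB frequency
#' distribution ([sojourn_density()]); for a new mutation it is averaged
#' over a uniformly distributed arrival time within the window
#' `[0, T_end]` ([adaptation_window()]), the allele starting from a single
#' copy. The establishment frequency seeding the deterministic integration
#' is `max(x0, c_est/(2N s0))`.
#'
#' @param a Aligned allele effect (\eqn{\delta} units, > 0).
#' @param origin `"standing"` or `"new"`.
#' @param scenario A [scenario()].
#' @param c_est Constant of the establishment frequency (default 1).
#' @param n_x0 Number of initial-frequency quadrature points (standing).
#' @param n_t0 Number of arrival-time quadrature points (new).
#' @return A probability in `[0, 1]`; 0 whenever `Lambda <= a/2`. For
#'   `origin = "new"` this is the per-arrival probability (arrival time
#'   uniform over the window).
#' @examples
#' sc <- scenario(N = 1000, Lambda = 30, sigma2 = 40, twoNU = 0,
#'                effect_dist = effect_dist_point(200))
#' fixation_probability(sqrt(200), "standing", sc)
#' @export
fixation_probability <- function(a, origin = c("standing", "new"), scenario,
                                 c_est = 1, n_x0 = 150, n_t0 = 80) {
  origin <- match.arg(origin)
  stopifnot(inherits(scenario, "scenario"))
  if (scenario$Lambda <= a / 2) return(0)
  N <- scenario$N
  VS <- 2 * N
  p1 <- establishment_profile(a, scenario)
  if (origin == "standing") {
    s0 <- (a / VS) * (scenario$Lambda - a / 2)
    xdrift <- c_est / (2 * N * s0)
    if (xdrift > 0.25) return(0)  # drift dominates: no deterministic ascent
    g <- sojourn_grid(a^2, N)
    # average over the segregating-state frequency range, decimated into
    # ~n_x0 probability-weighted bins
    xg <- g$x_seg
    m <- length(xg)
    w_full <- diff(c(0, g$cdf_seg))
    take <- unique(round(seq(1, m, length.out = min(n_x0, m))))
    bins <- findInterval(seq_len(m), take)
    w <- tapply(w_full, bins, sum)
    x0s <- xg[take]
    pest <- 1 - exp(2 * N * x0s * log1p(-p1[1]))
    dstar <- critical_D0_interp(a, scenario, x_lo = xdrift)
    reach <- vapply(x0s, function(x0) {
      xe <- min(max(x0, xdrift), 0.5)
      reach_probability(2 * N * x0, xe, p1[1], s0, scenario$Lambda,
                        dstar(xe), scenario)
    }, numeric(1))
    return(sum(w * pest * reach))
  }
  t_end <- adaptation_window(scenario$Lambda, scenario$sigma2, scenario$scale)
  if (t_end == 0) return(0)
  if (!is.finite(t_end))
    stop("new-allele fixation probability needs sigma2 > 0 (finite window)",
         call. = FALSE)
  s00 <- (a / VS) * (scenario$Lambda - a / 2)
  dstar <- critical_D0_interp(a, scenario,
                              x_lo = min(c_est / (2 * N * s00), 0.25))
  t0s <- (seq_len(n_t0) - 0.5) / n_t0 * t_end
  vals <- vapply(t0s, function(t0) {
    ti <- round(t0) + 1L
    if (ti > length(p1)) return(0)
    Dt0 <- scenario$Lambda * exp(-scenario$sigma2 * t0 / VS)
    st0 <- (a / VS) * (Dt0 - a / 2)
    if (st0 <= 0) return(0)
    xdrift <- c_est / (2 * N * st0)
    if (xdrift > 0.25) return(0)
    xe <- min(max(1 / (2 * N), xdrift), 0.5)
    p1[ti] * reach_probability(1, xe, p1[ti], st0, Dt0, dstar(xe), scenario)
  }, numeric(1))
  mean(vals)
}

#' Expected numbers of large-effect fixations (non-interference regime)
#'
#' Linear-in-`2NU` expectations, valid when the mutational input is low
#' (`2NU < 1`; a warning is issued above, where interference among
#' simultaneously ascending alleles — not modeled here — suppresses
#' fixations): standing fixations are the expected number of segregating
#' alleles times their fixation probability, integrated over the effect
#' distribution; new-allele fixations are the arrival rate times the window
#' length times the per-arrival fixation probability.
#'
#' @param scenario A [scenario()].
#' @param ... Passed to [fixation_probability()].
#' @return Named numeric vector `c(from_standing, from_new)`.
#' @export
expected_fixations <- function(scenario, ...) {
  stopifnot(inherits(scenario, "scenario"))
  if (scenario$twoNU >= 1)
    warning("2NU >= 1: interference is ignored by this approximation",
            call. = FALSE)
  if (scenario$twoNU == 0)
    return(c(from_standing = 0, from_new = 0))
  nodes <- effect_dist_nodes(scenario$effect_dist)
  t_end <- adaptation_window(scenario$Lambda, scenario$sigma2, scenario$scale)
  fs <- fn <- 0
  for (k in seq_along(nodes$Se)) {
    a <- sqrt(nodes$Se[k])
    mass <- sojourn_mass(nodes$Se[k], scenario$scale)
    fs <- fs + nodes$w[k] * mass *
      fixation_probability(a, "standing", scenario, ...)
    if (t_end > 0 && is.finite(t_end))
      fn <- fn + nodes$w[k] * fixation_probability(a, "new", scenario, ...)
  }
  c(from_standing = scenario$twoNU * fs,
    from_new = scenario$twoNU * t_end * fn)
}

#' Classify the shift-size regime of a large-effect allele
#'
#' Partitions shift sizes for a given `(a, sigma2, N)` into the four
#' qualitative regimes: `no_establishment` (`Lambda < a/2`: the allele is
#' selected against from the start), `establish_no_fix` (it can establish
#' but never reaches frequency 1/2), `standing_can_fix` (standing alleles
#' starting high enough can fix), and `most_established_fix` (the
#' standing fixation-to-establishment ratio exceeds `ratio_cutoff`). The
#' `Lambda` values where the labels change are found by bisection and
#' returned as thresholds.
#'
#' @param a Allele effect (> 0).
#' @param scenario A [scenario()] (its `Lambda` is the point classified).
#' @param origin Origin used for the fixation-based boundaries.
#' @param ratio_cutoff Fixation/establishment ratio defining
#'   `most_established_fix` (default 0.9).
#' @param eps Positivity floor: the fixation boundary is the smallest
#'   `Lambda` with fixation probability above `eps` (default 1e-3), since
#'   the smeared crossing probability decays continuously rather than
#'   hitting an exact zero.
#' @param tol Bisection tolerance on `Lambda`.
#' @return An object of class `"regime_label"`: list with `label` and
#'   `thresholds` (ordered `Lambda` boundaries: establishment, fixation,
#'   most-establishers-fix; `Inf` when a regime is never reached below
#'   `sqrt(VS)`).
#' @export
classify_regime <- function(a, scenario, origin = "standing",
                            ratio_cutoff = 0.9, eps = 1e-3, tol = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (is.null(tol)) tol <- max(a, 1) / 200
  L1 <- a / 2
  Lhi <- sqrt(2 * scenario$N)
  pfix <- function(L) fixation_probability(a, origin, set_lambda(scenario, L))
  pest_avg <- function(L) {
    sc <- set_lambda(scenario, L)
    if (L <= a / 2) return(0)
    p1 <- establishment_profile(a, sc)
    g <- sojourn_grid(a^2, scenario$N)
    w <- diff(c(0, g$cdf_seg))
    sum(w * (1 - exp(2 * scenario$N * g$x_seg * log1p(-p1[1]))))
  }
  bisect_up <- function(f) {
    # smallest Lambda in (L1, Lhi] with f(Lambda) TRUE, assuming monotone
    if (!f(Lhi)) return(Inf)
    lo <- L1; hi <- Lhi
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  L2 <- bisect_up(function(L) pfix(L) > eps)
  L3 <- if (is.finite(L2))
    bisect_up(function(L) {
      pe <- pest_avg(L)
      pe > 0 && pfix(L) / pe > ratio_cutoff
    }) else Inf
  Lam <- scenario$Lambda
  label <- if (Lam < L1) "no_establishment"
  else if (Lam < L2) "establish_no_fix"
  else if (is.finite(L3) && Lam >= L3) "most_established_fix"
  else "standing_can_fix"
  structure(list(label = label,
                 thresholds = c(establishment = L1, fixation = L2,
                                most_fix = L3),
                 a = a, sigma2 = scenario$sigma2, N = scenario$N),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat("Regime: ", x$label, "  (a = ", format(x$a), ", sigma2 = ",
      format(x$sigma2), ", N = ", x$N, ")\n  Lambda thresholds: ",
      "establishment > ", format(x$thresholds[1]),
      ", fixation > ", format(x$thresholds[2]),
      ", most establishers fix > ", format(x$thresholds[3]), "\n", sep = "")
  invisible(x)
}
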