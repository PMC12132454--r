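# Exact Wright-Fisher transition-matrix oracles at small N, used as
# independent references for the diffusion/branching approximations.

# Expected visits to each transient state (1..2N-1 copies) for a mutant
# entering as a single copy, under stabilizing selection only (D = 0).
wf_sojourn_visits <- function(N, Se) {
  twoN <- 2L * N
  xs <- (0:twoN) / twoN
  ex <- xs - (Se / twoN) * (0.5 - xs) * xs * (1 - xs)
  P <- t(vapply(1:(twoN - 1), function(i)
    stats::dbinom(0:twoN, twoN, min(max(ex[i + 1], 0), 1)),
    numeric(twoN + 1)))
  solve(diag(twoN - 1) - P[, 2:twoN])[1, ]
}

# Absorption probabilities at fixation from every transient state, with the
# distance from the optimum held fixed at D.
wf_fixation_prob <- function(N, a, D) {
  twoN <- 2L * N
  VS <- 2 * N
  xs <- (0:twoN) / twoN
  ex <- xs + (a * D / VS - (a^2 / VS) * (0.5 - xs)) * xs * (1 - xs)
  P <- t(vapply(1:(twoN - 1), function(i)
    stats::dbinom(0:twoN, twoN, min(max(ex[i + 1], 0), 1)),
    numeric(twoN + 1)))
  solve(diag(twoN - 1) - P[, 2:twoN], P[, twoN + 1])
}

# Diffusion sojourn mass integrated over the frequency cells of states
# klo..khi (midpoint cell boundaries), from the quadrature grid.
sojourn_cell_mass <- function(Se, N, klo, khi) {
  g <- optimshift:::sojourn_grid(Se, N)
  twoN <- 2 * N
  lo <- (klo - 0.5) / twoN
  hi <- (khi + 0.5) / twoN
  xx <- sort(unique(c(lo, g$x[g$x >= lo & g$x <= hi], hi)))
  tt <- exp(stats::approx(g$x, log(g$tau), xout = xx, rule = 2)$y)
  sum(diff(xx) * (tt[-1] + tt[-length(xx)]) / 2)
}

# Scenario shorthand for single-point-mass experiments.
point_scenario <- function(N, Lambda, sigma2, twoNU = 0, Se = 200) {
  suppressWarnings(scenario(N = N, Lambda = Lambda, sigma2 = sigma2,
                            twoNU = twoNU,
                            effect_dist = effect_dist_point(Se)))
}
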