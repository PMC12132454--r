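test_that("Lande decay evaluates its closed form", {
  sc <- trait_scale(5000)
  expect_equal(lande_distance(0, 80, 400, sc), 80)
  expect_equal(lande_distance(1000, 80, 0, sc), 80)
  expect_equal(lande_distance(25, 80, 400, sc), 80 * exp(-1))
  expect_error(lande_distance(-1, 80, 400, sc), ">= 0")
  expect_error(lande_distance(1, 80, -4, sc), ">= 0")
  t <- 0:50
  expect_true(all(diff(lande_distance(t, 80, 400, sc)) < 0))
})

test_that("mean fitness reduction reproduces the Gaussian-fitness values", {
  sc <- trait_scale(5000)
  VS <- 2 * 5000
  expect_equal(mean_fitness_reduction(0, sc), 0)
  expect_equal(mean_fitness_reduction(0.8 * sqrt(VS), sc),
               1 - exp(-0.32))
  expect_equal(mean_fitness_reduction(sqrt(2 * VS), sc), 1 - exp(-1))
  # variance inflates the effective width: smaller reduction of the mean term
  expect_lt(mean_fitness_reduction(50, sc, VA = 400),
            mean_fitness_reduction(50, sc))
})

test_that("the new-mutation window solves Lande decay to the delta scale", {
  sc <- trait_scale(5000)
  expect_equal(adaptation_window(1, 40, sc), 0)
  expect_equal(adaptation_window(0.5, 40, sc), 0)
  expect_equal(adaptation_window(100, 40, sc), 250 * log(100))
  expect_equal(adaptation_window(100, 80, sc),
               adaptation_window(100, 40, sc) / 2)
  expect_equal(adaptation_window(100, 0, sc), Inf)
})

test_that("establishment probability vanishes for shifts below a/2", {
  sc <- point_scenario(N = 1000, Lambda = 7, sigma2 = 40, Se = 200)
  expect_equal(establishment_probability(sqrt(200), 0.01, sc), 0)
  expect_equal(fixation_probability(sqrt(200), "standing", sc), 0)
  expect_equal(fixation_probability(sqrt(200), "new", sc), 0)
})

test_that("constant-selection establishment approaches the classic 2s limit", {
  N <- 5000
  a <- 0.2
  # s0 = (a/VS)(Lambda - a/2) = 0.005
  Lam <- 0.005 * (2 * N) / a + a / 2
  sc <- point_scenario(N = N, Lambda = Lam, sigma2 = 0, Se = 100)
  p <- establishment_probability(a, 1 / (2 * N), sc)
  expect_equal(p, 1 - exp(-2 * 0.005), tolerance = 0.05)
  expect_true(establishment_probability(a, 10 / (2 * N), sc) > p)
})

test_that("establishment matches exact Wright-Fisher absorption at N=50", {
  # constant selection held by sigma2 = 0; copies span the drift boundary
  for (pars in list(c(a = 0.3, D = 13.5), c(a = 0.6, D = 7))) {
    sc <- point_scenario(N = 50, Lambda = pars["D"], sigma2 = 0, Se = 50)
    u <- wf_fixation_prob(50, pars["a"], pars["D"])
    for (k in c(1, 5, 10, 25)) {
      pa <- establishment_probability(pars["a"], k / 100, sc)
      expect_lt(abs(pa - u[k]) / u[k], 0.05)
    }
  }
})

test_that("reaches_half honors its boundary cases", {
  sc <- point_scenario(N = 1000, Lambda = 40, sigma2 = 40, Se = 200)
  r <- reaches_half(sqrt(200), 0.5, sc)
  expect_true(r$reaches)
  expect_equal(r$time, 0)
  # just above a/2: selection reverses long before 1/2
  sc2 <- point_scenario(N = 1000, Lambda = 7.5, sigma2 = 40, Se = 200)
  expect_false(reaches_half(sqrt(200), 0.01, sc2)$reaches)
})

test_that("raising background variance only shrinks the reach-1/2 region", {
  a <- sqrt(200)
  for (L in c(20, 30, 40)) for (x0 in c(0.02, 0.1, 0.3)) {
    lo <- reaches_half(a, x0, point_scenario(1000, L, 40, Se = 200))$reaches
    hi <- reaches_half(a, x0, point_scenario(1000, L, 80, Se = 200))$reaches
    expect_true(lo || !hi)  # TRUE can flip to FALSE, never the reverse
  }
})

test_that("fixation probability is bounded by establishment and monotone in Lambda", {
  a <- sqrt(200)
  Ls <- c(10, 20, 30, 35, 40, 44)
  pf <- vapply(Ls, function(L)
    fixation_probability(a, "standing", point_scenario(1000, L, 40, Se = 200)),
    numeric(1))
  # tolerance at the quadrature floor: deep-subthreshold probabilities are
  # O(1e-6) leakage of the smeared crossing tail
  expect_true(all(diff(pf) >= -1e-5))
  expect_true(all(pf >= 0 & pf <= 1))
  # establishment averaged over standing frequencies bounds fixation
  for (i in seq_along(Ls)) {
    sc <- point_scenario(1000, Ls[i], 40, Se = 200)
    g <- optimshift:::sojourn_grid(200, 1000)
    w <- diff(c(0, g$cdf_seg))
    pe <- sum(w * establishment_probability(a, g$x_seg, sc))
    expect_lte(pf[i], pe + 1e-9)
  }
})

test_that("expected fixations are linear in the mutational input", {
  sc <- point_scenario(N = 1000, Lambda = 40, sigma2 = 40, twoNU = 0.5,
                       Se = 200)
  ef1 <- expected_fixations(sc)
  sc$twoNU <- 0.25
  ef2 <- expected_fixations(sc)
  expect_equal(unname(ef1 / ef2), c(2, 2))
  sc$twoNU <- 0
  expect_equal(unname(expected_fixations(sc)), c(0, 0))
  expect_warning(expected_fixations(point_scenario(1000, 40, 40, twoNU = 2,
                                                   Se = 200)),
                 "interference")
})

test_that("deep in the red region most fixations come from new mutations", {
  sc <- point_scenario(N = 1000, Lambda = 60, sigma2 = 40, twoNU = 0.5,
                       Se = 200)
  ef <- expected_fixations(sc)
  expect_gt(ef["from_new"], ef["from_standing"])
})

test_that("regime classification labels the canonical shift sizes", {
  a <- sqrt(200)
  r1 <- classify_regime(a, point_scenario(1000, 0.49 * a, 40, Se = 200))
  expect_equal(r1$label, "no_establishment")
  r2 <- classify_regime(a, point_scenario(1000, 0.51 * a, 80, Se = 200))
  expect_equal(r2$label, "establish_no_fix")
  expect_equal(unname(r1$thresholds["establishment"]), a / 2)
  # fixation threshold moves right as background variance grows
  expect_gt(r2$thresholds["fixation"], r1$thresholds["fixation"])
  expect_true(all(diff(unname(r1$thresholds)) >= 0))
})
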