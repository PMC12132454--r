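test_that("single-generation moments evaluate the closed forms exactly", {
  sc <- trait_scale(5000)
  m0 <- delta_x_moments(0, 0.3, 50, sc)
  expect_equal(m0$expected, 0)
  expect_equal(m0$variance, 0.3 * 0.7 / 1e4)
  m1 <- delta_x_moments(sqrt(200), 0.0025, 50, sc)
  expect_equal(m1$expected,
               0.0025 * 0.9975 * (sqrt(200) * 50 - 200 * 0.4975) / 1e4,
               tolerance = 1e-12)
  expect_error(delta_x_moments(1, 1.2, 10, sc), "0, 1")
})

test_that("selection on a rare allele reverses sign exactly at D = a/2", {
  sc <- trait_scale(5000)
  for (a in c(0.5, 3, sqrt(200))) {
    e <- delta_x_moments(a, 1e-6, a / 2, sc)$expected
    expect_equal(e / (1e-6 * (1 - 1e-6)), a^2 / (2 * 5000) * 1e-6,
                 tolerance = 1e-9)  # residual is the O(x) stabilizing term
    expect_gt(delta_x_moments(a, 1e-6, a / 2 + 0.01, sc)$expected, 0)
    expect_lt(delta_x_moments(a, 1e-6, a / 2 - 0.01, sc)$expected, 0)
    expect_equal(sign_reversal_distance(a), a / 2)
  }
})

test_that("hybrid engine with no large alleles is exactly the Lande recurrence", {
  sc <- point_scenario(N = 500, Lambda = 30, sigma2 = 60, twoNU = 0)
  set.seed(21)
  tr <- run_hybrid(sc, generations = 150)
  t <- tr$series$t
  expect_equal(tr$series$D, 30 * exp(-60 * t / 1000), tolerance = 1e-12)
  expect_true(all(tr$series$n_segregating == 0))
})

test_that("trajectories are byte-identical under the same seed", {
  sc <- point_scenario(N = 300, Lambda = 25, sigma2 = 30, twoNU = 2,
                       Se = 50)
  set.seed(22)
  tr1 <- run_hybrid(sc, generations = 400)
  set.seed(22)
  tr2 <- run_hybrid(sc, generations = 400)
  expect_identical(tr1$series, tr2$series)
  expect_identical(tr1$alleles, tr2$alleles)
})

test_that("the bookkeeping identity for D holds along a stochastic run", {
  sc <- point_scenario(N = 300, Lambda = 25, sigma2 = 30, twoNU = 5,
                       Se = 50)
  set.seed(23)
  tr <- run_hybrid(sc, generations = 300, full_horizon = TRUE)
  al <- tr$alleles
  xfin <- ifelse(al$fate == "fixed", 1, ifelse(al$fate == "lost", 0,
                                               al$x_final))
  x0eff <- ifelse(al$origin == "standing", al$x0, 0)
  shift <- sum(al$orientation * 2 * al$a * (xfin - x0eff))
  st <- tr$final_state
  expect_equal(st$D, sc$Lambda - st$mean_bg - shift, tolerance = 1e-9)
  # VA_large recomputable from the segregating set
  seg <- al$fate == "segregating"
  expect_equal(st$VA_large,
               sum(2 * al$a[seg]^2 * al$x_final[seg] * (1 - al$x_final[seg])),
               tolerance = 1e-12)
})

test_that("step_hybrid treats fixation as absorbing and counts its shift", {
  sc <- point_scenario(N = 200, Lambda = 30, sigma2 = 0, twoNU = 0, Se = 100)
  standing <- standing_architecture(Se = 100, orientation = 1, x0 = 0.95,
                                    N = 200)
  st <- population_state(sc, standing)
  set.seed(24)
  for (i in 1:200) st <- step_hybrid(st, sc)
  expect_equal(st$fate[1], 1L)  # fixed
  expect_equal(st$x[1], 1)
  D_after <- st$D
  for (i in 1:10) st <- step_hybrid(st, sc)
  expect_equal(st$x[1], 1)
  expect_equal(st$D, D_after)  # nothing left to change with sigma2 = 0
  # a fixation moves the mean by 2 a (1 - x0)
  expect_equal(st$D, 30 - 2 * 10 * (1 - 0.95), tolerance = 1e-9)
})

test_that("one-generation drift variance matches x(1-x)/2N in the engine", {
  N <- 500
  sc <- point_scenario(N = N, Lambda = 0, sigma2 = 0, twoNU = 0, Se = 100)
  n <- 1e4
  standing <- standing_architecture(Se = rep(1e-12, n), orientation = 1,
                                    x0 = rep(0.3, n), N = N)
  st <- population_state(sc, standing)
  set.seed(25)
  st <- step_hybrid(st, sc)
  v <- stats::var(st$x[seq_len(n)])
  expect_equal(v, 0.3 * 0.7 / (2 * N), tolerance = 0.05)
})

test_that("engine fixation probability matches the exact chain at N=50, fixed D", {
  # constant-distance Monte-Carlo with the engine's moment kernel
  N <- 50; a <- 0.6; D <- 7; twoN <- 2 * N
  sc <- trait_scale(N)
  u <- wf_fixation_prob(N, a, D)
  set.seed(26)
  nrep <- 1e4
  x <- rep(1 / twoN, nrep)
  alive <- rep(TRUE, nrep)
  for (g in 1:5000) {
    if (!any(alive)) break
    i <- which(alive)
    ex <- x[i] + delta_x_moments(a, x[i], D, sc)$expected
    x[i] <- stats::rbinom(length(i), twoN, pmin(pmax(ex, 0), 1)) / twoN
    alive[i] <- x[i] > 0 & x[i] < 1
  }
  pfix <- mean(x == 1)
  se <- sqrt(u[1] * (1 - u[1]) / nrep)
  expect_lt(abs(pfix - u[1]), 3 * se)
})

test_that("early stopping and the full-horizon flag behave as documented", {
  sc <- point_scenario(N = 300, Lambda = 20, sigma2 = 60, twoNU = 0)
  set.seed(27)
  tr <- run_hybrid(sc, generations = 5000)
  # stops once D < 1e-3 (no alleles can ever arise)
  expect_lt(tr$generations_run, 5000)
  expect_lt(tr$series$D[nrow(tr$series)], 1e-3)
  set.seed(27)
  tr_full <- run_hybrid(sc, generations = 200, full_horizon = TRUE)
  expect_equal(tr_full$generations_run, 200)
})

test_that("the memory guard aborts runaway segregating counts", {
  sc <- point_scenario(N = 200, Lambda = 10, sigma2 = 20, twoNU = 50,
                       Se = 30)
  set.seed(28)
  expect_error(run_hybrid(sc, generations = 200, max_alleles = 10),
               "max_alleles")
})

test_that("polygenic engine: no shift means fluctuations at the delta scale", {
  ed <- effect_dist_exponential(mean_Se = 1, Se_min = 0.02, Se_max = 6,
                                large_cutoff = 0)
  set.seed(29)
  tr <- run_polygenic(N = 200, Lambda = 0, twoNU = 30, effect_dist = ed,
                      generations = 1000)
  expect_lt(mean(abs(tr$series$D)), 3)
})

test_that("polygenic engine tracks Lande decay while D is substantial", {
  N <- 500
  ed <- effect_dist_exponential(mean_Se = 1, Se_min = 0.02, Se_max = 6,
                                large_cutoff = 0)
  nodes <- optimshift:::effect_dist_nodes(ed)
  v1 <- sum(nodes$w * vapply(nodes$Se,
                             optimshift:::sojourn_variance_per_input,
                             numeric(1), scale = trait_scale(N)))
  twoNU <- 60 / v1   # target MSDB variance ~60 (decay rate 0.06/gen)
  set.seed(30)
  D <- 0
  VA0 <- 0
  nrep <- 20
  for (r in 1:nrep) {
    tr <- run_polygenic(N = N, Lambda = 25, twoNU = twoNU, effect_dist = ed,
                        generations = 80)
    D <- D + tr$series$D
    VA0 <- VA0 + tr$series$VA_large[1]
  }
  D <- D / nrep
  VA0 <- VA0 / nrep
  lande <- 25 * exp(-VA0 * (0:80) / (2 * N))
  sel <- D > 5
  expect_lt(max(abs(D[sel] - lande[sel]) / lande[sel]), 0.1)
})

test_that("aligned standing alleles fix preferentially after the shift", {
  N <- 200
  ed <- effect_dist_exponential(mean_Se = 1, Se_min = 0.02, Se_max = 4,
                                large_cutoff = 0)
  set.seed(31)
  fixA <- segA <- fixO <- segO <- 0
  for (r in 1:40) {
    tr <- run_polygenic(N = N, Lambda = 12, twoNU = 8, effect_dist = ed,
                        generations = 2000)
    st <- tr$alleles[tr$alleles$origin == "standing" & tr$alleles$Se <= 2, ]
    fixA <- fixA + sum(st$orientation == 1 & st$fate == "fixed")
    segA <- segA + sum(st$orientation == 1)
    fixO <- fixO + sum(st$orientation == -1 & st$fate == "fixed")
    segO <- segO + sum(st$orientation == -1)
  }
  pv <- stats::prop.test(c(fixA, fixO), c(segA, segO),
                         alternative = "greater")$p.value
  expect_gt(fixA / segA, fixO / segO)
  expect_lt(pv, 0.01)
})

test_that("non-polygenic configurations draw a warning", {
  ed <- effect_dist_point(200)
  expect_warning(run_polygenic(N = 200, Lambda = 5, twoNU = 0.1,
                               effect_dist = ed, generations = 5),
                 "polygenic")
})
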