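test_that("neutral sojourn density has the 1/x shape above the entry frequency", {
  sc <- trait_scale(1000)
  f <- sojourn_density(0, sc)
  expect_equal(f(0.01) / f(0.02), 2, tolerance = 0.01)
  expect_equal(f(0.1) / f(0.4), (1 / 0.1) / (1 / 0.4), tolerance = 0.01)
  # pointwise neutral shape on [0.01, 0.99]
  xs <- seq(0.01, 0.99, by = 0.02)
  expect_equal(f(xs) / f(0.5), (1 / xs) / (1 / 0.5), tolerance = 0.01)
})

test_that("strong stabilizing selection confines alleles to low frequencies", {
  sc <- trait_scale(5000)
  g <- optimshift:::sojourn_grid(200, 5000)
  m <- length(g$x)
  mid <- (g$x[-1] + g$x[-m]) / 2
  tail_mass <- sum((diff(g$x) * (g$tau[-1] + g$tau[-m]) / 2)[mid > 0.2])
  expect_lt(tail_mass / g$mass, 0.01)
})

test_that("sojourn mass above a fixed frequency is non-increasing in Se", {
  sc <- trait_scale(1000)
  above <- function(Se) {
    g <- optimshift:::sojourn_grid(Se, 1000)
    m <- length(g$x)
    mid <- (g$x[-1] + g$x[-m]) / 2
    sum((diff(g$x) * (g$tau[-1] + g$tau[-m]) / 2)[mid > 0.05])
  }
  masses <- vapply(c(0, 2, 5, 30, 200), above, numeric(1))
  expect_true(all(diff(masses) <= 1e-9))
})

test_that("quadrature sojourn matches the exact Wright-Fisher chain at N=50", {
  # states 3..70 carry the comparison: the 1-2 copy boundary layer of the
  # discrete chain is not a diffusion quantity (checked in aggregate below)
  # and the near-loss/near-fixation tail has negligible occupancy
  for (Se in c(0, 2, 10)) {
    v <- wf_sojourn_visits(50, Se)
    cells <- vapply(3:70, function(k) sojourn_cell_mass(Se, 50, k, k),
                    numeric(1))
    expect_lt(max(abs(cells - v[3:70]) / v[3:70]), 0.05)
    # total segregating mass within 10% (entry-state discreteness)
    expect_equal(sojourn_mass(Se, trait_scale(50)), sum(v), tolerance = 0.1)
  }
})

test_that("sample_standing is empty without mutational input", {
  sc <- point_scenario(N = 1000, Lambda = 10, sigma2 = 40, twoNU = 0)
  arch <- sample_standing(sc)
  expect_equal(nrow(arch), 0)
  expect_equal(total_large_variance(arch), 0)
})

test_that("sampled standing variance matches the quadrature expectation", {
  sc <- point_scenario(N = 1000, Lambda = 10, sigma2 = 40, twoNU = 10,
                       Se = 200)
  v1 <- optimshift:::sojourn_variance_per_input(200, sc$scale)
  set.seed(11)
  vl <- replicate(200, total_large_variance(sample_standing(sc)))
  se <- stats::sd(vl) / sqrt(length(vl))
  expect_lt(abs(mean(vl) - 10 * v1), 3 * se)
})

test_that("standing allele counts are Poisson with the quadrature mean", {
  sc <- point_scenario(N = 1000, Lambda = 10, sigma2 = 40, twoNU = 0.01,
                       Se = 200)
  lambda <- 0.01 * sojourn_mass(200, sc$scale)
  set.seed(12)
  nonempty <- mean(replicate(1000, nrow(sample_standing(sc)) > 0))
  p <- 1 - exp(-lambda)
  expect_lt(abs(nonempty - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("standing orientations are symmetric", {
  sc <- point_scenario(N = 500, Lambda = 10, sigma2 = 40, twoNU = 50,
                       Se = 30)
  set.seed(13)
  ori <- unlist(replicate(10, sample_standing(sc)$orientation))
  expect_true(all(ori %in% c(-1L, 1L)))
  expect_lt(abs(mean(ori)), 3 / sqrt(length(ori)))
})

test_that("burn-in without mutational input stays empty", {
  sc <- point_scenario(N = 200, Lambda = 0, sigma2 = 0, twoNU = 0)
  set.seed(14)
  expect_equal(nrow(suppressWarnings(burnin_engine(sc, generations = 100))),
               0)
})

test_that("burn-in segregating counts match the quadrature Poisson mean", {
  # dispersion-style chi-square over replicate burn-ins (Se=30, 2NU=5)
  sc <- scenario(N = 1000, Lambda = 0, sigma2 = 0, twoNU = 5,
                 effect_dist = effect_dist_point(30))
  lambda <- 5 * sojourn_mass(30, sc$scale)
  set.seed(15)
  counts <- replicate(30, nrow(burnin_engine(sc, generations = 25000)))
  stat <- sum((counts - lambda)^2 / lambda)
  expect_lt(stat, stats::qchisq(0.99, df = length(counts)))
})

test_that("neutral burn-in reproduces the neutral frequency spectrum shape", {
  sc <- scenario(N = 200, Lambda = 0, sigma2 = 0, twoNU = 2,
                 effect_dist = effect_dist_point(1e-6, large_cutoff = 0))
  set.seed(16)
  arch <- burnin_engine(sc, generations = 10000, snapshot_every = 1000)
  xs <- unlist(lapply(attr(arch, "snapshots"), function(s) s$x0))
  # coarse neutral check: mass ratio of (0, 0.1] to (0.1, 0.5] vs 1/x law
  r_obs <- mean(xs <= 0.1) / mean(xs > 0.1 & xs <= 0.5)
  g <- optimshift:::sojourn_grid(0, 200)
  m <- length(g$x)
  mid <- (g$x[-1] + g$x[-m]) / 2
  w <- diff(g$x) * (g$tau[-1] + g$tau[-m]) / 2
  r_exp <- sum(w[mid <= 0.1]) / sum(w[mid > 0.1 & mid <= 0.5])
  expect_equal(r_obs, r_exp, tolerance = 0.2)
})
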