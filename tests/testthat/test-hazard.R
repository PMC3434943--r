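# grid of valid specs across all six families, reused by the property tests
spec_grid <- list(
  hazard_spec("constant", alpha = 0.01),
  hazard_spec("constant", alpha = 0.05),
  hazard_spec("gompertz", alpha = 0.0101, beta = 0.0264),
  hazard_spec("gompertz", alpha = 0.0029, beta = 0.0418),
  hazard_spec("gompertz_makeham", alpha = 0.005, beta = 0.04, c = 0.01),
  hazard_spec("gompertz_makeham", alpha = 0.01, beta = 0.03, c = 0),
  hazard_spec("logistic", alpha = 0.008, beta = 0.05, s = 0.3),
  hazard_spec("logistic", alpha = 0.01, beta = 0.04, s = 1.2),
  hazard_spec("logistic_makeham", alpha = 0.008, beta = 0.05, s = 0.5,
              c = 0.005),
  hazard_spec("weibull", a = 0.0002, b = 2.2),
  hazard_spec("weibull", a = 0.01, b = 1))

test_that("hazard evaluates the family formulas", {
  # hazard at age 0 equals the baseline mortality rate
  expect_equal(hazard(hazard_spec("gompertz", alpha = 0.0101, beta = 0.0264),
                      0), 0.0101)
  # direct evaluation 0.0065 * exp(0.0406 * 50)
  expect_equal(hazard(hazard_spec("gompertz", alpha = 0.0065, beta = 0.0406),
                      50), 0.0065 * exp(0.0406 * 50), tolerance = 1e-12)
  expect_equal(hazard(hazard_spec("constant", alpha = 0.02), c(0, 10, 99)),
               rep(0.02, 3))
  # logistic with s -> 0 collapses to the Gompertz hazard
  g <- hazard_spec("gompertz", alpha = 0.01, beta = 0.04)
  l0 <- hazard_spec("logistic", alpha = 0.01, beta = 0.04, s = 0)
  x <- c(0, 5, 20, 60)
  expect_equal(hazard(l0, x), hazard(g, x))
  # makeham with c = 0 is gompertz
  gm0 <- hazard_spec("gompertz_makeham", alpha = 0.01, beta = 0.04, c = 0)
  expect_equal(hazard(gm0, x), hazard(g, x))
  # gompertz with tiny beta approaches the constant hazard
  expect_equal(hazard(hazard_spec("gompertz", alpha = 0.02, beta = 1e-14),
                      c(1, 50)), rep(0.02, 2), tolerance = 1e-8)
})

test_that("invalid parameters and ages are rejected by name", {
  expect_error(hazard_spec("gompertz", alpha = -1, beta = 0.1), "'alpha'")
  expect_error(hazard_spec("gompertz", alpha = 0.01, beta = 0), "'beta'")
  expect_error(hazard_spec("gompertz_makeham", alpha = 0.01, beta = 0.1,
                           c = -0.1), "'c'")
  expect_error(hazard_spec("gompertz", alpha = 0.01), "'beta'")
  expect_error(hazard_spec("constant", alpha = 0.01, beta = 0.1), "'beta'")
  sp <- hazard_spec("gompertz", alpha = 0.01, beta = 0.05)
  expect_error(hazard(sp, -1), "'x'")
  expect_error(log_density(sp, -0.5), "'x'")
  expect_error(quantile(sp, probs = 0), "probs")
  expect_error(quantile(sp, probs = 1.2), "probs")
})

test_that("survival equals exp(-integral of hazard) for every family", {
  for (sp in spec_grid) {
    expect_equal(survival(sp, 0), 1, info = sp$family)
    for (x in c(3.7, 21, 68)) {
      q <- integrate(function(u) hazard(sp, u), 0, x,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
      expect_equal(survival(sp, x), exp(-q), tolerance = 1e-8,
                   info = paste(sp$family, x))
    }
    # survival is nonincreasing
    s <- survival(sp, seq(0, 90, by = 0.5))
    expect_true(all(diff(s) <= 1e-12), info = sp$family)
  }
  # closed-form checks
  expect_equal(survival(hazard_spec("constant", alpha = 0.01), 100),
               exp(-1))
  expect_equal(survival(hazard_spec("gompertz", alpha = 0.0078,
                                    beta = 0.0417), 37.14),
               0.5, tolerance = 1e-3)
})

test_that("log_density matches hazard * survival and integrates to one", {
  for (sp in spec_grid) {
    x <- c(2.5, 17, 55)
    expect_equal(exp(log_density(sp, x)), hazard(sp, x) * survival(sp, x),
                 tolerance = 1e-12, info = sp$family)
    # finite-difference derivative of the CDF 1 - survival
    h <- 1e-5
    fd <- (survival(sp, x - h) - survival(sp, x + h)) / (2 * h)
    expect_equal(exp(log_density(sp, x)), fd, tolerance = 1e-6,
                 info = sp$family)
    top <- quantile(sp, probs = 1 - 1e-9)
    tot <- integrate(function(u) exp(log_density(sp, u)), 0, top,
                     rel.tol = 1e-10)$value
    expect_equal(tot, 1, tolerance = 1e-6, info = sp$family)
  }
  expect_equal(log_density(hazard_spec("gompertz", alpha = 0.0101,
                                       beta = 0.0264), 0), log(0.0101))
  # weibull with shape 1 is the constant-hazard (exponential) density
  expect_equal(log_density(hazard_spec("weibull", a = 0.03, b = 1),
                           c(1, 10, 40)),
               log_density(hazard_spec("constant", alpha = 0.03),
                           c(1, 10, 40)),
               tolerance = 1e-12)
})

test_that("quantile inverts survival for every family", {
  for (sp in spec_grid) {
    p <- c(0.01, 0.1, 0.5, 0.9, 0.99)
    q <- quantile(sp, probs = p)
    expect_equal(survival(sp, q), 1 - p, tolerance = 1e-9,
                 info = sp$family)
    x <- c(5, 30, 70)
    expect_equal(quantile(sp, probs = 1 - survival(sp, x)), x,
                 tolerance = 1e-9, info = sp$family)
  }
  # bisection oracle on the quadrature-based survival
  sp <- hazard_spec("gompertz", alpha = 0.0078, beta = 0.0417)
  med_oracle <- uniroot(function(t)
    exp(-integrate(function(u) hazard(sp, u), 0, t,
                   rel.tol = 1e-12)$value) - 0.5,
    c(1, 200), tol = 1e-10)$root
  expect_equal(quantile(sp, 0.5), med_oracle, tolerance = 1e-8)
  expect_equal(quantile(sp, 0.5), 37.14, tolerance = 1e-4)
  expect_equal(quantile(hazard_spec("gompertz", alpha = 0.0065,
                                    beta = 0.0406), 0.5),
               41.21, tolerance = 1e-4)
  expect_equal(quantile(hazard_spec("constant", alpha = 0.01), 0.5),
               log(2) / 0.01)
})

test_that("simulated death times reproduce the generating distribution", {
  sp <- hazard_spec("gompertz", alpha = 0.0078, beta = 0.0417)
  t1 <- simulate_death_times(sp, 1000, seed = 9)
  t2 <- simulate_death_times(sp, 1000, seed = 9)
  expect_identical(t1, t2)
  expect_length(simulate_death_times(sp, 1, seed = 4), 1)
  expect_true(simulate_death_times(sp, 1, seed = 4) > 0)
  expect_error(simulate_death_times(sp, 5), "seed")

  # KS against the generating survival at n = 1e5, alpha level 0.001
  for (sp in spec_grid[c(1, 3, 7, 10)]) {
    t <- simulate_death_times(sp, 1e5, seed = 21)
    ks <- suppressWarnings(
      ks.test(t, function(q) 1 - survival(sp, q)))
    expect_gt(ks$p.value, 0.001)
  }

  # exponential mean 1/alpha at large n
  t <- simulate_death_times(hazard_spec("constant", alpha = 0.02), 1e5,
                            seed = 13)
  expect_equal(mean(t), 50, tolerance = 0.02)
  # CV-female sample median rounds to the printed day
  t <- simulate_death_times(sp_cvf <- hazard_spec("gompertz", alpha = 0.0078,
                                                  beta = 0.0417),
                            2e5, seed = 31)
  expect_equal(round(median(t)), 37)
})

test_that("simulation leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_death_times(hazard_spec("constant", alpha = 0.01), 10,
                                 seed = 99))
  expect_identical(.Random.seed, before)
})
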