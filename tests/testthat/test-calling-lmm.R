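test_that("calling design matrix implements the term vocabulary", {
  d <- data.frame(id = "a", age_days = 10, lifespan_days = 30,
                  diet = "C", mating = "mated")
  X <- build_calling_design(d, "intercept")
  expect_equal(dim(X), c(1L, 1L))
  expect_equal(unname(X[1, 1]), 1)
  expect_equal(unname(build_calling_design(d, "age2")[1, 1]), 100)
  # baseline coding: diet C zeroes every diet interaction
  expect_equal(unname(build_calling_design(d, "diet:age")[1, 1]), 0)
  d$diet <- "P"
  expect_equal(unname(build_calling_design(d, "diet:age")[1, 1]), 10)
  expect_equal(unname(build_calling_design(d, "age:lifespan")[1, 1]), 300)
  expect_equal(unname(build_calling_design(d, "diet:mating:age")[1, 1]), 0)
  expect_error(build_calling_design(d, "mass"), "unknown term")
  # column order follows the term list
  X2 <- build_calling_design(d, c("age", "intercept", "lifespan2"))
  expect_equal(colnames(X2), c("age", "intercept", "lifespan2"))
})

test_that("with no group variance the fit reduces to least squares", {
  set.seed(101)
  n <- 120
  d <- data.frame(x = runif(n, 0, 10), g = rep(1:30, each = 4))
  # errors centred within each group: the variance-ratio MLE is exactly 0
  e <- rnorm(n, 0, 2)
  e <- e - ave(e, d$g)
  d$y <- 3 + 1.7 * d$x + e
  X <- cbind(intercept = 1, x = d$x)
  f <- fit_lmm(X, d$y, d$g)
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-6)
  # ML loglik at the boundary equals the (ML) normal-regression loglik
  if (f$boundary) expect_equal(f$loglik, as.numeric(logLik(ols)),
                               tolerance = 1e-6)
})

test_that("profiled ML equals brute-force marginal-likelihood maximization", {
  # tiny datasets (<= 10 rows): direct optimization over all parameters
  cases <- list(
    list(ng = 3, ni = 2, beta = c(2, 0.5), su = 1.5, se = 1),
    list(ng = 4, ni = 2, beta = c(-1, 2), su = 0.3, se = 2),
    list(ng = 5, ni = 2, beta = c(0, 1), su = 2, se = 0.5))
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    set.seed(200 + k)
    g <- rep(seq_len(cs$ng), each = cs$ni)
    x <- runif(cs$ng * cs$ni, 0, 5)
    y <- cs$beta[1] + cs$beta[2] * x + rep(rnorm(cs$ng, 0, cs$su),
                                           each = cs$ni) +
      rnorm(cs$ng * cs$ni, 0, cs$se)
    X <- cbind(intercept = 1, x = x)
    f <- fit_lmm(X, y, g)
    bf <- lmm_brute_force(X, y, g)
    expect_equal(f$loglik, bf$loglik, tolerance = 1e-6, info = paste(k))
    expect_gte(f$loglik, bf$loglik - 1e-6)
    expect_equal(unname(coef(f)), unname(bf$beta), tolerance = 1e-3)
  }
})

test_that("the fit matches an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- sim_calling(150, seed = 33)
  f <- fit_calling_lmm(d)
  X <- build_calling_design(d, calling_terms_best())
  dd <- data.frame(y = d$calling_s, id = d$id)
  # lme4 warns about raw age^2/lifespan^2 column scales; irrelevant here
  m <- suppressWarnings(
    lme4::lmer(y ~ 0 + X + (1 | id), data = dd, REML = FALSE))
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(unname(coef(f)), unname(lme4::fixef(m)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$sigma_u, vc$sdcor[1], tolerance = 1e-3)
  expect_equal(f$sigma_e, vc$sdcor[2], tolerance = 1e-3)
})

test_that("fixed effects are recovered from a synthetic calling cohort", {
  d <- sim_calling(3000, seed = 44)
  f <- fit_calling_lmm(d)
  truth <- default_calling_coefficients()
  est <- coef(f)
  expect_equal(names(est), names(truth))
  # every coefficient within 3 reported SEs of its generating value
  expect_true(all(abs(est - truth) <= 3 * f$se))
  expect_false(f$boundary)
  expect_equal(f$sigma_u, 1500, tolerance = 0.15)
  expect_equal(f$sigma_e, 3000, tolerance = 0.05)
})

test_that("AIC with the random intercept never loses by more than its cost", {
  d <- sim_calling(200, seed = 55)
  f <- fit_calling_lmm(d)
  X <- build_calling_design(d, calling_terms_best())
  ols <- lm(d$calling_s ~ 0 + X)
  aic0 <- 2 * (ncol(X) + 1) - 2 * as.numeric(logLik(ols))
  expect_gte(aic0, f$aic - 2)
})

test_that("degenerate designs and inputs are rejected with names", {
  d <- sim_calling(60, seed = 66)
  expect_error(fit_calling_lmm(d, terms = c("intercept", "age", "age")),
               "collinear")
  expect_error(fit_calling_lmm(d[0, ]), "2 groups|groups")
  expect_error(fit_calling_lmm(d[, setdiff(names(d), "calling_s")]),
               "calling_s")
  expect_warning(fit_calling_lmm(d, reml = TRUE), "REML")
})

test_that("model comparison prefers the generating structure", {
  best <- calling_terms_best()
  no_diet_age <- setdiff(best, c("diet:age", "diet:age2"))
  # duplicate candidates tie exactly
  d0 <- sim_calling(100, seed = 77)
  cmp0 <- compare_calling_models(d0, list(a = best, b = best))
  expect_equal(cmp0$table$delta_aic, c(0, 0))
  # data carry the diet:age signal: the with-term model wins
  wins <- 0
  for (r in 1:20) {
    d <- sim_calling(1000, seed = 900 + r)
    cmp <- compare_calling_models(d, list(with = best,
                                          without = no_diet_age))
    tab <- cmp$table
    if (tab$candidate[1] == "with" &&
          tab$delta_aic[tab$candidate == "without"] > 2)
      wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("parsimony holds when no diet effect was generated", {
  cf <- default_calling_coefficients()
  cf[c("diet", "diet:age", "diet:age2")] <- 0
  best <- calling_terms_best()
  no_diet <- setdiff(best, c("diet", "diet:age", "diet:age2"))
  ok <- 0
  for (r in 1:20) {
    d <- sim_calling(500, coefs = cf, seed = 1500 + r)
    cmp <- compare_calling_models(d, list(with_diet = best,
                                          no_diet = no_diet))
    tab <- cmp$table
    if (tab$delta_aic[tab$candidate == "no_diet"] <= 2) ok <- ok + 1
  }
  expect_gte(ok, 16)
})

test_that("predict, residuals and random intercepts are consistent", {
  d <- sim_calling(150, seed = 88)
  f <- fit_calling_lmm(d)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, newdata = d), unname(fitted(f)))
  rm_ <- residuals(f, type = "marginal")
  rc <- residuals(f, type = "conditional")
  expect_equal(length(rm_), nrow(d))
  # conditional residuals have smaller spread than marginal ones
  expect_lt(sd(rc), sd(rm_))
  u <- random_intercepts(f)
  expect_equal(length(u), f$n_groups)
  expect_equal(mean(u), 0, tolerance = 200)
})
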