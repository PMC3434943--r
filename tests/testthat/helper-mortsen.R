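# Shared fixtures: all built in code at test time.

# small single-cell Gompertz cohort
gomp_cohort <- function(n, alpha, beta, seed, diet = NULL, mating = NULL) {
  sp <- hazard_spec("gompertz", alpha = alpha, beta = beta)
  d <- data.frame(lifespan_days = simulate_death_times(sp, n, seed = seed))
  if (!is.null(diet)) d$diet <- diet
  if (!is.null(mating)) d$mating <- mating
  d
}

fast_ctrl <- mortality_control(restarts = 0)

# brute-force marginal Gaussian likelihood of a random-intercept model:
# direct evaluation of the multivariate normal density with
# Sigma = sigma_u^2 Z Z' + sigma_e^2 I (independent oracle for fit_lmm)
lmm_marginal_loglik <- function(X, y, group, beta, sigma_u, sigma_e) {
  Z <- outer(as.character(group), unique(as.character(group)), `==`) * 1
  Sigma <- sigma_u^2 * tcrossprod(Z) + sigma_e^2 * diag(length(y))
  r <- y - drop(X %*% beta)
  L <- chol(Sigma)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) +
            sum(backsolve(L, r, transpose = TRUE)^2))
}

# brute-force direct maximization over (beta, log sigma_u, log sigma_e)
lmm_brute_force <- function(X, y, group) {
  p <- ncol(X)
  obj <- function(par)
    -lmm_marginal_loglik(X, y, group, par[seq_len(p)],
                         exp(par[p + 1]), exp(par[p + 2]))
  start <- c(qr.solve(X, y), log(stats::sd(y) / 2 + 1e-3),
             log(stats::sd(y) / 2 + 1e-3))
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
  o <- stats::optim(o$par, obj, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-12))
  list(loglik = -o$value, beta = o$par[seq_len(p)],
       sigma_u = exp(o$par[p + 1]), sigma_e = exp(o$par[p + 2]))
}

# longitudinal calling data for n_males from given fixed effects
sim_calling <- function(n_males, coefs = default_calling_coefficients(),
                        sigma_u = 1500, sigma_e = 3000, seed = 1) {
  ss <- default_sample_sizes()
  ss <- ss[ss$sex == "male", ]
  ss$n <- round(ss$n / sum(ss$n) * n_males)
  cfg <- experiment_config(sample_sizes = ss,
                           calling = list(coefficients = coefs,
                                          sigma_u = sigma_u,
                                          sigma_e = sigma_e),
                           seed = seed)
  e <- generate_experiment(cfg)
  join_calling(e$cohort, e$calling)
}
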