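#' Negative log-likelihood of a treatment-structured mortality model
#'
#' Evaluates \eqn{-\sum_i \log f(t_i)} for individual death times under a
#' hazard family whose leading parameters vary across treatment cells
#' according to a [model_structure()]. Parameters are on the working scale:
#' the log of every natural-scale parameter, with treatment effects as
#' additive log-scale coefficients (hence multiplicative on the hazard).
#'
#' The working vector is ordered: log-alpha coefficients (intercept then
#' effect terms), log-beta coefficients, then any auxiliary family
#' parameters (`c`, `s`) as single log-scale scalars shared across cells.
#'
#' @param data data.frame with `lifespan_days` and any treatment columns
#'   the structure references (`diet`, `mating`).
#' @param structure a [model_structure()].
#' @param params working-scale parameter vector.
#' @return the negative log-likelihood (scalar).
#' @export
neg_log_likelihood <- function(data, structure, params) {
  ll <- mort_loglik_env(data, structure)
  if (length(params) != ll$npar)
    stop("'params' must have length ", ll$npar, " for this structure, got ",
         length(params), call. = FALSE)
  ll$nll(params)
}

# Precompute design matrices and closures for one (data, structure) pair.
mort_loglik_env <- function(data, structure) {
  if (!nrow(data)) stop("no observations", call. = FALSE)
  t <- data$lifespan_days
  if (any(!is.finite(t)) || any(t <= 0))
    stop("'lifespan_days' must be finite and > 0", call. = FALSE)
  fam <- structure$family
  Xa <- structure_design(data, structure$alpha_terms)
  Xb <- if (fam == "constant") NULL else
    structure_design(data, structure$beta_terms)
  ka <- ncol(Xa); kb <- if (is.null(Xb)) 0L else ncol(Xb)
  extras <- setdiff(hazard_param_names(fam),
                    c("alpha", "beta", "a", "b"))
  npar <- ka + kb + length(extras)
  slot <- if (fam == "weibull") c("a", "b") else c("alpha", "beta")
  pnames <- c(paste0(slot[1], ".", colnames(Xa)),
              if (kb) paste0(slot[2], ".", colnames(Xb)), extras)

  gvec <- function(beta, t) {
    out <- expm1(beta * t) / beta
    if (any(small <- beta < 1e-10)) out[small] <- t[small]
    out
  }

  loglik_rows <- function(par) {
    la <- if (ka == 1L) par[[1L]] else drop(Xa %*% par[seq_len(ka)])
    alpha <- exp(la)
    if (fam == "constant") return(la - alpha * t)
    lb <- if (kb == 1L) par[[ka + 1L]] else drop(Xb %*% par[ka + seq_len(kb)])
    beta <- exp(lb)
    ex <- exp(par[ka + kb + seq_along(extras)])
    names(ex) <- extras
    switch(fam,
      gompertz = la + beta * t - alpha * gvec(beta, t),
      gompertz_makeham = {
        cc <- ex[["c"]]
        log(cc + alpha * exp(beta * t)) - cc * t - alpha * gvec(beta, t)
      },
      logistic = {
        s <- ex[["s"]]; g <- gvec(beta, t)
        ch <- if (s < 1e-10) alpha * g else log1p(s * alpha * g) / s
        la + beta * t - log1p(s * alpha * g) - ch
      },
      logistic_makeham = {
        s <- ex[["s"]]; cc <- ex[["c"]]; g <- gvec(beta, t)
        D <- 1 + s * alpha * g
        ch <- if (s < 1e-10) alpha * g else log1p(s * alpha * g) / s
        log(cc + alpha * exp(beta * t) / D) - cc * t - ch
      },
      weibull = la + lb + (exp(lb) - 1) * log(t) - alpha * t^beta)
  }

  nll <- function(par) {
    v <- -sum(loglik_rows(par))
    if (!is.finite(v)) 1e10 else v
  }

  # analytic working-scale gradient (gompertz & constant; others numeric)
  gr <- NULL
  if (fam == "constant") {
    gr <- function(par) {
      alpha <- exp(drop(Xa %*% par))
      -drop(crossprod(Xa, 1 - alpha * t))
    }
  } else if (fam == "gompertz") {
    gr <- function(par) {
      la <- if (ka == 1L) par[[1L]] else drop(Xa %*% par[seq_len(ka)])
      alpha <- exp(la)
      lb <- if (kb == 1L) par[[ka + 1L]] else
        drop(Xb %*% par[ka + seq_len(kb)])
      beta <- exp(lb)
      g <- gvec(beta, t)
      da <- 1 - alpha * g                               # dl/d log alpha_i
      db <- beta * t + alpha * g - alpha * t * exp(beta * t)  # dl/d log beta_i
      out <- -c(if (ka == 1L) sum(da) else drop(crossprod(Xa, da)),
                if (kb == 1L) sum(db) else drop(crossprod(Xb, db)))
      if (any(!is.finite(out))) out[!is.finite(out)] <- 0
      out
    }
  }

  list(nll = nll, gr = gr, npar = npar, ka = ka, kb = kb, extras = extras,
       pnames = pnames, Xa = Xa, Xb = Xb, t = t, family = fam,
       loglik_rows = loglik_rows)
}

# deterministic jittered multistart; logistic s in Gompertz limit etc.
mort_start_values <- function(ll) {
  t <- ll$t
  starts <- list()
  if (ll$family == "constant") {
    starts[[1]] <- log(length(t) / sum(t))
  } else if (ll$family == "weibull") {
    for (b0 in c(1, 1.5, 2.5)) {
      a0 <- length(t) / sum(t^b0)
      starts[[length(starts) + 1]] <-
        c(log(a0), rep(0, ll$ka - 1), log(b0), rep(0, ll$kb - 1))
    }
  } else {
    for (b0 in c(0.005, 0.02, 0.05, 0.1)) {
      g0 <- expm1(b0 * t) / b0
      a0 <- length(t) / sum(g0)          # profile MLE of alpha given beta
      base <- c(log(a0), rep(0, ll$ka - 1), log(b0), rep(0, ll$kb - 1))
      extras <- vapply(ll$extras, function(e)
        switch(e, c = log(0.1 * a0 + 1e-8), s = log(0.1)), numeric(1))
      starts[[length(starts) + 1]] <- c(base, extras)
    }
  }
  starts
}

#' Optimizer settings for mortality model fitting
#'
#' @param restarts number of jittered restarts around the best heuristic
#'   start (deterministic: the jitter stream has its own fixed seed).
#' @param jitter_sd working-scale s.d. of restart jitter.
#' @param reltol convergence tolerance on the working-scale objective.
#' @param restart_seed fixed seed for the restart jitter stream.
#' @export
mortality_control <- function(restarts = 5, jitter_sd = 0.3,
                              reltol = 1e-10, restart_seed = 871L) {
  list(restarts = restarts, jitter_sd = jitter_sd, reltol = reltol,
       restart_seed = restart_seed)
}

#' Fit a treatment-structured parametric mortality model
#'
#' Maximum-likelihood estimation of hazard-family parameters from exact
#' individual death times, with treatment effects (diet, mating, and their
#' interaction) on the baseline-mortality and rate-of-ageing parameters.
#' Optimization is on the log working scale (so natural-scale parameters
#' stay positive and treatment effects are multiplicative), from several
#' heuristic starting points plus deterministic jittered restarts, with a
#' derivative-free simplex stage followed by a gradient polish. Wald 95%
#' confidence intervals (log scale, exponentiated) are attached to the fit;
#' [confint.mortality_fit()] computes profile-likelihood intervals.
#'
#' @param data data.frame with column `lifespan_days` (> 0) and, when the
#'   structure references them, `diet` (levels C/P) and `mating`
#'   (virgin/mated). Every treatment cell referenced must hold >= 2 deaths.
#' @param alpha,beta one-sided formulas or character vectors giving the
#'   treatment terms on each parameter, e.g. `~ diet * mating`.
#' @param family hazard family (see [hazard_spec()]).
#' @param structure alternatively, a ready [model_structure()]; overrides
#'   `alpha`, `beta`, `family`.
#' @param control a [mortality_control()] list.
#' @return an object of class `mortality_fit` with components `structure`,
#'   `coefficients` (working scale), `estimates` (natural scale), `ci95`,
#'   `vcov` (working scale), `loglik`, `n_params`, `aic`, `converged`,
#'   `n_obs`.
#' @examples
#' sp <- hazard_spec("gompertz", alpha = 0.01, beta = 0.03)
#' d <- data.frame(lifespan_days = simulate_death_times(sp, 400, seed = 1))
#' fit <- fit_mortality(d)
#' coef(fit); confint(fit, method = "wald")
#' @export
fit_mortality <- function(data, alpha = ~1, beta = ~1, family = "gompertz",
                          structure = NULL, control = mortality_control()) {
  if (is.null(structure))
    structure <- model_structure(family, alpha_terms = alpha,
                                 beta_terms = beta)
  stopifnot(inherits(structure, "model_structure"))
  check_cohort_factors(data, union(structure$alpha_terms,
                                   structure$beta_terms))
  # canonical row order makes the likelihood sum (and so every output
  # bit) invariant to how the records were permuted on input
  keys <- list(data$lifespan_days)
  if ("diet" %in% names(data)) keys <- c(keys, list(data$diet))
  if ("mating" %in% names(data)) keys <- c(keys, list(data$mating))
  data <- data[do.call(order, keys), , drop = FALSE]
  ll <- mort_loglik_env(data, structure)

  starts <- mort_start_values(ll)
  vals <- vapply(starts, ll$nll, numeric(1))
  best_start <- starts[[which.min(vals)]]
  jitters <- with_seed(control$restart_seed, {
    lapply(seq_len(control$restarts), function(i)
      stats::rnorm(ll$npar, sd = control$jitter_sd))
  })
  start_set <- c(list(best_start),
                 lapply(jitters, function(j) best_start + j))

  simplex <- function(par, maxit) {
    if (length(par) == 1)
      stats::optim(par, ll$nll, method = "Brent", lower = par - 10,
                   upper = par + 10)
    else
      stats::optim(par, ll$nll, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = control$reltol))
  }
  best <- NULL
  for (st in start_set) {
    if (is.null(ll$gr)) {
      # derivative-free simplex stage, then numeric-gradient polish
      o1 <- tryCatch(simplex(st, 500), error = function(e) NULL)
      p1 <- if (is.null(o1)) st else o1$par
    } else p1 <- st
    o2 <- tryCatch(
      stats::optim(p1, ll$nll, gr = ll$gr, method = "BFGS",
                   control = list(maxit = 500, reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(o2)) next
    if (is.null(best) || o2$value < best$value - 1e-12) best <- o2
  }
  if (!is.null(best) && !is.null(ll$gr)) {
    # short simplex polish guards against a BFGS stall
    o3 <- tryCatch(simplex(best$par, 200), error = function(e) NULL)
    if (!is.null(o3) && o3$value < best$value)
      best <- stats::optim(o3$par, ll$nll, gr = ll$gr, method = "BFGS",
                           control = list(maxit = 500,
                                          reltol = control$reltol))
  }
  if (is.null(best))
    return(mort_fit_object(structure, ll, par = best_start, loglik = NA_real_,
                           vcov = NULL, converged = FALSE, data = data))
  converged <- is.finite(best$value) &&
    (is.null(best$convergence) || best$convergence == 0)
  H <- tryCatch(stats::optimHess(best$par, ll$nll, gr = ll$gr),
                error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V) && any(!is.finite(diag(V)) | diag(V) < 0)) V <- NULL
  mort_fit_object(structure, ll, par = best$par, loglik = -best$value,
                  vcov = V, converged = converged, data = data)
}

mort_fit_object <- function(structure, ll, par, loglik, vcov, converged,
                            data) {
  names(par) <- ll$pnames
  est <- exp(par)
  ci <- matrix(NA_real_, length(par), 2,
               dimnames = list(ll$pnames, c("lower", "upper")))
  if (!is.null(vcov)) {
    se <- sqrt(diag(vcov))
    z <- stats::qnorm(0.975)
    ci[, 1] <- exp(par - z * se)
    ci[, 2] <- exp(par + z * se)
    dimnames(vcov) <- list(ll$pnames, ll$pnames)
  }
  keep <- intersect(c("lifespan_days", "diet", "mating"), names(data))
  structure(list(structure = structure, coefficients = par, estimates = est,
                 ci95 = ci, vcov = vcov, loglik = loglik,
                 n_params = ll$npar, aic = 2 * ll$npar - 2 * loglik,
                 converged = converged, n_obs = length(ll$t),
                 model_data = data[keep]),
            class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, digits = 4, ...) {
  cat("Parametric mortality model (", structure_label(x$structure), ")\n",
      sep = "")
  cat("n =", x$n_obs, " logLik =", format(x$loglik, digits = 7),
      " AIC =", format(x$aic, digits = 7),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  tab <- cbind(estimate = x$estimates, x$ci95)
  print(signif(tab, digits))
  invisible(x)
}

#' @export
summary.mortality_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else
    rep(NA_real_, object$n_params)
  tab <- cbind(`log estimate` = object$coefficients, `SE(log)` = se,
               estimate = object$estimates, object$ci95)
  out <- list(structure = object$structure, table = tab,
              loglik = object$loglik, aic = object$aic,
              n_obs = object$n_obs, converged = object$converged)
  class(out) <- "summary.mortality_fit"
  out
}

#' @export
print.summary.mortality_fit <- function(x, digits = 4, ...) {
  cat("Parametric mortality model (", structure_label(x$structure), ")\n",
      sep = "")
  print(signif(x$table, digits))
  cat("n =", x$n_obs, " logLik =", format(x$loglik, digits = 7),
      " AIC =", format(x$aic, digits = 7),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  invisible(x)
}

#' @export
coef.mortality_fit <- function(object, scale = c("natural", "working"), ...) {
  scale <- match.arg(scale)
  if (scale == "natural") object$estimates else object$coefficients
}

#' @export
logLik.mortality_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.mortality_fit <- function(object, ...) object$vcov

#' Confidence intervals for mortality-model parameters
#'
#' Profile-likelihood intervals (default): each working-scale parameter is
#' profiled, the others re-optimized, and the bounds located where the
#' profiled deviance crosses the chi-squared(1) cutoff; bounds are
#' back-transformed to the natural scale. If a profile bound cannot be
#' bracketed, the Wald interval (normal approximation on the log scale,
#' exponentiated) is substituted with a warning.
#'
#' @param object a [fit_mortality()] result (converged).
#' @param parm parameter names (default all).
#' @param level confidence level.
#' @param method `"profile"` or `"wald"`.
#' @param ... unused.
#' @return matrix with columns `lower`, `upper` on the natural scale.
#' @export
confint.mortality_fit <- function(object, parm = NULL, level = 0.95,
                                  method = c("profile", "wald"), ...) {
  method <- match.arg(method)
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  pn <- names(object$coefficients)
  if (is.null(parm)) parm <- pn
  idx <- match(parm, pn)
  if (anyNA(idx)) stop("unknown parameter(s): ",
                       paste(parm[is.na(idx)], collapse = ", "), call. = FALSE)
  if (method == "wald") {
    out <- object$ci95[idx, , drop = FALSE]
    if (level != 0.95) {
      se <- sqrt(diag(object$vcov))[idx]
      z <- stats::qnorm(1 - (1 - level) / 2)
      out <- cbind(lower = exp(object$coefficients[idx] - z * se),
                   upper = exp(object$coefficients[idx] + z * se))
    }
    return(out)
  }
  ll <- mort_loglik_env(object$model_data, object$structure)
  mle <- object$coefficients
  nll0 <- -object$loglik
  cutoff <- stats::qchisq(level, df = 1) / 2
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else
    rep(0.5, length(mle))
  se[!is.finite(se) | se <= 0] <- 0.5

  warm <- mle
  prof_nll <- function(j, v) {
    if (length(mle) == 1) return(ll$nll(v))
    others <- warm[-j]
    fn <- function(q) {
      p <- numeric(length(mle)); p[j] <- v; p[-j] <- q
      ll$nll(p)
    }
    gn <- if (!is.null(ll$gr)) function(q) {
      p <- numeric(length(mle)); p[j] <- v; p[-j] <- q
      ll$gr(p)[-j]
    }
    o <- tryCatch(stats::optim(others, fn, gr = gn, method = "BFGS",
                               control = list(maxit = 300, reltol = 1e-10)),
                  error = function(e) NULL)
    if (is.null(o)) return(Inf)
    warm[-j] <<- o$par   # warm-start the next profile point
    o$value
  }

  one_bound <- function(j, dir) {
    warm <<- mle
    f <- function(v) prof_nll(j, v) - nll0 - cutoff
    step <- 2 * se[j]
    lo <- mle[j]; flo <- -cutoff
    for (k in 1:40) {
      hi <- mle[j] + dir * step
      fhi <- f(hi)
      if (is.finite(fhi) && fhi > 0) {
        r <- stats::uniroot(f, lower = min(lo, hi), upper = max(lo, hi),
                            f.lower = if (dir > 0) flo else fhi,
                            f.upper = if (dir > 0) fhi else flo,
                            tol = 1e-7)
        return(r$root)
      }
      if (is.finite(fhi)) { lo <- hi; flo <- fhi }
      step <- step * 1.7
    }
    NA_real_
  }

  out <- matrix(NA_real_, length(idx), 2,
                dimnames = list(pn[idx], c("lower", "upper")))
  for (i in seq_along(idx)) {
    j <- idx[i]
    b <- c(one_bound(j, -1), one_bound(j, +1))
    if (anyNA(b)) {
      warning("profile bound for '", pn[j],
              "' could not be bracketed; using Wald interval")
      b <- c(mle[j] - stats::qnorm(1 - (1 - level) / 2) * se[j],
             mle[j] + stats::qnorm(1 - (1 - level) / 2) * se[j])
    }
    out[i, ] <- exp(b)
  }
  out
}

# hazard_spec for one treatment cell of a fitted model
cell_spec <- function(fit, diet = "C", mating = "mated") {
  st <- fit$structure
  nd <- data.frame(diet = diet, mating = mating)
  xa <- structure_design(nd, st$alpha_terms)
  fam <- st$family
  ka <- ncol(xa)
  par <- fit$coefficients
  p1 <- exp(drop(xa %*% par[seq_len(ka)]))
  if (fam == "constant") return(hazard_spec("constant", alpha = p1))
  xb <- structure_design(nd, st$beta_terms)
  kb <- ncol(xb)
  p2 <- exp(drop(xb %*% par[ka + seq_len(kb)]))
  extras <- par[-seq_len(ka + kb)]
  args <- list(fam)
  if (fam == "weibull") {
    args$a <- p1; args$b <- p2
  } else {
    args$alpha <- p1; args$beta <- p2
  }
  for (nm in names(extras)) args[[nm]] <- exp(extras[[nm]])
  do.call(hazard_spec, args)
}

#' Predictions from a fitted mortality model
#'
#' @param object a `mortality_fit`.
#' @param newdata data.frame of treatment cells (columns `diet`, `mating`
#'   as required by the structure); defaults to the distinct cells of the
#'   fitting data.
#' @param ages ages (days) at which to evaluate `hazard`/`survival`;
#'   recycled against rows of `newdata` only if one of them has length 1.
#' @param type `"hazard"`, `"survival"`, or `"quantile"` (then `ages` is a
#'   probability in (0,1)).
#' @param ... unused.
#' @return data.frame of predictions, one row per cell x age.
#' @export
predict.mortality_fit <- function(object, newdata = NULL, ages = NULL,
                                  type = c("hazard", "survival", "quantile"),
                                  ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    used <- intersect(c("diet", "mating"), names(object$model_data))
    newdata <- if (length(used)) unique(object$model_data[used]) else
      data.frame(row.names = 1)
  }
  if (is.null(ages)) ages <- if (type == "quantile") 0.5 else 0
  out <- do.call(rbind, lapply(seq_len(nrow(newdata)), function(i) {
    sp <- cell_spec(object,
                    diet = if ("diet" %in% names(newdata))
                      newdata$diet[i] else "C",
                    mating = if ("mating" %in% names(newdata))
                      newdata$mating[i] else "mated")
    val <- switch(type,
      hazard = hazard(sp, ages),
      survival = survival(sp, ages),
      quantile = quantile(sp, probs = ages))
    cbind(newdata[rep(i, length(ages)), , drop = FALSE],
          data.frame(at = ages, value = val))
  }))
  rownames(out) <- NULL
  names(out)[names(out) == "at"] <-
    if (type == "quantile") "prob" else "age_days"
  out
}

#' Simulate death times from a fitted mortality model
#'
#' Draws one death time per row of `newdata` (default: the fitting data's
#' treatment rows), by inverse-CDF sampling from each row's fitted hazard.
#'
#' @param object a `mortality_fit`.
#' @param nsim number of simulated cohorts (columns).
#' @param seed integer seed (required).
#' @param newdata rows defining treatment cells; default = fitting data.
#' @param ... unused.
#' @return data.frame with `nsim` columns `sim_1`, ... of ages in days.
#' @export
simulate.mortality_fit <- function(object, nsim = 1, seed = NULL,
                                   newdata = NULL, ...) {
  if (is.null(seed)) stop("'seed' is required", call. = FALSE)
  if (is.null(newdata)) newdata <- object$model_data
  n <- nrow(newdata)
  used <- intersect(c("diet", "mating"), names(newdata))
  cells <- if (length(used)) unique(newdata[used]) else
    data.frame(row.names = 1)
  U <- with_seed(seed, matrix(stats::runif(n * nsim), n, nsim))
  out <- matrix(NA_real_, n, nsim)
  for (i in seq_len(nrow(cells))) {
    sp <- cell_spec(object,
                    diet = if ("diet" %in% used) cells$diet[i] else "C",
                    mating = if ("mating" %in% used) cells$mating[i] else
                      "mated")
    rows <- if (length(used)) {
      sel <- rep(TRUE, n)
      for (cn in used) sel <- sel & newdata[[cn]] == cells[[cn]][i]
      which(sel)
    } else seq_len(n)
    for (j in seq_len(nsim)) out[rows, j] <- quantile(sp, probs = U[rows, j])
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Cox-Snell residuals of a fitted mortality model
#'
#' The fitted cumulative hazard evaluated at each observed death time; if
#' the model is correct these are a unit-exponential sample.
#'
#' @param object a `mortality_fit`.
#' @param ... unused.
#' @export
residuals.mortality_fit <- function(object, ...) {
  ll <- mort_loglik_env(object$model_data, object$structure)
  # cumulative hazard = -(log density - log hazard); reconstruct per row
  d <- object$model_data
  used <- intersect(c("diet", "mating"), names(d))
  out <- numeric(nrow(d))
  cells <- if (length(used)) unique(d[used]) else data.frame(row.names = 1)
  for (i in seq_len(nrow(cells))) {
    sp <- cell_spec(object,
                    diet = if ("diet" %in% used) cells$diet[i] else "C",
                    mating = if ("mating" %in% used) cells$mating[i] else
                      "mated")
    sel <- rep(TRUE, nrow(d))
    for (cn in used) sel <- sel & d[[cn]] == cells[[cn]][i]
    out[sel] <- cumhaz(sp, d$lifespan_days[sel])
  }
  out
}

#' Diagnostic survival plot for a fitted mortality model
#'
#' Overlays the fitted survivor function (per treatment cell) on the
#' empirical survival (1 - ECDF) of the data.
#'
#' @param x a `mortality_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mortality_fit <- function(x, ...) {
  d <- x$model_data
  used <- intersect(c("diet", "mating"), names(d))
  cells <- if (length(used)) unique(d[used]) else data.frame(row.names = 1)
  tmax <- max(d$lifespan_days) * 1.05
  graphics::plot(NA, xlim = c(0, tmax), ylim = c(0, 1),
                 xlab = "adult age (days)", ylab = "survival", ...)
  ages <- seq(0, tmax, length.out = 200)
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(d))
    for (cn in used) sel <- sel & d[[cn]] == cells[[cn]][i]
    ti <- sort(d$lifespan_days[sel])
    graphics::lines(stats::stepfun(ti, c(1, 1 - seq_along(ti) / length(ti))),
                    do.points = FALSE, col = "grey50")
    sp <- cell_spec(x,
                    diet = if ("diet" %in% used) cells$diet[i] else "C",
                    mating = if ("mating" %in% used) cells$mating[i] else
                      "mated")
    graphics::lines(ages, survival(sp, ages), col = i + 1, lwd = 2)
  }
  invisible(x)
}
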