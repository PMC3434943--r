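#' Term sets for the calling-effort model
#'
#' Term labels are colon-separated products of the components `diet`
#' (indicator of diet P), `mating` (indicator of virgin), `age`, `age2`,
#' `lifespan`, `lifespan2` (ages and lifespans in days), plus
#' `"intercept"`. Baseline coding: diet = C, mating = mated, so each
#' coefficient is the change relative to a mated male on diet C.
#'
#' `calling_terms_best()` is the best-fit fixed-effect structure for
#' nightly calling effort: intercept, diet, mating, age, lifespan, age^2,
#' lifespan^2, diet:age, diet:age^2, age:lifespan. `calling_terms_full()`
#' is the full candidate structure with the diet x mating x age(^2)
#' three-way interactions, the lifespan(^2) x diet/mating/age two-way
#' interactions, and all lower-order terms.
#'
#' @return character vector of term labels.
#' @export
calling_terms_best <- function() {
  c("intercept", "diet", "mating", "age", "lifespan", "age2", "lifespan2",
    "diet:age", "diet:age2", "age:lifespan")
}

#' @rdname calling_terms_best
#' @export
calling_terms_full <- function() {
  c("intercept", "diet", "mating", "age", "age2", "lifespan", "lifespan2",
    "diet:mating", "diet:age", "mating:age", "diet:age2", "mating:age2",
    "diet:mating:age", "diet:mating:age2",
    "lifespan:diet", "lifespan:mating", "lifespan:age",
    "lifespan2:diet", "lifespan2:mating", "lifespan2:age")
}

calling_component <- function(nm, data) {
  switch(nm,
    diet      = as.numeric(data$diet == "P"),
    mating    = as.numeric(data$mating == "virgin"),
    age       = data$age_days,
    age2      = data$age_days^2,
    lifespan  = data$lifespan_days,
    lifespan2 = data$lifespan_days^2,
    stop("unknown term component '", nm, "'", call. = FALSE))
}

#' Build the fixed-effect design matrix for calling-effort models
#'
#' @param data data.frame with columns `age_days`, `lifespan_days`, and
#'   (when referenced) `diet`, `mating`.
#' @param terms character vector of term labels (see
#'   [calling_terms_best()]).
#' @return numeric matrix, one column per term, in the given order.
#' @export
build_calling_design <- function(data, terms = calling_terms_best()) {
  n <- nrow(data)
  cols <- lapply(terms, function(tm) {
    if (tm == "intercept") return(rep(1, n))
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, calling_component, data = data))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

# Profiled Gaussian random-intercept likelihood. For a fixed variance
# ratio theta = sigma_u^2 / sigma_e^2, V_i = I + theta J has
# V_i^{-1} = I - theta/(1 + n_i theta) J, so the GLS normal equations and
# the profiled sigma_e^2 are closed-form from group-wise sums; the fit is
# a 1-D optimization over log(theta).
lmm_profile <- function(X, y, group, theta, reml = FALSE) {
  N <- length(y); p <- ncol(X)
  S <- rowsum(X, group)               # group sums of columns
  m <- rowsum(y, group)[, 1]
  ni <- as.vector(table(group)[rownames(S)])
  w <- theta / (1 + ni * theta)
  A <- crossprod(X) - crossprod(S * sqrt(w))
  b <- drop(crossprod(X, y)) - drop(crossprod(S, w * m))
  beta <- solve(A, b)
  r <- y - drop(X %*% beta)
  rs <- rowsum(r, group)[, 1]
  rss <- sum(r^2) - sum(w * rs^2)
  logdet <- sum(log1p(ni * theta))
  if (reml) {
    s2 <- rss / (N - p)
    ll <- -0.5 * ((N - p) * log(2 * pi * s2) + logdet +
                    determinant(A, logarithm = TRUE)$modulus[1] -
                    p * log(s2) + (N - p))
  } else {
    s2 <- rss / N
    ll <- -0.5 * (N * log(2 * pi * s2) + logdet + N)
  }
  list(beta = beta, s2 = s2, loglik = ll, A = A, ni = ni, w = w, resid = r,
       rs = rs)
}

#' Fit a random-intercept Gaussian mixed model by maximum likelihood
#'
#' The engine behind [fit_calling_lmm()]: a Gaussian linear mixed model
#' with one random intercept per group, fit by (profiled) maximum
#' likelihood implemented in this package. For each candidate variance
#' ratio \eqn{\theta = \sigma_u^2/\sigma_e^2} the fixed effects and
#' \eqn{\sigma_e^2} have closed-form generalized-least-squares solutions,
#' leaving a one-dimensional optimization over \eqn{\log\theta}. ML is the
#' default so that AIC comparisons across fixed-effect structures are
#' valid; `reml = TRUE` is available but REML criteria must not be
#' compared across different fixed-effect structures (a warning is
#' emitted).
#'
#' @param X fixed-effect design matrix (full column rank).
#' @param y response vector.
#' @param group grouping factor (one random intercept per level; >= 2
#'   levels).
#' @param reml use REML instead of ML.
#' @return object of class `calling_lmm`: `coefficients`, `se`, `sigma_u`,
#'   `sigma_e`, `theta`, `loglik`, `aic`, `n_params`, `n_obs`, `n_groups`,
#'   `boundary` (TRUE when the variance-ratio optimum is at 0, i.e. the
#'   model degenerates to ordinary least squares), `fitted`, `residuals`
#'   (marginal), `ranef` (empirical-Bayes group intercepts).
#' @export
fit_lmm <- function(X, y, group, reml = FALSE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(group) == length(y))
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("need >= 2 groups for a random intercept", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (reml)
    warning("REML criteria are not comparable across fixed-effect ",
            "structures; use ML for AIC-based model selection")
  obj <- function(lt) -lmm_profile(X, y, group, exp(lt), reml = reml)$loglik
  opt <- stats::optimize(obj, interval = c(-20, 10), tol = 1e-9)
  at0 <- lmm_profile(X, y, group, 0, reml = reml)
  theta <- exp(opt$minimum)
  fit <- lmm_profile(X, y, group, theta, reml = reml)
  boundary <- FALSE
  if (at0$loglik >= fit$loglik - 1e-10) {
    theta <- 0; fit <- at0; boundary <- TRUE
  }
  se <- sqrt(fit$s2 * diag(solve(fit$A)))
  coefs <- fit$beta
  names(coefs) <- names(se) <- colnames(X)
  # empirical-Bayes (BLUP) group intercepts: shrunken group residual means
  u <- fit$w * fit$rs
  n_params <- ncol(X) + 2L
  fitted_marg <- drop(X %*% coefs)
  structure(list(coefficients = coefs, se = se,
                 sigma_u = sqrt(theta * fit$s2), sigma_e = sqrt(fit$s2),
                 theta = theta, loglik = fit$loglik,
                 aic = 2 * n_params - 2 * fit$loglik, n_params = n_params,
                 n_obs = length(y), n_groups = nlevels(droplevels(group)),
                 boundary = boundary, reml = reml,
                 fitted = fitted_marg, residuals = y - fitted_marg,
                 ranef = u, group = group),
            class = "calling_lmm")
}

#' Fit the calling-effort mixed model to longitudinal data
#'
#' Nightly calling effort (seconds per night) as a Gaussian function of
#' age, lifespan, diet and mating treatment with a random intercept per
#' male (which also absorbs within-individual temporal autocorrelation).
#' Lifespan terms let the model separate within-individual age trajectories
#' from selective disappearance of short-lived males.
#'
#' @param data data.frame with columns `id`, `age_days`, `calling_s`,
#'   `diet`, `mating`, `lifespan_days` (one row per male-night), e.g. the
#'   join produced by [join_calling()].
#' @param terms fixed-effect term labels, see [calling_terms_best()].
#' @param reml passed to [fit_lmm()].
#' @return a `calling_lmm` object (see [fit_lmm()]) with the term list
#'   attached.
#' @export
fit_calling_lmm <- function(data, terms = calling_terms_best(),
                            reml = FALSE) {
  need <- c("id", "age_days", "calling_s", "lifespan_days")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  X <- build_calling_design(data, terms)
  fit <- fit_lmm(X, data$calling_s, data$id, reml = reml)
  fit$terms <- terms
  fit
}

#' @export
print.calling_lmm <- function(x, digits = 4, ...) {
  cat("Random-intercept Gaussian mixed model (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat("n_obs =", x$n_obs, " groups =", x$n_groups,
      " logLik =", format(x$loglik, digits = 7),
      " AIC =", format(x$aic, digits = 7), "\n")
  cat("sigma_u =", signif(x$sigma_u, digits),
      " sigma_e =", signif(x$sigma_e, digits),
      if (x$boundary) " [variance ratio at boundary 0]", "\n")
  print(signif(cbind(estimate = x$coefficients, se = x$se), digits))
  invisible(x)
}

#' @export
summary.calling_lmm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(estimate = object$coefficients, se = object$se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  out <- list(table = tab, sigma_u = object$sigma_u,
              sigma_e = object$sigma_e, loglik = object$loglik,
              aic = object$aic, n_obs = object$n_obs,
              n_groups = object$n_groups, boundary = object$boundary,
              reml = object$reml)
  class(out) <- "summary.calling_lmm"
  out
}

#' @export
print.summary.calling_lmm <- function(x, digits = 4, ...) {
  cat("Random-intercept Gaussian mixed model (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  print(signif(x$table, digits))
  cat("sigma_u =", signif(x$sigma_u, digits),
      " sigma_e =", signif(x$sigma_e, digits), "\n")
  cat("n_obs =", x$n_obs, " groups =", x$n_groups,
      " logLik =", format(x$loglik, digits = 7),
      " AIC =", format(x$aic, digits = 7), "\n")
  invisible(x)
}

#' @export
coef.calling_lmm <- function(object, ...) object$coefficients

#' @export
logLik.calling_lmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.calling_lmm <- function(object, ...) object$fitted

#' Residuals of the calling-effort mixed model
#'
#' @param object a `calling_lmm`.
#' @param type `"marginal"` (response minus fixed-effect prediction) or
#'   `"conditional"` (also subtracting the empirical-Bayes group
#'   intercept).
#' @param ... unused.
#' @export
residuals.calling_lmm <- function(object,
                                  type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "conditional")
    r <- r - object$ranef[as.character(object$group)]
  unname(r)
}

#' Empirical-Bayes random intercepts
#'
#' @param object a `calling_lmm`.
#' @return named numeric vector, one shrunken intercept per group.
#' @export
random_intercepts <- function(object) {
  stopifnot(inherits(object, "calling_lmm"))
  object$ranef
}

#' @export
predict.calling_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.null(object$terms))
    stop("fit has no term list; predict requires fit_calling_lmm()",
         call. = FALSE)
  drop(build_calling_design(newdata, object$terms) %*% object$coefficients)
}

#' Compare candidate fixed-effect structures for calling effort
#'
#' Fits each candidate term list to the same rows by ML and ranks by AIC
#' with \eqn{\Delta}AIC and Akaike weights (the same arithmetic as the
#' mortality battery). Candidates whose fit fails are retained with NA
#' values and excluded from the weights.
#'
#' @param data as in [fit_calling_lmm()].
#' @param candidates named list of term-label vectors.
#' @return object of class `calling_comparison`: ranked `table`
#'   (candidate, k, loglik, aic, delta_aic, weight) and `fits`.
#' @export
compare_calling_models <- function(data, candidates) {
  stopifnot(length(candidates) >= 1)
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model_", seq_along(candidates))
  fits <- lapply(candidates, function(tm)
    tryCatch(fit_calling_lmm(data, terms = tm),
             error = function(e) { warning(conditionMessage(e)); NULL }))
  ll <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$loglik,
               numeric(1))
  k <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$n_params,
              numeric(1))
  aic <- 2 * k - 2 * ll
  ord <- order(ifelse(is.finite(aic), aic, Inf), k)
  tab <- data.frame(candidate = names(candidates)[ord], k = k[ord],
                    loglik = ll[ord], aic = aic[ord],
                    delta_aic = aic[ord] - min(aic[ord], na.rm = TRUE),
                    weight = akaike_weights(aic[ord]),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fits = fits[ord]),
            class = "calling_comparison")
}

#' @export
print.calling_comparison <- function(x, digits = 4, ...) {
  cat("Calling-effort model comparison (ML/AIC):\n")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 2)
  tab$aic <- round(tab$aic, 2)
  tab$delta_aic <- round(tab$delta_aic, 2)
  tab$weight <- signif(tab$weight, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
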