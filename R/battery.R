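#' Akaike weights from AIC values
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min AIC}. Invariant to adding a constant to
#' every AIC.
#'
#' @param aic numeric vector of AIC values (NA allowed; excluded and
#'   returned as NA weight).
#' @return numeric vector of weights summing to 1 over the non-NA entries.
#' @export
akaike_weights <- function(aic) {
  out <- rep(NA_real_, length(aic))
  ok <- is.finite(aic)
  if (!any(ok)) return(out)
  d <- aic[ok] - min(aic[ok])
  w <- exp(-d / 2)
  out[ok] <- w / sum(w)
  out
}

#' Fit and compare a battery of treatment-structured mortality models
#'
#' Fits every candidate [model_structure()] to the same cohort by maximum
#' likelihood and ranks them by AIC (\eqn{2k - 2\ell}), reporting
#' \eqn{\Delta}AIC and Akaike weights. Ties in AIC are broken in favour of
#' fewer parameters. Non-converged fits are retained and flagged but
#' excluded from weight normalization, with a warning. AICc is available
#' behind a flag; small-sample correction is not the default because plain
#' AIC is the standard in this literature's model batteries.
#'
#' @param data cohort data.frame (one sex at a time is the intended use;
#'   see [sex_lrt()] for the pooled-versus-sex-stratified test).
#' @param structures list of [model_structure()]; default
#'   [enumerate_structures()] — 25 Gompertz structures plus the
#'   constant-hazard "no senescence" model.
#' @param control optimizer settings, see [mortality_control()].
#' @param aicc use the small-sample corrected AICc for ranking?
#' @return an object of class `mortality_battery`: `table` (ranked
#'   data.frame: label, k, loglik, aic, delta_aic, weight, converged),
#'   `fits` (in table order), `best` (the top fit).
#' @export
run_battery <- function(data, structures = enumerate_structures(),
                        control = mortality_control(), aicc = FALSE) {
  stopifnot(length(structures) >= 1)
  fits <- lapply(structures, function(st)
    fit_mortality(data, structure = st, control = control))
  k <- vapply(fits, function(f) f$n_params, numeric(1))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  aic <- 2 * k - 2 * ll
  if (aicc) {
    n <- nrow(data)
    aic <- aic + 2 * k * (k + 1) / pmax(n - k - 1, 1)
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv))
    warning(sum(!conv), " fit(s) did not converge; excluded from weights")
  rank_aic <- ifelse(conv, aic, Inf)
  ord <- order(rank_aic, k)  # AIC ties broken by fewer parameters
  fits <- fits[ord]
  tab <- data.frame(
    label = vapply(fits, function(f) structure_label(f$structure),
                   character(1)),
    k = k[ord], loglik = ll[ord], aic = aic[ord],
    delta_aic = aic[ord] - min(aic[ord][conv[ord]]),
    weight = akaike_weights(ifelse(conv[ord], aic[ord], NA_real_)),
    converged = conv[ord],
    stringsAsFactors = FALSE)
  structure(list(table = tab, fits = fits, best = fits[[1]]),
            class = "mortality_battery")
}

#' @export
print.mortality_battery <- function(x, n = 10, digits = 4, ...) {
  cat("Mortality model battery:", nrow(x$table), "models, best =",
      x$table$label[1], "\n")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 2)
  tab$aic <- round(tab$aic, 2)
  tab$delta_aic <- round(tab$delta_aic, 2)
  tab$weight <- signif(tab$weight, 3)
  print(utils::head(tab, n), row.names = FALSE)
  if (nrow(tab) > n) cat("... and", nrow(tab) - n, "more\n")
  invisible(x)
}

#' Likelihood-ratio test between nested mortality models
#'
#' Twice the difference in maximized log-likelihoods, referred to a
#' chi-squared distribution with degrees of freedom equal to the
#' difference in parameter counts.
#'
#' @param full,reduced converged [fit_mortality()] results; `reduced` must
#'   be nested in `full` (same family with term subsets, or the
#'   constant-hazard model against a Gompertz-family model).
#' @param tol tolerance on a slightly negative statistic before it is
#'   treated as an optimizer failure.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced, tol = 1e-4) {
  stopifnot(inherits(full, "mortality_fit"), inherits(reduced, "mortality_fit"))
  if (!is_nested(reduced$structure, full$structure))
    stop("'reduced' is not nested in 'full'", call. = FALSE)
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -tol)
    stop("log-likelihood of the full model is below the reduced model's ",
         "(difference ", format(stat / 2), "); optimizer failure",
         call. = FALSE)
  stat <- max(stat, 0)
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("'full' has fewer parameters than 'reduced'",
                   call. = FALSE)
  # identical models: degenerate chi-square, statistic 0, p = 1
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

is_nested <- function(reduced, full) {
  if (reduced$family == full$family)
    return(all(reduced$alpha_terms %in% full$alpha_terms) &&
             all(reduced$beta_terms %in% full$beta_terms))
  # constant hazard sits on the beta -> 0 boundary of the Gompertz families
  reduced$family == "constant" &&
    full$family %in% c("gompertz", "gompertz_makeham") &&
    all(reduced$alpha_terms %in% full$alpha_terms)
}

#' Pooled-versus-sex-stratified likelihood-ratio test
#'
#' Compares the full Gompertz model with diet x mating x sex effects on
#' both parameters (equivalent to fitting the full diet x mating model
#' separately in each sex and summing log-likelihoods) against the same
#' full diet x mating model fit to the pooled sexes. A small p-value
#' supports analysing the sexes in separate model batteries.
#'
#' @param data cohort data.frame with columns `sex` (male/female), `diet`,
#'   `mating`, `lifespan_days`.
#' @param control see [mortality_control()].
#' @return list with `statistic`, `df`, `p_value`, and the per-sex and
#'   pooled fits.
#' @export
sex_lrt <- function(data, control = mortality_control()) {
  stopifnot("sex" %in% names(data))
  full_st <- model_structure("gompertz",
                             alpha_terms = c("diet", "mating", "diet:mating"),
                             beta_terms = c("diet", "mating", "diet:mating"))
  by_sex <- lapply(split(data, data$sex), fit_mortality,
                   structure = full_st, control = control)
  pooled <- fit_mortality(data, structure = full_st, control = control)
  ll_sexed <- sum(vapply(by_sex, function(f) f$loglik, numeric(1)))
  k_sexed <- sum(vapply(by_sex, function(f) f$n_params, numeric(1)))
  stat <- max(2 * (ll_sexed - pooled$loglik), 0)
  df <- k_sexed - pooled$n_params
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       fits_by_sex = by_sex, fit_pooled = pooled)
}
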