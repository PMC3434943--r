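#' Parametric hazard specifications
#'
#' Construct a hazard specification for one of the six mortality families
#' used in demographic analyses of actuarial senescence: constant
#' (exponential, "no senescence"), Gompertz, Gompertz-Makeham, logistic,
#' logistic-Makeham, and Weibull. Ages are continuous non-negative adult
#' ages in days (day 0 = eclosion), so all rate parameters are per day.
#'
#' Parameterizations follow the standard demographic forms:
#' \itemize{
#'   \item constant: \eqn{\mu(x) = \alpha}
#'   \item gompertz: \eqn{\mu(x) = \alpha e^{\beta x}} — \eqn{\alpha} is the
#'     baseline mortality rate (hazard at adult age 0), \eqn{\beta} the rate
#'     of ageing.
#'   \item gompertz_makeham: \eqn{\mu(x) = c + \alpha e^{\beta x}} with an
#'     age-independent Makeham term \eqn{c \ge 0}.
#'   \item logistic: \eqn{\mu(x) = \alpha e^{\beta x} /
#'     (1 + (s\alpha/\beta)(e^{\beta x} - 1))}; the shape \eqn{s \ge 0}
#'     controls late-age deceleration and \eqn{s \to 0} recovers Gompertz.
#'   \item logistic_makeham: the logistic hazard plus \eqn{c}.
#'   \item weibull: \eqn{\mu(x) = a b x^{b-1}}.
#' }
#'
#' @param family one of `"constant"`, `"gompertz"`, `"gompertz_makeham"`,
#'   `"logistic"`, `"logistic_makeham"`, `"weibull"`.
#' @param alpha baseline mortality rate (day^-1); required by all families
#'   except weibull.
#' @param beta rate of ageing (day^-1); required by the Gompertz and
#'   logistic families.
#' @param c Makeham age-independent hazard (day^-1, `>= 0`); Makeham
#'   families only.
#' @param s logistic deceleration shape (dimensionless, `>= 0`); logistic
#'   families only.
#' @param a,b Weibull scale (day^-b) and shape (dimensionless).
#' @return an object of class `hazard_spec`.
#' @examples
#' sp <- hazard_spec("gompertz", alpha = 0.0101, beta = 0.0264)
#' hazard(sp, 0)         # = alpha
#' survival(sp, c(0, 30, 60))
#' quantile(sp, 0.5)     # median adult lifespan in days
#' @export
hazard_spec <- function(family = c("gompertz", "constant", "gompertz_makeham",
                                   "logistic", "logistic_makeham", "weibull"),
                        alpha = NULL, beta = NULL, c = NULL, s = NULL,
                        a = NULL, b = NULL) {
  family <- match.arg(family)
  want <- hazard_param_names(family)
  given <- list(alpha = alpha, beta = beta, c = c, s = s, a = a, b = b)
  params <- vapply(want, function(nm) {
    v <- given[[nm]]
    if (is.null(v)) stop("family '", family, "' requires parameter '", nm, "'",
                         call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  extra <- setdiff(names(Filter(Negate(is.null), given)), want)
  if (length(extra))
    stop("parameter(s) ", paste0("'", extra, "'", collapse = ", "),
         " not used by family '", family, "'", call. = FALSE)
  validate_hazard_params(family, params)
  structure(list(family = family, params = params), class = "hazard_spec")
}

hazard_param_names <- function(family) {
  switch(family,
    constant         = "alpha",
    gompertz         = c("alpha", "beta"),
    gompertz_makeham = c("alpha", "beta", "c"),
    logistic         = c("alpha", "beta", "s"),
    logistic_makeham = c("alpha", "beta", "s", "c"),
    weibull          = c("a", "b"),
    stop("unknown hazard family '", family, "'", call. = FALSE))
}

validate_hazard_params <- function(family, params) {
  for (nm in names(params)) {
    v <- params[[nm]]
    if (!is.finite(v)) stop("parameter '", nm, "' must be finite", call. = FALSE)
    if (nm %in% c("c", "s")) {
      if (v < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
    } else if (v <= 0) stop("parameter '", nm, "' must be > 0", call. = FALSE)
  }
  invisible(params)
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat("<hazard_spec> family:", x$family, "\n")
  print(x$params)
  invisible(x)
}

#' @export
as.list.hazard_spec <- function(x, ...) {
  list(family = x$family, params = as.list(x$params))
}

check_age <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("age 'x' must be finite and >= 0", call. = FALSE)
  x
}

# expm1(beta*x)/beta, continuous limit x as beta -> 0; the workhorse of the
# Gompertz cumulative hazard (alpha * gfun = integral of alpha*exp(beta*u)).
gfun <- function(beta, x) {
  if (beta < 1e-10) x else expm1(beta * x) / beta
}

#' Hazard, survival and log-density of a hazard specification
#'
#' `hazard()` evaluates the instantaneous mortality rate (force of
#' mortality) at adult age `x`; `survival()` the survivor function
#' \eqn{S(x) = \exp(-\int_0^x \mu(u)\,du)}; `cumhaz()` the cumulative
#' hazard; `log_density()` the log of the death-time density
#' \eqn{\log \mu(x) + \log S(x)}.
#'
#' @param spec a [hazard_spec()].
#' @param x vector of ages in days, `>= 0`.
#' @return numeric vector, same length as `x`.
#' @export
hazard <- function(spec, x) {
  stopifnot(inherits(spec, "hazard_spec"))
  check_age(x)
  p <- spec$params
  switch(spec$family,
    constant = rep_len(p[["alpha"]], length(x)),
    gompertz = p[["alpha"]] * exp(p[["beta"]] * x),
    gompertz_makeham = p[["c"]] + p[["alpha"]] * exp(p[["beta"]] * x),
    logistic = logistic_haz(p[["alpha"]], p[["beta"]], p[["s"]], x),
    logistic_makeham = p[["c"]] +
      logistic_haz(p[["alpha"]], p[["beta"]], p[["s"]], x),
    weibull = p[["a"]] * p[["b"]] * x^(p[["b"]] - 1))
}

logistic_haz <- function(alpha, beta, s, x) {
  if (s < 1e-10) return(alpha * exp(beta * x))
  alpha * exp(beta * x) / (1 + s * alpha * gfun(beta, x))
}

#' @rdname hazard
#' @export
survival <- function(spec, x) exp(-cumhaz(spec, x))

#' @rdname hazard
#' @export
cumhaz <- function(spec, x) {
  stopifnot(inherits(spec, "hazard_spec"))
  check_age(x)
  p <- spec$params
  switch(spec$family,
    constant = p[["alpha"]] * x,
    gompertz = p[["alpha"]] * gfun(p[["beta"]], x),
    gompertz_makeham = p[["c"]] * x + p[["alpha"]] * gfun(p[["beta"]], x),
    logistic = logistic_cumhaz(p[["alpha"]], p[["beta"]], p[["s"]], x),
    logistic_makeham = p[["c"]] * x +
      logistic_cumhaz(p[["alpha"]], p[["beta"]], p[["s"]], x),
    weibull = p[["a"]] * x^p[["b"]])
}

logistic_cumhaz <- function(alpha, beta, s, x) {
  g <- gfun(beta, x)
  if (s < 1e-10) return(alpha * g)
  log1p(s * alpha * g) / s
}

#' @rdname hazard
#' @export
log_density <- function(spec, x) {
  log(hazard(spec, x)) - cumhaz(spec, x)
}

#' Quantiles of the death-time distribution
#'
#' Inverts the survivor function: returns the age `t` with
#' `1 - survival(t) = p`. Closed forms are used for the constant, Gompertz,
#' logistic and Weibull families; the Makeham families are solved by
#' bracketed root-finding on the cumulative hazard.
#'
#' @param x a [hazard_spec()].
#' @param probs probabilities in (0, 1).
#' @param ... unused.
#' @return ages in days, same length as `probs`.
#' @export
quantile.hazard_spec <- function(x, probs = c(0.25, 0.5, 0.75), ...) {
  spec <- x
  if (any(probs <= 0) || any(probs >= 1))
    stop("'probs' must lie strictly in (0, 1)", call. = FALSE)
  u <- -log1p(-probs)  # target cumulative hazard
  p <- spec$params
  out <- switch(spec$family,
    constant = u / p[["alpha"]],
    gompertz = inv_gomp_cumhaz(p[["alpha"]], p[["beta"]], u),
    logistic = {
      s <- p[["s"]]
      if (s < 1e-10) inv_gomp_cumhaz(p[["alpha"]], p[["beta"]], u)
      else {
        g <- expm1(s * u) / (s * p[["alpha"]])
        if (p[["beta"]] < 1e-10) g else log1p(p[["beta"]] * g) / p[["beta"]]
      }
    },
    weibull = (u / p[["a"]])^(1 / p[["b"]]),
    # Makeham families: monotone cumulative hazard, bracketed root-finding
    vapply(u, function(ui) {
      upper <- 1
      while (cumhaz(spec, upper) < ui) upper <- upper * 2
      stats::uniroot(function(t) cumhaz(spec, t) - ui,
                     lower = 0, upper = upper, tol = 1e-12)$root
    }, numeric(1)))
  unname(out)
}

inv_gomp_cumhaz <- function(alpha, beta, u) {
  if (beta < 1e-10) u / alpha else log1p(beta * u / alpha) / beta
}

#' Simulate death times from a hazard specification
#'
#' Draws i.i.d. adult ages at death by inverse-CDF sampling; the same seed
#' always reproduces the same draws (the caller's RNG state is preserved).
#'
#' @param spec a [hazard_spec()].
#' @param n number of deaths to draw.
#' @param seed integer seed (required, for reproducibility).
#' @return numeric vector of `n` positive ages in days.
#' @export
simulate_death_times <- function(spec, n, seed) {
  stopifnot(inherits(spec, "hazard_spec"), n >= 1)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for reproducible simulation", call. = FALSE)
  u <- with_seed(seed, stats::runif(n))
  quantile(spec, probs = u)
}

#' @export
simulate.hazard_spec <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_death_times(object, n = nsim, seed = seed)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
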