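#' Treatment structures on hazard parameters
#'
#' A `model_structure` records which treatment factors (diet, mating, and
#' their interaction) act on each of the two leading hazard parameters —
#' baseline mortality (Gompertz \eqn{\alpha}, Weibull scale) and rate of
#' ageing (Gompertz \eqn{\beta}, Weibull shape). Effects enter
#' multiplicatively on the natural scale (additively on the log working
#' scale), with baseline levels diet = C and mating = mated. Term sets obey
#' hierarchical marginality: `"diet:mating"` is only allowed when both main
#' effects are present. The constant-hazard ("no senescence") family has a
#' single parameter, so its `beta_terms` must be empty.
#'
#' @param family hazard family, see [hazard_spec()].
#' @param alpha_terms,beta_terms character subsets of
#'   `c("diet", "mating", "diet:mating")`, or one-sided formulas such as
#'   `~ diet * mating`.
#' @return an object of class `model_structure`.
#' @examples
#' model_structure("gompertz", alpha_terms = ~diet, beta_terms = ~diet * mating)
#' @export
model_structure <- function(family = "gompertz",
                            alpha_terms = character(0),
                            beta_terms = character(0)) {
  family <- match.arg(family, c("constant", "gompertz", "gompertz_makeham",
                                "logistic", "logistic_makeham", "weibull"))
  alpha_terms <- normalize_terms(alpha_terms)
  beta_terms <- normalize_terms(beta_terms)
  if (family == "constant" && length(beta_terms))
    stop("the constant-hazard family has no rate-of-ageing parameter; ",
         "'beta_terms' must be empty", call. = FALSE)
  structure(list(family = family, alpha_terms = alpha_terms,
                 beta_terms = beta_terms),
            class = "model_structure")
}

normalize_terms <- function(x) {
  if (inherits(x, "formula"))
    x <- attr(stats::terms(x), "term.labels")
  if (!length(x)) return(character(0))
  x <- vapply(strsplit(x, ":", fixed = TRUE), function(parts)
    paste(sort(parts), collapse = ":"), character(1))
  allowed <- c("diet", "mating", "diet:mating")
  bad <- setdiff(x, allowed)
  if (length(bad))
    stop("unsupported term(s): ", paste(bad, collapse = ", "),
         " (allowed: diet, mating, diet:mating)", call. = FALSE)
  x <- intersect(allowed, unique(x))  # canonical order
  if ("diet:mating" %in% x && !all(c("diet", "mating") %in% x))
    stop("'diet:mating' requires both main effects (marginality)",
         call. = FALSE)
  x
}

#' @export
print.model_structure <- function(x, ...) {
  lab <- function(t) if (length(t)) paste(t, collapse = " + ") else "1"
  cat("<model_structure> ", x$family, ": alpha ~ ", lab(x$alpha_terms),
      if (x$family != "constant") paste0(", beta ~ ", lab(x$beta_terms)),
      "\n", sep = "")
  invisible(x)
}

structure_label <- function(x) {
  lab <- function(t) if (length(t)) paste(t, collapse = "+") else "1"
  if (x$family == "constant") return("constant: a~1")
  sprintf("%s: a~%s, b~%s", x$family, lab(x$alpha_terms), lab(x$beta_terms))
}

#' Enumerate treatment-structured mortality models
#'
#' Builds the full battery of hierarchical treatment structures on the two
#' Gompertz parameters: each of \eqn{\alpha} and \eqn{\beta} takes one of
#' the five marginality-respecting term sets (none, diet, mating,
#' diet + mating, diet + mating + diet:mating), giving 25 Gompertz models,
#' plus the constant-hazard "no senescence" model.
#'
#' @param factors treatment factors to consider (default both).
#' @param family family used for the structured models.
#' @param include_constant add the constant-hazard model?
#' @return list of [model_structure()] objects (26 by default).
#' @export
enumerate_structures <- function(factors = c("diet", "mating"),
                                 family = "gompertz",
                                 include_constant = TRUE) {
  factors <- match.arg(factors, c("diet", "mating"), several.ok = TRUE)
  sets <- list(character(0))
  for (f in factors) sets <- c(sets, lapply(sets, function(s) c(s, f)))
  if (all(c("diet", "mating") %in% factors))
    sets <- c(sets, list(c("diet", "mating", "diet:mating")))
  out <- list()
  for (a in sets) for (b in sets)
    out[[length(out) + 1L]] <- model_structure(family, a, b)
  if (include_constant)
    out[[length(out) + 1L]] <- model_structure("constant")
  out
}

# Design matrix for one parameter's term set; baseline diet=C, mating=mated.
structure_design <- function(data, terms) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  cols <- list(
    "diet"        = function(d) as.numeric(d$diet == "P"),
    "mating"      = function(d) as.numeric(d$mating == "virgin"),
    "diet:mating" = function(d) as.numeric(d$diet == "P" & d$mating == "virgin"))
  names(cols) <- c("diet", "mating", "diet:mating")
  labels <- c("diet" = "dietP", "mating" = "matingvirgin",
              "diet:mating" = "dietP:matingvirgin")
  for (t in terms) X <- cbind(X, cols[[t]](data))
  colnames(X) <- c("(Intercept)", unname(labels[terms]))
  X
}

check_cohort_factors <- function(data, terms) {
  used <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("column(s) required by the model structure are missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("diet" %in% used && !all(data$diet %in% c("C", "P")))
    stop("column 'diet' must contain only levels C and P", call. = FALSE)
  if ("mating" %in% used && !all(data$mating %in% c("virgin", "mated")))
    stop("column 'mating' must contain only levels virgin and mated",
         call. = FALSE)
  if (length(used)) {
    cell <- interaction(data[used], drop = FALSE)
    sizes <- table(cell)
    if (any(sizes < 2))
      stop("treatment cell(s) with fewer than 2 deaths: ",
           paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
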