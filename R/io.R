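#' Read and write cohort and calling-effort CSV tables
#'
#' Cohort CSV: columns `id`, `sex`, `diet`, `mating`, `lifespan_days`
#' (required, header mandatory) plus optional `mass_g`, `pronotum_mm`;
#' unknown extra columns are preserved untouched. Calling CSV: `id`,
#' `age_days`, `calling_s`. Schema violations are reported with the
#' offending column and row numbers rather than silently dropped.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "diet", "mating", "lifespan_days")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  probs <- character(0)
  bad_rows <- function(ok) paste(utils::head(which(!ok), 5), collapse = ", ")
  if (anyDuplicated(d$id))
    probs <- c(probs, paste0("column 'id': duplicated value(s) ",
      paste(utils::head(unique(d$id[duplicated(d$id)]), 5), collapse = ", ")))
  ok <- d$sex %in% c("male", "female")
  if (!all(ok)) probs <- c(probs,
    paste0("column 'sex': invalid level at row(s) ", bad_rows(ok)))
  ok <- d$diet %in% c("C", "P")
  if (!all(ok)) probs <- c(probs,
    paste0("column 'diet': invalid level at row(s) ", bad_rows(ok)))
  ok <- d$mating %in% c("virgin", "mated")
  if (!all(ok)) probs <- c(probs,
    paste0("column 'mating': invalid level at row(s) ", bad_rows(ok)))
  life <- suppressWarnings(as.numeric(d$lifespan_days))
  ok <- is.finite(life) & life > 0
  if (!all(ok)) probs <- c(probs,
    paste0("column 'lifespan_days': non-numeric or <= 0 at row(s) ",
           bad_rows(ok)))
  if (length(probs))
    stop("invalid cohort CSV:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  d$lifespan_days <- life
  d
}

#' @rdname read_cohort
#' @export
read_calling <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age_days", "calling_s")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("calling CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  probs <- character(0)
  bad_rows <- function(ok) paste(utils::head(which(!ok), 5), collapse = ", ")
  age <- suppressWarnings(as.numeric(d$age_days))
  ok <- is.finite(age) & age >= 0
  if (!all(ok)) probs <- c(probs,
    paste0("column 'age_days': non-numeric or < 0 at row(s) ", bad_rows(ok)))
  cs <- suppressWarnings(as.numeric(d$calling_s))
  ok <- is.finite(cs)
  if (!all(ok)) probs <- c(probs,
    paste0("column 'calling_s': non-numeric at row(s) ", bad_rows(ok)))
  if (length(probs))
    stop("invalid calling CSV:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  d$age_days <- age
  d$calling_s <- cs
  d
}

#' @rdname read_cohort
#' @param x data.frame to write.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
write_calling <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join calling observations to their cohort records
#'
#' Adds `sex`, `diet`, `mating`, `lifespan_days` to each calling row by
#' `id`. Calling rows whose id has no cohort record are an error.
#'
#' @param cohort cohort data.frame (see [read_cohort()]).
#' @param calling calling data.frame (see [read_calling()]).
#' @return joined data.frame, one row per observation night.
#' @export
join_calling <- function(cohort, calling) {
  idx <- match(calling$id, cohort$id)
  if (anyNA(idx)) {
    orphan <- utils::head(unique(calling$id[is.na(idx)]), 5)
    stop("calling row(s) with no cohort record for id(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  cbind(calling,
        cohort[idx, c("sex", "diet", "mating", "lifespan_days")],
        row.names = NULL)
}

#' Read an experiment configuration from YAML or JSON
#'
#' Any field omitted from the file keeps its [experiment_config()]
#' default; tabular fields (`sample_sizes`, `gompertz`, `diets`) may be
#' given as lists of records.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return validated [experiment_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  experiment_config_from_list(raw)
}

experiment_config_from_list <- function(raw) {
  as_df <- function(x) {
    if (is.data.frame(x)) x
    else do.call(rbind, lapply(x, function(rec)
      as.data.frame(rec, stringsAsFactors = FALSE)))
  }
  args <- list()
  for (nm in c("sample_sizes", "gompertz", "diets"))
    if (!is.null(raw[[nm]])) args[[nm]] <- as_df(raw[[nm]])
  if (!is.null(raw$calling)) {
    cl <- raw$calling
    if (!is.null(cl$coefficients)) cl$coefficients <- unlist(cl$coefficients)
    def <- list(coefficients = default_calling_coefficients(),
                sigma_u = 1500, sigma_e = 3000)
    args$calling <- utils::modifyList(def, cl)
  }
  for (nm in c("schedule", "daily_rounding", "clip_calling", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(experiment_config, args)
}

#' Serialize fits and reports to JSON
#'
#' `fit_json()` turns a [fit_mortality()] result into a JSON-ready list
#' (structure, natural-scale estimates, 95% CIs, log-likelihood, AIC,
#' convergence flag); `battery_csv()` writes the ranked battery table;
#' `report_json()` assembles a [run_experiment()] report (provenance:
#' seed; per-stage tables) and writes it when `path` is given.
#'
#' @param fit,battery,report objects to serialize.
#' @param path optional output path.
#' @export
fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mortality_fit"))
  x <- list(
    structure = list(family = fit$structure$family,
                     alpha_terms = fit$structure$alpha_terms,
                     beta_terms = fit$structure$beta_terms),
    estimates = as.list(fit$estimates),
    ci95 = apply(fit$ci95, 1, function(r) list(lower = r[[1]],
                                               upper = r[[2]]),
                 simplify = FALSE),
    loglik = fit$loglik, n_params = fit$n_params, aic = fit$aic,
    converged = fit$converged, n_obs = fit$n_obs)
  if (!is.null(path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(x)
}

#' @rdname fit_json
#' @export
battery_csv <- function(battery, path) {
  stopifnot(inherits(battery, "mortality_battery"))
  utils::write.csv(battery$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname fit_json
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mortsen_report"))
  x <- list(
    provenance = list(seed = report$seed,
                      package_version =
                        as.character(utils::packageVersion("mortsen"))),
    battery = lapply(report$battery, function(b) b$table),
    sex_lrt = report$sex_lrt[c("statistic", "df", "p_value")],
    lifespan = as.data.frame(report$lifespan),
    calling = report$calling$table)
  if (!is.null(path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(x)
}
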