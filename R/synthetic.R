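#' Default design tables for the synthetic cricket experiment
#'
#' The synthetic generator emulates a 2 sex x 2 diet x 2 mating factorial
#' senescence experiment on adult field crickets. `default_sample_sizes()`
#' returns the per-cell cohort sizes; `default_gompertz_params()` the
#' per-cell Gompertz (alpha, beta) used to draw death times;
#' `default_diet_compositions()` the percent protein and digestible
#' carbohydrate of the two artificial diets (diet C is carbohydrate-rich,
#' P:C 9.33:74.66, i.e. 1:8; diet P is balanced at 42:42; both sum to 84%
#' with the remainder indigestible cellulose);
#' `default_calling_coefficients()` the fixed effects (seconds per night
#' and per day^k) of the male calling-effort model. The calling intercept
#' is set to 0 s: only treatment/covariate contrasts are specified by the
#' study design, and fixed-effect recovery does not depend on it.
#'
#' @return data.frames (or a named numeric vector for the coefficients).
#' @export
default_sample_sizes <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 4),
    diet = rep(c("C", "C", "P", "P"), 2),
    mating = rep(c("virgin", "mated"), 4),
    n = c(82, 76, 72, 70, 71, 76, 61, 67),
    stringsAsFactors = FALSE)
}

#' @rdname default_sample_sizes
#' @export
default_gompertz_params <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 4),
    diet = rep(c("C", "C", "P", "P"), 2),
    mating = rep(c("virgin", "mated"), 4),
    alpha = c(0.0101, 0.0065, 0.0073, 0.0059,
              0.0078, 0.0075, 0.0029, 0.0041),
    beta = c(0.0264, 0.0406, 0.0280, 0.0299,
             0.0417, 0.0482, 0.0418, 0.0423),
    stringsAsFactors = FALSE)
}

#' @rdname default_sample_sizes
#' @export
default_diet_compositions <- function() {
  data.frame(diet = c("C", "P"),
             protein_pct = c(9.33, 42),
             carb_pct = c(74.66, 42),
             stringsAsFactors = FALSE)
}

#' @rdname default_sample_sizes
#' @export
default_calling_coefficients <- function() {
  c(intercept = 0, diet = 1299.3, mating = 1059.1, age = 95.4,
    lifespan = 78.3, age2 = -3.2, lifespan2 = -1, "diet:age" = -123.6,
    "diet:age2" = 1.4, "age:lifespan" = 2.4)
}

#' Configuration of a synthetic cohort experiment
#'
#' Bundles everything the generator needs: per-cell sample sizes and
#' Gompertz parameters, diet compositions, the calling-effort observation
#' schedule (first recording at adult age 4 days, every 5 days until
#' death) and model (fixed effects plus random-intercept SD `sigma_u` and
#' residual SD `sigma_e`, both in seconds), realism flags, and the master
#' seed. `validate_config()` checks the invariants (nonnegative sizes,
#' protein + carbohydrate = 84 +/- 0.05 per diet, schedule interval >= 1,
#' positive hazard parameters, seed present) and fills in the derived
#' carbohydrate-to-protein ratio per diet.
#'
#' @param sample_sizes data.frame sex/diet/mating/n.
#' @param gompertz data.frame sex/diet/mating/alpha/beta.
#' @param diets data.frame diet/protein_pct/carb_pct.
#' @param calling list with `coefficients` (named, see
#'   [default_calling_coefficients()]), `sigma_u`, `sigma_e`.
#' @param schedule list with `first` (days) and `interval` (days, >= 1).
#' @param daily_rounding round death times up to whole days (emulating
#'   daily survival checks)?
#' @param clip_calling clip simulated calling to the 15-h recording window
#'   [0, 54000] s?
#' @param seed master integer seed; spawns independent sub-streams for
#'   death times, random intercepts, residuals and morphometrics.
#' @return a validated object of class `experiment_config`.
#' @export
experiment_config <- function(sample_sizes = default_sample_sizes(),
                              gompertz = default_gompertz_params(),
                              diets = default_diet_compositions(),
                              calling = list(
                                coefficients = default_calling_coefficients(),
                                sigma_u = 1500, sigma_e = 3000),
                              schedule = list(first = 4, interval = 5),
                              daily_rounding = FALSE, clip_calling = FALSE,
                              seed = NULL) {
  cfg <- structure(list(sample_sizes = sample_sizes, gompertz = gompertz,
                        diets = diets, calling = calling,
                        schedule = schedule,
                        daily_rounding = isTRUE(daily_rounding),
                        clip_calling = isTRUE(clip_calling), seed = seed),
                   class = "experiment_config")
  validate_config(cfg)
}

#' @rdname experiment_config
#' @param config an `experiment_config` (or plain list with the same
#'   fields).
#' @export
validate_config <- function(config) {
  cfg_stop <- function(path, msg)
    stop("invalid config at '", path, "': ", msg, call. = FALSE)
  ss <- config$sample_sizes
  if (!all(c("sex", "diet", "mating", "n") %in% names(ss)))
    cfg_stop("sample_sizes", "needs columns sex, diet, mating, n")
  if (any(!ss$sex %in% c("male", "female")))
    cfg_stop("sample_sizes$sex", "levels must be male/female")
  if (any(!ss$diet %in% c("C", "P")))
    cfg_stop("sample_sizes$diet", "levels must be C/P")
  if (any(!ss$mating %in% c("virgin", "mated")))
    cfg_stop("sample_sizes$mating", "levels must be virgin/mated")
  if (any(ss$n < 0) || any(ss$n != round(ss$n)))
    cfg_stop("sample_sizes$n", "must be nonnegative integers")
  gp <- config$gompertz
  if (!all(c("sex", "diet", "mating", "alpha", "beta") %in% names(gp)))
    cfg_stop("gompertz", "needs columns sex, diet, mating, alpha, beta")
  if (any(gp$alpha <= 0) || any(gp$beta <= 0))
    cfg_stop("gompertz", "alpha and beta must be > 0")
  key <- function(d) paste(d$sex, d$diet, d$mating)
  if (!all(key(ss) %in% key(gp)))
    cfg_stop("gompertz", "missing parameter rows for some design cells")
  di <- config$diets
  tot <- di$protein_pct + di$carb_pct
  if (any(abs(tot - 84) > 0.05))
    cfg_stop("diets", paste0("protein + carbohydrate must sum to 84 +/- ",
                             "0.05 (got ", paste(tot, collapse = ", "), ")"))
  config$diets$cp_ratio <- di$carb_pct / di$protein_pct
  sc <- config$schedule
  if (is.null(sc$first) || sc$first < 0)
    cfg_stop("schedule$first", "must be >= 0")
  if (is.null(sc$interval) || sc$interval < 1)
    cfg_stop("schedule$interval", "must be >= 1")
  cl <- config$calling
  if (is.null(names(cl$coefficients)) || !"intercept" %in%
        names(cl$coefficients))
    cfg_stop("calling$coefficients", "must be named and include 'intercept'")
  if (is.null(cl$sigma_u) || cl$sigma_u < 0)
    cfg_stop("calling$sigma_u", "must be >= 0")
  if (is.null(cl$sigma_e) || cl$sigma_e <= 0)
    cfg_stop("calling$sigma_e", "must be > 0")
  if (is.null(config$seed))
    cfg_stop("seed", "a master seed is required")
  config$seed <- as.integer(config$seed)
  class(config) <- "experiment_config"
  config
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config> seed:", x$seed, "\n")
  cat("cells:", nrow(x$sample_sizes), " total n:", sum(x$sample_sizes$n),
      "\n")
  cat("diet C:P carbohydrate:protein ratios:",
      paste(round(x$diets$cp_ratio, 2), collapse = ", "), "\n")
  cat("calling schedule: first", x$schedule$first, "d, every",
      x$schedule$interval, "d; sigma_u", x$calling$sigma_u, "s, sigma_e",
      x$calling$sigma_e, "s\n")
  cat("flags: daily_rounding", x$daily_rounding, "| clip_calling",
      x$clip_calling, "\n")
  invisible(x)
}

spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Observation schedule of a male of given lifespan
#'
#' Ages (days) at which calling effort is recorded: `first`,
#' `first + interval`, ... strictly before death.
#'
#' @param lifespan adult lifespan in days.
#' @param first,interval schedule parameters (days).
#' @return numeric vector (possibly empty).
#' @export
calling_schedule <- function(lifespan, first = 4, interval = 5) {
  if (lifespan <= first) return(numeric(0))
  seq(first, lifespan - 1e-9, by = interval)
}

#' Generate a complete synthetic experiment
#'
#' Draws one cohort (exact per-cell sample sizes; death times by
#' inverse-CDF sampling from each cell's Gompertz hazard, optionally
#' rounded up to whole days to emulate daily survival checks) and, for
#' males, longitudinal nightly calling-effort observations on the
#' configured schedule from the linear mixed model with per-male random
#' intercepts. The master seed spawns independent sub-streams for death
#' times, random intercepts, residuals and morphometrics, so toggling one
#' component does not shift the draws of another.
#'
#' @param config an [experiment_config()].
#' @param seed optional override of `config$seed`.
#' @return list of class `experiment_data`: `cohort` (id, sex, diet,
#'   mating, lifespan_days, mass_g, pronotum_mm) and `calling` (id,
#'   age_days, calling_s), plus the validated `config`.
#' @export
generate_experiment <- function(config, seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seeds <- spawn_seeds(config$seed, 4)

  ss <- merge(config$sample_sizes, config$gompertz,
              by = c("sex", "diet", "mating"), sort = FALSE)
  ss <- ss[order(ss$sex == "female", ss$diet, ss$mating == "mated"), ]
  total <- sum(ss$n)
  u_death <- with_seed(seeds[1], stats::runif(total))
  rows <- vector("list", nrow(ss))
  off <- 0L
  for (i in seq_len(nrow(ss))) {
    n <- ss$n[i]
    if (n == 0L) { rows[[i]] <- NULL; next }
    sp <- hazard_spec("gompertz", alpha = ss$alpha[i], beta = ss$beta[i])
    t <- quantile(sp, probs = u_death[off + seq_len(n)])
    if (config$daily_rounding) t <- ceiling(t)
    tag <- paste0(substr(ss$sex[i], 1, 1), "_", ss$diet[i],
                  toupper(substr(ss$mating[i], 1, 1)))
    rows[[i]] <- data.frame(
      id = sprintf("%s_%03d", tag, seq_len(n)),
      sex = ss$sex[i], diet = ss$diet[i], mating = ss$mating[i],
      lifespan_days = t, stringsAsFactors = FALSE)
    off <- off + n
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  morpho <- with_seed(seeds[4], {
    list(mass = stats::rnorm(nrow(cohort), 1.05, 0.12),
         pron = stats::rnorm(nrow(cohort), 8.2, 0.4))
  })
  cohort$mass_g <- round(pmax(morpho$mass, 0.3), 4)
  cohort$pronotum_mm <- round(pmax(morpho$pron, 4), 2)

  males <- cohort[cohort$sex == "male", ]
  ages <- lapply(males$lifespan_days, calling_schedule,
                 first = config$schedule$first,
                 interval = config$schedule$interval)
  n_obs <- lengths(ages)
  keep <- n_obs > 0
  u <- with_seed(seeds[2], stats::rnorm(nrow(males), 0,
                                        config$calling$sigma_u))
  calling <- data.frame(
    id = rep(males$id[keep], n_obs[keep]),
    age_days = unlist(ages[keep]),
    stringsAsFactors = FALSE)
  if (nrow(calling)) {
    des <- data.frame(
      age_days = calling$age_days,
      lifespan_days = rep(males$lifespan_days[keep], n_obs[keep]),
      diet = rep(males$diet[keep], n_obs[keep]),
      mating = rep(males$mating[keep], n_obs[keep]),
      stringsAsFactors = FALSE)
    cf <- config$calling$coefficients
    terms <- names(cf)
    X <- build_calling_design(des, terms)
    e <- with_seed(seeds[3], stats::rnorm(nrow(calling), 0,
                                          config$calling$sigma_e))
    y <- drop(X %*% cf) + rep(u[keep], n_obs[keep]) + e
    if (config$clip_calling) y <- pmin(pmax(y, 0), 54000)
    calling$calling_s <- y
  } else calling$calling_s <- numeric(0)

  structure(list(cohort = cohort, calling = calling, config = config),
            class = "experiment_data")
}

#' @export
print.experiment_data <- function(x, ...) {
  cat("<experiment_data> cohort:", nrow(x$cohort), "animals; calling:",
      nrow(x$calling), "male-nights (seed", x$config$seed, ")\n")
  print(table(x$cohort$sex, paste(x$cohort$diet, x$cohort$mating)))
  invisible(x)
}

#' Run the full analysis pipeline on one synthetic experiment
#'
#' Generate -> per-sex mortality model battery -> pooled-versus-sexed
#' likelihood-ratio test -> per-group lifespan table -> calling-effort
#' model comparison, returned as a single report.
#'
#' @param config an [experiment_config()].
#' @param seed optional override of the config's master seed.
#' @param structures battery structures (default [enumerate_structures()]).
#' @param calling_candidates named list of term lists for the calling
#'   comparison; default: the best-fit structure, the same without the
#'   diet x age terms, and the full candidate structure.
#' @param bootstrap_reps bootstrap replicates for the lifespan table.
#' @param control optimizer settings for the mortality fits.
#' @return list of class `mortsen_report` with elements `data`,
#'   `battery` (per sex), `sex_lrt`, `lifespan`, `calling`, `seed`.
#' @export
run_experiment <- function(config, seed = NULL,
                           structures = enumerate_structures(),
                           calling_candidates = NULL,
                           bootstrap_reps = 5000,
                           control = mortality_control()) {
  dat <- generate_experiment(config, seed = seed)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  battery <- stage("battery", lapply(
    split(dat$cohort, dat$cohort$sex), run_battery,
    structures = structures, control = control))
  lrt <- stage("sex_lrt", sex_lrt(dat$cohort, control = control))
  lt <- stage("lifespan", lifespan_table(
    dat$cohort, reps = bootstrap_reps,
    seed = spawn_seeds(dat$config$seed + 1L, 1)))
  if (is.null(calling_candidates)) {
    best <- calling_terms_best()
    calling_candidates <- list(
      best_fit = best,
      no_diet_age = setdiff(best, c("diet:age", "diet:age2")),
      full = calling_terms_full())
  }
  cal <- stage("calling", {
    joined <- join_calling(dat$cohort, dat$calling)
    compare_calling_models(joined, calling_candidates)
  })
  structure(list(data = dat, battery = battery, sex_lrt = lrt,
                 lifespan = lt, calling = cal, seed = dat$config$seed),
            class = "mortsen_report")
}

#' @export
print.mortsen_report <- function(x, ...) {
  cat("== Synthetic cohort experiment (seed", x$seed, ") ==\n\n")
  for (s in names(x$battery)) {
    cat("-- mortality battery,", s, "--\n")
    print(x$battery[[s]], n = 5)
    cat("\n")
  }
  cat(sprintf("Sex LRT: chi^2 = %.2f, df = %d, p = %.3g\n\n",
              x$sex_lrt$statistic, x$sex_lrt$df, x$sex_lrt$p_value))
  cat("-- lifespan table --\n")
  print(as.data.frame(lapply(x$lifespan, function(col)
    if (is.numeric(col)) round(col, 1) else col)), row.names = FALSE)
  cat("\n-- calling-effort comparison --\n")
  print(x$calling)
  invisible(x)
}
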