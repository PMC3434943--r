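#' Nonparametric lifespan summaries
#'
#' `group_median()` is the standard sample median (mean of the two central
#' order statistics for even n). `max_lifespan()` is "maximum lifespan" in
#' the demographic sense used here: the median of the longest-lived 10% of
#' the group (the `ceiling(n * top)` largest values). `bootstrap_ci()`
#' gives a percentile bootstrap confidence interval for any statistic of a
#' lifespan vector.
#'
#' @param lifespans numeric vector of adult lifespans (days), nonempty.
#' @return days (scalar).
#' @export
group_median <- function(lifespans) {
  if (!length(lifespans)) stop("empty lifespan group", call. = FALSE)
  stats::median(lifespans)
}

#' @rdname group_median
#' @param top fraction defining the longest-lived subset (default 0.10).
#' @export
max_lifespan <- function(lifespans, top = 0.10) {
  n <- length(lifespans)
  if (!n) stop("empty lifespan group", call. = FALSE)
  k <- ceiling(n * top)
  stats::median(sort(lifespans, decreasing = TRUE)[seq_len(k)])
}

#' @rdname group_median
#' @param statistic function of a numeric vector returning a scalar.
#' @param reps number of bootstrap resamples.
#' @param seed integer seed (required; same seed, same interval).
#' @param level confidence level.
#' @return `bootstrap_ci`: named vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(lifespans, statistic = group_median, reps = 5000,
                         seed, level = 0.95) {
  n <- length(lifespans)
  if (!n) stop("empty lifespan group", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for a reproducible bootstrap", call. = FALSE)
  stopifnot(reps >= 1)
  if (n == 1) {
    warning("single observation: degenerate bootstrap interval")
    v <- statistic(lifespans)
    return(c(lower = v, upper = v))
  }
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = n)
    apply(idx, 2, function(i) statistic(lifespans[i]))
  })
  q <- stats::quantile(boots, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Per-group lifespan summary table
#'
#' Median lifespan with a percentile-bootstrap 95% CI (resampling within
#' group) and "maximum lifespan" (median of the longest-lived 10%) for
#' every treatment group in a cohort.
#'
#' @param data cohort data.frame with `lifespan_days` and the grouping
#'   columns.
#' @param by character vector of grouping columns present in `data`.
#' @param reps bootstrap replicates per group.
#' @param seed integer master seed; each group gets its own derived stream.
#' @param top top fraction for maximum lifespan.
#' @return data.frame of class `lifespan_table`: group columns plus `n`,
#'   `median_days`, `ci_low`, `ci_high`, `max_median_days`.
#' @export
lifespan_table <- function(data, by = intersect(c("sex", "diet", "mating"),
                                                names(data)),
                           reps = 5000, seed, top = 0.10) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is required", call. = FALSE)
  stopifnot(all(by %in% names(data)), "lifespan_days" %in% names(data))
  groups <- split(data, data[by], drop = TRUE, sep = "|")
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                          length(groups)))
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    x <- g$lifespan_days
    ci <- bootstrap_ci(x, group_median, reps = reps, seed = sub_seeds[i])
    cbind(unique(g[by]),
          data.frame(n = length(x), median_days = group_median(x),
                     ci_low = ci[["lower"]], ci_high = ci[["upper"]],
                     max_median_days = max_lifespan(x, top = top)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lifespan_table", "data.frame")
  out
}
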