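# Median/quantile -> mean/SD conversion for studies that report medians with
# interquartile ranges or ranges instead of means. Mean estimators follow
# Luo et al.'s optimal-weight formulas; SD estimators follow Wan et al.
# Scenarios: S1 = (min, median, max), S2 = (q1, median, q3), S3 = all five.

#' Describe a quantile summary
#'
#' Bundles the reported order statistics of one study arm, with the
#' reporting scenario either declared or inferred from which fields are
#' present: S1 = minimum/median/maximum, S2 = quartiles/median,
#' S3 = all five numbers.
#'
#' @param n sample size (positive integer).
#' @param median sample median.
#' @param q1,q3 first and third quartiles (scenario S2/S3).
#' @param min,max sample extremes (scenario S1/S3).
#' @param scenario `"S1"`, `"S2"`, `"S3"`, or `NULL` to infer.
#' @return A `quantile_summary` list.
#' @export
quantile_summary <- function(n, median, q1 = NULL, q3 = NULL,
                             min = NULL, max = NULL, scenario = NULL) {
  has <- function(x) !is.null(x) && length(x) == 1L && is.finite(x)
  if (!has(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (!has(median)) stop("median is required", call. = FALSE)
  if (is.null(scenario)) {
    scenario <- if (has(q1) && has(q3) && has(min) && has(max)) "S3"
                else if (has(q1) && has(q3)) "S2"
                else if (has(min) && has(max)) "S1"
                else stop("cannot infer scenario: supply (q1, q3) and/or ",
                          "(min, max)", call. = FALSE)
  }
  scenario <- match.arg(scenario, c("S1", "S2", "S3"))
  need <- switch(scenario,
                 S1 = c("min", "max"),
                 S2 = c("q1", "q3"),
                 S3 = c("min", "q1", "q3", "max"))
  vals <- list(min = min, q1 = q1, q3 = q3, max = max)
  absent <- need[!vapply(vals[need], has, logical(1))]
  if (length(absent) > 0L) {
    stop("scenario ", scenario, " requires field(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ord <- c(vals$min, vals$q1, median, vals$q3, vals$max)
  if (is.unsorted(ord)) {
    stop("quantiles out of order: need min <= q1 <= median <= q3 <= max",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), median = median,
                 q1 = vals$q1, q3 = vals$q3,
                 min = vals$min, max = vals$max, scenario = scenario),
            class = "quantile_summary")
}

#' Estimate the mean from a quantile summary
#'
#' Applies the optimal-weight estimators of Luo and colleagues. For S2 the
#' estimate is `(0.7 + 0.39/n) * (q1 + q3)/2 + (0.3 - 0.39/n) * median`;
#' S1 weights the mid-range by `4/(4 + n^0.75)`; S3 combines mid-range,
#' mid-quartile and median. Weights sum to one in every scenario, so the
#' estimate equals the median whenever the summary is symmetric.
#'
#' @param q a [quantile_summary()].
#' @return Estimated mean, in the input units.
#' @export
estimate_mean <- function(q) {
  stopifnot(inherits(q, "quantile_summary"))
  n <- q$n
  switch(q$scenario,
    S1 = {
      w <- 4 / (4 + n^0.75)
      w * (q$min + q$max) / 2 + (1 - w) * q$median
    },
    S2 = {
      w <- 0.7 + 0.39 / n
      w * (q$q1 + q$q3) / 2 + (1 - w) * q$median
    },
    S3 = {
      w1 <- 2.2 / (2.2 + n^0.75)
      w2 <- 0.7 - 0.72 / n^0.55
      w1 * (q$min + q$max) / 2 + w2 * (q$q1 + q$q3) / 2 +
        (1 - w1 - w2) * q$median
    })
}

#' Estimate the SD from a quantile summary
#'
#' Applies the estimators of Wan and colleagues, which divide the observed
#' spread by its expectation under normality: for S2,
#' `(q3 - q1) / (2 * qnorm((0.75 n - 0.125)/(n + 0.25)))`; for S1,
#' `(max - min) / (2 * qnorm((n - 0.375)/(n + 0.25)))`; S3 averages the two.
#'
#' @param q a [quantile_summary()].
#' @return Estimated SD (non-negative). A degenerate spread (q3 == q1 or
#'   max == min) yields 0 with a warning.
#' @export
estimate_sd <- function(q) {
  stopifnot(inherits(q, "quantile_summary"))
  n <- q$n
  sd_range <- function() (q$max - q$min) /
    (2 * stats::qnorm((n - 0.375) / (n + 0.25)))
  sd_iqr <- function() (q$q3 - q$q1) /
    (2 * stats::qnorm((0.75 * n - 0.125) / (n + 0.25)))
  est <- switch(q$scenario,
                S1 = sd_range(),
                S2 = sd_iqr(),
                S3 = (sd_range() + sd_iqr()) / 2)
  if (est == 0) warning("degenerate spread: SD estimated as 0")
  est
}

#' Convert a quantile summary to an arm summary
#'
#' Composes [estimate_mean()] and [estimate_sd()], carrying `n` through.
#'
#' @param q a [quantile_summary()].
#' @return A list with elements `n`, `mean`, `sd`.
#' @examples
#' convert_summary(quantile_summary(n = 130, median = 10, q1 = 8, q3 = 12.5))
#' @export
convert_summary <- function(q) {
  list(n = q$n, mean = estimate_mean(q), sd = estimate_sd(q))
}
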