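# Standardized mean differences for two-arm continuous outcomes.
# Sign convention: case minus control (GDM minus non-GDM), so positive SMD
# means higher GDF-15 in cases.

#' Pooled within-group standard deviation
#'
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`, the denominator of
#' the standardized mean difference. Vectorized over studies.
#'
#' @param n_case,sd_case,n_control,sd_control per-arm sample sizes and SDs.
#' @return Pooled SD (non-negative), one value per study.
#' @export
pooled_sd <- function(n_case, sd_case, n_control, sd_control) {
  if (any(n_case + n_control - 2 < 1)) {
    stop("pooled SD needs at least 1 degree of freedom (n1 + n2 >= 3)",
         call. = FALSE)
  }
  sqrt(((n_case - 1) * sd_case^2 + (n_control - 1) * sd_control^2) /
         (n_case + n_control - 2))
}

#' Standardized mean difference with analytic variance
#'
#' Cohen's d is `(mean_case - mean_control) / pooled_sd` with variance
#' `(n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2))`. Hedges' g multiplies d by the
#' small-sample factor `J = 1 - 3/(4 (n1 + n2) - 9)` and uses variance
#' `(n1 + n2)/(n1 n2) + g^2 / (2 (n1 + n2 - 3.94))`. Confidence intervals
#' are the normal approximation `estimate +/- 1.96 se` throughout, which is
#' the convention the packaged analyses were computed under.
#'
#' @param n_case,mean_case,sd_case case-arm summaries (vectorized).
#' @param n_control,mean_control,sd_control control-arm summaries.
#' @param method `"cohen"` (default) or `"hedges"`.
#' @param study_id optional study labels (defaults to `study_1`, ...).
#' @param conf_level confidence level for the normal CI.
#' @return An `effect_table` data frame with columns `study_id`, `smd`,
#'   `variance`, `se`, `ci_low`, `ci_high`; the method is kept as an
#'   attribute.
#' @examples
#' smd(7, 0.714, 0.951, 9, 1.333, 2.958)  # single-study SMD = -0.27
#' @export
smd <- function(n_case, mean_case, sd_case,
                n_control, mean_control, sd_control,
                method = c("cohen", "hedges"),
                study_id = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  k <- length(n_case)
  stopifnot(length(mean_case) == k, length(sd_case) == k,
            length(n_control) == k, length(mean_control) == k,
            length(sd_control) == k)
  if (is.null(study_id)) study_id <- paste0("study_", seq_len(k))
  if (any(n_case < 2 | n_control < 2)) {
    stop("SMD needs n >= 2 in both arms (study ",
         study_id[which(n_case < 2 | n_control < 2)[1L]], ")", call. = FALSE)
  }
  sp <- pooled_sd(n_case, sd_case, n_control, sd_control)
  if (any(sp == 0)) {
    stop("zero pooled SD: study ", study_id[which(sp == 0)[1L]],
         " is degenerate", call. = FALSE)
  }
  n_case <- as.numeric(n_case)     # avoid integer overflow in n1 * n2
  n_control <- as.numeric(n_control)
  N <- n_case + n_control
  d <- (mean_case - mean_control) / sp
  if (method == "cohen") {
    est <- d
    v <- N / (n_case * n_control) + est^2 / (2 * N)
  } else {
    J <- 1 - 3 / (4 * N - 9)
    est <- J * d
    v <- N / (n_case * n_control) + est^2 / (2 * (N - 3.94))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(v)
  structure(
    data.frame(study_id = as.character(study_id), smd = est, variance = v,
               se = se, ci_low = est - z * se, ci_high = est + z * se,
               stringsAsFactors = FALSE),
    class = c("effect_table", "data.frame"),
    method = method, conf_level = conf_level)
}

#' Per-study effect sizes for a study collection
#'
#' Maps [smd()] over the rows of a [study_collection()], preserving order.
#'
#' @param collection a [study_collection()].
#' @param method `"cohen"` (default) or `"hedges"`.
#' @return An `effect_table`, one row per study.
#' @examples
#' compute_effects(load_gdf15_fixture("protein", "late"))
#' @export
compute_effects <- function(collection, method = c("cohen", "hedges")) {
  stopifnot(inherits(collection, "study_collection"))
  if (nrow(collection) == 0L) stop("empty study collection", call. = FALSE)
  smd(collection$n_case, collection$mean_case, collection$sd_case,
      collection$n_control, collection$mean_control, collection$sd_control,
      method = match.arg(method), study_id = collection$study_id)
}

#' @export
print.effect_table <- function(x, digits = 3, ...) {
  cat(sprintf("effect_table: %d stud%s, method = %s\n", nrow(x),
              if (nrow(x) == 1L) "y" else "ies", attr(x, "method")))
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  print.data.frame(out, row.names = FALSE)
  invisible(x)
}

# Coerce pooling input: an effect_table or any data frame carrying
# smd/variance (or estimate/variance) columns.
as_effect_input <- function(effects) {
  if (is.data.frame(effects)) {
    est_col <- intersect(c("smd", "estimate"), names(effects))[1L]
    if (!is.na(est_col) && "variance" %in% names(effects)) {
      id <- if ("study_id" %in% names(effects)) {
        as.character(effects$study_id)
      } else {
        paste0("study_", seq_len(nrow(effects)))
      }
      return(list(id = id, theta = effects[[est_col]],
                  v = effects$variance))
    }
  }
  stop("effects must be a data frame with smd (or estimate) and variance ",
       "columns, e.g. the output of compute_effects()", call. = FALSE)
}
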