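# Inverse-variance pooling: fixed effect and DerSimonian-Laird random
# effects. Heterogeneity (Q, I2, tau2) is always computed on the
# fixed-effect weights; tau2 and I2 are clamped at zero.

pool_core <- function(id, theta, v, model, conf_level = 0.95) {
  k <- length(theta)
  if (k < 1L) stop("need at least one study to pool", call. = FALSE)
  if (any(!is.finite(theta)) || any(!is.finite(v)) || any(v <= 0)) {
    stop("all effect variances must be finite and positive", call. = FALSE)
  }
  w <- 1 / v
  fe <- sum(w * theta) / sum(w)
  q_stat <- sum(w * (theta - fe)^2)
  df <- k - 1L
  i2 <- if (q_stat > 0) max(0, (q_stat - df) / q_stat) * 100 else 0
  if (model == "fixed") {
    tau2 <- 0
    w_star <- w
  } else {
    tau2 <- if (k >= 2L) {
      max(0, (q_stat - df) / (sum(w) - sum(w^2) / sum(w)))
    } else 0
    w_star <- 1 / (v + tau2)
  }
  pooled <- sum(w_star * theta) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(k = k, model = model, pooled = pooled, se = se,
         ci_low = pooled - z * se, ci_high = pooled + z * se,
         q_stat = q_stat, df = df, i_squared = i2, tau_squared = tau2,
         weights = stats::setNames(w_star / sum(w_star), id),
         study_ids = id, conf_level = conf_level),
    class = "pool_result")
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Weights each study by the reciprocal of its variance and reports the
#' weighted mean with a normal-approximation CI, plus Cochran's Q, I² and
#' degrees of freedom. Assumes one common true effect.
#'
#' @param effects an `effect_table` (see [compute_effects()]) or any data
#'   frame with `smd`/`estimate` and `variance` columns.
#' @param conf_level confidence level for the pooled CI.
#' @return A `pool_result` list: `k`, `model`, `pooled`, `se`, `ci_low`,
#'   `ci_high`, `q_stat`, `df`, `i_squared`, `tau_squared`, normalized
#'   `weights`.
#' @export
fixed_effect <- function(effects, conf_level = 0.95) {
  inp <- as_effect_input(effects)
  pool_core(inp$id, inp$theta, inp$v, "fixed", conf_level)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` computed from
#' the fixed-effect weights `w = 1/v`, then inverse-variance pooling with
#' weights `1/(v + tau2)`. With a single study (or `Q <= k-1`) the result
#' collapses to [fixed_effect()]. The pooled CI is the normal
#' approximation, without Knapp-Hartung adjustment.
#'
#' @inheritParams fixed_effect
#' @return A `pool_result`; see [fixed_effect()].
#' @examples
#' eff <- compute_effects(load_gdf15_fixture("mRNA", "late"))
#' dersimonian_laird(eff)  # pooled SMD 0.48 (0.14, 0.83)
#' @export
dersimonian_laird <- function(effects, conf_level = 0.95) {
  inp <- as_effect_input(effects)
  pool_core(inp$id, inp$theta, inp$v, "random_DL", conf_level)
}

#' Pool raw arm means (reference range)
#'
#' Treats each arm's mean as an estimate with variance `sd^2 / n` and pools
#' across arms; the CI of the pooled mean is reported as the reference
#' range of the measured quantity (here: the expected GDF-15 level among
#' controls). Pooling raw means only makes sense on a common measurement
#' scale, so mixed unit labels trigger a warning and the caller decides.
#'
#' @param n,mean,sd numeric vectors of arm summaries (one entry per arm);
#'   all `sd` must be positive.
#' @param units optional character vector of unit labels, checked for
#'   homogeneity.
#' @param model `"random"` (DerSimonian-Laird, default) or `"fixed"`.
#' @param conf_level confidence level.
#' @return A `pool_result` with an extra `reference_range` element
#'   (`c(ci_low, ci_high)`).
#' @examples
#' pool_raw_means(100, 50, 10)$reference_range  # 50 +/- 1.96 * 1
#' @export
pool_raw_means <- function(n, mean, sd, units = NULL,
                           model = c("random", "fixed"), conf_level = 0.95) {
  model <- match.arg(model)
  stopifnot(length(mean) == length(n), length(sd) == length(n))
  if (any(sd <= 0)) stop("all sds must be positive", call. = FALSE)
  if (!is.null(units) && length(unique(units)) > 1L) {
    warning("arms carry mixed units (", paste(unique(units), collapse = ", "),
            "); pooled mean is unit-ambiguous")
  }
  out <- pool_core(paste0("arm_", seq_along(n)), mean, sd^2 / n,
                   if (model == "fixed") "fixed" else "random_DL", conf_level)
  out$reference_range <- c(out$ci_low, out$ci_high)
  out
}

#' @export
print.pool_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s pooling of %d stud%s\n",
              if (x$model == "fixed") "Fixed-effect" else
                "Random-effects (DerSimonian-Laird)",
              x$k, if (x$k == 1L) "y" else "ies"))
  cat(sprintf("  pooled = %.*f, %d%% CI [%.*f, %.*f], se = %.*f\n",
              digits, x$pooled, round(100 * x$conf_level),
              digits, x$ci_low, digits, x$ci_high, digits, x$se))
  cat(sprintf("  Q = %.*f (df = %d), I2 = %.1f%%, tau2 = %.*f\n",
              digits, x$q_stat, x$df, x$i_squared, digits, x$tau_squared))
  if (!is.null(x$reference_range)) {
    cat(sprintf("  reference range: %.*f to %.*f\n",
                digits, x$reference_range[1], digits, x$reference_range[2]))
  }
  invisible(x)
}

#' Convert a pool result to a one-row data frame
#'
#' @param x a `pool_result`.
#' @param ... unused.
#' @return A one-row data frame of the scalar fields.
#' @export
as.data.frame.pool_result <- function(x, ...) {
  data.frame(k = x$k, model = x$model, pooled = x$pooled, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, q_stat = x$q_stat,
             df = x$df, i_squared = x$i_squared, tau_squared = x$tau_squared,
             stringsAsFactors = FALSE)
}
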