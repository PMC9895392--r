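# Publication-bias diagnostics and sensitivity analyses.

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Correlates standardized effect deviates with effect variances. Each
#' study's deviate is `u_i = (theta_i - theta_fe) / sqrt(v_i - 1/sum(w))`
#' where `theta_fe` is the fixed-effect pooled estimate and `w = 1/v`. The
#' Kendall score S counts concordant minus discordant (u, v) pairs, with
#' tied pairs contributing zero; `z = (|S| - c) / sqrt(k(k-1)(2k+5)/18)`
#' with continuity correction `c = 1` by default, and the two-sided normal
#' p-value is reported.
#'
#' @param effects an `effect_table` or data frame with `smd`/`estimate` and
#'   `variance` columns; at least 3 studies.
#' @param continuity_correction subtract 1 from |S| (the common software
#'   default)?
#' @return A `bias_test` list: `method`, `statistic` (Kendall score S),
#'   `test_value` (z), `p_value`, `continuity_corrected`.
#' @export
beggs_test <- function(effects, continuity_correction = TRUE) {
  inp <- as_effect_input(effects)
  k <- length(inp$theta)
  if (k < 3L) stop("Begg's test needs at least 3 studies", call. = FALSE)
  theta <- inp$theta
  v <- inp$v
  w <- 1 / v
  fe <- sum(w * theta) / sum(w)
  v_star <- v - 1 / sum(w)
  if (any(v_star <= 0)) {
    warning("non-positive deviate variance for some studies; ",
            "using absolute value")
    v_star <- abs(v_star)
  }
  u <- (theta - fe) / sqrt(v_star)
  pairs <- utils::combn(k, 2)
  s_terms <- sign(u[pairs[2, ]] - u[pairs[1, ]]) *
    sign(v[pairs[2, ]] - v[pairs[1, ]])
  S <- sum(s_terms)
  correction <- if (continuity_correction) 1 else 0
  z <- max(0, abs(S) - correction) / sqrt(k * (k - 1) * (2 * k + 5) / 18)
  p <- min(1, 2 * stats::pnorm(-z))
  structure(list(method = "begg", statistic = S, test_value = z,
                 df = NA_integer_, p_value = p,
                 continuity_corrected = continuity_correction, k = k),
            class = "bias_test")
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least-squares regression of the standardized effect
#' `theta_i / se_i` on precision `1 / se_i`; the intercept estimates
#' small-study asymmetry and is tested against zero with a two-sided t test
#' on `k - 2` degrees of freedom.
#'
#' @inheritParams beggs_test
#' @return A `bias_test` list: `method`, `statistic` (intercept),
#'   `test_value` (t), `df`, `p_value`, plus the intercept's `se` and the
#'   `slope`.
#' @export
eggers_test <- function(effects) {
  inp <- as_effect_input(effects)
  k <- length(inp$theta)
  if (k < 3L) stop("Egger's test needs at least 3 studies", call. = FALSE)
  se <- sqrt(inp$v)
  if (length(unique(se)) == 1L) {
    stop("all standard errors identical: Egger regression is singular",
         call. = FALSE)
  }
  y <- inp$theta / se
  x <- 1 / se
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  intercept <- cf["(Intercept)", "Estimate"]
  se_int <- cf["(Intercept)", "Std. Error"]
  t_val <- cf["(Intercept)", "t value"]
  p <- cf["(Intercept)", "Pr(>|t|)"]
  structure(list(method = "egger", statistic = intercept,
                 test_value = t_val, df = k - 2L, p_value = p,
                 se = se_int, slope = cf["x", "Estimate"],
                 continuity_corrected = NA, k = k),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, digits = 4, ...) {
  if (x$method == "begg") {
    cat(sprintf("Begg rank-correlation test (k = %d%s)\n", x$k,
                if (isTRUE(x$continuity_corrected))
                  ", continuity-corrected" else ""))
    cat(sprintf("  Kendall score S = %d, z = %.*f, two-sided p = %.*f\n",
                x$statistic, digits, x$test_value, digits, x$p_value))
  } else {
    cat(sprintf("Egger regression test (k = %d)\n", x$k))
    cat(sprintf("  intercept = %.*f (se %.*f), t(%d) = %.*f, p = %.*f\n",
                digits, x$statistic, digits, x$se, x$df,
                digits, x$test_value, digits, x$p_value))
  }
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the remaining studies after omitting each study in turn,
#' in input order.
#'
#' @param effects an `effect_table` with at least 2 studies.
#' @param model `"random"` (DerSimonian-Laird, default) or `"fixed"`.
#' @return A `loo_table` data frame with one row per omitted study
#'   (`omitted_study_id`, `k`, `pooled`, `se`, `ci_low`, `ci_high`,
#'   `tau_squared`, `i_squared`); the full `pool_result` objects are kept
#'   in the `"results"` attribute.
#' @export
leave_one_out <- function(effects, model = c("random", "fixed")) {
  model <- match.arg(model)
  inp <- as_effect_input(effects)
  k <- length(inp$theta)
  if (k < 2L) {
    stop("leave-one-out needs at least 2 studies", call. = FALSE)
  }
  pool_fun <- if (model == "fixed") fixed_effect else dersimonian_laird
  results <- lapply(seq_len(k), function(i) {
    sub <- data.frame(study_id = inp$id[-i], estimate = inp$theta[-i],
                      variance = inp$v[-i], stringsAsFactors = FALSE)
    pool_fun(sub)
  })
  rows <- do.call(rbind, lapply(results, as.data.frame))
  out <- cbind(data.frame(omitted_study_id = inp$id,
                          stringsAsFactors = FALSE),
               rows[, c("k", "pooled", "se", "ci_low", "ci_high",
                        "tau_squared", "i_squared")])
  rownames(out) <- NULL
  structure(out, class = c("loo_table", "data.frame"),
            results = results, model = model)
}

#' Criteria-restricted sensitivity analysis
#'
#' Restricts a collection to the studies that excluded preeclampsia or
#' other conditions that may influence the measured marker
#' (`excludes_confounders == "yes"`), then computes per-study SMDs and
#' pools them.
#'
#' @param collection a [study_collection()].
#' @param method SMD flavor, `"cohen"` (default) or `"hedges"`.
#' @param model `"random"` (default) or `"fixed"`.
#' @return A `pool_result` on the restricted subset.
#' @examples
#' restricted_analysis(load_gdf15_fixture("mRNA", "late"))  # 0.61 (0.09, 1.13)
#' @export
restricted_analysis <- function(collection, method = c("cohen", "hedges"),
                                model = c("random", "fixed")) {
  model <- match.arg(model)
  restricted <- filter_studies(collection, excludes_confounders = "yes")
  if (nrow(restricted) == 0L) {
    stop("no studies left after restricting to excludes_confounders = yes",
         call. = FALSE)
  }
  eff <- compute_effects(restricted, method = match.arg(method))
  if (model == "fixed") fixed_effect(eff) else dersimonian_laird(eff)
}
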