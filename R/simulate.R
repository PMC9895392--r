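# Synthetic meta-analyses under the standard random-effects model: per-study
# true effects delta_i ~ N(mu, tau2), equal within-arm SDs, arm-level normal
# data summarized to (n, mean, sd), with an optional selective-publication
# mechanism that discards nonsignificant studies with a given probability.

#' Configuration for the synthetic-study generator
#'
#' Defaults describe a world like the packaged GDF-15 analysis: 12 studies,
#' a true standardized effect of 0.5, moderate between-study heterogeneity
#' (tau2 = 0.15, close to the DerSimonian-Laird estimate on the late
#' mRNA stratum), and arm sizes spanning the bulk of the included studies.
#'
#' @param k number of retained studies (>= 2).
#' @param mu true mean standardized effect (case minus control).
#' @param tau_squared between-study variance of the true effects (>= 0).
#' @param n_case_range,n_control_range integer ranges (length-2) for arm
#'   sizes, drawn uniformly.
#' @param sigma_range range of the common within-arm SD, in measurement
#'   units.
#' @param control_mean_range range of the control-arm true mean.
#' @param suppress_prob probability in \[0, 1\] of discarding a study whose
#'   two-sided effect p-value is >= 0.05 (selective publication); 0 = none.
#' @param seed optional integer seed; identical seeds give identical
#'   collections.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(k = 12, mu = 0.5, tau_squared = 0.15,
                       n_case_range = c(10L, 60L),
                       n_control_range = c(10L, 60L),
                       sigma_range = c(0.5, 2),
                       control_mean_range = c(5, 15),
                       suppress_prob = 0, seed = NULL) {
  check_range <- function(r, what, lo_ok) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < lo_ok) {
      stop(what, " must be a valid non-empty range", call. = FALSE)
    }
  }
  if (!is.numeric(k) || k < 2 || k != round(k)) {
    stop("k must be an integer >= 2", call. = FALSE)
  }
  if (!is.finite(mu)) stop("mu must be finite", call. = FALSE)
  if (!is.finite(tau_squared) || tau_squared < 0) {
    stop("tau_squared must be >= 0", call. = FALSE)
  }
  check_range(n_case_range, "n_case_range", 2)
  check_range(n_control_range, "n_control_range", 2)
  check_range(sigma_range, "sigma_range", .Machine$double.eps)
  check_range(control_mean_range, "control_mean_range", -Inf)
  if (!is.finite(suppress_prob) || suppress_prob < 0 || suppress_prob > 1) {
    stop("suppress_prob must be in [0, 1]", call. = FALSE)
  }
  structure(list(k = as.integer(k), mu = mu, tau_squared = tau_squared,
                 n_case_range = as.integer(round(n_case_range)),
                 n_control_range = as.integer(round(n_control_range)),
                 sigma_range = sigma_range,
                 control_mean_range = control_mean_range,
                 suppress_prob = suppress_prob, seed = seed),
            class = "sim_config")
}

draw_in <- function(r) {
  if (is.integer(r)) sample(seq(r[1], r[2]), 1L) else stats::runif(1, r[1], r[2])
}

#' Simulate a synthetic study collection
#'
#' For each retained study: draw the true effect `delta ~ N(mu, tau2)`, arm
#' sizes, a common within-arm SD `sigma` and a control mean `m2`; set the
#' case mean to `m2 + delta * sigma`; draw individual normal values per arm
#' and summarize each arm to (n, sample mean, sample SD). When
#' `suppress_prob > 0`, a study whose two-sided z-test on Cohen's d has
#' p >= 0.05 is discarded with that probability, and generation continues
#' until `k` studies are retained.
#'
#' @param config a [sim_config()].
#' @return A [study_collection()] of `k` synthetic studies
#'   (`sim_001`, ...), `level = "mRNA"`, `timing = "late"`.
#' @examples
#' sim <- simulate_collection(sim_config(k = 5, seed = 1))
#' dersimonian_laird(compute_effects(sim))
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rows <- vector("list", config$k)
  retained <- 0L
  attempts <- 0L
  max_attempts <- 10000L * config$k
  while (retained < config$k) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("suppression mechanism rejected too many studies; ",
           "lower suppress_prob or increase arm sizes", call. = FALSE)
    }
    delta <- stats::rnorm(1, config$mu, sqrt(config$tau_squared))
    n1 <- draw_in(config$n_case_range)
    n2 <- draw_in(config$n_control_range)
    sigma <- draw_in(config$sigma_range)
    m2 <- draw_in(config$control_mean_range)
    m1 <- m2 + delta * sigma
    x1 <- stats::rnorm(n1, m1, sigma)
    x2 <- stats::rnorm(n2, m2, sigma)
    arm <- data.frame(n_case = n1, mean_case = mean(x1), sd_case = stats::sd(x1),
                      n_control = n2, mean_control = mean(x2),
                      sd_control = stats::sd(x2))
    if (config$suppress_prob > 0) {
      d <- smd(arm$n_case, arm$mean_case, arm$sd_case,
               arm$n_control, arm$mean_control, arm$sd_control)
      p <- 2 * stats::pnorm(-abs(d$smd / d$se))
      if (p >= 0.05 && stats::runif(1) < config$suppress_prob) next
    }
    retained <- retained + 1L
    rows[[retained]] <- arm
  }
  df <- do.call(rbind, rows)
  df$study_id <- sprintf("sim_%03d", seq_len(config$k))
  df$timing <- "late"
  df$level <- "mRNA"
  df$sample_type <- "synthetic"
  study_collection(df, provenance = sprintf(
    "simulated (seed = %s, mu = %g, tau2 = %g)",
    if (is.null(config$seed)) "none" else config$seed,
    config$mu, config$tau_squared))
}

#' Operating characteristics of the pipeline by simulation
#'
#' Runs the full pipeline (simulate, Cohen's d, DerSimonian-Laird pooling,
#' Begg and Egger tests) on `reps` independent synthetic collections and
#' summarizes rejection rates, mean tau2 estimate, and CI coverage of the
#' true `mu`, each with its Monte-Carlo standard error.
#'
#' @param config a [sim_config()]; its `seed` (if any) seeds the whole run.
#' @param reps number of replicates (>= 100).
#' @param alpha two-sided significance level for the bias tests.
#' @return An `oc_summary` list: `reps`, `alpha`, `egger_rejection`,
#'   `begg_rejection`, `coverage`, `mean_tau_squared`, `mean_pooled`, and
#'   `mc_se` (named vector of Monte-Carlo SEs for the three rates and the
#'   pooled mean).
#' @export
operating_characteristics <- function(config, reps, alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (reps < 100) stop("reps must be >= 100", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  inner <- config
  inner$seed <- NULL  # one seeded stream for the whole run
  egger_rej <- begg_rej <- cover <- logical(reps)
  tau2_hat <- pooled_hat <- numeric(reps)
  for (r in seq_len(reps)) {
    eff <- compute_effects(simulate_collection(inner))
    pool <- dersimonian_laird(eff)
    egger_rej[r] <- eggers_test(eff)$p_value < alpha
    begg_rej[r] <- suppressWarnings(beggs_test(eff)$p_value) < alpha
    cover[r] <- pool$ci_low <= config$mu && config$mu <= pool$ci_high
    tau2_hat[r] <- pool$tau_squared
    pooled_hat[r] <- pool$pooled
  }
  rate_se <- function(p) sqrt(p * (1 - p) / reps)
  rates <- c(egger = mean(egger_rej), begg = mean(begg_rej),
             coverage = mean(cover))
  structure(list(reps = reps, alpha = alpha,
                 egger_rejection = rates[["egger"]],
                 begg_rejection = rates[["begg"]],
                 coverage = rates[["coverage"]],
                 mean_tau_squared = mean(tau2_hat),
                 mean_pooled = mean(pooled_hat),
                 mc_se = c(egger = rate_se(rates[["egger"]]),
                           begg = rate_se(rates[["begg"]]),
                           coverage = rate_se(rates[["coverage"]]),
                           pooled = stats::sd(pooled_hat) / sqrt(reps)),
                 config = config),
            class = "oc_summary")
}

#' @export
print.oc_summary <- function(x, ...) {
  cat(sprintf("operating characteristics over %d replicates (alpha = %g)\n",
              x$reps, x$alpha))
  cat(sprintf("  Egger rejection: %.3f (MC se %.3f)\n",
              x$egger_rejection, x$mc_se[["egger"]]))
  cat(sprintf("  Begg rejection:  %.3f (MC se %.3f)\n",
              x$begg_rejection, x$mc_se[["begg"]]))
  cat(sprintf("  CI coverage of mu: %.3f (MC se %.3f)\n",
              x$coverage, x$mc_se[["coverage"]]))
  cat(sprintf("  mean pooled = %.3f (MC se %.3f), mean tau2 = %.3f\n",
              x$mean_pooled, x$mc_se[["pooled"]], x$mean_tau_squared))
  invisible(x)
}
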