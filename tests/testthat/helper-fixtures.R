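# Shared helpers: small builders for effect tables and study frames.

make_effects <- function(theta, v, id = paste0("s", seq_along(theta))) {
  structure(
    data.frame(study_id = id, smd = theta, variance = v, se = sqrt(v),
               ci_low = theta - stats::qnorm(0.975) * sqrt(v),
               ci_high = theta + stats::qnorm(0.975) * sqrt(v),
               stringsAsFactors = FALSE),
    class = c("effect_table", "data.frame"),
    method = "cohen", conf_level = 0.95)
}

make_study_df <- function(n = 2L) {
  data.frame(
    study_id = paste0("S", seq_len(n)), timing = "late", level = "mRNA",
    n_case = 10L + seq_len(n), mean_case = 5 + seq_len(n) / 10,
    sd_case = 1.2, n_control = 12L, mean_control = 4.8, sd_control = 1.1,
    stringsAsFactors = FALSE)
}

# Independent random effect-table instances for property loops.
random_effects <- function(k, rng_offset = 0) {
  make_effects(theta = rnorm(k, 0.3, 0.8) + rng_offset,
               v = runif(k, 0.02, 0.6))
}
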