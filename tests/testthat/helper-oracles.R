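# Independent closed-form oracles and small fixture builders.

# Closed-form logistic solution N(t) = K N0 e^{rt} / (K + N0 (e^{rt} - 1)).
logistic_closed <- function(t, r, K, N0) {
  K * N0 * exp(r * t) / (K + N0 * (exp(r * t) - 1))
}

# Fast sampler settings for unit tests (calibration studies live in the
# acceptance suite and use longer chains).
fast_mcmc <- function(n_samples = 400, seed = 1, ...) {
  mcmc_control(n_samples = n_samples, seed = seed, act_check = FALSE, ...)
}

# Synthetic treated arm generated from the fitted model itself: population
# carrying capacity matching the value fixed in fits, proportional noise.
make_arm <- function(n = 4, frac = 0.5, R = 1, noise_frac = 0.05, seed = 1,
                     K = 1400, group = "T1", noise_sd = NULL) {
  sizes <- stats::setNames(n, group)
  fr <- stats::setNames(frac, group)
  rt <- stats::setNames(R, group)
  cfg <- cohort_config(
    group_sizes = sizes, responder_fraction = fr, resistivity_truth = rt,
    noise_frac = noise_frac,
    noise_sd = if (is.null(noise_sd)) 20 else noise_sd,
    truth_priors = list(
      r_control = c(0.05, 0.30), r_responder = c(0.05, 0.15),
      r_nonresponder = c(0.15, 0.28), alpha_responder = c(0.13, 0.30),
      alpha_nonresponder = c(0, 0.07), K = c(K, K + 1e-9)),
    seed = seed)
  if (!is.null(noise_sd)) cfg$noise_frac <- NULL
  generate_cohort(cfg)
}

# One-mouse cohort data frame from explicit volumes.
one_mouse <- function(volumes, days = c(0, 7, 14), id = "m1", group = "T1") {
  data.frame(mouse_id = id, group = group, day = days[seq_along(volumes)],
             volume_mm3 = volumes, censored = 0L, stringsAsFactors = FALSE)
}

# Minimal stand-in cumulative fit holding given per-mouse draws
# (for resistivity arithmetic tests that need no MCMC).
fake_cumulative_fit <- function(draw_list) {
  structure(list(model = "cumulative", mouse_ids = names(draw_list),
                 draws = draw_list),
            class = "tumor_fit")
}
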