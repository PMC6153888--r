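# small cohort configurations shared across test files

small_upright_config <- function(seed = 11, n = 8, ...) {
  cohort_config(n_participants = n, duration_strategy_fraction = 0,
                orientations = "upright", seed = seed, ...)
}

noiseless_config <- function(seed = 1) {
  cohort_config(n_participants = 4, duration_strategy_fraction = 0,
                participant_sd = 0,
                generative_variant = "hv",
                true_params = anisotropy_params("hv", w_h = 0, w_v = 0),
                seed = seed)
}

# analytic mean absolute error of the hv curve
hv_curve <- function(w_h, w_v, alpha_deg) {
  sqrt((w_h * cospi(alpha_deg / 180))^2 + (w_v * sinpi(alpha_deg / 180))^2)
}
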