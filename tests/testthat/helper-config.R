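# Small, fast simulation configurations used across the tests. Cycle timing
# is compressed (60 s intercontraction interval, short rise/decay) so a
# 3-cycle recording spans ~3.5 min instead of ~30.

zero_cv <- function() setNames(rep(0, 6), stuc_feature_reference()$feature)

small_sim_config <- function(n_cycles = 3, noise = TRUE, cvw = NULL,
                             feature_means = NULL, ...) {
  fm <- c(burst_duration = 4, burst_count = 20)
  fm[names(feature_means)] <- feature_means
  sim_config(
    n_cycles = n_cycles, ici_mean = 60,
    feature_means = fm,
    within_animal_cv = cvw,
    contraction_rise_time = 5, post_void_decay_time = 5,
    min_fill_s = 15, leadin_s = 20, guard_trail_s = 6,
    pressure_noise_sd = if (noise) 0.5 else 0,
    baseline_noise_sd = if (noise) 0.02 else 0,
    ...
  )
}

small_extract_params <- function(n_events = 2, guard_s = 2, ...) {
  extract_params(n_events = n_events, guard_s = guard_s,
                 min_separation = 30, max_post_void = 30,
                 filling_window = 20, rise_margin = 8,
                 deriv_smooth = 0.5, deriv_gap = 0.5,
                 baseline_len = 15, ...)
}
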