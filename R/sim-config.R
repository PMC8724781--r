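#' Simulation configuration for cystometry recordings
#'
#' Builds a validated configuration for the micturition-cycle generator.
#' Defaults reproduce a standard continuous-infusion transurethral protocol:
#' saline infused at 0.088 ml/min, dual-channel acquisition at 2 kHz, and
#' per-event feature distributions centred on the week-1 reference values of
#' [stuc_feature_reference()].
#'
#' Each simulated cycle consists of a slow linear filling ramp from the
#' post-void minimum toward the threshold pressure, a raised-cosine active
#' contraction from threshold to peak over `contraction_rise_time`, a voiding
#' plateau spanning the EUS bursting window, and an exponential decay back to
#' the post-void minimum over `post_void_decay_time`. The EMG channel is a
#' deterministic amplitude envelope (tonic activity during filling, elevated
#' guarding activity immediately around the void, and an alternating
#' burst/quiet envelope during voiding) multiplied by a `carrier_freq`
#' sinusoid, plus additive Gaussian noise, so the raw trace is signed and
#' rectification is meaningful.
#'
#' Feature values are drawn per event from lognormal distributions (all six
#' features are strictly positive) whose means are `feature_means` and whose
#' fractional SDs are `within_animal_cv`; cohort simulation additionally
#' draws per-animal means with `between_animal_cv`. The intercontraction
#' interval is derived from the drawn volume threshold so that
#' `volume_threshold == ici * infusion_rate` holds exactly by construction.
#'
#' @param sampling_rate acquisition rate, Hz.
#' @param infusion_rate pump rate, ml/min.
#' @param n_cycles micturition cycles per recording. The default 6 yields 5
#'   events with a complete intercontraction interval (the last onset closes
#'   the fifth interval).
#' @param feature_means named numeric vector of population means for
#'   `peak_pressure` (mmHg, measured as peak minus post-void minimum),
#'   `threshold_pressure` (mmHg), `min_pressure` (mmHg), `volume_threshold`
#'   (ml), `burst_duration` (s), `burst_count`.
#' @param between_animal_cv,within_animal_cv named numeric vectors of
#'   fractional coefficients of variation per feature; defaults come from the
#'   analytic variance split in [stuc_feature_reference()].
#' @param ici_mean optional mean intercontraction interval, s. If supplied it
#'   overrides `feature_means["volume_threshold"]` via
#'   `volume = ici * infusion_rate / 60`.
#' @param contraction_rise_time,post_void_decay_time shape parameters of the
#'   pressure cycle, s.
#' @param plateau_end_frac fraction of the peak-to-minimum excursion still
#'   present at the end of the voiding plateau (the plateau declines linearly
#'   from the peak to `min + frac * (peak_raw - min)` before the decay).
#' @param leadin_s empty-bladder baseline recorded at the start of infusion,
#'   s; used downstream for catheter offset correction.
#' @param tail_s flat tail after the last void, s.
#' @param min_fill_s minimal filling time required between cycles, s; event
#'   draws violating the cycle geometry are redrawn.
#' @param burst_amplitude,tonic_amplitude,guard_amplitude EMG envelope
#'   amplitudes, mV: bursting peaks, filling-phase tonic activity, and the
#'   elevated peri-void guarding/post-void tonic activity.
#' @param quiet_fraction fraction of the bursting window occupied by quiet
#'   periods; the window opens and closes with a quiet period, so a cycle
#'   with `B` bursts contains `B + 1` quiet gaps.
#' @param guard_lead_s,guard_trail_s extent of the guarding envelope before
#'   contraction onset and after the post-void minimum, s.
#' @param carrier_freq EMG carrier frequency, Hz; must be below the Nyquist
#'   rate.
#' @param baseline_noise_sd additive EMG noise SD, mV.
#' @param pressure_noise_sd additive pressure noise SD, mmHg.
#' @param catheter_offset constant pressure offset added to the whole trace,
#'   mmHg (resistance of the catheter).
#' @param seed optional default RNG seed used when the simulation functions
#'   are called without one.
#' @return An object of class `stuc_sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cycles = 3, ici_mean = 60)
#' cfg
#' @export
sim_config <- function(sampling_rate = 2000,
                       infusion_rate = 0.088,
                       n_cycles = 6,
                       feature_means = NULL,
                       between_animal_cv = NULL,
                       within_animal_cv = NULL,
                       ici_mean = NULL,
                       contraction_rise_time = 15,
                       post_void_decay_time = 10,
                       plateau_end_frac = 0.5,
                       leadin_s = 30,
                       tail_s = 5,
                       min_fill_s = 20,
                       burst_amplitude = 0.5,
                       tonic_amplitude = 0.05,
                       guard_amplitude = 0.15,
                       quiet_fraction = 0.4,
                       guard_lead_s = 4,
                       guard_trail_s = 10,
                       carrier_freq = 250,
                       baseline_noise_sd = 0.02,
                       pressure_noise_sd = 0.5,
                       catheter_offset = 5,
                       seed = NULL) {
  ref <- stuc_feature_reference()
  feats <- stuc_features()
  fm <- setNames(ref$mean, ref$feature)
  if (!is.null(feature_means)) fm[names(feature_means)] <- feature_means
  cvb <- setNames(ref$cv_between, ref$feature)
  if (!is.null(between_animal_cv)) cvb[names(between_animal_cv)] <- between_animal_cv
  cvw <- setNames(ref$cv_within, ref$feature)
  if (!is.null(within_animal_cv)) cvw[names(within_animal_cv)] <- within_animal_cv
  if (!is.null(ici_mean)) fm[["volume_threshold"]] <- ici_mean * infusion_rate / 60

  cfg <- structure(list(
    sampling_rate = sampling_rate, infusion_rate = infusion_rate,
    n_cycles = as.integer(n_cycles), feature_means = fm[feats],
    between_animal_cv = cvb[feats], within_animal_cv = cvw[feats],
    contraction_rise_time = contraction_rise_time,
    post_void_decay_time = post_void_decay_time,
    plateau_end_frac = plateau_end_frac,
    leadin_s = leadin_s, tail_s = tail_s, min_fill_s = min_fill_s,
    burst_amplitude = burst_amplitude, tonic_amplitude = tonic_amplitude,
    guard_amplitude = guard_amplitude, quiet_fraction = quiet_fraction,
    guard_lead_s = guard_lead_s, guard_trail_s = guard_trail_s,
    carrier_freq = carrier_freq,
    baseline_noise_sd = baseline_noise_sd,
    pressure_noise_sd = pressure_noise_sd,
    catheter_offset = catheter_offset,
    seed = seed
  ), class = "stuc_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  fm <- cfg$feature_means
  stopifnot_msg(cfg$sampling_rate > 0, "sampling_rate must be > 0")
  stopifnot_msg(cfg$infusion_rate > 0, "infusion_rate must be > 0")
  stopifnot_msg(cfg$n_cycles >= 1, "n_cycles must be >= 1")
  stopifnot_msg(all(fm > 0), "all feature means must be > 0")
  stopifnot_msg(fm[["min_pressure"]] < fm[["threshold_pressure"]],
                "need min_pressure_mean < threshold_pressure_mean")
  stopifnot_msg(fm[["threshold_pressure"]] < fm[["peak_pressure"]],
                "need threshold_pressure_mean < peak_pressure_mean")
  ici_mean <- sim_ici_mean(cfg)
  stopifnot_msg(fm[["burst_duration"]] < ici_mean,
                "need burst_duration_mean < mean intercontraction interval")
  stopifnot_msg(all(cfg$between_animal_cv >= 0) && all(cfg$within_animal_cv >= 0),
                "coefficients of variation must be >= 0")
  stopifnot_msg(cfg$baseline_noise_sd >= 0 && cfg$pressure_noise_sd >= 0,
                "noise SDs must be >= 0")
  stopifnot_msg(cfg$carrier_freq > 0 && cfg$carrier_freq < cfg$sampling_rate / 2,
                "carrier_freq must lie below the Nyquist rate")
  stopifnot_msg(cfg$quiet_fraction > 0 && cfg$quiet_fraction < 1,
                "quiet_fraction must be in (0, 1)")
  # cycle geometry: contraction + bursting + decay must fit inside the mean ICI
  occupied <- cfg$contraction_rise_time + fm[["burst_duration"]] +
    cfg$post_void_decay_time
  if (occupied >= ici_mean) {
    stop("infeasible cycle geometry: contraction rise + burst duration + ",
         "post-void decay (", signif(occupied, 4), " s) must be shorter than ",
         "the mean intercontraction interval (", signif(ici_mean, 4), " s)",
         call. = FALSE)
  }
  invisible(cfg)
}

# mean ICI implied by the volume-threshold mean and the infusion rate
sim_ici_mean <- function(cfg) {
  cfg$feature_means[["volume_threshold"]] / (cfg$infusion_rate / 60)
}

#' @export
print.stuc_sim_config <- function(x, ...) {
  cat("Cystometry simulation configuration\n")
  cat(sprintf("  acquisition: %g Hz, infusion %g ml/min, %d cycles/recording\n",
              x$sampling_rate, x$infusion_rate, x$n_cycles))
  cat(sprintf("  mean intercontraction interval: %.1f s\n", sim_ici_mean(x)))
  cat(sprintf("  pressure noise SD %g mmHg, catheter offset %g mmHg\n",
              x$pressure_noise_sd, x$catheter_offset))
  cat("  feature means (between-CV / within-CV):\n")
  for (f in names(x$feature_means)) {
    cat(sprintf("    %-20s %8.3f  (%.3f / %.3f)\n", f, x$feature_means[[f]],
                x$between_animal_cv[[f]], x$within_animal_cv[[f]]))
  }
  invisible(x)
}
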