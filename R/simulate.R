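# Generative model of continuous-infusion cystometry recordings.
#
# Per cycle (onset-to-onset interval "ici"):
#   fill (linear, min -> threshold)  | duration ici - (rise + burst + decay)
#   rise (raised cosine, threshold -> raw peak) | contraction_rise_time
#   voiding plateau with EUS bursting            | burst_duration
#   decay (exponential, -> post-void minimum)    | post_void_decay_time
# The EMG is a deterministic envelope times a sinusoidal carrier plus
# additive noise; the envelope alternates burst/quiet during the plateau and
# carries elevated "guarding" tonic activity around the void so that quiet
# periods exist only inside the bursting window.

# lognormal draws parameterised by arithmetic mean and fractional CV
rln_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdl <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdl^2 / 2, sdlog = sdl)
}

# draw per-event feature tuples around `means`, enforcing cycle feasibility
draw_event_features <- function(n, means, cvw, cfg) {
  rate_s <- cfg$infusion_rate / 60        # ml/s
  draw_once <- function(m) {
    data.frame(
      peak_pressure = rln_mean_cv(m, means[["peak_pressure"]], cvw[["peak_pressure"]]),
      threshold_pressure = rln_mean_cv(m, means[["threshold_pressure"]], cvw[["threshold_pressure"]]),
      min_pressure = rln_mean_cv(m, means[["min_pressure"]], cvw[["min_pressure"]]),
      volume_threshold = rln_mean_cv(m, means[["volume_threshold"]], cvw[["volume_threshold"]]),
      burst_duration = rln_mean_cv(m, means[["burst_duration"]], cvw[["burst_duration"]]),
      burst_count = pmax(1, round(rln_mean_cv(m, means[["burst_count"]], cvw[["burst_count"]])))
    )
  }
  ev <- draw_once(n)
  ok <- function(e) {
    ici <- e$volume_threshold / rate_s
    e$min_pressure < e$threshold_pressure &
      e$threshold_pressure < e$min_pressure + e$peak_pressure &
      ici >= cfg$contraction_rise_time + e$burst_duration +
        cfg$post_void_decay_time + cfg$min_fill_s
  }
  bad <- which(!ok(ev))
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > 1000L) {
      stop("could not draw feasible event features after 1000 redraws; ",
           "check the cycle geometry and CVs of the configuration",
           call. = FALSE)
    }
    ev[bad, ] <- draw_once(length(bad))
    bad <- which(!ok(ev))
  }
  ev$ici <- ev$volume_threshold / rate_s   # exact conservation by construction
  ev
}

# EUS burst/quiet envelope over local time x in [0, D): B raised-cosine
# bursts separated (and flanked) by B + 1 quiet gaps
burst_envelope <- function(x, D, B, amp, quiet_fraction) {
  tq <- quiet_fraction * D / (B + 1)
  ta <- (1 - quiet_fraction) * D / B
  p <- tq + ta
  y <- x - tq
  phase <- y %% p
  in_burst <- y >= 0 & y < B * p - tq & phase < ta
  env <- numeric(length(x))
  u <- phase[in_burst] / ta
  env[in_burst] <- amp * (1 - cos(2 * pi * u)) / 2
  env
}

# deterministic (noise-free, offset-free) waveforms + ground-truth table
assemble_recording <- function(events, cfg) {
  fs <- cfg$sampling_rate
  r <- cfg$contraction_rise_time
  d <- cfg$post_void_decay_time
  n <- nrow(events)

  # cycle timing: onset-to-onset gap i is events$ici[i]
  fill <- numeric(n)
  fill[1] <- events$ici[1] - (r + events$burst_duration[1] + d)
  if (n > 1) {
    fill[2:n] <- events$ici[1:(n - 1)] -
      (r + events$burst_duration[1:(n - 1)] + d)
  }
  onset <- cfg$leadin_s + cumsum(fill + c(0, r + events$burst_duration[-n] + d))
  peak_t <- onset + r
  void_end <- onset + r + events$burst_duration + d
  total <- void_end[n] + cfg$tail_s

  nsamp <- floor(total * fs)
  t <- (seq_len(nsamp) - 1) / fs
  pressure <- numeric(nsamp)
  env <- rep(cfg$tonic_amplitude, nsamp)

  praw <- events$min_pressure + events$peak_pressure
  seg <- function(t0, t1) which(t >= t0 & t < t1)

  prev_min <- 0   # empty bladder at infusion start
  for (i in seq_len(n)) {
    Ti <- events$threshold_pressure[i]
    Mi <- events$min_pressure[i]
    Di <- events$burst_duration[i]
    f0 <- onset[i] - fill[i]
    # filling ramp prev_min -> threshold
    j <- seg(f0, onset[i])
    pressure[j] <- prev_min + (Ti - prev_min) * (t[j] - f0) / fill[i]
    # raised-cosine contraction rise threshold -> raw peak
    j <- seg(onset[i], peak_t[i])
    u <- (t[j] - onset[i]) / r
    pressure[j] <- Ti + (praw[i] - Ti) * (1 - cos(pi * u)) / 2
    # voiding plateau: linear decline, bursting EMG
    j <- seg(peak_t[i], peak_t[i] + Di)
    vend <- Mi + cfg$plateau_end_frac * (praw[i] - Mi)
    u <- (t[j] - peak_t[i]) / Di
    pressure[j] <- praw[i] + (vend - praw[i]) * u
    env[j] <- burst_envelope(t[j] - peak_t[i], Di, events$burst_count[i],
                             cfg$burst_amplitude, cfg$quiet_fraction)
    # post-void exponential decay -> minimum
    j <- seg(peak_t[i] + Di, void_end[i])
    u <- (t[j] - peak_t[i] - Di) / d
    kdec <- 5
    pressure[j] <- Mi + (vend - Mi) *
      (exp(-kdec * u) - exp(-kdec)) / (1 - exp(-kdec))
    # guarding EMG activity around the void (outside the bursting window)
    j <- seg(onset[i] - cfg$guard_lead_s, peak_t[i])
    env[j] <- cfg$guard_amplitude
    j <- seg(peak_t[i] + Di, void_end[i] + cfg$guard_trail_s)
    env[j] <- cfg$guard_amplitude
    prev_min <- Mi
  }
  # tail after the last void: minimum pressure, sustained post-void tonic EMG
  j <- seg(void_end[n], total)
  pressure[j] <- events$min_pressure[n]
  env[j] <- cfg$guard_amplitude

  truth <- data.frame(
    event_index = seq_len(n),
    peak_pressure = events$peak_pressure,
    threshold_pressure = events$threshold_pressure,
    min_pressure = events$min_pressure,
    ici = c(events$ici[-n] * 0 + diff(onset), NA_real_),
    volume_threshold = c(events$volume_threshold[-n], NA_real_),
    burst_count = events$burst_count,
    burst_duration = events$burst_duration,
    onset_time = onset, peak_time = peak_t, void_end_time = void_end
  )
  # realized inter-onset gaps equal the drawn ICIs by construction; keep the
  # drawn values so volume = ici * rate is exact to machine precision
  if (n > 1) truth$ici[seq_len(n - 1)] <- events$ici[seq_len(n - 1)]
  list(pressure = pressure, envelope = env, truth = truth, t = t)
}

# add carrier + noise + offset, wrap into a stuc_recording
materialize_recording <- function(parts, cfg, animal_id, session_id) {
  nsamp <- length(parts$pressure)
  pressure <- parts$pressure + cfg$catheter_offset
  if (cfg$pressure_noise_sd > 0) {
    pressure <- pressure + rnorm(nsamp, 0, cfg$pressure_noise_sd)
  }
  emg <- parts$envelope * sin(2 * pi * cfg$carrier_freq * parts$t)
  if (cfg$baseline_noise_sd > 0) {
    emg <- emg + rnorm(nsamp, 0, cfg$baseline_noise_sd)
  }
  stuc_recording(pressure, emg, cfg$sampling_rate,
                 animal_id = animal_id, session_id = session_id,
                 infusion_rate = cfg$infusion_rate)
}

#' Simulate one cystometry recording with known ground truth
#'
#' Generates a dual-channel recording containing `config$n_cycles` rhythmic
#' micturition cycles. Per-event feature values are drawn around the
#' configuration's feature means with the within-animal CVs; the
#' intercontraction interval is derived from the drawn volume threshold so
#' that `volume_threshold == ici * infusion_rate` exactly.
#'
#' @param config a [sim_config()].
#' @param rng_seed integer seed; falls back to `config$seed`. Results are
#'   bit-reproducible for a fixed seed.
#' @param animal_id,session_id identifiers stamped into the recording
#'   metadata and the truth table.
#' @return A list with elements `recording` (a [stuc_recording()]) and
#'   `truth` (a data.frame with one row per cycle: true feature values and
#'   the fiducial times of contraction onset, peak and void end). The last
#'   cycle has no following onset, so its `ici` and `volume_threshold` are
#'   `NA`.
#' @examples
#' cfg <- sim_config(n_cycles = 2, ici_mean = 60, within_animal_cv = setNames(
#'   rep(0, 6), stuc_feature_reference()$feature))
#' sim <- simulate_recording(cfg, rng_seed = 1)
#' sim$truth
#' @export
simulate_recording <- function(config, rng_seed = NULL,
                               animal_id = "a01", session_id = 1L) {
  seed <- if (!is.null(rng_seed)) rng_seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  ev <- draw_event_features(config$n_cycles, config$feature_means,
                            config$within_animal_cv, config)
  parts <- assemble_recording(ev, config)
  rec <- materialize_recording(parts, config, animal_id, session_id)
  truth <- cbind(data.frame(animal_id = animal_id, session_id = session_id,
                            stringsAsFactors = FALSE), parts$truth)
  list(recording = rec, truth = truth)
}

# per-animal/session ground-truth feature draws for a cohort
draw_cohort_truth <- function(config, n_animals, n_sessions, session_effect) {
  feats <- stuc_features()
  eff <- matrix(1, nrow = n_sessions, ncol = length(feats),
                dimnames = list(NULL, feats))
  if (!is.null(session_effect)) {
    for (f in names(session_effect)) {
      v <- session_effect[[f]]
      if (length(v) != n_sessions) {
        stop("session_effect[['", f, "']] must have length n_sessions",
             call. = FALSE)
      }
      eff[, f] <- 1 + v
    }
  }
  animal_means <- sapply(feats, function(f) {
    rln_mean_cv(n_animals, config$feature_means[[f]], config$between_animal_cv[[f]])
  })
  animal_means <- matrix(animal_means, nrow = n_animals,
                         dimnames = list(NULL, feats))
  list(animal_means = animal_means, session_multiplier = eff)
}

#' Simulate a multi-animal, multi-session cohort
#'
#' Draws per-animal feature means from the population means with the
#' between-animal CVs (one draw per animal, shared across its sessions, so
#' animals act as blocks in across-session analyses), then generates one
#' recording per animal x session with per-event within-animal variability.
#' There is no systematic session effect unless `session_effect` is given.
#'
#' @param config a [sim_config()].
#' @param n_animals number of animals (>= 2).
#' @param n_sessions recording sessions per animal (>= 1).
#' @param rng_seed integer seed; falls back to `config$seed`.
#' @param session_effect optional named list, one entry per affected feature,
#'   each a numeric vector of length `n_sessions` of fractional shifts of the
#'   population mean (e.g. `list(peak_pressure = c(0, 0.2, 0))` raises the
#'   session-2 mean by 20%).
#' @return A list with `recordings` (list of [stuc_recording()], one per
#'   animal x session, animals varying slowest) and `truth` (row-bound
#'   per-event ground-truth table). Note a full-scale cohort held in memory
#'   is large; see [cohort_study()] for a streaming
#'   simulate-and-extract driver.
#' @export
simulate_cohort <- function(config, n_animals, n_sessions = 1,
                            rng_seed = NULL, session_effect = NULL) {
  out <- cohort_walk(config, n_animals, n_sessions, rng_seed, session_effect,
                     keep_recordings = TRUE)
  list(recordings = out$recordings, truth = out$truth)
}

#' Draw the ground-truth feature table of a cohort without synthesizing
#' signals
#'
#' Same variance-component model as [simulate_cohort()] (per-animal means
#' with between-animal CV, per-event values with within-animal CV, optional
#' session effect) but skips waveform synthesis. Useful for Monte-Carlo work
#' on the statistics where only true feature values are needed.
#'
#' @inheritParams simulate_cohort
#' @param n_events events per animal x session.
#' @return A long data.frame: `animal_id`, `session_id`, `event_index`, one
#'   column per feature.
#' @export
simulate_cohort_features <- function(config, n_animals, n_sessions = 1,
                                     n_events = 5, rng_seed = NULL,
                                     session_effect = NULL) {
  seed <- if (!is.null(rng_seed)) rng_seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  if (n_animals < 2) stop("n_animals must be >= 2", call. = FALSE)
  if (n_sessions < 1) stop("n_sessions must be >= 1", call. = FALSE)
  truth <- draw_cohort_truth(config, n_animals, n_sessions, session_effect)
  rows <- vector("list", n_animals * n_sessions)
  k <- 0L
  for (a in seq_len(n_animals)) {
    for (s in seq_len(n_sessions)) {
      means <- truth$animal_means[a, ] * truth$session_multiplier[s, ]
      ev <- draw_event_features(n_events, as.list(means),
                                config$within_animal_cv, config)
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(animal_id = sprintf("a%02d", a), session_id = s,
                   event_index = seq_len(n_events), stringsAsFactors = FALSE),
        ev[c(stuc_features(), "ici")]
      )
    }
  }
  do.call(rbind, rows)
}

# shared cohort driver: generates each recording in turn and either keeps it
# or hands it to `callback(recording, truth_rows)` and drops it
cohort_walk <- function(config, n_animals, n_sessions, rng_seed,
                        session_effect, keep_recordings, callback = NULL) {
  seed <- if (!is.null(rng_seed)) rng_seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  if (n_animals < 2) stop("n_animals must be >= 2", call. = FALSE)
  if (n_sessions < 1) stop("n_sessions must be >= 1", call. = FALSE)
  truth <- draw_cohort_truth(config, n_animals, n_sessions, session_effect)
  recordings <- if (keep_recordings) vector("list", n_animals * n_sessions)
  truth_rows <- vector("list", n_animals * n_sessions)
  k <- 0L
  for (a in seq_len(n_animals)) {
    aid <- sprintf("a%02d", a)
    for (s in seq_len(n_sessions)) {
      means <- truth$animal_means[a, ] * truth$session_multiplier[s, ]
      ev <- draw_event_features(config$n_cycles, as.list(means),
                                config$within_animal_cv, config)
      parts <- assemble_recording(ev, config)
      rec <- materialize_recording(parts, config, aid, s)
      tr <- cbind(data.frame(animal_id = aid, session_id = s,
                             stringsAsFactors = FALSE), parts$truth)
      k <- k + 1L
      truth_rows[[k]] <- tr
      if (keep_recordings) recordings[[k]] <- rec
      if (!is.null(callback)) callback(rec, tr)
    }
  }
  list(recordings = recordings, truth = do.call(rbind, truth_rows))
}
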