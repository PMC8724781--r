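# Per-recording extraction driver: conditioning -> void detection ->
# bladder features -> EUS features -> stable-window selection.

#' Extract urodynamic features from one recording
#'
#' Runs the full extraction chain on a recording: conditioning
#' (rectification, block-mean resampling, offset correction), voiding-peak
#' detection, threshold-pressure detection, bladder feature measurement, EMG
#' baseline estimation and per-void burst quantification, then selection of
#' the `params$n_events` successive events with the most stable
#' intercontraction interval.
#'
#' Events whose threshold detection fails are excluded from selection and
#' reported in the QC log rather than imputed.
#'
#' @param rec a [stuc_recording()] (or an already conditioned
#'   `stuc_conditioned`).
#' @param params an [extract_params()].
#' @return A list of class `stuc_session_features`:
#'   \describe{
#'     \item{events}{per-event feature data.frame (all detected events).}
#'     \item{selected}{indices of the selected stable events.}
#'     \item{table}{long-format rows (`animal_id`, `session_id`,
#'       `event_index`, `feature`, `value`) for the selected events — the
#'       six features per event.}
#'     \item{qc}{character vector of QC messages (exclusions, failures).}
#'     \item{baseline}{the EMG baseline used.}
#'   }
#' @export
extract_session_features <- function(rec, params = extract_params()) {
  cond <- if (inherits(rec, "stuc_conditioned")) rec else {
    condition_recording(rec, params$effective_rate, params$baseline_window)
  }
  meta <- cond$metadata
  qc <- character(0)
  # light smoothing before values are read off: suppresses the upward bias
  # of a max (and downward bias of a min) taken over many noisy samples
  psm <- boxcar_smooth(cond$pressure, params$measure_smooth, cond$rate)
  voids <- detect_voids(psm, cond$rate, params)
  if (nrow(voids) == 0) {
    stop("no voiding contraction detected in recording ", meta$animal_id,
         "/", meta$session_id, call. = FALSE)
  }
  ev <- measure_events(psm, cond$rate, voids, meta$infusion_rate, params)
  failed <- which(!ev$ok)
  if (length(failed) > 0) {
    qc <- c(qc, sprintf(
      "event %d: threshold detection failed, excluded from averages", failed))
  }
  # EMG void windows: contraction onset - pre_void to the post-void minimum
  win_start <- ifelse(is.na(ev$onset_time), voids$peak_time - params$pre_void,
                      ev$onset_time - params$pre_void)
  windows <- cbind(win_start, voids$post_void_min_time)
  baseline <- estimate_emg_baseline(cond$emg, cond$rate, windows, params)
  ev$burst_count <- NA_real_
  ev$burst_duration <- NA_real_
  for (i in seq_len(nrow(ev))) {
    w <- windows[i, ]
    ev$burst_count[i] <- count_burst_events(cond$emg, cond$rate, w,
                                            baseline, params)
    qp <- detect_quiet_periods(cond$emg, cond$rate, w, baseline, params)
    ev$burst_duration[i] <- burst_duration(qp)
  }
  sel <- select_stable_events(ev, n = params$n_events,
                              start_time = params$stable_start)
  feats <- stuc_features()
  sub <- ev[sel, ]
  table <- data.frame(
    animal_id = meta$animal_id,
    session_id = meta$session_id,
    event_index = rep(seq_along(sel), times = length(feats)),
    feature = rep(feats, each = length(sel)),
    value = unlist(sub[feats], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  validate_feature_table(table)
  structure(list(events = ev, selected = sel, table = table, qc = qc,
                 baseline = baseline, metadata = meta),
            class = "stuc_session_features")
}

#' @export
print.stuc_session_features <- function(x, ...) {
  cat(sprintf("Session features: animal %s, session %s\n",
              x$metadata$animal_id, x$metadata$session_id))
  cat(sprintf("  %d events detected, stable window: events %s\n",
              nrow(x$events), paste(range(x$selected), collapse = "-")))
  means <- tapply(x$table$value, x$table$feature, mean)
  for (f in stuc_features()) {
    cat(sprintf("  mean %-20s %.3f\n", f, means[[f]]))
  }
  if (length(x$qc) > 0) cat("  QC:", paste(x$qc, collapse = "; "), "\n")
  invisible(x)
}

#' Simulate and extract a whole cohort, one recording at a time
#'
#' Streaming driver for cohort-scale work: each recording is generated with
#' the cohort variance model of [simulate_cohort()], immediately run through
#' [extract_session_features()], and discarded, so memory stays flat
#' regardless of cohort size.
#'
#' @inheritParams simulate_cohort
#' @param params an [extract_params()].
#' @return A list: `features` (long-format feature table over all selected
#'   events of all recordings), `truth` (ground-truth table), `qc`
#'   (per-recording QC messages).
#' @export
cohort_study <- function(config, n_animals, n_sessions = 1, rng_seed = NULL,
                         session_effect = NULL, params = extract_params()) {
  tables <- list()
  qc <- character(0)
  collect <- function(rec, truth_rows) {
    sf <- extract_session_features(rec, params)
    tables[[length(tables) + 1L]] <<- sf$table
    if (length(sf$qc) > 0) {
      qc <<- c(qc, sprintf("%s/%s: %s", rec$metadata$animal_id,
                           rec$metadata$session_id, sf$qc))
    }
  }
  out <- cohort_walk(config, n_animals, n_sessions, rng_seed, session_effect,
                     keep_recordings = FALSE, callback = collect)
  list(features = do.call(rbind, tables), truth = out$truth, qc = qc)
}
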