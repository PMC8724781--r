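# Micturition event detection and bladder-side feature measurement on the
# conditioned pressure trace.

#' Extraction parameters
#'
#' Tunable parameters of the feature-extraction pipeline with their
#' defaults. Peak prominence and minimum separation sit an order of
#' magnitude below typical voiding peak amplitudes (~20 mmHg) and
#' intercontraction intervals (~300 s); the slope-change criterion and its
#' windows govern threshold-pressure detection; the EMG parameters govern
#' burst counting and quiet-period detection at the effective rate.
#'
#' @param effective_rate analysis rate after block-mean resampling, Hz.
#' @param baseline_window pressure offset-correction window, s.
#' @param peak_prominence minimum peak prominence for void detection, mmHg.
#' @param min_separation minimum separation between voiding peaks, s.
#' @param max_post_void latest time after a peak at which its post-void
#'   minimum may occur, s; bounds the minimum search so that on nearly flat
#'   filling ramps noise cannot push the minimum deep into the next filling
#'   phase.
#' @param detect_rate coarse rate used to locate candidate voiding peaks, Hz
#'   (peaks are refined on the effective-rate trace).
#' @param slope_k slope-change criterion: contraction onset is the latest
#'   sustained crossing of filling-slope mean + `slope_k` * SD.
#' @param filling_window window used to estimate the filling-slope mean and
#'   SD, s (must cover at least 10 effective samples).
#' @param rise_margin gap between the end of the filling window and the
#'   peak, s; should exceed the contraction rise time.
#' @param deriv_smooth boxcar width used to smooth pressure before
#'   differentiation, s.
#' @param deriv_gap half-gap of the central-difference derivative, s.
#' @param n_events number of successive events averaged per session.
#' @param stable_start optional user-supplied start time of the stable
#'   window, s; overrides automatic minimum-CV selection.
#' @param ici_fiducial `"onset"` (contraction onset to next onset, default)
#'   or `"peak"` (peak to next peak) for the intercontraction interval.
#' @param guard_s distance kept between the EMG baseline window and any
#'   detected void, s.
#' @param baseline_len maximum EMG baseline window length, s.
#' @param quiet_k quiet-period criterion: rectified amplitude below baseline
#'   mean + `quiet_k` * SD.
#' @param min_quiet minimum quiet-period duration, s.
#' @param min_peak_sep minimum separation of counted EMG burst peaks, s.
#' @param min_peak_prom_sd minimum topographic prominence of a counted
#'   burst peak, in baseline SDs; separates bursts (which rise from
#'   near-silent quiet gaps) from tonic activity whose noise fluctuations
#'   also cross the amplitude criterion.
#' @param min_peak_prom_frac minimum prominence of a counted burst peak as
#'   a fraction of the peak's own elevation above the baseline mean.
#' @param measure_smooth boxcar width (s) of the light smoothing applied to
#'   the conditioned pressure before peak, minimum and threshold values are
#'   read off, suppressing extreme-value noise bias.
#' @param pre_void time before contraction onset included in the EMG void
#'   window, s.
#' @return A list of class `stuc_extract_params`.
#' @export
extract_params <- function(effective_rate = 100,
                           baseline_window = c(0, 10),
                           peak_prominence = 10,
                           min_separation = 60,
                           max_post_void = 60,
                           detect_rate = 2,
                           slope_k = 3,
                           filling_window = 60,
                           rise_margin = 30,
                           deriv_smooth = 1,
                           deriv_gap = 1,
                           n_events = 5,
                           stable_start = NULL,
                           ici_fiducial = c("onset", "peak"),
                           guard_s = 30,
                           baseline_len = 60,
                           quiet_k = 1,
                           min_quiet = 0.02,
                           min_peak_sep = 0.05,
                           min_peak_prom_sd = 10,
                           min_peak_prom_frac = 0.5,
                           measure_smooth = 0.5,
                           pre_void = 1) {
  structure(list(
    effective_rate = effective_rate, baseline_window = baseline_window,
    peak_prominence = peak_prominence, min_separation = min_separation,
    max_post_void = max_post_void,
    detect_rate = detect_rate, slope_k = slope_k,
    filling_window = filling_window, rise_margin = rise_margin,
    deriv_smooth = deriv_smooth, deriv_gap = deriv_gap,
    n_events = n_events, stable_start = stable_start,
    ici_fiducial = match.arg(ici_fiducial),
    guard_s = guard_s, baseline_len = baseline_len, quiet_k = quiet_k,
    min_quiet = min_quiet, min_peak_sep = min_peak_sep,
    min_peak_prom_sd = min_peak_prom_sd,
    min_peak_prom_frac = min_peak_prom_frac,
    measure_smooth = measure_smooth, pre_void = pre_void
  ), class = "stuc_extract_params")
}

# centred boxcar smoother; edges keep the original samples
boxcar_smooth <- function(x, w_s, rate) {
  w <- as.integer(round(w_s * rate))
  if (w < 2) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  na <- is.na(sm)
  sm[na] <- x[na]
  sm
}

# local maxima of a vector (first sample of any plateau)
local_maxima <- function(z) {
  n <- length(z)
  if (n < 3) return(integer(0))
  which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
}

# topographic prominence of candidate index c within z: height above the
# higher of the two saddles toward the nearest higher ground on each side
# (or the side minimum when no higher ground exists on that side)
prominence_of <- function(z, c) {
  h <- z[c]
  scan <- function(idx) {
    m <- Inf
    for (i in idx) {
      if (z[i] > h) break
      if (z[i] < m) m <- z[i]
    }
    m
  }
  ls <- scan(rev(seq_len(c - 1)))
  rs <- scan(if (c < length(z)) (c + 1):length(z) else integer(0))
  h - max(ls, rs)
}

#' Detect voiding contractions in a conditioned pressure trace
#'
#' Voiding peaks are local maxima whose topographic prominence exceeds
#' `peak_prominence`, separated by at least `min_separation` seconds
#' (enforced greedily, keeping the taller peak). Candidates are located on a
#' coarse block-mean trace (`detect_rate`) and refined on the full
#' effective-rate trace. Each event's post-void minimum is the pressure
#' minimum between its peak and the next peak (or the record end), with the
#' search bounded at `max_post_void` seconds after the peak. A trace with no
#' qualifying peak yields an empty table, not an error.
#'
#' @param pressure conditioned (offset-corrected) pressure vector, mmHg.
#' @param rate sampling rate of `pressure`, Hz.
#' @param params an [extract_params()].
#' @return A data.frame sorted by time with columns `peak_time`,
#'   `peak_pressure_raw`, `post_void_min_time`, `post_void_min_pressure`,
#'   `cycle_start`, `cycle_end` (s, mmHg).
#' @export
detect_voids <- function(pressure, rate, params = extract_params()) {
  stopifnot(length(pressure) >= 2)
  block <- max(1L, as.integer(floor(rate / params$detect_rate)))
  crate <- rate / block
  z <- if (block > 1L) {
    nb <- length(pressure) %/% block
    colMeans(matrix(pressure[seq_len(nb * block)], nrow = block))
  } else pressure
  cand <- local_maxima(z)
  # cheap pre-filter: a peak of the required prominence must rise at least
  # that far above the global minimum
  cand <- cand[z[cand] >= min(z) + params$peak_prominence]
  if (length(cand) > 0) {
    prom <- vapply(cand, function(c) prominence_of(z, c), 0)
    cand <- cand[prom >= params$peak_prominence]
  }
  if (length(cand) == 0) {
    return(data.frame(peak_time = numeric(0), peak_pressure_raw = numeric(0),
                      post_void_min_time = numeric(0),
                      post_void_min_pressure = numeric(0),
                      cycle_start = numeric(0), cycle_end = numeric(0)))
  }
  # minimum separation, tallest first
  keep <- logical(length(cand))
  for (i in order(z[cand], decreasing = TRUE)) {
    ti <- cand[i] / crate
    if (!any(keep & abs(cand / crate - ti) < params$min_separation)) {
      keep[i] <- TRUE
    }
  }
  cand <- sort(cand[keep])
  # refine each peak on the full-resolution trace (+-2 coarse blocks)
  half <- 2L * block
  peak_idx <- vapply(cand, function(c) {
    centre <- (c - 1L) * block + block %/% 2L + 1L
    i0 <- max(1L, centre - half); i1 <- min(length(pressure), centre + half)
    i0 + which.max(pressure[i0:i1]) - 1L
  }, 0L)
  peak_idx <- sort(unique(peak_idx))
  np <- length(peak_idx)
  min_idx <- integer(np)
  for (i in seq_len(np)) {
    i0 <- peak_idx[i] + 1L
    i1 <- if (i < np) peak_idx[i + 1] else length(pressure)
    i1 <- min(i1, peak_idx[i] + as.integer(params$max_post_void * rate))
    seg <- pressure[i0:i1]
    min_idx[i] <- i0 + which.min(seg) - 1L
  }
  data.frame(
    peak_time = (peak_idx - 1) / rate,
    peak_pressure_raw = pressure[peak_idx],
    post_void_min_time = (min_idx - 1) / rate,
    post_void_min_pressure = pressure[min_idx],
    cycle_start = c(0, (min_idx[-np] - 1) / rate),
    cycle_end = (min_idx - 1) / rate
  )
}

#' Threshold pressure at contraction onset
#'
#' The contraction onset is where the slope of the pressure record shows an
#' abrupt increase above the filling slope. The smoothed first derivative is
#' compared to a criterion of filling-slope mean + `slope_k` * SD estimated
#' over a filling window well before the peak; the onset is the latest
#' upward crossing of the criterion that stays above it through the point of
#' steepest rise. If the derivative never exceeds the criterion the event is
#' flagged as a detection failure (`ok = FALSE`).
#'
#' @param pressure conditioned pressure vector, mmHg.
#' @param rate Hz.
#' @param peak_time peak time of the event, s.
#' @param prev_bound left bound of the search (previous post-void minimum or
#'   record start), s.
#' @param params an [extract_params()].
#' @return A list: `ok`, `time` (s), `threshold_pressure` (mmHg).
#' @export
find_threshold_pressure <- function(pressure, rate, peak_time,
                                    prev_bound = 0, params = extract_params()) {
  n <- length(pressure)
  w <- max(3L, as.integer(round(params$deriv_smooth * rate)))
  if (w %% 2L == 0L) w <- w + 1L
  g <- max(1L, as.integer(round(params$deriv_gap * rate)))
  sm <- as.numeric(stats::filter(pressure, rep(1 / w, w), sides = 2))
  d <- rep(NA_real_, n)
  lo <- (g + 1):(n - g)
  d[lo] <- (sm[lo + g] - sm[lo - g]) * rate / (2 * g)

  peak_idx <- round(peak_time * rate) + 1L
  end_f <- peak_idx - as.integer(round(params$rise_margin * rate))
  start_f <- max(floor(prev_bound * rate) + 1L,
                 end_f - as.integer(round(params$filling_window * rate)))
  fail <- list(ok = FALSE, time = NA_real_, threshold_pressure = NA_real_)
  if (end_f - start_f + 1L < 10L) return(fail)  # need >= 10 effective samples
  dwin <- d[start_f:end_f]
  if (all(is.na(dwin))) return(fail)
  mu <- mean(dwin, na.rm = TRUE)
  sdv <- sd(dwin, na.rm = TRUE)
  crit <- mu + params$slope_k * sdv + 1e-12

  # steepest rise between the filling window and the peak
  search <- start_f:min(peak_idx, n)
  ds <- d[search]
  if (all(is.na(ds))) return(fail)
  imax <- search[which.max(ds)]
  if (is.na(d[imax]) || d[imax] <= crit) return(fail)
  # walk back from the steepest rise while the criterion holds
  j <- imax
  while (j > start_f && !is.na(d[j - 1]) && d[j - 1] > crit) j <- j - 1L
  list(ok = TRUE, time = (j - 1) / rate, threshold_pressure = pressure[j])
}

#' Bladder-side features for a sequence of detected events
#'
#' Computes, per event: `peak_pressure` (raw peak minus post-void minimum),
#' `min_pressure` (the post-void minimum), `threshold_pressure` (at the
#' detected onset), `ici` (onset-to-onset by default; peak-to-peak behind
#' `params$ici_fiducial`), and `volume_threshold = ici * infusion_rate`
#' (ml/min converted to ml/s). The final event has no following onset and
#' contributes no ICI or volume threshold. Events whose threshold detection
#' failed have `NA` threshold and are flagged `ok = FALSE`.
#'
#' @param pressure conditioned pressure vector, mmHg.
#' @param rate Hz.
#' @param voids output of [detect_voids()].
#' @param infusion_rate ml/min.
#' @param params an [extract_params()].
#' @return A data.frame with one row per event: `event_index`, `onset_time`,
#'   `peak_time`, the five bladder features and `ok`.
#' @export
measure_events <- function(pressure, rate, voids, infusion_rate,
                           params = extract_params()) {
  if (infusion_rate <= 0) stop("infusion_rate must be > 0", call. = FALSE)
  np <- nrow(voids)
  out <- data.frame(
    event_index = seq_len(np),
    onset_time = NA_real_, peak_time = voids$peak_time,
    peak_pressure = voids$peak_pressure_raw - voids$post_void_min_pressure,
    threshold_pressure = NA_real_,
    min_pressure = voids$post_void_min_pressure,
    ici = NA_real_, volume_threshold = NA_real_,
    ok = rep(TRUE, np)
  )
  if (np == 0) return(out)
  for (i in seq_len(np)) {
    prev_bound <- if (i == 1) 0 else voids$post_void_min_time[i - 1]
    th <- find_threshold_pressure(pressure, rate, voids$peak_time[i],
                                  prev_bound, params)
    out$ok[i] <- th$ok
    out$onset_time[i] <- th$time
    out$threshold_pressure[i] <- th$threshold_pressure
  }
  if (np > 1) {
    for (i in seq_len(np - 1)) {
      ici <- if (params$ici_fiducial == "peak") {
        voids$peak_time[i + 1] - voids$peak_time[i]
      } else {
        out$onset_time[i + 1] - out$onset_time[i]
      }
      if (!is.na(ici) && ici <= 0) {
        stop("nonpositive intercontraction interval between events ", i,
             " and ", i + 1, call. = FALSE)
      }
      out$ici[i] <- ici
      out$volume_threshold[i] <- ici * infusion_rate / 60
    }
  }
  out
}

#' Select the stable window of successive events
#'
#' Returns the indices of `n` successive events with complete features,
#' choosing the contiguous window that minimizes the coefficient of
#' variation of the intercontraction interval (ties broken by the earliest
#' window). A user-supplied `start_time` overrides automatic selection: the
#' window then begins at the first valid event at or after that time.
#'
#' @param features output of [measure_events()] (optionally augmented with
#'   EMG features).
#' @param n events to select.
#' @param start_time optional override, s.
#' @return Integer vector of `n` row indices into `features`.
#' @export
select_stable_events <- function(features, n = 5, start_time = NULL) {
  valid <- which(features$ok & !is.na(features$ici) &
                   !is.na(features$threshold_pressure))
  # windows must be contiguous in the original event sequence
  runs <- split(valid, cumsum(c(1, diff(valid) != 1)))
  if (!is.null(start_time)) {
    cand <- valid[features$onset_time[valid] >= start_time]
    if (length(cand) == 0 ||
        !(all((cand[1]:(cand[1] + n - 1)) %in% valid))) {
      stop("fewer than ", n, " valid successive events after start_time ",
           start_time, call. = FALSE)
    }
    return(cand[1]:(cand[1] + n - 1))
  }
  best <- NULL
  best_cv <- Inf
  for (run in runs) {
    if (length(run) < n) next
    for (s in seq_len(length(run) - n + 1)) {
      idx <- run[s:(s + n - 1)]
      ici <- features$ici[idx]
      cv <- sd(ici) / mean(ici)
      if (cv < best_cv - 1e-12) {
        best_cv <- cv
        best <- idx
      }
    }
  }
  if (is.null(best)) {
    stop("insufficient valid events: need ", n, " successive, found ",
         length(valid), " valid in total", call. = FALSE)
  }
  best
}
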