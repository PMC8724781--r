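# Quantification of EUS bursting during voiding: burst events are rectified
# EMG peaks exceeding baseline mean + 2 SD; burst duration runs from the
# onset of the first quiet period to the end of the last quiet period.

#' EMG baseline statistics
#'
#' Mean and SD of the rectified, resampled EMG over a filling-phase window
#' kept at least `guard_s` seconds away from every detected void. The
#' longest eligible contiguous stretch is used, truncated to
#' `baseline_len` seconds.
#'
#' @param emg_rect rectified resampled EMG vector, mV.
#' @param rate Hz.
#' @param void_windows two-column matrix (start, end) of void windows, s;
#'   may have zero rows.
#' @param params an [extract_params()].
#' @return A list of class `stuc_emg_baseline`: `mean`, `sd` (mV), `window`
#'   (start, end in s).
#' @export
estimate_emg_baseline <- function(emg_rect, rate, void_windows,
                                  params = extract_params()) {
  n <- length(emg_rect)
  t <- (seq_len(n) - 1) / rate
  eligible <- rep(TRUE, n)
  if (nrow(void_windows) > 0) {
    for (i in seq_len(nrow(void_windows))) {
      eligible[t >= void_windows[i, 1] - params$guard_s &
                 t <= void_windows[i, 2] + params$guard_s] <- FALSE
    }
  }
  if (!any(eligible)) {
    stop("no EMG baseline window available: the guard excludes every sample",
         call. = FALSE)
  }
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values)
  best <- ok[which.max(runs$lengths[ok])]
  i0 <- starts[best]
  i1 <- min(ends[best], i0 + as.integer(params$baseline_len * rate) - 1L)
  if (i1 - i0 + 1L < rate) {
    stop("EMG baseline window shorter than 1 s after applying the guard",
         call. = FALSE)
  }
  structure(list(mean = mean(emg_rect[i0:i1]), sd = sd(emg_rect[i0:i1]),
                 window = c((i0 - 1) / rate, (i1 - 1) / rate)),
            class = "stuc_emg_baseline")
}

#' Count EUS burst events during a void
#'
#' Number of EMG peaks inside the void window whose amplitude exceeds
#' baseline mean + 2 SD, with a minimum inter-peak separation
#' (`params$min_peak_sep`, enforced greedily keeping the larger peak).
#' Because sustained tonic or guarding activity can also cross a purely
#' amplitude-based criterion through its noise fluctuations, counted peaks
#' must additionally have a topographic prominence of at least
#' `params$min_peak_prom_sd` baseline SDs and at least
#' `params$min_peak_prom_frac` of their own elevation above the baseline
#' mean: genuine bursts emerge from near-silent quiet gaps and clear both
#' easily, while tonic or guarding activity does not. Zero is a valid
#' count.
#'
#' @param emg_rect rectified resampled EMG, mV.
#' @param rate Hz.
#' @param void_window `c(start, end)`, s.
#' @param baseline an [estimate_emg_baseline()].
#' @param params an [extract_params()].
#' @return Integer count.
#' @export
count_burst_events <- function(emg_rect, rate, void_window, baseline,
                               params = extract_params()) {
  idx <- window_indices(void_window, rate, length(emg_rect))
  length(emg_burst_peaks(emg_rect[idx], rate, baseline, params))
}

# indices (within seg) of accepted burst peaks: amplitude, prominence and
# minimum-separation criteria
emg_burst_peaks <- function(seg, rate, baseline, params) {
  thr <- baseline$mean + 2 * baseline$sd
  cand <- local_maxima(seg)
  cand <- cand[seg[cand] > thr]
  if (length(cand) > 0) {
    prom <- vapply(cand, function(c) prominence_of(seg, c), 0)
    min_prom <- pmax(params$min_peak_prom_sd * baseline$sd,
                     params$min_peak_prom_frac * (seg[cand] - baseline$mean))
    cand <- cand[prom >= min_prom]
  }
  if (length(cand) == 0) return(integer(0))
  keep <- logical(length(cand))
  min_sep <- params$min_peak_sep * rate
  for (i in order(seg[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < min_sep)) keep[i] <- TRUE
  }
  sort(cand[keep])
}

#' Detect EMG quiet periods within a void window
#'
#' Maximal intervals where the rectified amplitude stays below baseline
#' mean + `quiet_k` * SD for at least `min_quiet` seconds. Quiet periods
#' are the silent gaps of the bursting episode, so when two or more burst
#' peaks are detected in the window the search is confined to the episode
#' they delimit (first to last burst peak, extended by one median
#' inter-burst interval on each side); this keeps unrelated low tonic
#' activity elsewhere in the window from being read as quiescence.
#' Returned sorted and non-overlapping; an empty result is valid (e.g. for
#' a constantly supra-threshold signal).
#'
#' @inheritParams count_burst_events
#' @return A data.frame with columns `start`, `end` (s).
#' @export
detect_quiet_periods <- function(emg_rect, rate, void_window, baseline,
                                 params = extract_params()) {
  idx <- window_indices(void_window, rate, length(emg_rect))
  seg <- emg_rect[idx]
  pk <- emg_burst_peaks(seg, rate, baseline, params)
  if (length(pk) >= 2) {
    period <- stats::median(diff(pk))
    i0 <- max(1L, as.integer(floor(pk[1] - period)))
    i1 <- min(length(seg), as.integer(ceiling(pk[length(pk)] + period)))
    idx <- idx[i0:i1]
    seg <- seg[i0:i1]
  }
  thr <- baseline$mean + params$quiet_k * baseline$sd
  quiet <- seg < thr
  if (!any(quiet)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  runs <- rle(quiet)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= max(1, params$min_quiet * rate))
  if (length(ok) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(start = (idx[starts[ok]] - 1) / rate,
             end = (idx[ends[ok]] - 1) / rate)
}

#' EUS burst duration from quiet-period boundaries
#'
#' Time from the onset of the first quiet period to the end of the last
#' quiet period; 0 if no quiet period was detected.
#'
#' @param quiet_periods output of [detect_quiet_periods()].
#' @return Duration in seconds.
#' @examples
#' burst_duration(data.frame(start = c(10, 17.9), end = c(10.05, 17.95)))
#' @export
burst_duration <- function(quiet_periods) {
  if (nrow(quiet_periods) < 1) return(0)
  max(quiet_periods$end) - min(quiet_periods$start)
}

window_indices <- function(window, rate, n) {
  i0 <- max(1L, floor(window[1] * rate) + 1L)
  i1 <- min(n, floor(window[2] * rate) + 1L)
  if (i1 < i0) stop("void window outside the record", call. = FALSE)
  i0:i1
}
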