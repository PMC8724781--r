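# Record conditioning: EMG rectification, block-mean resampling to an
# effective low rate, and catheter offset correction of the pressure trace.

#' Full-wave rectification
#'
#' Elementwise absolute value of the EMG trace. Idempotent.
#'
#' @param emg numeric vector, mV.
#' @return Nonnegative numeric vector of the same length.
#' @export
rectify <- function(emg) {
  if (!is.numeric(emg) || any(!is.finite(emg))) {
    stop("emg must be a finite numeric vector", call. = FALSE)
  }
  abs(emg)
}

#' Block-mean resampling to a lower effective rate
#'
#' Smooths a signal by software resampling: each output sample is the mean of
#' `from_rate / to_rate` consecutive input samples (a boxcar decimation). A
#' trailing partial block is dropped. Resampling at the original rate is the
#' identity.
#'
#' @param x numeric vector.
#' @param from_rate original sampling rate, Hz.
#' @param to_rate target effective rate, Hz; `from_rate / to_rate` must be a
#'   positive integer.
#' @return Numeric vector of length `floor(length(x) / (from_rate/to_rate))`.
#' @examples
#' resample_block_mean(rep(3, 40), 2000, 100)  # two samples, both 3
#' @export
resample_block_mean <- function(x, from_rate, to_rate) {
  if (to_rate > from_rate) {
    stop("to_rate must not exceed from_rate", call. = FALSE)
  }
  ratio <- from_rate / to_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("from_rate must be an integer multiple of to_rate", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(x)
  nb <- length(x) %/% ratio
  if (nb == 0L) stop("signal shorter than one resampling block", call. = FALSE)
  colMeans(matrix(x[seq_len(nb * ratio)], nrow = ratio))
}

#' Catheter offset correction
#'
#' Subtracts the pressure recorded at the beginning of infusion, when the
#' bladder is relatively empty, estimated as the mean over `baseline_window`.
#' After correction the baseline-window mean is exactly zero; the operation
#' is translation-invariant (correcting `x + c` gives the same output as
#' correcting `x`).
#'
#' @param pressure numeric vector, mmHg.
#' @param rate sampling rate of `pressure`, Hz.
#' @param baseline_window `c(start, end)` in seconds, within the record.
#' @return A list with `corrected` (vector) and `offset` (mmHg).
#' @export
correct_offset <- function(pressure, rate, baseline_window = c(0, 10)) {
  n <- length(pressure)
  if (length(baseline_window) != 2 || baseline_window[2] <= baseline_window[1]) {
    stop("baseline_window must be c(start, end) with end > start", call. = FALSE)
  }
  i0 <- floor(baseline_window[1] * rate) + 1
  i1 <- min(n, ceiling(baseline_window[2] * rate))
  if (i0 < 1 || i0 > n || i1 < i0) {
    stop("baseline_window lies outside the record", call. = FALSE)
  }
  offset <- mean(pressure[i0:i1])
  list(corrected = pressure - offset, offset = offset)
}

#' Condition a recording for feature extraction
#'
#' Applies the standard conditioning chain: the EMG channel is rectified and
#' block-mean resampled to `effective_rate`; the pressure channel is
#' resampled identically and corrected for catheter offset against the
#' beginning-of-infusion baseline window.
#'
#' @param rec a [stuc_recording()].
#' @param effective_rate target rate, Hz (default 100, i.e. 0.1 kHz).
#' @param baseline_window offset-correction window, s.
#' @return An object of class `stuc_conditioned`: `pressure` (corrected,
#'   mmHg), `emg` (rectified, mV), `rate`, `offset`, `baseline_window`, and
#'   the original metadata.
#' @export
condition_recording <- function(rec, effective_rate = 100,
                                baseline_window = c(0, 10)) {
  stopifnot(inherits(rec, "stuc_recording"))
  if (effective_rate > rec$sampling_rate) {
    stop("effective_rate must not exceed the acquisition rate", call. = FALSE)
  }
  p <- resample_block_mean(rec$pressure, rec$sampling_rate, effective_rate)
  e <- resample_block_mean(rectify(rec$emg), rec$sampling_rate, effective_rate)
  oc <- correct_offset(p, effective_rate, baseline_window)
  structure(list(
    pressure = oc$corrected, emg = e, rate = effective_rate,
    offset = oc$offset, baseline_window = baseline_window,
    metadata = rec$metadata
  ), class = "stuc_conditioned")
}

#' @export
print.stuc_conditioned <- function(x, ...) {
  cat(sprintf("Conditioned recording: animal %s, session %s\n",
              x$metadata$animal_id, x$metadata$session_id))
  cat(sprintf("  %d samples @ %g Hz effective, offset %.3f mmHg removed\n",
              length(x$pressure), x$rate, x$offset))
  invisible(x)
}
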