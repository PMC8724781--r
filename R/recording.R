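#' Dual-channel cystometry recording
#'
#' Container for one recording session: bladder pressure (mmHg) and EUS EMG
#' (mV) sampled at a common rate, plus acquisition metadata. Sample times are
#' implicit: sample `i` is at `(i - 1) / sampling_rate` seconds.
#'
#' @param pressure numeric vector, mmHg.
#' @param emg numeric vector, mV; same length as `pressure`.
#' @param sampling_rate Hz.
#' @param animal_id,session_id identifiers stored in the metadata.
#' @param infusion_rate ml/min.
#' @param notes free-text notes (also carries unknown header keys on read).
#' @return An object of class `stuc_recording`.
#' @export
stuc_recording <- function(pressure, emg, sampling_rate,
                           animal_id = "a01", session_id = 1L,
                           infusion_rate = 0.088, notes = "") {
  if (length(pressure) != length(emg)) {
    stop("pressure and emg channels must have equal length", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0", call. = FALSE)
  }
  if (infusion_rate <= 0) stop("infusion_rate must be > 0", call. = FALSE)
  structure(list(
    pressure = as.numeric(pressure), emg = as.numeric(emg),
    sampling_rate = sampling_rate,
    metadata = list(animal_id = as.character(animal_id),
                    session_id = session_id,
                    infusion_rate = infusion_rate,
                    notes = notes)
  ), class = "stuc_recording")
}

#' @export
print.stuc_recording <- function(x, ...) {
  n <- length(x$pressure)
  cat(sprintf("Cystometry recording: animal %s, session %s\n",
              x$metadata$animal_id, x$metadata$session_id))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), infusion %g ml/min\n",
              n, x$sampling_rate, n / x$sampling_rate,
              x$metadata$infusion_rate))
  cat(sprintf("  pressure range %.2f..%.2f mmHg, EMG SD %.4f mV\n",
              min(x$pressure), max(x$pressure), stats::sd(x$emg)))
  invisible(x)
}

#' Quick-look plot of a recording
#'
#' Pressure and EMG stacked on a shared time axis, for visual QC. Long
#' recordings are thinned to at most `max_points` samples per channel.
#'
#' @param x a `stuc_recording`.
#' @param max_points thinning limit per channel.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stuc_recording <- function(x, max_points = 20000, ...) {
  n <- length(x$pressure)
  idx <- if (n > max_points) round(seq(1, n, length.out = max_points)) else seq_len(n)
  t <- (idx - 1) / x$sampling_rate
  op <- par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(par(op))
  plot(t, x$pressure[idx], type = "l", ylab = "pressure (mmHg)", xlab = "", ...)
  plot(t, x$emg[idx], type = "l", ylab = "EUS EMG (mV)", xlab = "time (s)", ...)
  invisible(x)
}
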