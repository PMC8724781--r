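#' Reference urodynamic feature values for adult female rats
#'
#' Population-level reference values for the six standard urodynamic
#' features measured during continuous-infusion transurethral cystometry in
#' ketamine--xylazine anesthetized adult female Sprague-Dawley rats. These
#' are the defaults used by [sim_config()]: `mean` and `sd` describe the
#' distribution of per-animal session means (each animal's value being the
#' average of five successive micturition events), and `icc` is the
#' within-session average-measures intraclass correlation, ICC(3,k) with
#' k = 5 events, used to split the total variance into its between-animal
#' and within-animal (event-to-event) components.
#'
#' The split is analytic: with `sigma_b` the between-animal SD and `sigma_w`
#' the event-to-event SD, the variance of a 5-event animal mean is
#' `sigma_b^2 + sigma_w^2/5` and ICC(3,k=5) equals
#' `sigma_b^2 / (sigma_b^2 + sigma_w^2/5)`, so
#' `sigma_b = sqrt(icc) * sd` and `sigma_w = sqrt(5 * (1 - icc)) * sd`.
#'
#' @return A data.frame with one row per feature and columns `feature`,
#'   `mean`, `sd`, `icc`, `units`, plus the derived fractional coefficients
#'   of variation `cv_between` and `cv_within`.
#' @examples
#' stuc_feature_reference()
#' @export
stuc_feature_reference <- function() {
  ref <- data.frame(
    feature = c("peak_pressure", "threshold_pressure", "min_pressure",
                "volume_threshold", "burst_duration", "burst_count"),
    mean = c(21.4, 4.43, 1.28, 0.48, 8.33, 53.9),
    sd   = c(1.89, 1.39, 0.82, 0.18, 1.59, 13.83),
    icc  = c(0.86, 0.87, 0.83, 0.97, 0.91, 0.94),
    units = c("mmHg", "mmHg", "mmHg", "ml", "s", "count"),
    stringsAsFactors = FALSE
  )
  k <- 5
  ref$cv_between <- sqrt(ref$icc) * ref$sd / ref$mean
  ref$cv_within  <- sqrt(k * (1 - ref$icc)) * ref$sd / ref$mean
  ref
}

# canonical feature order used throughout
stuc_features <- function() {
  c("peak_pressure", "threshold_pressure", "min_pressure",
    "volume_threshold", "burst_duration", "burst_count")
}
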