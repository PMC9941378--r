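# Hypotension exposure statistics on the 1-minute grid.
#
# Two estimands per blood-pressure component:
#   * lowest value sustained cumulatively for >= 120 minutes — the
#     duration-th smallest minute value (contiguity not required);
#   * time-weighted average below a threshold — area between the threshold
#     and the pressure curve where the curve is below it, divided by the
#     ICU length of stay.

#' Exposure window for a patient
#'
#' Runs from ICU admission to the onset of the outcome or ICU discharge,
#' whichever occurs earlier.
#'
#' @param admission,discharge minutes (admission < discharge).
#' @param outcome_onset minutes or `NA` if the outcome never occurred.
#' @return integer pair `c(start, end)`.
#' @export
exposure_window <- function(admission, outcome_onset, discharge) {
  if (discharge <= admission)
    stop("discharge must be after admission", call. = FALSE)
  if (!is.na(outcome_onset) && outcome_onset < admission)
    stop("outcome onset precedes ICU admission", call. = FALSE)
  end <- if (is.na(outcome_onset)) discharge else min(outcome_onset, discharge)
  c(start = admission, end = end)
}

#' Lowest pressure sustained cumulatively for a given duration
#'
#' The smallest integer value `v` such that at least `duration_min` minutes
#' of the series are at or below `v`; equivalently the `duration_min`-th
#' smallest minute value.  Minutes need not be consecutive.
#'
#' @param values integer minute values (NA minutes are not counted).
#' @param duration_min cumulative minutes required; default 120.
#' @return mmHg, or `NA` when fewer than `duration_min` minutes are valued
#'   (such patients are excluded from that component's analysis).
#' @export
lowest_sustained <- function(values, duration_min = 120) {
  v <- values[!is.na(values)]
  if (length(v) < duration_min) return(NA_real_)
  sort(v, partial = duration_min)[duration_min]
}

#' Time-weighted average below a threshold
#'
#' `sum over minutes of max(0, threshold - value) / los_min`: depth and
#' duration of hypotension below the threshold both count; pressure above
#' the threshold contributes nothing.  The denominator is the total ICU
#' length of stay in minutes, not the number of observed minutes.
#'
#' @param values integer minute values (`NA` minutes contribute 0 area).
#' @param threshold mmHg, > 0.
#' @param los_min total ICU length of stay in minutes, > 0.
#' @return mmHg (>= 0; 0 iff no valued minute falls below the threshold).
#' @export
time_weighted_average_below <- function(values, threshold, los_min) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (is.na(los_min) || los_min <= 0) stop("los_min must be > 0", call. = FALSE)
  v <- values[!is.na(values)]
  sum(pmax(0, threshold - v)) / los_min
}

# Default TWA thresholds: the change-points estimated for ICU mortality.
DEFAULT_TWA_THRESHOLDS <- c(map = 69, sbp = 100, dbp = 60, pp = 57)

#' Exposure summary for one preprocessed patient
#'
#' Computes, per component, the lowest value sustained cumulatively for
#' `duration_min` minutes and the time-weighted average below the
#' component-specific threshold, over the exposure window (admission to
#' outcome onset or discharge).
#'
#' @param series a `bphinge_minute_series` from [preprocess_patient()].
#' @param los_min total ICU length of stay in minutes (TWA denominator; see
#'   `twa_denominator`).
#' @param outcome_onset minutes, or `NA`; truncates the exposure window.
#' @param duration_min cumulative-duration requirement, default 120.
#' @param thresholds named mmHg thresholds per component for the TWA.
#' @param twa_denominator `"full_los"` (default) divides the area by the
#'   total ICU stay; `"window"` divides by the (possibly outcome-truncated)
#'   exposure-window length.
#' @return one-row data.table per component: `patient_id`, `component`,
#'   `lowest_sustained`, `twa_below`, `threshold_used`, `minutes_observed`.
#' @export
exposure_summary <- function(series, los_min, outcome_onset = NA,
                             duration_min = 120,
                             thresholds = DEFAULT_TWA_THRESHOLDS,
                             twa_denominator = c("full_los", "window")) {
  twa_denominator <- match.arg(twa_denominator)
  win <- exposure_window(series$window[1], outcome_onset,
                         min(series$window[2], series$window[1] + los_min))
  keep <- series$minutes >= win[1] & series$minutes < win[2]
  denom <- if (twa_denominator == "full_los") los_min else win[2] - win[1]
  comps <- names(series$values)
  k <- length(comps)
  ls_v <- twa_v <- thr_v <- rep(NA_real_, k)
  mo <- integer(k)
  for (j in seq_len(k)) {
    v <- series$values[[comps[j]]][keep]
    thr <- thresholds[[comps[j]]]
    ls_v[j] <- lowest_sustained(v, duration_min)
    if (!is.null(thr) && !is.na(thr)) {
      thr_v[j] <- thr
      twa_v[j] <- time_weighted_average_below(v, thr, denom)
    }
    mo[j] <- sum(!is.na(v))
  }
  data.table::data.table(patient_id = series$patient_id, component = comps,
                         lowest_sustained = ls_v, twa_below = twa_v,
                         threshold_used = thr_v, minutes_observed = mo)
}

#' Brute-force oracle for the lowest sustained value
#'
#' Scans every integer threshold in `range` and returns the smallest one
#' with at least `duration_min` minutes at or below it.  Independent of
#' [lowest_sustained()]; intended for validation.
#'
#' @param values integer minute values.
#' @param duration_min cumulative minutes required.
#' @param range integer candidate thresholds to scan.
#' @return mmHg or `NA` if no threshold qualifies.
#' @export
lowest_sustained_bruteforce <- function(values, duration_min = 120,
                                        range = 10:250) {
  v <- values[!is.na(values)]
  for (thr in range) {
    if (sum(v <= thr) >= duration_min) return(as.numeric(thr))
  }
  NA_real_
}
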