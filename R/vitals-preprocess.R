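# Raw blood-pressure readings -> clean per-patient 1-minute integer series.
#
# Stages, in order: plausibility filtering (whole readings removed),
# reading-level derivation of MAP and pulse pressure, invasive-priority
# merging per minute, linear interpolation to a 1-minute integer grid, and
# the 2-hour measurement-frequency eligibility rule.

FILTER_REASONS <- c("SBP >= 300", "SBP <= 20", "SBP <= DBP + 5",
                    "DBP >= 225", "DBP <= 5", "MAP >= 250", "MAP <= 10")

#' Remove implausible blood-pressure readings
#'
#' A reading is removed whole (all of its components) when any of these
#' artifact conditions holds, with inclusive boundaries: SBP >= 300 or
#' <= 20 mmHg; SBP <= DBP + 5 mmHg; DBP >= 225 or <= 5 mmHg; MAP >= 250 or
#' <= 10 mmHg.  Conditions involving an absent component are not triggered.
#'
#' @param readings data.table/data.frame with numeric columns `sbp`, `dbp`,
#'   `map` (any may be `NA`) and arbitrary other columns.
#' @return list with `retained` (surviving rows), `removed` (dropped rows
#'   with a `reason` column listing every matched condition, `;`-separated),
#'   and `n_removed`.
#' @export
apply_plausibility_filters <- function(readings) {
  readings <- data.table::as.data.table(readings)
  if (nrow(readings) == 0L) {
    removed <- data.table::copy(readings)[, reason := character(0)]
    return(list(retained = readings, removed = removed, n_removed = 0L))
  }
  sbp <- readings$sbp; dbp <- readings$dbp; map <- readings$map
  hit <- cbind(
    !is.na(sbp) & sbp >= 300,
    !is.na(sbp) & sbp <= 20,
    !is.na(sbp) & !is.na(dbp) & sbp <= dbp + 5,
    !is.na(dbp) & dbp >= 225,
    !is.na(dbp) & dbp <= 5,
    !is.na(map) & map >= 250,
    !is.na(map) & map <= 10
  )
  any_hit <- rowSums(hit) > 0
  removed <- readings[any_hit]
  if (nrow(removed)) {
    removed[, reason := apply(hit[any_hit, , drop = FALSE], 1L, function(h)
      paste(FILTER_REASONS[h], collapse = "; "))]
  } else removed[, reason := character(0)]
  list(retained = readings[!any_hit], removed = removed,
       n_removed = sum(any_hit))
}

#' Derive mean arterial pressure from systolic and diastolic pressure
#'
#' `MAP = (2 x DBP + SBP) / 3`.  Used only for readings that lack a measured
#' MAP; rounding is deferred to the minute grid.  A missing operand yields
#' `NA`, never zero.
#'
#' @param sbp,dbp mmHg, vectorized.
#' @return mmHg (possibly fractional).
#' @export
derive_map <- function(sbp, dbp) {
  (2 * dbp + sbp) / 3
}

#' Derive pulse pressure
#'
#' `PP = SBP - DBP`, computed at reading level after plausibility filtering
#' (which guarantees SBP > DBP + 5, hence PP > 5).  Missing operand -> `NA`.
#'
#' @param sbp,dbp mmHg, vectorized.
#' @return mmHg.
#' @export
derive_pp <- function(sbp, dbp) {
  sbp - dbp
}

#' Fill missing MAP and attach PP at reading level
#'
#' Adds a derived MAP (formula of [derive_map()]) to readings that lack a
#' measured one, and a `pp` column ([derive_pp()]) wherever both SBP and
#' DBP are present.  Run after filtering and before merging, so PP is
#' interpolated as its own series rather than as a difference of two
#' independently interpolated ones.
#'
#' @param readings filtered readings with `sbp`, `dbp`, `map` columns.
#' @return the readings with `map` completed and `pp` added.
#' @export
derive_components <- function(readings) {
  readings <- data.table::as.data.table(readings)
  readings[, map := ifelse(is.na(map), derive_map(sbp, dbp), map)]
  readings[, pp := derive_pp(sbp, dbp)]
  readings[]
}

#' Merge invasive and non-invasive readings onto a per-minute stream
#'
#' For each minute and component, invasive values win; non-invasive values
#' are used only for minutes with no invasive reading of that component.
#' Two same-source readings within one minute resolve to the later one (by
#' input order within the minute) and the collision is counted.
#'
#' @param readings filtered readings with columns `time_min`, `source`
#'   (`"invasive"`/`"noninvasive"`), and component columns.
#' @param components character vector of component columns to merge.
#' @return list: `merged` (long data.table: component, time_min, value),
#'   `invasive_fraction` (invasive readings / total readings),
#'   `n_collisions`.
#' @export
merge_sources <- function(readings,
                          components = c("map", "sbp", "dbp", "pp")) {
  readings <- data.table::as.data.table(readings)
  total <- nrow(readings)
  inv_frac <- if (total) sum(readings$source == "invasive") / total else NA_real_
  if (total == 0L) {
    return(list(merged = data.table::data.table(component = character(),
                                                time_min = integer(),
                                                value = numeric()),
                invasive_fraction = inv_frac, n_collisions = 0L))
  }
  comps <- intersect(components, names(readings))
  cc <- tt <- ss <- rr <- list(); vv <- list()
  for (comp in comps) {
    keep <- which(!is.na(readings[[comp]]))
    cc[[comp]] <- rep(comp, length(keep))
    tt[[comp]] <- as.integer(readings$time_min[keep])
    vv[[comp]] <- readings[[comp]][keep]
    ss[[comp]] <- readings$source[keep]
    rr[[comp]] <- keep
  }
  comp_v <- unlist(cc, use.names = FALSE)
  if (length(comp_v) == 0L) {
    return(list(merged = data.table::data.table(component = character(),
                                                time_min = integer(),
                                                value = numeric()),
                invasive_fraction = inv_frac, n_collisions = 0L))
  }
  t_v <- unlist(tt, use.names = FALSE)
  v_v <- unlist(vv, use.names = FALSE)
  s_v <- unlist(ss, use.names = FALSE)
  r_v <- unlist(rr, use.names = FALSE)
  pri <- ifelse(s_v == "invasive", 2L, 1L)
  key <- paste(comp_v, t_v)
  n_coll <- length(key) - length(unique(paste(key, s_v)))
  # invasive beats noninvasive; within a source the later row wins
  ord <- order(comp_v, t_v, pri, r_v)
  last <- !duplicated(key[ord], fromLast = TRUE)
  sel <- ord[last]
  merged <- data.table::data.table(component = comp_v[sel],
                                   time_min = t_v[sel], value = v_v[sel])
  list(merged = merged, invasive_fraction = inv_frac,
       n_collisions = as.integer(n_coll))
}

#' Interpolate merged per-minute values to a 1-minute integer grid
#'
#' Linear interpolation between consecutive measured minutes for each
#' component independently, then rounding half-up to the nearest integer.
#' Minutes before the first or after the last measurement of a component
#' carry no value (no extrapolation).  A component with fewer than two
#' measured minutes is marked insufficient and left entirely `NA`.
#'
#' @param merged long table from [merge_sources()].
#' @param window integer pair `c(start, end)` in minutes; the grid covers
#'   minutes `start, ..., end - 1`.
#' @param patient_id carried into the result.
#' @return `bphinge_minute_series`: list with `patient_id`, `window`,
#'   `minutes`, and per component integer `values` plus `provenance`
#'   (`"measured"`, `"interpolated"`, or `NA` outside coverage), and
#'   `insufficient` flags.
#' @export
interpolate_to_minutes <- function(merged, window, patient_id = NA_integer_) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  minutes <- seq.int(window[1], window[2] - 1L)
  comps <- unique(merged$component)
  values <- provenance <- list()
  insufficient <- character(0)
  for (comp in comps) {
    idx <- which(merged$component == comp &
                 merged$time_min >= window[1] & merged$time_min < window[2])
    tm <- merged$time_min[idx]
    val <- merged$value[idx]
    o <- order(tm)
    tm <- tm[o]; val <- val[o]
    v <- rep(NA_real_, length(minutes))
    prov <- rep(NA_character_, length(minutes))
    if (length(tm) < 2L) {
      insufficient <- c(insufficient, comp)
    } else {
      span <- minutes >= tm[1] & minutes <= tm[length(tm)]
      v[span] <- stats::approx(tm, val, xout = minutes[span],
                               method = "linear", ties = "ordered")$y
      prov[span] <- "interpolated"
      prov[match(tm, minutes)] <- "measured"
      v <- round_half_up(v)
    }
    values[[comp]] <- v
    provenance[[comp]] <- prov
  }
  structure(list(patient_id = patient_id, window = as.integer(window),
                 minutes = minutes, values = values,
                 provenance = provenance, insufficient = insufficient),
            class = "bphinge_minute_series")
}

#' @export
print.bphinge_minute_series <- function(x, ...) {
  cat(sprintf("<minute series> patient %s, window [%d, %d) min\n",
              x$patient_id, x$window[1], x$window[2]))
  for (comp in names(x$values)) {
    n_obs <- sum(!is.na(x$values[[comp]]))
    cat(sprintf("  %s: %d/%d minutes valued%s\n", toupper(comp), n_obs,
                length(x$minutes),
                if (comp %in% x$insufficient) " (insufficient)" else ""))
  }
  invisible(x)
}

#' Measurement-frequency eligibility (2-hour gap rule)
#'
#' A patient is ineligible when any gap between consecutive retained
#' readings, pooled across components and sources, strictly exceeds
#' `gap_limit` minutes.  Gaps from the window start to the first reading
#' and from the last reading to the window end count too.
#'
#' @param time_min reading times (minutes) of all retained readings.
#' @param window integer pair `c(start, end)`.
#' @param gap_limit minutes; default 120 (2 hours), exceeded strictly.
#' @return list `eligible` (logical) and `max_gap` (minutes).
#' @export
check_measurement_frequency <- function(time_min, window, gap_limit = 120) {
  stopifnot(length(window) == 2L, window[2] >= window[1])
  t <- sort(unique(time_min[time_min >= window[1] & time_min <= window[2]]))
  if (length(t) == 0L) {
    return(list(eligible = FALSE, max_gap = as.numeric(window[2] - window[1])))
  }
  gaps <- diff(c(window[1], t, window[2]))
  max_gap <- max(gaps)
  list(eligible = max_gap <= gap_limit, max_gap = as.numeric(max_gap))
}

#' Full preprocessing of one patient's raw readings
#'
#' Applies, in order: plausibility filters, reading-level MAP/PP derivation,
#' invasive-priority merging, the 2-hour measurement-frequency rule, and
#' linear interpolation to the 1-minute integer grid.
#'
#' @param readings one patient's raw readings (`time_min`, `sbp`, `dbp`,
#'   `map`, `source`).
#' @param window integer pair `c(start, end)` in minutes (typically
#'   `c(0, los_min)`).
#' @param gap_limit minutes for the eligibility rule.
#' @param patient_id carried into the result.
#' @return `bphinge_minute_series` with extra fields `eligible`, `max_gap`,
#'   `invasive_fraction`, `n_removed`, `n_collisions`, `removal_log`.
#' @export
preprocess_patient <- function(readings, window, gap_limit = 120,
                               patient_id = NA_integer_) {
  filt <- apply_plausibility_filters(readings)
  der <- derive_components(filt$retained)
  mrg <- merge_sources(der)
  freq <- check_measurement_frequency(der$time_min, window, gap_limit)
  series <- interpolate_to_minutes(mrg$merged, window, patient_id)
  series$eligible <- freq$eligible
  series$max_gap <- freq$max_gap
  series$invasive_fraction <- mrg$invasive_fraction
  series$n_removed <- filt$n_removed
  series$n_collisions <- mrg$n_collisions
  series$removal_log <- filt$removed
  series
}

#' Convert a minute series to a long data.table
#'
#' One row per minute with columns `patient_id`, `minute`, `map`, `sbp`,
#' `dbp`, `pp`, and `provenance` (of MAP), matching the columnar on-disk
#' format.
#'
#' @param series a `bphinge_minute_series`.
#' @return data.table.
#' @export
minute_series_table <- function(series) {
  data.table::data.table(
    patient_id = series$patient_id,
    minute = series$minutes,
    map = series$values$map %||% rep(NA_real_, length(series$minutes)),
    sbp = series$values$sbp %||% rep(NA_real_, length(series$minutes)),
    dbp = series$values$dbp %||% rep(NA_real_, length(series$minutes)),
    pp  = series$values$pp  %||% rep(NA_real_, length(series$minutes)),
    provenance = series$provenance$map %||%
      rep(NA_character_, length(series$minutes)))
}
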