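# Cohort construction: SOFA scoring, sepsis/septic-shock definitions,
# outcome definitions, vasopressor dose conversion, and the exclusion
# cascade with attrition reporting.

#' SOFA score from six organ-system inputs
#'
#' Standard 0-4 scoring per organ, summed.  A missing organ input scores 0
#' (documented, conservative choice that keeps the sepsis gate
#' deterministic).
#'
#' @param pf_ratio PaO2/FiO2 (mmHg).
#' @param ventilated logical; respiratory scores 3-4 require ventilatory
#'   support.
#' @param platelets platelet count, 10^3/uL.
#' @param bilirubin mg/dL.
#' @param map mmHg (lowest on the day scored).
#' @param vasopressor_rate norepinephrine-equivalent rate, mcg/kg/min; 0 if
#'   none.
#' @param gcs Glasgow Coma Scale, 3-15.
#' @param creatinine mg/dL.
#' @return list with `total` and per-organ scores.
#' @export
compute_sofa <- function(pf_ratio = NA, ventilated = FALSE, platelets = NA,
                         bilirubin = NA, map = NA, vasopressor_rate = 0,
                         gcs = NA, creatinine = NA) {
  resp <- if (is.na(pf_ratio)) 0L
    else if (pf_ratio < 100 && isTRUE(ventilated)) 4L
    else if (pf_ratio < 200 && isTRUE(ventilated)) 3L
    else if (pf_ratio < 300) 2L
    else if (pf_ratio < 400) 1L else 0L
  coag <- if (is.na(platelets)) 0L
    else if (platelets < 20) 4L
    else if (platelets < 50) 3L
    else if (platelets < 100) 2L
    else if (platelets < 150) 1L else 0L
  liver <- if (is.na(bilirubin)) 0L
    else if (bilirubin >= 12) 4L
    else if (bilirubin >= 6) 3L
    else if (bilirubin >= 2) 2L
    else if (bilirubin >= 1.2) 1L else 0L
  vr <- if (is.na(vasopressor_rate)) 0 else vasopressor_rate
  if (vr < 0) stop("vasopressor rate must be >= 0", call. = FALSE)
  cardio <- if (vr > 0.1) 4L
    else if (vr > 0) 3L
    else if (!is.na(map) && map < 70) 1L else 0L
  cns <- if (is.na(gcs)) 0L
    else if (gcs < 6) 4L
    else if (gcs <= 9) 3L
    else if (gcs <= 12) 2L
    else if (gcs <= 14) 1L else 0L
  renal <- if (is.na(creatinine)) 0L
    else if (creatinine >= 5) 4L
    else if (creatinine >= 3.5) 3L
    else if (creatinine >= 2) 2L
    else if (creatinine >= 1.2) 1L else 0L
  list(total = resp + coag + liver + cardio + cns + renal,
       respiration = resp, coagulation = coag, liver = liver,
       cardiovascular = cardio, cns = cns, renal = renal)
}

#' Sepsis predicate
#'
#' Sepsis = evidence of infection (admission diagnosis OR non-prophylactic
#' antibiotics for more than 48 h) AND day-1 SOFA score >= 2.
#'
#' @param infection_dx logical; infection listed among admission diagnoses.
#' @param antibiotics_gt48h logical; antibiotics administered for > 48 h.
#' @param sofa_total day-1 SOFA score.
#' @return logical, vectorized.
#' @export
is_sepsis <- function(infection_dx, antibiotics_gt48h, sofa_total) {
  (infection_dx | antibiotics_gt48h) & sofa_total >= 2
}

#' Septic-shock predicate
#'
#' Operational definition: lactate > 2 mmol/L together with any vasopressor
#' use.  A missing lactate ("no reading available") cannot satisfy the
#' lactate condition.
#'
#' @param lactate mmol/L, `NA` if never measured.
#' @param any_vasopressor logical.
#' @return logical, vectorized.
#' @export
is_septic_shock <- function(lactate, any_vasopressor) {
  !is.na(lactate) & lactate > 2 & any_vasopressor
}

#' Norepinephrine-equivalent average vasopressor rate
#'
#' `rate = sum over drugs (factor_drug x cumulative_dose_mcg) /
#' (weight_kg x los_min)`, in mcg/kg/min.  Conversion factors are supplied
#' as configuration; the shipped defaults are literature conventions
#' (norepinephrine 1, epinephrine 1, dopamine 0.01, phenylephrine 0.1,
#' vasopressin 2.5 per unit with the unit-to-mcg scale folded into the dose
#' column, dobutamine 0 as an inotrope without pressor equivalence).
#'
#' @param doses named numeric vector of cumulative doses in mcg (vasopressin
#'   in units x its configured scale); names are drug names.
#' @param weight_kg admission weight, > 0.
#' @param los_min ICU length of stay in minutes, > 0.
#' @param factors named conversion factors; unnamed drugs are an error.
#' @return mcg/kg/min (0 when no doses).
#' @export
nee_rate <- function(doses, weight_kg, los_min,
                     factors = c(norepinephrine = 1, epinephrine = 1,
                                 dopamine = 0.01, phenylephrine = 0.1,
                                 vasopressin = 2.5, dobutamine = 0)) {
  if (weight_kg <= 0) stop("weight must be > 0", call. = FALSE)
  if (los_min <= 0) stop("LOS must be > 0", call. = FALSE)
  if (length(doses) == 0L) return(0)
  if (any(doses < 0)) stop("negative cumulative dose", call. = FALSE)
  unknown <- setdiff(names(doses), names(factors))
  if (length(unknown))
    stop("no conversion factor for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sum(factors[names(doses)] * doses) / (weight_kg * los_min)
}

#' Define ICU outcomes from timestamped events
#'
#' ICU mortality is assessed from 24 h after admission to discharge: deaths
#' before the 24-hour mark do not count for the primary analysis.
#' Myocardial injury onsets at the first troponin (I or T) strictly
#' exceeding 0.03 ng/mL; AKI onsets at the first qualifying diagnosis-code
#' event.  Composites are AKI-or-death and MI-or-death.
#'
#' @param events data.table for one patient: `type` in
#'   `c("death", "aki", "troponin")`, `time_min`, `value` (troponin in
#'   ng/mL).
#' @param los_min ICU length of stay (minutes).
#' @param troponin_cut ng/mL; strict exceedance, default 0.03.
#' @return list: `icu_death`, `death_time`, `aki`, `aki_time`, `mi`,
#'   `mi_time`, `aki_or_death`, `mi_or_death`.
#' @export
define_outcomes <- function(events, los_min, troponin_cut = 0.03) {
  events <- data.table::as.data.table(events)
  first_time <- function(sel) {
    t <- events$time_min[sel]
    if (length(t)) min(t) else NA_real_
  }
  dth <- first_time(events$type == "death")
  icu_death <- !is.na(dth) && dth >= 1440 && dth <= los_min
  aki_t <- first_time(events$type == "aki")
  trop <- events$type == "troponin"
  if (any(trop) && any(is.na(events$value[trop])))
    stop("troponin event without a ng/mL value", call. = FALSE)
  mi_t <- first_time(trop & !is.na(events$value) & events$value > troponin_cut)
  aki <- !is.na(aki_t)
  mi <- !is.na(mi_t)
  list(icu_death = icu_death, death_time = dth,
       aki = aki, aki_time = aki_t, mi = mi, mi_time = mi_t,
       aki_or_death = aki || icu_death, mi_or_death = mi || icu_death)
}

#' Apply the inclusion/exclusion cascade and report attrition
#'
#' Criteria, in order; each patient is attributed to the first criterion
#' they fail: adult (age >= 18); valid sex and admission diagnosis; ICU
#' stay >= 24 h; no surgery before ICU admission; sepsis; APACHE IVa score
#' present; valid BMI (10 < BMI < 60, height and weight known); no DNR
#' order on admission; no mechanical circulatory support; sufficient
#' blood-pressure measurement frequency (no gap > 2 h).  With
#' `secondary = TRUE`, two further criteria remove patients whose AKI or
#' myocardial injury occurred within 24 h of admission and those with a
#' history of organ dysfunction (chronic kidney disease, myocardial
#' infarction, stroke, coronary artery disease).
#'
#' @param patients data.table from [generate_patients()] (or equivalent)
#'   with a `sofa_total` column or the SOFA inputs to compute one.
#' @param eligibility data.table `patient_id`, `eligible` from
#'   preprocessing; patients absent from it are treated as BP-ineligible.
#' @param outcomes optional data.table with `patient_id`, `aki_time`,
#'   `mi_time` (minutes) used by the secondary-cohort criteria.
#' @param secondary apply the secondary-outcome exclusions.
#' @return list: `cohort` (included rows, with `sofa_total` and `sepsis`
#'   columns), `attrition` (data.table step/criterion/n_removed/n_remaining).
#' @export
apply_exclusions <- function(patients, eligibility, outcomes = NULL,
                             secondary = FALSE) {
  p <- data.table::as.data.table(data.table::copy(patients))
  if (!"sofa_total" %in% names(p)) {
    p[, sofa_total := mapply(function(pf, vent, plt, bili, m, vaso, g, cr) {
      compute_sofa(pf, vent, plt, bili, m,
                   if (isTRUE(vaso)) 0.05 else 0, g, cr)$total
    }, pf_ratio, ventilator, platelets, bilirubin, day1_lowest_map,
       any_vasopressor, gcs, creatinine)]
  }
  p[, sepsis := is_sepsis(infection_dx, antibiotics_gt48h, sofa_total)]
  elig <- data.table::as.data.table(eligibility)
  p[, bp_eligible := elig$eligible[match(patient_id, elig$patient_id)]]
  p[is.na(bp_eligible), bp_eligible := FALSE]

  crit <- list(
    adult = quote(age >= 18),
    valid_sex_diagnosis = quote(!is.na(male)),
    los_ge_24h = quote(los_min >= 1440),
    no_pre_icu_surgery = quote(!surgery_before_icu),
    sepsis = quote(sepsis),
    apache_present = quote(!is.na(apache_iva)),
    valid_bmi = quote(!is.na(bmi) & bmi > 10 & bmi < 60),
    no_dnr = quote(!dnr),
    no_mech_circ_support = quote(!mech_circ_support),
    bp_frequency = quote(bp_eligible)
  )
  if (secondary) {
    if (is.null(outcomes))
      stop("secondary cohort requires an outcomes table", call. = FALSE)
    oc <- data.table::as.data.table(outcomes)
    p[, aki_time := oc$aki_time[match(patient_id, oc$patient_id)]]
    p[, mi_time := oc$mi_time[match(patient_id, oc$patient_id)]]
    crit$no_outcome_within_24h <- quote(
      (is.na(aki_time) | aki_time >= 1440) &
      (is.na(mi_time) | mi_time >= 1440))
    crit$no_organ_dysfunction_history <- quote(
      !hx_ckd & !hx_mi & !hx_stroke & !hx_cad)
  }

  keep <- rep(TRUE, nrow(p))
  removed_at <- rep(NA_character_, nrow(p))
  for (name in names(crit)) {
    pass <- eval(crit[[name]], envir = p)
    pass[is.na(pass)] <- FALSE
    newly <- keep & !pass
    removed_at[newly] <- name
    keep <- keep & pass
  }
  attrition <- data.table::data.table(
    step = seq_along(crit), criterion = names(crit),
    n_removed = vapply(names(crit),
                       function(nm) sum(removed_at == nm, na.rm = TRUE),
                       integer(1)))
  n <- nrow(p)
  attrition[, n_remaining := n - cumsum(n_removed)]
  list(cohort = p[keep], attrition = attrition[])
}

#' Crude percentage and odds-ratio arithmetic from printed counts
#'
#' Utility for checking published contingency summaries: percentage of
#' events in a group, and the crude (unadjusted) odds ratio comparing two
#' groups from their n/event counts.
#'
#' @param events,n events and group size.
#' @return `crude_pct`: percentage rounded to 1 decimal.
#' @export
crude_pct <- function(events, n) {
  round(100 * events / n, 1)
}

#' @rdname crude_pct
#' @param events1,n1 comparison group; `events0,n0` reference group.
#' @param events0,n0 reference group counts.
#' @return `crude_or`: cross-product odds ratio.
#' @export
crude_or <- function(events1, n1, events0, n0) {
  (events1 / (n1 - events1)) / (events0 / (n0 - events0))
}
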