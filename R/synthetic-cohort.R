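# Synthetic septic-ICU cohort generator.
#
# Produces patient-level covariates mirroring the baseline table of a large
# septic ICU cohort, minute-resolution latent blood-pressure trajectories,
# interleaved invasive/non-invasive reading streams with configurable
# artifact and gap injection, vasopressor records, and outcomes drawn from a
# known hinge dose-response on the TRUE latent exposure.  Because the truth
# is retained alongside the readings, every downstream stage (filtering,
# interpolation, exposure metrics, change-point regression) can be validated
# against ground truth.

#' Simulation configuration for the synthetic septic-ICU cohort
#'
#' Bundles and validates every knob of the generator.  Defaults describe a
#' septic ICU population whose true lowest MAP sustained for 120 minutes is
#' centred near 62 mmHg (SD 10), whose ICU mortality follows a hinge
#' dose-response with change-point 69 mmHg and pre-threshold slope -0.13
#' log-odds per mmHg, and whose monitoring mixes 5-minute-median invasive
#' lines with aperiodic cuff readings.
#'
#' @param n_patients number of patients (>= 1).
#' @param seed master integer seed; per-patient streams are derived from it.
#' @param change_point,pre_slope,plateau_logit hinge dose-response for ICU
#'   mortality on the true lowest sustained MAP: the log-odds are
#'   `plateau_logit` at or above `change_point` (mmHg) and change by
#'   `pre_slope` (log-odds per mmHg, <= 0) per mmHg of pressure below it,
#'   so lower pressure means higher risk.
#' @param covariate_effects named log-odds-per-unit effects added to the
#'   outcome linear predictor, applied to mean-centred covariates.
#'   Supported names: `age` (centred at 64), `apache` (centred at 67).
#' @param map_target_mean,map_target_sd mmHg; centre/spread of each
#'   patient's deepest sustained MAP level (the true exposure distribution).
#' @param baseline_map_mean,baseline_map_sd,baseline_pp_mean,baseline_pp_sd
#'   mmHg; patient-level resting MAP and pulse-pressure baselines.
#' @param ar_phi,ar_sd AR(1) coefficient and stationary SD (mmHg) of the
#'   minute-level fluctuation around the episode profile.
#' @param episode_rate_per_hr rate of additional short hypotensive dips.
#' @param episode_depth_mean mmHg; mean depth of those dips.
#' @param continuous_interval_min minutes between archived invasive
#'   readings; each is the median of the latent 1-minute values it covers.
#' @param aperiodic_mean_interval_min mean minutes between cuff readings for
#'   patients without an arterial line.
#' @param invasive_fraction probability a patient has an arterial line.
#' @param nibp_noise_sd mmHg; measurement noise of cuff readings.
#' @param artifact_rate probability a reading is replaced by an implausible
#'   artifact (one that the plausibility filters should remove).
#' @param gap_rate_per_hr rate of monitoring gaps; readings inside a gap are
#'   dropped.
#' @param gap_duration_range minutes; uniform range of gap durations.
#' @param los_meanlog,los_sdlog,los_range log-normal ICU length-of-stay
#'   parameters (minutes) and truncation range.
#' @param short_stay_fraction fraction of patients given a stay below 24 h
#'   (these are later removed by the cohort exclusion cascade).
#' @param aki_hinge,mi_hinge hinge parameter lists
#'   (`change_point`, `pre_slope`, `plateau_logit`) for the acute kidney
#'   injury and troponin-positive myocardial-injury event generators.
#' @return a validated `bphinge_sim_config` list.
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 1)
#' cfg$hinge$change_point
#' @export
sim_config <- function(n_patients = 2000,
                       seed = 1,
                       change_point = 69,
                       pre_slope = -0.13,
                       plateau_logit = -5.14,
                       covariate_effects = c(age = 0.015, apache = 0.03),
                       map_target_mean = 62,
                       map_target_sd = 10,
                       baseline_map_mean = 78,
                       baseline_map_sd = 7,
                       baseline_pp_mean = 40,
                       baseline_pp_sd = 9,
                       ar_phi = 0.95,
                       ar_sd = 2.5,
                       episode_rate_per_hr = 0.05,
                       episode_depth_mean = 8,
                       continuous_interval_min = 5,
                       aperiodic_mean_interval_min = 20,
                       invasive_fraction = 0.2,
                       nibp_noise_sd = 3,
                       artifact_rate = 0.02,
                       gap_rate_per_hr = 0.02,
                       gap_duration_range = c(15, 150),
                       los_meanlog = log(2880),
                       los_sdlog = 0.5,
                       los_range = c(1440, 10080),
                       short_stay_fraction = 0.02,
                       aki_hinge = list(change_point = 69, pre_slope = -0.08,
                                        plateau_logit = -4.3),
                       mi_hinge = list(change_point = 69, pre_slope = -0.06,
                                       plateau_logit = -4.8)) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 1)
    stop_config("n_patients", "must be >= 1")
  n_patients <- as.integer(n_patients)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_config("seed", "must be a single integer")
  if (change_point < 10 || change_point > 250)
    stop_config("change_point", "must lie in the physiologic range 10-250 mmHg")
  if (pre_slope > 0)
    stop_config("pre_slope", "must be <= 0 (log-odds per mmHg of pressure)")
  assert_flag01(invasive_fraction, "invasive_fraction")
  assert_flag01(artifact_rate, "artifact_rate")
  assert_flag01(short_stay_fraction, "short_stay_fraction")
  if (gap_rate_per_hr < 0) stop_config("gap_rate_per_hr", "must be >= 0")
  if (episode_rate_per_hr < 0) stop_config("episode_rate_per_hr", "must be >= 0")
  if (continuous_interval_min < 1)
    stop_config("continuous_interval_min", "must be >= 1 minute")
  if (aperiodic_mean_interval_min <= 0)
    stop_config("aperiodic_mean_interval_min", "must be > 0")
  if (ar_phi < 0 || ar_phi >= 1) stop_config("ar_phi", "must be in [0, 1)")
  if (map_target_sd <= 0) stop_config("map_target_sd", "must be > 0")
  if (length(gap_duration_range) != 2L || any(gap_duration_range <= 0) ||
      gap_duration_range[1] > gap_duration_range[2])
    stop_config("gap_duration_range", "must be an increasing positive pair")
  if (length(los_range) != 2L || los_range[1] <= 0 ||
      los_range[1] > los_range[2])
    stop_config("los_range", "must be an increasing positive pair of minutes")
  for (h in list(aki_hinge, mi_hinge)) {
    if (h$change_point < 10 || h$change_point > 250 || h$pre_slope > 0)
      stop_config("aki_hinge/mi_hinge", "hinge parameters out of range")
  }

  structure(list(
    n_patients = n_patients, seed = as.integer(seed),
    hinge = list(change_point = change_point, pre_slope = pre_slope,
                 plateau_logit = plateau_logit),
    covariate_effects = covariate_effects,
    map_target_mean = map_target_mean, map_target_sd = map_target_sd,
    baseline_map_mean = baseline_map_mean, baseline_map_sd = baseline_map_sd,
    baseline_pp_mean = baseline_pp_mean, baseline_pp_sd = baseline_pp_sd,
    ar_phi = ar_phi, ar_sd = ar_sd,
    episode_rate_per_hr = episode_rate_per_hr,
    episode_depth_mean = episode_depth_mean,
    continuous_interval_min = continuous_interval_min,
    aperiodic_mean_interval_min = aperiodic_mean_interval_min,
    invasive_fraction = invasive_fraction,
    nibp_noise_sd = nibp_noise_sd,
    artifact_rate = artifact_rate,
    gap_rate_per_hr = gap_rate_per_hr,
    gap_duration_range = gap_duration_range,
    los_meanlog = los_meanlog, los_sdlog = los_sdlog, los_range = los_range,
    short_stay_fraction = short_stay_fraction,
    aki_hinge = aki_hinge, mi_hinge = mi_hinge
  ), class = "bphinge_sim_config")
}

# Deterministic per-patient seed derived from (master seed, patient id).
# Kept below 2^31 so set.seed() accepts it.
patient_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(id) * 1103) %% 2147483629)
}

#' Generate patient-level covariates and admission metadata
#'
#' Draws demographics, severity scores, admission descriptors, pre-admission
#' medications, categorical admission labs (with explicit "none" = no
#' reading available levels), history flags, day-1 SOFA organ inputs,
#' vasopressor exposure, and ICU length of stay.  Marginal category
#' frequencies follow the baseline profile of a large US septic ICU cohort.
#' A small fraction of patients deliberately fail each cohort exclusion
#' criterion (short stay, missing APACHE, invalid BMI, DNR order,
#' mechanical circulatory support, pre-ICU surgery) so that attrition
#' reporting is exercised end to end.
#'
#' @param config a [sim_config()] object.
#' @return `data.table` with one row per patient.
#' @export
generate_patients <- function(config) {
  stopifnot(inherits(config, "bphinge_sim_config"))
  n <- config$n_patients
  set.seed(patient_seed(config$seed, 0L))

  eth_p <- c(caucasian = 0.75, african_american = 0.11, hispanic = 0.06,
             native_american = 0.01, asian = 0.02, other_unknown = 0.05)
  adm_p <- c(emergency_department = 0.59, other_ward = 0.31, elective = 0.08,
             other_hospital = 0.03, other_unknown = 0.003)
  yr_p  <- c(`2004_2008` = 0.06, `2009_2012` = 0.38, `2013_2016` = 0.56)
  bed_p <- c(lt_100 = 0.03, `100_249` = 0.20, `250_500` = 0.24,
             gt_500 = 0.44, unknown = 0.09)
  hb_p  <- c(lt_8 = 0.09, `8_11` = 0.53, ge_11 = 0.37, none = 0.01)
  alb_p <- c(lt_2 = 0.09, `2_3` = 0.41, ge_3 = 0.30, none = 0.19)
  wbc_p <- c(lt_4000 = 0.06, `4000_12000` = 0.47, ge_12000 = 0.46, none = 0.01)
  bun_p <- c(le_30 = 0.58, gt_30 = 0.41, none = 0.01)
  lac_p <- c(lt_2 = 0.42, `2_5` = 0.17, ge_5 = 0.02, none = 0.39)

  age    <- round(rtruncnorm(n, 64, 15, 18, 100))
  male   <- stats::runif(n) < 0.54
  bmi    <- round(rtruncnorm(n, 29, 8, 12, 58), 1)
  bad_bmi <- stats::runif(n) < 0.01
  bmi[bad_bmi] <- sample(c(8, 62, NA_real_), sum(bad_bmi), replace = TRUE)
  apache <- round(rtruncnorm(n, 67, 22, 5, 200))
  apache[stats::runif(n) < 0.01] <- NA_integer_
  height_m <- rtruncnorm(n, 1.70, 0.10, 1.45, 2.05)
  weight_kg <- round(ifelse(is.na(bmi), rtruncnorm(n, 80, 15, 40, 180),
                            pmax(35, bmi) * height_m^2), 1)

  lactate_cat <- rcat(n, lac_p)
  lactate <- rep(NA_real_, n)
  lactate[lactate_cat == "lt_2"] <- round(stats::runif(sum(lactate_cat == "lt_2"), 0.4, 1.9), 1)
  lactate[lactate_cat == "2_5"]  <- round(stats::runif(sum(lactate_cat == "2_5"), 2.0, 4.9), 1)
  lactate[lactate_cat == "ge_5"] <- round(stats::runif(sum(lactate_cat == "ge_5"), 5.0, 14), 1)

  ventilator <- stats::runif(n) < 0.36
  # day-1 SOFA organ inputs; ventilated patients have worse oxygenation
  pf_ratio   <- round(rtruncnorm(n, ifelse(ventilator, 230, 350), 90, 60, 520))
  platelets  <- round(rtruncnorm(n, 220, 90, 10, 600))
  bilirubin  <- round(pmin(exp(stats::rnorm(n, log(0.8), 0.6)), 25), 1)
  gcs        <- pmin(15L, pmax(3L, round(rtruncnorm(n, 14.2, 2.2, 3, 16))))
  creatinine <- round(pmin(exp(stats::rnorm(n, log(1.1), 0.5)), 12), 2)
  day1_lowest_map <- round(rtruncnorm(n, 68, 10, 35, 95))

  # vasopressor exposure rises with severity
  p_vaso <- stats::plogis(-1.2 + 0.02 * (ifelse(is.na(apache), 67, apache) - 67))
  any_vaso <- stats::runif(n) < p_vaso
  nee_cum_mcg <- ifelse(any_vaso,
                        round(exp(stats::rnorm(n, log(6000), 1.0))), 0)

  los_min <- round(pmin(pmax(stats::qlnorm(stats::runif(n),
                                           config$los_meanlog, config$los_sdlog),
                             config$los_range[1]), config$los_range[2]))
  short <- stats::runif(n) < config$short_stay_fraction
  los_min[short] <- round(stats::runif(sum(short), 600, 1430))

  dt <- data.table::data.table(
    patient_id = seq_len(n),
    age = age, male = male,
    ethnicity = factor(rcat(n, eth_p), levels = names(eth_p)),
    bmi = bmi, apache_iva = apache,
    admission_type = factor(rcat(n, adm_p), levels = names(adm_p)),
    admission_year = factor(rcat(n, yr_p), levels = names(yr_p)),
    bed_size = factor(rcat(n, bed_p), levels = names(bed_p)),
    med_aspirin = stats::runif(n) < 0.12,
    med_diuretic = stats::runif(n) < 0.14,
    med_ace = stats::runif(n) < 0.10,
    med_arb = stats::runif(n) < 0.04,
    med_beta_blocker = stats::runif(n) < 0.16,
    med_ccb = stats::runif(n) < 0.08,
    hemoglobin_cat = factor(rcat(n, hb_p), levels = names(hb_p)),
    albumin_cat = factor(rcat(n, alb_p), levels = names(alb_p)),
    wbc_cat = factor(rcat(n, wbc_p), levels = names(wbc_p)),
    bun_cat = factor(rcat(n, bun_p), levels = names(bun_p)),
    lactate_cat = factor(lactate_cat, levels = names(lac_p)),
    lactate = lactate,
    hx_hypertension = stats::runif(n) < 0.54,
    hx_diabetes = stats::runif(n) < 0.35,
    hx_copd = stats::runif(n) < 0.23,
    hx_chf = stats::runif(n) < 0.18,
    hx_pvd = stats::runif(n) < 0.06,
    hx_valve = stats::runif(n) < 0.04,
    hx_pe = stats::runif(n) < 0.02,
    hx_neuromuscular = stats::runif(n) < 0.013,
    hx_hypothyroid = stats::runif(n) < 0.11,
    hx_liver = stats::runif(n) < 0.05,
    hx_aids = stats::runif(n) < 0.01,
    hx_cancer = stats::runif(n) < 0.16,
    hx_arthritis = stats::runif(n) < 0.025,
    hx_coagulopathy = stats::runif(n) < 0.05,
    hx_anemia = stats::runif(n) < 0.009,
    hx_home_oxygen = stats::runif(n) < 0.05,
    hx_transplant = stats::runif(n) < 0.017,
    hx_ckd = stats::runif(n) < 0.19,
    hx_mi = stats::runif(n) < 0.09,
    hx_stroke = stats::runif(n) < 0.12,
    hx_cad = stats::runif(n) < 0.12,
    ventilator = ventilator,
    dnr = stats::runif(n) < 0.03,
    mech_circ_support = stats::runif(n) < 0.01,
    surgery_before_icu = stats::runif(n) < 0.02,
    infection_dx = stats::runif(n) < 0.90,
    antibiotics_gt48h = stats::runif(n) < 0.60,
    pf_ratio = pf_ratio, platelets = platelets, bilirubin = bilirubin,
    gcs = gcs, creatinine = creatinine, day1_lowest_map = day1_lowest_map,
    any_vasopressor = any_vaso, nee_cumulative_mcg = nee_cum_mcg,
    weight_kg = weight_kg, los_min = los_min
  )
  dt
}

#' Generate one patient's blood-pressure reading stream and ground truth
#'
#' Builds a latent 1-minute trajectory for each component: pulse pressure
#' (PP) and mean pressure (MAP) follow mean-reverting AR(1) fluctuations
#' around patient baselines; a sustained primary hypotensive episode pulls
#' MAP down to a patient-specific target level for at least two hours, and
#' shorter secondary dips are superimposed.  DBP and SBP are then derived so
#' that the textbook identities MAP = (2 DBP + SBP)/3 and PP = SBP - DBP
#' hold exactly in the latent truth, with SBP > DBP + 5 enforced.  Readings
#' are emitted as block medians for invasive lines (every
#' `continuous_interval_min` minutes) and noisy aperiodic cuff values for
#' non-invasive monitoring; artifacts and monitoring gaps are injected at
#' the configured rates.
#'
#' @param patient one-row patient record from [generate_patients()] (needs
#'   `patient_id` and `los_min`).
#' @param config a [sim_config()].
#' @param keep_series if `TRUE`, the latent minute matrix is returned in the
#'   truth record (memory-heavy for large cohorts).
#' @return list with `readings` (data.table: patient_id, time_min, sbp,
#'   dbp, map, source) and `truth` (list: true lowest sustained 120-minute
#'   value per component from the rounded latent series, and optionally the
#'   latent series itself).
#' @export
generate_vitals <- function(patient, config, keep_series = FALSE) {
  stopifnot(inherits(config, "bphinge_sim_config"))
  L <- as.integer(patient$los_min)
  if (is.na(L) || L <= 0) stop("patient LOS must be > 0", call. = FALSE)
  set.seed(patient_seed(config$seed, patient$patient_id))

  lat <- latent_trajectory(L, config)
  rounded <- lapply(lat, round_half_up)
  lowest120 <- function(v) if (L >= 120L) sort(v)[120L] else NA_real_

  truth <- list(
    patient_id = patient$patient_id,
    true_lowest120_map = lowest120(rounded$map),
    true_lowest120_sbp = lowest120(rounded$sbp),
    true_lowest120_dbp = lowest120(rounded$dbp),
    true_lowest120_pp  = lowest120(rounded$pp)
  )
  if (keep_series) truth$latent <- rounded

  invasive <- stats::runif(1) < config$invasive_fraction
  readings <- emit_readings(lat, L, invasive, config)
  readings <- inject_artifacts(readings, config)
  readings <- inject_gaps(readings, L, config)
  readings[, patient_id := patient$patient_id]
  data.table::setcolorder(readings, c("patient_id", "time_min", "sbp",
                                      "dbp", "map", "source"))
  list(readings = readings[], truth = truth)
}

# Latent 1-minute trajectories for MAP/PP; DBP/SBP derived for consistency.
latent_trajectory <- function(L, config) {
  innov_sd <- config$ar_sd * sqrt(1 - config$ar_phi^2)
  ar1 <- function(n) {
    as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), config$ar_phi,
                             method = "recursive",
                             init = stats::rnorm(1, 0, config$ar_sd)))
  }
  b_map <- stats::rnorm(1, config$baseline_map_mean, config$baseline_map_sd)
  b_pp  <- max(12, stats::rnorm(1, config$baseline_pp_mean, config$baseline_pp_sd))

  dip <- numeric(L)                       # mmHg pulled off the MAP baseline
  if (L >= 150L) {
    # primary sustained episode: reaches a patient-specific target level
    target <- stats::rnorm(1, config$map_target_mean, config$map_target_sd)
    depth <- max(0, b_map - target)
    dur <- min(L, 130L + as.integer(round(stats::rexp(1, 1 / 120))))
    start <- as.integer(floor(stats::runif(1, 0, L - dur + 1)))
    idx <- seq.int(start + 1L, start + dur)
    dip[idx] <- pmax(dip[idx], depth)
  }
  n_ep <- stats::rpois(1, L / 60 * config$episode_rate_per_hr)
  for (k in seq_len(n_ep)) {
    d <- stats::rexp(1, 1 / config$episode_depth_mean)
    dur <- as.integer(round(stats::runif(1, 20, 80)))
    if (dur >= L) next
    start <- as.integer(floor(stats::runif(1, 0, L - dur)))
    idx <- seq.int(start + 1L, start + dur)
    dip[idx] <- pmax(dip[idx], d)
  }

  map <- b_map - dip + ar1(L)
  pp  <- pmax(6, b_pp - 0.35 * dip + ar1(L))
  map <- pmax(map, 12 + pp / 3)           # keep latent DBP physiologic (> 12)
  dbp <- map - pp / 3
  sbp <- dbp + pp
  list(map = map, sbp = sbp, dbp = dbp, pp = pp)
}

# Median of consecutive blocks of `step` minutes (last block may be
# partial).  Odd steps go through runmed() for speed.
block_medians <- function(v, step) {
  L <- length(v)
  if (step == 1L) return(v)
  nfull <- L %/% step
  med <- numeric(ceiling(L / step))
  if (nfull > 0L) {
    if (step %% 2L == 1L) {
      rm <- stats::runmed(v, step, endrule = "keep")
      med[seq_len(nfull)] <- rm[seq.int((step + 1L) %/% 2L, by = step,
                                        length.out = nfull)]
    } else {
      for (b in seq_len(nfull))
        med[b] <- stats::median(v[((b - 1L) * step + 1L):(b * step)])
    }
  }
  if (L %% step) med[nfull + 1L] <- stats::median(v[(nfull * step + 1L):L])
  med
}

emit_readings <- function(lat, L, invasive, config) {
  out <- list()
  if (invasive) {
    step <- as.integer(config$continuous_interval_min)
    starts <- seq.int(1L, L, by = step)
    out$inv <- data.table::data.table(
      time_min = starts - 1L,
      sbp = block_medians(lat$sbp, step),
      dbp = block_medians(lat$dbp, step),
      map = block_medians(lat$map, step),
      source = "invasive")
    nibp_mean <- 60
  } else {
    nibp_mean <- config$aperiodic_mean_interval_min
  }
  # aperiodic cuff readings: jittered nursing schedule (0.5-1.5x the mean
  # interval, so cadence alone never breaches the 2-h gap rule), latent
  # value at the minute + noise, MAP absent
  n_max <- ceiling(L / (0.5 * nibp_mean)) + 5L
  t <- cumsum(stats::runif(n_max, 0.5, 1.5) * nibp_mean)
  t <- unique(as.integer(floor(t[t < L])))
  if (length(t)) {
    out$nibp <- data.table::data.table(
      time_min = t,
      sbp = lat$sbp[t + 1L] + stats::rnorm(length(t), 0, config$nibp_noise_sd),
      dbp = lat$dbp[t + 1L] + stats::rnorm(length(t), 0, config$nibp_noise_sd),
      map = NA_real_,
      source = "noninvasive")
  }
  r <- data.table::rbindlist(out)
  data.table::setorder(r, time_min)
  r
}

# Replace a fraction of readings by values violating a plausibility filter.
inject_artifacts <- function(readings, config) {
  if (config$artifact_rate <= 0 || nrow(readings) == 0L) return(readings)
  hit <- which(stats::runif(nrow(readings)) < config$artifact_rate)
  if (!length(hit)) return(readings)
  type <- sample(c("sbp_high", "sbp_low", "dbp_high", "dbp_low",
                   "map_high", "map_low", "pinched"),
                 length(hit), replace = TRUE)
  sbp <- readings$sbp; dbp <- readings$dbp; map <- readings$map
  u <- stats::runif(length(hit))
  for (j in seq_along(hit)) {
    i <- hit[j]
    switch(type[j],
      sbp_high = { sbp[i] <- 300 + 100 * u[j] },
      sbp_low  = { sbp[i] <- 20 * u[j] },
      dbp_high = { dbp[i] <- 225 + 55 * u[j] },
      dbp_low  = { dbp[i] <- 5 * u[j] },
      map_high = { map[i] <- 250 + 70 * u[j] },
      map_low  = { map[i] <- 10 * u[j] },
      pinched  = { sbp[i] <- dbp[i] + 5 * u[j] }
    )
  }
  data.table::set(readings, j = "sbp", value = sbp)
  data.table::set(readings, j = "dbp", value = dbp)
  data.table::set(readings, j = "map", value = map)
  readings
}

inject_gaps <- function(readings, L, config) {
  if (config$gap_rate_per_hr <= 0 || nrow(readings) == 0L) return(readings)
  n_gaps <- stats::rpois(1, L / 60 * config$gap_rate_per_hr)
  if (n_gaps == 0L) return(readings)
  start <- stats::runif(n_gaps, 0, L)
  dur <- stats::runif(n_gaps, config$gap_duration_range[1],
                      config$gap_duration_range[2])
  drop <- rep(FALSE, nrow(readings))
  for (g in seq_len(n_gaps)) {
    drop <- drop | (readings$time_min >= start[g] &
                    readings$time_min < start[g] + dur[g])
  }
  readings[!drop]
}

#' Draw an outcome from the hinge dose-response on the true exposure
#'
#' The outcome log-odds sit at `plateau_logit` (plus covariate terms) when
#' the true exposure is at or above the change-point and rise linearly as
#' pressure falls below it: `logit P = plateau_logit + pre_slope *
#' (min(x, cp) - cp) + covariate terms`, with `pre_slope <= 0` expressed in
#' log-odds per mmHg of pressure, so each mmHg below the change-point adds
#' `|pre_slope|` to the log-odds.
#'
#' @param true_exposure mmHg; true lowest sustained pressure.
#' @param covariates named numeric vector of mean-centred covariate values
#'   (e.g. `c(age = age - 64, apache = apache - 67)`); may be empty.
#' @param hinge_params list with `change_point`, `pre_slope`,
#'   `plateau_logit`.
#' @param covariate_effects named log-odds-per-unit effects matched to
#'   `covariates` by name.
#' @return list with `p` (outcome probability) and `outcome` (0/1 draw from
#'   the current RNG stream).  Vectorized over `true_exposure` when
#'   `covariates` is a matrix/data.frame with matching rows.
#' @export
assign_outcome <- function(true_exposure, covariates = numeric(),
                           hinge_params,
                           covariate_effects = numeric()) {
  cp <- hinge_params$change_point
  lp <- hinge_params$plateau_logit +
    hinge_params$pre_slope * (pmin(true_exposure, cp) - cp)
  if (length(covariate_effects)) {
    cv <- if (is.matrix(covariates) || is.data.frame(covariates)) {
      as.matrix(covariates)[, names(covariate_effects), drop = FALSE] %*%
        covariate_effects
    } else {
      sum(covariate_effects * covariates[names(covariate_effects)])
    }
    lp <- lp + as.numeric(cv)
  }
  p <- stats::plogis(lp)
  list(p = p, outcome = as.integer(stats::runif(length(p)) < p))
}

# Draw ICU mortality, AKI, and myocardial-injury outcomes from the hinge
# dose-responses on the TRUE lowest sustained MAP; adds p_death/death/aki/mi
# columns to the truth table.  Uses its own derived RNG stream so outcome
# draws do not depend on how the vitals were generated.
assign_cohort_outcomes <- function(patients, truth, config) {
  set.seed(patient_seed(config$seed, -1L))
  cov <- cbind(age = patients$age - 64,
               apache = ifelse(is.na(patients$apache_iva), 0,
                               patients$apache_iva - 67))
  x_true <- truth$true_lowest120_map
  x_eff <- ifelse(is.na(x_true), config$map_target_mean, x_true)
  death <- assign_outcome(x_eff, cov, config$hinge, config$covariate_effects)
  aki   <- assign_outcome(x_eff, cov, config$aki_hinge, config$covariate_effects)
  mi    <- assign_outcome(x_eff, cov, config$mi_hinge, config$covariate_effects)
  truth[, `:=`(p_death = death$p, death = death$outcome,
               aki = aki$outcome, mi = mi$outcome)]
  truth[]
}

#' Simulate an exposure-level cohort for estimator validation
#'
#' Skips the vitals layer entirely: draws the true lowest sustained MAP
#' directly from its population distribution together with age and APACHE
#' IVa covariates, then assigns ICU mortality through the hinge
#' dose-response.  This is the canonical test bed for the change-point and
#' spline estimators, where the exposure distribution must be controlled
#' exactly.
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @param config a [sim_config()]; the hinge, covariate effects, and
#'   exposure mean/SD are taken from it.
#' @return `data.table` with exposure, covariates, true probability, and
#'   outcome.
#' @export
simulate_exposure_cohort <- function(n, seed, config = sim_config()) {
  set.seed(as.integer(seed) %% 2147483629L)
  x <- stats::rnorm(n, config$map_target_mean, config$map_target_sd)
  age <- round(rtruncnorm(n, 64, 15, 18, 100))
  apache <- round(rtruncnorm(n, 67, 22, 5, 200))
  cov <- cbind(age = age - 64, apache = apache - 67)
  res <- assign_outcome(x, cov, config$hinge, config$covariate_effects)
  data.table::data.table(
    patient_id = seq_len(n), exposure = x, age = age, apache_iva = apache,
    p_true = res$p, outcome = res$outcome)
}

#' Simulate a full synthetic septic-ICU cohort
#'
#' Runs [generate_patients()], then [generate_vitals()] per patient, assigns
#' ICU mortality from the hinge dose-response on the TRUE lowest sustained
#' MAP (so that measurement error in the reading stream attenuates, rather
#' than defines, the estimand), and generates acute-kidney-injury and
#' troponin events from their own hinge dose-responses.
#'
#' @param config a [sim_config()].
#' @param keep_series keep latent minute series in the truth table (only
#'   sensible for small cohorts).
#' @return list with `patients`, `readings`, `truth` (per-patient true
#'   exposures, outcome probability and draw), `events` (death / aki /
#'   troponin rows: patient_id, type, time_min, value), and `vasopressors`.
#' @export
simulate_cohort <- function(config = sim_config(), keep_series = FALSE) {
  patients <- generate_patients(config)
  res <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    res[[i]] <- generate_vitals(patients[i], config, keep_series = keep_series)
  }
  readings <- data.table::rbindlist(lapply(res, `[[`, "readings"))
  truth <- data.table::rbindlist(lapply(res, function(r) {
    r$truth[c("patient_id", "true_lowest120_map", "true_lowest120_sbp",
              "true_lowest120_dbp", "true_lowest120_pp")]
  }))
  if (keep_series) {
    attr(truth, "latent") <- lapply(res, function(r) r$truth$latent)
  }

  truth <- assign_cohort_outcomes(patients, truth, config)

  los <- patients$los_min
  is_death <- truth$death == 1L
  is_aki <- truth$aki == 1L
  is_mi <- truth$mi == 1L
  ev <- list(
    data.table::data.table(patient_id = patients$patient_id[is_death],
                           type = "death",
                           time_min = los[is_death],
                           value = NA_real_),
    data.table::data.table(patient_id = patients$patient_id[is_aki],
                           type = "aki",
                           time_min = round(stats::runif(sum(is_aki), 60,
                                                         los[is_aki])),
                           value = NA_real_),
    data.table::data.table(patient_id = patients$patient_id[is_mi],
                           type = "troponin",
                           time_min = round(stats::runif(sum(is_mi), 60,
                                                         los[is_mi])),
                           value = round(stats::runif(sum(is_mi), 0.031, 2), 3))
  )
  events <- data.table::rbindlist(ev)
  data.table::setorder(events, patient_id, time_min)

  vaso <- patients[patients$any_vasopressor == TRUE,
                   list(patient_id = patient_id, drug = "norepinephrine",
                        cumulative_dose_mcg = nee_cumulative_mcg)]

  list(patients = patients, readings = readings, truth = truth,
       events = events, vasopressors = vaso)
}

#' Write a simulated cohort to delimited text files
#'
#' Emits `patients.csv`, `vitals.csv` (long format: patient_id, timestamp
#' ISO 8601, component, value, source), `truth.csv`, `events.csv`,
#' `vasopressors.csv`, and the generating configuration as `config.yaml`.
#'
#' @param sim result of [simulate_cohort()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @param origin POSIXct origin mapped to minute 0.
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(sim, config, dir,
                         origin = as.POSIXct("2014-01-01 00:00:00", tz = "UTC")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "vitals.csv", "truth.csv",
                            "events.csv", "vasopressors.csv", "config.yaml"))
  r <- sim$readings
  long <- data.table::rbindlist(lapply(c("sbp", "dbp", "map"), function(comp) {
    keep <- !is.na(r[[comp]])
    data.table::data.table(
      patient_id = r$patient_id[keep],
      timestamp = format(origin + r$time_min[keep] * 60,
                         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      component = toupper(comp),
      value = round(r[[comp]][keep], 1),
      source = r$source[keep])
  }))
  data.table::fwrite(sim$patients, paths[1])
  data.table::fwrite(long, paths[2])
  data.table::fwrite(sim$truth, paths[3])
  data.table::fwrite(sim$events, paths[4])
  data.table::fwrite(sim$vasopressors, paths[5])
  yaml::write_yaml(unclass(config), paths[6])
  invisible(paths)
}
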