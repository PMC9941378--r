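test_that("SOFA organ scores match the published criteria table", {
  # cardiovascular: MAP below 70 without vasopressors scores 1
  expect_equal(compute_sofa(map = 65)$cardiovascular, 1L)
  expect_equal(compute_sofa(map = 75)$cardiovascular, 0L)
  expect_equal(compute_sofa(map = 65, vasopressor_rate = 0.05)$cardiovascular, 3L)
  expect_equal(compute_sofa(map = 80, vasopressor_rate = 0.2)$cardiovascular, 4L)
  # coagulation
  expect_equal(compute_sofa(platelets = 250)$coagulation, 0L)
  expect_equal(compute_sofa(platelets = 140)$coagulation, 1L)
  expect_equal(compute_sofa(platelets = 15)$coagulation, 4L)
  # respiration requires ventilation for scores 3-4
  expect_equal(compute_sofa(pf_ratio = 180, ventilated = TRUE)$respiration, 3L)
  expect_equal(compute_sofa(pf_ratio = 180, ventilated = FALSE)$respiration, 2L)
  expect_equal(compute_sofa(pf_ratio = 90, ventilated = TRUE)$respiration, 4L)
  # liver, CNS, renal spot checks
  expect_equal(compute_sofa(bilirubin = 3.5)$liver, 2L)
  expect_equal(compute_sofa(gcs = 12)$cns, 2L)
  expect_equal(compute_sofa(gcs = 15)$cns, 0L)
  expect_equal(compute_sofa(creatinine = 2.5)$renal, 2L)
  # all organs normal -> 0; missing organs score 0
  expect_equal(compute_sofa(pf_ratio = 450, platelets = 250, bilirubin = 0.5,
                            map = 80, gcs = 15, creatinine = 0.9)$total, 0L)
  expect_equal(compute_sofa()$total, 0L)
  # a compound patient sums organ scores
  s <- compute_sofa(pf_ratio = 180, ventilated = TRUE, platelets = 90,
                    bilirubin = 3.5, map = 65, gcs = 12, creatinine = 2.5)
  expect_equal(s$total, 3L + 2L + 2L + 1L + 2L + 2L)
})

test_that("sepsis requires infection evidence and SOFA >= 2", {
  expect_true(is_sepsis(TRUE, FALSE, 3))
  expect_false(is_sepsis(FALSE, FALSE, 4))   # antibiotics <= 48 h only
  expect_true(is_sepsis(FALSE, TRUE, 2))
  expect_false(is_sepsis(TRUE, TRUE, 1))     # SOFA below threshold
})

test_that("septic shock requires measured lactate above 2 with vasopressor use", {
  expect_true(is_septic_shock(3.1, TRUE))
  expect_false(is_septic_shock(1.5, TRUE))
  expect_false(is_septic_shock(3.1, FALSE))
  expect_false(is_septic_shock(NA, TRUE))    # no reading available
  expect_false(is_septic_shock(2.0, TRUE))   # strict exceedance
})

test_that("norepinephrine-equivalent rate follows the dose formula", {
  expect_equal(nee_rate(c(norepinephrine = 7200), 80, 1440), 0.0625)
  expect_equal(nee_rate(numeric(), 80, 1440), 0)
  expect_equal(nee_rate(c(dopamine = 100000), 50, 2000), 0.01)
  expect_equal(nee_rate(c(norepinephrine = 3600, epinephrine = 3600), 100, 720),
               0.1)
  expect_error(nee_rate(c(norepinephrine = -5), 80, 1440), "negative")
  expect_error(nee_rate(c(milrinone = 100), 80, 1440), "milrinone")
  expect_error(nee_rate(c(norepinephrine = 100), 0, 1440), "weight")
})

test_that("outcome definitions respect the 24-hour mortality window and troponin rule", {
  ev <- function(...) data.table::data.table(...)
  # death at hour 12: outside the assessment window
  o <- define_outcomes(ev(type = "death", time_min = 720, value = NA_real_),
                       los_min = 720)
  expect_false(o$icu_death)
  o2 <- define_outcomes(ev(type = "death", time_min = 3000, value = NA_real_),
                        los_min = 3000)
  expect_true(o2$icu_death)
  # troponin strictly above 0.03 ng/mL
  o3 <- define_outcomes(ev(type = "troponin", time_min = 1800, value = 0.04),
                        los_min = 4000)
  expect_true(o3$mi)
  expect_equal(o3$mi_time, 1800)
  o4 <- define_outcomes(ev(type = "troponin", time_min = 1800, value = 0.03),
                        los_min = 4000)
  expect_false(o4$mi)
  expect_error(define_outcomes(ev(type = "troponin", time_min = 10,
                                  value = NA_real_), 4000), "ng/mL")
  # composites
  o5 <- define_outcomes(ev(type = c("aki", "death"), time_min = c(900, 3000),
                           value = NA_real_), los_min = 3000)
  expect_true(o5$aki_or_death)
  expect_true(o5$mi_or_death)   # via death
  expect_equal(o5$aki_time, 900)
})

test_that("exclusion cascade attributes each patient to its first failing step", {
  cfg <- sim_config(n_patients = 500, seed = 23)
  p <- generate_patients(cfg)
  elig <- data.table::data.table(patient_id = p$patient_id,
                                 eligible = rep(c(TRUE, TRUE, TRUE, FALSE), length.out = nrow(p)))
  res <- apply_exclusions(p, elig)
  # attrition identity: input n = cohort n + removals
  expect_equal(nrow(p), nrow(res$cohort) + sum(res$attrition$n_removed))
  expect_equal(res$attrition$n_remaining[nrow(res$attrition)], nrow(res$cohort))
  # included patients satisfy all criteria
  expect_true(all(res$cohort$los_min >= 1440))
  expect_true(all(!res$cohort$dnr))
  expect_true(all(res$cohort$sepsis))
  expect_true(all(res$cohort$bmi > 10 & res$cohort$bmi < 60))
  # specific failures land at the right step
  q <- data.table::copy(p)
  q$los_min[1] <- 1200; q$bmi[2] <- 62
  res2 <- apply_exclusions(q, elig)
  att <- res2$attrition
  expect_gte(att[att$criterion == "los_ge_24h", ]$n_removed, 1L)
  expect_gte(att[att$criterion == "valid_bmi", ]$n_removed, 1L)
})

test_that("secondary cohort drops early outcomes and organ-dysfunction history", {
  cfg <- sim_config(n_patients = 300, seed = 29)
  p <- generate_patients(cfg)
  elig <- data.table::data.table(patient_id = p$patient_id, eligible = TRUE)
  oc <- data.table::data.table(patient_id = p$patient_id,
                               aki_time = NA_real_, mi_time = NA_real_)
  oc$aki_time[1:10] <- 720   # AKI at hour 12
  res <- apply_exclusions(p, elig, outcomes = oc, secondary = TRUE)
  expect_true(all(c("no_outcome_within_24h", "no_organ_dysfunction_history")
                  %in% res$attrition$criterion))
  expect_true(all(!res$cohort$hx_ckd & !res$cohort$hx_mi &
                  !res$cohort$hx_stroke & !res$cohort$hx_cad))
  expect_false(any(res$cohort$patient_id %in%
                     p$patient_id[1:10][res$cohort$sepsis[1:10]] &
                   !is.na(res$cohort$aki_time) & res$cohort$aki_time < 1440))
  expect_error(apply_exclusions(p, elig, secondary = TRUE), "outcomes")
})
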