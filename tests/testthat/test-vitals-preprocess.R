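test_that("plausibility filters remove whole readings with inclusive boundaries", {
  r <- data.table::rbindlist(list(
    make_reading(0, sbp = 310, dbp = 80),           # SBP >= 300
    make_reading(1, sbp = 300, dbp = 80),           # boundary, removed
    make_reading(2, sbp = 20, dbp = 10),            # SBP <= 20
    make_reading(3, sbp = 120, dbp = 118),          # SBP <= DBP + 5
    make_reading(4, sbp = 125, dbp = 120),          # boundary: 125 <= 125
    make_reading(5, sbp = 126, dbp = 120),          # kept: 126 > 125
    make_reading(6, dbp = 225, sbp = 240),          # DBP >= 225
    make_reading(7, dbp = 5, sbp = 90),             # DBP <= 5
    make_reading(8, map = 250, sbp = 180, dbp = 100),
    make_reading(9, map = 10, sbp = 60, dbp = 40),
    make_reading(10, sbp = 120, dbp = 70, map = 87) # retained
  ))
  res <- apply_plausibility_filters(r)
  expect_equal(res$n_removed, 9L)
  expect_equal(sort(res$retained$time_min), c(5, 10))
  expect_match(res$removed[time_min == 0]$reason, "SBP >= 300")
  expect_match(res$removed[time_min == 3]$reason, "SBP <= DBP \\+ 5")
  expect_match(res$removed[time_min == 9]$reason, "MAP <= 10")
  # whole-reading removal: the offending reading's other components are gone
  expect_false(80 %in% res$retained$dbp)

  # idempotence
  res2 <- apply_plausibility_filters(res$retained)
  expect_equal(res2$n_removed, 0L)
  expect_equal(res2$retained, res$retained)

  # empty input
  res0 <- apply_plausibility_filters(r[0])
  expect_equal(nrow(res0$retained), 0L)
})

test_that("MAP and PP derivations follow their formulas and propagate missingness", {
  expect_equal(derive_map(120, 60), 80)
  expect_equal(derive_map(90, 60), 70)
  expect_equal(derive_map(100, 70), 80)
  expect_true(is.na(derive_map(NA, 60)))
  expect_equal(derive_pp(120, 60), 60)
  expect_equal(derive_pp(100, 40), 60)
  expect_true(is.na(derive_pp(100, NA)))

  # derived MAP fills in only where no measured MAP exists
  r <- data.table::rbindlist(list(
    make_reading(0, sbp = 120, dbp = 60, map = 82),
    make_reading(1, sbp = 120, dbp = 60)))
  d <- derive_components(r)
  expect_equal(d$map, c(82, 80))
  expect_equal(d$pp, c(60, 60))
})

test_that("invasive readings take priority and collisions resolve to the later reading", {
  r <- data.table::rbindlist(list(
    make_reading(0, map = 65, source = "invasive"),
    make_reading(0, map = 80, source = "noninvasive"),
    make_reading(5, map = 80, source = "noninvasive"),
    make_reading(9, map = 70, source = "invasive"),
    make_reading(9, map = 72, source = "invasive")   # same-minute duplicate
  ))
  res <- merge_sources(r, components = "map")
  m <- res$merged
  expect_equal(m[time_min == 0]$value, 65)
  expect_equal(m[time_min == 5]$value, 80)
  expect_equal(m[time_min == 9]$value, 72)
  expect_equal(res$n_collisions, 1L)
})

test_that("invasive fraction is the share of invasive readings", {
  r <- data.table::rbindlist(c(
    lapply(1:48, function(i) make_reading(i, map = 70, source = "invasive")),
    lapply(49:100, function(i) make_reading(i, map = 70, source = "noninvasive"))))
  expect_equal(merge_sources(r)$invasive_fraction, 0.48)
})

test_that("interpolation is linear, rounds half-up, and never extrapolates", {
  mk <- function(t, v) data.table::data.table(component = "map", time_min = t,
                                              value = v)
  s <- interpolate_to_minutes(mk(c(0, 10), c(60, 70)), window = c(0, 15))
  expect_equal(s$values$map[6], 65)                       # midpoint
  expect_equal(s$provenance$map[1], "measured")
  expect_equal(s$provenance$map[6], "interpolated")
  expect_true(all(is.na(s$values$map[12:15])))            # no extrapolation

  s2 <- interpolate_to_minutes(mk(c(0, 3), c(60, 62)), window = c(0, 4))
  expect_equal(s2$values$map, c(60, 61, 61, 62))          # 60.67 -> 61

  s3 <- interpolate_to_minutes(mk(seq(0, 20, 5), rep(70, 5)), window = c(0, 21))
  expect_true(all(s3$values$map == 70))

  # single reading -> component insufficient
  s4 <- interpolate_to_minutes(mk(3, 70), window = c(0, 10))
  expect_true("map" %in% s4$insufficient)
  expect_true(all(is.na(s4$values$map)))

  # order independence: shuffled input gives identical output
  set.seed(4)
  t <- sort(sample(0:200, 30)); v <- round(runif(30, 50, 90), 1)
  a <- interpolate_to_minutes(mk(t, v), c(0, 201))
  perm <- sample(30)
  b <- interpolate_to_minutes(mk(t[perm], v[perm]), c(0, 201))
  expect_identical(a$values, b$values)
})

test_that("the 2-hour gap rule uses strict exceedance and counts window edges", {
  expect_true(check_measurement_frequency(seq(0, 600, 60), c(0, 600))$eligible)
  res <- check_measurement_frequency(c(0, 130, 200), c(0, 200))
  expect_false(res$eligible)
  expect_equal(res$max_gap, 130)
  # exactly 120 minutes is allowed
  expect_true(check_measurement_frequency(c(0, 120, 240), c(0, 240))$eligible)
  # leading/trailing unmonitored spans count
  expect_false(check_measurement_frequency(c(125, 180), c(0, 200))$eligible)
  expect_false(check_measurement_frequency(c(0, 60), c(0, 200))$eligible)
  # no readings at all
  res0 <- check_measurement_frequency(numeric(0), c(0, 300))
  expect_false(res0$eligible)
  expect_equal(res0$max_gap, 300)
})

test_that("PP equals SBP minus DBP at minutes where both were measured", {
  cfg <- sim_config(n_patients = 3, seed = 13)
  p <- generate_patients(cfg)
  g <- generate_vitals(p[1], cfg)
  s <- preprocess_patient(g$readings, c(0L, p$los_min[1]), 120L, 1L)
  meas <- which(s$provenance$sbp == "measured" & s$provenance$dbp == "measured" &
                s$provenance$pp == "measured")
  expect_gt(length(meas), 10)
  expect_true(all(abs(s$values$pp[meas] -
                      (s$values$sbp[meas] - s$values$dbp[meas])) <= 1))
})

test_that("noise-free invasive 1-minute data reproduce the latent truth exactly", {
  cfg <- clean_config(n = 3, seed = 17)
  p <- generate_patients(cfg)
  for (i in seq_len(nrow(p))) {
    g <- generate_vitals(p[i], cfg, keep_series = TRUE)
    s <- preprocess_patient(g$readings, c(0L, p$los_min[i]), 120L,
                            p$patient_id[i])
    for (comp in c("map", "sbp", "dbp", "pp")) {
      expect_identical(s$values[[comp]], as.numeric(g$truth$latent[[comp]]))
    }
    expect_true(s$eligible)
    expect_equal(s$n_removed, 0L)
  }
})
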