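# Shared fixtures: small reading tables and noise-free generator configs.

make_reading <- function(time_min, sbp = NA_real_, dbp = NA_real_,
                         map = NA_real_, source = "invasive") {
  data.table::data.table(patient_id = 1L, time_min = time_min, sbp = sbp,
                         dbp = dbp, map = map, source = source)
}

# invasive readings with all three components at given minutes
make_readings <- function(time_min, map, sbp = map + 25, dbp = map - 12,
                          source = "invasive") {
  data.table::data.table(patient_id = 1L, time_min = time_min, sbp = sbp,
                         dbp = dbp, map = map, source = source)
}

# generator config with all measurement imperfections switched off:
# invasive-only, 1-minute cadence, no artifacts, no gaps, no short stays
clean_config <- function(n = 5, seed = 42, ...) {
  sim_config(n_patients = n, seed = seed, artifact_rate = 0,
             gap_rate_per_hr = 0, invasive_fraction = 1,
             continuous_interval_min = 1, short_stay_fraction = 0, ...)
}

# random integer minute series for oracle comparisons
random_series <- function(rng_n, min_len = 130, max_len = 500) {
  len <- sample(min_len:max_len, 1)
  # mixture of plateaus and noise so ties and runs both occur
  base <- sample(30:110, 1)
  v <- base + cumsum(sample(c(-1L, 0L, 1L), len, replace = TRUE))
  dips <- sample(0:3, 1)
  for (d in seq_len(dips)) {
    s <- sample(seq_len(len - 20), 1)
    w <- sample(10:60, 1)
    idx <- s:min(len, s + w)
    v[idx] <- v[idx] - sample(5:30, 1)
  }
  pmax(15L, pmin(240L, as.integer(v)))
}
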