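# End-to-end orchestration: simulate -> preprocess -> cohort -> exposure ->
# models -> report, with plain CSV/JSON artifacts and a run manifest.

# Table-2-analogue category definitions per component: one normotensive
# reference and overlapping "< cutoff" comparison groups.
COMPONENT_CATEGORIES <- list(
  map = list(reference = function(x) x >= 75,
             cutoffs = c(`<75` = 75, `<65` = 65, `<55` = 55, `<45` = 45)),
  sbp = list(reference = function(x) x >= 110,
             cutoffs = c(`<110` = 110, `<100` = 100, `<90` = 90, `<80` = 80)),
  dbp = list(reference = function(x) x >= 60,
             cutoffs = c(`<60` = 60, `<50` = 50, `<40` = 40, `<30` = 30)),
  pp  = list(reference = function(x) x >= 40 & x < 50,
             cutoffs = c(`<40` = 40, `<30` = 30, `<20` = 20))
)

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param outdir output directory for artifacts.
#' @param components blood-pressure components to model.
#' @param duration_min cumulative-duration requirement (minutes).
#' @param thresholds named TWA thresholds (mmHg).
#' @param gap_limit eligibility gap limit (minutes).
#' @param n_bins,ma_window binned moving-average settings.
#' @param spline_k basis dimension per smooth.
#' @param nboot bootstrap replicates for hinge CIs.
#' @param stages subset of the six stages to run (in canonical order).
#' @return a `bphinge_run_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), outdir = tempfile("bphinge_run_"),
                            components = c("map", "sbp", "dbp", "pp"),
                            duration_min = 120,
                            thresholds = DEFAULT_TWA_THRESHOLDS,
                            gap_limit = 120, n_bins = 100, ma_window = 5,
                            spline_k = 10, nboot = 50,
                            stages = c("simulate", "preprocess", "cohort",
                                       "exposure", "models", "report")) {
  stopifnot(inherits(sim, "bphinge_sim_config"))
  components <- match.arg(components, c("map", "sbp", "dbp", "pp"),
                          several.ok = TRUE)
  stages <- match.arg(stages, c("simulate", "preprocess", "cohort",
                                "exposure", "models", "report"),
                      several.ok = TRUE)
  structure(list(sim = sim, outdir = outdir, components = components,
                 duration_min = duration_min, thresholds = thresholds,
                 gap_limit = gap_limit, n_bins = n_bins,
                 ma_window = ma_window, spline_k = spline_k, nboot = nboot,
                 stages = stages),
            class = "bphinge_run_config")
}

#' Simulate, preprocess, and measure exposures in one streaming pass
#'
#' Generates each patient's reading stream, preprocesses it, and reduces it
#' to exposure summaries immediately, so minute-level series are never held
#' for the whole cohort at once.  This is the memory-lean path for large
#' validation runs; [run_pipeline()] keeps full artifacts instead.
#'
#' @param config a [sim_config()].
#' @param duration_min,thresholds,gap_limit as in [pipeline_config()].
#' @return list: `patients`, `truth` (with outcomes), `exposures` (long
#'   per-component summaries of the measured series), `eligibility`.
#' @export
simulate_and_measure <- function(config, duration_min = 120,
                                 thresholds = DEFAULT_TWA_THRESHOLDS,
                                 gap_limit = 120) {
  patients <- generate_patients(config)
  n <- nrow(patients)
  expo <- elig <- truth <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_vitals(patients[i], config)
    truth[[i]] <- g$truth
    s <- preprocess_patient(g$readings, c(0L, patients$los_min[i]),
                            gap_limit, patients$patient_id[i])
    elig[[i]] <- data.table::data.table(
      patient_id = patients$patient_id[i], eligible = s$eligible,
      max_gap = s$max_gap, invasive_fraction = s$invasive_fraction,
      n_readings = nrow(g$readings), n_removed = s$n_removed)
    expo[[i]] <- exposure_summary(s, patients$los_min[i],
                                  duration_min = duration_min,
                                  thresholds = thresholds)
  }
  truth <- data.table::rbindlist(lapply(truth, function(tr) {
    tr[c("patient_id", "true_lowest120_map", "true_lowest120_sbp",
         "true_lowest120_dbp", "true_lowest120_pp")]
  }))
  truth <- assign_cohort_outcomes(patients, truth, config)
  list(patients = patients, truth = truth,
       exposures = data.table::rbindlist(expo),
       eligibility = data.table::rbindlist(elig))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, preprocess, cohort,
#' exposure, models, report), writing every artifact as CSV/JSON under
#' `config$outdir` together with a manifest (configuration hash, seed, row
#' counts, package version).  Deterministic stages are byte-identical when
#' re-run with the same configuration.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "bphinge_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("bphinge")),
                   seed = config$sim$seed, stages = list())
  cfg_path <- file.path(config$outdir, "run_config.yaml")
  yaml::write_yaml(list(sim = unclass(config$sim),
                        pipeline = unclass(config)[setdiff(names(config), "sim")]),
                   cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  mark_incomplete <- function() {
    writeLines("incomplete", file.path(config$outdir, "INCOMPLETE"))
  }

  sim <- measured <- cohort <- NULL
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      mark_incomplete()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)),
      res)
    invisible(NULL)
  }

  run_stage("simulate", function() {
    sim <<- simulate_cohort(config$sim)
    write_cohort(sim, config$sim, config$outdir)
    list(n_patients = nrow(sim$patients), n_readings = nrow(sim$readings),
         n_events = nrow(sim$events))
  })

  run_stage("preprocess", function() {
    if (is.null(sim)) stop("no simulated data in memory; enable 'simulate'")
    patients <- sim$patients
    rl <- split(sim$readings, by = "patient_id")
    series_tab <- elig <- expo <- vector("list", nrow(patients))
    for (i in seq_len(nrow(patients))) {
      pid <- patients$patient_id[i]
      r <- rl[[as.character(pid)]]
      if (is.null(r)) r <- sim$readings[0]
      s <- preprocess_patient(r, c(0L, patients$los_min[i]),
                              config$gap_limit, pid)
      elig[[i]] <- data.table::data.table(
        patient_id = pid, eligible = s$eligible, max_gap = s$max_gap,
        invasive_fraction = s$invasive_fraction, n_readings = nrow(r),
        n_removed = s$n_removed, n_collisions = s$n_collisions)
      expo[[i]] <- exposure_summary(s, patients$los_min[i],
                                    duration_min = config$duration_min,
                                    thresholds = config$thresholds)
    }
    measured <<- list(eligibility = data.table::rbindlist(elig),
                      exposures = data.table::rbindlist(expo))
    data.table::fwrite(measured$eligibility,
                       file.path(config$outdir, "eligibility.csv"))
    list(n_patients = nrow(patients),
         n_ineligible = sum(!measured$eligibility$eligible),
         n_readings_removed = sum(measured$eligibility$n_removed),
         invasive_fraction = round(with(measured$eligibility,
           sum(invasive_fraction * n_readings, na.rm = TRUE) /
             sum(n_readings[!is.na(invasive_fraction)])), 4))
  })

  run_stage("cohort", function() {
    if (is.null(measured)) stop("preprocess stage required")
    res <- apply_exclusions(sim$patients, measured$eligibility)
    cohort <<- res$cohort
    data.table::fwrite(res$attrition,
                       file.path(config$outdir, "attrition.csv"))
    data.table::fwrite(cohort, file.path(config$outdir, "cohort.csv"))
    list(n_input = nrow(sim$patients), n_cohort = nrow(cohort))
  })

  run_stage("exposure", function() {
    if (is.null(measured)) stop("preprocess stage required")
    data.table::fwrite(measured$exposures,
                       file.path(config$outdir, "exposures.csv"))
    list(n_rows = nrow(measured$exposures))
  })

  run_stage("models", function() {
    if (is.null(cohort) || is.null(measured)) stop("cohort stage required")
    ana <- merge(cohort[, c("patient_id", "age", "bmi", "apache_iva",
                            "male", "ventilator", "lactate_cat"),
                        with = FALSE],
                 sim$truth[, c("patient_id", "death"), with = FALSE],
                 by = "patient_id")
    results <- list()
    for (comp in config$components) {
      e <- measured$exposures[measured$exposures$component == comp]
      d <- merge(ana, e[, c("patient_id", "lowest_sustained", "twa_below"),
                        with = FALSE], by = "patient_id")
      d <- d[!is.na(d$lowest_sustained)]
      res <- list(n = nrow(d), events = sum(d$death))
      if (nrow(d) >= config$n_bins && sum(d$death) >= 20 &&
          length(unique(d$lowest_sustained)) >= 20) {
        bins <- binned_moving_average(d$lowest_sustained, d$death,
                                      config$n_bins, config$ma_window)
        data.table::fwrite(bins, file.path(
          config$outdir, sprintf("curve_binned_%s.csv", comp)))
        sp <- fit_spline_logistic(d, "death",
                                  smooth_terms = c("lowest_sustained", "age",
                                                   "bmi", "apache_iva"),
                                  linear_terms = c("male", "ventilator",
                                                   "lactate_cat"),
                                  k = config$spline_k)
        grid <- seq(stats::quantile(d$lowest_sustained, 0.01),
                    stats::quantile(d$lowest_sustained, 0.99), length.out = 100)
        curve <- predict_probability_curve(sp, grid)
        data.table::fwrite(curve, file.path(
          config$outdir, sprintf("curve_spline_%s.csv", comp)))
        hf <- fit_hinge_logistic(d, "lowest_sustained", "death",
                                 covariates = c("age", "apache_iva"),
                                 nboot = config$nboot,
                                 boot_seed = config$sim$seed)
        hc <- predict_hinge_curve(hf, grid)
        data.table::fwrite(hc, file.path(
          config$outdir, sprintf("curve_hinge_%s.csv", comp)))
        cats <- COMPONENT_CATEGORIES[[comp]]
        groups <- lapply(cats$cutoffs, function(cut) d$lowest_sustained < cut)
        names(groups) <- names(cats$cutoffs)
        if (comp == "pp")
          groups <- c(list(`>=50` = d$lowest_sustained >= 50), groups)
        groups <- Filter(function(g) any(g) && sum(d$death[g]) > 0, groups)
        ort <- categorical_or(d, "death", cats$reference(d$lowest_sustained),
                              groups,
                              covariates = c("age", "bmi", "apache_iva",
                                             "lactate_cat"))
        data.table::fwrite(ort, file.path(
          config$outdir, sprintf("or_table_%s.csv", comp)))
        res <- c(res, list(
          change_point = hf$change_point,
          change_point_std = hf$change_point_std,
          slope = hf$slope, slope_std = hf$slope_std,
          hinge_ci = if (!is.null(hf$ci)) as.list(as.data.frame(t(hf$ci))),
          flags = hf$flags,
          spline_gcv = sp$gcv,
          spline_edf = as.list(sp$edf),
          exposure_mean = hf$exposure_mean, exposure_sd = hf$exposure_sd))
      } else {
        res$note <- "insufficient data for modelling"
      }
      results[[comp]] <- res
    }
    jsonlite::write_json(results, file.path(config$outdir, "model_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(components = paste(names(results), collapse = ","))
  })

  run_stage("report", function() {
    report_artifacts(config$outdir, config$components)
  })

  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  unlink(file.path(config$outdir, "INCOMPLETE"))
  invisible(manifest)
}

#' Render figures and a summary from pipeline artifacts
#'
#' Per component: the univariable binned moving-average curve overlaid with
#' the spline fit, the hinge-model curve on the standardized exposure
#' scale, and (when present) the categorical odds-ratio table; sections
#' with missing artifacts are skipped with a notice.
#'
#' @param outdir pipeline output directory.
#' @param components components to include.
#' @return list of rendered sections (invisibly inside [run_pipeline()]).
#' @export
report_artifacts <- function(outdir, components = c("map", "sbp", "dbp", "pp")) {
  sections <- character(0)
  skipped <- character(0)
  pdf_path <- file.path(outdir, "report.pdf")
  grDevices::pdf(pdf_path, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (comp in components) {
    f_bin <- file.path(outdir, sprintf("curve_binned_%s.csv", comp))
    f_spl <- file.path(outdir, sprintf("curve_spline_%s.csv", comp))
    f_hng <- file.path(outdir, sprintf("curve_hinge_%s.csv", comp))
    if (file.exists(f_bin) && file.exists(f_spl)) {
      bins <- data.table::fread(f_bin)
      spl <- data.table::fread(f_spl)
      p <- ggplot2::ggplot() +
        ggplot2::geom_point(data = bins,
                            ggplot2::aes(x = exposure_mid, y = moving_average),
                            alpha = 0.5, size = 0.8) +
        ggplot2::geom_ribbon(data = spl,
                             ggplot2::aes(x = grid, ymin = lo, ymax = hi),
                             alpha = 0.2) +
        ggplot2::geom_line(data = spl, ggplot2::aes(x = grid, y = fit)) +
        ggplot2::labs(x = sprintf("Lowest %s sustained 120 min (mmHg)",
                                  toupper(comp)),
                      y = "ICU mortality",
                      title = sprintf("%s: binned moving average and spline fit",
                                      toupper(comp))) +
        ggplot2::theme_minimal()
      print(p)
      sections <- c(sections, sprintf("risk_curve_%s", comp))
    } else skipped <- c(skipped, sprintf("risk_curve_%s", comp))
    if (file.exists(f_hng)) {
      hng <- data.table::fread(f_hng)
      p <- ggplot2::ggplot(hng, ggplot2::aes(x = grid_std, y = fit)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = sprintf("Standardized lowest %s", toupper(comp)),
                      y = "Predicted ICU mortality",
                      title = sprintf("%s: hinge model", toupper(comp))) +
        ggplot2::theme_minimal()
      print(p)
      sections <- c(sections, sprintf("hinge_curve_%s", comp))
    } else skipped <- c(skipped, sprintf("hinge_curve_%s", comp))
  }
  if (length(skipped))
    message("report: skipped sections with missing artifacts: ",
            paste(skipped, collapse = ", "))
  list(sections = paste(sections, collapse = ","),
       skipped = paste(skipped, collapse = ","))
}
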