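# Statistical estimators relating hypotension exposure to outcomes:
# binned moving-average risk curves, penalized thin-plate spline logistic
# regression with GCV-selected smoothness, hinge (change-point) threshold
# logistic regression via profile likelihood with bootstrap intervals,
# categorical odds-ratio tables, subgroup models, and generalized variance
# inflation factors.

#' Equal-count binned outcome proportions with a moving average
#'
#' Orders the cohort by exposure, splits it into `n_bins` equal-count bins
#' (any remainder spread one patient at a time over the first bins),
#' computes the outcome proportion per bin, and smooths with a centred
#' simple moving average of `window` bins (windows shrink symmetrically at
#' the edges).
#'
#' @param exposure numeric exposure values.
#' @param outcome 0/1 outcome flags.
#' @param n_bins number of bins, default 100.
#' @param window moving-average width in bins (odd), default 5.
#' @return data.table: bin, n, exposure_lo, exposure_hi, exposure_mid,
#'   proportion, moving_average.
#' @export
binned_moving_average <- function(exposure, outcome, n_bins = 100,
                                  window = 5) {
  n <- length(exposure)
  stopifnot(length(outcome) == n)
  if (n < n_bins)
    stop(sprintf("n = %d is below the number of bins (%d); use fewer bins",
                 n, n_bins), call. = FALSE)
  ord <- order(exposure)
  x <- exposure[ord]; y <- outcome[ord]
  base <- n %/% n_bins; rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin <- rep(seq_len(n_bins), times = sizes)
  prop <- as.numeric(tapply(y, bin, mean))
  half <- (window - 1L) %/% 2L
  ma <- vapply(seq_len(n_bins), function(i) {
    lo <- max(1L, i - half); hi <- min(n_bins, i + half)
    mean(prop[lo:hi])
  }, numeric(1))
  data.table::data.table(
    bin = seq_len(n_bins),
    n = sizes,
    exposure_lo = as.numeric(tapply(x, bin, min)),
    exposure_hi = as.numeric(tapply(x, bin, max)),
    exposure_mid = as.numeric(tapply(x, bin, stats::median)),
    proportion = prop,
    moving_average = ma)
}

#' Penalized thin-plate spline logistic regression with GCV
#'
#' Additive logistic model with low-rank thin-plate regression-spline
#' smooths of the listed continuous terms and parametric (linear/factor)
#' terms for the rest; smoothing parameters are chosen by generalized
#' cross-validation.  Fitting is delegated to [mgcv::gam()].
#'
#' @param data data.frame/data.table.
#' @param outcome name of the 0/1 outcome column.
#' @param smooth_terms character; columns modelled with `s(, bs = "tp")`.
#' @param linear_terms character; columns entering parametrically.
#' @param k basis dimension per smooth, default 10.
#' @return `bphinge_spline_fit`: list with the `gam` object, `gcv`,
#'   per-smooth `edf` and smoothing parameters `sp`, `coefficients`, and
#'   the observed exposure `range` of each smooth term.
#' @export
fit_spline_logistic <- function(data, outcome, smooth_terms,
                                linear_terms = character(), k = 10) {
  data <- as.data.frame(data)
  rhs <- c(sprintf("s(%s, bs = \"tp\", k = %d)", smooth_terms, k),
           linear_terms)
  fml <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- mgcv::gam(fml, family = stats::binomial(), data = data,
                   method = "GCV.Cp")
  if (!fit$converged)
    stop("penalized IRLS did not converge; outer iteration info: ",
         paste(utils::capture.output(fit$outer.info), collapse = " "),
         call. = FALSE)
  if (max(abs(stats::coef(fit))) > 20)
    warning("very large coefficients: possible separation", call. = FALSE)
  edf <- vapply(fit$smooth, function(sm) {
    sum(fit$edf[sm$first.para:sm$last.para])
  }, numeric(1))
  names(edf) <- vapply(fit$smooth, function(sm) sm$label, character(1))
  ranges <- lapply(smooth_terms, function(v) range(data[[v]], na.rm = TRUE))
  names(ranges) <- smooth_terms
  structure(list(gam = fit, gcv = as.numeric(fit$gcv.ubre), edf = edf,
                 sp = fit$sp, coefficients = stats::coef(fit),
                 outcome = outcome, smooth_terms = smooth_terms,
                 linear_terms = linear_terms, ranges = ranges,
                 data_means = vapply(
                   c(smooth_terms,
                     linear_terms[vapply(linear_terms, function(v)
                       is.numeric(data[[v]]), logical(1))]),
                   function(v) mean(data[[v]], na.rm = TRUE), numeric(1)),
                 factor_refs = {
                   fl <- linear_terms[vapply(linear_terms, function(v)
                     is.factor(data[[v]]) || is.character(data[[v]]) ||
                       is.logical(data[[v]]), logical(1))]
                   stats::setNames(lapply(fl, function(v) {
                     col <- data[[v]]
                     if (is.factor(col)) factor(levels(col)[1], levels(col))
                     else if (is.logical(col)) FALSE
                     else sort(unique(col))[1]
                   }), fl)
                 }),
            class = "bphinge_spline_fit")
}

#' Predicted probability curve from a spline fit
#'
#' Pointwise predicted outcome probability over an exposure grid, holding
#' the other continuous covariates at their means and categorical
#' covariates at their reference levels, with delta-method 95% confidence
#' bands on the link scale.  Refuses to extrapolate outside the observed
#' exposure range.
#'
#' @param fit a `bphinge_spline_fit`.
#' @param grid exposure values (within the observed range).
#' @param term which smooth term the grid varies; default the first.
#' @param level confidence level, default 0.95.
#' @return data.table: grid, fit, lo, hi (probabilities).
#' @export
predict_probability_curve <- function(fit, grid, term = fit$smooth_terms[1],
                                      level = 0.95) {
  rng <- fit$ranges[[term]]
  if (any(grid < rng[1] | grid > rng[2]))
    stop(sprintf("grid outside the observed range of %s [%.1f, %.1f]; refusing to extrapolate",
                 term, rng[1], rng[2]), call. = FALSE)
  nd <- data.frame(g = grid)
  names(nd) <- term
  for (v in setdiff(names(fit$data_means), term)) nd[[v]] <- fit$data_means[[v]]
  for (v in names(fit$factor_refs)) nd[[v]] <- fit$factor_refs[[v]]
  pr <- mgcv::predict.gam(fit$gam, newdata = nd, type = "link", se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.table::data.table(grid = grid,
                         fit = stats::plogis(pr$fit),
                         lo = stats::plogis(pr$fit - z * pr$se.fit),
                         hi = stats::plogis(pr$fit + z * pr$se.fit))
}

#' Standardize a numeric vector, keeping the transform
#'
#' @param x numeric, with `sd(x) > 0`.
#' @return `bphinge_standardizer`: list with `z`, `mean`, `sd`, and
#'   functions `to_z(x)` / `to_raw(z)` for converting change-points between
#'   scales.
#' @export
standardize <- function(x) {
  m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("sd is zero; cannot standardize", call. = FALSE)
  structure(list(z = (x - m) / s, mean = m, sd = s,
                 to_z = function(v) (v - m) / s,
                 to_raw = function(z) z * s + m),
            class = "bphinge_standardizer")
}

hinge_deficit <- function(x, cp) pmax(0, cp - x)

# One constrained fit at a fixed candidate change-point.
fit_at_candidate <- function(cp, x, y, Z) {
  X <- cbind(`(Intercept)` = 1, deficit = hinge_deficit(x, cp), Z)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 50)))
  list(loglik = -fit$deviance / 2, coef = fit$coefficients,
       converged = fit$converged)
}

#' Hinge (change-point) threshold logistic regression
#'
#' Models the outcome log-odds as flat in the exposure above an unknown
#' change-point `e` and linear below it:
#' `logit P(y=1) = alpha + beta_d * max(0, e - x) + gamma' z`, where
#' `beta_d >= 0` is the log-odds increase per mmHg of pressure deficit
#' below `e`.  The change-point is estimated by profile likelihood over a
#' grid of candidates (1 mmHg resolution between the 5th and 95th exposure
#' percentiles by default), refitting all other coefficients at each
#' candidate; likelihood ties break to the smallest candidate.  The
#' reported `slope` is the pre-threshold slope of the log-odds in the
#' exposure, `-beta_d` (expected <= 0); `slope_std` re-expresses it per
#' standard deviation of the exposure, and `change_point_std` is the
#' change-point on the standardized exposure scale.  Percentile bootstrap
#' confidence intervals (resampling patients) are computed for both the
#' change-point and the slope when `nboot > 0`.
#'
#' @param data data.frame/data.table.
#' @param exposure,outcome column names (exposure in mmHg; outcome 0/1).
#' @param covariates character vector of adjustment columns (factors
#'   allowed); may be empty.
#' @param grid candidate change-points; default integer mmHg between the
#'   5th and 95th percentiles.
#' @param nboot bootstrap replicates for the CIs (0 to skip), default 200.
#' @param level confidence level, default 0.95.
#' @param boot_seed integer seed for the bootstrap resampling.
#' @return `bphinge_hinge_fit`: `change_point`, `change_point_std`,
#'   `slope`, `slope_std`, `plateau_logit` (adjusted log-odds at the
#'   change-point, covariates held at their means), `coefficients`, `profile`
#'   (candidate vs log-likelihood), `ci` (when bootstrapped), `flags`
#'   (boundary / positive-slope warnings), `exposure_mean`, `exposure_sd`.
#' @export
fit_hinge_logistic <- function(data, exposure, outcome,
                               covariates = character(),
                               grid = NULL, nboot = 200, level = 0.95,
                               boot_seed = 1L) {
  data <- as.data.frame(data)
  x <- data[[exposure]]
  y <- data[[outcome]]
  if (length(unique(x)) < 20)
    stop("exposure needs >= 20 distinct values", call. = FALSE)
  if (sum(y) < 20) stop("needs >= 20 events", call. = FALSE)
  Z <- if (length(covariates)) {
    stats::model.matrix(stats::as.formula(
      paste("~", paste(covariates, collapse = " + "))), data)[, -1, drop = FALSE]
  } else NULL
  if (is.null(grid)) {
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    grid <- seq(ceiling(q[1]), floor(q[2]), by = 1)
  }
  grid <- sort(unique(grid))

  profile_fit <- function(x, y, Z, grid) {
    fits <- lapply(grid, fit_at_candidate, x = x, y = y, Z = Z)
    ll <- vapply(fits, `[[`, numeric(1), "loglik")
    best <- which(ll == max(ll))[1]        # ties -> smallest candidate
    list(cp = grid[best], fit = fits[[best]], ll = ll, best = best)
  }
  pf <- profile_fit(x, y, Z, grid)

  flags <- character(0)
  if (pf$best == 1L || pf$best == length(pf$ll)) {
    flags <- c(flags, "boundary")
    warning("profile maximum at the grid boundary; no interior change-point",
            call. = FALSE)
  }
  beta_d <- unname(pf$fit$coef["deficit"])
  if (beta_d < 0) {
    flags <- c(flags, "positive_pre_slope")
    warning("pre-threshold slope is positive (risk falls with deeper hypotension)",
            call. = FALSE)
  }
  # flat-profile check: does the hinge term improve on the no-deficit null
  # at the chi-square(1) level?  (The candidate search inflates the LR
  # slightly, so this is a screening flag, not a formal test.)
  null_fit <- suppressWarnings(stats::glm.fit(
    cbind(rep(1, length(y)), Z), y, family = stats::binomial(),
    control = list(maxit = 50)))
  if (2 * (max(pf$ll) - (-null_fit$deviance / 2)) < stats::qchisq(0.95, 1)) {
    flags <- c(flags, "flat_profile")
  }

  std <- standardize(x)
  ci <- NULL
  if (nboot > 0) {
    set.seed(as.integer(boot_seed) %% 2147483629L)
    n <- length(x)
    bs <- matrix(NA_real_, nboot, 2,
                 dimnames = list(NULL, c("change_point", "slope")))
    for (b in seq_len(nboot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Zb <- if (is.null(Z)) NULL else Z[idx, , drop = FALSE]
      pb <- profile_fit(x[idx], y[idx], Zb, grid)
      bs[b, ] <- c(pb$cp, -unname(pb$fit$coef["deficit"]))
    }
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- rbind(change_point = stats::quantile(bs[, 1], probs, names = FALSE),
                slope = stats::quantile(bs[, 2], probs, names = FALSE))
    colnames(ci) <- c("lo", "hi")
  }

  # plateau log-odds at the covariate means (the adjusted baseline risk)
  plateau <- unname(pf$fit$coef["(Intercept)"]) +
    (if (is.null(Z)) 0 else sum(colMeans(Z) * pf$fit$coef[-(1:2)]))

  structure(list(
    change_point = pf$cp,
    change_point_std = std$to_z(pf$cp),
    slope = -beta_d,
    slope_std = -beta_d * std$sd,
    plateau_logit = plateau,
    coefficients = pf$fit$coef,
    profile = data.table::data.table(candidate = grid, loglik = pf$ll),
    ci = ci, flags = flags,
    exposure_mean = std$mean, exposure_sd = std$sd,
    exposure = exposure, outcome = outcome, covariates = covariates
  ), class = "bphinge_hinge_fit")
}

#' @export
print.bphinge_hinge_fit <- function(x, ...) {
  cat(sprintf("Hinge threshold logistic regression (%s ~ %s)\n",
              x$outcome, x$exposure))
  cat(sprintf("  change-point: %.0f mmHg (standardized %.2f)\n",
              x$change_point, x$change_point_std))
  cat(sprintf("  pre-threshold slope: %.4f per mmHg (%.3f per SD)\n",
              x$slope, x$slope_std))
  cat(sprintf("  plateau log-odds (at covariate means): %.3f\n",
              x$plateau_logit))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI change-point: [%.1f, %.1f]; slope: [%.4f, %.4f]\n",
                x$ci["change_point", 1], x$ci["change_point", 2],
                x$ci["slope", 1], x$ci["slope", 2]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Predicted probability curve from a hinge fit
#'
#' Evaluates the fitted hinge model over an exposure grid with covariates
#' held at zero contribution (i.e. the adjusted baseline profile).
#'
#' @param fit a `bphinge_hinge_fit`.
#' @param grid exposure values (mmHg).
#' @param standardized if `TRUE`, also return the grid on the standardized
#'   exposure scale.
#' @return data.table: grid, (grid_std), fit.
#' @export
predict_hinge_curve <- function(fit, grid, standardized = TRUE) {
  lp <- fit$plateau_logit - fit$slope * hinge_deficit(grid, fit$change_point)
  out <- data.table::data.table(grid = grid, fit = stats::plogis(lp))
  if (standardized) {
    data.table::set(out, j = "grid_std",
                    value = (grid - fit$exposure_mean) / fit$exposure_sd)
  }
  out[]
}

#' Adjusted odds-ratio table for categorical exposure levels
#'
#' For each named comparison group, fits a multivariable logistic
#' regression of the outcome on the group indicator (comparison vs the
#' fixed reference group; patients in neither are dropped) plus the stated
#' covariates.  Groups may overlap, mirroring cumulative `< cutoff`
#' categories contrasted against one normotensive reference.
#'
#' @param data data.frame/data.table.
#' @param outcome 0/1 outcome column name.
#' @param reference logical vector marking the reference group.
#' @param groups named list of logical vectors marking comparison groups.
#' @param covariates character vector of adjustment columns.
#' @param level confidence level, default 0.95.
#' @return data.table: label, n, events, pct, or, lo, hi, p, note; first
#'   row is the reference (OR 1).
#' @export
categorical_or <- function(data, outcome, reference, groups,
                           covariates = character(), level = 0.95) {
  data <- as.data.frame(data)
  y <- data[[outcome]]
  if (!any(reference)) stop("empty reference group", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ref_row <- data.table::data.table(
    label = "reference", n = sum(reference),
    events = sum(y[reference]),
    pct = crude_pct(sum(y[reference]), sum(reference)),
    or = 1, lo = NA_real_, hi = NA_real_, p = NA_real_, note = "")
  rows <- lapply(names(groups), function(lab) {
    g <- groups[[lab]]
    if (!any(g)) stop(sprintf("empty comparison group '%s'", lab),
                      call. = FALSE)
    keep <- reference | g
    d <- data[keep, , drop = FALSE]
    d$.grp <- as.integer(g[keep])
    row <- data.table::data.table(
      label = lab, n = sum(g), events = sum(y[g]),
      pct = crude_pct(sum(y[g]), sum(g)),
      or = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_, note = "")
    if (identical(unname(g), unname(reference))) {
      row$or <- 1
      row$note <- "identical to reference"
      return(row)
    }
    if (sum(y[g]) == 0 || sum(y[reference]) == 0) {
      row$note <- "zero events; OR undefined"
      return(row)
    }
    fml <- stats::as.formula(paste(
      outcome, "~ .grp",
      if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
      else ""))
    fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                       data = d))
    est <- summary(fit)$coefficients[".grp", ]
    row$or <- exp(est["Estimate"])
    row$lo <- exp(est["Estimate"] - z * est["Std. Error"])
    row$hi <- exp(est["Estimate"] + z * est["Std. Error"])
    row$p <- est["Pr(>|z|)"]
    row
  })
  data.table::rbindlist(c(list(ref_row), rows))
}

#' Subgroup analysis with the grouping variable dropped from covariates
#'
#' Fits the exposure-effect logistic model separately in each level of the
#' grouping variable; the grouping variable itself never enters the design
#' matrix.  Subgroups with no events are reported without an estimate.
#'
#' @param data data.frame/data.table.
#' @param exposure,outcome column names.
#' @param by name of the grouping column (factor or character).
#' @param covariates adjustment columns; any equal to `by` are removed.
#' @param level confidence level, default 0.95.
#' @return data.table: subgroup, n, events, or (per exposure unit), lo, hi,
#'   p, note.
#' @export
subgroup_analysis <- function(data, exposure, outcome, by,
                              covariates = character(), level = 0.95) {
  data <- as.data.frame(data)
  covariates <- setdiff(covariates, by)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lv <- if (is.factor(data[[by]])) levels(droplevels(data[[by]])) else
    sort(unique(data[[by]]))
  rows <- lapply(lv, function(g) {
    d <- data[data[[by]] == g, , drop = FALSE]
    row <- data.table::data.table(
      subgroup = as.character(g), n = nrow(d),
      events = sum(d[[outcome]]),
      or = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_, note = "")
    if (nrow(d) == 0L) { row$note <- "empty subgroup"; return(row) }
    if (sum(d[[outcome]]) == 0) { row$note <- "no events"; return(row) }
    fml <- stats::as.formula(paste(
      outcome, "~", exposure,
      if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
      else ""))
    fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                       data = d))
    stopifnot(!(by %in% colnames(attr(fit$terms, "factors"))))
    est <- summary(fit)$coefficients[exposure, ]
    row$or <- exp(est["Estimate"])
    row$lo <- exp(est["Estimate"] - z * est["Std. Error"])
    row$hi <- exp(est["Estimate"] + z * est["Std. Error"])
    row$p <- est["Pr(>|z|)"]
    row
  })
  data.table::rbindlist(rows)
}

#' Generalized variance inflation factors
#'
#' Determinant-ratio formulation on the correlation matrix of the design
#' columns (intercept excluded): for the columns of a term,
#' `GVIF = det(R_term) det(R_rest) / det(R)`; `GVIF^(1/(2 df))` makes
#' terms of different dimension comparable.
#'
#' @param design numeric design matrix without an intercept column.
#' @param terms character vector, one entry per design column, naming the
#'   model term each column belongs to.
#' @return data.table: term, df, gvif, gvif_adj
#'   (`gvif^(1/(2 df))`).
#' @export
gvif <- function(design, terms = colnames(design)) {
  design <- as.matrix(design)
  stopifnot(length(terms) == ncol(design))
  qrx <- qr(cbind(1, design))
  if (qrx$rank < ncol(design) + 1L) {
    aliased <- colnames(design)[setdiff(seq_len(ncol(design)),
                                        qrx$pivot[seq_len(qrx$rank)] - 1L)]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(design)
  detR <- det(R)
  dets <- function(idx) if (length(idx) == 0L) 1 else det(R[idx, idx, drop = FALSE])
  out <- lapply(unique(terms), function(tm) {
    i <- which(terms == tm)
    g <- dets(i) * dets(setdiff(seq_len(ncol(design)), i)) / detR
    data.table::data.table(term = tm, df = length(i), gvif = g,
                           gvif_adj = g^(1 / (2 * length(i))))
  })
  data.table::rbindlist(out)
}
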