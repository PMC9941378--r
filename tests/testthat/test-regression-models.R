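test_that("equal-count binning and the moving average behave as defined", {
  set.seed(1)
  x <- runif(10000)
  b <- binned_moving_average(x, rep(0L, 10000))
  expect_true(all(b$n == 100))
  expect_true(all(b$proportion == 0) && all(b$moving_average == 0))
  expect_equal(sum(b$n), 10000)

  # remainder spread over the first bins
  b2 <- binned_moving_average(runif(1030), rbinom(1030, 1, 0.2))
  expect_equal(b2$n, c(rep(11L, 30), rep(10L, 70)))
  expect_equal(sum(b2$n), 1030)

  expect_error(binned_moving_average(runif(50), rbinom(50, 1, 0.5)),
               "fewer bins")
})

test_that("a step-function risk shows up as a step in the moving average", {
  set.seed(2)
  x <- runif(5000)
  y <- as.integer(x < median(x))
  b <- binned_moving_average(x, y)
  expect_true(all(b$moving_average[1:47] == 1))
  expect_true(all(b$moving_average[53:100] == 0))
})

test_that("standardization stores an exact inverse transform", {
  set.seed(3)
  x <- rnorm(500, 62, 10)
  st <- standardize(x)
  expect_equal(st$to_z(st$mean), 0)
  expect_equal((69 - st$mean) / st$sd, st$to_z(69))
  expect_equal(st$to_raw(st$to_z(69)), 69)
  # the population-scale arithmetic: mean 62, SD 10 puts 69 at z = 0.7
  expect_equal((69 - 62) / 10, 0.7)
  expect_error(standardize(rep(5, 10)), "sd is zero")
})

test_that("hinge profile over a small grid equals an independent brute-force refit", {
  set.seed(11)
  n <- 400
  x <- rnorm(n, 62, 10)
  age <- rnorm(n, 64, 15)
  p <- plogis(-1.2 + 0.1 * pmax(0, 66 - x) + 0.01 * (age - 64))
  y <- rbinom(n, 1, p)
  d <- data.frame(exposure = x, outcome = y, age = age)
  grid <- c(55, 60, 65, 70, 75)
  fit <- fit_hinge_logistic(d, "exposure", "outcome", "age",
                            grid = grid, nboot = 0)
  # independent oracle: formula-interface glm at each candidate
  oracle_ll <- vapply(grid, function(e) {
    as.numeric(logLik(glm(outcome ~ I(pmax(0, e - exposure)) + age,
                          family = binomial(), data = d)))
  }, numeric(1))
  expect_equal(fit$change_point, grid[which.max(oracle_ll)])
  expect_equal(fit$profile$loglik, oracle_ll, tolerance = 1e-6)
  # refitting at the reported change-point reproduces the coefficients
  refit <- glm(outcome ~ I(pmax(0, fit$change_point - exposure)) + age,
               family = binomial(), data = d)
  expect_equal(unname(fit$coefficients),
               unname(coef(refit)[c(1, 2, 3)]), tolerance = 1e-6)
  expect_equal(fit$slope, -unname(coef(refit)[2]), tolerance = 1e-6)
  # standardized-scale reporting is consistent
  expect_equal(fit$slope_std, fit$slope * sd(x))
  expect_equal(fit$change_point_std, (fit$change_point - mean(x)) / sd(x))
})

test_that("a null exposure effect is flagged as a flat profile", {
  set.seed(13)
  n <- 2000
  d <- data.frame(exposure = rnorm(n, 62, 10),
                  outcome = rbinom(n, 1, 0.1))
  fit <- suppressWarnings(fit_hinge_logistic(d, "exposure", "outcome",
                                             nboot = 0))
  expect_true("flat_profile" %in% fit$flags)
})

test_that("hinge fits are deterministic given data and bootstrap seed", {
  d <- simulate_exposure_cohort(1500, seed = 5)
  f1 <- suppressWarnings(fit_hinge_logistic(d, "exposure", "outcome",
                                            c("age", "apache_iva"),
                                            nboot = 15, boot_seed = 9))
  f2 <- suppressWarnings(fit_hinge_logistic(d, "exposure", "outcome",
                                            c("age", "apache_iva"),
                                            nboot = 15, boot_seed = 9))
  expect_identical(f1$change_point, f2$change_point)
  expect_identical(f1$ci, f2$ci)
  expect_equal(nrow(f1$profile), length(unique(f1$profile$candidate)))
  # fitted log-odds are constant above the change-point
  curve <- predict_hinge_curve(f1, seq(f1$change_point, 100, by = 5))
  expect_true(all(abs(diff(qlogis(curve$fit))) < 1e-12))
})

test_that("spline fit shrinks null effects and refuses extrapolation", {
  n <- 4000
  # GCV occasionally leaves wiggle in a null smooth on a single draw, so
  # the shrinkage property is asserted on the median across replicates
  edf_null <- vapply(1:5, function(s) {
    set.seed(s)
    x1 <- rnorm(n, 62, 10)
    x2 <- rnorm(n, 50, 5)            # no true effect
    y <- rbinom(n, 1, plogis(-2 - 0.06 * (x1 - 62)))
    f <- fit_spline_logistic(data.frame(y = y, x1 = x1, x2 = x2), "y",
                             smooth_terms = c("x1", "x2"))
    f$edf[["s(x2)"]]
  }, numeric(1))
  expect_lt(median(edf_null), 1.5)

  set.seed(18)
  x1 <- rnorm(n, 62, 10)
  x2 <- rnorm(n, 50, 5)
  y <- rbinom(n, 1, plogis(-2 - 0.06 * (x1 - 62)))
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  fit <- fit_spline_logistic(d, "y", smooth_terms = c("x1", "x2"))
  expect_true(all(fit$sp > 0))
  grid <- quantile(x1, seq(0.1, 0.9, 0.1), names = FALSE)
  c1 <- predict_probability_curve(fit, grid, term = "x1")
  expect_true(all(c1$fit > 0 & c1$fit < 1))
  expect_true(all(c1$lo <= c1$fit & c1$fit <= c1$hi))
  # determinism: identical profile, identical curve
  c2 <- predict_probability_curve(fit, grid, term = "x1")
  expect_identical(c1, c2)
  expect_error(predict_probability_curve(fit, max(x1) + 5, term = "x1"),
               "extrapolate")
})

test_that("categorical odds-ratio tables are internally consistent", {
  d <- simulate_exposure_cohort(8000, seed = 19)
  ref <- d$exposure >= 75
  groups <- list(`<75` = d$exposure < 75, `<65` = d$exposure < 65)
  tab <- categorical_or(d, "outcome", ref, groups,
                        covariates = c("age", "apache_iva"))
  expect_equal(tab$or[1], 1)
  expect_equal(tab$label[1], "reference")
  # crude percentages recompute exactly from the table's own columns
  expect_equal(tab$pct, round(100 * tab$events / tab$n, 1))
  # deeper hypotension group carries the larger adjusted OR
  expect_gt(tab$or[3], tab$or[2])
  expect_gt(tab$or[2], 1)
  expect_true(all(tab$lo[-1] <= tab$or[-1] & tab$or[-1] <= tab$hi[-1]))
  # comparison group identical to the reference -> OR 1 by convention
  tab2 <- categorical_or(d, "outcome", ref, list(same = ref))
  expect_equal(tab2$or[2], 1)
  expect_match(tab2$note[2], "identical")
  expect_error(categorical_or(d, "outcome", rep(FALSE, nrow(d)), groups),
               "reference")
})

test_that("crude count arithmetic matches printed-table conventions", {
  expect_equal(crude_pct(473, 1611), 29.4)
  expect_equal(crude_or(20, 100, 10, 100), (20 / 80) / (10 / 90))
})

test_that("subgroup models drop the grouping variable and flag empty strata", {
  d <- simulate_exposure_cohort(6000, seed = 23)
  d$age_band <- cut(d$age, c(0, 45, 65, Inf), labels = c("<45", "45-64", ">65"))
  tab <- subgroup_analysis(d, "exposure", "outcome", by = "age_band",
                           covariates = c("age_band", "apache_iva"))
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$events > 0))
  # homogeneous true effect: per-subgroup CIs mutually overlap
  expect_true(max(tab$lo) <= min(tab$hi))
  # zero-event subgroup is flagged without an estimate
  d2 <- d[1:200, ]
  d2$outcome[d2$age_band == "<45"] <- 0L
  tab2 <- subgroup_analysis(d2, "exposure", "outcome", by = "age_band",
                            covariates = "apache_iva")
  expect_equal(tab2$note[tab2$subgroup == "<45"], "no events")
  expect_true(is.na(tab2$or[tab2$subgroup == "<45"]))
})

test_that("generalized VIF matches closed forms and the car implementation", {
  set.seed(29)
  n <- 2000
  # orthogonal predictors -> all GVIF 1
  X <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  colnames(X) <- c("a", "b", "c")
  g <- gvif(X)
  expect_equal(g$gvif, rep(1, 3), tolerance = 1e-5)
  # two correlated predictors: VIF = 1 / (1 - r^2)
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  X2 <- cbind(x1 = x1, x2 = x2)
  r2 <- cor(x1, x2)^2
  g2 <- gvif(X2)
  expect_equal(g2$gvif, rep(1 / (1 - r2), 2), tolerance = 1e-8)
  expect_equal(1 / (1 - 0.81), 5.263, tolerance = 0.001)
  # duplicated column -> rank-deficiency error naming the column
  X3 <- cbind(x1 = x1, x2 = x2, x1_copy = x1)
  expect_error(gvif(X3), "rank deficient")

  # cross-check against car::vif on a model with a factor term
  d <- data.frame(y = rnorm(n), x1 = x1, x2 = x2,
                  f = factor(sample(letters[1:3], n, TRUE)))
  fit <- lm(y ~ x1 + x2 + f, data = d)
  ours <- gvif(model.matrix(fit)[, -1],
               terms = c("x1", "x2", "f", "f"))
  theirs <- car::vif(fit)
  expect_equal(ours$gvif, unname(theirs[, "GVIF"]), tolerance = 1e-6)
  expect_equal(ours$gvif_adj, unname(theirs[, 3]), tolerance = 1e-6)
})
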