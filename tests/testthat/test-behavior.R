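test_that("activity standardization controls for area and duration", {
  expect_equal(standardize_activity(0, 10, 45), 0)
  expect_equal(standardize_activity(7, 10, 45), 7 / 10 * 60 / 45)
  expect_equal(standardize_activity(3, 2, 60), 1.5)
  expect_error(standardize_activity(3, 0, 60), "positive")
  # invariant to splitting a sample into equal-density sub-samples
  whole <- standardize_activity(12, 6, 45)
  halves <- standardize_activity(c(6, 6), c(3, 3), 45)
  expect_equal(halves, rep(whole, 2))
})

test_that("activity trend fitting recovers exact and null relationships", {
  # perfectly linear sqrt(activity): r^2 = 1
  d <- tibble::tibble(
    current_speed = seq(0.1, 1.5, length.out = 10),
    activity = (3 - 1.5 * seq(0.1, 1.5, length.out = 10))^2
  )
  g <- suppressWarnings(glance(fit_activity_trend(d))) # perfect fit warns
  expect_equal(g$r_squared, 1)
  expect_lt(g$slope, 0)
  # constant predictor is flagged, not an error
  dc <- tibble::tibble(current_speed = rep(1, 5), activity = runif(5))
  expect_true(glance(fit_activity_trend(dc))$degenerate)
  # spearman option
  gs <- suppressWarnings(glance(fit_activity_trend(d, method = "spearman")))
  expect_equal(gs$rho, -1)
})

test_that("declining activity is detected at the study's effect size", {
  cfg <- field_sim_config()
  set.seed(202)
  slopes <- replicate(40, {
    fs <- simulate_field_study(cfg)
    glance(fit_activity_trend(fs$samples))$slope
  })
  expect_gt(mean(slopes < 0), 0.95)
})

test_that("null activity data give nominal slope coverage", {
  cfg <- field_sim_config(activity_decay = 0, baseline_activity = 5)
  set.seed(303)
  covered <- replicate(60, {
    fs <- simulate_field_study(cfg)
    g <- glance(fit_activity_trend(fs$samples))
    g$slope_lo <= 0 && 0 <= g$slope_hi
  })
  # 95% CI: with 60 replicates allow binomial fluctuation around 0.95
  expect_gte(mean(covered), 0.85)
})

test_that("logistic threshold fit recovers known coefficients", {
  set.seed(99)
  d <- simulate_direction_logit(500, beta0 = -3, beta1 = 4)
  fit <- fit_logistic_threshold(d, "direction")
  td <- tidy(fit)
  expect_lt(abs(td$estimate[1] - (-3)), 3 * td$std_error[1])
  expect_lt(abs(td$estimate[2] - 4), 3 * td$std_error[2])
  expect_false(fit$separated)
  expect_gt(fit$auc, 0.5)
  expect_lte(fit$auc, 1)
  g <- glance(fit)
  expect_equal(g$n, 500)
  expect_gt(g$chi2, 0)
})

test_that("validity rule refuses sparse outcome levels", {
  set.seed(1)
  d <- simulate_direction_logit(200, beta0 = -20, beta1 = 2) # all counter
  expect_error(fit_logistic_threshold(d, "direction"), "Validity rule")
  # under the threshold in one level only
  d2 <- tibble::tibble(
    current_speed = runif(100, 0.5, 1.5),
    direction = c(rep("along", 80), rep("counter", 20))
  )
  expect_error(fit_logistic_threshold(d2, "direction"), "counter = 20")
})

test_that("perfectly separated data are flagged, not reported as a fit", {
  d <- tibble::tibble(
    current_speed = c(runif(40, 0.5, 0.74), runif(40, 0.76, 1.5)),
    direction = c(rep("counter", 40), rep("along", 40))
  )
  fit <- fit_logistic_threshold(d, "direction")
  expect_true(fit$separated)
  expect_true(is.na(fit$breaking_point))
  expect_warning(breaking_point(fit), "separated")
})

test_that("transverse swimmers are excluded from the direction logit", {
  set.seed(17)
  d <- simulate_direction_logit(400, beta0 = -2.6, beta1 = 4)
  d_extra <- dplyr::bind_rows(
    d,
    tibble::tibble(
      current_speed = runif(200, 0.5, 1.5),
      direction = "transverse"
    )
  )
  f1 <- fit_logistic_threshold(d, "direction")
  f2 <- fit_logistic_threshold(d_extra, "direction")
  expect_equal(f1$n, f2$n)
  expect_equal(f1$beta1, f2$beta1)
})

test_that("breaking point is -beta0/beta1 and scale-invariant", {
  expect_equal(breaking_point(0, 4), 0)
  expect_equal(breaking_point(-3, 4), 0.75)
  expect_equal(breaking_point(-6, 8), 0.75)
  expect_warning(bp <- breaking_point(1, 0), "zero")
  expect_true(is.na(bp))
})

test_that("breaking-point bias shrinks as the sample grows", {
  true_bp <- 0.65
  err <- vapply(c(100, 2000), function(n) {
    set.seed(1000 + n)
    est <- replicate(30, {
      d <- simulate_direction_logit(n, beta0 = -true_bp * 5, beta1 = 5)
      f <- fit_logistic_threshold(d, "direction", min_per_level = 10)
      f$breaking_point
    })
    abs(stats::median(est, na.rm = TRUE) - true_bp)
  }, numeric(1))
  expect_lt(err[2], err[1] + 0.02)
  expect_lt(err[2], 0.03)
})

test_that("depth outcome uses the pelagic level as the event", {
  set.seed(55)
  n <- 2000
  cur <- runif(n, 0.5, 1.5)
  p <- stats::plogis(-2.88 + 4 * cur)
  d <- tibble::tibble(
    current_speed = cur,
    depth = ifelse(runif(n) < p, "pelagic", "bottom")
  )
  fit <- fit_logistic_threshold(d, "depth")
  expect_equal(fit$event, "pelagic")
  expect_gt(fit$beta1, 0)
  expect_lt(abs(fit$breaking_point - 0.72), 0.1)
})
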