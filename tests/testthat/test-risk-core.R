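test_that("turbine mortality combines components through the fault tree", {
  # any zero exposure component kills the top event
  rc0 <- risk_components(p_p = 0, p_o = 1, p_a = 1, p_z = 1, p_b = 1, p_e = 1, p_d = 1)
  expect_equal(turbine_mortality(rc0), 0)

  rc <- risk_components(
    p_p = 1, p_o = 1, p_a = 1, p_z = 1,
    p_s = 0.1, p_b = 0.5, p_e = 0.5, p_d = 0.5
  )
  expect_equal(turbine_mortality(rc, exact = TRUE), 0.2125)
  expect_equal(turbine_mortality(rc, exact = FALSE), 0.225)

  # operating night setting with field-data joint exposure factor
  night <- risk_components(
    p_op = 2.22e-3, p_a = 0.90, p_z = 0.65,
    p_s = 0, p_b = 0.03, p_e = 0.75, p_d = 0.75
  )
  expect_equal(signif(turbine_mortality(night), 3), 2.19e-5)
})

test_that("joint exposure factor takes precedence over separate p_p * p_o", {
  with_joint <- risk_components(
    p_p = 0.5, p_o = 0.5, p_op = 0.1,
    p_a = 1, p_z = 1, p_b = 1, p_e = 1, p_d = 1
  )
  expect_equal(turbine_mortality(with_joint), 0.1)
})

test_that("approximation exceeds the exact OR form by exactly the cross term", {
  set.seed(11)
  for (i in 1:40) {
    p <- runif(8)
    rc <- risk_components(
      p_p = p[1], p_o = p[2], p_a = p[3], p_z = p[4],
      p_s = p[5], p_b = p[6], p_e = p[7], p_d = p[8]
    )
    gap <- turbine_mortality(rc, exact = FALSE) - turbine_mortality(rc, exact = TRUE)
    expect_equal(gap, prod(p))
    expect_gte(gap, 0)
  }
})

test_that("turbine mortality is monotone non-decreasing in every component", {
  set.seed(13)
  nms <- c("p_p", "p_o", "p_a", "p_z", "p_s", "p_b", "p_e", "p_d")
  for (i in 1:30) {
    base <- as.list(stats::setNames(runif(8), nms))
    p0 <- turbine_mortality(do.call(risk_components, base))
    for (nm in nms) {
      up <- base
      up[[nm]] <- min(1, up[[nm]] + runif(1) * (1 - up[[nm]]))
      expect_gte(turbine_mortality(do.call(risk_components, up)), p0)
    }
  }
})

test_that("expected mortalities scale the top event by population size", {
  expect_equal(expected_mortalities(0, 10000), 0)
  expect_equal(expected_mortalities(1.83e-5, 10000), 0.183)
  expect_equal(expected_mortalities(0.5, 3), 1.5)
  expect_error(expected_mortalities(0.5, -1), "non-negative")
})

test_that("yearly total is the hours-weighted sum of hourly losses", {
  expect_equal(yearly_total(c(0, 0, 0), c(100, 200, 300)), 0)
  expect_equal(yearly_total(c(0.1, 0.2), c(10, 5)), 2.0)
  expect_error(yearly_total(c(0.1), c(-1)), "non-negative")
  # linearity in both arguments
  set.seed(3)
  h <- runif(5, 0, 2000)
  v <- runif(5)
  expect_equal(yearly_total(2 * v, h), 2 * yearly_total(v, h))
  expect_equal(yearly_total(v, 2 * h), 2 * yearly_total(v, h))
  w <- runif(5)
  expect_equal(
    yearly_total(v + w, h),
    yearly_total(v, h) + yearly_total(w, h)
  )
})

test_that("population projection steps the budget and floors at zero", {
  s0 <- population_state(n_tot = 100)
  expect_equal(project_population(s0, 1)$n_tot, 100)

  balanced <- population_state(100,
    births = 10, deaths = 5,
    turbine_mortality = 5
  )
  expect_equal(project_population(balanced, 1)$n_tot, 100)

  crash <- population_state(3, deaths = 10)
  expect_equal(project_population(crash, 1)$n_tot, 0)

  # rates unchanged by projection
  s1 <- project_population(balanced, 2)
  expect_equal(s1$births, 10)
  expect_equal(s1$turbine_mortality, 5)
})
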