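test_that("reverse escape rule reproduces hand-evaluated cases", {
  # already safe at entry
  expect_false(reverse_fails(x_r = 0, x_d = 5, v_c = 3, v_b = 2, t_e = 10))
  # drifting fish: pushed through after 4.21 s but needs 5.92 s
  expect_true(reverse_fails(x_r = 5, x_d = 5, v_c = 3, v_b = 2, t_e = 10, alpha = 25))
  # holding fish (v_b cos(alpha) >= v_c): only endurance matters; needs 2.96 s > 1 s
  expect_true(reverse_fails(x_r = 5, x_d = 5, v_c = 2, v_b = 4, t_e = 1, alpha = 25))
  expect_false(reverse_fails(x_r = 5, x_d = 5, v_c = 2, v_b = 4, t_e = 10, alpha = 25))
  # no transverse speed at all
  expect_true(reverse_fails(x_r = 1, x_d = 5, v_c = 1, v_b = 0, t_e = 100))
})

test_that("diverge escape rule reproduces hand-evaluated cases", {
  expect_false(diverge_fails(x_r = 0, x_d = 0, v_c = 2, v_b = 0))
  expect_false(diverge_fails(x_r = 5, x_d = 10, v_c = 2, v_b = 2)) # 5 s >= 2.5 s
  expect_true(diverge_fails(x_r = 10, x_d = 5, v_c = 3, v_b = 1.5)) # 1.67 < 6.67
  expect_true(diverge_fails(x_r = 1, x_d = 10, v_c = 2, v_b = 0))
})

test_that("escape rules agree with a small-dt kinematic simulation", {
  set.seed(77)
  n <- 1000
  x_r <- runif(n, 0, 20)
  x_d <- runif(n, 0.5, 15)
  v_c <- runif(n, 0.5, 3.5)
  v_b <- runif(n, 0.1, 5)
  t_e <- runif(n, 1, 40)

  for (strategy in c("reverse", "diverge")) {
    rule <- if (strategy == "reverse") {
      reverse_fails(x_r, x_d, v_c, v_b, t_e, alpha = 25)
    } else {
      diverge_fails(x_r, x_d, v_c, v_b)
    }
    bf1 <- brute_force_fails(strategy, x_r, x_d, v_c, v_b, t_e, alpha = 25, dt = 0.002)
    bf2 <- brute_force_fails(strategy, x_r, x_d, v_c, v_b, t_e, alpha = 25, dt = 0.001)
    stable <- bf1 == bf2 # drop knife-edge cases unresolved at this dt
    expect_gt(mean(stable), 0.98)
    expect_equal(rule[stable], bf1[stable])
  }
})

test_that("disc entry sampling has the right support and mean", {
  # entry at the centre of a 20 m rotor: full radius to either edge
  centre <- sample_entry_path(20, 1, u = matrix(c(0, 0.25), 1))
  expect_equal(centre, 10)
  # entry on the rim
  rim <- sample_entry_path(20, 1, u = matrix(c(1, 0), 1))
  expect_equal(rim, 0)
  set.seed(20)
  x <- sample_entry_path(20, 1e5, method = "disc")
  expect_true(all(x >= 0 & x <= 10))
  expect_equal(mean(x), disc_mean_escape_numeric(10), tolerance = 0.01)
  # uniform option spans the full diameter
  set.seed(21)
  xu <- sample_entry_path(20, 1e5, method = "uniform")
  expect_true(all(xu >= 0 & xu <= 20))
  expect_equal(mean(xu), 10, tolerance = 0.1)
})

test_that("lowlight scales the detection distance", {
  expect_equal(realized_detection(10, "daylight"), 10)
  expect_equal(realized_detection(10, "lowlight"), 1)
  expect_equal(realized_detection(10, "lowlight", lowlight_factor = 1), 10)
})

test_that("Monte Carlo avoidance matches closed forms and is seed-stable", {
  # degenerate: every draw fails
  hopeless <- list(
    v_b = trait_dist("point", value = 0.01),
    x_d_day = trait_dist("point", value = 0.01)
  )
  expect_equal(
    monte_carlo_pa(hopeless, 20, 3,
      strategy = "diverge", n_runs = 1000, seed = 1
    )$p_a,
    1
  )
  # closed form: x_r ~ U[0, 20], fail iff x_r > x_d v_b / v_c = 5
  dists <- list(
    v_b = trait_dist("point", value = 1),
    x_d_day = trait_dist("point", value = 10)
  )
  est <- monte_carlo_pa(dists, 20, 2,
    strategy = "diverge", entry = "uniform",
    n_runs = 1e5, seed = 42
  )
  expect_lt(abs(est$p_a - 0.75), 3 * est$se)
  # bit-identical under a fixed seed
  est2 <- monte_carlo_pa(dists, 20, 2,
    strategy = "diverge", entry = "uniform",
    n_runs = 1e5, seed = 42
  )
  expect_identical(est$p_a, est2$p_a)
  # configuration errors
  expect_error(monte_carlo_pa(list(), 20, 2), "at least")
  expect_error(
    monte_carlo_pa(dists, 20, 2, strategy = "reverse"),
    "t_e"
  )
})

test_that("avoidance failure responds monotonically to drivers (paired seeds)", {
  for (strategy in c("reverse", "diverge")) {
    for (taxon in c("trevally", "sergeant")) {
      dists <- default_traits(taxon)
      pa <- function(...) {
        monte_carlo_pa(dists,
          strategy = strategy, n_runs = 1e4, seed = 500, ...
        )$p_a
      }
      base <- pa(rotor_diameter = 5, v_c = 2, light = "daylight")
      expect_gte(pa(rotor_diameter = 20, v_c = 2, light = "daylight"), base)
      expect_gte(pa(rotor_diameter = 5, v_c = 3, light = "daylight"), base)
      expect_gte(pa(rotor_diameter = 5, v_c = 2, light = "lowlight"), base)
    }
    # slower taxon fails at least as often (same seed, same scenario)
    p_fast <- monte_carlo_pa(default_traits("trevally"), 20, 2,
      strategy = strategy, n_runs = 1e4, seed = 500
    )$p_a
    p_slow <- monte_carlo_pa(default_traits("sergeant"), 20, 2,
      strategy = strategy, n_runs = 1e4, seed = 500
    )$p_a
    expect_gte(p_slow, p_fast)
  }
})

test_that("tidy() summarises a Monte Carlo estimate", {
  dists <- list(
    v_b = trait_dist("point", value = 1),
    x_d_day = trait_dist("point", value = 10)
  )
  td <- tidy(monte_carlo_pa(dists, 20, 2, strategy = "diverge", n_runs = 100, seed = 1))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("p_a", "se", "n_runs", "strategy", "light", "rotor_diameter", "v_c"))
})
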