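# Independent oracles used across the suite. These re-derive expected
# behavior by routes that do not share code with the package: explicit
# time-stepping of the escape kinematics, and numerical integration of
# the disc-entry geometry.

# Brute-force kinematic simulation of both escape strategies. The fish
# state (transverse progress, downstream drift, elapsed time) is stepped
# with a small dt; all instances are advanced together until resolved.
# Returns a logical vector: TRUE = the avoidance attempt failed.
brute_force_fails <- function(strategy, x_r, x_d, v_c, v_b,
                              t_e = Inf, alpha = 25, dt = 0.002,
                              t_max = 200) {
  n <- length(x_r)
  x_d <- rep_len(x_d, n)
  v_c <- rep_len(v_c, n)
  v_b <- rep_len(v_b, n)
  t_e <- rep_len(t_e, n)
  alpha <- rep_len(alpha, n)
  if (strategy == "reverse") {
    v_trans <- v_b * sin(alpha * pi / 180)
    v_drift <- v_c - v_b * cos(alpha * pi / 180) # may be <= 0
  } else {
    v_trans <- v_b
    v_drift <- v_c
  }
  trans <- numeric(n)
  drift <- numeric(n)
  t <- 0
  fail <- rep(NA, n)
  done <- x_r <= 0
  fail[done] <- FALSE
  while (!all(done) && t < t_max) {
    trans <- trans + v_trans * dt
    drift <- drift + v_drift * dt
    t <- t + dt
    safe <- !done & trans >= x_r
    fail[safe] <- FALSE
    done <- done | safe
    hit <- !done & drift >= x_d # pushed into the rotor
    exhausted <- !done & strategy == "reverse" & t >= t_e
    fail[hit | exhausted] <- TRUE
    done <- done | hit | exhausted
  }
  # anything unresolved at t_max is a stationary stalemate: success
  fail[is.na(fail)] <- FALSE
  fail
}

# Numerical-integration oracle for the mean required escape path when
# entry is uniform over the disc area and escape is to the nearer
# lateral edge: E[x_r] over the disc of radius R, by 2-D quadrature.
disc_mean_escape_numeric <- function(radius, n_grid = 2001) {
  xs <- seq(-radius, radius, length.out = n_grid)
  ys <- seq(-radius, radius, length.out = n_grid)
  h <- xs[2] - xs[1]
  total <- 0
  area <- 0
  for (y in ys) {
    w <- radius^2 - y^2
    if (w <= 0) next
    half <- sqrt(w)
    inside <- abs(xs) <= half
    total <- total + sum(half - abs(xs[inside])) * h * h
    area <- area + sum(inside) * h * h
  }
  total / area
}

# Direct simulation of direction observations from a logistic law in
# current speed (no package code involved).
simulate_direction_logit <- function(n, beta0, beta1,
                                     current_range = c(0.5, 1.5)) {
  current <- stats::runif(n, current_range[1], current_range[2])
  p <- stats::plogis(beta0 + beta1 * current)
  tibble::tibble(
    current_speed = current,
    direction = ifelse(stats::runif(n) < p, "along", "counter")
  )
}
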