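#' Basic-event probabilities for one turbine-mortality setting
#'
#' Bundles the eight basic events of the collision fault tree into a
#' validated list. The top event, turbine mortality, requires a chain of
#' events: the fish passes through the turbine array (`p_p`), co-occurs
#' with an operating rotor (`p_o`), fails to avoid it (`p_a`), is carried
#' into the hazardous part of the swept disc (`p_z`), and is then injured
#' either by hydraulic stress (`p_s`) or by a blade strike, which needs a
#' blade incident (`p_b`), a failed close-range evasion (`p_e`) and
#' damaging contact (`p_d`).
#'
#' Where field observations give the joint probability of array passage
#' and co-occurrence directly (passes at rotor depth per interval divided
#' by population size), supply it as `p_op`; it then takes precedence over
#' the separate `p_p * p_o` product.
#'
#' @param p_p,p_o,p_a,p_z,p_s,p_b,p_e,p_d Probabilities in \[0, 1\].
#' @param p_op Optional joint array-passage x co-occurrence probability;
#'   overrides `p_p * p_o` when given.
#'
#' @return An object of class `risk_components` (a named list).
#' @examples
#' rc <- risk_components(
#'   p_op = 2.22e-3, p_a = 0.90, p_z = 0.65,
#'   p_s = 0, p_b = 0.03, p_e = 0.75, p_d = 0.75
#' )
#' turbine_mortality(rc)
#' @export
risk_components <- function(p_p = 1, p_o = 1, p_a = 1, p_z = 1,
                            p_s = 0, p_b = 0, p_e = 0, p_d = 0,
                            p_op = NULL) {
  fields <- list(
    p_p = p_p, p_o = p_o, p_a = p_a, p_z = p_z,
    p_s = p_s, p_b = p_b, p_e = p_e, p_d = p_d
  )
  for (nm in names(fields)) {
    if (length(fields[[nm]]) != 1) {
      stop(sprintf("`%s` must be a single probability.", nm), call. = FALSE)
    }
    check_probability(fields[[nm]], nm)
  }
  if (!is.null(p_op)) {
    if (length(p_op) != 1) stop("`p_op` must be a single probability.", call. = FALSE)
    check_probability(p_op, "p_op")
  }
  structure(c(fields, list(p_op = p_op)), class = "risk_components")
}

#' @export
print.risk_components <- function(x, ...) {
  cat("<risk_components>\n")
  ex <- unlist(x[!vapply(x, is.null, logical(1))])
  print(ex)
  invisible(x)
}

#' Probability of turbine mortality for one setting
#'
#' Combines the basic-event probabilities through the fault tree's gates:
#' an AND gate over exposure events and the injury OR gate,
#' \deqn{P_{TM} = P_p P_o P_a P_z (P_s + P_b P_e P_d - P_s P_b P_e P_d).}
#' The commonly used approximation drops the cross term
#' \eqn{P_s P_b P_e P_d} (rare-event form); the exact OR form is never
#' larger than the approximation, so the exact form is the default.
#'
#' @param components A [risk_components()] object.
#' @param exact If `TRUE` (default) use the exact OR gate; if `FALSE`,
#'   the rare-event approximation `p_s + p_b*p_e*p_d`.
#'
#' @return Probability of turbine mortality per time interval.
#' @export
turbine_mortality <- function(components, exact = TRUE) {
  c <- components
  if (!inherits(c, "risk_components")) {
    c <- do.call(risk_components, as.list(c))
  }
  exposure <- if (!is.null(c$p_op)) {
    and_gate(c(c$p_op, c$p_a, c$p_z))
  } else {
    and_gate(c(c$p_p, c$p_o, c$p_a, c$p_z))
  }
  strike <- and_gate(c(c$p_b, c$p_e, c$p_d))
  injury <- if (exact) {
    or_gate(c(c$p_s, strike))
  } else {
    c$p_s + strike
  }
  exposure * injury
}

#' Expected number of turbine mortalities per interval
#'
#' With population-representative component probabilities, the top-event
#' probability applies to each of the `n_tot` population members, so the
#' expected loss per interval is their product.
#'
#' @param p_tm Turbine-mortality probability per interval, in \[0, 1\].
#' @param n_tot Population size (individuals, >= 0).
#' @return Expected individuals lost per interval.
#' @export
expected_mortalities <- function(p_tm, n_tot) {
  check_probability(p_tm, "p_tm")
  check_positive(n_tot, "n_tot", strict = FALSE)
  p_tm * n_tot
}

#' Yearly expected loss from per-setting hourly losses
#'
#' A year is partitioned into representative settings (tidal-current bin x
#' light condition, each with its hours per year); the yearly total is the
#' sum of each setting's hourly expected loss weighted by its hours.
#'
#' @param hourly_n_tm Numeric vector of expected losses per hour, one per
#'   setting.
#' @param hours Hours per year assigned to each setting (>= 0).
#' @return Expected individuals lost per year.
#' @examples
#' yearly_total(c(0.1, 0.2), c(10, 5)) # 2
#' @export
yearly_total <- function(hourly_n_tm, hours) {
  if (length(hourly_n_tm) != length(hours)) {
    stop("`hourly_n_tm` and `hours` must have equal length.", call. = FALSE)
  }
  check_positive(hourly_n_tm, "hourly_n_tm", strict = FALSE)
  check_positive(hours, "hours", strict = FALSE)
  sum(hourly_n_tm * hours)
}

#' Population state for the mortality budget
#'
#' Population size changes through births, immigration, deaths, emigration
#' and turbine mortality:
#' \deqn{dN_{TOT}/dt = dN_B/dt + dN_I/dt - dN_D/dt - dN_E/dt - dN_{TM}/dt.}
#'
#' @param n_tot Population size (individuals, >= 0).
#' @param births,immigration,deaths,emigration,turbine_mortality Rates in
#'   individuals per year.
#' @return An object of class `population_state`.
#' @export
population_state <- function(n_tot, births = 0, immigration = 0,
                             deaths = 0, emigration = 0,
                             turbine_mortality = 0) {
  check_positive(n_tot, "n_tot", strict = FALSE)
  rates <- c(
    births = births, immigration = immigration, deaths = deaths,
    emigration = emigration, turbine_mortality = turbine_mortality
  )
  if (anyNA(rates) || any(!is.finite(rates))) {
    stop("All rates must be finite.", call. = FALSE)
  }
  structure(
    list(
      n_tot = n_tot, births = births, immigration = immigration,
      deaths = deaths, emigration = emigration,
      turbine_mortality = turbine_mortality
    ),
    class = "population_state"
  )
}

#' Project a population state forward
#'
#' A simple forward (Euler) step of the population budget; rates are held
#' constant over the step and the projected size is floored at zero
#' (negative abundance is meaningless).
#'
#' @param state A [population_state()].
#' @param dt Step length in years (> 0).
#' @return A new `population_state` with updated `n_tot`; rates unchanged.
#' @export
project_population <- function(state, dt = 1) {
  stopifnot(inherits(state, "population_state"))
  check_positive(dt, "dt", strict = TRUE)
  net <- state$births + state$immigration - state$deaths -
    state$emigration - state$turbine_mortality
  out <- state
  out$n_tot <- max(0, state$n_tot + dt * net)
  out
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "<population_state> n_tot = %g (net rate %+g / yr)\n",
    x$n_tot,
    x$births + x$immigration - x$deaths - x$emigration - x$turbine_mortality
  ))
  invisible(x)
}
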