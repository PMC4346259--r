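#' Turbine geometry and kinematics
#'
#' A validated description of a horizontal-axis hydrokinetic rotor: its
#' diameter, blade count, rotational speed (held constant above cut-in),
#' the current speed at which it starts rotating, and the two safety-zone
#' parameters that define the hazardous fraction of the swept disc — the
#' blade speed below which strikes are harmless (inner zone) and the
#' fraction of the disc from which the hydrodynamic bow wave deflects
#' incoming water (outer zone; about 10% for large rotors, about 20% for
#' small ones).
#'
#' @param diameter Rotor diameter, m (> 0).
#' @param n_blades Number of rotor blades (>= 1).
#' @param rpm Rotational speed, revolutions per minute (>= 0).
#' @param cut_in Cut-in current speed, m/s (>= 0).
#' @param v_safe_blade Local blade speed below which collision is
#'   harmless, m/s (default 5).
#' @param f_outer Outer safety-zone fraction of the disc, in \[0, 1)
#'   (default 0.10; use ~0.20 for small rotors).
#' @return An object of class `turbine_spec`.
#' @examples
#' turbine_spec(diameter = 20, n_blades = 2, rpm = 14, cut_in = 0.75)
#' @export
turbine_spec <- function(diameter, n_blades = 2, rpm = 14, cut_in = 0.75,
                         v_safe_blade = 5, f_outer = 0.10) {
  check_positive(diameter, "diameter")
  if (n_blades < 1 || n_blades != round(n_blades)) {
    stop("`n_blades` must be a whole number >= 1.", call. = FALSE)
  }
  check_positive(rpm, "rpm", strict = FALSE)
  check_positive(cut_in, "cut_in", strict = FALSE)
  check_positive(v_safe_blade, "v_safe_blade", strict = FALSE)
  if (f_outer < 0 || f_outer >= 1) {
    stop("`f_outer` must lie in [0, 1).", call. = FALSE)
  }
  spec <- structure(
    list(
      diameter = diameter, n_blades = n_blades, rpm = rpm,
      cut_in = cut_in, v_safe_blade = v_safe_blade, f_outer = f_outer
    ),
    class = "turbine_spec"
  )
  # a parked or slow rotor (inner fraction 1) is safe everywhere, which is
  # consistent; only a genuine partition overflow is a configuration error
  inner <- inner_safe_fraction(spec)
  if (inner < 1 && inner + f_outer > 1) {
    stop("Inner and outer safety zones exceed the whole disc (inner_safe_fraction + f_outer > 1).",
      call. = FALSE
    )
  }
  spec
}

#' @export
print.turbine_spec <- function(x, ...) {
  cat(sprintf(
    "<turbine_spec> D = %g m, %d blades, %g rpm (tip %.2f m/s), cut-in %g m/s\n",
    x$diameter, x$n_blades, x$rpm, tip_speed(x), x$cut_in
  ))
  invisible(x)
}

#' Blade-tip speed
#'
#' @param turbine A [turbine_spec()].
#' @return Tip speed in m/s: `pi * diameter * rpm / 60`.
#' @export
tip_speed <- function(turbine) {
  stopifnot(inherits(turbine, "turbine_spec"))
  pi * turbine$diameter * turbine$rpm / 60
}

#' Inner safety-zone fraction of the swept disc
#'
#' Blades move slowly near the hub; strikes there are harmless. The inner
#' safety zone extends from the nacelle to the radius where the local
#' blade speed reaches `v_safe_blade`. Since local blade speed grows
#' linearly with radius and disc area with radius squared, the zone's
#' share of the disc area is `(v_safe_blade / tip_speed)^2`. A stationary
#' rotor is entirely safe (fraction 1).
#'
#' @param turbine A [turbine_spec()].
#' @return Area fraction in \[0, 1\].
#' @examples
#' # tip speed 10 m/s, safe below 5 m/s: a quarter of the disc
#' inner_safe_fraction(turbine_spec(20, rpm = 60 * 10 / (pi * 20)))
#' @export
inner_safe_fraction <- function(turbine) {
  stopifnot(inherits(turbine, "turbine_spec"))
  tip <- tip_speed(turbine)
  if (tip <= 0) {
    return(1)
  }
  min(1, (turbine$v_safe_blade / tip)^2)
}

#' Hazard-zone probability P_z
#'
#' The probability that a fish drifting through the swept disc crosses its
#' hazardous part: zero below the cut-in speed (rotor parked), otherwise
#' the disc fraction left after removing the inner (slow-blade) and outer
#' (flow-deflection) safety zones.
#'
#' @param turbine A [turbine_spec()].
#' @param v_c Current speed, m/s.
#' @return Probability in \[0, 1\] (vectorized over `v_c`).
#' @examples
#' tu <- turbine_spec(20, rpm = 60 * 10 / (pi * 20), cut_in = 0.75)
#' hazard_zone(tu, c(0.5, 2)) # 0 below cut-in, 0.65 above
#' @export
hazard_zone <- function(turbine, v_c) {
  stopifnot(inherits(turbine, "turbine_spec"))
  check_positive(v_c, "v_c", strict = FALSE)
  hz <- max(0, 1 - inner_safe_fraction(turbine) - turbine$f_outer)
  ifelse(v_c < turbine$cut_in, 0, hz)
}

#' Effective streamwise extent of a fish body
#'
#' The length of trajectory during which a fish body can be swept by a
#' blade, as a function of its orientation: a fish aligned with the flow
#' (angle of attack 0) presents its full length `l_f`; a fish crossing
#' the disc transversally (90 degrees) presents only its body depth
#' `h_f`. With `h_f = 0` this reduces to the classical `cos(angle) * l_f`
#' blade-strike term.
#'
#' @param l_f Fish total length, m (>= 0).
#' @param h_f Fish body depth, m (>= 0, default 0).
#' @param angle_of_attack Angle between the fish axis and the turbine
#'   axis, degrees.
#' @return Effective extent in metres: `l_f*|cos| + h_f*|sin|`.
#' @export
effective_extent <- function(l_f, h_f = 0, angle_of_attack = 0) {
  check_positive(l_f, "l_f", strict = FALSE)
  check_positive(h_f, "h_f", strict = FALSE)
  a <- angle_of_attack * pi / 180
  l_f * abs(cos(a)) + h_f * abs(sin(a))
}

#' Blade-incident probability P_b
#'
#' Probability that a rotor blade sweeps across the fish's trajectory
#' while it passes through the hazard zone: with `n_blades` blades
#' passing a point `n_blades * rpm / 60` times per second and the fish
#' occupying the passage plane for `extent / v_cf` seconds,
#' \deqn{P_b = n \cdot (R/60) \cdot \cos(\alpha_a) L_f / v_{cf},}
#' generalized here through [effective_extent()] so a transverse fish
#' retains a small body-depth cross-section. Clamped at 1.
#'
#' @param turbine A [turbine_spec()].
#' @param l_f Fish total length, m.
#' @param v_cf Combined speed of fish and current through the rotor
#'   plane, m/s (> 0).
#' @param angle_of_attack Degrees between fish axis and turbine axis
#'   (0 = head/tail-on to the rotor plane).
#' @param h_f Body depth, m (default 0 reproduces the classical formula).
#' @return Probability in \[0, 1\].
#' @examples
#' blade_incident(turbine_spec(20, n_blades = 2, rpm = 15),
#'   l_f = 0.4, v_cf = 1
#' ) # 0.2
#' @export
blade_incident <- function(turbine, l_f, v_cf, angle_of_attack = 0, h_f = 0) {
  stopifnot(inherits(turbine, "turbine_spec"))
  check_positive(v_cf, "v_cf", strict = TRUE)
  extent <- effective_extent(l_f, h_f, angle_of_attack)
  pmin(1, turbine$n_blades * (turbine$rpm / 60) * extent / v_cf)
}

#' Turbine-injury probability P_i
#'
#' OR gate over the two injury pathways inside the hazard zone: hydraulic
#' stress, or a damaging blade strike (blade incident AND evasion failure
#' AND blade damage).
#'
#' @param p_s Hydraulic-stress probability.
#' @param p_b Blade-incident probability.
#' @param p_e Evasion-failure probability.
#' @param p_d Blade-damage probability.
#' @return Probability in \[0, 1\].
#' @examples
#' turbine_injury(p_s = 0, p_b = 0.03, p_e = 0.75, p_d = 0.75) # 0.016875
#' @export
turbine_injury <- function(p_s, p_b, p_e, p_d) {
  or_gate(c(p_s, and_gate(c(p_b, p_e, p_d))))
}
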