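#' Rotor swept area
#'
#' Area of the circular disc traced by the rotor blades, perpendicular to
#' the flow.
#'
#' @param diameter Rotor diameter in metres (> 0).
#' @return Area in square metres.
#' @examples
#' rotor_swept_area(20) # 314.16
#' @export
rotor_swept_area <- function(diameter) {
  check_positive(diameter, "diameter")
  pi * (diameter / 2)^2
}

#' Array-passage probability from movement speed and population range
#'
#' Probability that a population-representative specimen transits the
#' turbine-array area within one time interval, assuming random movement:
#' `P_p = v_p / R_p`, where both the average movement speed `v_p`
#' (array units per interval) and the population range `R_p` (array
#' units) are expressed in units of the turbine-array footprint. Where the
#' array overlaps preferred habitat (spawning grounds, migration routes),
#' an `affinity` multiplier > 1 raises the probability. The result is
#' clamped at 1.
#'
#' @param v_p Average movement speed, turbine-array units per interval
#'   (>= 0).
#' @param r_p Population range, turbine-array units (> 0).
#' @param affinity Habitat-affinity multiplier (>= 0, default 1).
#' @return Probability in \[0, 1\].
#' @examples
#' array_passage(v_p = 5, r_p = 30) # 0.1667
#' @export
array_passage <- function(v_p, r_p, affinity = 1) {
  check_positive(v_p, "v_p", strict = FALSE)
  check_positive(r_p, "r_p", strict = TRUE)
  check_positive(affinity, "affinity", strict = FALSE)
  pmin(1, affinity * v_p / r_p)
}

#' Joint exposure probability from standardized field activity
#'
#' Converts a standardized fish-activity record (fish per square metre of
#' entrance area per video sample) into the joint probability that a
#' given population member comes across the rotor disc per assessment
#' interval: the along-current activity is scaled from the sample
#' duration to the interval, multiplied by the rotor swept area, and
#' divided by population size. This joint quantity replaces the separate
#' `p_p * p_o` product in the fault tree when field data are available.
#'
#' @param activity Fish entries per square metre per video sample (>= 0).
#' @param frac_along_current Proportion of fish swimming along-current,
#'   in \[0, 1\].
#' @param rotor_area Rotor swept area in square metres (> 0).
#' @param n_tot Population size (> 0).
#' @param interval Assessment interval in hours (default 1).
#' @param sample_duration Video sample duration in minutes (default 45).
#' @return Joint probability `p_o * p_p` per interval, clamped to \[0, 1\].
#' @examples
#' # strongest-current bin of a semidiurnal tidal channel survey:
#' co_occurrence_rate(0.001, 1, rotor_area = 314, n_tot = 10000) # 4.19e-5
#' @export
co_occurrence_rate <- function(activity, frac_along_current, rotor_area,
                               n_tot, interval = 1, sample_duration = 45) {
  check_positive(activity, "activity", strict = FALSE)
  check_probability(frac_along_current, "frac_along_current")
  check_positive(rotor_area, "rotor_area")
  check_positive(n_tot, "n_tot")
  check_positive(interval, "interval")
  check_positive(sample_duration, "sample_duration")
  hourly <- activity * (60 * interval / sample_duration)
  pmin(1, pmax(0, hourly * frac_along_current * rotor_area / n_tot))
}
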