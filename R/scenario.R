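#' Assemble a collision-risk scenario
#'
#' A scenario bundles everything needed for an end-to-end run of the
#' fault-tree model: the turbine, the population, the fish (either fixed
#' component probabilities or trait distributions for the Monte Carlo
#' avoidance simulation), assigned injury probabilities by light
#' condition, run options, and a table of settings — one per
#' tidal-current x light condition with its hours per year.
#'
#' Per-setting columns of `settings`: `label`, `current_speed` (m/s,
#' representative of the bin), `light` (`"daylight"`/`"lowlight"`),
#' `hours` (h/yr), and optional overrides (`NA` = not overridden):
#' `p_op` (joint exposure), `activity` + `frac_along_current`
#' (+ `sample_duration`) for the field-data exposure path, and any of
#' `p_p`, `p_o`, `p_a`, `p_z`, `p_b`, `p_e`, `p_d`, `p_s`.
#'
#' @param turbine A [turbine_spec()] (or a list of its arguments).
#' @param population List with `n_tot` (> 0) and, for the movement-based
#'   exposure path, `v_p`, `r_p` (turbine-array units) and optional
#'   `affinity`.
#' @param fish List describing the fish: `strategy` (`"reverse"` or
#'   `"diverge"`), optional `traits` (named list of [trait_dist()];
#'   required when avoidance failure is simulated), `l_f` (scalar length,
#'   m, required when blade incidents are computed), `h_f` (body depth,
#'   m, default 0), `v_sust` (sustained speed, m/s, default 0).
#' @param assigned Assigned injury probabilities keyed by light condition:
#'   `list(daylight = list(p_e=, p_d=, p_s=), lowlight = ...)`.
#' @param settings Data frame of settings (see Details).
#' @param run Run options: `n_runs` (default 1e5), `seed` (default 1),
#'   `exact` (default `TRUE`), `entry` (`"disc"`/`"uniform"`),
#'   `lowlight_factor` (default 0.1), `eps_v_cf` (floor on the passage
#'   speed of a reversing fish, default 0.1 m/s).
#' @return An object of class `scenario`.
#' @seealso [run_scenario()], [read_scenario()]
#' @export
scenario <- function(turbine, population, fish = list(), assigned = NULL,
                     settings = NULL, run = list()) {
  if (!inherits(turbine, "turbine_spec")) {
    turbine <- do.call(turbine_spec, turbine)
  }
  assigned <- assigned %||% list(
    daylight = list(p_e = 0.50, p_d = 0.75, p_s = 0),
    lowlight = list(p_e = 0.75, p_d = 0.75, p_s = 0)
  )
  run <- utils::modifyList(
    list(
      n_runs = 1e5, seed = 1, exact = TRUE, entry = "disc",
      lowlight_factor = 0.1, eps_v_cf = 0.1
    ),
    run
  )
  fish <- utils::modifyList(
    list(strategy = "diverge", h_f = 0, v_sust = 0),
    fish
  )
  s <- structure(
    list(
      turbine = turbine, population = population, fish = fish,
      assigned = assigned, settings = tibble::as_tibble(settings),
      run = run
    ),
    class = "scenario"
  )
  problems <- validate_scenario(s)
  if (length(problems) > 0) {
    stop(
      paste0(
        "Invalid scenario:\n",
        paste0("  - ", problems, collapse = "\n")
      ),
      call. = FALSE
    )
  }
  s
}

#' Validate a scenario, collecting every violation
#'
#' @param s A scenario-shaped list.
#' @return Character vector of problems (empty when valid), each naming
#'   the offending field.
#' @export
validate_scenario <- function(s) {
  p <- character(0)
  add <- function(msg) p <<- c(p, msg)
  tu <- s$turbine
  if (!inherits(tu, "turbine_spec")) {
    add("turbine: not a turbine_spec")
  } else if (inner_safe_fraction(tu) < 1 &&
    inner_safe_fraction(tu) + tu$f_outer > 1) {
    add("turbine: inner_safe_fraction + f_outer exceeds 1")
  }
  pop <- s$population
  if (is.null(pop$n_tot) || !is.numeric(pop$n_tot) || pop$n_tot <= 0) {
    add("population$n_tot: must be a positive number")
  }
  if (!is.null(pop$r_p) && pop$r_p <= 0) add("population$r_p: must be > 0")
  if (!is.null(pop$v_p) && pop$v_p < 0) add("population$v_p: must be >= 0")
  if (!s$fish$strategy %in% c("reverse", "diverge")) {
    add("fish$strategy: must be 'reverse' or 'diverge'")
  }
  if (!is.null(s$fish$traits)) {
    bad <- names(s$fish$traits)[!vapply(
      s$fish$traits, inherits, logical(1), "trait_dist"
    )]
    if (length(bad) > 0) {
      add(sprintf("fish$traits: not trait_dist objects: %s", paste(bad, collapse = ", ")))
    }
  }
  for (li in c("daylight", "lowlight")) {
    blk <- s$assigned[[li]]
    if (is.null(blk)) {
      add(sprintf("assigned$%s: missing", li))
      next
    }
    for (nm in c("p_e", "p_d", "p_s")) {
      v <- blk[[nm]]
      if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
        add(sprintf("assigned$%s$%s: must be a probability in [0, 1]", li, nm))
      }
    }
  }
  st <- s$settings
  if (is.null(st) || nrow(st) == 0) {
    add("settings: at least one setting is required")
  } else {
    for (nm in c("label", "current_speed", "light", "hours")) {
      if (!nm %in% names(st)) add(sprintf("settings$%s: column missing", nm))
    }
    if ("hours" %in% names(st)) {
      if (any(st$hours < 0)) add("settings$hours: must be >= 0")
      if (sum(st$hours) > 8766) {
        add(sprintf(
          "settings$hours: sum %g exceeds hours in a year (8766)",
          sum(st$hours)
        ))
      }
    }
    if ("light" %in% names(st) &&
      !all(st$light %in% c("daylight", "lowlight"))) {
      add("settings$light: values must be 'daylight' or 'lowlight'")
    }
    if ("current_speed" %in% names(st) && any(st$current_speed <= 0)) {
      add("settings$current_speed: must be > 0 (use the bin representative)")
    }
    for (nm in intersect(
      c("p_op", "p_p", "p_o", "p_a", "p_z", "p_b", "p_e", "p_d", "p_s"),
      names(st)
    )) {
      v <- st[[nm]]
      if (any(!is.na(v) & (v < 0 | v > 1))) {
        add(sprintf("settings$%s: overrides must lie in [0, 1]", nm))
      }
    }
  }
  p
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>\n")
  print(x$turbine)
  cat(sprintf(
    "  population n_tot = %g; fish strategy '%s'; %d settings (%g h/yr)\n",
    x$population$n_tot, x$fish$strategy,
    nrow(x$settings), sum(x$settings$hours)
  ))
  invisible(x)
}

setting_override <- function(st, i, nm) {
  if (nm %in% names(st) && !is.na(st[[nm]][i])) st[[nm]][i] else NULL
}

#' Run a collision-risk scenario
#'
#' For each setting the engine resolves every fault-tree component in
#' turn and combines them into the probability of turbine mortality and
#' the expected hourly and yearly losses:
#'
#' * exposure `p_o x p_p`: a `p_op` override wins; else a field-activity
#'   record (`activity`, `frac_along_current`) through
#'   [co_occurrence_rate()]; else the movement model [array_passage()]
#'   times the setting's `p_o` (default 1);
#' * avoidance failure `p_a`: an override, else [monte_carlo_pa()] over
#'   the fish trait distributions at the setting's current and light;
#' * hazard zone `p_z`: [hazard_zone()] (zero below cut-in) unless
#'   overridden;
#' * blade incident `p_b`: an override, else [blade_incident()] with the
#'   passage posture implied by the escape strategy — a fish that failed
#'   the 'reverse' strategy drifts in tail-first at
#'   `v_cf = max(eps, v_c - v_sust)` with angle of attack 0, one that
#'   failed 'diverge' crosses at `v_cf = v_c` with angle 90 degrees;
#' * `p_e`, `p_d`, `p_s`: assigned by light condition, overridable.
#'
#' Below the cut-in speed the rotor is parked, so `p_z`, `p_b`, `p_e`,
#' `p_d` and `p_s` are zero. The run is deterministic for a fixed
#' `run$seed`.
#'
#' @param s A [scenario()].
#' @return A tibble of class `risk_report`: one row per setting with all
#'   eight components, `p_tm_exact`, `p_tm_approx`, `hourly_n_tm` and
#'   `yearly_n_tm`, plus a `total` row carrying the summed hours and
#'   yearly loss. The `p_tm` used for losses follows `run$exact`.
#' @export
run_scenario <- function(s) {
  stopifnot(inherits(s, "scenario"))
  st <- s$settings
  tu <- s$turbine
  rows <- purrr::map(seq_len(nrow(st)), function(i) {
    v_c <- st$current_speed[i]
    light <- st$light[i]
    operating <- v_c >= tu$cut_in
    ov <- function(nm) setting_override(st, i, nm)

    # exposure: joint override > field activity > movement model
    p_op <- ov("p_op")
    p_p <- NA_real_
    p_o <- NA_real_
    if (is.null(p_op)) {
      act <- ov("activity")
      if (!is.null(act)) {
        p_op <- co_occurrence_rate(
          activity = act,
          frac_along_current = ov("frac_along_current") %||% 1,
          rotor_area = rotor_swept_area(tu$diameter),
          n_tot = s$population$n_tot,
          sample_duration = ov("sample_duration") %||% 45
        )
      } else {
        p_p <- ov("p_p")
        if (is.null(p_p)) {
          if (is.null(s$population$v_p) || is.null(s$population$r_p)) {
            stop(sprintf(
              "setting '%s': no p_op/activity/p_p override and population$v_p/r_p missing",
              st$label[i]
            ), call. = FALSE)
          }
          p_p <- array_passage(
            v_p = s$population$v_p, r_p = s$population$r_p,
            affinity = s$population$affinity %||% 1
          )
        }
        p_o <- ov("p_o") %||% 1
      }
    }

    p_a <- ov("p_a")
    if (is.null(p_a)) {
      if (is.null(s$fish$traits)) {
        stop(sprintf(
          "settings$p_a: no override for '%s' and fish$traits missing",
          st$label[i]
        ), call. = FALSE)
      }
      p_a <- monte_carlo_pa(
        s$fish$traits, tu$diameter, v_c,
        light = light, strategy = s$fish$strategy,
        n_runs = s$run$n_runs, seed = s$run$seed,
        entry = s$run$entry, lowlight_factor = s$run$lowlight_factor
      )$p_a
    }
    p_z <- ov("p_z") %||% hazard_zone(tu, v_c)
    if (!operating) {
      p_b <- 0
      p_e <- 0
      p_d <- 0
      p_s <- 0
    } else {
      p_b <- ov("p_b")
      if (is.null(p_b)) {
        if (is.null(s$fish$l_f)) {
          stop(sprintf(
            "settings$p_b: no override for '%s' and fish$l_f missing",
            st$label[i]
          ), call. = FALSE)
        }
        p_b <- if (s$fish$strategy == "reverse") {
          blade_incident(tu, s$fish$l_f,
            v_cf = max(s$run$eps_v_cf, v_c - s$fish$v_sust),
            angle_of_attack = 0, h_f = s$fish$h_f
          )
        } else {
          blade_incident(tu, s$fish$l_f,
            v_cf = v_c,
            angle_of_attack = 90, h_f = s$fish$h_f
          )
        }
      }
      p_e <- ov("p_e") %||% s$assigned[[light]]$p_e
      p_d <- ov("p_d") %||% s$assigned[[light]]$p_d
      p_s <- ov("p_s") %||% s$assigned[[light]]$p_s
    }
    comp <- risk_components(
      p_p = p_p %|NA|% 1, p_o = p_o %|NA|% 1,
      p_a = p_a, p_z = p_z, p_s = p_s, p_b = p_b, p_e = p_e, p_d = p_d,
      p_op = p_op
    )
    p_tm_exact <- turbine_mortality(comp, exact = TRUE)
    p_tm_approx <- turbine_mortality(comp, exact = FALSE)
    p_tm <- if (isTRUE(s$run$exact)) p_tm_exact else p_tm_approx
    hourly <- expected_mortalities(p_tm, s$population$n_tot)
    tibble::tibble(
      label = st$label[i], current_speed = v_c, light = light,
      hours = st$hours[i],
      p_op = p_op %||% NA_real_, p_p = p_p, p_o = p_o,
      p_a = p_a, p_z = p_z, p_b = p_b, p_e = p_e, p_d = p_d, p_s = p_s,
      p_tm_exact = p_tm_exact, p_tm_approx = p_tm_approx,
      hourly_n_tm = hourly,
      yearly_n_tm = hourly * st$hours[i]
    )
  })
  out <- dplyr::bind_rows(rows)
  total <- tibble::tibble(
    label = "total",
    hours = sum(out$hours),
    yearly_n_tm = yearly_total(out$hourly_n_tm, out$hours)
  )
  out <- dplyr::bind_rows(out, total)
  attr(out, "scenario") <- s
  class(out) <- c("risk_report", class(out))
  out
}

`%|NA|%` <- function(x, y) if (length(x) == 1 && is.na(x)) y else x

#' Write a risk report as CSV
#'
#' Numbers are written at full precision; round only for display.
#'
#' @param report A `risk_report` from [run_scenario()].
#' @param path Output CSV path.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_csv(report, path)
  invisible(report)
}

#' Read / write a scenario configuration file
#'
#' Scenario configurations are YAML (or JSON) documents with blocks
#' `turbine`, `population`, `fish` (including a `traits` block of
#' distribution specs: `family`, family parameters, optional
#' `lower`/`upper`), `assigned`, `run` and a list of `settings`. Writing
#' then reading a configuration reproduces the same scenario.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `read_scenario()`: a [scenario()]. `write_scenario()`: `path`,
#'   invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_scenario(cfg)
}

#' @rdname read_scenario
#' @param s A [scenario()].
#' @export
write_scenario <- function(s, path) {
  stopifnot(inherits(s, "scenario"))
  cfg <- list(
    turbine = unclass(s$turbine),
    population = s$population,
    fish = c(
      s$fish[setdiff(names(s$fish), "traits")],
      if (!is.null(s$fish$traits)) {
        list(traits = purrr::map(s$fish$traits, trait_to_config))
      }
    ),
    assigned = s$assigned,
    run = s$run,
    settings = purrr::pmap(s$settings, function(...) {
      row <- list(...)
      row[!vapply(row, function(v) length(v) == 1 && is.na(v), logical(1))]
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

#' @rdname read_scenario
#' @param cfg A configuration list (parsed YAML/JSON).
#' @export
as_scenario <- function(cfg) {
  fish <- cfg$fish %||% list()
  if (!is.null(fish$traits)) {
    fish$traits <- purrr::map(fish$traits, config_to_trait)
  }
  settings <- dplyr::bind_rows(purrr::map(cfg$settings, tibble::as_tibble))
  scenario(
    turbine = cfg$turbine,
    population = cfg$population,
    fish = fish,
    assigned = cfg$assigned,
    settings = settings,
    run = cfg$run %||% list()
  )
}

trait_to_config <- function(d) {
  out <- c(list(family = d$family), d$params)
  if (is.finite(d$lower)) out$lower <- d$lower
  if (is.finite(d$upper)) out$upper <- d$upper
  out
}

config_to_trait <- function(x) {
  if (inherits(x, "trait_dist")) {
    return(x)
  }
  args <- x[setdiff(names(x), c("family", "lower", "upper"))]
  do.call(trait_dist, c(
    list(family = x$family),
    args,
    list(lower = x$lower %||% -Inf, upper = x$upper %||% Inf)
  ))
}
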