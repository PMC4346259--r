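#' Standardize fish activity to entrance area and time
#'
#' Fish activity is the number of times a fish entered the recorded water
#' volume per video sample. Dividing by the entrance area of the recorded
#' volume controls for visibility (turbid water shrinks the area through
#' which entering fish can be seen) and rescaling by the sample duration
#' expresses it per hour.
#'
#' @param count Number of fish entries in the sample (>= 0).
#' @param entrance_area Entrance area of the recorded volume, m^2 (> 0).
#' @param duration Sample duration, minutes (> 0).
#' @return Activity in fish per m^2 per hour (vectorized).
#' @examples
#' standardize_activity(7, entrance_area = 10, duration = 45) # 0.933
#' @export
standardize_activity <- function(count, entrance_area, duration = 45) {
  check_positive(count, "count", strict = FALSE)
  check_positive(entrance_area, "entrance_area")
  check_positive(duration, "duration")
  (count / entrance_area) * (60 / duration)
}

#' Regression of fish activity on current speed
#'
#' Fits the per-sample standardized activity against current speed, with a
#' square-root transform of the response to stabilize the variance of
#' count-derived activities, or by Spearman rank correlation.
#'
#' @param samples A data frame with one row per video sample, containing
#'   `current_speed` and either `activity` or the triplet
#'   `count`, `entrance_area`, `duration_min` from which activity is
#'   standardized.
#' @param method `"sqrt_lm"` (OLS of sqrt(activity) on current speed) or
#'   `"spearman"`.
#' @return An object of class `activity_trend`. Use [generics::glance()]
#'   for the fit statistics (`r_squared`, `f_stat`, `p_value`, slope and
#'   its confidence interval for the linear fit; `rho` and `p_value` for
#'   Spearman).
#' @export
fit_activity_trend <- function(samples, method = c("sqrt_lm", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(samples), "current_speed" %in% names(samples))
  if (!"activity" %in% names(samples)) {
    if (!all(c("count", "entrance_area", "duration_min") %in% names(samples))) {
      stop("`samples` needs `activity` or `count` + `entrance_area` + `duration_min`.",
        call. = FALSE
      )
    }
    samples <- dplyr::mutate(
      samples,
      activity = standardize_activity(.data$count, .data$entrance_area, .data$duration_min)
    )
  }
  if (nrow(samples) < 3) {
    stop("Need at least 3 samples to fit an activity trend.", call. = FALSE)
  }
  check_positive(samples$activity, "activity", strict = FALSE)
  degenerate <- stats::sd(samples$current_speed) == 0
  fit <- NULL
  if (method == "sqrt_lm" && !degenerate) {
    fit <- stats::lm(sqrt(activity) ~ current_speed, data = samples)
  }
  structure(
    list(
      method = method, fit = fit, data = samples,
      degenerate = degenerate,
      spearman = if (method == "spearman" && !degenerate) {
        suppressWarnings(stats::cor.test(samples$activity, samples$current_speed,
          method = "spearman"
        ))
      }
    ),
    class = "activity_trend"
  )
}

#' @export
print.activity_trend <- function(x, ...) {
  cat("<activity_trend>", x$method, "\n")
  print(glance(x))
  invisible(x)
}

#' @rdname fit_activity_trend
#' @param x An `activity_trend` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.activity_trend <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(
      method = x$method, n = nrow(x$data), degenerate = TRUE
    ))
  }
  if (x$method == "spearman") {
    return(tibble::tibble(
      method = "spearman", n = nrow(x$data),
      rho = unname(x$spearman$estimate),
      p_value = x$spearman$p.value,
      degenerate = FALSE
    ))
  }
  s <- summary(x$fit)
  ci <- stats::confint(x$fit)["current_speed", ]
  tibble::tibble(
    method = "sqrt_lm", n = nrow(x$data),
    r_squared = s$r.squared,
    f_stat = unname(s$fstatistic["value"]),
    df1 = unname(s$fstatistic["numdf"]),
    df2 = unname(s$fstatistic["dendf"]),
    p_value = stats::pf(s$fstatistic["value"], s$fstatistic["numdf"],
      s$fstatistic["dendf"],
      lower.tail = FALSE
    ),
    slope = unname(stats::coef(x$fit)["current_speed"]),
    slope_lo = unname(ci[1]), slope_hi = unname(ci[2]),
    degenerate = FALSE
  )
}

#' Logistic threshold model of a binary swimming behavior
#'
#' Fits a maximum-likelihood logistic regression of a binary behavioral
#' outcome on current speed, restricted to currents at or above
#' `min_current` (default 0.5 m/s) so that the effect of faster flows is
#' disclosed. For `outcome = "direction"` the modelled event is
#' along-current (vs counter-current) swimming, with transverse swimmers
#' excluded; for `outcome = "depth"` it is pelagic (vs bottom) swimming.
#' To ensure test validity the fit refuses unless both outcome levels
#' hold at least `min_per_level` observations (default 30) after the
#' current restriction. The fitted model is compared with a constant
#' (no-predictor) model by a likelihood-ratio chi-squared test, and its
#' discrimination is summarized by the area under the ROC curve
#' (midrank-tie, i.e. trapezoidal, estimator).
#'
#' @param fish A data frame with one row per observed fish, containing
#'   `current_speed` and the outcome column (`direction` with levels
#'   `"counter"`, `"along"`, `"transverse"`; or `depth` with levels
#'   `"bottom"`, `"pelagic"`).
#' @param outcome `"direction"` or `"depth"`.
#' @param min_current Lower current-speed restriction, m/s (default 0.5).
#' @param min_per_level Validity rule: minimum observations required in
#'   each outcome level (default 30).
#' @return An object of class `logistic_threshold` with elements `beta0`,
#'   `beta1`, `n`, `chi2`, `df`, `p_value`, `auc`, `breaking_point`,
#'   `separated` and the underlying `glm` fit. [generics::tidy()] returns
#'   the coefficient table, [generics::glance()] the one-row summary.
#' @seealso [breaking_point()]
#' @export
fit_logistic_threshold <- function(fish, outcome = c("direction", "depth"),
                                   min_current = 0.5, min_per_level = 30) {
  outcome <- match.arg(outcome)
  stopifnot(is.data.frame(fish), "current_speed" %in% names(fish))
  if (!outcome %in% names(fish)) {
    stop(sprintf("`fish` has no `%s` column.", outcome), call. = FALSE)
  }
  d <- dplyr::filter(fish, .data$current_speed >= min_current)
  if (outcome == "direction") {
    d <- dplyr::filter(d, .data$direction %in% c("counter", "along"))
    d$y <- as.integer(d$direction == "along")
    levels_lab <- c("counter", "along")
  } else {
    d <- dplyr::filter(d, .data$depth %in% c("bottom", "pelagic"))
    d$y <- as.integer(d$depth == "pelagic")
    levels_lab <- c("bottom", "pelagic")
  }
  tab <- c(sum(d$y == 0), sum(d$y == 1))
  if (any(tab < min_per_level)) {
    stop(sprintf(
      "Validity rule violated for `%s`: need >= %d observations per level at current >= %g m/s, got %s = %d and %s = %d.",
      outcome, min_per_level, min_current,
      levels_lab[1], tab[1], levels_lab[2], tab[2]
    ), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(y ~ current_speed, data = d, family = stats::binomial())
  )
  beta <- stats::coef(fit)
  fitted <- stats::fitted(fit)
  # quasi-complete separation: divergent coefficients / degenerate fits
  separated <- !fit$converged || any(abs(beta) > 1e3) ||
    all(fitted > 1 - 1e-8 | fitted < 1e-8)
  chi2 <- fit$null.deviance - fit$deviance
  df <- fit$df.null - fit$df.residual
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = d$y, predictor = fitted,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
  structure(
    list(
      outcome = outcome, event = levels_lab[2],
      beta0 = unname(beta[1]), beta1 = unname(beta[2]),
      n = nrow(d), chi2 = chi2, df = df,
      p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
      auc = auc,
      breaking_point = if (!separated && beta[2] != 0) {
        unname(-beta[1] / beta[2])
      } else {
        NA_real_
      },
      separated = separated,
      min_current = min_current,
      fit = fit, data = d
    ),
    class = "logistic_threshold"
  )
}

#' @export
print.logistic_threshold <- function(x, ...) {
  cat(sprintf(
    "<logistic_threshold> P(%s) ~ current speed (n = %d, current >= %g m/s)\n",
    x$event, x$n, x$min_current
  ))
  cat(sprintf(
    "  beta0 = %.3f, beta1 = %.3f; LR chi2(%d) = %.2f, p = %.3g; AUC = %.3f\n",
    x$beta0, x$beta1, x$df, x$chi2, x$p_value, x$auc
  ))
  if (x$separated) {
    cat("  WARNING: separation / non-convergence detected; estimates unreliable.\n")
  } else {
    cat(sprintf("  breaking point: %.3f m/s\n", x$breaking_point))
  }
  invisible(x)
}

#' @rdname fit_logistic_threshold
#' @param x A `logistic_threshold` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.logistic_threshold <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p_value = s[, "Pr(>|z|)"]
  )
}

#' @rdname fit_logistic_threshold
#' @exportS3Method generics::glance
glance.logistic_threshold <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, event = x$event, n = x$n,
    beta0 = x$beta0, beta1 = x$beta1,
    chi2 = x$chi2, df = x$df, p_value = x$p_value, auc = x$auc,
    breaking_point = x$breaking_point, separated = x$separated
  )
}

#' Breaking point of a logistic behavior model
#'
#' The current speed at which the modelled behavior becomes the more
#' probable one (modelled probability 0.5): `-beta0 / beta1`. It is
#' invariant under common rescaling of the two coefficients. Undefined
#' (returned as `NA` with a warning) when the slope is zero or the fit is
#' separated.
#'
#' @param object A [fit_logistic_threshold()] fit, or the intercept
#'   `beta0` (with `beta1` supplied).
#' @param beta1 Slope coefficient when `object` is given as `beta0`.
#' @param ... Unused.
#' @return Breaking point in m/s.
#' @examples
#' breaking_point(-3, 4) # 0.75
#' @export
breaking_point <- function(object, ...) UseMethod("breaking_point")

#' @rdname breaking_point
#' @export
breaking_point.logistic_threshold <- function(object, ...) {
  if (object$separated) {
    warning("Fit is separated/non-converged; breaking point undefined.")
    return(NA_real_)
  }
  breaking_point(object$beta0, object$beta1)
}

#' @rdname breaking_point
#' @export
breaking_point.numeric <- function(object, beta1, ...) {
  if (any(beta1 == 0)) {
    warning("`beta1` is zero; breaking point undefined.")
    return(ifelse(beta1 == 0, NA_real_, -object / beta1))
  }
  -object / beta1
}
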