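#' Fault-tree gate algebra
#'
#' Probabilities of intermediate events in a fault tree are combined from
#' the probabilities of their child events through AND gates (all children
#' must occur) and OR gates (at least one child occurs). Child events are
#' treated as independent.
#'
#' @param probs Numeric vector of event probabilities, each in \[0, 1\].
#'
#' @return A single probability in \[0, 1\]: the product for `and_gate()`,
#'   `1 - prod(1 - probs)` (inclusion-exclusion) for `or_gate()`.
#'
#' @examples
#' and_gate(c(0.5, 0.4)) # 0.2
#' or_gate(c(0.5, 0.5)) # 0.75
#' @export
and_gate <- function(probs) {
  check_probability(probs, "probs")
  prod(probs)
}

#' @rdname and_gate
#' @export
or_gate <- function(probs) {
  check_probability(probs, "probs")
  # 1 - prod(1 - p) computed in log space: stable for probabilities many
  # orders of magnitude below 1 (rare-event settings), exact at p = 1
  -expm1(sum(log1p(-probs)))
}

# Shared validator: probabilities must be finite and in [0, 1].
check_probability <- function(x, name) {
  if (length(x) == 0) {
    stop(sprintf("`%s` must contain at least one probability.", name),
      call. = FALSE
    )
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric probabilities.", name),
      call. = FALSE
    )
  }
  if (any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]; got values outside.", name),
      call. = FALSE
    )
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE, len_ok = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric.", name), call. = FALSE)
  }
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (bad) {
    stop(sprintf(
      "`%s` must be %s.", name,
      if (strict) "strictly positive" else "non-negative"
    ), call. = FALSE)
  }
  invisible(x)
}
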