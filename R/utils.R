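#' Evaluate an expression with a private, restorable RNG state
#'
#' All stochastic routines in the package take an explicit integer seed and
#' leave the caller's `.Random.seed` untouched, so simulations are
#' bit-reproducible and never interfere with user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rlang::abort("`seed` must be a single non-missing integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# scalar argument checks used across modules -------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    rlang::abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    rlang::abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x,
      if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < lower) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

#' Validate a tibble of exponential decay components
#'
#' A component table has one row per fluorescent species with columns
#' `lifetime` (ns, > 0) and `amplitude` (fraction in `[0, 1]`); amplitudes
#' must sum to 1 within `1e-9`.
#'
#' @param components A data frame with columns `lifetime` and `amplitude`.
#' @return The validated components as a tibble (invisibly usable).
#' @export
#' @examples
#' check_components(decay_components(c(3.46, 0.8), c(0.5, 0.5)))
check_components <- function(components) {
  components <- tibble::as_tibble(components)
  if (!all(c("lifetime", "amplitude") %in% names(components))) {
    rlang::abort("`components` needs columns `lifetime` and `amplitude`.")
  }
  if (nrow(components) == 0L) {
    rlang::abort("`components` must contain at least one species.")
  }
  if (any(!is.finite(components$lifetime)) || any(components$lifetime <= 0)) {
    rlang::abort("All component lifetimes must be finite and strictly positive (ns).")
  }
  if (any(components$amplitude < 0)) {
    rlang::abort("Component amplitude fractions must be non-negative.")
  }
  if (abs(sum(components$amplitude) - 1) > 1e-9) {
    rlang::abort(sprintf(
      "Component amplitude fractions must sum to 1 (got %.12f).",
      sum(components$amplitude)
    ))
  }
  components
}

#' Construct a component table
#'
#' @param lifetime Numeric vector of lifetimes in ns.
#' @param amplitude Numeric vector of amplitude fractions summing to 1.
#' @return A tibble with columns `lifetime`, `amplitude`.
#' @export
decay_components <- function(lifetime, amplitude) {
  check_components(tibble::tibble(lifetime = lifetime, amplitude = amplitude))
}
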