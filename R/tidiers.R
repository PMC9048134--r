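# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decay fit
#'
#' @param x A [fit_decay()] result.
#' @param tau_donor Optional donor reference lifetime; when given, a
#'   per-component FRET efficiency column is added.
#' @param ... Unused.
#' @return One row per component: `lifetime`, `amplitude`, `fixed` (and
#'   `efficiency` when `tau_donor` is supplied).
#' @export
tidy.decay_fit <- function(x, tau_donor = NULL, ...) {
  out <- x$components
  if (!is.null(tau_donor)) {
    out$efficiency <- fret_efficiency(pmin(out$lifetime, tau_donor), tau_donor)
  }
  out
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$components),
    chi2_reduced = x$chi2_reduced,
    cstat = x$cstat,
    n_photons = x$n_photons,
    tau_avg = amplitude_weighted_lifetime(x$components[, c("lifetime", "amplitude")]),
    converged = x$converged
  )
}

#' Tidy a global decay fit
#'
#' @param x A [global_fit()] result.
#' @param ... Unused.
#' @return Long tibble: `record`, `species` (1 = longest lifetime),
#'   `lifetime`, `amplitude`.
#' @export
tidy.global_decay_fit <- function(x, ...) {
  x$amplitudes |>
    tidyr::pivot_longer(-"record",
      names_to = "species", names_prefix = "amp_",
      names_transform = as.integer, values_to = "amplitude"
    ) |>
    dplyr::mutate(lifetime = x$shared_lifetimes[.data$species], .before = "amplitude")
}

#' @rdname tidy.global_decay_fit
#' @export
glance.global_decay_fit <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    n_components = length(x$shared_lifetimes),
    chi2_reduced_global = x$chi2_reduced_global,
    converged = x$converged
  )
}

#' Tidy a binding fit
#'
#' @param x A [fit_binding_curve()] result.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "fret_max"),
    estimate = c(x$kd, x$fret_max),
    std.error = c(x$kd_se, x$fret_max_se)
  )
}

#' @rdname tidy.binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(
    kd = x$kd, kd_se = x$kd_se,
    fret_max = x$fret_max, fret_max_se = x$fret_max_se,
    is_bound_only = x$is_bound_only,
    resolvable_limit = x$resolvable_limit,
    n_records = x$n_records,
    converged = x$converged
  )
}

#' Tidy an acceptor-multiplicity fit
#'
#' @param x A [fit_acceptor_multiplicity()] result.
#' @param ... Unused.
#' @return The per-candidate model-comparison table.
#' @export
tidy.bleach_fit <- function(x, ...) {
  x$model_comparison
}

#' @rdname tidy.bleach_fit
#' @export
glance.bleach_fit <- function(x, ...) {
  tibble::tibble(
    inferred_multiplicity = x$inferred_multiplicity,
    best_n = x$best_n,
    e_single = x$e_single,
    free_fraction = x$free_fraction,
    curvature_stat = x$curvature_stat,
    model_comparison_score = x$model_comparison_score
  )
}
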