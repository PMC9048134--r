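# ggplot2 visualization methods for the result classes.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decay fit
#'
#' Decay histogram with the fitted multi-exponential model overlaid on a
#' log count axis, plus a weighted-residual panel underneath the spirit of
#' conventional TCSPC software output.
#'
#' @param object A [fit_decay()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  d <- object$histogram |>
    dplyr::mutate(
      model = object$model_counts,
      residual = (.data$counts - .data$model) / sqrt(pmax(.data$counts, 1))
    ) |>
    dplyr::filter(.data$time_ns > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ns)) +
    ggplot2::geom_point(ggplot2::aes(y = pmax(.data$counts, 0.5)),
      size = 0.3, alpha = 0.4
    ) +
    ggplot2::geom_line(ggplot2::aes(y = pmax(.data$model, 0.5)),
      color = "red", linewidth = 0.4
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (ns)", y = "photons / channel",
      title = sprintf(
        "%d-component fit, chi2_red = %.3f",
        nrow(object$components), object$chi2_reduced
      )
    )
}

#' Plot a binding fit
#'
#' Per-cell observed FRET against acceptor intensity (log axis) with the
#' fitted hyperbola.
#'
#' @param object A [fit_binding_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binding_fit <- function(object, ...) {
  d <- object$records
  grid <- tibble::tibble(
    acceptor = exp(seq(log(max(min(d$acceptor), 1e-6)), log(max(d$acceptor)),
      length.out = 200L
    ))
  )
  grid$fret <- object$fret_max * grid$acceptor / (object$kd + grid$acceptor)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$acceptor, y = .data$fret)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = grid, color = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "acceptor intensity (AU)", y = "observed FRET",
      title = as.character(report_kd_bound(object))
    )
}

#' Plot an acceptor-multiplicity fit
#'
#' Normalized donor-versus-acceptor trajectory with the fitted candidate
#' forward curves; curvature distinguishes single- from multi-acceptor
#' complexes.
#'
#' @param object A [fit_acceptor_multiplicity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bleach_fit <- function(object, ...) {
  d <- object$series
  a_max <- max(d$acceptor)
  curves <- purrr::map_dfr(seq_len(nrow(object$model_comparison)), function(i) {
    row <- object$model_comparison[i, ]
    predict_bleach_curve(row$n_acceptors, max(row$e_single, 1e-3)) |>
      dplyr::mutate(candidate = factor(row$n_acceptors))
  })
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = d,
      ggplot2::aes(x = .data$acceptor / a_max, y = .data$donor / max(.data$donor))
    ) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(
        x = .data$acceptor, y = .data$donor / max(.data$donor),
        color = .data$candidate
      )
    ) +
    ggplot2::labs(
      x = "acceptor (normalized)", y = "donor (normalized)",
      color = "acceptors",
      title = sprintf("inferred multiplicity: %s", object$inferred_multiplicity)
    )
}

#' Plot a species-population curve
#'
#' @param curve Output of [species_population_curve()].
#' @return A ggplot object.
#' @export
plot_species_curve <- function(curve) {
  ggplot2::ggplot(
    curve,
    ggplot2::aes(
      x = .data$bin_center, y = .data$mean_amplitude,
      color = .data$species, group = .data$species
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "bin center", y = "mean amplitude fraction", color = "species"
    )
}

#' Plot a FLIM lifetime map
#'
#' @param object A [pixel_lifetime_map()] result.
#' @param ... Unused.
#' @return A ggplot object (raster of per-pixel lifetimes; undefined
#'   pixels are blank).
#' @export
autoplot.lifetime_map <- function(object, ...) {
  d <- expand.grid(
    row = seq_len(nrow(object$lifetime)),
    col = seq_len(ncol(object$lifetime))
  )
  d$lifetime <- as.vector(object$lifetime)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$lifetime)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "tau (ns)")
}
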