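# Plain-text readers/writers for the pipeline's tabular inputs.

#' Read and write decay histograms as CSV with a JSON sidecar
#'
#' The on-disk format is a two-column CSV (`channel`, `counts`) plus a
#' JSON sidecar (`<path>.json`) holding `channel_width_ps` and
#' `origin_channel`.
#'
#' @param histogram A [decay_histogram()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `path` invisibly (writer); a `decay_histogram` (reader).
#' @export
write_decay_csv <- function(histogram, path) {
  h <- as_decay_histogram(histogram)
  readr::write_csv(h[, c("channel", "counts")], path)
  jsonlite::write_json(
    list(
      channel_width_ps = attr(h, "channel_width_ps"),
      origin_channel = attr(h, "origin_channel")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar)
  } else {
    list(channel_width_ps = 16, origin_channel = 1L)
  }
  as_decay_histogram(d,
    channel_width_ps = meta$channel_width_ps,
    origin_channel = as.integer(meta$origin_channel)
  )
}

#' Read or write a bleach series CSV
#'
#' Columns `step`, `donor`, `acceptor`.
#'
#' @param series Bleach-series tibble.
#' @param path CSV path.
#' @export
write_bleach_csv <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series)[, c("step", "donor", "acceptor")], path)
  invisible(path)
}

#' @rdname write_bleach_csv
#' @export
read_bleach_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("step", "donor", "acceptor") %in% names(d))) {
    rlang::abort("Bleach-series CSV needs columns step, donor, acceptor.")
  }
  d
}

#' Read or write a cell-population CSV
#'
#' Columns `cell`, `acceptor`, `fret`, `tau_avg`, and optionally the
#' species amplitudes `amp_donor`, `amp_medium`, `amp_high`.
#'
#' @param records Cell-record tibble.
#' @param path CSV path.
#' @export
write_population_csv <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("acceptor", "fret") %in% names(d))) {
    rlang::abort("Cell-population CSV needs at least columns acceptor, fret.")
  }
  d
}

#' Write a decay or binding fit as JSON
#'
#' @param fit A `decay_fit`, `global_decay_fit`, `binding_fit` or
#'   `bleach_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  payload <- if (inherits(fit, "decay_fit")) {
    list(
      components = as.data.frame(fit$components),
      chi2_reduced = fit$chi2_reduced,
      n_photons = fit$n_photons,
      converged = fit$converged
    )
  } else if (inherits(fit, "global_decay_fit")) {
    list(
      shared_lifetimes = fit$shared_lifetimes,
      amplitudes = as.data.frame(fit$amplitudes),
      chi2_reduced_global = fit$chi2_reduced_global,
      converged = fit$converged
    )
  } else if (inherits(fit, "binding_fit")) {
    as.list(glance(fit))
  } else if (inherits(fit, "bleach_fit")) {
    c(as.list(glance(fit)), list(model_comparison = as.data.frame(fit$model_comparison)))
  } else {
    rlang::abort("Unsupported fit class.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
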