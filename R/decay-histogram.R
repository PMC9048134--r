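#' TCSPC decay histograms
#'
#' A decay histogram stores binned photon arrival delays after pulsed
#' excitation: one row per time channel with the channel index, the bin
#' mid-point delay in ns, and the photon count. The channel width (ps) and
#' the origin channel (index of excitation time zero, 1 by default) travel
#' as attributes so the object is self-describing.
#'
#' @param counts Non-negative numeric vector of per-channel photon counts
#'   (real-valued counts are allowed: noiseless expected histograms use them).
#' @param channel_width_ps Channel width in picoseconds (default 16 ps,
#'   typical for photon-counting hardware).
#' @param origin_channel Index of the channel corresponding to time zero.
#' @return A tibble of class `decay_histogram` with columns `channel`,
#'   `time_ns`, `counts`.
#' @export
#' @examples
#' h <- decay_histogram(c(100, 90, 81), channel_width_ps = 16)
#' n_photons(h)
decay_histogram <- function(counts, channel_width_ps = 16, origin_channel = 1L) {
  if (!is.numeric(counts) || length(counts) < 1L) {
    rlang::abort("`counts` must be a numeric vector with at least one channel.")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    rlang::abort("`counts` must be finite and non-negative.")
  }
  check_scalar(channel_width_ps, "channel_width_ps", lower = 0, closed_lower = FALSE)
  origin_channel <- check_count(origin_channel, "origin_channel", lower = 1L)
  if (origin_channel > length(counts)) {
    rlang::abort("`origin_channel` lies beyond the last channel.")
  }
  dt_ns <- channel_width_ps / 1000
  out <- tibble::tibble(
    channel = seq_along(counts),
    time_ns = (seq_along(counts) - origin_channel + 0.5) * dt_ns,
    counts = as.numeric(counts)
  )
  attr(out, "channel_width_ps") <- channel_width_ps
  attr(out, "origin_channel") <- origin_channel
  class(out) <- c("decay_histogram", class(out))
  out
}

#' @rdname decay_histogram
#' @param x A `decay_histogram`.
#' @export
n_photons <- function(x) {
  sum(as_decay_histogram(x)$counts)
}

#' Coerce a data frame to a decay histogram
#'
#' Accepts an existing `decay_histogram` or any data frame with `channel`
#' and `counts` columns (as read from a two-column CSV).
#'
#' @param x Object to coerce.
#' @param channel_width_ps,origin_channel Metadata used when `x` carries none.
#' @return A `decay_histogram`.
#' @export
as_decay_histogram <- function(x, channel_width_ps = 16, origin_channel = 1L) {
  if (inherits(x, "decay_histogram")) {
    return(x)
  }
  x <- tibble::as_tibble(x)
  if (!all(c("channel", "counts") %in% names(x))) {
    rlang::abort("Need columns `channel` and `counts` to build a decay histogram.")
  }
  x <- dplyr::arrange(x, .data$channel)
  decay_histogram(x$counts,
    channel_width_ps = channel_width_ps,
    origin_channel = origin_channel
  )
}

channel_width_ns <- function(h) attr(h, "channel_width_ps") / 1000

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf(
    "<decay_histogram: %d channels x %g ps, %.0f photons>\n",
    nrow(x), attr(x, "channel_width_ps"), sum(x$counts)
  ))
  NextMethod()
}
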