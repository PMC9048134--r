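# Conversions among lifetimes, FRET efficiencies, distances and relative
# concentrations. Efficiencies are kept as fractions throughout; rounding
# to percent happens only when reporting.

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_DA / tau_D`, the observed FRET of a quenched donor
#' relative to the donor-alone reference lifetime.
#'
#' @param tau_da Donor lifetime in presence of acceptor (ns), vectorized.
#' @param tau_d Donor-alone lifetime (ns), default 3.46 (the fusion-construct
#'   reference; 3.51 is the non-fusion fluorophore value).
#' @return Efficiency fraction(s) in `[0, 1)`.
#' @export
#' @examples
#' fret_efficiency(0.8, 3.46) # ~0.769, i.e. 77%
fret_efficiency <- function(tau_da, tau_d = 3.46) {
  if (any(!is.finite(tau_da)) || any(tau_da <= 0)) {
    rlang::abort("`tau_da` must be positive and finite (ns).")
  }
  check_scalar(tau_d, "tau_d", lower = 0, closed_lower = FALSE)
  if (any(tau_da > tau_d + 1e-12)) {
    rlang::abort(
      "`tau_da` exceeds `tau_d`: negative FRET usually signals a mis-paired donor reference."
    )
  }
  pmax(1 - tau_da / tau_d, 0)
}

#' Donor-acceptor distance from FRET efficiency
#'
#' `R = R0 * (1/E - 1)^(1/6)` with the Forster distance `R0` (63.34 A for
#' the donor/acceptor pair used here, assuming an orientation factor
#' kappa^2 = 2/3). Strictly decreasing in `E`.
#'
#' @param e Efficiency fraction(s), strictly inside `(0, 1)`.
#' @param r0 Forster distance in Angstrom (default 63.34).
#' @return Distance(s) in Angstrom.
#' @export
#' @examples
#' fret_distance(0.5) # equals R0
fret_distance <- function(e, r0 = 63.34) {
  check_scalar(r0, "r0", lower = 0, closed_lower = FALSE)
  if (any(!is.finite(e))) rlang::abort("`e` must be finite.")
  if (any(e <= 0)) {
    rlang::abort("`e` must be > 0: zero efficiency implies infinite separation.")
  }
  if (any(e >= 1)) {
    rlang::abort("`e` must be < 1: unit efficiency implies zero separation.")
  }
  r0 * (1 / e - 1)^(1 / 6)
}

#' Relative protein concentration from average FRET
#'
#' Inverts the hyperbolic binding curve: with
#' `FRET = FRET_max * [A] / (K_D + [A])`, the acceptor concentration index
#' is `[A] = K_D * E / (FRET_max - E)` (arbitrary units).
#'
#' @param e_avg Average observed FRET fraction(s), `0 <= e_avg < fret_max`.
#' @param kd Apparent dissociation constant (AU, > 0).
#' @param fret_max Maximal FRET at saturating concentration (default 0.7447).
#' @return Concentration(s) in AU.
#' @export
#' @examples
#' fret_concentration(0.7447 / 2, kd = 5) # half-maximal FRET -> K_D
fret_concentration <- function(e_avg, kd, fret_max = 0.7447) {
  check_scalar(kd, "kd", lower = 0, closed_lower = FALSE)
  check_scalar(fret_max, "fret_max", lower = 0, upper = 1, closed_upper = FALSE)
  if (any(!is.finite(e_avg)) || any(e_avg < 0)) {
    rlang::abort("`e_avg` must be finite and non-negative.")
  }
  if (any(e_avg >= fret_max)) {
    rlang::abort("`e_avg` at or above `fret_max`: saturated FRET, concentration unbounded.")
  }
  kd * e_avg / (fret_max - e_avg)
}

#' Species population versus lifetime or concentration
#'
#' Bins per-cell three-species amplitude fractions (donor-only / medium /
#' high FRET) along either the amplitude-weighted lifetime axis or the
#' concentration axis (via [fret_concentration()]), and reports per-bin
#' mean amplitudes -- the concentration-dependent assembly profile of the
#' FRET species.
#'
#' @param records Cell-record tibble with columns `tau_avg`, `fret`, and
#'   amplitude columns `amp_donor`, `amp_medium`, `amp_high`. Records with
#'   missing amplitudes are skipped (count reported via a message).
#' @param by Binning axis: `"tau_avg"` or `"concentration"`.
#' @param n_bins Number of equal-occupancy bins (default 12).
#' @param kd,fret_max Binding parameters used when `by = "concentration"`.
#' @return A tibble with one row per bin and species: `bin`, `bin_center`,
#'   `n_cells`, `species`, `mean_amplitude`.
#' @export
species_population_curve <- function(records, by = c("tau_avg", "concentration"),
                                     n_bins = 12L, kd = 5.0, fret_max = 0.7447) {
  by <- match.arg(by)
  n_bins <- check_count(n_bins, "n_bins", lower = 1L)
  records <- tibble::as_tibble(records)
  amp_cols <- c("amp_donor", "amp_medium", "amp_high")
  if (!all(amp_cols %in% names(records))) {
    rlang::abort("`records` must carry amplitude columns amp_donor/amp_medium/amp_high.")
  }
  ok <- stats::complete.cases(records[, amp_cols])
  if (any(!ok)) {
    rlang::inform(sprintf("Skipping %d record(s) with missing amplitudes.", sum(!ok)))
    records <- records[ok, ]
  }
  if (nrow(records) == 0L) rlang::abort("No records with complete amplitudes.")
  bad_sum <- abs(records$amp_donor + records$amp_medium + records$amp_high - 1) > 1e-6
  if (any(bad_sum)) {
    rlang::abort("Per-record amplitudes must sum to 1.")
  }
  axis <- switch(by,
    tau_avg = records$tau_avg,
    concentration = fret_concentration(
      pmin(records$fret, fret_max * (1 - 1e-9)),
      kd = kd, fret_max = fret_max
    )
  )
  records$.axis <- axis
  # equal-occupancy bins; duplicated quantiles collapse for degenerate axes
  brks <- unique(stats::quantile(axis, probs = seq(0, 1, length.out = n_bins + 1L)))
  records$.bin <- if (length(brks) > 2L) {
    cut(axis, breaks = brks, include.lowest = TRUE, labels = FALSE)
  } else {
    1L
  }
  records |>
    dplyr::group_by(bin = .data$.bin) |>
    dplyr::summarise(
      bin_center = stats::median(.data$.axis),
      n_cells = dplyr::n(),
      amp_donor = mean(.data$amp_donor),
      amp_medium = mean(.data$amp_medium),
      amp_high = mean(.data$amp_high),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(
      dplyr::all_of(amp_cols),
      names_to = "species", names_prefix = "amp_",
      values_to = "mean_amplitude"
    ) |>
    dplyr::mutate(
      species = factor(.data$species, levels = c("donor", "medium", "high"))
    ) |>
    dplyr::arrange(.data$species, .data$bin)
}
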