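#' Simulate a TCSPC decay histogram
#'
#' Draws photon arrival delays from an amplitude-weighted mixture of
#' exponential decays (plus an optional uniform background fraction) and
#' bins them into fixed-width time channels, emulating a photon-counting
#' record. Signal photons arriving after the measurement window are lost,
#' so the histogram total can fall slightly short of `n_photons`.
#'
#' @param components Component table (see [decay_components()]): lifetimes in
#'   ns with amplitude fractions summing to 1.
#' @param n_photons Number of photons to draw (typically ~1e6 per record).
#' @param n_channels Number of time channels (default 3840, a 61.44 ns window
#'   at 16 ps).
#' @param channel_width_ps Channel width in ps (default 16).
#' @param background_fraction Fraction of photons drawn uniformly over the
#'   window (default 0).
#' @param irf_sigma_ps Standard deviation (ps) of an optional Gaussian
#'   instrument-response jitter convolved onto the arrival times; 0 (the
#'   default) gives the delta-IRF model under which the fitter operates.
#' @param seed Integer seed; identical arguments and seed give identical
#'   histograms.
#' @return A [decay_histogram()].
#' @export
#' @examples
#' h <- simulate_decay(decay_components(3.46, 1), n_photons = 1e4, seed = 1)
simulate_decay <- function(components, n_photons,
                           n_channels = 3840L, channel_width_ps = 16,
                           background_fraction = 0, irf_sigma_ps = 0, seed) {
  components <- check_components(components)
  n_photons <- check_count(n_photons, "n_photons", lower = 0L)
  n_channels <- check_count(n_channels, "n_channels", lower = 1L)
  check_scalar(channel_width_ps, "channel_width_ps", lower = 0, closed_lower = FALSE)
  check_scalar(background_fraction, "background_fraction",
    lower = 0, upper = 1, closed_upper = FALSE
  )
  check_scalar(irf_sigma_ps, "irf_sigma_ps", lower = 0)
  dt <- channel_width_ps / 1000
  window <- n_channels * dt
  counts <- with_seed(seed, {
    if (n_photons == 0L) {
      numeric(n_channels)
    } else {
      n_bg <- stats::rbinom(1L, n_photons, background_fraction)
      n_sig <- n_photons - n_bg
      comp <- sample.int(nrow(components), n_sig,
        replace = TRUE, prob = components$amplitude
      )
      t_sig <- stats::rexp(n_sig, rate = 1 / components$lifetime[comp])
      if (irf_sigma_ps > 0) {
        t_sig <- t_sig + stats::rnorm(n_sig, 0, irf_sigma_ps / 1000)
        t_sig <- t_sig[t_sig >= 0]
      }
      t_bg <- stats::runif(n_bg, 0, window)
      t_all <- c(t_sig, t_bg)
      t_all <- t_all[t_all < window]
      tabulate(pmin(floor(t_all / dt) + 1L, n_channels), nbins = n_channels)
    }
  })
  decay_histogram(counts, channel_width_ps = channel_width_ps)
}

#' Noiseless expected decay histogram
#'
#' Exact expected per-channel counts of the mixture model used by
#' [simulate_decay()]: the integral of the decay density over each channel,
#' scaled to `n_photons`. Useful as a zero-noise oracle for fitter
#' round-trips; the returned counts are real-valued.
#'
#' @inheritParams simulate_decay
#' @return A [decay_histogram()] with real-valued counts.
#' @export
expected_decay <- function(components, n_photons,
                           n_channels = 3840L, channel_width_ps = 16,
                           background_fraction = 0) {
  components <- check_components(components)
  check_scalar(n_photons, "n_photons", lower = 0)
  n_channels <- check_count(n_channels, "n_channels", lower = 1L)
  check_scalar(channel_width_ps, "channel_width_ps", lower = 0, closed_lower = FALSE)
  check_scalar(background_fraction, "background_fraction",
    lower = 0, upper = 1, closed_upper = FALSE
  )
  dt <- channel_width_ps / 1000
  edges <- (0:n_channels) * dt
  # bin mass per component: exp(-t_lo/tau) - exp(-t_hi/tau)
  mass <- vapply(seq_len(nrow(components)), function(j) {
    e <- exp(-edges / components$lifetime[j])
    components$amplitude[j] * (e[-length(e)] - e[-1])
  }, numeric(n_channels))
  counts <- n_photons * (
    (1 - background_fraction) * rowSums(mass) +
      background_fraction / n_channels
  )
  decay_histogram(counts, channel_width_ps = channel_width_ps)
}

#' Simulate a progressive acceptor-photobleaching trajectory
#'
#' Emulates the stepwise acceptor-selective photobleaching experiment: a
#' population of complexes each carries `n_acceptors` acceptors; at every
#' bleach step each surviving acceptor independently survives with
#' probability `step_survival`. The donor intensity of a complex with `k`
#' surviving acceptors is `1 - E_k`, where `E_k` is the k-acceptor FRET
#' efficiency of the additive-rate model (see [predict_bleach_curve()]);
#' donors are never bleached. Population sums are reported with
#' multiplicative Gaussian noise.
#'
#' @param n_acceptors Acceptors per complex (>= 0; 0 gives a no-FRET
#'   control with a flat donor trace).
#' @param e_single Single-acceptor FRET efficiency in `[0, 1)`.
#' @param n_steps Number of bleach steps (default 50); the series includes
#'   the pre-bleach point, so it has `n_steps + 1` rows.
#' @param step_survival Per-acceptor survival probability per step, in
#'   `(0, 1]`.
#' @param n_complexes Number of complexes in the population.
#' @param noise_sd Standard deviation of the multiplicative Gaussian noise
#'   applied to the donor and acceptor sums (fraction; 0 = noiseless).
#' @param seed Integer seed.
#' @return A tibble with columns `step`, `donor`, `acceptor` (class
#'   `bleach_series`). Intensities are in complex units: `acceptor` is the
#'   number of surviving acceptors, `donor` sums `1 - E_k` over complexes.
#' @export
simulate_bleach_series <- function(n_acceptors, e_single, n_steps = 50L,
                                   step_survival = 0.93, n_complexes = 1000L,
                                   noise_sd = 0.02, seed) {
  n_acceptors <- check_count(n_acceptors, "n_acceptors", lower = 0L)
  check_scalar(e_single, "e_single", lower = 0, upper = 1, closed_upper = FALSE)
  n_steps <- check_count(n_steps, "n_steps", lower = 1L)
  check_scalar(step_survival, "step_survival",
    lower = 0, upper = 1, closed_lower = FALSE
  )
  n_complexes <- check_count(n_complexes, "n_complexes", lower = 1L)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    k <- rep.int(n_acceptors, n_complexes) # surviving acceptors per complex
    rows <- vector("list", n_steps + 1L)
    for (s in 0:n_steps) {
      if (s > 0L && step_survival < 1) {
        k <- stats::rbinom(n_complexes, k, step_survival)
      }
      donor <- sum(1 - k_acceptor_efficiency(k, e_single))
      acceptor <- sum(k)
      if (noise_sd > 0) {
        donor <- donor * (1 + stats::rnorm(1L, 0, noise_sd))
        acceptor <- acceptor * (1 + stats::rnorm(1L, 0, noise_sd))
      }
      rows[[s + 1L]] <- tibble::tibble(
        step = s, donor = max(donor, 0), acceptor = max(acceptor, 0)
      )
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("bleach_series", class(out))
    out
  })
}

#' Simulate a cell population on the hyperbolic FRET binding curve
#'
#' Each cell's acceptor fluorescence (the index of protein concentration,
#' in arbitrary units) is drawn log-uniformly over `expression_range`; its
#' observed FRET follows the hyperbola
#' `FRET = fret_max * [A] / (kd + [A])` plus Gaussian noise (clipped to
#' `[0, 1)`), and the amplitude-weighted lifetime is derived as
#' `tau_avg = tau_donor * (1 - FRET)`.
#'
#' @param n_cells Number of cells (>= 1).
#' @param expression_range Length-2 numeric, log-uniform range of acceptor
#'   intensity in AU (default `c(0.1, 50)`, a 500-fold spread).
#' @param kd Apparent dissociation constant in AU (> 0).
#' @param fret_max Maximal FRET efficiency, in `[0, 1)` (default 0.7447).
#' @param fret_noise_sd SD of additive Gaussian FRET noise (default 0.05).
#' @param tau_donor Donor-alone lifetime in ns (default 3.46).
#' @param seed Integer seed.
#' @return A tibble of cell records: `cell`, `acceptor`, `fret`, `tau_avg`.
#' @export
simulate_cell_population <- function(n_cells, expression_range = c(0.1, 50),
                                     kd, fret_max = 0.7447,
                                     fret_noise_sd = 0.05,
                                     tau_donor = 3.46, seed) {
  n_cells <- check_count(n_cells, "n_cells", lower = 1L)
  if (length(expression_range) != 2L || any(expression_range <= 0) ||
    expression_range[2] < expression_range[1]) {
    rlang::abort("`expression_range` must be an increasing positive pair (AU).")
  }
  check_scalar(kd, "kd", lower = 0, closed_lower = FALSE)
  check_scalar(fret_max, "fret_max", lower = 0, upper = 1, closed_upper = FALSE)
  check_scalar(fret_noise_sd, "fret_noise_sd", lower = 0)
  check_scalar(tau_donor, "tau_donor", lower = 0, closed_lower = FALSE)
  with_seed(seed, {
    a <- exp(stats::runif(
      n_cells, log(expression_range[1]), log(expression_range[2])
    ))
    fret <- fret_max * a / (kd + a)
    if (fret_noise_sd > 0) {
      fret <- fret + stats::rnorm(n_cells, 0, fret_noise_sd)
    }
    fret <- pmin(pmax(fret, 0), 1 - 1e-12)
    tibble::tibble(
      cell = seq_len(n_cells),
      acceptor = a,
      fret = fret,
      tau_avg = tau_donor * (1 - fret)
    )
  })
}

#' Simulate a FLIM stack of per-pixel decay histograms
#'
#' Every pixel of the input lifetime map receives an independent simulated
#' mono-exponential decay with that pixel's lifetime, binned on a common
#' channel grid. The result is a 3-D array (rows x cols x channels) with
#' the channel width attached, the in-memory analogue of a multi-page TIFF
#' time stack.
#'
#' @param region_lifetime_map Numeric matrix of lifetimes in ns (all > 0).
#' @param photons_per_pixel Photons recorded in every pixel (>= 0).
#' @param n_channels,channel_width_ps Channel grid (defaults 256 channels of
#'   16 ps; pixel decays need fewer channels than point TCSPC records).
#' @param seed Integer seed.
#' @return A 3-D array of class `flim_stack` with attribute
#'   `channel_width_ps`.
#' @export
simulate_flim_stack <- function(region_lifetime_map, photons_per_pixel,
                                n_channels = 256L, channel_width_ps = 16,
                                seed) {
  if (!is.matrix(region_lifetime_map) || !is.numeric(region_lifetime_map)) {
    rlang::abort("`region_lifetime_map` must be a numeric matrix of lifetimes (ns).")
  }
  if (any(!is.finite(region_lifetime_map)) || any(region_lifetime_map <= 0)) {
    rlang::abort("All lifetimes in `region_lifetime_map` must be positive.")
  }
  photons_per_pixel <- check_count(photons_per_pixel, "photons_per_pixel", lower = 0L)
  n_channels <- check_count(n_channels, "n_channels", lower = 1L)
  check_scalar(channel_width_ps, "channel_width_ps", lower = 0, closed_lower = FALSE)
  dt <- channel_width_ps / 1000
  window <- n_channels * dt
  dims <- dim(region_lifetime_map)
  with_seed(seed, {
    stack <- array(0, dim = c(dims[1], dims[2], n_channels))
    for (i in seq_len(dims[1])) {
      for (j in seq_len(dims[2])) {
        if (photons_per_pixel > 0L) {
          t <- stats::rexp(photons_per_pixel, rate = 1 / region_lifetime_map[i, j])
          t <- t[t < window]
          stack[i, j, ] <- tabulate(floor(t / dt) + 1L, nbins = n_channels)
        }
      }
    }
    attr(stack, "channel_width_ps") <- channel_width_ps
    class(stack) <- c("flim_stack", class(stack))
    stack
  })
}

#' Simulate a cell population under the mass-action assembly model
#'
#' Couples the expression spread of [simulate_cell_population()] to the
#' equilibrium assembly model ([equilibrium_species()]): each cell's total
#' catalytic-subunit and regulatory-micropeptide concentrations are set by
#' its log-uniform expression level, the equilibrium species are solved,
#' and the three-species decay amplitudes (donor-only / single-acceptor /
#' multi-acceptor) follow from [assembly_to_fret_species()]. The cell's
#' `tau_avg` and `fret` are then the amplitude-weighted mixtures of the
#' species lifetimes.
#'
#' @param n_cells Number of cells.
#' @param expression_range Log-uniform range of total catalytic-subunit
#'   concentration in AU.
#' @param acceptor_ratio Acceptor-labeled micropeptide expressed per
#'   catalytic subunit (default 5, the transfection ratio the generator
#'   emulates).
#' @param kd_alpha_plm,kd_alpha_alpha,kd_plm_tetramer Equilibrium constants
#'   in AU passed to [equilibrium_species()]; `kd_alpha_alpha = Inf`
#'   disables dimerization (single-acceptor regime).
#' @param species_lifetimes Length-3 lifetimes (ns) of the donor-only,
#'   medium- and high-FRET species (default `c(3.46, 1.8, 0.8)`).
#' @param acceptor_label_fraction Fraction of micropeptide carrying an
#'   acceptor label (default 1; lower values model unlabeled competitor).
#' @param fret_noise_sd SD of additive noise on observed FRET.
#' @param tau_donor Donor-alone lifetime (ns).
#' @param seed Integer seed.
#' @return A tibble of cell records with columns `cell`, `acceptor`, `fret`,
#'   `tau_avg`, `amp_donor`, `amp_medium`, `amp_high`.
#' @export
simulate_assembly_population <- function(n_cells, expression_range = c(0.05, 20),
                                         acceptor_ratio = 5,
                                         kd_alpha_plm = 5.0,
                                         kd_alpha_alpha = 1.2,
                                         kd_plm_tetramer = Inf,
                                         species_lifetimes = c(3.46, 1.8, 0.8),
                                         acceptor_label_fraction = 1,
                                         fret_noise_sd = 0,
                                         tau_donor = 3.46, seed) {
  n_cells <- check_count(n_cells, "n_cells", lower = 1L)
  if (length(species_lifetimes) != 3L || any(species_lifetimes <= 0)) {
    rlang::abort("`species_lifetimes` must be three positive lifetimes (ns).")
  }
  with_seed(seed, {
    x <- exp(stats::runif(
      n_cells, log(expression_range[1]), log(expression_range[2])
    ))
    amps <- purrr::map(x, function(total_alpha) {
      st <- equilibrium_species(
        total_alpha = total_alpha,
        total_plm = acceptor_ratio * total_alpha,
        kd_alpha_plm = kd_alpha_plm,
        kd_alpha_alpha = kd_alpha_alpha,
        kd_plm_tetramer = kd_plm_tetramer
      )
      assembly_to_fret_species(
        st,
        labeling_fractions = list(donor = 1, acceptor = acceptor_label_fraction)
      )
    })
    amp <- do.call(rbind, amps)
    tau_avg <- as.numeric(amp %*% species_lifetimes)
    fret <- 1 - tau_avg / tau_donor
    if (fret_noise_sd > 0) {
      fret <- pmin(pmax(fret + stats::rnorm(n_cells, 0, fret_noise_sd), 0), 1 - 1e-12)
      tau_avg <- tau_donor * (1 - fret) # keep fret/tau_avg consistent
    }
    tibble::tibble(
      cell = seq_len(n_cells),
      acceptor = x * acceptor_ratio,
      fret = fret,
      tau_avg = tau_avg,
      amp_donor = amp[, 1],
      amp_medium = amp[, 2],
      amp_high = amp[, 3]
    )
  })
}
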