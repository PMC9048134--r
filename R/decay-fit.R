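# Poisson maximum-likelihood decomposition of TCSPC decay histograms.
#
# The per-channel model is a multinomial over the measurement window:
#   p_i  proportional to  (1 - bg) * sum_j a_j * q_ij  +  bg / n_channels
# where q_ij is the mass of an exponential with lifetime tau_j in channel i.
# Minimizing the C-statistic 2 * sum(m_i - c_i + c_i log(c_i / m_i)) with
# m_i = N_total * p_i is equivalent to Poisson ML conditioned on the total.
# Counts span orders of magnitude, which is why least squares is avoided.

# per-component channel masses on the bin edges grid; columns sum to ~1
component_bin_mass <- function(lifetimes, n_channels, dt) {
  edges <- (0:n_channels) * dt
  vapply(lifetimes, function(tau) {
    e <- exp(-edges / tau)
    e[-length(e)] - e[-1]
  }, numeric(n_channels))
}

softmax <- function(z) {
  z <- c(0, z) # first amplitude is the reference
  e <- exp(z - max(z))
  e / sum(e)
}

# C-statistic (2x negative Poisson log-likelihood up to a constant)
cstat <- function(counts, model) {
  model <- pmax(model, 1e-300)
  pos <- counts > 0
  2 * (sum(model - counts) + sum(counts[pos] * log(counts[pos] / model[pos])))
}

# Reduced chi-squared with Pearson weights (expected counts), restricted
# to channels where the model predicts at least one photon. Pearson
# weighting keeps the per-channel expectation at exactly 1 under Poisson
# noise at any count level; the >= 1 floor excludes far-tail channels
# whose near-zero expectations would otherwise make the statistic
# heavy-tailed.
chi2_reduced_stat <- function(counts, model, n_par) {
  keep <- model >= 1
  dof <- max(sum(keep) - n_par, 1L)
  sum((counts[keep] - model[keep])^2 / model[keep]) / dof
}

#' Fit exponential decay components to a TCSPC histogram
#'
#' Maximum-likelihood multi-exponential fitting under Poisson counting
#' statistics. Lifetimes listed in `fixed_lifetimes` are held constant
#' (e.g. a donor-alone reference of 3.46 ns in mixed records); remaining
#' lifetimes and all amplitude fractions are free. Free lifetimes are
#' initialized log-spaced over `[channel width, window / 3]` and the fit is
#' restarted once from perturbed initials if it fails to converge or when a
#' deterministic perturbed restart finds a better optimum.
#'
#' @param histogram A [decay_histogram()] (or data frame with `channel`,
#'   `counts`).
#' @param n_components Number of exponential species, 1--4.
#' @param fixed_lifetimes Optional numeric vector of lifetimes (ns) held
#'   fixed; must not exceed `n_components` entries.
#' @param background_fraction Known uniform background fraction (default 0,
#'   not fitted).
#' @return An object of class `decay_fit`: components sorted by descending
#'   lifetime, reduced chi-squared (Neyman weights, as conventional TCSPC
#'   software reports), photon count, convergence flag.
#' @export
#' @examples
#' h <- expected_decay(decay_components(3.46, 1), 1e6)
#' fit_decay(h, n_components = 1)
fit_decay <- function(histogram, n_components, fixed_lifetimes = NULL,
                      background_fraction = 0) {
  h <- as_decay_histogram(histogram)
  n_components <- check_count(n_components, "n_components", lower = 1L)
  if (n_components > 4L) {
    rlang::abort("`n_components` must be between 1 and 4.")
  }
  if (!is.null(fixed_lifetimes)) {
    if (any(fixed_lifetimes <= 0)) rlang::abort("Fixed lifetimes must be positive.")
    if (length(fixed_lifetimes) > n_components) {
      rlang::abort("More fixed lifetimes than components.")
    }
  }
  total <- sum(h$counts)
  if (total < 1e3) {
    rlang::abort("Histogram has fewer than 1000 photons; fit is not attempted.")
  }
  # crude identifiability guard: ~2 extra decades of photons per extra species
  if (total < 10^(2 + n_components)) {
    rlang::warn(sprintf(
      "%d components may not be identifiable from %.0f photons.",
      n_components, total
    ))
  }
  dt <- channel_width_ns(h)
  n_ch <- nrow(h)
  n_fixed <- length(fixed_lifetimes)
  n_free <- n_components - n_fixed
  window <- n_ch * dt

  objective <- function(par) {
    tau_free <- exp(par[seq_len(n_free)])
    amps <- if (n_components > 1L) softmax(par[n_free + seq_len(n_components - 1L)]) else 1
    q <- component_bin_mass(c(fixed_lifetimes, tau_free), n_ch, dt)
    p <- as.numeric(q %*% amps)
    p <- (1 - background_fraction) * p + background_fraction / n_ch
    cstat(h$counts, total * p / sum(p))
  }

  init_free <- if (n_free > 0L) {
    log(exp(seq(log(dt), log(window / 3), length.out = n_free + 2L))[-c(1L, n_free + 2L)])
  } else {
    numeric(0)
  }
  init <- c(init_free, rep(0, n_components - 1L))

  run <- function(start) {
    stats::nlminb(start, objective,
      control = list(iter.max = 1000L, eval.max = 4000L, rel.tol = 1e-10)
    )
  }
  opt <- run(init)
  # one deterministic restart from perturbed initials
  opt2 <- run(init + 0.35 * rep_len(c(1, -1), length(init)))
  if (opt2$objective < opt$objective - 1e-9 || opt$convergence != 0) {
    if (opt2$objective < opt$objective) opt <- opt2
  }
  # either run reporting success, or both independent starts agreeing on
  # the same optimum, counts as convergence (nlminb labels razor-flat
  # noiseless optima "singular convergence")
  converged <- opt$convergence == 0 || opt2$convergence == 0 ||
    abs(opt$objective - opt2$objective) <= 1e-8 * (abs(opt$objective) + 1) ||
    # a C-statistic far below one photon of misfit is a perfect fit,
    # whatever nlminb labels it
    max(opt$objective, opt2$objective) < 1e-2
  if (!converged) {
    rlang::warn("Decay fit did not report convergence; result is flagged.")
  }

  tau_free <- exp(opt$par[seq_len(n_free)])
  amps <- if (n_components > 1L) {
    softmax(opt$par[n_free + seq_len(n_components - 1L)])
  } else {
    1
  }
  lifetimes <- c(fixed_lifetimes, tau_free)
  q <- component_bin_mass(lifetimes, n_ch, dt)
  p <- as.numeric(q %*% amps)
  p <- (1 - background_fraction) * p + background_fraction / n_ch
  model <- total * p / sum(p)
  n_par <- n_free + (n_components - 1L)
  ord <- order(lifetimes, decreasing = TRUE)
  components <- tibble::tibble(
    lifetime = lifetimes[ord],
    amplitude = amps[ord],
    fixed = c(rep(TRUE, n_fixed), rep(FALSE, n_free))[ord]
  )
  structure(
    list(
      components = components,
      chi2_reduced = chi2_reduced_stat(h$counts, model, n_par),
      cstat = opt$objective,
      n_photons = total,
      n_par = n_par,
      fixed_lifetimes = fixed_lifetimes,
      background_fraction = background_fraction,
      converged = converged,
      model_counts = model,
      histogram = h
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit: %d component(s), chi2_red = %.4f, %.0f photons%s>\n",
    nrow(x$components), x$chi2_reduced, x$n_photons,
    if (x$converged) "" else ", NOT CONVERGED"
  ))
  print(x$components)
  invisible(x)
}

#' Choose the number of decay components by sequential fitting
#'
#' Fits 1 to `max_components` species and returns the smallest number for
#' which adding one more improves the reduced chi-squared by less than
#' `improvement_threshold` -- the residual/chi-squared stopping rule used
#' when deciding that a further species is unsupported by the data.
#'
#' @inheritParams fit_decay
#' @param max_components Largest model considered (default 4).
#' @param improvement_threshold Minimum chi2_red drop that justifies an
#'   extra component (default 0.02).
#' @return A list with `n_components` (the selection) and `fits` (all
#'   attempted `decay_fit` objects, indexed by component count).
#' @export
select_components <- function(histogram, max_components = 4L,
                              improvement_threshold = 0.02,
                              fixed_lifetimes = NULL) {
  max_components <- check_count(max_components, "max_components", lower = 1L)
  fits <- vector("list", max_components)
  ok <- logical(max_components)
  for (k in seq_len(max_components)) {
    fits[[k]] <- tryCatch(
      suppressWarnings(fit_decay(histogram, k,
        fixed_lifetimes = fixed_lifetimes[seq_len(min(k, length(fixed_lifetimes)))]
      )),
      error = function(e) NULL
    )
    ok[k] <- !is.null(fits[[k]])
  }
  if (!any(ok)) rlang::abort("All decay fits failed.")
  chi2 <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$chi2_reduced, 0)
  n_sel <- max_components
  for (k in seq_len(max_components - 1L)) {
    if (!is.na(chi2[k]) && !is.na(chi2[k + 1L]) &&
      (chi2[k] - chi2[k + 1L]) < improvement_threshold) {
      n_sel <- k
      break
    }
  }
  list(n_components = n_sel, fits = fits, chi2_reduced = chi2)
}

# per-record amplitude profile for a multinomial mixture with known
# component channel distributions (columns of qn must each sum to 1).
# The log-likelihood is concave in the amplitudes; a short EM warm-up
# followed by a logit-space quasi-Newton polish converges fast and gives
# the smooth, tightly-solved inner optimum the outer profile needs.
profile_amplitudes <- function(counts, qn, start = NULL) {
  k <- ncol(qn)
  a <- if (is.null(start)) rep(1 / k, k) else pmax(start, 1e-8)
  a <- a / sum(a)
  total <- sum(counts)
  pos <- counts > 0
  cp <- counts[pos]
  qp <- qn[pos, , drop = FALSE]
  for (it in 1:25) { # EM warm-up
    mix <- pmax(as.numeric(qp %*% a), 1e-300)
    a <- as.numeric(crossprod(qp / mix, cp)) * a / total
  }
  negll <- function(z) {
    aa <- softmax(z)
    -sum(cp * log(pmax(as.numeric(qp %*% aa), 1e-300)))
  }
  z0 <- log(pmax(a[-1], 1e-12)) - log(max(a[1], 1e-12))
  opt <- stats::nlminb(z0, negll,
    control = list(iter.max = 200L, eval.max = 600L, rel.tol = 1e-12)
  )
  list(amplitudes = softmax(opt$par), loglik = -opt$objective)
}

#' Global analysis of multiple decays with shared lifetimes
#'
#' Joint Poisson maximum likelihood over a batch of TCSPC records: all
#' records share the same set of lifetimes (the donor component held at
#' `fixed_donor_lifetime`, the FRET-species lifetimes free and common) and
#' each record has its own amplitude fractions. Amplitudes are profiled
#' out exactly by expectation-maximization inside an outer optimization
#' over the shared lifetimes.
#'
#' @param histograms List of [decay_histogram()] objects on identical
#'   channel grids (at least 2).
#' @param n_components Total number of species including the donor.
#' @param fixed_donor_lifetime Donor-alone lifetime held fixed (ns),
#'   default 3.46.
#' @return An object of class `global_decay_fit` with `shared_lifetimes`
#'   (descending, the fixed donor first), `amplitudes` (tibble: record x
#'   species), and `chi2_reduced_global`.
#' @export
global_fit <- function(histograms, n_components, fixed_donor_lifetime = 3.46) {
  if (!is.list(histograms) || length(histograms) < 1L) {
    rlang::abort("`histograms` must be a non-empty list of decay histograms.")
  }
  check_scalar(fixed_donor_lifetime, "fixed_donor_lifetime",
    lower = 0, closed_lower = FALSE
  )
  n_components <- check_count(n_components, "n_components", lower = 1L)
  hs <- lapply(histograms, as_decay_histogram)
  widths <- vapply(hs, function(h) attr(h, "channel_width_ps"), 0)
  sizes <- vapply(hs, nrow, 0L)
  if (length(unique(widths)) != 1L || length(unique(sizes)) != 1L) {
    rlang::abort("All histograms must share one channel grid (width and length).")
  }
  dt <- channel_width_ns(hs[[1]])
  n_ch <- nrow(hs[[1]])
  counts <- lapply(hs, function(h) h$counts)
  totals <- vapply(counts, sum, 0)
  n_free <- n_components - 1L
  window <- n_ch * dt
  amp_cache <- lapply(seq_along(hs), function(i) rep(1 / n_components, n_components))

  profile_obj <- function(log_tau_free) {
    tau <- c(fixed_donor_lifetime, exp(log_tau_free))
    q <- component_bin_mass(tau, n_ch, dt)
    qn <- sweep(q, 2, colSums(q), "/") # condition each species on the window
    ll <- 0
    for (i in seq_along(counts)) {
      em <- profile_amplitudes(counts[[i]], qn, start = amp_cache[[i]])
      amp_cache[[i]] <<- em$amplitudes
      ll <- ll + em$loglik
    }
    -ll
  }

  if (n_free > 0L) {
    # initialize shared lifetimes from a fit to the pooled histogram:
    # summing records preserves the species lifetimes (amplitudes pool)
    init <- tryCatch({
      pooled <- decay_histogram(Reduce(`+`, counts),
        channel_width_ps = attr(hs[[1]], "channel_width_ps")
      )
      pf <- suppressWarnings(
        fit_decay(pooled, n_components, fixed_lifetimes = fixed_donor_lifetime)
      )
      log(sort(pf$components$lifetime[!pf$components$fixed], decreasing = TRUE))
    }, error = function(e) {
      log(exp(seq(log(dt), log(window / 3), length.out = n_free + 2L))[-c(1L, n_free + 2L)])
    })
    opt <- stats::nlminb(init, profile_obj,
      control = list(iter.max = 400L, eval.max = 1500L, rel.tol = 1e-10)
    )
    tau_free <- exp(opt$par)
    converged <- opt$convergence == 0
  } else {
    tau_free <- numeric(0)
    profile_obj(numeric(0))
    converged <- TRUE
  }
  tau <- c(fixed_donor_lifetime, tau_free)
  q <- component_bin_mass(tau, n_ch, dt)
  qn <- sweep(q, 2, colSums(q), "/")
  # final tight amplitude pass + fit quality
  chi2_num <- 0
  dof <- 0
  amps <- matrix(0, length(counts), n_components)
  for (i in seq_along(counts)) {
    em <- profile_amplitudes(counts[[i]], qn, start = amp_cache[[i]])
    amps[i, ] <- em$amplitudes
    model <- totals[i] * as.numeric(qn %*% em$amplitudes)
    keep <- model >= 1
    chi2_num <- chi2_num + sum((counts[[i]][keep] - model[keep])^2 / model[keep])
    dof <- dof + sum(keep) - (n_components - 1L)
  }
  dof <- max(dof - n_free, 1L)
  ord <- order(tau, decreasing = TRUE)
  # keep the fixed donor identifiable in the output ordering
  amp_tbl <- tibble::as_tibble(amps[, ord, drop = FALSE],
    .name_repair = ~ paste0("amp_", seq_len(n_components))
  )
  amp_tbl <- dplyr::mutate(amp_tbl, record = dplyr::row_number(), .before = 1)
  structure(
    list(
      shared_lifetimes = tau[ord],
      fixed_donor_lifetime = fixed_donor_lifetime,
      amplitudes = amp_tbl,
      chi2_reduced_global = chi2_num / dof,
      n_records = length(counts),
      converged = converged
    ),
    class = "global_decay_fit"
  )
}

#' @export
print.global_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<global_decay_fit: %d records, lifetimes %s ns, chi2_red = %.4f>\n",
    x$n_records, paste(sprintf("%.3f", x$shared_lifetimes), collapse = "/"),
    x$chi2_reduced_global
  ))
  invisible(x)
}

#' Amplitude-weighted average lifetime
#'
#' `tau_avg = sum(a_i * tau_i)` over the fitted components; the per-cell
#' summary from which observed FRET is computed as `1 - tau_avg / tau_D`.
#'
#' @param components Component table (see [decay_components()]).
#' @return Lifetime in ns.
#' @export
#' @examples
#' amplitude_weighted_lifetime(decay_components(c(3.46, 0.8), c(0.5, 0.5)))
amplitude_weighted_lifetime <- function(components) {
  components <- check_components(components)
  sum(components$amplitude * components$lifetime)
}

#' Per-pixel lifetime map from a FLIM stack
#'
#' Estimates each pixel's lifetime with the mean-arrival-time estimator:
#' the mean photon delay (bin centers) is inverted through the truncated
#' exponential mean `m(tau) = tau - T * exp(-T/tau) / (1 - exp(-T/tau))`,
#' correcting the bias from the finite measurement window `T`. Pixels with
#' fewer than `min_photons` photons (or a mean delay at or beyond the
#' uniform limit `T/2`) are undefined (`NA`).
#'
#' @param flim_stack A `flim_stack` (rows x cols x channels array with a
#'   `channel_width_ps` attribute), as from [simulate_flim_stack()].
#' @param min_photons Minimum photons per analyzed pixel (default 10).
#' @return A list with matrices `lifetime` (ns, `NA` where undefined) and
#'   `intensity` (photons per pixel), of class `lifetime_map`.
#' @export
pixel_lifetime_map <- function(flim_stack, min_photons = 10L) {
  if (!is.array(flim_stack) || length(dim(flim_stack)) != 3L) {
    rlang::abort("`flim_stack` must be a rows x cols x channels array.")
  }
  if (prod(dim(flim_stack)) == 0L) rlang::abort("Empty FLIM stack.")
  width_ps <- attr(flim_stack, "channel_width_ps")
  if (is.null(width_ps)) rlang::abort("`flim_stack` lacks a `channel_width_ps` attribute.")
  min_photons <- check_count(min_photons, "min_photons", lower = 1L)
  dt <- width_ps / 1000
  n_ch <- dim(flim_stack)[3]
  window <- n_ch * dt
  centers <- (seq_len(n_ch) - 0.5) * dt
  truncated_mean <- function(tau) {
    tau - window * exp(-window / tau) / (1 - exp(-window / tau))
  }
  dims <- dim(flim_stack)[1:2]
  intensity <- apply(flim_stack, c(1, 2), sum)
  lifetime <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      n <- intensity[i, j]
      if (n < min_photons) next
      m <- sum(flim_stack[i, j, ] * centers) / n
      if (m >= window / 2 - 1e-9) next # at/beyond the uniform limit
      lifetime[i, j] <- stats::uniroot(
        function(tau) truncated_mean(tau) - m,
        lower = dt / 100, upper = 1e4 * window, tol = 1e-12
      )$root
    }
  }
  structure(list(lifetime = lifetime, intensity = intensity),
    class = "lifetime_map"
  )
}
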