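# Progressive acceptor photobleaching: analytic donor/acceptor forward
# model, curvature statistic, and acceptor-multiplicity classification.
#
# Additive-rate model: each bound acceptor contributes the same transfer
# rate, so with rho = E1 / (1 - E1) a complex with k surviving acceptors
# has efficiency E_k = k * rho / (1 + k * rho). Bleaching the first of
# several acceptors therefore dequenches the donor only partially, which
# delays donor recovery and bends the donor-vs-acceptor plot (convex);
# a single acceptor gives an exactly affine relation.

k_acceptor_efficiency <- function(k, e_single) {
  rho <- e_single / (1 - e_single)
  k * rho / (1 + k * rho)
}

#' Analytic donor/acceptor curve under progressive acceptor bleaching
#'
#' Expected normalized donor intensity versus surviving-acceptor fraction
#' `s` for complexes carrying `n_acceptors` acceptors:
#' `donor(s) = sum_k C(n, k) s^k (1-s)^(n-k) (1 - E_k)` with the
#' additive-rate efficiencies `E_k`; the expected normalized acceptor
#' signal is `s` itself. `donor(0) = 1` (full dequenching) and
#' `donor(1) = 1 - E_n` (pre-bleach quenching).
#'
#' @param n_acceptors Acceptors per complex (>= 1).
#' @param e_single Single-acceptor FRET efficiency, in `(0, 1)`.
#' @param survival_grid Acceptor survival fractions in `[0, 1]` at which to
#'   evaluate the curve (default 101 points).
#' @return A tibble with columns `survival`, `acceptor`, `donor`.
#' @export
#' @examples
#' predict_bleach_curve(2, 0.5, survival_grid = 0.5) # donor = 0.5833...
predict_bleach_curve <- function(n_acceptors, e_single,
                                 survival_grid = seq(0, 1, length.out = 101L)) {
  n_acceptors <- check_count(n_acceptors, "n_acceptors", lower = 1L)
  check_scalar(e_single, "e_single",
    lower = 0, upper = 1,
    closed_lower = FALSE, closed_upper = FALSE
  )
  if (any(survival_grid < 0) || any(survival_grid > 1)) {
    rlang::abort("`survival_grid` values must lie in [0, 1].")
  }
  donor <- vapply(survival_grid, function(s) {
    k <- 0:n_acceptors
    sum(stats::dbinom(k, n_acceptors, s) * (1 - k_acceptor_efficiency(k, e_single)))
  }, 0)
  tibble::tibble(survival = survival_grid, acceptor = survival_grid, donor = donor)
}

normalize_bleach_axes <- function(series) {
  d <- tibble::as_tibble(series)
  if (!all(c("donor", "acceptor") %in% names(d))) {
    rlang::abort("A bleach series needs `donor` and `acceptor` columns.")
  }
  rng_a <- range(d$acceptor)
  rng_d <- range(d$donor)
  if (diff(rng_a) <= 0) rlang::abort("Acceptor signal is constant; nothing was bleached.")
  d$acceptor_norm <- (d$acceptor - rng_a[1]) / diff(rng_a)
  d$donor_norm <- if (diff(rng_d) > 0) (d$donor - rng_d[1]) / diff(rng_d) else 0
  d
}

#' Curvature of the donor-versus-acceptor bleaching relation
#'
#' Normalizes both axes to `[0, 1]`, fits
#' `donor = a + b * acceptor + c * acceptor^2` by least squares, and
#' returns the quadratic coefficient `c` with a case-resampling bootstrap
#' confidence interval. Positive `c` (convex) is the multi-acceptor
#' signature of the forward model; a single acceptor gives `c = 0`.
#'
#' @param series Bleach-series tibble (`step`, `donor`, `acceptor`) with at
#'   least 10 steps; acceptor intensities are expected to decrease over
#'   steps (a non-monotone trend beyond noise level triggers a warning).
#' @param n_boot Bootstrap resamples (default 400).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble: `curvature`, `ci_lower`, `ci_upper`, `n_steps`.
#' @export
curvature_statistic <- function(series, n_boot = 400L, conf = 0.95, seed = 1L) {
  d <- tibble::as_tibble(series)
  if (nrow(d) < 10L) rlang::abort("Need at least 10 bleach steps.")
  n_boot <- check_count(n_boot, "n_boot", lower = 0L)
  if (all(c("step", "acceptor") %in% names(d))) {
    d <- dplyr::arrange(d, .data$step)
    up_moves <- diff(d$acceptor) > 0.1 * max(d$acceptor)
    if (mean(up_moves) > 0.2) {
      rlang::warn("Acceptor series is substantially non-monotone; bleach ordering suspect.")
    }
  }
  d <- normalize_bleach_axes(d)
  quad_c <- function(x, y) {
    stats::.lm.fit(cbind(1, x, x^2), y)$coefficients[3]
  }
  c_hat <- quad_c(d$acceptor_norm, d$donor_norm)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(d), replace = TRUE)
        # a quadratic needs >= 3 distinct abscissae
        if (length(unique(d$acceptor_norm[idx])) < 3L) {
          return(NA_real_)
        }
        quad_c(d$acceptor_norm[idx], d$donor_norm[idx])
      }, 0)
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  tibble::tibble(
    curvature = c_hat, ci_lower = ci[1], ci_upper = ci[2], n_steps = nrow(d)
  )
}

# least-squares fit of one candidate forward model to a bleach series.
# Parameters: donor scale at full dequench (d0), single-acceptor
# efficiency (e), fraction of FRET-inactive donors (phi).
fit_bleach_model <- function(s_obs, donor_obs, n, with_free_fraction = TRUE) {
  model_donor <- function(par) {
    e <- par[1]
    phi <- if (with_free_fraction) par[2] else 0
    d0 <- par[3]
    curve <- vapply(s_obs, function(s) {
      k <- 0:n
      sum(stats::dbinom(k, n, s) * (1 - k_acceptor_efficiency(k, e)))
    }, 0)
    d0 * (phi + (1 - phi) * curve)
  }
  rss <- function(par) sum((donor_obs - model_donor(par))^2)
  init <- c(e = 0.4, phi = 0.1, d0 = max(donor_obs))
  opt <- stats::optim(init, rss,
    method = "L-BFGS-B",
    lower = c(1e-4, 0, 1e-8), upper = c(0.95, 0.95, Inf),
    control = list(maxit = 500L, factr = 1e4)
  )
  # second start at high efficiency to dodge local minima
  opt2 <- stats::optim(c(0.7, 0.3, max(donor_obs)), rss,
    method = "L-BFGS-B",
    lower = c(1e-4, 0, 1e-8), upper = c(0.95, 0.95, Inf),
    control = list(maxit = 500L, factr = 1e4)
  )
  if (opt2$value < opt$value) opt <- opt2
  list(par = opt$par, rss = opt$value)
}

#' Infer acceptor multiplicity from a bleaching trajectory
#'
#' Fits the analytic forward model for each candidate acceptor count
#' (free single-acceptor efficiency, free fraction of FRET-inactive
#' donors, free donor scale) and selects among candidates with the
#' small-sample-corrected information criterion (AICc). If the best and
#' runner-up scores differ by less than `ambiguity_margin` the multiplicity
#' is reported as ambiguous rather than forced; exact ties resolve toward
#' the smaller count (parsimony).
#'
#' @param series Bleach-series tibble (`step`, `donor`, `acceptor`).
#' @param candidate_n Candidate acceptor counts (default `1:3`).
#' @param ambiguity_margin Minimum AICc separation for a confident call
#'   (default 2).
#' @return An object of class `bleach_fit`: `inferred_multiplicity`
#'   (`"1"`, `">=2"` or `"ambiguous"`), `best_n`, `e_single`,
#'   `free_fraction`, `curvature_stat`, `model_comparison` (per-candidate
#'   tibble with RSS and AICc).
#' @export
fit_acceptor_multiplicity <- function(series, candidate_n = 1:3,
                                      ambiguity_margin = 2) {
  d <- tibble::as_tibble(series)
  if (nrow(d) < 10L) rlang::abort("Need at least 10 bleach steps.")
  if (any(candidate_n < 1L)) rlang::abort("`candidate_n` values must be >= 1.")
  candidate_n <- sort(unique(as.integer(candidate_n)))
  a_max <- max(d$acceptor)
  if (a_max <= 0) rlang::abort("Acceptor signal is identically zero.")
  s_obs <- pmin(pmax(d$acceptor / a_max, 0), 1)
  n_obs <- nrow(d)

  fits <- purrr::map(candidate_n, function(n) {
    f <- fit_bleach_model(s_obs, d$donor, n)
    # n = 1 is affine in s: efficiency and free fraction are confounded,
    # so it carries one fewer identifiable parameter
    p <- if (n == 1L) 2L else 3L
    aicc <- n_obs * log(max(f$rss, 1e-300) / n_obs) + 2 * p +
      2 * p * (p + 1) / max(n_obs - p - 1, 1)
    list(n = n, par = f$par, rss = f$rss, aicc = aicc, n_par = p)
  })
  comparison <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      n_acceptors = f$n, rss = f$rss, aicc = f$aicc,
      e_single = unname(f$par[1]), free_fraction = unname(f$par[2])
    )
  })
  scores <- comparison$aicc
  best_i <- which(scores == min(scores))[1] # ties -> smaller n (sorted)
  margin <- if (length(scores) > 1L) {
    sort(scores)[2] - min(scores)
  } else {
    Inf
  }
  best_n <- comparison$n_acceptors[best_i]
  multiplicity <- if (margin < ambiguity_margin) {
    "ambiguous"
  } else if (best_n == 1L) {
    "1"
  } else {
    ">=2"
  }
  curv <- curvature_statistic(d, n_boot = 0L)
  structure(
    list(
      inferred_multiplicity = multiplicity,
      best_n = best_n,
      e_single = comparison$e_single[best_i],
      free_fraction = comparison$free_fraction[best_i],
      curvature_stat = curv$curvature,
      model_comparison_score = margin,
      model_comparison = comparison,
      series = d
    ),
    class = "bleach_fit"
  )
}

#' Classify a bleaching trajectory as single- or multi-acceptor
#'
#' Combined decision rule used when turning trajectories into
#' stoichiometry evidence: a trajectory is called multi-acceptor when the
#' curvature bootstrap confidence interval lies strictly above zero (the
#' convexity signature of the forward model) or when the information
#' criterion of [fit_acceptor_multiplicity()] selects `n >= 2` decisively
#' (score separation at least `ambiguity_margin`). Otherwise it is called
#' single-acceptor; the model-comparison fit is only computed when the
#' curvature test is inconclusive, since an unambiguous curvature sign
#' already settles the call.
#'
#' @inheritParams fit_acceptor_multiplicity
#' @param n_boot,conf,seed Passed to [curvature_statistic()].
#' @return A list: `multiplicity` (`"1"` or `">=2"`), `curvature` (the
#'   [curvature_statistic()] row), and `fit` (the
#'   [fit_acceptor_multiplicity()] result, or `NULL` when the curvature
#'   test alone decided).
#' @export
classify_acceptor_multiplicity <- function(series, candidate_n = 1:3,
                                           ambiguity_margin = 2,
                                           n_boot = 400L, conf = 0.95,
                                           seed = 1L) {
  curv <- curvature_statistic(series, n_boot = n_boot, conf = conf, seed = seed)
  if (!is.na(curv$ci_lower) && curv$ci_lower > 0) {
    return(list(multiplicity = ">=2", curvature = curv, fit = NULL))
  }
  fit <- fit_acceptor_multiplicity(series,
    candidate_n = candidate_n,
    ambiguity_margin = ambiguity_margin
  )
  multiplicity <- if (fit$inferred_multiplicity == ">=2") ">=2" else "1"
  list(multiplicity = multiplicity, curvature = curv, fit = fit)
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf(
    "<bleach_fit: multiplicity %s (best n = %d, E1 = %.3f, dAICc to runner-up = %.2f)>\n",
    x$inferred_multiplicity, x$best_n, x$e_single, x$model_comparison_score
  ))
  invisible(x)
}
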