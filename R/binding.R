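# Hyperbolic FRET binding-curve estimation and the mass-action model of
# concentration-dependent complex assembly.

#' Fit the hyperbolic FRET binding curve
#'
#' Least-squares fit of `FRET = FRET_max * [A] / (K_D + [A])` to per-cell
#' observed FRET versus acceptor intensity (the concentration index, AU).
#' Standard errors come from a seeded case-resampling bootstrap; the
#' per-cell fit is unweighted because cell populations are heteroscedastic
#' in ways no single weighting captures.
#'
#' @param records Cell-record tibble with columns `acceptor` and `fret`
#'   (>= 20 records spanning at least one decade of acceptor intensity is
#'   recommended; a narrower design triggers an identifiability warning).
#' @param bootstrap_n Bootstrap resamples for standard errors (default 500;
#'   0 skips the bootstrap).
#' @param seed Seed for the bootstrap resampling.
#' @param resolvable_limit Smallest K_D the design can resolve (AU,
#'   default 0.5); stored for [report_kd_bound()].
#' @return An object of class `binding_fit` with elements `kd`, `fret_max`,
#'   `kd_se`, `fret_max_se`, `is_bound_only`, `resolvable_limit`,
#'   `converged`, `n_records`.
#' @export
fit_binding_curve <- function(records, bootstrap_n = 500L, seed = 1L,
                              resolvable_limit = 0.5) {
  records <- tibble::as_tibble(records)
  if (!all(c("acceptor", "fret") %in% names(records))) {
    rlang::abort("`records` needs columns `acceptor` and `fret`.")
  }
  if (nrow(records) < 3L) rlang::abort("Need at least 3 records to fit two parameters.")
  bootstrap_n <- check_count(bootstrap_n, "bootstrap_n", lower = 0L)
  acc <- records$acceptor
  if (any(acc < 0)) rlang::abort("Acceptor intensities must be non-negative.")

  fit_once <- function(d) {
    start <- list(
      fret_max = max(min(max(d$fret), 0.99), 0.05),
      kd = max(stats::median(d$acceptor), 1e-6)
    )
    fit <- minpack.lm::nlsLM(
      fret ~ fret_max * acceptor / (kd + acceptor),
      data = d, start = start,
      lower = c(fret_max = 1e-6, kd = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14)
    )
    stats::coef(fit)
  }

  if (max(acc) / max(min(acc), 1e-12) < 10) {
    rlang::warn(
      class = "flimfret_identifiability_warning",
      message = "Acceptor intensities span less than one decade; K_D is weakly identified."
    )
  }
  est <- tryCatch(fit_once(records), error = function(e) NULL)
  converged <- !is.null(est)
  if (!converged) {
    rlang::warn("Binding-curve fit failed to converge; result is flagged.")
    est <- c(fret_max = NA_real_, kd = NA_real_)
  }

  if (converged) {
    if (min(acc) > est[["kd"]] && max(acc) / max(min(acc), 1e-12) >= 10) {
      rlang::warn(
        class = "flimfret_identifiability_warning",
        message = sprintf(
          "All acceptor intensities exceed the fitted K_D (%.3g AU): the binding curve is sampled only near saturation.",
          est[["kd"]]
        )
      )
    }
  }

  kd_se <- fret_max_se <- NA_real_
  boot <- NULL
  if (converged && bootstrap_n > 0L) {
    boot <- with_seed(seed, {
      purrr::map(seq_len(bootstrap_n), function(b) {
        idx <- sample.int(nrow(records), replace = TRUE)
        tryCatch(fit_once(records[idx, ]), error = function(e) {
          c(fret_max = NA_real_, kd = NA_real_)
        })
      })
    })
    boot <- do.call(rbind, boot)
    kd_se <- stats::sd(boot[, "kd"], na.rm = TRUE)
    fret_max_se <- stats::sd(boot[, "fret_max"], na.rm = TRUE)
  }

  kd <- unname(est[["kd"]])
  ci_lower <- if (!is.null(boot)) {
    unname(stats::quantile(boot[, "kd"], 0.025, na.rm = TRUE))
  } else {
    NA_real_
  }
  structure(
    list(
      kd = kd,
      fret_max = unname(est[["fret_max"]]),
      kd_se = kd_se,
      fret_max_se = fret_max_se,
      kd_ci_lower = ci_lower,
      is_bound_only = isTRUE(!is.na(kd) &&
        (kd <= resolvable_limit || (!is.na(ci_lower) && ci_lower <= 0))),
      resolvable_limit = resolvable_limit,
      converged = converged,
      n_records = nrow(records),
      bootstrap_n = bootstrap_n,
      records = records
    ),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit>", report_kd_bound(x), "\n")
  cat(sprintf(
    "  FRET_max = %.4f%s  (n = %d cells%s)\n",
    x$fret_max,
    if (is.na(x$fret_max_se)) "" else sprintf(" +/- %.4f", x$fret_max_se),
    x$n_records,
    if (x$converged) "" else ", NOT CONVERGED"
  ))
  invisible(x)
}

#' Report a dissociation constant, falling back to a resolution bound
#'
#' Very avid interactions saturate below the resolvable concentration
#' range, so their K_D can only be bounded. If the point estimate is at or
#' below `resolvable_limit` (ties break toward the conservative bound) or
#' the bootstrap CI reaches zero, the displayed value is
#' `"K_D < limit AU"`; otherwise the point estimate with its standard
#' error.
#'
#' @param fit A [fit_binding_curve()] result.
#' @param resolvable_limit Override of the limit stored in the fit (AU).
#' @return A display string; the `is_bound_only` attribute carries the flag.
#' @export
report_kd_bound <- function(fit, resolvable_limit = fit$resolvable_limit) {
  stopifnot(inherits(fit, "binding_fit"))
  check_scalar(resolvable_limit, "resolvable_limit", lower = 0)
  if (!fit$converged || is.na(fit$kd)) {
    return(structure("K_D not determined (fit did not converge)",
      is_bound_only = NA
    ))
  }
  bound <- fit$kd <= resolvable_limit ||
    (!is.na(fit$kd_ci_lower) && fit$kd_ci_lower <= 0)
  if (bound) {
    structure(sprintf("K_D < %.3g AU", resolvable_limit), is_bound_only = TRUE)
  } else {
    structure(
      sprintf(
        "K_D = %.3g%s AU", fit$kd,
        if (is.na(fit$kd_se)) "" else sprintf(" +/- %.2g", fit$kd_se)
      ),
      is_bound_only = FALSE
    )
  }
}

#' Mass-action equilibrium of the regulatory-complex species
#'
#' Solves the coupled equilibria of a catalytic protomer `A` (the
#' alpha-beta unit; the beta interaction is constitutive at these
#' concentrations and is not a free equilibrium) binding a regulatory
#' micropeptide `P`, protomer dimerization with a single dimerization
#' constant applied regardless of micropeptide occupancy, and optional
#' sequestration of `P` into tetramers that cannot bind `A`:
#' \deqn{AP: [AP] = [A][P]/K_{AP}}
#' \deqn{dimers: [XY] = c_{XY} [X][Y]/K_{AA}, c = 1 (identical), 2 (mixed)}
#' \deqn{tetramer: [P_4] = [P]^4/K_{tet}^3}
#' Because the protomer total `M = [A] + [AP]` satisfies a closed-form
#' quadratic and micropeptide conservation is monotone in `[P]`, the state
#' is found by one bracketed root solve; converged states satisfy both
#' conservation laws to better than 1e-10 relative.
#'
#' @param total_alpha Total catalytic-subunit concentration (AU, >= 0).
#' @param total_plm Total micropeptide concentration (AU, >= 0).
#' @param kd_alpha_plm Protomer-micropeptide dissociation constant (AU).
#' @param kd_alpha_alpha Protomer dimerization constant (AU); `Inf`
#'   disables dimerization.
#' @param kd_plm_tetramer Tetramerization scale (AU); `Inf` (default)
#'   disables the tetramer species.
#' @return A tibble of class `equilibrium_state`: columns `species`,
#'   `concentration`; attributes `total_alpha`, `total_plm`.
#' @export
equilibrium_species <- function(total_alpha, total_plm,
                                kd_alpha_plm, kd_alpha_alpha = Inf,
                                kd_plm_tetramer = Inf) {
  check_scalar(total_alpha, "total_alpha", lower = 0)
  check_scalar(total_plm, "total_plm", lower = 0)
  check_scalar(kd_alpha_plm, "kd_alpha_plm", lower = 0, closed_lower = FALSE)
  check_scalar(kd_alpha_alpha, "kd_alpha_alpha", lower = 0, closed_lower = FALSE)
  check_scalar(kd_plm_tetramer, "kd_plm_tetramer", lower = 0, closed_lower = FALSE)

  # protomer total M = A + AP from quadratic 2 M^2 / Kaa + M = total_alpha
  # stable form of the quadratic root (no cancellation for weak dimerization)
  m_tot <- if (is.finite(kd_alpha_alpha)) {
    2 * total_alpha / (1 + sqrt(1 + 8 * total_alpha / kd_alpha_alpha))
  } else {
    total_alpha
  }

  state_at <- function(p) {
    frac_ap <- (p / kd_alpha_plm) / (1 + p / kd_alpha_plm)
    a <- m_tot * (1 - frac_ap)
    ap <- m_tot * frac_ap
    if (is.finite(kd_alpha_alpha)) {
      d00 <- a^2 / kd_alpha_alpha
      d01 <- 2 * a * ap / kd_alpha_alpha
      d11 <- ap^2 / kd_alpha_alpha
    } else {
      d00 <- d01 <- d11 <- 0
    }
    p4 <- if (is.finite(kd_plm_tetramer)) p^4 / kd_plm_tetramer^3 else 0
    c(a = a, ap = ap, d00 = d00, d01 = d01, d11 = d11, p = p, p4 = p4)
  }
  plm_total_at <- function(p) {
    s <- state_at(p)
    s[["p"]] + s[["ap"]] + s[["d01"]] + 2 * s[["d11"]] + 4 * s[["p4"]]
  }

  p_free <- if (total_plm == 0) {
    0
  } else {
    stats::uniroot(function(p) plm_total_at(p) - total_plm,
      lower = 0, upper = total_plm, tol = .Machine$double.eps^0.9,
      maxiter = 2000L
    )$root
  }
  s <- state_at(p_free)
  alpha_sum <- s[["a"]] + s[["ap"]] + 2 * (s[["d00"]] + s[["d01"]] + s[["d11"]])
  plm_sum <- plm_total_at(p_free)
  rel <- function(x, tot) if (tot > 0) abs(x - tot) / tot else abs(x)
  if (rel(alpha_sum, total_alpha) > 1e-10 || rel(plm_sum, total_plm) > 1e-10) {
    rlang::abort(sprintf(
      "Equilibrium solve did not converge: conservation residuals %.3g (alpha), %.3g (micropeptide).",
      rel(alpha_sum, total_alpha), rel(plm_sum, total_plm)
    ))
  }
  out <- tibble::tibble(
    species = c(
      "protomer_free", "protomer_plm", "dimer_0plm", "dimer_1plm",
      "dimer_2plm", "plm_free", "plm_tetramer"
    ),
    concentration = unname(s[c("a", "ap", "d00", "d01", "d11", "p", "p4")])
  )
  attr(out, "total_alpha") <- total_alpha
  attr(out, "total_plm") <- total_plm
  class(out) <- c("equilibrium_state", class(out))
  out
}

#' Map an equilibrium state to three-species decay amplitudes
#'
#' Classifies donor-containing complexes by the number of acceptor-labeled
#' micropeptides bound: zero acceptors contribute to the donor-only
#' species, exactly one to the medium-FRET species, and two or more to the
#' high-FRET species. Each complex is weighted by its catalytic-subunit
#' (donor) content; unlabeled micropeptide competitor is accounted for
#' binomially via the acceptor labeling fraction.
#'
#' @param state An [equilibrium_species()] result.
#' @param labeling_fractions List with elements `donor` and `acceptor`,
#'   each a fraction in `[0, 1]`; only the acceptor fraction affects the
#'   amplitudes (every catalytic subunit has the same donor probability,
#'   which cancels in the normalization).
#' @return Named numeric vector `c(donor, medium, high)` summing to 1.
#' @export
assembly_to_fret_species <- function(state,
                                     labeling_fractions = list(donor = 1, acceptor = 1)) {
  stopifnot(inherits(state, "equilibrium_state"))
  fa <- labeling_fractions$acceptor
  fd <- labeling_fractions$donor
  check_scalar(fa, "labeling_fractions$acceptor", lower = 0, upper = 1)
  check_scalar(fd, "labeling_fractions$donor", lower = 0, upper = 1)
  conc <- stats::setNames(state$concentration, state$species)
  # donor weight = catalytic subunits per complex; acceptor sites = bound
  # micropeptides, each labeled independently with probability fa
  classes <- list(
    list(w = conc[["protomer_free"]] * 1, n_sites = 0L),
    list(w = conc[["protomer_plm"]] * 1, n_sites = 1L),
    list(w = conc[["dimer_0plm"]] * 2, n_sites = 0L),
    list(w = conc[["dimer_1plm"]] * 2, n_sites = 1L),
    list(w = conc[["dimer_2plm"]] * 2, n_sites = 2L)
  )
  w_tot <- sum(vapply(classes, function(cl) cl$w, 0))
  if (w_tot <= 0) {
    rlang::abort("State contains no donor-bearing (catalytic-subunit) species.")
  }
  amp <- c(donor = 0, medium = 0, high = 0)
  for (cl in classes) {
    if (cl$w == 0) next
    k <- 0:cl$n_sites
    pk <- stats::dbinom(k, cl$n_sites, fa)
    amp[["donor"]] <- amp[["donor"]] + cl$w * pk[1]
    if (cl$n_sites >= 1L) amp[["medium"]] <- amp[["medium"]] + cl$w * pk[2]
    if (cl$n_sites >= 2L) amp[["high"]] <- amp[["high"]] + cl$w * sum(pk[-(1:2)])
  }
  amp / w_tot
}
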