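# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths.

# Brute-force mass-action solver: dense refined grid search over the free
# monomer concentrations, minimizing the conservation residuals, with all
# species computed directly from the law of mass action.
brute_force_equilibrium <- function(total_alpha, total_plm,
                                    kd_ap, kd_aa, kd_tet = Inf,
                                    n_grid = 61L, n_refine = 6L) {
  species_at <- function(a, p) {
    ap <- a * p / kd_ap
    d00 <- if (is.finite(kd_aa)) a^2 / kd_aa else 0
    d01 <- if (is.finite(kd_aa)) 2 * a * ap / kd_aa else 0
    d11 <- if (is.finite(kd_aa)) ap^2 / kd_aa else 0
    p4 <- if (is.finite(kd_tet)) p^4 / kd_tet^3 else 0
    c(a = a, ap = ap, d00 = d00, d01 = d01, d11 = d11, p = p, p4 = p4)
  }
  resid <- function(a, p) {
    s <- species_at(a, p)
    ra <- (s[["a"]] + s[["ap"]] + 2 * (s[["d00"]] + s[["d01"]] + s[["d11"]]) -
      total_alpha) / max(total_alpha, 1e-12)
    rp <- (s[["p"]] + s[["ap"]] + s[["d01"]] + 2 * s[["d11"]] + 4 * s[["p4"]] -
      total_plm) / max(total_plm, 1e-12)
    ra^2 + rp^2
  }
  a_rng <- c(0, max(total_alpha, 1e-12))
  p_rng <- c(0, max(total_plm, 1e-12))
  best <- c(a = total_alpha / 2, p = total_plm / 2)
  for (r in seq_len(n_refine)) {
    a_grid <- seq(a_rng[1], a_rng[2], length.out = n_grid)
    p_grid <- seq(p_rng[1], p_rng[2], length.out = n_grid)
    vals <- outer(a_grid, p_grid, Vectorize(resid))
    idx <- arrayInd(which.min(vals), dim(vals))
    best <- c(a = a_grid[idx[1]], p = p_grid[idx[2]])
    da <- diff(a_rng) / (n_grid - 1)
    dp <- diff(p_rng) / (n_grid - 1)
    a_rng <- c(max(best[["a"]] - 2 * da, 0), best[["a"]] + 2 * da)
    p_rng <- c(max(best[["p"]] - 2 * dp, 0), best[["p"]] + 2 * dp)
  }
  species_at(best[["a"]], best[["p"]])
}

# Exact moments of the k-surviving-acceptor donor intensity: K ~ Bin(n, s),
# donor per complex = 1 - E_K with the additive-rate efficiency.
bleach_donor_moments <- function(n, e, s) {
  rho <- e / (1 - e)
  k <- 0:n
  w <- dbinom(k, n, s)
  d <- 1 - k * rho / (1 + k * rho)
  c(mean = sum(w * d), var = sum(w * d^2) - sum(w * d)^2)
}

# Convenience: turn a predicted curve into a bleach-series tibble
curve_as_series <- function(curve) {
  tibble::tibble(
    step = seq_len(nrow(curve)) - 1L,
    donor = curve$donor,
    acceptor = curve$acceptor
  )
}
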