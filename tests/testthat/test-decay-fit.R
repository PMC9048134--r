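test_that("noiseless expected decays are refit exactly (oracle round trip)", {
  # 1 component
  f1 <- fit_decay(expected_decay(decay_components(3.46, 1), 1e6), 1)
  expect_equal(f1$components$lifetime, 3.46, tolerance = 1e-4 / 3.46)

  # 2 components, free
  cmp2 <- decay_components(c(3.0, 0.8), c(0.6, 0.4))
  f2 <- fit_decay(expected_decay(cmp2, 1e6), 2)
  expect_equal(f2$components$lifetime, c(3.0, 0.8), tolerance = 1e-4)
  expect_equal(f2$components$amplitude, c(0.6, 0.4), tolerance = 1e-4)

  # 3 components with the donor lifetime fixed
  cmp3 <- decay_components(c(3.46, 1.8, 0.8), c(0.3, 0.4, 0.3))
  f3 <- fit_decay(expected_decay(cmp3, 1e6), 3, fixed_lifetimes = 3.46)
  expect_equal(f3$components$lifetime, c(3.46, 1.8, 0.8), tolerance = 1e-4)
  expect_equal(f3$components$amplitude, c(0.3, 0.4, 0.3), tolerance = 1e-4)
})

test_that("three-species mixtures at 1e6 photons are recovered within spec", {
  cmp3 <- decay_components(c(3.46, 1.8, 0.8), c(1, 1, 1) / 3)
  h <- simulate_decay(cmp3, 1e6, seed = 101)
  f <- fit_decay(h, 3, fixed_lifetimes = 3.46)
  free <- f$components[!f$components$fixed, ]
  expect_equal(free$lifetime, c(1.8, 0.8), tolerance = 0.05 / 0.8)
  expect_true(all(abs(f$components$amplitude - 1 / 3) < 0.03))
  expect_true(f$converged)
})

test_that("reduced chi-squared of correct fits is calibrated near 1", {
  chi2 <- vapply(seq_len(50), function(i) {
    h <- simulate_decay(decay_components(3.46, 1), 1e5, seed = 2000 + i)
    suppressWarnings(fit_decay(h, 1))$chi2_reduced
  }, 0)
  expect_gt(mean(chi2), 0.95)
  expect_lt(mean(chi2), 1.05)
})

test_that("likelihood never decreases with extra components and fits are guarded", {
  h <- simulate_decay(decay_components(c(3.2, 0.9), c(0.5, 0.5)), 2e5, seed = 77)
  sel <- suppressWarnings(select_components(h, max_components = 3))
  cst <- vapply(sel$fits, function(f) f$cstat, 0)
  expect_true(all(diff(cst) <= 1e-6)) # monotone in nested models

  expect_error(
    fit_decay(decay_histogram(rep(1, 100)), 1),
    "fewer than 1000 photons"
  )
  expect_warning(
    fit_decay(simulate_decay(decay_components(2, 1), 2000, seed = 1), 3),
    "identifiable"
  )
  expect_error(fit_decay(h, 2, fixed_lifetimes = c(3, 2, 1)), "More fixed")
})

test_that("component selection finds the true model order", {
  h1 <- simulate_decay(decay_components(3.46, 1), 1e6, seed = 301)
  expect_identical(select_components(h1, max_components = 3)$n_components, 1L)

  cmp3 <- decay_components(c(3.46, 1.8, 0.8), c(1, 1, 1) / 3)
  h3 <- simulate_decay(cmp3, 1e6, seed = 302)
  sel <- select_components(h3, max_components = 4)
  expect_identical(sel$n_components, 3L)
})

test_that("global analysis recovers shared lifetimes and per-record amplitudes", {
  set.seed(1) # amplitudes of the synthetic batch only
  amps <- lapply(1:8, function(i) {
    x <- stats::rexp(3)
    x / sum(x)
  })
  hs <- lapply(seq_along(amps), function(i) {
    simulate_decay(decay_components(c(3.46, 1.8, 0.8), amps[[i]]), 3e5,
      seed = 400 + i
    )
  })
  gf <- global_fit(hs, 3, fixed_donor_lifetime = 3.46)
  expect_equal(gf$shared_lifetimes[1], 3.46) # held fixed
  expect_equal(gf$shared_lifetimes[2:3], c(1.8, 0.8), tolerance = 0.05 / 0.8)
  amp_hat <- as.matrix(gf$amplitudes[, -1])
  for (i in seq_along(amps)) {
    expect_equal(unname(amp_hat[i, ]), amps[[i]], tolerance = 0.05)
  }

  # donor-only records in the batch get near-zero FRET amplitudes
  hs_mix <- c(hs[1:3], lapply(4:6, function(i) {
    simulate_decay(decay_components(3.46, 1), 3e5, seed = 600 + i)
  }))
  gf2 <- global_fit(hs_mix, 3, fixed_donor_lifetime = 3.46)
  amp2 <- as.matrix(gf2$amplitudes[, -1])
  expect_true(all(amp2[4:6, 2:3] <= 0.02))
})

test_that("a single-record global fit agrees with the direct fit", {
  h <- simulate_decay(
    decay_components(c(3.46, 1.8, 0.8), c(0.2, 0.5, 0.3)), 3e5,
    seed = 500
  )
  g <- global_fit(list(h), 3, fixed_donor_lifetime = 3.46)
  f <- fit_decay(h, 3, fixed_lifetimes = 3.46)
  expect_equal(g$shared_lifetimes, f$components$lifetime, tolerance = 1e-5)
  expect_equal(unname(as.matrix(g$amplitudes[, -1])[1, ]),
    f$components$amplitude,
    tolerance = 1e-4
  )
})

test_that("global fit rejects incompatible channel grids", {
  h1 <- simulate_decay(decay_components(3, 1), 1e4, n_channels = 256, seed = 1)
  h2 <- simulate_decay(decay_components(3, 1), 1e4, n_channels = 512, seed = 2)
  expect_error(global_fit(list(h1, h2), 2), "channel grid")
})

test_that("amplitude-weighted lifetime behaves like a weighted mean", {
  expect_equal(amplitude_weighted_lifetime(decay_components(3.46, 1)), 3.46)
  expect_equal(
    amplitude_weighted_lifetime(decay_components(c(3.46, 0.8), c(0.5, 0.5))),
    2.13
  )
  expect_error(
    amplitude_weighted_lifetime(tibble::tibble(lifetime = numeric(), amplitude = numeric())),
    "at least one"
  )

  # order invariance and range bounds over random component sets
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    tau <- stats::runif(k, 0.2, 5)
    a <- stats::rexp(k)
    a <- a / sum(a)
    cmp <- decay_components(tau, a)
    perm <- sample(k)
    t1 <- amplitude_weighted_lifetime(cmp)
    t2 <- amplitude_weighted_lifetime(cmp[perm, ])
    expect_equal(t1, t2, tolerance = 1e-12)
    expect_gte(t1, min(tau))
    expect_lte(t1, max(tau))
    # identity: 1 - tau_avg / tau_d equals amplitude-weighted species efficiency
    tau_d <- max(tau) + 1
    expect_equal(1 - t1 / tau_d, sum(a * (1 - tau / tau_d)), tolerance = 1e-12)
  }
})
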