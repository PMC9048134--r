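test_that("simulated decays reproduce the exponential arrival-time law", {
  h <- simulate_decay(decay_components(3.46, 1), n_photons = 1e6, seed = 7)
  # fraction of photons arriving before one lifetime: exponential CDF 1 - e^-1
  frac <- sum(h$counts[h$time_ns < 3.46]) / n_photons(h)
  expect_equal(frac, 1 - exp(-1), tolerance = 0.002 / (1 - exp(-1)))

  # equal-amplitude mixture: mean arrival time is the mixture mean
  hm <- simulate_decay(decay_components(c(3.46, 0.8), c(0.5, 0.5)),
    n_photons = 5e5, seed = 8
  )
  mean_t <- sum(hm$time_ns * hm$counts) / n_photons(hm)
  expect_equal(mean_t, 2.13, tolerance = 0.01)
})

test_that("decay simulation handles edge cases and rejects bad inputs", {
  h0 <- simulate_decay(decay_components(3.46, 1), n_photons = 0, seed = 1)
  expect_equal(n_photons(h0), 0)
  expect_true(all(h0$counts == 0))

  expect_error(
    simulate_decay(tibble::tibble(lifetime = -1, amplitude = 1), 10, seed = 1),
    "positive"
  )
  expect_error(
    simulate_decay(tibble::tibble(lifetime = c(1, 2), amplitude = c(0.6, 0.6)),
      10,
      seed = 1
    ),
    "sum to 1"
  )
  expect_error(
    simulate_decay(decay_components(3.46, 1), n_photons = -5, seed = 1),
    "n_photons"
  )
})

test_that("the optional Gaussian instrument-response jitter broadens the decay", {
  sharp <- simulate_decay(decay_components(0.8, 1), 2e5, n_channels = 512, seed = 44)
  blurred <- simulate_decay(decay_components(0.8, 1), 2e5,
    n_channels = 512,
    irf_sigma_ps = 200, seed = 44
  )
  expect_lt(max(blurred$counts), max(sharp$counts))
  expect_lte(n_photons(blurred), n_photons(sharp))
})

test_that("every generator is bit-reproducible given the same seed", {
  a <- simulate_decay(decay_components(c(2, 0.5), c(0.3, 0.7)), 1e4, seed = 42)
  b <- simulate_decay(decay_components(c(2, 0.5), c(0.3, 0.7)), 1e4, seed = 42)
  expect_identical(a$counts, b$counts)

  s1 <- simulate_bleach_series(2, 0.5, seed = 11)
  s2 <- simulate_bleach_series(2, 0.5, seed = 11)
  expect_identical(s1, s2)

  p1 <- simulate_cell_population(50, kd = 5, seed = 13)
  p2 <- simulate_cell_population(50, kd = 5, seed = 13)
  expect_identical(p1, p2)

  f1 <- simulate_flim_stack(matrix(3.46, 3, 3), 500, seed = 14)
  f2 <- simulate_flim_stack(matrix(3.46, 3, 3), 500, seed = 14)
  expect_identical(unclass(f1), unclass(f2))

  # generators do not disturb the caller's RNG stream
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_decay(decay_components(1, 1), 100, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("simulated histogram means converge to the expected decay", {
  cmp <- decay_components(c(3.0, 0.7), c(0.4, 0.6))
  n_rep <- 50L
  n_phot <- 2e4
  acc <- Reduce(`+`, lapply(seq_len(n_rep), function(i) {
    simulate_decay(cmp, n_phot, n_channels = 128L, seed = 1000 + i)$counts
  })) / n_rep
  exp_counts <- expected_decay(cmp, n_phot, n_channels = 128L)$counts
  # mean of n_rep Poisson replicates: 3-sigma band, checked where expected >= 5
  keep <- exp_counts >= 5
  z <- (acc[keep] - exp_counts[keep]) / sqrt(exp_counts[keep] / n_rep)
  expect_lt(mean(abs(z) > 3), 0.01)
})

test_that("expected_decay matches closed forms and normalization", {
  cmp <- decay_components(c(3.46, 1.2), c(0.25, 0.75))
  n_ch <- 512L
  h <- expected_decay(cmp, 1e6, n_channels = n_ch)
  tail_mass <- sum(cmp$amplitude * exp(-(n_ch * 0.016) / cmp$lifetime))
  expect_equal(sum(h$counts), 1e6 * (1 - tail_mass), tolerance = 1e-12)

  # mono-exponential channel ratio is exactly geometric
  hm <- expected_decay(decay_components(2.5, 1), 1e5, n_channels = 256L)
  k <- 40L
  expect_equal(hm$counts[1 + k] / hm$counts[1], exp(-k * 0.016 / 2.5),
    tolerance = 1e-12
  )
})

test_that("single-acceptor bleach series are affine and survival=1 is static", {
  s <- simulate_bleach_series(1, 0.4,
    n_steps = 50, step_survival = 0.93,
    n_complexes = 2000, noise_sd = 0, seed = 3
  )
  r2 <- suppressWarnings(summary(lm(donor ~ acceptor, data = s)))$r.squared
  expect_gt(r2, 0.999)

  s_static <- simulate_bleach_series(2, 0.5,
    n_steps = 20, step_survival = 1,
    n_complexes = 500, noise_sd = 0, seed = 4
  )
  expect_equal(length(unique(s_static$donor)), 1L)
  expect_equal(length(unique(s_static$acceptor)), 1L)
})

test_that("two-acceptor bleach intensity at half survival matches enumeration", {
  # binomial enumeration: 0.25 * 1 + 0.5 * (1 - 0.5) + 0.25 * (1 - 2/3) = 7/12
  curve <- predict_bleach_curve(2, 0.5, survival_grid = 0.5)
  expect_equal(curve$donor, 7 / 12, tolerance = 1e-12)

  # Monte-Carlo generator agrees with the analytic curve within 3 SE
  for (cfg in list(c(1, 0.3), c(2, 0.5), c(3, 0.7))) {
    n <- cfg[1]
    e <- cfg[2]
    n_cx <- 1e4
    s <- simulate_bleach_series(n, e,
      n_steps = 30, step_survival = 0.9,
      n_complexes = n_cx, noise_sd = 0, seed = 50 + n
    )
    for (st in c(5L, 10L, 20L)) {
      s_true <- 0.9^st
      mom <- bleach_donor_moments(n, e, s_true)
      obs <- s$donor[s$step == st] / n_cx
      expect_lt(abs(obs - mom[["mean"]]), 3 * sqrt(mom[["var"]] / n_cx) + 1e-12)
    }
  }
})

test_that("cell populations follow the hyperbola and respect the FRET cap", {
  pop <- simulate_cell_population(1,
    expression_range = c(5, 5), kd = 5,
    fret_max = 0.7447, fret_noise_sd = 0, seed = 1
  )
  expect_equal(pop$fret, 0.7447 / 2, tolerance = 1e-12)
  expect_equal(pop$tau_avg, 3.46 * (1 - 0.7447 / 2), tolerance = 1e-12)

  pop_lo <- simulate_cell_population(1,
    expression_range = c(1e-6, 1e-6), kd = 5,
    fret_noise_sd = 0, seed = 1
  )
  expect_lt(pop_lo$fret, 1e-6)

  for (sd_i in seq_len(3)) {
    pop_n <- simulate_cell_population(400,
      kd = 5, fret_max = 0.7447,
      fret_noise_sd = 0.05, seed = 20 + sd_i
    )
    expect_true(all(pop_n$fret <= 0.7447 + 4 * 0.05))
    expect_true(all(pop_n$fret >= 0))
    # record-level consistency between fret and tau_avg
    expect_equal(pop_n$fret, 1 - pop_n$tau_avg / 3.46, tolerance = 1e-9)
  }

  expect_error(simulate_cell_population(0, kd = 5, seed = 1), "n_cells")
  expect_error(simulate_cell_population(10, kd = 0, seed = 1), "kd")
})

test_that("FLIM stacks give region-resolved lifetimes and flag empty pixels", {
  flat <- simulate_flim_stack(matrix(3.46, 6, 6), 1e4, seed = 31)
  m <- pixel_lifetime_map(flat)
  expect_equal(mean(m$lifetime), 3.46, tolerance = 0.01)

  two <- matrix(3.46, 4, 8)
  two[, 5:8] <- 2.0
  stk <- simulate_flim_stack(two, 5e3, seed = 32)
  m2 <- pixel_lifetime_map(stk)
  contrast <- mean(m2$lifetime[, 1:4]) - mean(m2$lifetime[, 5:8])
  expect_gt(contrast, 1)

  empty <- simulate_flim_stack(matrix(2, 2, 2), 0, seed = 33)
  m0 <- pixel_lifetime_map(empty)
  expect_true(all(is.na(m0$lifetime)))
  expect_true(all(m0$intensity == 0))

  expect_error(simulate_flim_stack(matrix(-1, 2, 2), 100, seed = 1), "positive")
})
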