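# flimfret

Stoichiometry of membrane-protein complexes from live-cell FLIM/FRET
data.

Fluorescently tagged subunits let three measurements report on how a
membrane complex is put together in an intact cell: time-correlated
single photon counting (TCSPC) resolves discrete FRET species through
the donor's multi-exponential decay; acceptor-sensitization surveys
across a transfected cell population trace out hyperbolic binding
curves, `FRET = FRET_max [A] / (K_D + [A])`, whose half-saturation point
is an apparent affinity; and progressive acceptor photobleaching
discriminates one acceptor per complex (a linear donor-vs-acceptor
trace) from several (a convex one). The motivating system is the sodium
pump (Na/K-ATPase): its catalytic alpha subunit, obligatory beta
subunit, and the regulatory micropeptide phospholemman (FXYD1), whose
pairwise multiplicities decide among candidate architectures for the
regulatory complex — from a minimal alphabeta–PLM protomer to a dimer of
protomers, (alphabeta–PLM)₂.

`flimfret` implements the full inference chain in tidyverse style
(data frames in, tibbles out, `tidy()`/`glance()`/`autoplot()` methods):

* **Synthetic data** — seeded generators for TCSPC histograms (Poisson
  photon statistics, optional Gaussian IRF jitter and uniform
  background), FLIM stacks, photobleaching trajectories, and cell
  populations with log-uniform expression, including a mass-action
  assembly model that couples expression to species amplitudes.
* **Decay analysis** — Poisson maximum-likelihood multi-exponential
  fitting (`fit_decay()`), component-number selection by a
  chi-squared-improvement stopping rule (`select_components()`), global
  analysis with shared lifetimes and a fixed donor reference
  (`global_fit()`), amplitude-weighted lifetimes, per-pixel FLIM
  lifetime maps.
* **FRET conversions** — `E = 1 − τ_DA/τ_D`; `R = R₀(1/E − 1)^(1/6)`
  (R₀ = 63.34 Å, κ² = 2/3); concentration from average FRET by inverting
  the binding hyperbola; species-population-versus-concentration curves.
* **Binding** — hyperbolic K_D/FRET_max fits with bootstrap errors,
  resolution-bound reporting for near-constitutive interactions
  ("K_D < 0.5 AU"), and a mass-action equilibrium model of
  concentration-dependent assembly.
* **Photobleaching** — the binomial additive-rate forward model,
  curvature statistics with bootstrap intervals, and single- versus
  multi-acceptor classification.
* **Stoichiometry** — rule-based elimination among five candidate
  architectures and an end-to-end seeded pipeline (`run_pipeline()`)
  with byte-reproducible JSON reports.

## Worked example

```r
library(flimfret)

# --- TCSPC: three FRET species in a million-photon record -----------------
h <- simulate_decay(
  decay_components(c(3.46, 1.8, 0.8), c(1, 1, 1) / 3),
  n_photons = 1e6, seed = 1
)
select_components(h, max_components = 4)$n_components
#> [1] 3

fit3 <- fit_decay(h, 3, fixed_lifetimes = 3.46)
tidy(fit3, tau_donor = 3.46)
#> # A tibble: 3 × 4
#>   lifetime amplitude fixed efficiency
#>      <dbl>     <dbl> <lgl>      <dbl>
#> 1    3.46      0.347 TRUE       0
#> 2    1.65      0.369 FALSE      0.523
#> 3    0.752     0.284 FALSE      0.783
```

Four components are rejected by the stopping rule; three species emerge
with a non-FRET donor (efficiency 0), a medium-FRET and a high-FRET
population. A single record leaves lifetime–amplitude trade-offs (here
the medium lifetime drifts to 1.65 ns); tying lifetimes across records
with `global_fit(histograms, 3, fixed_donor_lifetime = 3.46)` recovers
the shared species lifetimes to a few hundredths of a nanosecond.

```r
# --- Binding: apparent affinity from a 600-cell population ----------------
pop <- simulate_cell_population(600, kd = 5, fret_max = 0.7447,
                                fret_noise_sd = 0.05, seed = 2)
fit <- fit_binding_curve(pop, bootstrap_n = 200, seed = 3)
fit
#> <binding_fit> K_D = 5 +/- 0.17 AU
#>   FRET_max = 0.7506 +/- 0.0076  (n = 600 cells)

# --- Photobleaching: how many acceptors per complex? ----------------------
series <- simulate_bleach_series(n_acceptors = 2, e_single = 0.5, seed = 4)
classify_acceptor_multiplicity(series, seed = 5)$multiplicity
#> [1] ">=2"

# --- Elimination: which architectures survive the evidence? ---------------
consistent_models(stoich_evidence("multiple", "multiple", "dimer"))
#> Consistent stoichiometry model(s): D
#> # A tibble: 1 × 5
#>   model alpha  beta   plm description
#>   <chr> <int> <int> <int> <chr>
#> 1 D         2     2     2 (alphabeta-PLM)2: dimer of protomers
```

The K_D comes back at the generating 5 AU with FRET_max near 74.5%; a
curved donor/acceptor trace classifies the complex as multi-acceptor;
and evidence of multiple micropeptides, multiple beta subunits and a
catalytic-subunit dimer leaves exactly one architecture standing, the
dimer of protomers.

`run_pipeline(pipeline_config("model_d", seed = 1))` executes the whole
chain on synthetic data and `write_pipeline_report()` serializes a
byte-reproducible report. A thin command-line wrapper over the same
functions ships in `inst/cli/flimfret.R`; the methods vignette
(`vignettes/flim-fret-stoichiometry.Rmd`) documents the models,
parameter choices and limitations.

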