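---
title: "Inferring membrane-complex stoichiometry from FLIM/FRET data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring membrane-complex stoichiometry from FLIM/FRET data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimfret)
```

## The problem

Many membrane transporters work as oligomers, but their quaternary
arrangement in a living cell is hard to see: crystal structures capture
detergent-solubilized monomeric units, and biochemical cross-linking can
create or destroy contacts. Live-cell Förster resonance energy transfer
(FRET) offers a route around this. If a catalytic subunit is fused to a
donor fluorophore and a candidate partner to an acceptor, three
complementary measurements carry stoichiometric information:

1. **Time-correlated single photon counting (TCSPC).** The donor's
   fluorescence decay shortens when FRET occurs. A multi-exponential
   decomposition of a pooled cell population resolves discrete FRET
   species -- unbound donors, complexes with one acceptor, complexes with
   several -- through their distinct lifetimes.
2. **Acceptor-sensitization binding curves.** Across a population of
   transiently transfected cells, expression varies over orders of
   magnitude. Plotting per-cell FRET against acceptor intensity (a proxy
   for protein concentration) traces out a binding curve whose
   half-saturation point is an apparent dissociation constant in relative
   (arbitrary) units.
3. **Progressive acceptor photobleaching.** Stepwise selective
   destruction of acceptors dequenches the donor. With one acceptor per
   complex the donor-versus-acceptor trace is a straight line; with
   several acceptors it is convex, because destroying the first acceptor
   still leaves FRET to the survivors.

The motivating application is the sodium pump (Na/K-ATPase): a catalytic
alpha subunit, an obligatory beta subunit, and the regulatory micropeptide
phospholemman (FXYD1). Combining the three measurement types for the
alpha--PLM, alpha--beta and alpha--alpha pairings lets one eliminate
candidate architectures for the regulatory complex, from a minimal
alphabeta--PLM protomer up to a dimer of protomers or a disordered
aggregate. This package implements that entire inference chain, plus a
seeded synthetic-data generator that emulates each measurement, so the
pipeline can be exercised, calibrated, and tested without a microscope.

## Decay model and Poisson maximum likelihood

A TCSPC record is a histogram of photon delays on a grid of fixed-width
channels (16 ps by default; 3840 channels span a 61.44 ns window). The
signal model is an amplitude-weighted mixture of exponentials with an
optional uniform background:

$$p_i \propto (1-b)\sum_j a_j\left(e^{-t_{i-1}/\tau_j} - e^{-t_i/\tau_j}\right) + b/N.$$

Counts per channel span four orders of magnitude, so unweighted least
squares would let the bright early channels dominate. `fit_decay()`
instead minimizes the C-statistic (twice the negative Poisson
log-likelihood up to a constant), conditioning on the observed total so
the photon count is not a free parameter. Free lifetimes are optimized in
log space with amplitude fractions through a softmax; starts are
log-spaced over `[channel width, window/3]`, and a second deterministic
run from perturbed starts guards against local minima. A fit is flagged
unconverged only if neither run reports success *and* the two runs
disagree about the optimum.

**Fit quality.** We report a reduced chi-squared with Pearson weights
(the model's expected counts), restricted to channels where the model
predicts at least one photon. Pearson weighting keeps the per-channel
expectation at exactly 1 under Poisson noise at every count level, and
the one-photon floor removes far-tail channels whose near-zero
expectations make the statistic heavy-tailed. Under this convention a
correctly specified million-photon fit lands in roughly [0.94, 1.06],
matching the range conventional TCSPC software reports for
single-exponential donors. (Neyman weighting, `max(counts, 1)`, was
rejected: with half the window essentially empty it deflates the
statistic to about 0.57 and destroys its diagnostic value.)

**Component selection.** `select_components()` fits 1..k models
sequentially and stops when one more component improves the reduced
chi-squared by less than `improvement_threshold` (default 0.02). On a
million-photon three-species mixture this rule selects three components
and rejects a fourth, mirroring how an analyst reads a residual plot.

**Global analysis.** `global_fit()` ties the species lifetimes across a
batch of records -- the donor component fixed at its donor-alone
reference, the FRET lifetimes shared -- while every record keeps its own
amplitudes. Amplitudes are profiled out exactly: for fixed lifetimes the
per-record likelihood is unimodal in the amplitude simplex, and a short
EM warm-up followed by a logit-space quasi-Newton polish solves it
tightly; the outer optimizer then works on at most a few shared
parameters. The outer start comes from fitting the pooled (summed)
histogram, which preserves the species lifetimes by construction and is
far more reliable than a generic log-spaced start.

**Donor reference.** The donor-alone lifetime is a configuration value,
3.46 ns by default for the fusion construct; the non-fusion fluorophore
value (3.51 ns) can be supplied instead where appropriate. The donor is
treated as mono-exponential: its minor second component (a few percent in
amplitude) is deliberately ignored, consistent with how such donors are
conventionally approximated.

**FLIM maps.** Per-pixel photon budgets are far smaller than point
TCSPC records, so `pixel_lifetime_map()` uses the mean-arrival-time
estimator rather than per-pixel MLE: the empirical mean delay is inverted
through the truncated-exponential mean
$m(\tau) = \tau - T e^{-T/\tau}/(1-e^{-T/\tau})$, correcting the finite
window. Pixels under a photon threshold (10 by default) or with mean
delays at the uniform limit are reported as undefined rather than zero.

## FRET conversions

Three closed forms connect the quantities:

* efficiency from lifetimes: $E = 1 - \tau_{DA}/\tau_D$;
* distance from efficiency: $R = R_0 (1/E - 1)^{1/6}$, with
  $R_0 = 63.34$ Å for the donor/acceptor pair used here and an
  orientation factor $\kappa^2 = 2/3$ held fixed (not fitted);
* concentration from average FRET, inverting the binding hyperbola:
  $[A] = K_D \, E / (E_{max} - E)$.

Efficiencies are stored as fractions and rounded only at the reporting
layer. Note a pitfall this creates: a species lifetime of 1.8 ns against
a 3.46 ns donor gives $E = 0.480$, which displays as 48%, while the same
species is often quoted as ~49% when computed from unrounded fitted
lifetimes. The package always reports what it computed and never forces a
conventionally quoted value.

```{r}
fret_efficiency(c(3.46, 1.8, 0.8), tau_d = 3.46)
fret_distance(0.769)
```

## Binding curves and apparent affinity

`fit_binding_curve()` fits
$\mathrm{FRET} = E_{max}[A]/(K_D + [A])$ to per-cell records by
unweighted nonlinear least squares (no credible per-cell weights exist in
this assay; cell populations are heteroscedastic in ways no single
weighting captures), with standard errors from a seeded case-resampling
bootstrap (500 resamples by default). Designs narrower than one decade of
acceptor intensity, or sampled entirely above the fitted $K_D$, raise an
identifiability warning.

Very avid interactions saturate below the resolvable concentration
range. `report_kd_bound()` therefore reports $K_D$ estimates at or below
a resolvable limit (0.5 AU by default), or whose bootstrap interval
reaches zero, as a bound ("K_D < 0.5 AU") rather than a number; ties go
to the conservative bound.

**The AU scale.** Concentrations are relative fluorescence units: 1 AU
is anchored to the mean acceptor intensity of a reference population.
Absolute molar constants are not recoverable from this assay, and none
are claimed; only ratios of apparent $K_D$s across pairings are
interpreted.

## Mass-action assembly model

`equilibrium_species()` solves the coupled equilibria of a catalytic
protomer $A$ (the alpha-beta unit -- the beta interaction is so avid that
it is treated as constitutive), a micropeptide $P$, protomer dimerization
with a single constant $K_{AA}$ applied regardless of micropeptide
occupancy (the simplest coupling consistent with a dimer-of-protomers
product), and optional sequestration of $P$ into tetramers that cannot
bind $A$. Writing $M = [A] + [AP]$, protomer conservation is a quadratic
in $M$ with the stable root $M = 2T_\alpha/(1 + \sqrt{1+8T_\alpha/K_{AA}})$,
and micropeptide conservation is then monotone in free $[P]$, so the
whole state reduces to one bracketed root solve; converged states satisfy
both conservation laws to better than $10^{-10}$ relative, and the unit
tests check them against an independent brute-force grid solver.

`assembly_to_fret_species()` maps a state to the three decay species by
counting acceptor-labeled micropeptides per donor-containing complex --
zero, one, or at least two -- weighting complexes by their catalytic
(donor) content and handling unlabeled competitor binomially through the
acceptor labeling fraction. The open mechanistic question of *why* the
multi-acceptor species shows its particular efficiency is deliberately
left open: species efficiencies are free empirical parameters, not
derived from acceptor counts.

```{r}
st <- equilibrium_species(1, 5, kd_alpha_plm = 5, kd_alpha_alpha = 1.2)
assembly_to_fret_species(st)
```

Sweeping total expression through this model reproduces the
species-population structure seen in pooled-cell lifetime surveys: the
donor-only amplitude falls monotonically with FRET, the multi-acceptor
amplitude rises monotonically, and the single-acceptor amplitude is
biphasic with an interior maximum near an average lifetime of ~2 ns
(`species_population_curve()` bins the records, 12 equal-occupancy bins
by default; bin count and placement are configurable because no standard
convention exists).

## Progressive photobleaching

The forward model assumes each bound acceptor contributes the same
additive transfer rate: with $\rho = E_1/(1-E_1)$, a complex with $k$
surviving acceptors transfers with $E_k = k\rho/(1+k\rho)$. If each
acceptor independently survives a bleach step with probability $s$, the
expected normalized donor signal is the binomial mixture

$$D(s) = \sum_{k=0}^n \binom{n}{k} s^k (1-s)^{n-k}\,(1 - E_k),$$

with the expected acceptor signal $s$ itself. For $n=1$ this collapses
to the exact line $D(s) = 1 - sE_1$; for $n \ge 2$ the curve is convex
-- donor dequenching is delayed because early acceptor losses leave FRET
to the survivors. This is the model's key qualitative signature, and
`simulate_bleach_series()` (independent per-acceptor Bernoulli survival,
donors never bleached, multiplicative Gaussian noise on population sums)
reproduces it by construction; the analytic curve and the Monte-Carlo
generator agree within sampling error by test.

Two statistics quantify the signature. `curvature_statistic()` fits a
quadratic to the axis-normalized trace and returns the second-order
coefficient with a bootstrap confidence interval; positive curvature is
the multi-acceptor signature. `fit_acceptor_multiplicity()` fits the
forward model for each candidate acceptor count (free single-step
efficiency, free fraction of FRET-inactive donors, free scale) and
compares candidates by small-sample-corrected AIC; for $n=1$ the
efficiency and inactive fraction are confounded, so that model carries
one fewer identifiable parameter. Score separations under 2 are reported
as ambiguous rather than forced, and exact ties resolve to the smaller
count.

`classify_acceptor_multiplicity()` combines the two: a curvature
interval strictly above zero, or a decisive information-criterion
preference for $n \ge 2$, calls a trajectory multi-acceptor; otherwise
single. On the reference design (50 steps, 2% multiplicative noise,
single-step efficiency 0.5) this separates one- from two-acceptor
trajectories with >95% accuracy, limited almost entirely by the
confidence level of the curvature interval on the single-acceptor side.
Trajectories may be analyzed per cell or pooled; both enter the same
functions.

The per-step bleach dose is instrument-dependent and is therefore a free
parameter (`step_survival`, default 0.93 per step, which takes a
50-step series to ~2.7% surviving acceptors).

## From classifications to architectures

`stoich_evidence()` holds three categorical findings: micropeptide
multiplicity, essential-subunit multiplicity, and the assembly state of
the catalytic subunit. `consistent_models()` applies the elimination
table over five candidate architectures (single protomer A; two
micropeptide sites B; micropeptide tetramer C; dimer of protomers D;
higher-order oligomer E, interpreted as three or more catalytic
subunits). Unknown findings eliminate nothing; added evidence can only
shrink the set (a tested invariant); contradictory evidence yields an
explicit empty result rather than an error. The linear
donor/acceptor trace for the catalytic-catalytic pairing is mapped to
"exactly one acceptor-labeled partner", i.e. a dimer -- how a trimer
would have manifested in that experiment is not modeled.

`run_pipeline()` wires everything together on synthetic data: assembly
population, global decay analysis, species curve, binding fits, bleach
classification, evidence, elimination. Evidence thresholds are explicit
and deliberately conservative: each bleaching arm uses a 99% curvature
interval (three pairings are tested jointly), and FRET is only declared
present in an arm when the donor trend against acceptor is both
statistically significant and material (donor dynamic range above 5%,
comfortably beyond the 2% noise floor). With dimerization on, the
pipeline concludes architecture D; with dimerization off and single-copy
partners it concludes A; reruns with the same configuration produce
byte-identical JSON reports.

## What the generator does and does not emulate

Emulated: Poisson photon statistics and window truncation; a delta
instrument response (with an optional Gaussian-jitter hook, off by
default -- justified by the clean single-exponential donor-alone fits
this emulates); uniform background (default 0); log-uniform cell
expression over a configurable range (default 500-fold), chosen to
reproduce the wide cell-to-cell spread such surveys show; hyperbolic
concentration dependence of FRET with additive Gaussian noise clipped to
$[0,1)$; per-acceptor Bernoulli photobleaching; mass-action species
amplitudes.

Not emulated: spectral bleed-through and cross-excitation (their
corrections are instrument-specific), donor photobleaching, detector
afterpulsing and dead time, membrane geometry and defocus, photon-level
TTTR records, and any kinetics (the assembly model is equilibrium-only,
with no Hill cooperativity). Passing tests therefore demonstrate that the
estimators recover the truth of *this* generative family at realistic
sizes -- not that real microscope data are free of the systematic effects
listed above.

## Numerical choices and problem sizes

* Decay fits: `nlminb`, relative tolerance $10^{-10}$, one deterministic
  perturbed restart; noiseless round trips recover lifetimes to
  $10^{-4}$ ns.
* Equilibrium: single bracketed `uniroot` to machine tolerance;
  conservation enforced at $10^{-10}$ relative.
* Bootstraps: seeded; 500 resamples for binding standard errors, 400 for
  curvature intervals.
* The test suite runs the full designs where they are cheap (600-cell
  binding populations; 200 trajectories per class for classifier
  accuracy; million-photon single fits) and scaled-down versions where
  they are not (global analysis over 8 records of $3\times10^5$ photons;
  pipeline replicates at $5\times10^4$--$10^5$ photons per record with
  3--4 records), sizes chosen so the full suite completes in a few
  minutes while keeping every estimator in its asymptotic regime.

## Known limitations

* The AU concentration scale is relative; cross-study comparison of
  $K_D$s requires a shared intensity anchor.
* The micropeptide tetramer makes total acceptor intensity overestimate
  the *available* monomer concentration; the tetramer is available as an
  explicit equilibrium species, but no correction is applied to measured
  binding curves.
* Multiplicity classification assumes the additive-rate efficiency
  model; strongly coupled acceptors (non-additive rates) would bias the
  inferred single-step efficiency, though not the linear-versus-convex
  distinction itself.
* The elimination logic is set-based, not probabilistic: it propagates
  categorical findings and does not average over model uncertainty.
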