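---
title: "Secondary neutron spectrometry with an extended-range Bonner sphere set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary neutron spectrometry with an extended-range Bonner sphere set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonnerspec)
```

## The problem

Proton therapy beams produce secondary neutrons wherever the beam strikes
the nozzle, the patient (or phantom), or the room. Their energies span
eleven decades, from room-thermalized neutrons near 2.5e-8 MeV up to the
beam energy (200-250 MeV), and because the dose equivalent per neutron is
strongly energy dependent, radiation-protection work needs the *spectrum*,
not just a count.

The workhorse instrument is the Bonner Sphere Spectrometer (BSS): a thermal
neutron detector placed at the center of polyethylene moderator spheres of
increasing diameter (conventionally 2 to 12 inches, spheres 1-6). Small
spheres respond best to slow neutrons, large spheres to fast ones; the
vector of counts across spheres encodes the spectrum. Conventional sets are
blind above roughly 12 MeV, so extended-range sets add spheres with lead
and aluminium layers (spheres 7-10) whose spallation reactions restore
sensitivity up to hundreds of MeV. Extended-range hardware is rare; a
practical workaround is to *measure* with the conventional six spheres,
*simulate* the extended four, rescale the simulated counts onto the
experimental scale, and unfold the combined ("hybrid") vector.

`bonnerspec` implements that entire chain -- forward folding, count
scaling, MLEM unfolding, lethargy-space spectrum analysis -- plus the
analytical Bragg-curve (Bortfeld) machinery used to validate the proton
beam model through R90/R80/R20 range comparisons. A synthetic-data module
stands in for the transport code and the physical detector so that every
stage can be exercised, tested and demonstrated offline.

## Data model and forward model

Everything lives on a shared logarithmic energy grid
(`build_energy_grid()`): by default 114 bins from 0.001 eV (1e-9 MeV) to
250 MeV, edges equispaced in log10, centers at the geometric mean of their
edges. Energies are MeV everywhere; eV appears only in file headers.

A `fluence_spectrum` stores *bin-integrated* fluence phi_j (cm^-2). The
forward model is the plain discrete sum

    m_i = sum_j R_ij * phi_j

(`fold_counts()`), with R the response matrix in cm^2 (expected counts per
unit fluence). No bin-width weight enters the sum -- that convention
matters, because the *display* representation divides by the lethargy
width ln(E_{j+1}/E_j) (`to_lethargy()`), and confusing the two
representations is the classic unit bug in this field. Folding refuses
grid mismatches outright; re-gridding a tabulated response is an explicit,
log-log interpolation (`interpolate_response()`), with segments touching a
zero response interpolated linearly so zero-padded tables stay finite.

Folded count uncertainties combine two independent sources in quadrature:
the per-bin statistical uncertainty of the fluence (weighted by
w_ij = R_ij phi_j as a weighted RMS, which returns a uniform per-bin
uncertainty unchanged) and the response-matrix uncertainty. The defaults
used by the synthetic pipeline are 2.5% for tally statistics and 10% flat
for experimental counts, typical figures for well-converged transport runs
and commercial neutron ball cart detectors respectively.

## What the synthetic generator emulates

`spectrum_components()` + `generate_spectrum()` build the characteristic
three-peak secondary-neutron spectrum as additive lethargy densities:

* **thermal**: Maxwellian, phi(E) proportional to (E/kT^2) exp(-E/kT); its
  lethargy representation E^2 exp(-E/kT) peaks at exactly E = 2 kT, so the
  default kT = 2.59e-8 MeV places the thermal peak at 5.18e-8 MeV;
* **epithermal / moderation**: a 1/E slowing-down continuum (flat in
  lethargy) between 1e-6 and 0.1 MeV with logistic roll-offs of 0.25
  decades;
* **evaporation**: a Maxwellian with nuclear temperature 0.15 MeV (lethargy
  peak at 0.30 MeV);
* **direct** (intranuclear cascade): a Gaussian in log10 E, default center
  15.36 MeV, width 0.35 decades.

Amplitudes are per-component lethargy peak heights, so relative peak
intensities can be set directly; the defaults (0.55 / 0.15 / 0.59 / 1)
describe a 210 MeV beam with the detector off-axis in a concrete bunker,
where wall return raises the thermal and moderation continuum. Component
additivity is exact by construction and is tested as a property.

`generate_response_matrix()` is a surrogate for a transport-computed
response library: smooth log-normal bells whose peak energy increases
strictly with sphere diameter (1e-7 up to ~1.5 MeV for spheres 1-6), plus,
for spheres 7-10, a saturating high-energy component above ~25 MeV with
sphere 9 carrying the largest high-energy response integral -- the
qualitative fingerprints of real conventional and extended-range response
functions. The shapes are *not* any published matrix: real responses have
asymmetric tails, resonance dips, and absolute scales tied to the central
detector. Passing tests therefore demonstrate the correctness of the
folding/unfolding machinery, not the fidelity of any specific instrument.
Users with a real matrix load it with `read_response()` and bypass the
generator entirely. A seed drives a small (1-2%) reproducible jitter;
identical seeds give bit-identical matrices.

`simulate_counts()` draws Poisson counts at `exposure x folded mean`
(normal approximation beyond 2^30 to stay inside integer-valued Poisson
samplers), with 1/sqrt(N) or a flat 10% relative uncertainty. The default
exposure of 2000 puts conventional-sphere counts at order 1e3-1e4,
i.e. usable counting statistics.

## MLEM unfolding

Recovering 114 bins from 10 counts is an ill-posed inverse problem. The
package uses the canonical Poisson Expectation-Maximization estimator
(`mlem_unfold()`): with sensitivity s_j = sum_i R_ij,

    n_j <- n_j * [ sum_i R_ij m_i / (R n)_i ] / s_j .

Its defining properties -- non-negativity, preservation of the initial
guess's support, monotone non-decreasing Poisson log-likelihood
sum_i [m_i log(Rn)_i - (Rn)_i], scale equivariance, fixed point at any
exactly consistent spectrum -- are all asserted in the test suite.

Choices that the algorithm's name does not pin down:

* **Stopping rule**: maximum over bins of |delta n_j| / max(n_j, 1e-30)
  below `tolerance` (default 1e-5), capped at `max_iterations` (default
  5000). Both the iteration count and the convergence flag are reported.
  A count-residual chi-square stop would also be defensible; the
  spectrum-change rule was chosen because it is what the iteration itself
  controls, and the refolded residuals are reported separately anyway.
* **Initial guess**: a strictly positive flat-in-lethargy spectrum when
  nothing better is available (maximally uninformative with full support).
  `run_pipeline()` instead starts from the transport-predicted spectrum,
  which is how hybrid campaigns actually run the unfolder.
* **No uncertainty weighting**: per-sphere uncertainties ride along for
  reporting; the update is plain MLEM.

Because the system is massively under-determined, the converged *spectrum*
depends on the initial guess; only the refolded counts are strongly
constrained. The package treats refolded-count residuals as the primary
quality metric (on the noise-free synthetic set they reach below 0.1% per
sphere within 2e5 iterations, a few seconds of runtime), and the
spectrum-level comparison `compare_spectra()` -- mean of
|a_j - b_j| / max(a_j, 1e-30) over bins up to 12 MeV, both-zero bins
excluded, first argument the reference -- is the honest headline metric
for shape agreement inside the conventional set's validity range.

The hybrid assembly follows the measurement protocol: the average
proportional factor mean(experimental_i / simulated_i) over the measured
spheres (`compute_scaling_factor()`; arithmetic mean by default, geometric
available since "average" is ambiguous), applied multiplicatively to the
simulated counts of the remaining spheres
(`assemble_hybrid_counts()`). The arithmetic mean has the pleasant
round-trip identity that the mean ratio of experimental to scaled
simulated counts is exactly one.

## Spectrum analysis choices

* Peak tables (`find_peaks()`) read intensities in the lethargy
  representation, because that is the representation in which such tables
  and figures are universally quoted. Default windows: thermal 1e-9 to
  1e-6 MeV, evaporation 0.1 to 5 MeV, direct 5 to 250 MeV. The 5 MeV
  evaporation/direct split is a package choice: published evaporation
  peaks sit at 0.3-0.94 MeV and direct peaks at 7.6-124 MeV, so any cut
  between ~2 and ~6 MeV separates them; it is configurable.
* Ties at equal maxima resolve to the lowest-energy bin; regions that are
  exactly zero are omitted with a warning rather than reported as
  zero-height peaks.
* `region_fluence()` pro-rates partially covered bins by log-energy
  fraction (uniform-in-lethargy within a bin), making it exactly additive
  over disjoint windows.
* `smooth_adjacent()` is the three-point moving average (two-point at the
  ends) used to clean artificial single-bin structure from unfolded
  spectra; it never widens the data range.
* `region_ratio_report()` packages the with/without-environment
  comparisons (thermal-to-broad-peak intensity ratios, thermal /
  moderation / total fluence ratios) used to quantify room-return effects.

## Depth-dose validation

The beam model is validated through ranges, not absolute dose. The
analytical Bragg curve (`bortfeld_model()`) combines the power-law
range-energy relation (exponent p = 1.77 for water, configurable) with
Gaussian range straggling sigma:

    D(z) = Phi * Int_0^inf [u^(1/p-1) + b u^(1/p)] N(z + u; R0, sigma) du

The closed form is a pair of parabolic cylinder functions; the package
evaluates the integral by Gauss-Legendre quadrature instead, with a
substitution u = w^p that removes the integrable end-of-range singularity
and composite panels near the falloff. Against adaptive quadrature the
implementation agrees to ~1e-8 relative, and in the sigma -> 0 limit it
reproduces the un-straggled power law to better than 0.5%.

`fit_bortfeld()` does Levenberg-Marquardt least squares over
(R0, sigma, Phi, b), initialized from the curve itself (R0 from the 80%
distal depth, sigma from the 80-20 distal distance / 1.683). On noise-free
model-generated curves the parameters are recovered to machine precision
across a grid of (R0, sigma); an iteration-cap exit with negligible
residual is accepted as converged because zero-residual fits stall
polishing at a parameter bound. R-levels (`extract_r_levels()`) are read
off the *distal* falloff only: the first crossing of each fraction of the
maximum beyond the global maximum, linearly interpolated, evaluated on a
0.001 cm grid for fitted models. The `"200"`/`"210"` MeV presets of
`generate_depth_dose()` are calibrated once per session (a two-parameter
Nelder-Mead solve, cached) so their noise-free curves reproduce the
reference simulated ranges -- 25.85/25.92/26.27 cm at 200 MeV and
28.08/28.17/28.56 cm at 210 MeV -- to within ~0.01 cm.

Measured ranges are corrected for the chamber's water-equivalent thickness
by a rigid shift (`wet_correct()`, default +WET, e.g. +0.4 cm for a Bragg
peak chamber; the sign is configurable because depth-referencing
conventions differ between facilities). `compare_r_tables()` produces the
standard validation report: percent differences use the experimental value
as denominator and are rounded to two decimals half-even, matching how
such tables are printed.

## Worked pipeline

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1)
out <- run_pipeline(cfg, "pipeline_out")
out$scaling_factor        # experimental counts per simulated count
out$refold_residuals      # per-sphere refolded-count residuals
out$peaks                 # thermal / evaporation / direct peak table
out$avg_rel_diff_pct      # unfolded vs reference, bins up to 12 MeV
```

Every stage failure is reported with its stage name; re-running an
identical configuration reproduces byte-identical output files (all
randomness flows from `seed`, and writers emit full-precision text).

## Problem sizes and runtime

The shipped tests and the reproduction script use the full 114-bin grid
and 10-sphere set throughout; the deep MLEM consistency check runs 2e5
iterations (seconds), the Bortfeld recovery grid covers four (R0, sigma)
combinations on 400-point curves, and the Poisson dispersion check uses
1e4 replicates at mean 100. These sizes keep the whole suite under a
minute while exercising every code path at production dimensions.

## Known limitations

* The response surrogates are qualitative; absolute fluences and
  facility-specific scaling factors require a real response matrix and
  transport-computed spectra, which the package deliberately does not
  attempt to reproduce.
* MLEM is the only unfolder; no regularized, weighted, or stochastic
  variants are provided.
* No fluence-to-dose-equivalent conversion (H*(10)) is included.
* The Bortfeld fit assumes a single pristine Bragg peak; spread-out
  peaks, lateral profiles and nuclear-halo corrections are out of scope.
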