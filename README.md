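# bonnerspec

Secondary-neutron spectrometry around proton therapy beams, in R:
forward folding of fluence spectra through Bonner-sphere response
matrices, MLEM unfolding of hybrid experimental/simulated count vectors,
lethargy-space spectrum analysis, and proton-beam validation via
analytical Bragg-curve (Bortfeld) fitting with R90/R80/R20 range
extraction.

## Who this is for

Medical and health physicists characterizing stray neutron fields with a
Bonner Sphere Spectrometer (BSS) — six polyethylene moderator spheres of
increasing diameter around a thermal-neutron detector, optionally
extended above ~20 MeV by four spheres with lead/aluminium layers. The
package implements the analysis chain used when only the conventional
six spheres can be measured and the extended four must be simulated:
measured and rescaled simulated counts are combined into one hybrid
vector and unfolded into a 114-bin spectrum from 0.001 eV to 250 MeV.

## The models

**Forward model.** Counts of sphere *i* are the discrete folding of the
bin-integrated fluence spectrum through the response matrix (cm²):

    m_i = Σ_j R_ij φ_j

**Unfolding.** Maximum Likelihood Expectation Maximization for the
Poisson inverse problem `m_i ~ Poisson((Rn)_i)`, the multiplicative
update with sensitivity normalization

    n_j ← n_j · [Σ_i R_ij m_i/(Rn)_i] / [Σ_i R_ij]

which preserves non-negativity and support and never decreases the
Poisson log-likelihood. With 10 counts and 114 bins the problem is
under-determined: the refolded-count residuals are the primary quality
metric and the initial guess (by default the transport-predicted
spectrum, as in real hybrid campaigns) shapes the result.

**Beam validation.** The analytical Bragg curve with power-law
range–energy (p = 1.77 in water) and Gaussian range straggling,

    D(z) = Φ ∫₀^∞ [u^{1/p−1} + b·u^{1/p}] N(z+u; R0, σ) du,

is fitted by Levenberg–Marquardt; R90/R80/R20 are read off the distal
falloff of the fitted model and compared between simulation and
measurement.

A synthetic-data module generates three-peak secondary-neutron spectra
(thermal Maxwellian, 1/E moderation continuum, evaporation Maxwellian,
Gaussian-in-log direct peak), surrogate response matrices, Poisson
counts, and preset 200/210 MeV depth-dose curves, so the whole chain
runs and is tested without transport simulations or detector hardware.

## Worked example

Fit a synthetic 200 MeV Bragg curve and extract its ranges:

```r
library(bonnerspec)
fit <- fit_bortfeld(generate_depth_dose("200"))
print(fit)
#> <bortfeld_fit> R0 = 25.917 cm, sigma = 0.265 cm, tail = 5.555e-19, p = 1.77
#>   r90 = 25.850 cm, r80 = 25.920 cm, r20 = 26.270 cm
#>   relative RMSE = 0
```

R90 is the depth at which the distal dose falls to 90% of the Bragg-peak
maximum; the 200 MeV preset is calibrated to 25.85/25.92/26.27 cm.
Comparing simulated against measured range tables:

```r
cmp <- compare_r_tables(
  data.frame(energy = c(200, 210), r90 = c(25.85, 28.08),
             r80 = c(25.92, 28.17), r20 = c(26.27, 28.56)),
  data.frame(energy = c(200, 210), r90 = c(25.83, 28.10),
             r80 = c(25.87, 28.14), r20 = c(26.37, 28.64)))
print(cmp)
#> R-level comparison (MC vs EXP)
#>  energy level mc_cm exp_cm abs_diff_cm diff_pct
#>     200   r90 25.85  25.83        0.02     0.08
#>     200   r80 25.92  25.87        0.05     0.19
#>     200   r20 26.27  26.37        0.10     0.38
#>     210   r90 28.08  28.10        0.02     0.07
#>     210   r80 28.17  28.14        0.03     0.11
#>     210   r20 28.56  28.64        0.08     0.28
#>
#> Between-energy depth differences (cm)
#>  level energy_from energy_to mc_cm exp_cm
#>    r90         200       210  2.23   2.27
#>    r80         200       210  2.25   2.27
#>    r20         200       210  2.29   2.27
#>
#> average depth difference: MC 2.26 cm, EXP 2.27 cm
```

Sub-0.4% range agreement and matching 210−200 MeV depth shifts are the
acceptance signature of a validated beam model. The full spectrometry
chain — generate a reference field, fold it, draw noisy experimental
counts for spheres 1–6, rescale the simulated counts of spheres 7–10,
unfold the hybrid vector, and analyze the peaks:

```r
out <- run_pipeline(pipeline_config(seed = 1), "pipeline_out")
round(out$scaling_factor)     # 1973 experimental counts per simulated count
print(out$peaks, row.names = FALSE)
#>       region   energy_MeV intensity rel_intensity
#>      thermal 5.619320e-08  1070.928     0.5539800
#>  evaporation 2.808491e-01  1189.914     0.6155299
#>       direct 1.406585e+01  1933.153     1.0000000
round(out$avg_rel_diff_pct, 1)  # 1.7  (% vs reference, bins <= 12 MeV)
```

The unfolded peak table recovers the generator's relative intensities
(thermal 0.55, evaporation ≈ 0.6 including the moderation continuum,
direct 1) with peak energies at 5.2e-8, 0.30 and 15 MeV, and the
unfolded spectrum agrees with the reference to ~2% on average below
12 MeV, the validity range of the conventional sphere set.

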