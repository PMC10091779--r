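# t2sivim — combined T2\*-diffusion relaxometry of the placenta

`t2sivim` is an R package for quantitative analysis of combined
T2\*-diffusion placental MRI, where echo time (TE) and diffusion weighting
(b) are varied jointly in one acquisition. It is aimed at perinatal-imaging
researchers who want to turn such acquisitions — or the standard multi-echo
gradient-echo (MEGE) series — into parameter maps, ROI summaries,
gestational-age normative curves and cross-sectional z-scores, for example
to compare pregnancies complicated by preterm premature rupture of membranes
(PPROM) against healthy controls.

## Models

Three nested magnitude-signal models, with $T_{E,\min}$ the lowest acquired
TE, diffusivities in 10⁻³ mm²/s:

* **Mono-exponential T2\*** (MEGE series):
  $S(TE) = S_0\,e^{-TE/T_2^*}$ — absolute TE, so $S_0$ is proton density.
* **T2\*-ADC**:
  $S(TE,b) = S_0\,e^{-(TE-T_{E,\min})/T_2^*}\,e^{-b\,\mathrm{ADC}}$.
* **T2\*-IVIM** (two compartments — fast/perfusing blood and slow/diffusing
  tissue water):
  $S(TE,b) = S_0\left[f\,e^{-(TE-T_{E,\min})/T_{2,\mathrm{fast}}^*}e^{-bD^*}
  + (1-f)\,e^{-(TE-T_{E,\min})/T_{2,\mathrm{slow}}^*}e^{-b\,\mathrm{ADC}}\right]$.

Fitting is bounded Levenberg–Marquardt with analytic Jacobians, segmented
(high-b first) initialization for the IVIM model, seeded multistart, and a
post-hoc labeling rule that makes the larger-diffusivity compartment the
perfusion one. Cohort statistics: per-quantity ordinary-least-squares
control regression over gestational age, homoscedastic cross-sectional
z-scores, Welch t-tests between groups, and z-score/outcome regressions.
A Rician-noise simulator, a lobule-structured placental phantom and a
two-group cohort generator provide the validation bed; the generator's
default control trends carry the published normative slopes.
See `vignettes/placental-t2s-ivim.Rmd` for the full methods account.

## Worked example

Build the default 264-point acquisition scheme, then run a small
slope-recovery experiment: simulate 30 control subjects whose ROI-mean
MEGE-T2\* follows the default normative trend (−3.004 ms/week), fit every
voxel, and refit the regression.

```r
library(t2sivim)

scheme <- build_paper_scheme()
scheme
#> Acquisition scheme: 264 points, 4 TEs (TEmin 78 ms), 14 unique b-values

rec <- slope_recovery("mege_t2star", n_control = 30, n_voxels = 50, seed = 5)
print(rec, digits = 4)
#>      quantity slope_true slope_recovered slope_error     r2 residual_sd
#> 1 mege_t2star     -3.004          -2.729       0.275 0.8745       5.571
#>   n_control
#> 1        30
```

The recovered slope (−2.73 ms/week) agrees with the generating slope to
within the design's sampling error (≈0.24 ms/week at 30 subjects with
5 ms between-subject SD). `r2 = 0.87` is the control regression's fit and
`residual_sd` is the SD that scales the z-scores.

An end-to-end demonstration — simulate a 20 + 8 two-group cohort, fit all
three models, and write normative, z-score, group-test and outcome tables
plus a provenance JSON —

```r
run_demo("demo_out", seed = 7)
```

A thin command-line front-end over the same functions lives at
`inst/cli/t2sivim.R` (subcommands `simulate-phantom`, `simulate-cohort`,
`fit`, `cohort`, `demo`).

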