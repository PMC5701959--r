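# dynqsm

Estimation of MRI contrast-agent concentration and steady-state cerebral
blood volume (CBV) from dynamic susceptibility contrast (DSC) phase data,
via quantitative susceptibility mapping (QSM).

## Who this is for

DSC-MRI perfusion normally converts the bolus-induced magnitude signal
drop into concentration through the transverse relaxivity r2\* — which is
unknown in vivo and differs between blood and tissue.  The phase route
avoids relaxivity entirely: a paramagnetic gadolinium agent raises tissue
susceptibility χ in proportion to its concentration,

    [CA] = (χ_Gd − χ_0) / χ_mol ,          χ_mol = 308 ppm/M

and QSM reconstructs χ from the gradient-echo phase by dipole
deconvolution.  With the susceptibility time series anchored to a CSF
reference (ventricular CSF sees no contrast agent), the steady-state CBV
follows from the tissue-versus-blood susceptibility changes between
baseline and the post-bolus steady state:

    CBV = 100 · (1/ρ) · (1 − Hct_LV)/(1 − Hct_SV) · Δχ_tissue / Δχ_blood

in mL/100 g, with ρ = 1.04 g/mL and hematocrits 0.45 / 0.25.  Blood Δχ is
measured in the superior sagittal sinus from *unfiltered* drift-corrected
phase through the infinite-cylinder relation
χ = 6φ / (γ·TE·(3cos²θ − 1)·B0).

The package implements the full pipeline — digital head phantom and
forward simulation, quality-guided phase unwrapping, background-field
removal, thresholded and regularized dipole inversion, criteria-based CSF
reference selection, concentration / ΔR2\* / CBV / relaxivity estimation,
and test-retest repeatability analyses (ICC, Bland-Altman, threshold and
regularization sweeps, age regression) — for methodological work on
dynamic QSM where ground truth is required.

## Worked example

```r
library(dynqsm)

cfg <- run_config(grid_shape = c(64, 64, 64), seed = 1, noise_sd = 0)
out <- run_pipeline(cfg)
print(out$cbv, digits = 4)
#>       region delta_chi_tissue delta_chi_tissue_raw delta_chi_blood   cbv method
#> wm        wm         0.004402             0.004832          0.1698 1.828    qsm
#> gm        gm         0.009184             0.008450          0.1698 3.813    qsm
#> brain  brain        0.008066             0.008070          0.1698 3.349    qsm
out$relaxivity
#> <relaxivity_fit> r2* = 99.67 mM^-1 s^-1 (intercept -0.256 s^-1, r = 0.999, n = 56)
```

The phantom's true CBV is 1.91 mL/100 g in white matter and 3.85 in grey
matter; the pipeline recovers 1.83 and 3.81 from the simulated
acquisition (TE 29 ms, B0 3 T, 70 frames at 1.24 s), i.e. within a few
percent.  `delta_chi_tissue` is the steady-state tissue susceptibility
change (ppm) after the regional cross-talk calibration
(`delta_chi_tissue_raw` is the plain region mean); `delta_chi_blood` is
the geometry-calibrated vessel measurement (true value 0.171 ppm at the
default dose).  The pooled ΔR2\*-versus-concentration regression over
the uncorrected voxelwise maps lands somewhat above the configured
tissue relaxivity of 85 mM⁻¹s⁻¹, reflecting the residual concentration
underestimation of raw susceptibility maps; the relaxivity estimator
itself recovers the configured value within a few percent when given
the true concentration series (see the test suite).

Theory-expected steady-state values (the arithmetic behind the expected
ranges for a 5-10 mM bolus peak with peak-to-tail ratio 9):

```r
print(theory_expected_values(peak_conc_range = c(5, 10),
                             peak_to_tail_ratio = 9), digits = 4)
#>   compartment bound concentration delta_chi delta_chi_report
#> 1       blood lower       0.55556  0.171111            0.170
#> 2       blood upper       1.11111  0.342222            0.340
#> 3          wm lower       0.01505  0.004635            0.005
#> 4          wm upper       0.03010  0.009270            0.009
#> 5          gm lower       0.03033  0.009343            0.009
#> 6          gm upper       0.06067  0.018685            0.019
```

See the methods vignette (`vignettes/dynamic-qsm-methods.Rmd`) for the
model, the phantom design, and the reasoning behind every numerical
choice in the reconstruction chain.

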