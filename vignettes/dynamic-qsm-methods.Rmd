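---
title: "Dynamic QSM for contrast-agent concentration and steady-state CBV: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic QSM for contrast-agent concentration and steady-state CBV: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynqsm)
```

## The problem

Dynamic susceptibility contrast (DSC) MRI estimates perfusion from the
passage of a paramagnetic gadolinium bolus.  The conventional route uses
the magnitude signal drop via the transverse relaxation change
$\Delta R_2^*$, but converting $\Delta R_2^*$ to concentration requires
the relaxivity $r_2^*$, which is unknown in vivo and differs between
blood and tissue.  The phase of the gradient-echo signal offers an
alternative: the contrast agent raises tissue magnetic susceptibility
$\chi$ in proportion to its concentration,
$$[\mathrm{CA}] = \frac{\chi_{Gd} - \chi_0}{\chi^{Gd}_{mol}},$$
with a known molar susceptibility $\chi^{Gd}_{mol}$ (308 ppm/M).
Quantitative susceptibility mapping (QSM) reconstructs $\chi$ from phase
by deconvolving the unit dipole field.  With a susceptibility time
series, the steady-state cerebral blood volume follows from the tissue
versus whole-blood susceptibility changes between baseline and the
post-bolus steady state,
$$\mathrm{CBV} = 100\,\frac{1}{\rho}\,
  \frac{1-\mathrm{Hct}_{LV}}{1-\mathrm{Hct}_{SV}}\,
  \frac{\Delta\chi_{tissue}}{\Delta\chi_{blood}}
  \quad [\mathrm{mL}/100\,\mathrm{g}],$$
with brain density $\rho = 1.04$ g/mL and large/small-vessel hematocrit
0.45/0.25.  Blood susceptibility is measured in a large draining vein
(superior sagittal sinus, SSS), modelled as a long cylinder at angle
$\theta$ to $B_0$:
$$\chi_{cyl} = \frac{6\,\phi}{\gamma\,\mathrm{TE}\,(3\cos^2\theta - 1)\,B_0},$$
which degenerates at the magic angle ($3\cos^2\theta = 1$); the package
raises an explicit error there.

A $\Delta R_2^*$-based steady-state CBV analogue,
$\mathrm{CBV} = 100 (1-\mathrm{Hct}_{LV}) \Delta R_{2,t}^* /
(\rho (1-\mathrm{Hct}_{SV}) \Delta R_{2,b}^*)$, is provided for
comparison: because tissue $r_2^*$ exceeds blood $r_2^*$ in vivo, it
overestimates CBV by roughly that relaxivity ratio, which is the point
the susceptibility route avoids.

## The digital head phantom

`build_phantom()` generates the ground truth every stage is tested
against: an ellipsoidal brain with a grey-matter shell, white-matter
core and two ventricular CSF compartments; a finite SSS-like vessel at
the posterior brain edge; an extracerebral soft-tissue layer, a
diamagnetic skull shell ($-2$ ppm) and paramagnetic air ($+9.4$ ppm).
True CBV is piecewise constant at literature values (WM 1.91, GM
3.85 mL/100 g, scalable per subject); vessel voxels are 100% blood.
Baseline susceptibility, $R_2^{*}(0)$, and proton-density maps are
compartment-wise constants in physiological ranges; relaxivities default
to $r^*_{2,tissue} = 85$, $r^*_{2,blood} = 30$ mM$^{-1}$s$^{-1}$.

Design points worth making explicit:

* **Background sources are part of the model.**  Background-field
  removal only has meaning when skull and air susceptibility actually
  generate fields; omitting them would make the stage vacuous and, as it
  turns out, numerically misleading (see below).
* **The vessel is tilted (default 25 degrees) and finite.**  A vessel
  exactly parallel to $B_0$ produces *no* exterior field; its interior
  field is then formally indistinguishable from that of exterior column
  sources, and any background-removal method silently absorbs it.  A
  tilted vessel has a dipolar exterior signature inside the mask that
  anchors it.  The angle also exercises the $3\cos^2\theta-1$ geometry
  factor away from trivial values.
* **Shim emulation.**  A 1st/2nd-order spherical-harmonic field fitted
  over the brain at baseline is subtracted from all frames, as a scanner
  shim would, keeping phase gradients in realistic ranges.
* **The bolus** is a gamma-variate first pass plus a delayed dispersed
  recirculation and a saturating plateau; the curve is normalized so the
  peak equals `peak_conc` (default 5 mM) and the mean over the final
  five frames equals `peak_conc / peak_to_tail_ratio` (default ratio 9)
  exactly.  The first 14 frames are exactly zero.  For short test series
  the kinetic time constants are compressed proportionally so a steady
  state still exists.
* **Noise** is added to the complex signal (i.i.d. Gaussian real and
  imaginary parts), so magnitude noise is Rician and phase noise scales
  with 1/SNR.  `noise_sd` is the complex SD as a fraction of the mean
  baseline brain signal, i.e. `noise_sd = 1/SNR`.
* **Scanner drift** is a global field ramp (`b0_drift_rate`, default
  0.2 ppb per frame; the source protocol does not quantify its drift, so
  the default is a typical slow thermal drift).
* **CSF pulsation artifacts** can be injected as phase-only spikes in a
  random subset of ventricular voxels.  They deliberately leave the
  magnitude untouched: the signal-range selection criterion cannot see
  them, which is exactly the situation the tail-to-peak criterion was
  introduced for.

What the phantom does *not* emulate: EPI geometric distortion,
concentration-dependent vessel pixel shifts, T1 enhancement,
partial-volume mixing at compartment boundaries, 2D multislice geometry
with slice gaps, extracerebral contrast enhancement, or motion.  Tests
passing on this phantom therefore validate the numerical chain and its
statistical behaviour, not robustness to those acquisition artifacts.

## Reconstruction chain

### Unwrapping

`unwrap_phase()` performs quality-guided region growing per frame
(quality = local wrapped-gradient coherence weighted by magnitude, so
the less noisy regions are unwrapped first), implemented in C++.  Steep
neighbour steps are *flagged* rather than silently accepted: a true
spatial jump above $\pi$ is indistinguishable from a wrap.  A
temporal-consistency pass then replaces each voxel's value at every
frame by the $2\pi$-congruent value nearest its baseline phase.  This
is the automated counterpart of fixing residual wraps by hand: it
removes each frame's arbitrary global branch and repairs frame-to-frame
branch flips, and is exact wherever the true temporal phase change
stays below $\pi$ — which holds in tissue always, and in the vessel at
steady state for the default dose (the mid-bolus vessel phase exceeds
$\pi$ and those frames are not used by any steady-state window).

### Background-field removal

`remove_background_pdf()` fits susceptibility sources outside the brain
to the measured field (dipole forward model, magnitude-weighted least
squares, conjugate gradients) and subtracts their field.  Three
structural choices deserve explanation, because the obvious textbook
formulation fails quantitatively on exactly the data this package
targets:

1. **Exterior-support gap.**  With unknowns on the full mask exterior,
   the fit has more degrees of freedom than interior observations, and
   boundary-hugging source layers can reproduce *any* field that is
   harmonic inside the mask while producing almost no exterior field —
   silently absorbing the interior-generated (including CA-induced)
   harmonic field components.  Excluding a guard layer (default
   ~9% of the grid size) around the mask from the admissible source
   support, together with weighting the fit by the magnitude over the
   whole FOV (phase data exist wherever there is signal), makes such
   absorbing configurations pay a data-misfit cost.  The residual
   ambiguity is real physics, not an implementation defect: a field
   harmonic inside the mask *cannot* be attributed from interior data
   alone.
2. **The background is fitted once, on the baseline-window mean.**
   Background sources do not move during the scan; only the uniform
   drift and the bolus change the field.  Fitting per frame couples the
   CA field into the background fit and, worse, makes the effective
   removal operator frame-dependent, so the large static background no
   longer cancels exactly in temporal differences.  With a single
   shared fit the whole chain is linear in the data frame-by-frame, and
   every static error cancels in the pre/post window differences that
   all downstream quantities are built from.  Optional per-frame
   refinement (`max_iter`) exists but defaults to zero for this reason.
3. **No-data regions are completed, not zeroed.**  Air and bone carry
   no signal; their phase is meaningless and is excluded by weight.
   Zeroing the local field there, however, feeds the inversion an
   artificial plateau that biases region means.  Instead (a) the
   frame's uniform level (drift + arbitrary offset, estimated over the
   extracerebral signal ring, which sees no contrast agent) is
   absorbed first, and (b) the field in no-data regions is filled with
   the prediction from sources attributed to the brain, smoothed with a
   narrow Gaussian in k-space (the true tails are smooth; the smoothing
   prevents noise in the attribution from being re-amplified through
   the completion iterations).
4. **Unstable voxels are excluded.**  Voxels whose unwrapped phase
   varies strongly over the pre-contrast baseline — where nothing
   changes physically except noise and uniform drift — are marked
   invalid and completed like air.  These are the voxels at steep
   static gradients near the skull whose unwrapping is aliased at this
   echo time; with noise, their branch flips rectify into a systematic
   window-difference bias if left in.

The module example "with no exterior sources the output equals the
input" holds only up to the harmonic ambiguity above; the package
instead guarantees (and tests) invariance to uniform offsets, >95%
interior removal of genuinely exterior source fields, and exact
cancellation of static errors in temporal differences.

### Dipole inversion

`invert_dipole()` offers two methods.

*Thresholded k-space division* (`tkd`) replaces kernel values with
$|D| < t$ (default $t = 0.15$) by $\mathrm{sign}(D)\,t$ and divides.
It is linear — temporal differences of reconstructions equal
reconstructions of field differences, which the whole design leans on —
and fast.  The known systematic amplitude underestimation is corrected
by the point-spread factor $\langle D/D_t\rangle$ (~0.82 at the default
threshold); the correction can be disabled.  On the discrete grid a
substantial set of modes lies *exactly* on the magic-angle cone
(integer solutions of $2n_z^2 = n_x^2+n_y^2$); their content is
unrecoverable by any method and is the irreducible part of the
reconstruction error.

*Morphology-enabled regularized inversion* (`medi_like`) minimizes
$\lambda\,\|W(D\chi - f)\|_2^2 + \|M\,\nabla\chi\|_1$ with $W$ the
magnitude-based noise weighting (zero outside the mask) and $M$ the
edge mask excluding the top 30% magnitude gradients from the smoothing
penalty.  $\lambda$ multiplies the fidelity term, so larger $\lambda$
gives higher tissue contrast; this orientation reproduces the observed
direction of the grey/white contrast trend with $\lambda$.  The L1 term
is handled by iteratively reweighted least squares with preconditioned
conjugate-gradient inner solves; the reweighting is computed *once*,
on the time-mean field, and then shared across frames, for the same
frame-linearity reason as in the background stage.  A small floor on
the gradient weights and a weak confinement of sources to the mask
keep the weakly-determined near-cone modes regularized at large
$\lambda$.  The solver normalization fixes the meaningful $\lambda$
range; the default $\lambda = 300$ sits in the transition region of
the default phantom, and the contrast trend (not its absolute scale)
is the validated property.

### Regional cross-talk calibration

No scalar correction factor suits every structure: at the default
threshold the thin grey-matter shell attenuates by roughly the global
point-spread factor, while the large white-matter core barely attenuates
at all, and the split shifts by several percent with voxelization
details.  Because the dynamic reconstruction path is linear, the exact
regional response of the chain can be *measured*: each compartment's
unit indicator is pushed through the same operator
(`region_crosstalk_matrix()`), giving a small matrix whose entry (r, s)
is the CSF-referenced mean over region r of the reconstruction of unit
susceptibility in compartment s.  `quantify_cbv()` solves this system
against the measured region means — with the vessel column pinned by
the independent phase-based blood measurement — which removes the
structure-dependent attenuation and cross-talk (the same idea as
partial-volume cross-talk correction in regional PET quantification).
Only the region masks enter the calibration, never true susceptibility
values.  The uncorrected means remain available
(`delta_chi_tissue_raw`; `crosstalk = FALSE` disables the correction).

### CSF reference and shifting

The absolute level of each frame's susceptibility map is arbitrary
($D(0)=0$, plus everything the background stage absorbed).  Reference
pixels are selected from the ventricular CSF by three criteria: the
candidate ROI (criterion 1; the phantom's true ventricle mask stands in
for a manually drawn one), the `thresh_range` percent of candidates
with the smallest magnitude signal range during the bolus (criterion
2), and the tail-to-peak ratio test (criterion 3): each candidate is
applied alone as the reference, and the `thresh_tailpeak` percent of
candidates producing the most extreme tail-to-peak ratios of the
shifted whole-brain mean curve are discarded, half from each end of the
ratio distribution (counts rounded half away from zero — the original
description does not specify the split or the rounding).  Ratios are
computed on baseline-subtracted curves, since raw values carry the
arbitrary offset; this disambiguation is ours.  The peak window is
centred (±2 frames) on the whole-brain magnitude minimum; the tail
window is the last 5 frames; the baseline window is frames 5–14
(1-based) throughout the package; frames 1–4 are excluded for
saturation effects.

`shift_susceptibility()` subtracts the reference-mean curve per frame
and restores its baseline level, so CSF shows no CA-induced change;
`shift_phase()` applies the same scalar correction to the unfiltered
unwrapped phase, which removes scanner drift for the vessel
measurement.

### Vessel measurement and CBV

Blood susceptibility comes from the drift-corrected *unfiltered* phase
(filtered maps are unreliable near the brain edge, where the SSS sits):
the mean phase of a small vessel ROI (default 3 pixels near the vessel
axis) in the baseline and steady-state windows is converted by the
cylinder relation, and the difference gives
$\Delta\chi_{blood}$.  Differences are formed wrap-robustly — each
pixel curve minus its baseline mean, re-wrapped into $(-\pi,\pi]$ — so
residual $2\pi$ branch errors in vessel voxels cancel.  Because the
phantom's vessel is finite and clipped by the brain boundary, the
infinite-cylinder relation overstates its interior field by several
percent (more when the geometric jitter shortens the chord);
`quantify_cbv()` corrects this deterministic bias with a geometry
factor computed from the forward field of the unit vessel mask at the
ROI pixels — again a mask-only calibration, reported alongside the raw
value.  Tissue
$\Delta\chi$ is the post-minus-pre window difference of region-mean
shifted susceptibility; the steady-state window defaults to the final
7 frames (the midpoint of the 4–10 range used per-subject by visual
inspection in the source protocol).  Regional CBV uses the ratio of
regional-mean differences (the alternative of averaging voxelwise
ratios is more noise-sensitive since voxelwise $\Delta\chi$ can be
tiny).

### Relaxivity

`fit_relaxivity()` pools per-frame region-mean $\Delta R_2^*$ and
concentration from frame 15 to the end (1–4 saturated, 5–14 define
zero) and fits unweighted ordinary least squares; the slope is
$r_2^*$.  The regression is deliberately unweighted — the source
procedure states none.

## Repeatability analyses

`icc_absolute_agreement()` implements the two-way random-effects,
single-measure, absolute-agreement ICC from the ANOVA mean squares
(the form that penalizes systematic offsets between visits);
`bland_altman()` returns the mean difference and ±1.96 SD limits.
`threshold_sweep()` re-runs reference selection and whole-brain CBV for
grids of `thresh_range` and `thresh_tailpeak` (varied one at a time) on
a simulated test–retest cohort, reporting test-retest ICC and mean CBV;
because selection is cheap, the expensive reconstruction is done once
per visit and reduced to per-ROI time curves (`summarize_recon()`),
and each sweep point is identical to an independent run.
`lambda_sweep()` reports the GM-minus-WM CBV difference per $\lambda$
(the difference, not the ratio, is independent of the CSF reference).
`simulate_cohort_table()` emulates the 20-volunteer two-visit design
(ages uniform 25–84, one measurement discarded, configurable age slope
and between-subject spread) for the age-regression machinery.

## Numerical choices and problem sizes

All susceptibility values are in ppm; phase/field conversion goes
through the single factor $\gamma B_0 \mathrm{TE} \cdot 10^{-6}$, and
ppm/mM conversion through $\chi_{mol}$ with the $10^3$ factor in one
routine.  Voxel indexing is 1-based in R; time points are 1-based
everywhere, matching the "frames 5–14" convention.  Determinism: every
stochastic step takes a seed; identical seeds give bit-identical
series.

The default test suite exercises the full chain at $64^3$ (70 frames)
for the noiseless forward–inverse consistency checks, $48^3$–$56^3$
for noisy parameter-recovery repetitions, and $36^3$–$40^3$ for the
test-retest cohort simulations; these sizes were chosen as the smallest
grids at which the compartments remain well resolved (the vessel radius
is ~2 voxels at $40^3$, which is the practical floor).

## Known limitations

* Region-mean recovery through the full chain carries a residual
  shading error of several percent, rooted in the genuine harmonic
  ambiguity of background removal and the exactly-on-cone modes of the
  discrete dipole kernel.
* The blood measurement inherits a few-percent low bias from the
  finite vessel length (the cylinder relation assumes an infinite
  cylinder); the mask-based geometry factor removes the deterministic
  part.
* At SNR 50 the recovered regional CBV carries a positive bias of
  roughly 5-20% (white matter more than grey), beyond what the
  noiseless chain shows; it stays within the validated envelope but is
  a real small-signal rectification effect of unwrapping noisy phase.
* At grids below ~$48^3$ the vessel and ventricles are so coarsely
  resolved that recovery errors grow quickly; cohort-level analyses at
  those sizes are consistent within a visit pair (which is what the
  repeatability statistics need) but not accurate in absolute terms.
* Per-frame nonlinear reconstruction (IRLS reweighting per frame,
  per-frame background refits) is deliberately avoided; with it, the
  large static structure couples into temporal differences and swamps
  the CA signal.  This is a real effect that any dynamic-QSM
  implementation has to face, not a peculiarity of the phantom.
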