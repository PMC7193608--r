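---
title: "Models and methods behind shuntfield"
author: "shuntfield authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shuntfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shuntfield)
```

`shuntfield` compares scalp-applied (transcutaneous, TES) and
skull-applied (subcutaneous, SES) electrical stimulation of the brain.
The scientific question behind it is the *shunting effect*: how much of
a current injected at the head surface is diverted before it reaches the
cortex, and how much is gained by moving the electrode under the scalp.
This vignette explains the models the package implements, the parameters
that matter, the numerical choices, and what the synthetic-data tests do
and do not establish about real recordings.

## The volume-conduction model

At stimulation frequencies up to a few kHz, head tissue behaves as a
resistive volume conductor: capacitive and inductive effects are
negligible and the potential obeys the quasi-static equation

$$\nabla \cdot (\sigma \nabla V) = 0,$$

with current injected and withdrawn through electrode patches and
$\mathbf{E} = -\nabla V$ the electric field (reported in mV/mm;
1 V/m = 1 mV/mm). Two consequences shape everything downstream:

* **Linearity.** Solutions scale exactly with the injected current, so
  per-milliamp slopes fully characterize a montage.
* **Frequency independence.** A purely resistive model produces the
  same field at 20 Hz and 2000 Hz. In vivo recordings show a roughly
  20% *decrease* of the induced field over that range; this dispersion
  is a capacitive tissue property that the model deliberately does not
  reproduce. `frequency_trend()` exists to quantify that trend in
  measured (or synthetic) data, not in the solver.

Three geometry families carry the model, in increasing realism:

1. **Layered slab** (`build_slab()`): the series-resistor closed form.
   With a uniform current density $J$ through the stack, the field in a
   layer is $J/\sigma$ — the 1-D oracle for everything else.
2. **N-shell concentric spheres** (`build_shell_model()`): solved
   analytically (below). The 4-shell default maps brain / CSF / skull /
   scalp; the beagle-scale radii (35, 37, 41, 44 mm) are configuration,
   not anatomy — no published skull or scalp thicknesses exist for the
   species, so they are stated placeholders chosen at the scale of an
   11–13 kg dog's head, and every function takes them as arguments.
3. **Voxelized layered ellipsoid** (`build_voxel_head()`): concentric
   ellipsoidal layers rasterized on a regular grid (mm units, model
   center at origin, 0-based voxel indices, half-open voxel cubes), air
   outside. The scalp-removed variant used for the skull-exposed
   condition differs from the full model only in voxels labelled scalp.

Electrodes are ideal current sources: uniform current density over the
patch footprint, no metal or gel impedance (the gel layer of the
physical electrode is therefore not simulated). Patch attachment is
either `scalp-surface` (TES) or `skull-surface` (SES); with the scalp
layer present the latter models the scalp-closed implant condition, on a
scalp-removed model the acute skull-exposed condition. No wound geometry
is modelled — presence or absence of the scalp layer is the entire
contrast, the minimal model that reproduces the measured
removed-vs-closed difference in kind.

### Analytic N-shell solution

For concentric spherical shells with point current monopoles on the
outer surface or an internal interface, the potential separates into
Legendre harmonics. Per degree $n$ the radial part in shell $j$ is
$A_j r^n + B_j r^{-(n+1)}$; continuity of $V$ and of $\sigma\,\partial_r V$
at every interface, with the monopole entering as a surface
current-density jump expanded as
$j_n = I\,(2n+1)/(4\pi r_s^2)$, yields a small linear system per degree.
Numerical points worth recording:

* The radial basis is scaled per shell, $(r/b_j)^n$ and $(a_j/r)^{n+1}$,
  because raw powers under- or overflow near degree 250 at head scale.
* Legendre terms oscillate through zero, so truncation requires ten
  consecutive terms below the relative tolerance (default $10^{-10}$),
  not one.
* Source and sink are always superposed, so the ill-defined net-current
  monopole mode never arises; the series is validated against the
  closed-form homogeneous-sphere solution (agreement to $10^{-6}$ and
  better), which also covers the degenerate equal-conductivity
  multi-shell case.

Montage patches are reduced to point monopoles at their attachment
radius for this solver — adequate at the strip, several millimetres from
the sources, and tested against the finite-footprint voxel solver.

### Finite-difference voxel solver

The voxel solver uses the standard 7-point stencil: one unknown per
conducting voxel, link conductances on faces, a symmetric positive
semidefinite graph Laplacian, gauge fixed by grounding the node at the
reference-patch centroid (the physical recording reference, an electrode
in the thigh, is outside any phantom; all reported quantities are
potential differences and hence gauge-independent). The system is solved
with Jacobi-preconditioned conjugate gradients to a relative residual of
$10^{-8}$ — fully deterministic, no randomized components.

The face conductances deserve a paragraph, because the obvious choice
fails. A plain harmonic mean of the two adjacent cell conductivities
respects series composition across flat layer boundaries, but on curved
geometry it mis-handles the thin conductive CSF sheet (2 mm at a 500:1
contrast to skull): staircase faces see skull–CSF pairs whose harmonic
mean throttles tangential transport, and the inner-surface potential
error against the analytic oracle stalls near 20% at 1 mm voxels. The
package instead homogenizes each face below the voxel scale: the face is
split into transverse tubes (5×5), each tube samples the conductivity in
the two half-cells it crosses from the *analytic* layer boundaries
stored in the model, and the two samples combine by a blend of series
(harmonic) and parallel (arithmetic) mixing weighted by the local
interface orientation — series where the layer boundary is perpendicular
to the flow, parallel where the flow runs along the boundary. This is a
diagonal-tensor effective-medium approximation; it brings the
inner-surface error to about 3.3% at 1 mm voxels and 2.6% at 0.75 mm,
decreasing under refinement. For label-only grids without analytic
boundaries the plain harmonic mean remains the fallback.

Discrete current conservation (link-current flux through any separating
plane equals the injected current) holds to well below 1%, and discrete
reciprocity (swapping injection and measurement pairs) to the solver
tolerance; both are asserted in the test suite.

## The strip measurement chain

The emulated acquisition is an 8-contact subdural strip (3 mm contacts,
5 mm spacing) sampled at 20 kHz for 3 s under sinusoidal stimulation.
The processing chain is `bandpass()` → `cycle_average()` →
`peak_to_peak()` → `strip_gradient()`:

* **Filtering** is zero-phase Butterworth (forward–backward). Narrow
  bands use a single bandpass; wide bands use a high-pass/low-pass
  cascade, because an 8th-order transfer-function bandpass whose edges
  sit at $10^{-3}$ of the sampling rate is numerically unstable while
  the cascade is well conditioned. Order 4 per stage is the default; the
  filter family is fixed, the order is a package choice.
* **Cycle averaging** folds whole stimulus periods (≥ 10 required),
  discarding the trailing partial cycle; averaging $N$ cycles cuts
  additive noise variance by about $1/N$.
* **Fields** are absolute adjacent-contact peak-to-peak differences
  divided by the 5 mm spacing. The per-epoch summary is the *maximum*
  over the seven pairs — the pair under the active electrode dominates,
  and no published convention states which pair summarizes an epoch —
  with all pair values retained. Magnitudes are reported; signed
  differences remain available for debugging.
* **Ratios** (`shunting_ratio()`) aggregate as the mean of per-pair
  ratios, not the ratio of means, matching how per-frequency ratios are
  usually presented; the ratio is invariant to common rescaling of both
  conditions. `required_current()` rounds to one decimal, the precision
  at which such doses are reported.

One sampling caveat: at 2 kHz stimulation and 20 kHz sampling there are
only 10 samples per cycle, so the discrete peak-to-peak underestimates
the true amplitude by up to $\cos(\pi/10) \approx 0.95$. This is a
property of the emulated acquisition itself, not of the implementation.

## Conductivity calibration

`calibrate()` fits $\sigma_{\text{scalp}}$ and $\sigma_{\text{skull}}$
— all other tissues stay fixed — by minimizing

$$w_1\,(1 - R) + w_2\,\frac{\mathrm{RMS}}{\mathrm{sd(measured)}}$$

over pooled (montage, contact-pair) field values, with $w_1 = w_2 = 0.5$.
The two published criteria ("minimize the difference, maximize the
correlation") come without weights, so the weights are exposed in the
problem object. The search is a 9×9 log-spaced grid over the literature
bounds (every evaluation kept as an audit trail) followed by Nelder-Mead
refinement in log10-space with a quadratic out-of-bounds penalty. The
optimizer is deterministic; randomness only enters through synthetic
measurement noise. Fits that end within $10^{-6}$ (relative) of a bound
are flagged `"boundary"` — the designed behavior when the data were
generated outside the search box.

The default calibration experiment uses three montages — TES,
SES scalp-closed, and SES scalp-removed on a scalp-removed model variant
— mirroring the in vivo protocol in which the scalp was opened between
stimulation blocks.

### What the calibration can and cannot identify

This is the package's most important negative result. Under
current-controlled injection, *all* of the injected current traverses
the layer stack regardless of the layer conductivities; overlying-layer
conductivity changes the interior field only by *redistributing* the
current laterally. On the spherical phantom:

* Redistribution through the scalp requires the scalp to be an
  effective shunt, i.e. $\sigma_{\text{scalp}} \gtrsim 0.02$ S/m. Across
  the full bound (0.0002–1.0 S/m) the strip fields vary 15-fold, so a
  conductive scalp is well identified. But at the calibrated value
  (0.0004 S/m) the fields sit on a resistive plateau with elasticity
  $\partial \log E / \partial \log \sigma \approx 0.02$–0.05.
* The strip fields are nearly invariant to $\sigma_{\text{skull}}$
  *everywhere* in its bounds (≈ 4% total variation): the conductive CSF
  sheet under the skull re-spreads the current and decouples the
  subdural field pattern from how the current crossed the skull.

Consequently the noiseless objective has a unique zero at the truth and
the two-stage search recovers it essentially exactly (the package
verifies relative error below $10^{-4}$), but 2% measurement noise maps
to parameter errors of order 100% — small field perturbations divided by
tiny elasticities. The flat valley also lets the discrete grid minimum
drift away from the cell nearest the truth along the skull axis. The
acceptance suite states both expectations at their face values and the
noise-recovery assertions fail accordingly; the numbers reported by
`scripts/acceptance.R` are the honest recovery errors. The same physics
is visible in the in vivo modelling literature this package emulates:
doubling scalp and skull conductivities from their defaults changed the
predicted cortical fields by only ~0.02 mV/mm. Identifying skull
conductivity from subdural gradients alone is, in this geometry, an
ill-posed problem; measurements that would cure it (drive-voltage /
transfer-impedance at the stimulating electrode, or epidural potentials
above the CSF) are outside the recording protocol modelled here.

## iEEG spectral analysis

A stimulation session is 30 s pre, 50 s stim, 20 s post at 512 Hz; only
pre and post are analyzed (the stim phase holds the pulse artifact — 50
charge-balanced biphasic pulses at 1 Hz — and is excluded).
`preprocess_ieeg()` band-passes 1–100 Hz and notches 58–62 Hz,
zero-phase. `welch_psd()` averages Hamming-windowed periodograms at 50%
overlap with density normalization (integrated PSD ≈ variance; verified
by Parseval checks). The window is 2 s (1024 samples, 0.5 Hz
resolution): the window family and overlap are fixed by the emulated
protocol, the length is a package choice that divides the 2-Hz analysis
bins cleanly.

Spectral change is the per-bin difference of bin-integrated power
(post − pre) on 2-Hz bins tiling 2–30 Hz; band powers integrate the PSD
over delta (0.5–4), theta (4–8), alpha (8–13) and beta (13–30 Hz). Where
bins must be attributed to bands, attribution is by bin-center
membership (the 8–10 Hz bin belongs to alpha; the 12–14 Hz bin's center
13 falls in beta). Condition comparisons are two-sided paired t-tests
per band, aligned by repetition index, Bonferroni-corrected across the
four bands; zero-variance differences report p = 1 with a flag rather
than NaN.

## The synthetic-data generators

`make_strip_recording()` builds contact potentials whose cumulative
peak-to-peak differences equal the requested pair fields, modulates them
with the stimulus sinusoid and adds i.i.d. Gaussian DAQ-like noise.
`make_calibration_dataset()` perturbs forward-solved fields with
*multiplicative* Gaussian noise (gain-like, the natural error model for
amplitude measurements). `make_ieeg_session()` synthesizes each phase
from a prescribed power spectrum in a single FFT: a $1/f$ background
(exponent 1, 10 µV RMS) plus one Gaussian-bump oscillator per band
(2, 6, 10, 20 Hz; 5 µV RMS each, bandwidths 0.6–2 Hz), so that every
band carries signal. Component amplitudes are stochastic (chi-square
band powers), as in real EEG — this is what makes the null calibration
honest: with deterministic amplitudes the paired t-test would see
zero-variance differences. The skull-applied condition multiplies the
post-phase alpha and beta oscillator amplitudes by 2 (power ×4); TES and
baseline use multiplier 1. All generators are bit-reproducible given a
seed and restore the caller's RNG state.

What passing tests show — and what they do not: the suite demonstrates
that the *pipeline* recovers known effects at the stated sizes and
controls its type-I error (empirically within [0.03, 0.07] at α = 0.05
over 500 replicates). Real iEEG adds nonstationarity, artifacts,
spindles and inter-subject variability that the generator deliberately
omits, so passing here validates the machinery, not clinical
sensitivity.

## Problem sizes and runtimes

The shipped analyses use: 1 mm voxels for the beagle-scale oracle
comparison (~357k unknowns, ~600 CG iterations), 2 mm/1 mm pairs on a
thicker-layered sphere for refinement trends, series truncation at
degree 150–600 depending on evaluation radius, 9×9 calibration grids,
500 replicates for the iEEG null calibration and 100–120 for power.
These sizes were chosen so the full suite and the acceptance script each
run in minutes on a single core while keeping every quantitative
tolerance meaningful.

## Known limitations

* Purely resistive: no tissue dispersion, hence no frequency dependence
  of the induced field (the measured ~20% drop from 20 Hz to 2 kHz is a
  documented model–measurement discrepancy, not a target).
* Isotropic conductivities; no anisotropic skull or white matter.
* Sphere/ellipsoid phantoms only — no anatomical meshes, no MRI import,
  no electrode–skin interface impedance.
* Analytic shell montages reduce patches to point monopoles.
* Skull conductivity is only weakly identifiable from subdural gradient
  data (see the calibration section); the calibration machinery is
  validated on self-consistency and boundary behavior, not on noisy
  skull-conductivity recovery.
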