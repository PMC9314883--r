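---
title: "Methods: synthetic phantoms, bias correction, multi-decoder segmentation and 10 g dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic phantoms, bias correction, multi-decoder segmentation and 10 g dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `persardose`, the choices made
where the design was genuinely open, and what the synthetic study does
and does not demonstrate.

## Overview

The toolkit mirrors a subject-specific RF dosimetry workflow for
parallel-transmit (PTx) neuroimaging at 7T: a single T1-weighted-like
volume is segmented into eight tissue classes plus background by a 2.5D
multi-decoder network; dielectric and density properties are assigned per
class; and the local 10 g-averaged SAR is evaluated for arbitrary RF
shims through per-voxel Q-matrices. A DREAM-based bias-correction chain
is provided for the semi-automatic labelling route, and a seeded
synthetic-data generator supplies all inputs so the full pipeline is
testable offline.

## The synthetic-data generator

`make_phantom()` builds a minimal head-and-neck anatomy from nested
ellipsoidal shells (outside in: muscle, fat, bone, CSF, gray matter,
white matter core), two eye spheres seated anteriorly, one to three
air cavities embedded in local bone blocks with a guaranteed wall of at
least 2 voxels (2 mm at the default 1 mm isotropic resolution), and a
neck cylinder with a bone core that keeps the body a single 6-connected
component. A 1 mm skin layer is enforced by relabelling surface fat as
muscle. Shell radii jitter by ±5% per seed, which is what the
leave-one-out study treats as intersubject variability.

Design choices worth recording:

* **Cavity and eye sizes.** Cavity radii are 5.5% of the grid extent,
  giving an internal-air fraction of the body near 1%, similar to adult
  paranasal sinuses relative to head volume. Structures much smaller than
  this are not resolvable targets at the scaled-down grid sizes the
  package uses for its studies.
* **Intensity model.** `simulate_t1w()` assigns MP-RAGE-like per-tissue
  means (bright fat/white matter, intermediate gray matter and muscle,
  dark CSF/bone/air) multiplied by a bias field. Noise is
  signal-proportional: `noise_sd = 0.05` means 5% of the local noiseless
  intensity in every tissue. A Rician variant is available
  (`noise_model = "rician"`); Gaussian is the default. With this
  convention, the low absolute SNR of the neck arises through the bias
  drop-off rather than through the noise model, which is the failure
  mode the segmentation has to be robust to.
* **Bias severity.** `make_b1_maps()` generates smooth transmit
  (`b1plus`, clamped to [0.02, 1.6] so the STEAM flip stays below the
  90° DREAM ambiguity) and receive profiles with 40% relative variation
  at a 36 mm correlation length, both attenuated towards the neck by a
  logistic profile of strength 0.85. These defaults are deliberately
  severe, matching ultra-high-field conditions where the bias dominates
  within-tissue contrast.
* **E-fields.** `make_efields()` produces band-limited Gaussian random
  complex 3-vector fields (1/e autocorrelation length = `smoothness_mm`,
  default 30 mm), modulated per channel by an exponential envelope and
  radial phase ramp from azimuthally placed rim positions, and zeroed
  outside the body. The fields are *not* Maxwell-consistent; the
  dosimetry algebra downstream is agnostic to the field source, which is
  exactly what these tests need. Electromagnetic solving is out of scope.

## DREAM bias correction

From the stimulated-echo and FID images, the actual flip angle is
`α = arctan √(2·STE/FID)`, `b1plus = α / α_nominal` (STEAM angle, default
50°), and the receive-weighted proton density follows from the FID
amplitude given α and the imaging angle (default 10°). The forward
simulator `simulate_dream()` uses `STE = M0B1⁻ sin β sin²α / 2`,
`FID = M0B1⁻ sin β cos²α`, making estimation an exact round trip on
noiseless input — a property the tests assert to 1e-10.

The "spherical function basis" of the fitting step is realized as real
solid harmonics `r^l P_l^m(cos θ){cos,sin}(mφ)` evaluated on the voxel
lattice, centered on the mask centroid and radius-normalized for
conditioning, fit by QR least squares. The default order L = 6 (49
coefficients) is a configuration choice: high enough to follow 7T-scale
transmit/receive structure, low enough that the piecewise-constant
tissue M0 component is rejected as non-smooth — that smoothness argument
is this package's interpretation of "removing the M0 component", and the
receive profile `b1minus_hat` is simply the harmonic fit of M0B1⁻.

The GRE and FSE bias fields are `sin(γτ·b1plus)·b1minus_hat` and
`sin³(γτ·b1plus)·b1minus_hat`, normalized to mean 1 over the mask; `γτ`
defaults to the imaging flip (10°) for GRE and the refocusing angle
(70°) for FSE. Correction divides by `max(bias, floor)` with
`floor = 0.05 · mean(bias)`: below the floor (deep neck) the correction
intentionally makes no recovery claim, it only avoids noise blow-up.
Recovery properties are therefore asserted on the region above the
floor.

## The multi-decoder segmentation network

One shared encoder, nine parallel decoders, one sigmoid output per
class. The default topology: encoder = 3×3 conv block + 6 × (2×2 max
pool + conv block) with widths 8, 16, …, 512 doubling after each
pooling; each decoder = 6 × 2×2 transposed-conv block (first upsampling
quarters the bottleneck width, then halving, floored at the base width)
with 3×3 refine blocks at the three intermediate scales and a 1×1
output conv. That is 23 layers along an input-to-output path, 6 of them
pooling, and 5.17 million trainable parameters — 5 million to the
nearest million; the layer-wise reconciliation ships as a test
(`expected_parameter_count()` in `test-forknet.R`).

Two choices depart from the plainest reading of the source topology and
are this package's own:

* **Lateral skip connections.** Each transposed-conv output receives an
  additive, bias-free 1×1 projection of the matching encoder scale.
  Without them, decoders reconstructing from a 2⁶-fold downsampled
  bottleneck could not localize small structures (air cavities, eyes,
  the thin CSF shell) in the scaled-down study — held-out Dice plateaued
  far below target with internal air at zero. The projections add ~8% to
  the parameter count and no path depth.
* **Output bias initialization at −2.** Sigmoid outputs start near 0.12
  rather than 0.5, so rare-class decoders skip the initial phase of
  pushing the whole map down and do not saturate into a dead zone.

Batch normalization uses momentum 0.9 and ε = 0.001; activations are
ReLU; optimization is ADAM (β₁ = 0.9, β₂ = 0.999) with the framework
default learning rate 1e-3 for the full protocol (batches of 10
randomized slices, 40 epochs, 90/10 train/validation split). The loss is
one minus soft Dice, `(2Σpt + s)/(Σp + Σt + s)` with smoothing s = 1,
averaged unweighted over the nine outputs and aggregated over the batch.
Slices are the raw (biased) images scaled per volume by the 99th
percentile intensity — scaling is numerically necessary even though the
protocol otherwise uses no pre-processing. Fusion sums the three
orientation outputs and takes the argmax (ties to the lowest channel);
voxels whose summed outputs are all exactly zero take the modal label of
their 26-neighborhood, background excluded whenever a tissue neighbor
exists.

### The scaled-down cross-validation study

The package's own study conditions (chosen once; also the configuration
of `study_config()`): three synthetic subjects at 64³ voxels (1 mm),
base width 4, three pooling steps, 10 epochs, each leave-one-out fold
run under its own seed. Because this schedule performs roughly 75× fewer
weight updates than the full protocol, the mini study uses learning rate
1e-2 stepping to 3e-3 for the last three epochs; the full-protocol
default remains 1e-3. The acceptance bar is majority-of-folds held-out
mean Dice ≥ 0.85 over the eight tissue classes.

What passing shows: the architecture, loss, optimizer and fusion can
recover unseen anatomy of the same family under severe synthetic bias.
What it does not show: performance on real 7T data, where contrast
mechanisms, anatomy and artifacts are far richer than nested ellipsoids;
fat/muscle discrimination in particular rides on chemical-shift
information in real ground-truth pipelines that the T1w-like generator
does not emulate (no Dixon water/fat simulation).

## 10 g averaging and Q-matrices

Pointwise SAR uses the peak-amplitude phasor convention
`SAR = σ|E|²/(2ρ)` — the factor 2 silently changes all absolute values,
so it is fixed package-wide and recorded here. Background and internal
air have σ = 0 and contribute neither power nor mass.

For each tissue voxel the 10 g region grows over tissue voxels in order
of increasing Euclidean voxel-center distance, ties broken by
lexicographic (i, j, k) index; the final voxel contributes the fraction
that makes the accumulated mass exactly 0.010 kg. This reproduces
correct averaging at the body surface, where cube-based volumes would be
truncated. Whether the final voxel should be fractional or whole is not
standardized; fractional was chosen so every region has the same mass,
and the brute-force sorted-accumulation oracle in the tests pins the
behavior at every voxel to 1e-12. Distance ordering is contiguity-free:
a region may bridge a zero-mass gap (e.g., across a sinus), which is a
known, documented difference from strictly contiguous growing.

Q-matrices store, per tissue voxel, the packed upper triangle of
`P_ab = σ/(2ρ)·E_a·conj(E_b)` summed over field components, averaged
entry-wise over the identical 10 g regions. For any shim,
`SAR₁₀g(v) = wᴴQ(v)w` evaluates as one matrix product over the packed
storage; equivalence with the direct combined-field pipeline is asserted
to 1e-10 across seeded random shims. Hermitian symmetry holds by
construction and diagonal imaginary round-off is cleared explicitly.

Random shims draw phases uniform on [0, 2π) and amplitudes uniform on
[0, 1] — the amplitude law is a configuration choice, recorded in
results — then normalize to 1 W total input power. The quadrature
reference mode is an equal-amplitude shim with successive phase
increments of 360°/C on a synthetic multi-port field set (C = 16 by
default); physical birdcage modelling is out of scope.

For ground-truth vs generated-model comparisons, the per-shim peak
underestimation error is `100·(peak_GT − peak_gen)/peak_GT` (positive =
unsafe). The safety margin is defined constructively: the multiplicative
factor on generated-model peaks such that the stated fraction of shims
(default 95%) is conservative, i.e.
`margin = 100·(quantile(peak_GT/peak_gen, 0.95) − 1)`, with quantiles by
linear interpolation between order statistics. Other margin
constructions exist (e.g., deriving a factor directly from the error
quantile); this explicit form is used consistently and reported next to
the error quantiles it derives from. The generic "one-size-fits-all"
comparison evaluates, for each model and shim, the overestimation
incurred by taking the worst case over the other models.

## Tissue properties

`default_tissue_properties()` carries literature-style dielectric and
density values at 300 MHz (the 7T proton frequency) of the
Gabriel/IT'IS family; the table is an editable YAML configuration and no
test depends on its specific numbers. Internal air and background are
non-conducting; internal air is additionally excluded from averaging
mass, consistent with its zero-power role.

## Numerical and engineering notes

* The network runs on BLAS matrix products with activations kept as
  `(H·W·N) × C` matrices and cached gather indices for the 3×3
  convolutions and 2×2 transposed convolutions; batch-normalization
  kernels and the region-growing averager are the only compiled (Rcpp)
  code. Training and inference are deterministic for a fixed seed on a
  fixed BLAS.
* Batch statistics use biased variance; running statistics update with
  momentum 0.9 and are the inference-time statistics.
* The solid-harmonic design matrix is radius-normalized and solved by
  QR; rank deficiency (degenerate masks) is an explicit error.
* Study problem sizes (64³ training phantoms, 2 mm dosimetry grids at
  24³–32³, 100–1000 shims) were chosen as the smallest at which every
  structure of interest spans several voxels and every statistic
  stabilizes; `run_study()` accepts larger values unchanged.
* Generators restore the caller's RNG state; every artifact written by
  the study driver carries the seeds and configuration that produced it.

## Known limitations

* Synthetic anatomy and fields only: no claim transfers quantitatively
  to real subjects or real coils; the published full-scale figures
  (segmentation accuracy on volunteers, percent-level peak-SAR errors)
  are not reproducible without scanner data and an FDTD solver and are
  not asserted anywhere in this package.
* The bias estimator's M0 removal by smoothness leaks where true
  receive structure is as sharp as tissue structure.
* VOP compression, PTx pulse design, coil co-simulation and thermometry
  validation are out of scope.
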