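---
title: "Models and methods behind usdot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind usdot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(usdot)
```

`usdot` is a desk-scale virtual trial for ultrasound-guided time-domain
diffuse optical tomography (DOT) of breast lesions. It chains five models:
a voxelized breast phantom generator, a dual-scale stochastic acoustic
medium, a chromophore-based optical ground truth, a time-domain diffusion
forward solver with instrument-response convolution and photon-counting
noise, and a two-region nonlinear reconstruction whose per-wavelength
outputs feed benign/malignant classifiers. This vignette records the
models, their assumptions, the tunable parameters, and the design choices
made where the design was genuinely open.

## Coordinate conventions and units

All lengths are in millimetres, times in picoseconds, optical coefficients
in mm^-1. The probe frame puts `z = 0` at the top (probe) surface with z
increasing into the tissue; `y = 0` is the ultrasound imaging plane. Voxel
grids are isotropic; voxel centers sit at `(i - 0.5) * spacing + origin`
for 1-based indices.

## Phantom generation

The generator is a deliberately simple stand-in for a full anatomical
virtual-trial toolchain: only the *statistical* roles of the tissue
classes matter downstream (their acoustic and optical property
distributions), not ductal anatomy. A slab fills the domain with skin
layers (default 1.5 mm) at the top and bottom surfaces; the interior is an
adipose/glandular mixture obtained by thresholding, at the configured
fat-fraction quantile, a Gaussian random field with a 15 mm correlation
length plus a central bias — glandular tissue thereby forms a
centimetre-scale central fibroglandular compartment, as in real and
virtual-trial breasts, rather than voxel-scale binary noise (which would
give the diffuse bulk an unrealistically rough effective medium); the
adipose fraction of the interior is matched exactly at threshold time.
Sparse arteries, veins and ducts are drawn as jittered tubes. Compression to the 45 mm slab of a flat handheld probe is a
volume-preserving anisotropic rescale (z compressed, x/y dilated by the
inverse square root), resampled by nearest neighbour — a mechanical
deformation model is out of scope and the downstream stages only consume
the compressed slab.

Lesions are digitized spheres whose radius is modulated by a random
combination of low-order spherical harmonics; the single `irregularity`
knob scales the modulation (0 gives a sphere; the equivalent-sphere radius
is rescaled once to the requested mean radius). Lesion placement keeps the
center of mass within `0.3 l` of the imaging plane, where `l` is the
lesion's y-extent. The study pipeline additionally constrains the center
to `|x| <= 10` mm and depth 8–22 mm: this models the acquisition protocol
in which the operator centers the handheld probe on the B-mode-visible
lesion. Without it a lesion can land outside the optode array's sensitive
volume, where no reconstruction method has data to work with — a
field-of-view artifact, not a property of the method under study.

The optical computation domain is a 64 x 58 x 30 mm cuboid; coarse voxels
whose majority fine label is air are reassigned to adipose or glandular
tissue (whichever prevails in the breast), so the optical cuboid is fully
tissue-filled.

## Acoustic medium

Each tissue i receives a mean speed of sound drawn once per phantom,
`vbar_i ~ N(mu_i, sigma_macro_i)` (the between-phantom, macroscopic
scale), and voxelwise Gaussian texture with standard deviation
`sigma_micro_i` (the within-tissue, microscopic scale that produces
B-mode brightness differences). The texture is white by default: the model
specifies only a mean and a standard deviation, and speckle statistics are
out of scope; a correlated option (Gaussian kernel of configurable length)
exists for users who want smoother media. Texture levels are drawn
uniformly between 1% and 5% of each tissue's mean speed; the lesion is
fixed at 0.5% so it is strictly darker than every surrounding tissue, as
masses are in B-mode. Default speeds (adipose 1470, glandular 1515,
lesion 1550 m/s; the remaining tissues share the glandular distribution)
follow the common soft-tissue convention and are config-overridable; mass
density defaults to 1000 kg/m^3. The exported medium (NIfTI grids plus a
YAML transducer card: 7 MHz center frequency, 256 elements, 0.2 mm pitch,
1465 m/s beamforming reference) is a bridge for an external wave
simulator; wave propagation and B-mode formation are not performed here —
the geometric quality of ultrasound-derived priors is emulated directly
(below).

## Optical ground truth

Absorption follows the linear spectral model
`mua(lambda) = sum_i eps_i(lambda) C_i` over deoxy-/oxy-hemoglobin (uM)
and lipid/water/collagen (volume fractions); reduced scattering follows
the power law `musp(lambda) = a (lambda/lambda0)^-b` with `lambda0 = 600`
nm and a per-wavelength Gaussian noise term of 10% of the local `musp`,
clipped at a 0.05 mm^-1 floor to keep the diffusion model valid. The
bundled specific-absorption panel at the eight probing wavelengths (635,
670, 685, 785, 905, 930, 975, 1060 nm) is a fixture compiled to track
standard literature compilations; it is user-overridable, and every
number in the package's tests refers to the bundled table.

Per-tissue chromophore concentrations are drawn once per phantom per
tissue (no intra-tissue spatial variation), from distributions chosen so
that malignant lesions carry more total hemoglobin, water and collagen
and less lipid than benign ones, cysts are water-dominated with very low
scattering amplitude (`a ~ N(0.3, 0.01)` mm^-1, drawn for 25% of benign
lesions), benign lesions draw `a ~ N(1.5, 0.25)` and malignant
`a ~ N(1.4, 0.25)` mm^-1, and the bulk spectra sit clearly below the
lesion spectra across most wavelengths. The concentration tables are
modeling choices of this package (the units convention is that
`eps * C` yields mm^-1); they live in one function
(`tissue_compositions()`) so they can be overridden wholesale.

## Forward model

Photon migration is modeled by the time-domain diffusion equation with
Robin boundary conditions,

    (1/c) dPhi/dt = div(kappa grad Phi) - mua Phi,
    Phi + 2 A kappa dPhi/dn = 0 on the boundary,

with `kappa = 1/(3 musp)`, `c = c0/n` (default n = 1.4) and `A` computed
from the Groenhuis polynomial approximation of the effective Fresnel
reflection coefficient (A = 3.25 at n = 1.4). Discretization is
cell-centered finite volumes on the voxel grid with harmonic face
averaging of `kappa`, stepped by implicit Euler (default 25 ps x 400
steps). The pulsed source is realized as an initial condition: a
unit-integral Gaussian of width 0.5 mm deposited one transport mean free
path below the optode (the standard diffusion-approximation source
placement). Detectors read the exitance `Phi/(2A)` through a Gaussian
surface profile of width 1 mm. Each implicit step is solved by a
Jacobi-preconditioned conjugate-gradient iteration in compiled code,
warm-started from a linear extrapolation of the two previous fields.
Verification: against the infinite-medium
Green's function the relative L2 error is below 5% at 1.5 mm / 10 ps
resolution (and converges as the grid is refined); the absorption scaling
law exp(-delta_mua c t), reciprocity, photon conservation under
reflective boundaries, and dt-halving stability are covered in the test
suite.

Measured curves are convolved with the instrument response function (the
bundled synthetic IRF is a unit-area Gaussian of 400 ps FWHM; measured
IRFs load from two-column ASCII). Poisson noise anchors the photon budget
at the largest source-detector separation: that pair's time integral is
scaled to `Nexpect` counts (default 1e6 — the estimation procedure for a
1-minute clinical acquisition is described in the literature but no
number is printed, so the default is configurable), all other pairs keep
their integral ratios, and every native time bin is replaced by a Poisson
draw.

## Preprocessing

For each curve, the region of interest runs from the first sample at or
above 10% of the peak to the last sample at or above 1% of the peak —
sample-level comparison, no sub-sample interpolation: the convention is
ambiguous at the source and the 25 ps grid makes the difference
negligible, so the reproducible choice wins. Eighty equal-width bins span
the ROI; bin values are trapezoidal integrals (with exact fractional-edge
handling) normalized to unit total mass, so the operator is invariant to
positive rescaling of the curve. The Poisson-motivated weight of bin k is
`p_k / N` with `N` the total ROI counts; zero-count bins receive a
`1/N^2` floor so the weighted misfit stays finite.

## Two-region reconstruction

The reconstruction fits five parameters per wavelength — inclusion and
bulk absorption, inclusion and bulk reduced scattering, and a fictitious
time shift `tshift` absorbing timing offsets — by minimizing half the
weighted sum of squared binned residuals over all source-detector pairs
separated by more than 27 mm (the cut favors absorption convergence and
suppresses local perturbations such as blood vessels). The prior mask
defines the two regions; the model curves come from the same numerical
solver, are IRF-convolved, evaluated at `t + tshift` by linear
interpolation on the native grid, and binned with the data's ROI and
edges. Bounds are `0 < mua < 0.06`, `0 < musp < 2.2` mm^-1 (with a 0.05
floor on `musp` for diffusion validity) and `|tshift| <= 25` ps. The
optimizer is a box-bounded Levenberg–Marquardt least-squares iteration
with forward-difference Jacobian; the solver tolerance (relative
residual 1e-7 per step) keeps iterative-solver noise well below the
finite-difference curve changes. Initialization — on which the source
method is silent — uses the homogeneous analytic fit for both regions
and `tshift = 0`: it is cheap, deterministic and unbiased between the
two regions. Convergence tolerances default to 1e-6 (relative objective)
and 1e-4 (relative step) with at most 100 iterations, all configurable.

The homogeneous fit matches the standard extrapolated-boundary dipole
solution of the time-domain diffusion equation for a semi-infinite medium
(isotropic source at depth `1/musp`, image source mirrored about the
extrapolated boundary at `2AD`), preprocessed exactly like the data.

## Prior quality emulation

Interactive B-mode segmentation is replaced by two components. The
2D-to-3D extrapolation takes an imaging-plane mask and extrudes it with a
spherical profile: with `d(x, z)` the interior distance field and `dmax`
its maximum, the solid contains offset `|y| < sqrt(dmax^2 - (dmax -
d)^2)`, so a disk becomes the corresponding ball, the y = 0 slice equals
the input, and the y-extent is bounded by `dmax`. (A plain threshold of
the distance field at `|y|` was considered and rejected: it produces a
double cone whose Dice overlap with the ball is only 2/3.)

The degradation emulator reproduces the measured geometric quality of
ultrasound-derived priors without simulating images: the truth mask's
signed chamfer distance field is perturbed by a smooth Gaussian field
(correlation ~1.5 voxels, amplitude 1.3 in voxel units) and re-thresholded
by bisection to hit a target relative volume mismatch, then shifted by
the rounded target displacement. Defaults draw the volume mismatch from
`N(-0.5, 0.17)` — the systematic ~50% volume underestimation caused by
beamforming with a reference speed below the true lesion speed — and
per-axis displacements from `N(0.04, 0.13)`, `N(0.08, 0.05)` and
`N(0.14, 0.08)` mm. The noise amplitude is the emulator's calibration
knob: at the default operating point the emulated population's mean Dice
overlap against truth sits near 0.55. Degradation keeps the largest
connected component, so the prior invariant (single 6-connected region)
is preserved.

## Classification

Each lesion contributes 16 features: the log of the eight reconstructed
(or ground-truth) inclusion absorption coefficients and the eight reduced
scattering coefficients. Log transformation improves separability;
z-scoring uses training-split statistics only. Logistic regression and a
kernel SVM use stratified 60:40 train:test splits; the SVM is
model-selected by 5-fold cross-validated training accuracy over kernels
{Gaussian, polynomial degree 3, sigmoid} and cost C in {0.5, 1, 2, 3, 4,
5} (the stated ranges, densified to a six-point grid). The fully
connected network uses a stratified 60:20:20 train:validation:test split
and is the fixed 16/32/16/1 dense architecture with rectified-linear
hidden units and a sigmoid output trained on the hinge loss (labels
encoded +/-1, the sigmoid mapped to the margin scale as 2s - 1), by
mini-batch (32) stochastic gradient updates with Adam-style per-parameter
step sizes, at most 500 epochs and early stopping with patience 25 on
the validation hinge loss; none of the training hyperparameters are
specified at the source, so standard values are used and fixed by seed.
Metrics come from the malignant-positive confusion counts; the F1 score
is the standard harmonic mean of precision and recall (the printed
formula dividing by "accuracy + precision" is treated as a typographical
slip). Undefined metrics (zero denominators) are reported as NA, never
as zero.

## Problem sizes used by the shipped tests

The package's automated acceptance checks run at desk scale on one CPU:

- Green's-function verification: 110 mm cube at 1.5 mm / 10 ps x 400
  steps (73^3 voxels).
- Parameter recovery and preprocessing checks: the 64 x 58 x 30 mm
  optical cuboid at 4 mm voxels, 50 ps x 200 steps.
- Prior-quality calibration: 100 degraded masks of a 12 mm ball on the
  2 mm optical grid.
- Ground-truth classification: 728 lesions (349 benign including the
  cyst branch, 379 malignant).
- End-to-end study: an eight-phantom cohort on the 0.5 mm anatomical /
  4 mm optical grids with 100 ps x 80 steps and the optimizer capped at
  25 iterations, with both the ground-truth and the degraded prior mode.
  These sizes are the package's choice of a reproducible desk-scale
  experiment; the full-scale conditions (0.5 mm / 2 mm grids, 25 ps x 400
  steps, hundreds of phantoms) remain the configurable defaults of
  `study_config()`. At a cohort this small the held-out classification
  split contains only a few lesions, so the study's accuracy estimates are
  reported and asserted but carry large sampling noise; the
  reconstruction-error ordering between prior modes is the robust
  desk-scale readout.

## What the synthetic data do and do not show

The generator emulates the *distributional* structure of the application:
tissue-class optical contrasts, lesion-class separations, photon-budget
noise, and prior-quality statistics. It does not emulate ductal anatomy,
chest-wall effects, mechanical compression physics, speckle formation, or
segmentation-specific failure modes (shadowing, posterior enhancement).
Passing tests therefore demonstrate that the pipeline — solver,
preprocessing, two-region fit, prior emulation, classifiers — behaves
correctly and reproduces the study's orderings (ground-truth features
classify perfectly; reconstruction degrades separability; degraded priors
degrade it further and increase absorption-recovery error), not that the
specific accuracy figures would transfer to clinical data.

## Known limitations

- The two-region model is misspecified on heterogeneous bulk by design;
  absorption recovery carries heavy tails (a fraction of fits miss by
  more than 50%, growing when the prior is degraded), which is the
  phenomenon under study rather than a defect.
- Reduced-scattering recovery from late-window far-pair data is weakly
  constrained and noisier than absorption recovery.
- The homogeneous analytic initialization assumes a semi-infinite medium;
  on the 30 mm-deep slab it is biased by escape through the bottom
  boundary, which is harmless for its role as an initializer.
- At coarse study grids (4 mm) small lesions occupy few voxels, so the
  volume targets of the prior emulator quantize visibly.
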