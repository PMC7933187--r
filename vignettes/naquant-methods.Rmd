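---
title: "Methods: three-compartment sodium quantification in naquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-compartment sodium quantification in naquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`naquant` treats each imaging voxel as three compartments — extracellular
water, intracellular water and fat — with

$$TSC = ECV \cdot C_{EC} + ICV \cdot C_{IC} + (1 - WF) \cdot C_{fat},
\qquad ICV = WF - ECV.$$

The central assumptions are:

* the extracellular sodium concentration is fixed, $C_{EC} = 140$ mM, so
  the model can be solved for $C_{IC}$ once TSC, WF and ECV are measured;
* contrast agent distributes only extracellularly, so the
  relaxation-rate change $\Delta R_1$ after injection is proportional to
  ECV, with the pectoral muscle ($ECV_{ref} = 0.12$) anchoring the scale.
  Contrast relaxivity and dose cancel in the normalization, which is why
  neither appears anywhere in the data model;
* sodium relaxation is purely quadrupolar and biexponential, with a
  60:40 fast/slow split of the transverse decay, and one global set of
  tissue relaxation times ($T_1 = 37$ ms, $T_{2s} = 0.5$ ms,
  $T_{2l} = 15$ ms) rather than per-voxel maps;
* the fat compartment carries a small sodium concentration, estimated
  operationally as the mean TSC over voxels with WF below 10% (falling
  back to an explicit value, literature $\approx 10$ mM, when no such
  voxels exist).

The inversion
$C_{IC} = (TSC - ECV\,C_{EC} - (1-WF)\,C_{fat}) / (WF - ECV)$ is exact:
`invert_model()` keeps a raw (unclipped) $C_{IC}$ map on which the
forward identity is asserted to $10^{-9}$ mM, alongside a clipped
($\ge 0$) map for reporting. Whether negative voxels should be clamped is
not settled usage, so both are surfaced.

# Pipeline stages and tunable parameters

**Sodium chain** (in fixed order): B1 normalization → PSF deconvolution →
relaxation ($\lambda$) correction → calibration. The order is a design
choice; B1 and $\lambda$ are multiplicative so their order is immaterial,
but deconvolution must precede the (nonlinear) calibration inversion.

| Parameter | Default | Units | Role |
|---|---|---|---|
| TR / TE / FA | 60 / 0.2 / 80 | ms, ms, deg | sodium protocol; enter $\lambda$ |
| readout duration | 10 | ms | T2 weighting across k-space; sets PSF width |
| smoothing FWHM (B1 ref) | 15 | mm | denoises the uniform-phantom reference |
| RL iterations | 10 | – | deconvolution effort; diminishing returns after ~25 |
| $C_{EC}$ | 140 | mM | model scalar |
| $ECV_{ref}$ | 0.12 | – | muscle anchor |
| fat threshold | WF < 0.10 | – | voxels used for the $C_{fat}$ estimate |
| display threshold | WF > 0.50 | – | fibroglandular/tumor segmentation |
| `icv_floor` | 0.05 | – | identifiability floor (below) |

The relaxation factor
$\lambda = \frac{1-e^{-TR/T_1}}{1-\cos(FA)\,e^{-TR/T_1}}
(f e^{-TE/T_{2s}} + (1-f) e^{-TE/T_{2l}})$
is strictly increasing in TR and both T2 components and decreasing in TE;
these monotonicities are asserted over parameter grids in the tests. The
T1 fit model used by `fit_t1_mono()` deliberately includes the same
flip-angle steady-state term, so measurement and correction share one
signal model. Note one ambiguity inherited from the source material: the
tissue $T_{2l}$ is 15 ms in the methods defaults while the central column
of the relaxation error-propagation table uses 16 ms; the package default
is 15 ms and the table replication uses the tabulated values — both are
exposed, neither is guessed to be "correct".

**Identifiability floor.** As $ICV = WF - ECV \to 0$ the $C_{IC}$
division explodes; voxels with $ICV <$ `icv_floor` (default 0.05) are
marked invalid — never silently zeroed — and excluded from ROI
statistics, which report the exclusion count.

**PSF.** `compute_psf()` models the center-out ultra-short-TE readout in
the image domain: each Cartesian k-space sample is assigned the time
$t(k) = TE + T_{ro}|k|/k_{max}$ (radially linear center-out timing, a
stand-in for the actual spiral-like trajectory whose timing is a free
parameter here), weighted by the biexponential decay, and inverse
transformed. The kernel is kept with its absolute DC gain (its sum equals
the k-space origin weight) as a bookkeeping contract; the blur operator
used by both the simulator and Richardson–Lucy is the clipped,
unit-renormalized kernel (below).

**Calibration.** Gel ROI means are taken over interiors (one-voxel
morphological erosion) to avoid partial-volume edge voxels, divided by
each gel's own $\lambda$, and fit by ordinary least squares against
concentration. TSC inversion then applies the tissue $\lambda$. The whole
chain is invariant to a global receive gain applied to calibration and
tissue images together.

**Water/fat separation.** Single-peak fat model at $-3.4$ ppm (the
minimal faithful model for four echoes at 2.04/2.24/2.44/2.64 ms), solved
per voxel by a coarse grid search over field offsets (robust to water/fat
swaps) with parabolic refinement of the residual, one Gaussian smoothing
pass of the field map, and a final linear solve. Swap correction by
region growing is out of scope.

# Numerical choices

* **Nonnegative blur operator.** The computed PSF has small negative
  ringing (a few percent of its mass) because the biexponential k-space
  weighting is not positive definite. Richardson–Lucy is a
  nonnegative-kernel method: its fixed point can only match a forward
  model with a nonnegative kernel. Both `apply_psf()` (the simulator's
  blur) and `deconvolve()` therefore share one operator: negatives
  clipped, renormalized to unit mass. A kernel whose negative mass
  exceeds 10% of its total is rejected instead. Flux is conserved to
  within 1% and restoration is asserted to strictly reduce RMSE on
  constructed blur pairs.
* **Single acquisition PSF.** The forward model blurs the
  $\lambda$-weighted concentration map with one kernel (the 3% agar class
  for gel phantoms, the tissue class for the breast). Real acquisitions
  blur each tissue with its own T2-dependent PSF; that spatially-varying
  effect is outside this image-domain model and is listed as a limitation
  below.
* **Optimizer.** Relaxometry fits use bounded Levenberg–Marquardt
  (`minpack.lm`) with multi-start from a coarse log-grid (the
  biexponential fit has a well-known local-minimum trap), cost tolerance
  $10^{-10}$. Non-convergence and non-identifiable inputs (flat T1
  series, effectively monoexponential T2 decay) are flagged on the result
  object, not raised as errors.
* **Ties and determinism.** The field-map grid argmin breaks ties by
  first index; all simulator noise is drawn from a seed-local RNG that
  neither disturbs nor is disturbed by the caller's RNG state, so every
  generator is bit-for-bit reproducible from its seed and the pipeline
  re-run is byte-identical.
* **Degenerate inputs.** Zero reference images, empty gel lists, gels
  that do not fit the matrix, empty ROIs, non-positive muscle
  $\Delta R_1$, mismatched grids, and slope $\le 0$ calibrations are all
  hard errors; negative TSC and out-of-range ECV are clipped with counts
  carried on the result (silent data modification is disallowed).
* **Mean-uncertainty convention.** The sweep statistic is
  $100 (\max - \min) / (2 c_0)$. Two $c_0$ conventions are implemented:
  the output at the central (unperturbed) parameter value — the
  convention that reproduces the published $C_{EC}$/ECV table — and the
  centre of the output interval, which the published methods phrase
  suggests but which does not reproduce all printed cells. The published
  short-T2 column and the long-T2 TSC uncertainty cannot be reproduced
  from their printed values under either convention and are documented as
  irreproducible rather than targeted.

# The digital phantom: what it emulates, what it does not

The simulator generates the three study configurations with exact ground
truth:

* **Calibration phantom:** five 3% agar gel spheres (25–125 mM in 25 mM
  steps) in a 50 mM saline bath cylinder. Gel/bath geometry and volumes
  are not specified by the source protocol, so simple spheres-in-cylinder
  geometry is declared here (sphere radius 8% of the matrix on a ring),
  making ROI truth exact.
* **Validation phantom:** ten gels (three 140 mM gels emulating 0/4/8%
  agar plus seven 3% gels at 25–125 mM), inserted without a bath. The
  gel relaxation classes come from an unavailable supplement; the
  simulator declares realistic saline/agar values (0%: $T_1$ 55,
  $T_2$ 35/35; 3%: 35, 5/25; 4%: 32, 3.5/20; 8%: 28, 2/14 ms) — more agar,
  shorter and more biexponential relaxation.
* **Breast phantom:** a half-ellipsoid breast (fat shell, fibroglandular
  core, embedded tumor sphere) on a pectoral-muscle slab. Tissue truth:
  tumor $C_{IC} = 30$ mM, ECV 0.25, WF 0.9 (hence TSC 55.5 mM);
  fibroglandular 15 mM / 0.10 / 0.85; fat WF 0.05; muscle carries
  $ECV_{ref}$ exactly. Proton maps live on a grid twice as fine as the
  sodium grid and are block-averaged before inversion (averaging matches
  the physical direction of partial voluming).

Forward models: sodium = per-voxel $\lambda \cdot$TSC → PSF blur →
smooth multiplicative B1 bias (radial quadratic droop by default, a
seeded smoothed random field optionally) → Rician magnitude noise;
multi-echo GRE = single-peak water/fat signal with a smooth field map and
complex Gaussian noise; post-contrast T1 from
$\Delta R_1 \propto ECV$ with Gaussian map noise. SNR is defined as the
mean noiseless signal over the object divided by the per-channel noise
SD.

What the phantom does **not** emulate — and hence what passing tests do
not show about real data: spatially varying (per-tissue) PSFs,
non-Cartesian k-space artifacts and trajectory-specific aliasing, coil
sensitivity beyond one multiplicative field, inter-modality
misregistration (all maps are generated co-registered; the pipeline only
asserts grid compatibility), multi-peak fat spectra, B1+ effects on the
T1 maps, physiological variation of $C_{EC}$ or muscle ECV, and partial
volumes more complex than piecewise-constant labels.

# Problem sizes and experiment design

Grids are chosen at desk scale: 64³ sodium (128³ proton) for single-run
phantom validation — where the full chain recovers every gel within the
tested 7% band at SNR 30 and within 1% noiselessly — and 48³ sodium for
the twenty-seed tumor-recovery experiment, whose tumor sphere then spans
about six sodium voxels across, enough that interior voxels dominate the
ROI. The recovery criterion (tumor-ROI median $C_{IC}$ within ±10%, ECV
within ±0.03 at sodium SNR 20) is computed over seeds of the full
generator-plus-pipeline loop, calibrating afresh each seed.

# Known limitations

* A single global PSF and global relaxation times: altered tumor
  relaxation biases TSC multiplicatively through $\lambda$ and is only
  explored through the deterministic sweeps.
* The $C_{fat}$ rule measures blurred fat-voxel TSC, which includes the
  small water compartment of fat voxels; in the simulator this
  overestimates the pure fat concentration by a few mM, a second-order
  effect on $C_{IC}$ (weighted by $1 - WF$).
* Richardson–Lucy with a clipped kernel cannot undo the (physical)
  negative-lobe ringing it never models, and amplifies noise if iterated
  far beyond the default.
* ECV rests entirely on the muscle anchor: B1-related bias of the muscle
  T1 measurement propagates multiplicatively into every ECV and C_IC
  value, and near-zero uptake makes ECV (and then $C_{IC}$) poorly
  determined — mirrored by the `icv_floor` invalidation, not repaired.
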