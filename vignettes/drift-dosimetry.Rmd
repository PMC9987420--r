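---
title: "Dosimetric consequences of intrafraction tumor drift in lung SBRT: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosimetric consequences of intrafraction tumor drift in lung SBRT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftdose)
```

## The problem

Lung SBRT delivers ablative doses with steep spatial gradients to a
target that moves with respiration. Treatment planning absorbs the
breathing motion into an internal target volume (ITV, the union of the
gross tumor volume over the breathing phases) plus a setup margin (PTV),
but residual *intrafraction* drift — the slow displacement of the mean
target position during a single delivery — is not absorbed by anything.
With the prescription isodose sitting directly on the PTV surface, a
few millimetres of drift can push part of the target into the penumbra.

`driftdose` simulates this end to end on digital phantoms: it builds
respiratory lung phantoms, synthesizes a surrogate SBRT dose
distribution, perturbs it by rigid isocenter shifts, quantifies DVH
endpoint degradation, and averages that degradation over a 3-D normal
drift distribution.

## The phantom model

A phantom is a voxelized thorax surrogate on an isotropic 1 mm grid
(default 120 × 120 × 140 voxels, axis order ML, AP, SI): a 10 mm
chest-wall shell at the lateral grid boundary (0 HU), lung tissue
(−720 HU), and a spherical tumor (0 HU) that translates rigidly along
SI. The study grid crosses tumor diameters {20, 30, 40} mm with
peak-to-peak SI amplitudes {10, 20, 30} mm — nine phantoms.

Eleven phases span the half-cycle from peak to valley. Only the
endpoints of the trajectory are physically fixed (phase 1 at
+A/2, the last, end-exhalation (EE), phase at −A/2); we sample the
intermediate phases on a cosine, `z_k = (A/2)·cos(πk/10)`, which is
smooth, symmetric and endpoint-exact. The EE (valley) phase is the
dose-accumulation reference, following the usual convention that EE is
the most stable and most populated part of the cycle.

Voxel membership is decided by the voxel centre (no partial-volume HU).
The AVG CT (planning surrogate) is the voxelwise phase mean, the MIP the
voxelwise maximum; thresholding the MIP midway between lung and tumor HU
(−360 HU, chosen as the midpoint because only the existence of a
threshold, not its value, is specified for this anatomy) recovers
exactly the union of the phase GTVs, which is the ITV. The PTV is the
ITV dilated by an isotropic 5 mm margin via an exact Euclidean distance
transform.

At 1 mm spacing the voxelized spheres and capsules agree with their
closed-form volumes to within ~1–3%; tests assert 2% for spheres and 3%
for capsules and dilations.

## The surrogate dose engine

A commercial treatment planning system is not part of this package; in
its place stands a parametric dose model in which dose depends only on
the signed Euclidean distance `sd(x)` to the PTV surface (negative
inside):

$$D(x) = D_{max}\,\Phi\!\left(\frac{-sd(x) + c}{w}\right),\qquad
c = w\,\Phi^{-1}(L),\qquad D_{max} = \frac{6000\ \mathrm{cGy}}{L},$$

with `Φ` the standard normal CDF, `L` the prescription isodose fraction
(0.65 or 0.85) and `w` the penumbra width (mm). By construction the
prescription dose (6000 cGy) falls exactly on the PTV surface, so the
plan covers ≥ 95% of the PTV by design (coverage is still verified at
run time), dose is monotone in `sd`, plateaus at `D_max` deep inside and
vanishes outside.

Two numerical details matter:

* **Signed distance.** Voxel-centre-to-voxel-centre distances overshoot
  the continuous surface by half a voxel on each side, so
  `signed_distance()` subtracts `spacing/2` from the magnitude. Without
  this correction the realized penumbra is systematically shallower
  than the model; with it, the profile crosses 6000 cGy at the PTV
  surface to within ~0.1 mm.
* **Width calibration.** `w` is calibrated per isodose level so that
  the mean dose gradient (chord slope) over the interval from the
  superior ITV boundary to 4.5 mm beyond it matches the target values
  −249 cGy/mm (65%) and −137 cGy/mm (85%) on the 30 mm / 20 mm
  phantom. The chord gradient is *not* monotone in `w`: it vanishes for
  both a near-step penumbra (the whole interval sits on the plateau)
  and a near-flat one. Calibration therefore brackets the wide branch —
  widths of ~12 mm (65%) and ~8 mm (85%), the physically realistic
  penumbra regime — by locating the steepest-gradient width first and
  bisecting outward. Steeper targets give narrower widths on this
  branch, and the 65% plan is steeper than the 85% plan pointwise
  throughout the boundary interval.

## Perturbation and 4-D accumulation

Intrafraction variation is modeled as a rigid shift `s` of the
isocenter: all beams are mis-aimed together, so the delivered dose
pattern translates, `D'(x) = D(x − s)`, resampled with trilinear
interpolation and clamp-to-edge extension (the dose field is flat at
the grid boundary by construction). The shift grid is the study's
0.5–4.5 mm in 1 mm steps along the six cardinal directions — 30
perturbed plans per case.

ITV endpoints are evaluated on the static (planning-anatomy) dose. GTV
endpoints use the simplified 4-D accumulation: each phase is assigned
the same static dose distribution, and a GTV voxel at EE position `x`
receives the equally weighted mean of the dose sampled at
`x + (z_k − z_EE)·ê_SI` over the eleven phases. Equal phase weights are
an explicit modeling choice (no phase-occupancy weighting is specified
for this design); the accumulation is invariant to phase reversal by
the symmetry of the cosine trajectory.

## DVH endpoints

`D_x` is the minimum dose received by the best-covered x% of a
structure — on the discrete voxel multiset, the order statistic
`s_desc[⌈n·x/100⌉]`, equivalently the largest dose `d` with
`V(d) ≥ x%`. This discrete inverse of the empirical cumulative DVH is
used rather than an interpolated quantile; on the ≥ 4000-voxel
structures of the study the difference between quantile conventions is
below 0.1% volume, and on tiny structures the discrete convention is the
exact one. `ΔD_x` is the percent change of `D_x` against the
unperturbed plan (negative = degradation) and is invariant under a
common rescaling of both dose distributions.

## Drift statistics

Residual drift is a zero-mean 3-D normal vector with independent
per-axis standard deviations δ = (1.5, 1.5, 1.2) mm in SI, AP, ML —
post-treatment CBCT residuals reported for CBCT-corrected lung SBRT.
The magnitude of an isotropic 3-D normal vector is Maxwell-distributed:

$$Q(r) = \operatorname{erf}\!\left(\frac{r}{\sqrt2\,\delta}\right)
 - \sqrt{\tfrac{2}{\pi}}\,\frac{r}{\delta}\,e^{-r^2/2\delta^2}.$$

The range [0, 3δ] is partitioned into twelve 0.25δ bins,
`P_i = Q(i·0.25δ) − Q((i−1)·0.25δ)`, with the tail beyond 2.75δ absorbed
into bin 12. The table is scale-free (computed in δ units): it is
independent of the δ values. The largest bin holds 14.6% (bin 6), the
smallest 0.4% (bin 1), and 19.9% / 73.9% of drift magnitudes fall within
1δ / 2δ.

The distribution is anisotropic while the Maxwell magnitude model is
isotropic; the resolution adopted here is the one the bin/node pairing
implies: probabilities are computed scale-free, and the query nodes
`r_i = (2i−1)·0.125·δ_axis` use the per-axis δ of each shift direction
(SI/AP 1.5 mm, ML 1.2 mm). Endpoint samples are interpolated linearly
onto the nodes per direction, anchored at ΔD(0) = 0 — the analytically
forced value for the unperturbed plan — with linear extrapolation of
the final segment for nodes beyond the last sample (with δ ≤ 1.5 mm all
nodes fall inside the sampled 4.5 mm, so extrapolation is never
exercised in the default study). Node values are averaged over the six
directions and weighted by `P_i`:

$$\overline{\Delta D_x} = \sum_{i=1}^{12} P_i\,\Delta D_x(r_i).$$

Being a convex average anchored at small shifts, the weighted mean is
always milder than the worst sampled shift.

## First-order gradient model

Near the ITV boundary the dose change of a voxel displaced by `u` along
a profile is approximately `u · ∇̄d`, the displacement times the mean
dose gradient (chord slope) over the traversed interval. The chord
slope is used rather than averaged finite differences — identical for
continuous profiles and cheaper. For the calibrated plans the
prediction at the boundary voxel agrees with the actual shifted-dose
change to within a few percent for shifts up to 2 mm (tests assert
15%), degrading gracefully toward 4.5 mm where curvature enters.

## Study sizes and runtime

The default study is 9 phantoms × 2 isodose levels at 1 mm spacing on a
120 × 120 × 140 grid: 30 perturbed plans per case, 2160 endpoint rows
in total, completing in a few minutes on a single core. The test suite
exercises the same code paths on 70 × 70 × 90 grids; the
Monte-Carlo validation of the bin probabilities draws 10⁶ vectors. The
pipeline is deterministic — the seed only governs Monte-Carlo
validation utilities — and a repeated run with the same configuration
is byte-identical.

## What the generator does and does not emulate

The phantoms emulate rigid SI-only motion of a spherical, homogeneous
tumor in homogeneous lung, with an idealized chest wall whose geometry
(10 mm shell at the lateral boundary) is a modeling choice. They do not
emulate tumor deformation, hysteresis, irregular breathing, imaging
artifacts, tissue-heterogeneity dose effects, or beam-by-beam interplay
— passing tests show the geometric/statistical machinery is right, not
that any particular patient would show these numbers.

Known limitations of the surrogate dose model:

* It has no clinical plateau: dose keeps rising inside the PTV toward
  `D_max` over a scale of ~3 penumbra widths. For the 2 cm tumor at the
  65% level (width ≈ 12 mm) the interior gradient never fully dies out,
  so the max–min spread at the ITV centre stays slightly above the
  500 cGy reporting threshold; the 3 and 4 cm tumors show the expected
  quiet core at both isodose levels. Conclusions about the *location*
  of uncertainty (boundary vs. core) are therefore drawn from the 3 cm
  calibration phantom.
* The accumulated GTV dose can *gain* a few hundredths of a percent at
  small shifts (the shifted dose re-centres on the trajectory
  midpoint) before degradation takes over, so GTV degradation is
  monotone in the signed sense rather than in absolute value.
* Absolute degradation magnitudes depend on the calibrated penumbra;
  only their structure (ordering across isodose levels, growth with
  shift, compromise under probability weighting) is meaningful.
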