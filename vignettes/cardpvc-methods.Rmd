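---
title: "Methods: simulating anatomically guided partial-volume correction in gated cardiac PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating anatomically guided partial-volume correction in gated cardiac PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cardiac ^18^F-FDG PET images of a doubly gated (ECG + respiratory) acquisition
are nearly motion-free but count-starved: a single gate of a 30-minute scan
with 5 respiratory and 10 cardiac gates keeps only 36 s of data. At the 2-6 mm
resolution of clinical PET, partial-volume effects (PVE) blur the thin LV
wall, the right ventricle and any scarred region, and the low counts make the
reconstructions noisy. `cardpvc` simulates this setting end to end so that
partial-volume correction (PVC) strategies built into the reconstruction —
resolution recovery (RR), edge-preserving penalties, and the Bowsher
anatomical prior — can be compared quantitatively against a known ground
truth, including the non-ideal cases where the anatomical side information is
shifted, morphologically mismatched, anisotropic, or where respiratory motion
is left uncorrected.

# The phantom

The generator (`build_phantom()`) is a parametric stand-in for a voxelized
anthropomorphic thorax: an elliptical-cylinder thorax with a subcutaneous fat
rim, two lung ellipsoids, a liver ellipsoid, a spine cylinder, and a heart
modelled as a truncated prolate-ellipsoid LV shell (endocardial semi-axes
24/24/40 mm, wall 10 mm, base plane 16 mm above the LV centre) with a
crescent-shaped RV wrapped around it. Only the tissue topology matters for
the questions the package answers — wall thickness, lesion transmurality,
and which tissues are distinguishable in each anatomical modality — so a
simple analytic geometry is preferable to an anatomical surface model: every
mask, volume and transmural depth is known in closed form.

Tissue activities are the single-gate FDG values: LV 18, RV 12, blood pool
5.5, lung 0.9, liver 6.5 kBq/cc. Two lesions are embedded in the LV wall:

* **L1**, non-transmural: a subendocardial wedge in the mid inferolateral
  wall crossing 60 % of the wall thickness, ~3 ml, activity 8 kBq/cc.
  The transmural depth coordinate converts the ellipsoidal level sets to
  metric distance by dividing by the local level-set gradient, so the 60 %
  fraction is a physical wall fraction (verified along the wall normal to
  within one voxel).
* **L2**, transmural: a wedge spanning the full 90° apical-inferior sector
  over a short longitudinal band, 1.5 ml, activity 0 kBq/cc.

The wedge extents were calibrated once against the target volumes on the
0.8 mm grid and frozen; the measured volumes are 2.98 ml and 1.50 ml.

The attenuation map uses standard 511-keV values (0.096 cm^-1 soft
tissue/blood/muscle, 0.027 lung, 0.12 bone; fat is grouped with soft tissue).
Two anatomical images are derived from the same label field:

* **HRCT-like**: Hounsfield conversion `1000 (mu/mu_water - 1)` plus a
  +300 HU contrast-enhanced blood plateau. Scar tissue shares the attenuation
  of healthy muscle, so by construction this image cannot show the lesions.
* **MR-like**: class intensities LV 10, lesion 55, blood 45, pericardium 70,
  lung 10, soft tissue 30, fat 100, bone 0, corrupted with Rician noise
  (sigma = 5 a.u., i.e. 5 % of the fat intensity — the level is a package
  choice; the noise model is the standard magnitude-image model
  `sqrt((v + n1)^2 + n2^2)`). An anisotropic variant averages the MR over
  8 mm axial slabs and replicates them, emulating a thick-slice acquisition.

Misalignment and mismatch variants: rigid shifts of the anatomy (including
seeded random directions at 1/2/4/6 mm), heart volume scaling (0.9 and 1.05,
applied as the cube root on linear dimensions), and a cardiac-phase surrogate
(-8 % cavity radius, +8 % wall thickness) standing in for "the next gate".
The phase surrogate's magnitude is a convention, not an inference — nothing
in the study's claims depends on its exact value, only on the mismatch being
of realistic visual size. Respiratory states displace the heart rigidly along
a cranio-caudal (20 mm) plus anterior (12 mm) trajectory.

The default grid is 0.8 mm isotropic over a 192 mm cube; all package studies
run the same geometry at 2 mm ("desk scale") so that the full pipeline fits
in minutes on one core. The vignette states problem sizes as the package's
standard configurations: phantom 96^3 at 2 mm, reconstruction 64^3 at 3 mm,
84 angles, 10 noise realizations.

# Acquisition model

The projector is a multi-slice 2-D parallel-beam pair using Joseph's method
(ray-driven linear interpolation), 84 or 168 uniform angles over 180°, 2 mm
radial bins. Forward and back projection share one loop body, so the pair is
an exact adjoint — the test suite checks both against a dense system matrix.
A cylindrical scanner geometry would add nothing to the questions studied
here, which depend on the resolution model and the penalties, not on the
scanner's sampling pattern.

Camera resolution is a shift-invariant Gaussian (FWHM 4.3 mm transaxial,
4.5 mm axial) applied in image space before projection; attenuation enters as
per-ray survival factors `exp(-integral mu dl)` computed by the same
projector, reused identically in simulation and reconstruction so that
attenuation cancels exactly in the matched-model limit. Scatter and randoms
are not modelled. The expected sinogram is globally scaled to the gate's
count budget (3.9e6 counts for the 36-s doubly gated frame), and Poisson
realizations are drawn per seeded stream. Because the calibration is folded
into the system matrix, reconstructions come out directly in kBq/cc.

Gaussian kernels are truncated at 6 sigma so that two successive blurs agree
with the combined-width blur to 1e-6 (at 4 sigma the truncated tails are the
dominant error). The user-facing blur renormalizes the kernel over in-bounds
taps (constants are preserved exactly); the reconstruction engine uses the
plain zero-padded operator, which is symmetric and therefore a legitimate
adjoint pair inside the EM system model. Blur semigroup behaviour assumes
sigma of at least ~1.2 voxels; below that, discretely sampled Gaussians stop
composing exactly, which is why the resolution model is always applied on
grids no coarser than ~3 mm.

# Reconstruction

`osem()` implements ordered-subsets EM with angle-interleaved subsets
processed in bit-reversed order; with RR enabled, the resolution kernel is
applied at each forward and backward projection step, and the sensitivity
uses the same model. The full-scale iteration scheme is 3i42s + 2i24s + 2i1s.
The desk default keeps the same stage structure and effective iteration
count (3i42s + 2i21s + 2i1s at 84 angles; 24 does not divide 84). The
effective iteration count matters: the characteristic severe noise of
long-iterated unregularized RR — the phenomenon the penalized methods are
meant to fix — only develops near convergence, and a shorter desk scheme
would understate it.

`map_osem()` adds a penalty: relative difference (RD) with edge parameter
gamma, smoothed isotropic total variation (TV), or the Bowsher prior —
RD with gamma = 0 restricted, per voxel, to the `n` of 18 neighbours
(3x3x3 minus corners) most similar in a co-registered anatomical image. Pair
weights are 1/distance; the Bowsher selection is asymmetric and purely
anatomical. The penalty value uses a 1/2 pair-counting convention so that RD
with gamma = 0 and a full-neighbourhood Bowsher graph are the same penalty.

Two numerical choices deserve explanation:

* **Optimizer.** A plain one-step-late (OSL) update diverges at the
  weights this study uses: the penalty gradient can exceed the per-subset
  sensitivity, the OSL denominator changes sign, and clipping it produces
  multiplicative blow-up. The engine instead solves, per voxel and subset,
  the M-step of a separable quadratic surrogate: the penalty enters through
  its exact analytic gradient plus a De Pierro-type curvature (computed with
  the pair denominators frozen at the current image), giving a positive-root
  quadratic update that is unconditionally non-negative. The curvature only
  damps the path: any fixed point satisfies the exact stationarity condition
  of the penalized objective (OSL is the zero-curvature special case), which
  the KKT test in the suite verifies. With beta = 0 the update reduces
  bitwise to OSEM.
* **Penalty normalization.** Published penalty weights are only meaningful
  relative to a system normalization. The engine weights the penalty
  gradient by `s_bar / kappa0`, where `s_bar` is the median voxel
  sensitivity of the full system and `kappa0` is a fixed per-family
  constant (500 for RD/Bowsher, 1.0 for TV). This makes a given beta
  behave consistently across count levels, grids and geometries. The two
  constants were calibrated once, by the study's own parameter-selection
  procedure on 3 realizations: the RD/Bowsher constant from the knee of
  the Bowsher bias-noise curve (so beta 10 with n 9 sits at the clinical
  operating point, with the 0.1-50 grid spanning mild to strong
  smoothing), and the TV constant from the rule that the TV weight
  matches the selected noise level (TV beta 0.005 then reconstructs at
  LV noise 0.65 vs 0.61 for the Bowsher reference). They are package
  constants, not tuning knobs.

Other numerics: EM ratio floor `1e-12 x max(data)`; sensitivity floor
`1e-3 x median positive subset sensitivity`; uniform initial image scaled to
the total counts; penalty floor epsilon `1e-6 x image max` (RD denominator
and TV smoothing). Post-smoothing is a 5 mm isotropic Gaussian where named.

# Evaluation

Region masks follow the resample-then-threshold rule: ground truth is
block-averaged (exact overlap weights, valid for non-integer ratios like
2 mm to 3 mm or 0.8 mm to 1.35 mm) onto the reconstruction grid, and a
region keeps the voxels with at least 70 % of its true activity, restricted
to the majority-resampled label support; LV voxels overlapping a lesion are
excluded. Figures of merit over the noise ensemble: LV bias (region mean
minus truth), ensemble noise (voxelwise n-1 stddev averaged over the mask),
contrast (`r/BP - 1` for ventricles, `1 - r/LV` for lesions), RC, CRC and
CNR (contrast over relative background noise; blood pool for ventricles, LV
for lesions), with a two-sided paired t test at alpha 0.01 between
algorithms. RC is refused for the transmural lesion (true mean zero), and
CRC returns a flagged NA when the true contrast is zero. Region means are
computed region-first, then averaged over realizations; 10 realizations are
the desk default (the full-scale counts of 20/25 are configuration fields).

# Polar maps

The LV is delineated analytically from the phantom geometry (an image-driven
fallback estimates the axis and mid-wall radius from a mask, the entry point
for real data); a fixed 6 mm thickness is imposed around the mid-wall
surface. Sampling crosses the wall along the in-plane short-axis radial
direction at quarter-voxel steps — the convention of bull's-eye tools that
work on short-axis stacks. The 3-D surface normal is *not* used: near the
apex its axial component makes samples leak out of thin longitudinal bands,
which would corrupt the transmural-lesion segment. Max-count and mean-count
rasters collapse to the 17 segments; ring boundaries at fractions
0.155/0.222/0.65 of the apex-base axis place the apical ring exactly on the
transmural lesion's band, and the apical ring is numbered from the inferior
sector so the transmural lesion falls in segment 13 and the non-transmural
lesion in segment 11 (the layout is fixed in `pm_layout_17()` and documented
there). Expected ground-truth behaviour, asserted in the tests: the
mean-count map shows segment 11 at roughly the transmurality-weighted
mixture of scar and wall and segment 13 near zero, while the max-count map
hides the non-transmural lesion entirely (its healthy 40 % carries full
activity) — which is exactly why both map types are produced.

# What the simulation does and does not show

The generator reproduces the features the study's claims rest on: realistic
single-gate count levels, PVE from a Gaussian camera model, tissue-accurate
attenuation, an anatomy that either does (MR) or does not (HRCT) show scar,
and controlled misregistration. It does not attempt beating-heart
kinematics, scatter/randoms, detector geometry effects, or anatomical
texture; absolute figures of merit therefore transfer to real data only as
orderings and trends, not as numbers. Desk-scale grids (2-3 mm) make the
lesions 2-3 voxels thick, which depresses all contrast-recovery figures
relative to a 1.35 mm reconstruction; comparisons between algorithms remain
meaningful because all algorithms share the same grid, scheme and data.

# Reproducing the study

`run_study(study_config())` executes the whole desk-scale pipeline
(generate, project, draw the noise ensemble, reconstruct with the five
algorithm families, evaluate metrics, polar maps and profiles) and writes
CSV/JSON artifacts. `scripts/acceptance.R` regenerates the default phantom
and reports the machine-checkable quantities. The test suite contains the
property-based acceptance checks: projector-oracle equivalence, penalty
gradient correctness, MLEM monotonicity and count conservation, noise-free
matched-model recovery with Gibbs overshoot, the qualitative algorithm
ranking with significance, metric fixed points, and the polar-map
contracts.
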