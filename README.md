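# cardpvc

Simulation framework for evaluating **anatomically guided partial-volume
correction (PVC) in doubly gated cardiac ¹⁸F-FDG PET**.

A single cardiac/respiratory gate freezes heart motion but keeps only a
fraction of the scan's counts (36 s of a 30-min scan with 5 × 10 gates), and
the 2–6 mm resolution of PET blurs the thin left-ventricular wall and any
myocardial scar (the partial-volume effect). One family of corrections builds
the fix into iterative reconstruction: resolution recovery (RR), edge-
preserving penalties, or the Bowsher prior, which steers smoothing along a
co-registered anatomical image (CT or MR). `cardpvc` generates a fully known
digital thorax phantom with a non-transmural (3 ml, 60 % transmurality,
8 kBq/cc) and a transmural (1.5 ml, 0 kBq/cc) LV lesion, simulates the PET
acquisition, reconstructs with the competing algorithms, and quantifies what
each one does to lesion contrast and detectability — including the non-ideal
cases of shifted, mismatched or anisotropic anatomy and uncorrected
respiratory motion.

## The model in brief

* **Phantom** — parametric thorax (lungs, liver, spine, fat) with a truncated
  prolate-ellipsoid LV shell and crescent RV; piecewise-constant activities
  (LV 18, RV 12, blood 5.5, lung 0.9, liver 6.5 kBq/cc), a matched 511-keV
  attenuation map, a contrast-enhanced CT-like image (no lesion contrast, by
  construction) and an MR-like image (lesion contrast 55 vs LV 10, Rician
  noise), plus shifted / volume-scaled / phase-mismatched / thick-slice
  variants.
* **Acquisition** — adjoint-consistent Joseph parallel-beam projector,
  image-space Gaussian camera resolution (FWHM 4.3/4.5 mm), per-ray
  attenuation survival factors, count calibration to the gate budget
  (3.9 × 10⁶ counts for the 36-s gate), seeded Poisson realizations.
* **Reconstruction** — OSEM (scheme 3i42s + 2i24s + 2i1s at full scale) with
  optional RR and optional penalties: relative difference
  `P = (β/2) Σ w (f_j−f_k)² / (f_j+f_k+γ|f_j−f_k|+ε)`, smoothed isotropic
  TV, and the Bowsher prior (RD with γ = 0 over the n anatomically nearest
  of 18 neighbours). Penalized updates use a separable quadratic surrogate
  (exact gradient + De Pierro curvature), unconditionally positive, bitwise
  equal to OSEM at β = 0.
* **Evaluation** — 70 %-threshold region masks on the reconstruction grid;
  bias, ensemble noise, RC, CRC = contrastᵣᵉᶜ/contrastᵗʳᵘᵉ,
  CNR = contrastᵣᵉᶜ/relative background noise; paired t tests at α = 0.01;
  septal–lateral profiles; 17-segment max-count and mean-count polar maps
  (lesions in segments 11 and 13).

## Worked example

Desk-scale comparison of the three PVC strategies on one noise ensemble
(2 mm phantom, 3 mm reconstruction, 84 angles — a few minutes per algorithm
on one core):

```r
library(cardpvc)

ph   <- build_phantom(phantom_params(voxel_mm = 2))
geom <- sinogram_geometry(n_angles = 84, n_radial = 137, radial_mm = 2,
                          n_slices = 64, slice_mm = 3)
sim   <- simulate_acquisition(ph$activity, ph$mu_map, geom,
                              total_counts = 3.9e6)
reals <- poisson_realizations(sim, 10, seed = 1)
masks <- region_masks(ph, c(64, 64, 64), 3)

scheme <- list(c(3, 42), c(2, 21), c(2, 1))
rr5 <- lapply(reals, osem, geom = geom,
              spec = recon_spec(scheme, rr = TRUE, post_fwhm = 5))
tv  <- lapply(reals, map_osem, geom = geom,
              spec = recon_spec(scheme, rr = TRUE,
                                prior = prior_spec("TV", beta = 0.005)),
              anatomy = NULL)
bow <- lapply(reals, map_osem, geom = geom,
              spec = recon_spec(scheme, rr = TRUE,
                                prior = prior_spec("BOWSHER", beta = 10, n = 9)),
              anatomy = ph$mr)

acts <- c(lv = 18, rv = 12, blood = 5.5, l1 = 8, l2 = 0)
for (r in list(OSEM_RR_5mm = rr5, TV = tv, Bowsher_MR = bow)) {
  rep <- metrics_report(r, masks, acts)
  print(rep[rep$region == "l1", c("region", "rc", "crc", "cnr")])
}
```

On this configuration the non-transmural lesion's figures are, per
algorithm (CRC / CNR): OSEM+RR+5 mm 0.60 / 4.5, TV(β = 0.005) 0.63 / 8.2,
Bowsher-MR(β = 10, n = 9) 0.86 / 13.9 — the anatomical prior recovers the
most lesion contrast at the lowest noise, the edge-preserving prior sits in
between, and plain smoothed resolution recovery trails both. A shifted MR
(4–6 mm) costs the Bowsher reconstruction its contrast advantage. The same
comparison runs end to end via `run_study(study_config())`, which also
writes metrics/manifest CSVs and polar-map summaries.

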