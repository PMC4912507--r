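#' Parameters of the parametric thorax phantom
#'
#' Defines a single cardiac/respiratory gate of a male-thorax phantom: an
#' elliptical-cylinder thorax with a subcutaneous fat rim, two lung
#' ellipsoids, a liver ellipsoid, a spine cylinder, and a heart built from a
#' truncated prolate-ellipsoid LV shell with a crescent RV, plus two
#' myocardial lesions. Tissue activities follow the standard single-gate
#' FDG setting (LV 18, RV 12, blood pool 5.5, lung 0.9, liver 6.5 kBq/cc; a
#' non-transmural scar at 8 kBq/cc and a transmural scar at 0 kBq/cc).
#' Attenuation is 0.096 1/cm for soft tissue/blood/muscle, 0.027 for lung
#' and 0.12 for bone (511 keV). MR-like class intensities are LV 10,
#' lesion 55, blood 45, pericardium 70, lung 10, soft tissue 30, fat 100,
#' bone 0.
#'
#' The default grid is 0.8 mm isotropic over a 192 mm cube; the desk-scale
#' studies use the same geometry at 2 mm.
#'
#' @param voxel_mm isotropic voxel size (mm).
#' @param extent_mm physical edge length of the cubic grid (mm).
#' @param wall_mm LV wall thickness at end-diastole (mm).
#' @param l1_transmurality fraction of the wall crossed by the
#'   non-transmural lesion, measured from the endocardium.
#' @param heart_scale volumetric scale factor applied to the heart (used by
#'   [mismatch_phantom]).
#' @param phase_delta cardiac-phase surrogate: 1 advances the phantom to
#'   the next phase, modelled as an 8 % cavity-radius reduction and an 8 %
#'   wall thickening.
#' @param heart_offset_mm rigid heart displacement (mm), used for
#'   respiratory states.
#' @param mr_sigma Rician noise level of the MR image (a.u.; default 5 % of
#'   the fat intensity).
#' @param seed integer seed controlling all randomness in the generator.
#' @return a `phantom_params` list; invariants are checked.
#' @export
phantom_params <- function(voxel_mm = 0.8, extent_mm = 192,
                           wall_mm = 10, l1_transmurality = 0.6,
                           heart_scale = 1, phase_delta = 0,
                           heart_offset_mm = c(0, 0, 0),
                           mr_sigma = 5, seed = 1L) {
  p <- list(
    voxel_mm = voxel_mm,
    extent_mm = extent_mm,
    dim = rep(as.integer(round(extent_mm / voxel_mm)), 3L),
    activities = c(lv = 18, rv = 12, lung = 0.9, blood = 5.5, liver = 6.5,
                   l1 = 8, l2 = 0, soft = 0, fat = 0, bone = 0,
                   pericardium = 0, air = 0),
    mu = c(lv = 0.096, rv = 0.096, lung = 0.027, blood = 0.096,
           liver = 0.096, l1 = 0.096, l2 = 0.096, soft = 0.096,
           fat = 0.096, bone = 0.12, pericardium = 0.096, air = 0),
    mr_intensity = c(lv = 10, rv = 10, lesion = 55, blood = 45,
                     pericardium = 70, lung = 10, soft = 30, fat = 100,
                     bone = 0, air = 0),
    mu_water = 0.096,
    hrct_blood_hu = 300,
    # heart geometry (mm, grid centred on the origin)
    heart_centre = c(8, 0, 8),
    lv_endo = c(24, 24, 40),      # semi-axes of the endocardial ellipsoid
    wall_mm = wall_mm,
    base_offset = 16,             # base plane above the LV centre
    rv_centre_off = c(-26, 6, 2),
    rv_epi = c(26, 24, 38),
    rv_wall_mm = 5,
    pericardium_mm = 3,
    # thorax
    thorax_semi = c(88, 62),
    fat_rim_mm = 8,
    spine_centre = c(0, -48),
    spine_radius = 10,
    lung_centres = list(c(-52, 8, 0), c(52, 8, 0)),
    lung_semi = c(26, 36, 80),
    liver_centre = c(35, 5, -65),
    liver_semi = c(40, 35, 30),
    # lesions (angles: 0 deg = +x lateral wall, 90 deg = +y anterior wall)
    l1_phi_deg = 330, l1_half_phi_deg = 27,
    l1_z_rel = c(-26, -6),        # relative to the heart centre
    l1_transmurality = l1_transmurality,
    l2_phi_deg = 270, l2_half_phi_deg = 45,
    l2_t_range = c(0.155, 0.222), # fraction of the apex-base axis
    # motion / mismatch controls
    heart_scale = heart_scale,
    phase_delta = phase_delta,
    heart_offset_mm = heart_offset_mm,
    diaphragm_motion_mm = 20,
    ap_expansion_mm = 12,
    resp_gates = 5L, card_gates = 10L, scan_minutes = 30,
    mr_sigma = mr_sigma,
    seed = as.integer(seed)
  )
  stopifnot(all(p$activities >= 0), p$voxel_mm > 0,
            p$l1_transmurality > 0, p$l1_transmurality <= 1,
            p$wall_mm > 0, p$heart_scale > 0)
  class(p) <- "phantom_params"
  p
}

# derived heart geometry after scale / phase surrogates
heart_geometry <- function(p) {
  ls <- p$heart_scale^(1 / 3)           # linear scale from volume scale
  endo <- p$lv_endo * ls
  wall <- p$wall_mm * ls
  if (p$phase_delta != 0) {
    endo <- endo * (1 - 0.08 * p$phase_delta)
    wall <- wall * (1 + 0.08 * p$phase_delta)
  }
  ctr <- p$heart_centre + p$heart_offset_mm
  g <- list(
    centre = ctr,
    endo = endo,
    epi = endo + wall,
    wall = wall,
    base_z = ctr[3] + p$base_offset * ls,
    rv_centre = ctr + p$rv_centre_off * ls,
    rv_epi = p$rv_epi * ls,
    rv_endo = p$rv_epi * ls - p$rv_wall_mm * ls,
    peri = p$pericardium_mm
  )
  g$a_mid <- mean(c(g$endo[1], g$epi[1]))
  g$b_mid <- mean(c(g$endo[3], g$epi[3]))
  g$apex_z <- ctr[3] - g$b_mid
  if (any(abs(ctr[1:2]) + g$epi[1:2] + g$peri > p$thorax_semi))
    stop("heart geometry does not fit inside the thorax")
  g
}

# squared ellipsoidal norm of grid coordinates about a centre
ellip_rho <- function(X, Y, Z, centre, semi) {
  sqrt(((X - centre[1]) / semi[1])^2 +
       ((Y - centre[2]) / semi[2])^2 +
       ((Z - centre[3]) / semi[3])^2)
}

# tissue codes used internally (label_map collapses these to the 8 MR classes)
TISSUES <- c(air = 0L, soft = 1L, fat = 2L, lung = 3L, bone = 4L,
             liver = 5L, pericardium = 6L, rv = 7L, rv_blood = 8L,
             lv = 9L, blood = 10L, l1 = 11L, l2 = 12L)

#' Generate the linked ground-truth phantom bundle
#'
#' Builds the piecewise-constant activity image, the matched 511-keV
#' attenuation map, the 8-class tissue label map, the derived anatomical
#' images (contrast-enhanced CT-like, MR-like with Rician noise, and an
#' anisotropic 8 mm-slice MR), the lesion masks and the tissue masks, all
#' on the phantom grid. Deterministic given `params$seed`.
#'
#' @param params a [phantom_params] object.
#' @return a `phantom_set` list with elements `activity`, `mu_map`,
#'   `label_map`, `hrct`, `mr`, `mr_aniso`, `tissue`, `masks`
#'   (logical arrays `lv`, `rv`, `bp`, `l1`, `l2`), `geom` and `params`.
#' @export
build_phantom <- function(params = phantom_params()) {
  p <- params
  g <- heart_geometry(p)
  if (p$l1_transmurality * g$wall > g$wall + 1e-9)
    stop("lesion transmural extent exceeds the wall thickness")
  d <- p$dim
  xs <- axis_coords(d[1], p$voxel_mm)
  ys <- axis_coords(d[2], p$voxel_mm)
  zs <- axis_coords(d[3], p$voxel_mm)
  X <- array(xs, d)
  Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  tis <- array(TISSUES[["air"]], d)
  inside_thorax <- (X / p$thorax_semi[1])^2 + (Y / p$thorax_semi[2])^2 <= 1
  tis[inside_thorax] <- TISSUES[["soft"]]
  fat_in <- (X / (p$thorax_semi[1] - p$fat_rim_mm))^2 +
            (Y / (p$thorax_semi[2] - p$fat_rim_mm))^2 <= 1
  tis[inside_thorax & !fat_in] <- TISSUES[["fat"]]
  for (lc in p$lung_centres) {
    lr <- ellip_rho(X, Y, Z, lc, p$lung_semi)
    tis[lr <= 1 & inside_thorax] <- TISSUES[["lung"]]
  }
  lv_rho <- ellip_rho(X, Y, Z, p$liver_centre, p$liver_semi)
  tis[lv_rho <= 1 & inside_thorax] <- TISSUES[["liver"]]
  spine <- (X - p$spine_centre[1])^2 + (Y - p$spine_centre[2])^2 <=
           p$spine_radius^2
  tis[spine & inside_thorax] <- TISSUES[["bone"]]

  # heart: pericardial shell, then RV, then LV (later assignments override)
  below_base <- Z <= g$base_z
  rho_epi <- ellip_rho(X, Y, Z, g$centre, g$epi)
  rho_endo <- ellip_rho(X, Y, Z, g$centre, g$endo)
  rho_peri <- ellip_rho(X, Y, Z, g$centre, g$epi + g$peri)
  rho_rv_epi <- ellip_rho(X, Y, Z, g$rv_centre, g$rv_epi)
  rho_rv_endo <- ellip_rho(X, Y, Z, g$rv_centre, g$rv_endo)
  rho_rv_peri <- ellip_rho(X, Y, Z, g$rv_centre, g$rv_epi + g$peri)

  peri <- ((rho_peri <= 1 & rho_epi > 1) |
           (rho_rv_peri <= 1 & rho_rv_epi > 1)) & below_base
  tis[peri & inside_thorax] <- TISSUES[["pericardium"]]
  rv_wall <- rho_rv_epi <= 1 & rho_rv_endo > 1 & rho_epi > 1 & below_base
  tis[rv_wall] <- TISSUES[["rv"]]
  rv_bp <- rho_rv_endo <= 1 & rho_epi > 1 & below_base
  tis[rv_bp] <- TISSUES[["rv_blood"]]
  lv_wall <- rho_epi <= 1 & rho_endo > 1 & below_base
  tis[lv_wall] <- TISSUES[["lv"]]
  lv_bp <- rho_endo <= 1 & below_base
  above_base_bp <- rho_epi <= 1 & !below_base    # valve-plane blood
  tis[lv_bp | above_base_bp] <- TISSUES[["blood"]]

  # transmural depth psi: 0 at the epicardium, 1 at the endocardium.
  # Ellipsoidal level sets are converted to approximate metric distances by
  # dividing by the local level-set gradient magnitude, so psi is (to first
  # order) the fraction of the physical wall thickness.
  grad_of <- function(rho, semi) {
    g <- sqrt(((X - g$centre[1]) / semi[1]^2)^2 +
              ((Y - g$centre[2]) / semi[2]^2)^2 +
              ((Z - g$centre[3]) / semi[3]^2)^2) / pmax(rho, 1e-9)
    pmax(g, 1e-9)
  }
  d_endo <- (rho_endo - 1) / grad_of(rho_endo, g$endo)
  d_epi <- (1 - rho_epi) / grad_of(rho_epi, g$epi)
  psi <- d_epi / pmax(1e-9, d_epi + d_endo)
  phi <- atan2(Y - g$centre[2], X - g$centre[1]) * 180 / pi
  ang_dist <- function(a, b) abs(((a - b + 180) %% 360) - 180)

  l1 <- lv_wall &
        ang_dist(phi, p$l1_phi_deg) <= p$l1_half_phi_deg &
        Z >= g$centre[3] + p$l1_z_rel[1] & Z <= g$centre[3] + p$l1_z_rel[2] &
        psi >= 1 - p$l1_transmurality
  axis_len <- g$base_z - g$apex_z
  l2_z <- g$apex_z + p$l2_t_range * axis_len
  l2 <- lv_wall &
        ang_dist(phi, p$l2_phi_deg) <= p$l2_half_phi_deg &
        Z >= l2_z[1] & Z <= l2_z[2]
  tis[l1] <- TISSUES[["l1"]]
  tis[l2] <- TISSUES[["l2"]]

  lut <- function(tbl) {
    v <- numeric(length(TISSUES))
    v[TISSUES + 1L] <- tbl
    array(v[tis + 1L], d)
  }
  act <- lut(c(p$activities[["air"]], p$activities[["soft"]],
               p$activities[["fat"]], p$activities[["lung"]],
               p$activities[["bone"]], p$activities[["liver"]],
               p$activities[["pericardium"]], p$activities[["rv"]],
               p$activities[["blood"]], p$activities[["lv"]],
               p$activities[["blood"]], p$activities[["l1"]],
               p$activities[["l2"]]))
  mu <- lut(c(p$mu[["air"]], p$mu[["soft"]], p$mu[["fat"]], p$mu[["lung"]],
              p$mu[["bone"]], p$mu[["liver"]], p$mu[["pericardium"]],
              p$mu[["rv"]], p$mu[["blood"]], p$mu[["lv"]], p$mu[["blood"]],
              p$mu[["l1"]], p$mu[["l2"]]))

  # 8 anatomical classes: 1 LV/RV muscle, 2 lesion, 3 blood, 4 pericardium,
  # 5 lung, 6 soft tissue (incl. liver), 7 fat, 8 bone, 0 air
  class_of <- integer(length(TISSUES))
  class_of[TISSUES[c("lv", "rv")] + 1L] <- 1L
  class_of[TISSUES[c("l1", "l2")] + 1L] <- 2L
  class_of[TISSUES[c("blood", "rv_blood")] + 1L] <- 3L
  class_of[TISSUES[["pericardium"]] + 1L] <- 4L
  class_of[TISSUES[["lung"]] + 1L] <- 5L
  class_of[TISSUES[c("soft", "liver")] + 1L] <- 6L
  class_of[TISSUES[["fat"]] + 1L] <- 7L
  class_of[TISSUES[["bone"]] + 1L] <- 8L
  labels <- array(class_of[tis + 1L], d)

  vox <- p$voxel_mm
  activity <- pvc_image(act, vox)
  mu_map <- pvc_image(mu, vox)
  label_map <- pvc_image(labels, vox)
  hrct <- derive_hrct(mu_map, label_map, mu_water = p$mu_water,
                      blood_hu = p$hrct_blood_hu)
  mr <- derive_mr(label_map, mr_class_intensities(p), p$mr_sigma, p$seed)
  mr_aniso <- make_anisotropic(mr, pick_aniso_mm(vox))

  masks <- list(lv = lv_wall & !l1 & !l2, rv = rv_wall,
                bp = tis == TISSUES[["blood"]], l1 = l1, l2 = l2)
  structure(list(activity = activity, mu_map = mu_map,
                 label_map = label_map, hrct = hrct, mr = mr,
                 mr_aniso = mr_aniso, tissue = tis, masks = masks,
                 geom = g, params = p),
            class = "phantom_set")
}

# 8 mm MR slices when the grid allows it, else the nearest integer multiple
pick_aniso_mm <- function(vox) {
  f <- max(1, round(8 / vox))
  f * vox
}

#' @export
print.phantom_set <- function(x, ...) {
  d <- dim(img_data(x$activity))
  cat(sprintf("<phantom_set> %d^3 voxels @ %.3g mm\n", d[1], x$params$voxel_mm))
  vol <- prod(img_spacing(x$activity)) / 1000
  cat(sprintf("  L1 %.2f ml, L2 %.2f ml, LV wall %.2f ml\n",
              sum(x$masks$l1) * vol, sum(x$masks$l2) * vol,
              sum(x$masks$lv) * vol))
  invisible(x)
}

mr_class_intensities <- function(p) {
  c(`0` = p$mr_intensity[["air"]], `1` = p$mr_intensity[["lv"]],
    `2` = p$mr_intensity[["lesion"]], `3` = p$mr_intensity[["blood"]],
    `4` = p$mr_intensity[["pericardium"]], `5` = p$mr_intensity[["lung"]],
    `6` = p$mr_intensity[["soft"]], `7` = p$mr_intensity[["fat"]],
    `8` = p$mr_intensity[["bone"]])
}

#' Derive a contrast-enhanced CT-like image from the attenuation map
#'
#' Converts the 511-keV attenuation map to Hounsfield units
#' (HU = 1000 (mu/mu_water - 1)) and raises blood-pool voxels to a
#' contrast-enhanced plateau. Because the lesions share the attenuation of
#' LV muscle, they are indistinguishable from healthy wall in this image by
#' construction.
#'
#' @param mu_map attenuation [pvc_image] (1/cm).
#' @param label_map aligned 8-class label [pvc_image].
#' @param mu_water water attenuation used for the HU conversion (1/cm).
#' @param blood_hu plateau value for the contrast-enhanced blood pool.
#' @return HU [pvc_image].
#' @export
derive_hrct <- function(mu_map, label_map, mu_water = 0.096,
                        blood_hu = 300) {
  if (!all(dim(img_data(mu_map)) == dim(img_data(label_map))))
    stop("attenuation map and label map are not aligned")
  hu <- 1000 * (img_data(mu_map) / mu_water - 1)
  hu[img_data(label_map) == 3] <- blood_hu
  pvc_image(hu, img_spacing(mu_map))
}

#' Derive an MR-like image from the tissue classes
#'
#' Assigns a per-class intensity to each label and corrupts the result with
#' Rician noise (the magnitude of a complex Gaussian perturbation), the
#' standard noise model for magnitude MR images. With `rician_sigma = 0`
#' the class-value map is returned exactly.
#'
#' @param label_map 8-class label [pvc_image] (0 = air).
#' @param intensities named vector mapping class codes (as names) to
#'   intensities; every class present must have an entry.
#' @param rician_sigma noise level (a.u.).
#' @param seed integer seed.
#' @return MR-like [pvc_image].
#' @export
derive_mr <- function(label_map, intensities, rician_sigma = 0, seed = 1L) {
  lab <- img_data(label_map)
  classes <- sort(unique(as.vector(lab)))
  missing <- setdiff(as.character(classes), names(intensities))
  if (length(missing))
    stop("no MR intensity configured for class(es): ",
         paste(missing, collapse = ", "))
  lutv <- rep(NA_real_, max(classes) + 1)
  lutv[classes + 1] <- unname(intensities[as.character(classes)])
  v <- array(lutv[lab + 1], dim(lab))
  if (rician_sigma > 0) {
    set.seed(seed)
    n1 <- array(stats::rnorm(length(v), 0, rician_sigma), dim(lab))
    n2 <- array(stats::rnorm(length(v), 0, rician_sigma), dim(lab))
    v <- sqrt((v + n1)^2 + n2^2)
  }
  pvc_image(v, img_spacing(label_map))
}

#' Random rigid-shift vectors for misregistration studies
#'
#' Seeded directions uniform on the unit sphere, each scaled by each
#' requested magnitude, for probing the robustness of anatomical priors to
#' PET-anatomy misalignment.
#'
#' @param magnitudes_mm positive shift magnitudes (mm).
#' @param n_directions number of random unit directions.
#' @param seed integer seed.
#' @return list of length `n_directions * length(magnitudes_mm)` of 3-vectors.
#' @export
random_shift_vectors <- function(magnitudes_mm = c(1, 2, 4, 6),
                                 n_directions = 10, seed = 1L) {
  stopifnot(all(magnitudes_mm > 0))
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * n_directions), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  out <- vector("list", n_directions * length(magnitudes_mm))
  i <- 0L
  for (m in magnitudes_mm) for (k in seq_len(n_directions)) {
    i <- i + 1L
    out[[i]] <- dirs[k, ] * m
  }
  out
}

#' Regenerate the anatomy with a mismatched heart
#'
#' Rebuilds the phantom with the heart volume scaled by `heart_scale`
#' (linear scale `heart_scale^(1/3)`) and/or advanced by one cardiac-phase
#' surrogate step, leaving non-cardiac tissues unchanged. Only the
#' anatomical images of the result should be used: the activity of the
#' returned set describes the mismatched anatomy, not the reference gate.
#'
#' @param params reference [phantom_params].
#' @param heart_scale volumetric scale (0.9 = diastolic volume reduced by
#'   10 %, 1.05 = heart enlarged by 5 %).
#' @param phase_delta 0 for the same cardiac phase, 1 for the next phase.
#' @return a `phantom_set` built from the modified geometry.
#' @export
mismatch_phantom <- function(params, heart_scale = 1, phase_delta = 0) {
  stopifnot(heart_scale > 0)
  p <- params
  p$heart_scale <- p$heart_scale * heart_scale
  p$phase_delta <- phase_delta
  build_phantom(p)
}

#' Phantoms along a respiratory trajectory
#'
#' Returns `n_states` phantoms with the heart rigidly displaced along a
#' cranio-caudal plus antero-posterior trajectory spanning the diaphragm
#' motion amplitude. State 1 is the reference end-expiration phantom; the
#' displacement grows monotonically with the state index (peak inspiration
#' moves the heart caudally by the full amplitude and anteriorly by the AP
#' expansion).
#'
#' @param params reference [phantom_params].
#' @param n_states number of respiratory states (>= 1).
#' @return list of `phantom_set` objects.
#' @export
respiratory_states <- function(params, n_states = 5) {
  stopifnot(n_states >= 1)
  out <- vector("list", n_states)
  for (k in seq_len(n_states)) {
    u <- if (n_states == 1) 0 else (k - 1) / (n_states - 1)
    p <- params
    p$heart_offset_mm <- params$heart_offset_mm +
      c(0, params$ap_expansion_mm * u, -params$diaphragm_motion_mm * u)
    out[[k]] <- build_phantom(p)
  }
  out
}

#' Threshold rule behind the evaluation masks
#'
#' Given resampled ground-truth values over a region's support, keeps the
#' voxels whose value is at least `fraction` of the region's true activity.
#' @param values resampled ground-truth values (array or vector).
#' @param support logical support of the region on the same grid.
#' @param true_value the region's piecewise-constant activity.
#' @param fraction threshold fraction in (0, 1].
#' @return logical mask.
#' @export
threshold_region <- function(values, support, true_value, fraction = 0.7) {
  stopifnot(fraction > 0, fraction <= 1)
  support & (values >= fraction * true_value)
}

#' Evaluation masks on the reconstruction grid
#'
#' Resamples the ground-truth activity and the region supports to the
#' reconstruction grid by volume-weighted block averaging, then keeps, per
#' region, the voxels whose resampled value is at least
#' `threshold_fraction` of that region's true activity, restricted to the
#' (majority-resampled) label support. LV voxels overlapping a lesion are
#' excluded from the LV mask.
#'
#' @param phantom a `phantom_set`.
#' @param grid_dim,grid_voxel_mm the reconstruction grid.
#' @param threshold_fraction threshold in (0, 1] (0.7 by default).
#' @return list with logical masks `lv`, `rv`, `bp`, `l1`, `l2`, the
#'   resampled truth `truth`, the threshold used, and `empty` flags.
#' @export
region_masks <- function(phantom, grid_dim, grid_voxel_mm,
                         threshold_fraction = 0.7) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  p <- phantom$params
  truth <- resample_image(phantom$activity, grid_dim, grid_voxel_mm)
  tv <- img_data(truth)
  resamp_support <- function(mask) {
    frac <- resample_image(pvc_image(mask * 1, p$voxel_mm),
                           grid_dim, grid_voxel_mm)
    img_data(frac) >= 0.5
  }
  act <- p$activities
  sup <- lapply(phantom$masks, resamp_support)
  masks <- list(
    lv = threshold_region(tv, sup$lv, act[["lv"]], threshold_fraction),
    rv = threshold_region(tv, sup$rv, act[["rv"]], threshold_fraction),
    bp = threshold_region(tv, sup$bp, act[["blood"]], threshold_fraction),
    l1 = threshold_region(tv, sup$l1, act[["l1"]], threshold_fraction),
    l2 = threshold_region(tv, sup$l2, act[["l2"]], threshold_fraction)
  )
  masks$lv <- masks$lv & !sup$l1 & !sup$l2
  empty <- vapply(masks, function(m) sum(m) == 0, logical(1))
  if (any(empty))
    warning("empty region mask(s): ", paste(names(masks)[empty],
                                            collapse = ", "))
  c(masks, list(truth = truth, threshold = threshold_fraction,
                empty = empty))
}

#' Lesion volumes of a phantom in millilitres
#' @param phantom a `phantom_set`.
#' @return named vector (ml) for the L1 and L2 masks.
#' @export
lesion_volumes_ml <- function(phantom) {
  vol <- prod(img_spacing(phantom$activity)) / 1000
  c(l1 = sum(phantom$masks$l1) * vol, l2 = sum(phantom$masks$l2) * vol)
}
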