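test_that("tissue activities follow the study values", {
  ph <- desk_phantom()
  act <- img_arr(ph$activity)
  expect_equal(mean(act[ph$masks$lv]), 18)
  expect_true(all(act[ph$masks$l2] == 0))
  expect_equal(mean(act[ph$masks$l1]), 8)
  expect_equal(mean(act[ph$masks$rv]), 12)
  expect_equal(mean(act[ph$masks$bp]), 5.5)
  # all-zero activities give an identically zero image, masks unchanged
  p0 <- phantom_params(voxel_mm = 2)
  p0$activities[] <- 0
  ph0 <- build_phantom(p0)
  expect_true(all(img_arr(ph0$activity) == 0))
  expect_identical(ph0$masks$l1, ph$masks$l1)
})

test_that("lesion volumes and transmurality match the study design", {
  ph <- desk_phantom()
  v <- lesion_volumes_ml(ph)
  expect_lt(abs(v[["l1"]] - 3) / 3, 0.1)
  expect_lt(abs(v[["l2"]] - 1.5) / 1.5, 0.1)
  # transmural fraction at the L1 centre, measured along the wall normal
  g <- ph$geom; p <- ph$params
  zc <- g$centre[3] + mean(p$l1_z_rel)
  phi <- p$l1_phi_deg * pi / 180
  zr <- (zc - g$centre[3]) / g$b_mid
  rmid <- g$a_mid * sqrt(1 - zr^2)
  pm <- c(g$centre[1] + rmid * cos(phi), g$centre[2] + rmid * sin(phi), zc)
  nrm <- c(rmid * cos(phi) / g$a_mid^2, rmid * sin(phi) / g$a_mid^2,
           zr / g$b_mid)
  nrm <- nrm / sqrt(sum(nrm^2))
  uu <- seq(-8, 8, by = 0.05)
  pts <- sweep(outer(uu, nrm), 2, pm, "+")
  s <- attr(ph$activity, "spacing")
  d <- dim(img_arr(ph$activity))
  u <- round(sweep(sweep(pts, 2, s, "/"), 2, (d + 1) / 2, "+"))
  tis <- ph$tissue[cbind(u[, 1], u[, 2], u[, 3])]
  frac <- sum(tis == 11L) / sum(tis %in% c(9L, 11L))
  vox_tol <- ph$params$voxel_mm / ph$geom$wall
  expect_lt(abs(frac - 0.6), vox_tol + 0.02)
  # L1 and L2 disjoint, LV mask excludes lesions
  expect_false(any(ph$masks$l1 & ph$masks$l2))
  expect_false(any(ph$masks$lv & (ph$masks$l1 | ph$masks$l2)))
})

test_that("total activity is consistent across grid resolutions", {
  # voxelized tissue volumes at 2 mm agree with 1.6 mm within the
  # discretization error of the boundary shell
  ph2 <- desk_phantom()
  ph1 <- cached("phantom_1p6", build_phantom(phantom_params(voxel_mm = 1.6)))
  tot <- function(ph) sum(img_arr(ph$activity)) *
    prod(attr(ph$activity, "spacing")) / 1000
  expect_lt(abs(tot(ph2) - tot(ph1)) / tot(ph1), 0.02)
})

test_that("generation is bit-reproducible under a fixed seed", {
  p <- phantom_params(voxel_mm = 4, seed = 42)
  a <- build_phantom(p); b <- build_phantom(p)
  expect_identical(img_arr(a$mr), img_arr(b$mr))
  expect_identical(img_arr(a$activity), img_arr(b$activity))
})

test_that("HRCT follows the HU definition and hides lesions", {
  ph <- desk_phantom()
  hu <- img_arr(ph$hrct)
  mu <- img_arr(ph$mu_map)
  lab <- img_arr(ph$label_map)
  # mu = mu_water -> 0 HU; mu = 0 -> -1000 HU (outside the blood plateau)
  expect_equal(unique(hu[mu == 0.096 & lab != 3]), 0)
  expect_equal(unique(hu[mu == 0]), -1000)
  expect_equal(unique(hu[lab == 3]), 300)
  # lesion voxels indistinguishable from adjacent LV muscle
  expect_equal(unique(hu[ph$masks$l1]), unique(hu[ph$masks$lv]))
})

test_that("MR assigns the class intensities; Rician noise is seeded", {
  p <- phantom_params(voxel_mm = 2, mr_sigma = 0)
  ph <- build_phantom(p)
  mr <- img_arr(ph$mr)
  lab <- img_arr(ph$label_map)
  expect_equal(unique(mr[lab == 7]), 100)  # fat
  expect_equal(unique(mr[lab == 8]), 0)    # bone
  expect_equal(unique(mr[lab == 2]), 55)   # lesion
  expect_equal(unique(mr[lab == 1]), 10)   # myocardium
  # sigma 0 equals the class map exactly; noisy version is seed-stable
  mrn1 <- derive_mr(ph$label_map, cardpvc:::mr_class_intensities(p), 5, 7)
  mrn2 <- derive_mr(ph$label_map, cardpvc:::mr_class_intensities(p), 5, 7)
  expect_identical(img_arr(mrn1), img_arr(mrn2))
  expect_gt(sd(img_arr(mrn1)[lab == 7]), 1)
  expect_error(derive_mr(ph$label_map, c(`1` = 10), 0), "class")
})

test_that("random shift vectors have the requested magnitudes", {
  v <- random_shift_vectors(c(1, 2, 4, 6), 10, seed = 3)
  expect_length(v, 40)
  mags <- vapply(v, function(x) sqrt(sum(x^2)), numeric(1))
  expect_equal(mags, rep(c(1, 2, 4, 6), each = 10), tolerance = 1e-9)
  expect_identical(random_shift_vectors(c(1, 2, 4, 6), 10, seed = 3), v)
  expect_false(identical(random_shift_vectors(c(1), 2, seed = 4),
                         random_shift_vectors(c(1), 2, seed = 5)))
})

test_that("mismatched anatomy scales the heart volume as requested", {
  p <- phantom_params(voxel_mm = 2)
  ref <- desk_phantom()
  heart_vol <- function(ph) sum(ph$tissue >= 6L)  # pericardium + heart
  for (sc in c(0.9, 1.05)) {
    mm <- mismatch_phantom(p, heart_scale = sc)
    expect_lt(abs(heart_vol(mm) / heart_vol(ref) - sc), 0.025)
  }
  same <- mismatch_phantom(p, heart_scale = 1, phase_delta = 0)
  expect_identical(img_arr(same$hrct), img_arr(ref$hrct))
  # phase surrogate shrinks the cavity and thickens the wall
  ph2 <- mismatch_phantom(p, heart_scale = 1, phase_delta = 1)
  expect_lt(sum(ph2$masks$bp), sum(ref$masks$bp))
  expect_gt(ph2$geom$wall, ref$geom$wall)
})

test_that("respiratory states displace the heart monotonically", {
  p <- phantom_params(voxel_mm = 4)
  states <- respiratory_states(p, 5)
  expect_identical(img_arr(states[[1]]$activity),
                   img_arr(build_phantom(p)$activity))
  cz <- vapply(states, function(s) s$geom$centre[3], numeric(1))
  expect_true(all(diff(cz) < 0))
  expect_equal(cz[1] - cz[5], 20)  # diaphragm amplitude
  expect_length(respiratory_states(p, 1), 1)
})

test_that("region masks follow the 70 % threshold rule", {
  # 1-D toy: region value 10, resampled profile, threshold 0.7 -> >= 7 rule
  vals <- c(10, 9, 7, 6.9, 0)
  sup <- rep(TRUE, 5)
  expect_equal(sum(threshold_region(vals, sup, 10, 0.7)), 3)
  # threshold 1.0 on the native grid keeps exactly the label support
  ph <- desk_phantom()
  m <- region_masks(ph, dim(img_arr(ph$activity)), 2, 1.0)
  expect_identical(m$lv, ph$masks$lv)
  # default masks on the recon grid are nonempty and inside the label support
  md <- desk_masks()
  expect_true(all(!md$empty))
  sup_lv <- img_arr(resample_image(pvc_image(ph$masks$lv * 1, 2),
                                   c(64, 64, 64), 3)) > 0
  expect_true(all(sup_lv[md$lv]))
})
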