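test_that("one full MLEM iteration equals the dense-matrix textbook update", {
  set.seed(41)
  geom <- sinogram_geometry(n_angles = 10, n_radial = 16, radial_mm = 1.5,
                            n_slices = 1, slice_mm = 1.2)
  A <- dense_system_matrix(8, 1.2, geom)
  xtrue <- array(runif(64) + 0.1, c(8, 8, 1))
  y <- A %*% as.vector(xtrue)
  data <- cardpvc:::new_sinogram(array(y, c(16, 10, 1)), geom, "counts",
                                 calib = 1)
  att <- cardpvc:::new_sinogram(array(1, c(16, 10, 1)), geom, "attenuation")
  f0 <- 2.5
  spec <- recon_spec(scheme = list(c(1, 1)), rr = FALSE, dim = 8,
                     voxel_mm = 1.2, init_value = f0)
  f1 <- osem(data, att, geom, spec)
  # hand-assembled MLEM: f * A'(y / A f) / A'1 (empty rays contribute 0)
  q <- A %*% rep(f0, 64)
  ratio <- ifelse(q > 0, y / q, 0)
  upd <- rep(f0, 64) * as.vector(t(A) %*% ratio) / as.vector(t(A) %*%
             rep(1, length(y)))
  expect_equal(as.vector(img_arr(f1)), upd, tolerance = 1e-8)
  # all-zero data drives the image to zero after one update
  data0 <- data; data0$values[] <- 0
  expect_true(all(img_arr(osem(data0, att, geom, spec)) == 0))
})

test_that("MLEM is monotone in likelihood and conserves counts on a toy", {
  set.seed(42)
  toy <- toy2d(n = 24, voxel = 2)
  geom <- toy_geom(24, 2, n_angles = 36)
  sim <- simulate_acquisition(toy$activity, toy$mu, geom, psf_model(4.3, 0),
                              total_counts = 5e4)
  yl <- poisson_realizations(sim, 1, seed = 1)[[1]]
  spec1 <- recon_spec(scheme = list(c(1, 1)), rr = FALSE, dim = 24,
                      voxel_mm = 2)
  f <- osem(yl, geom = geom, spec = spec1)
  ll <- poisson_loglik(f, yl, geom)
  for (k in 1:20) {
    spec_n <- recon_spec(scheme = list(c(1, 1)), rr = FALSE, dim = 24,
                         voxel_mm = 2, init_value = f)
    f <- osem(yl, geom = geom, spec = spec_n)
    ll_new <- poisson_loglik(f, yl, geom)
    expect_gte(ll_new, ll - 1e-9 * abs(ll))
    ll <- ll_new
  }
  q <- yl$calib * yl$att$values * forward_project(f, geom)$values
  expect_lt(abs(sum(q) - sum(yl$values)) / sum(yl$values), 1e-4)
})

test_that("beta = 0 MAP is bitwise identical to OSEM", {
  toy <- toy2d(n = 16, voxel = 2)
  geom <- toy_geom(16, 2, n_angles = 12)
  sim <- simulate_acquisition(toy$activity, toy$mu, geom, psf_model(4.3, 0),
                              total_counts = 2e4)
  yl <- poisson_realizations(sim, 1, seed = 2)[[1]]
  base <- recon_spec(scheme = list(c(2, 4)), rr = TRUE,
                     psf = psf_model(4.3, 0), dim = 16, voxel_mm = 2)
  withp <- base; withp$prior <- prior_spec("RD", beta = 0, gamma = 0)
  fa <- osem(yl, geom = geom, spec = base)
  fb <- map_osem(yl, geom = geom, spec = withp)
  expect_identical(img_arr(fa), img_arr(fb))
})

test_that("image roughness decreases monotonically with the prior weight", {
  set.seed(43)
  toy <- toy2d(n = 24, voxel = 2)
  geom <- toy_geom(24, 2, n_angles = 24)
  sim <- simulate_acquisition(toy$activity, toy$mu, geom, psf_model(4.3, 0),
                              total_counts = 3e4)
  yl <- poisson_realizations(sim, 1, seed = 3)[[1]]
  uniform <- toy$r <= 0.6 * 24 * 2 / 2 & toy$r >= 0.45 * 24 * 2 / 2
  rough <- vapply(c(0, 4, 10, 30, 50), function(b) {
    spec <- recon_spec(scheme = list(c(2, 4), c(1, 1)), rr = TRUE,
                       psf = psf_model(4.3, 0), dim = 24, voxel_mm = 2,
                       prior = if (b > 0) prior_spec("RD", beta = b,
                                                     gamma = 0))
    f <- if (b > 0) map_osem(yl, geom = geom, spec = spec)
         else osem(yl, geom = geom, spec = spec)
    stats::sd(img_arr(f)[, , 1][uniform])
  }, numeric(1))
  expect_true(all(diff(rough) < 0))
})

test_that("converged 1-subset MAP satisfies the KKT balance", {
  set.seed(44)
  toy <- toy2d(n = 16, voxel = 2)
  geom <- toy_geom(16, 2, n_angles = 24)
  sim <- simulate_acquisition(toy$activity, toy$mu, geom, psf_model(0, 0),
                              total_counts = 1e5)
  yl <- poisson_realizations(sim, 1, seed = 4)[[1]]
  prior <- prior_spec("RD", beta = 50, gamma = 10, epsilon = 1e-4)
  spec <- recon_spec(scheme = list(c(1200, 1)), rr = FALSE, dim = 16,
                     voxel_mm = 2, prior = prior)
  f <- map_osem(yl, geom = geom, spec = spec)
  # gradient of the log-likelihood at the fixed point
  q <- yl$calib * yl$att$values * forward_project(f, geom)$values
  resid <- yl$calib * yl$att$values * (yl$values / (q + 1e-300) - 1)
  gl <- img_arr(back_project(resid, geom, c(16, 16, 1), 2))
  gp <- attr(f, "prior_scale") * img_arr(penalty_gradient(f, prior))
  bal <- img_arr(f) * (gl - gp)
  inner <- array(FALSE, c(16, 16, 1)); inner[3:14, 3:14, 1] <- TRUE
  expect_lt(sqrt(sum(bal[inner]^2)), 1e-3 * sqrt(sum(img_arr(f)[inner]^2)))
})

test_that("post-smoothing is an identity at 0 and conserves interior mass", {
  set.seed(45)
  a <- array(0, c(24, 24, 24)); a[10:15, 10:15, 10:15] <- runif(216) + 1
  img <- pvc_image(a, 2)
  expect_identical(img_arr(post_smooth(img, 0)), a)
  sm <- post_smooth(img, 5)
  expect_equal(sum(img_arr(sm)), sum(a), tolerance = 1e-6)
  # point source smoothed at 5 mm has ~5 mm FWHM
  pt <- array(0, c(41, 41, 41)); pt[21, 21, 21] <- 1
  b <- post_smooth(pvc_image(pt, 1), 5)
  prof <- img_arr(b)[, 21, 21]
  fi <- stats::approxfun(1:41, prof - max(prof) / 2)
  fwhm <- stats::uniroot(fi, c(21, 28))$root - stats::uniroot(fi, c(14, 21))$root
  expect_lt(abs(fwhm - 5), 0.5)
})

test_that("subset counts must divide the angle count", {
  toy <- toy2d(n = 16, voxel = 2)
  geom <- toy_geom(16, 2, n_angles = 10)
  sim <- simulate_acquisition(toy$activity, toy$mu, geom, psf_model(0, 0),
                              total_counts = 1e4)
  spec <- recon_spec(scheme = list(c(1, 3)), rr = FALSE, dim = 16,
                     voxel_mm = 2)
  expect_error(osem(sim, geom = geom, spec = spec), "divide")
})
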