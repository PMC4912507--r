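test_that("fwhm_to_sigma closed form", {
  expect_equal(fwhm_to_sigma(0), 0)
  expect_equal(fwhm_to_sigma(4.3), 1.8260, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(5.0), 2.1233, tolerance = 1e-4)
})

test_that("projector matches a dense system matrix and its adjoint", {
  set.seed(21)
  geom <- sinogram_geometry(n_angles = 12, n_radial = 16, radial_mm = 1.5,
                            n_slices = 1, slice_mm = 1.2)
  A <- dense_system_matrix(8, 1.2, geom)
  x <- array(runif(64), c(8, 8, 1))
  fp <- forward_project(pvc_image(x, 1.2), geom)
  expect_lt(max(abs(A %*% as.vector(x) - as.vector(fp$values))), 1e-8)
  # adjoint inner-product identity on a random pair
  y <- array(runif(length(fp$values)), dim(fp$values))
  bp <- back_project(y, geom, c(8, 8, 1), 1.2)
  expect_lt(abs(sum(fp$values * y) - sum(img_arr(bp) * x)), 1e-8)
  # linearity
  x2 <- array(runif(64), c(8, 8, 1))
  f12 <- forward_project(pvc_image(2 * x + 3 * x2, 1.2), geom)
  f1 <- forward_project(pvc_image(x, 1.2), geom)
  f2 <- forward_project(pvc_image(x2, 1.2), geom)
  expect_equal(f12$values, 2 * f1$values + 3 * f2$values, tolerance = 1e-12)
  # zero image -> zero sinogram; uniform sinogram backprojects positive
  expect_true(all(forward_project(pvc_image(array(0, c(8, 8, 1)), 1.2),
                                  geom)$values == 0))
  bp1 <- back_project(array(1, dim(fp$values)), geom, c(8, 8, 1), 1.2)
  expect_true(all(img_arr(bp1) > 0))
})

test_that("central ray of a uniform disc equals the analytic chord", {
  n <- 64
  xs <- (seq_len(n) - (n + 1) / 2)
  X <- outer(xs, rep(1, n)); Y <- outer(rep(1, n), xs)
  d <- array(0, c(n, n, 1)); d[X^2 + Y^2 <= 20^2] <- 2
  geom <- sinogram_geometry(n_angles = 4, n_radial = 95, radial_mm = 1,
                            n_slices = 1, slice_mm = 1)
  fp <- forward_project(pvc_image(d, 1), geom)
  centre <- (geom$n_radial + 1) / 2
  expect_equal(fp$values[centre, 1, 1], 2 * 2 * 20, tolerance = 0.01 * 80)
})

test_that("attenuation factors: closed form, bounds, monotonicity", {
  n <- 64
  mu <- array(0.096, c(n, n, 1))
  geom <- sinogram_geometry(n_angles = 2, n_radial = 95, radial_mm = 1,
                            n_slices = 1, slice_mm = 1)
  af <- attenuation_factors(pvc_image(mu, 1), geom)
  centre <- (geom$n_radial + 1) / 2
  # 64 mm uniform path at 0.096 1/cm
  expect_equal(af$values[centre, 1, 1], exp(-0.1 * 0.096 * 64),
               tolerance = 1e-10)
  expect_true(all(af$values > 0 & af$values <= 1))
  af2 <- attenuation_factors(pvc_image(2 * mu, 1), geom)
  expect_true(all(af2$values <= af$values + 1e-14))
  mu0 <- attenuation_factors(pvc_image(array(0, c(8, 8, 1)), 1),
                             toy_geom(8, 1))
  expect_true(all(mu0$values == 1))
  expect_error(attenuation_factors(pvc_image(array(-1, c(8, 8, 1)), 1),
                                   toy_geom(8, 1)), ">= 0")
})

test_that("simulated acquisition is calibrated and scale-invariant", {
  toy <- toy2d()
  geom <- toy_geom()
  sim <- simulate_acquisition(toy$activity, toy$mu, geom, psf_model(4.3, 0),
                              total_counts = 1e5)
  expect_equal(sum(sim$values), 1e5, tolerance = 1e-6)
  # global activity scaling is absorbed by the calibration
  act2 <- pvc_image(3 * img_arr(toy$activity), attr(toy$activity, "spacing"))
  sim2 <- simulate_acquisition(act2, toy$mu, geom, psf_model(4.3, 0),
                               total_counts = 1e5)
  expect_equal(sim2$values, sim$values, tolerance = 1e-10)
  expect_equal(sim2$calib, sim$calib / 3, tolerance = 1e-10)
  # no psf, no attenuation -> scaled plain forward projection
  mu0 <- pvc_image(array(0, dim(img_arr(toy$mu))), attr(toy$mu, "spacing"))
  sim3 <- simulate_acquisition(toy$activity, mu0, geom, psf_model(0, 0),
                               total_counts = 1e5)
  fp <- forward_project(toy$activity, geom)
  expect_equal(sim3$values, fp$values * 1e5 / sum(fp$values),
               tolerance = 1e-10)
  expect_error(simulate_acquisition(pvc_image(array(0, c(32, 32, 1)), 2),
                                    toy$mu, geom, psf_model(), 1e5),
               "zero total")
})

test_that("gaussian_blur: constants, FWHM, sum conservation, semigroup", {
  cimg <- pvc_image(array(5, c(16, 16, 16)), 2)
  expect_lt(max(abs(img_arr(gaussian_blur(cimg, c(5, 5, 5))) - 5)), 1e-10)
  # measured FWHM of a blurred point source
  pt <- array(0, c(41, 41, 41)); pt[21, 21, 21] <- 1
  b <- gaussian_blur(pvc_image(pt, 1), c(5, 5, 5), renormalize = FALSE)
  prof <- img_arr(b)[, 21, 21]
  f <- stats::approxfun(1:41, prof - max(prof) / 2)
  fwhm <- stats::uniroot(f, c(21, 28))$root - stats::uniroot(f, c(14, 21))$root
  expect_lt(abs(fwhm - 5), 0.5)
  expect_equal(sum(img_arr(b)), 1, tolerance = 1e-6)
  # semigroup: blur(a) then blur(b) == blur(sqrt(a^2+b^2)) for interior
  # content once sigma exceeds a voxel
  set.seed(22)
  a <- array(0, c(44, 44, 44)); a[18:26, 18:26, 18:26] <- runif(9^3)
  r <- pvc_image(a, 1)
  b1 <- gaussian_blur(gaussian_blur(r, c(3, 3, 3), renormalize = FALSE),
                      c(4, 4, 4), renormalize = FALSE)
  b2 <- gaussian_blur(r, rep(5, 3), renormalize = FALSE)
  expect_lt(max(abs(img_arr(b1) - img_arr(b2))), 1e-6)
})

test_that("Poisson realizations are seeded and have correct moments", {
  toy <- toy2d(n = 8, voxel = 2)
  geom <- toy_geom(8, 2, n_angles = 6)
  sim <- simulate_acquisition(toy$activity, toy$mu, geom, psf_model(0, 0),
                              total_counts = 500)
  r1 <- poisson_realizations(sim, 3, seed = 5)
  r2 <- poisson_realizations(sim, 3, seed = 5)
  expect_identical(r1[[2]]$values, r2[[2]]$values)
  expect_true(all(r1[[1]]$values == round(r1[[1]]$values)))
  # zero expectation -> all-zero realization
  zero <- sim; zero$values[] <- 0
  expect_true(all(poisson_realizations(zero, 1, 1)[[1]]$values == 0))
  # sample mean of a bin with expectation 7 over many draws
  bin <- sim; bin$values[] <- 7
  draws <- vapply(poisson_realizations(bin, 400, seed = 9),
                  function(s) s$values[1, 1, 1], numeric(1))
  expect_lt(abs(mean(draws) - 7), 3 * sqrt(7 / 400))
})

test_that("gate budget arithmetic over gating modes", {
  expect_equal(gate_budget(30, 5, 10, "DUAL")$seconds, 36)
  ecg <- gate_budget(30, 5, 10, "ECG")
  expect_equal(ecg$seconds, 180)
  expect_equal(ecg$count_scale, 5)
  expect_true(ecg$average_resp_states)
  ecgr <- gate_budget(30, 5, 10, "ECG+R")
  expect_false(ecgr$average_resp_states)
  expect_equal(gate_budget(30, 1, 1, "DUAL")$seconds, 1800)
  expect_error(gate_budget(0, 5, 10, "DUAL"))
})
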