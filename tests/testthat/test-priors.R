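test_that("18-neighbourhood is the corner-free 3x3x3 shell", {
  off <- neighbourhood_18()
  expect_equal(nrow(off), 18)
  expect_false(any(rowSums(abs(off)) == 3))          # corners excluded
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(-off) %in% key(off)))          # closed under negation
  expect_true("1 0 0" %in% key(off) && "1 1 0" %in% key(off))
  expect_false("1 1 1" %in% key(off))
})

test_that("relative-difference penalty matches hand-evaluated pairs", {
  f <- pvc_image(array(c(3, 1), c(2, 1, 1)), 1)
  expect_equal(penalty_value(f, prior_spec("RD", beta = 1, gamma = 0,
                                           epsilon = 1e-12)), 1.0,
               tolerance = 1e-9)
  v1 <- penalty_value(f, prior_spec("RD", beta = 1, gamma = 1,
                                    epsilon = 1e-12))
  expect_equal(v1, 4 / 6, tolerance = 1e-9)
  expect_lt(v1, 1.0)  # monotone decreasing in gamma
  # constant image -> zero penalty (TV returns its eps floor)
  cimg <- pvc_image(array(4, c(5, 5, 5)), 1)
  expect_equal(penalty_value(cimg, prior_spec("RD", beta = 2, gamma = 3)), 0)
  spec_tv <- prior_spec("TV", beta = 2, epsilon = 0.01)
  expect_equal(penalty_value(cimg, spec_tv) - 2 * 125 * 0.01, 0,
               tolerance = 1e-12)
  expect_error(penalty_value(pvc_image(array(-1, c(2, 2, 2)), 1),
                             prior_spec("RD", beta = 1)), "non-negative")
})

test_that("penalty gradients match central finite differences", {
  set.seed(31)
  a <- pvc_image(array(runif(6 * 6 * 3) + 0.5, c(6, 6, 3)), 1)
  for (spec in list(prior_spec("RD", beta = 2, gamma = 5, epsilon = 0.01),
                    prior_spec("RD", beta = 1, gamma = 0, epsilon = 0.02),
                    prior_spec("TV", beta = 0.5, epsilon = 0.01))) {
    g <- img_arr(penalty_gradient(a, spec))
    fd <- array(0, dim(g)); h <- 1e-5
    for (i in seq_along(fd)) {
      ap <- img_arr(a); am <- img_arr(a)
      ap[i] <- ap[i] + h; am[i] <- am[i] - h
      fd[i] <- (penalty_value(pvc_image(ap, 1), spec) -
                penalty_value(pvc_image(am, 1), spec)) / (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
  }
  # the gradient sum equals the derivative along the all-ones direction
  # (the intensity-dependent denominator makes it negative, not zero)
  spec_s <- prior_spec("RD", beta = 2, gamma = 5, epsilon = 0.01)
  gg <- img_arr(penalty_gradient(a, spec_s))
  h <- 1e-6
  dir_fd <- (penalty_value(pvc_image(img_arr(a) + h, 1), spec_s) -
             penalty_value(pvc_image(img_arr(a) - h, 1), spec_s)) / (2 * h)
  expect_equal(sum(gg), dir_fd, tolerance = 1e-6)
  expect_lt(sum(gg), 0)
  # constant image -> zero gradient
  cimg <- pvc_image(array(2, c(4, 4, 4)), 1)
  expect_true(all(img_arr(penalty_gradient(cimg,
    prior_spec("RD", beta = 1, gamma = 2))) == 0))
})

test_that("Bowsher selection equals an exhaustive sort on a 3x3x3 toy", {
  set.seed(32)
  an <- pvc_image(array(sample(1:27), c(3, 3, 3)), 1)
  g6 <- bowsher_select(an, 6)
  off <- neighbourhood_18()
  a <- img_arr(an)
  nb <- sweep(off, 2, c(2, 2, 2), "+")
  lin <- nb[, 1] + (nb[, 2] - 1) * 3 + (nb[, 3] - 1) * 9
  dd <- abs(a[lin] - a[14])
  expect_setequal(g6$idx[14, ] + 1, lin[order(dd)][1:6])
  # constant anatomy: all ties -> first n offsets in canonical order
  cn <- pvc_image(array(1, c(5, 5, 5)), 1)
  g3 <- bowsher_select(cn, 3)
  ctr <- 63  # voxel (3,3,3) 1-based linear
  first3 <- sweep(off[1:3, , drop = FALSE], 2, c(3, 3, 3), "+")
  lin3 <- first3[, 1] + (first3[, 2] - 1) * 5 + (first3[, 3] - 1) * 25
  expect_identical(g3$idx[ctr, ] + 1L, as.integer(lin3))
})

test_that("Bowsher never selects across a sharp anatomical boundary", {
  a <- array(0, c(6, 6, 3)); a[4:6, , ] <- 100   # two-region anatomy
  g <- bowsher_select(pvc_image(a, 1), 6)
  left <- which(array(col(matrix(0, 6, 6)) > 0 & row(matrix(0, 6, 6)) <= 3,
                      c(6, 6)))
  # voxel (3,3,2): boundary voxel on the low side
  v <- 3 + (3 - 1) * 6 + (2 - 1) * 36
  sel <- g$idx[v, ] + 1
  xcoord <- ((sel - 1) %% 6) + 1
  expect_true(all(xcoord <= 3))
})

test_that("RD with gamma 0 equals Bowsher over the full neighbourhood", {
  set.seed(33)
  an <- pvc_image(array(runif(125), c(5, 5, 5)), 1)
  act <- pvc_image(array(runif(125) + 0.2, c(5, 5, 5)), 1)
  graph <- bowsher_select(an, 18)
  vb <- penalty_value(act, prior_spec("BOWSHER", beta = 3, n = 18,
                                      epsilon = 0.02), graph)
  vr <- penalty_value(act, prior_spec("RD", beta = 3, gamma = 0,
                                      epsilon = 0.02))
  expect_equal(vb, vr, tolerance = 1e-12)
})

test_that("penalties are translation invariant and RD is scale degree 1", {
  set.seed(34)
  a <- array(0, c(10, 10, 6)); a[4:7, 4:7, 3:4] <- runif(32) + 1
  img <- pvc_image(a, 1)
  shifted <- pvc_image(cardpvc:::integer_roll(a, c(2, 1, 1), 0), 1)
  for (spec in list(prior_spec("RD", beta = 1, gamma = 2, epsilon = 1e-9),
                    prior_spec("TV", beta = 1, epsilon = 1e-9))) {
    expect_equal(penalty_value(shifted, spec), penalty_value(img, spec),
                 tolerance = 1e-6)
  }
  spec0 <- prior_spec("RD", beta = 1, gamma = 2, epsilon = 1e-300)
  for (cc in c(0.5, 2, 7)) {
    expect_equal(penalty_value(pvc_image(cc * a, 1), spec0),
                 cc * penalty_value(img, spec0), tolerance = 1e-9)
  }
})

test_that("TV of a two-level step approaches beta x height x interface area", {
  a <- array(1, c(8, 8, 4)); a[5:8, , ] <- 3   # step of height 2, 8x4 faces
  img <- pvc_image(a, 1)
  vals <- vapply(c(1e-2, 1e-4, 1e-6), function(eps)
    penalty_value(img, prior_spec("TV", beta = 1, epsilon = eps)) -
      1 * prod(dim(a)) * eps,
    numeric(1))
  expect_equal(vals[3], 2 * 8 * 4, tolerance = 1e-3)
  expect_true(all(diff(abs(vals - 64)) <= 0))
})
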