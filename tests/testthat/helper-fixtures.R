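# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# desk-scale phantom (2 mm voxels, full geometry)
desk_phantom <- function() cached("desk_phantom",
  build_phantom(phantom_params(voxel_mm = 2)))

# evaluation masks of the desk phantom on the 3 mm reconstruction grid
desk_masks <- function() cached("desk_masks",
  region_masks(desk_phantom(), c(64, 64, 64), 3))

desk_geom <- function() cached("desk_geom",
  sinogram_geometry(n_angles = 84, n_radial = 137, radial_mm = 2,
                    n_slices = 64, slice_mm = 3))

# annulus-in-disc single-slice toy: LV-like ring (value 5) around a cool
# core (value 1) in a warm disc, with a uniform attenuating cylinder
toy2d <- function(n = 32, voxel = 2) {
  xs <- (seq_len(n) - (n + 1) / 2) * voxel
  X <- outer(xs, rep(1, n)); Y <- outer(rep(1, n), xs)
  r <- sqrt(X^2 + Y^2)
  act <- array(0, c(n, n, 1))
  act[r <= 0.75 * n * voxel / 2] <- 5
  act[r <= 0.37 * n * voxel / 2] <- 1
  mu <- array(0, c(n, n, 1))
  mu[r <= 0.85 * n * voxel / 2] <- 0.096
  list(activity = pvc_image(act, c(voxel, voxel, voxel)),
       mu = pvc_image(mu, c(voxel, voxel, voxel)),
       r = r, n = n, voxel = voxel)
}

toy_geom <- function(n = 32, voxel = 2, n_angles = 48)
  sinogram_geometry(n_angles = n_angles,
                    n_radial = 2 * ceiling(n * voxel * sqrt(2) / 2 / 2) + 5,
                    radial_mm = 2, n_slices = 1, slice_mm = voxel)

# dense system matrix of the projector on a small single-slice grid
dense_system_matrix <- function(n, voxel, geom) {
  nvox <- n * n
  A <- matrix(0, geom$n_radial * geom$n_angles, nvox)
  for (v in seq_len(nvox)) {
    e <- array(0, c(n, n, 1)); e[v] <- 1
    A[, v] <- as.vector(forward_project(pvc_image(e, voxel), geom)$values)
  }
  A
}

# Poisson log-likelihood of an image under the simulated system model
poisson_loglik <- function(f, data, geom) {
  q <- data$calib * data$att$values * forward_project(f, geom)$values
  sum(data$values * log(q + 1e-300) - q)
}

img_arr <- function(x) {
  a <- unclass(x); attr(a, "spacing") <- NULL; a
}
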