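#' Parallel-beam sinogram geometry
#'
#' Multi-slice 2-D parallel-beam geometry: uniform angles over 180 degrees,
#' uniform radial bins, independent axial slices. The default 168 angles
#' are divisible by the subset counts of the full iteration scheme
#' (42, 24, 1); the desk-scale studies use 84 angles (divisible by 12, 6,
#' 1). The radial extent must cover the projected image.
#'
#' @param n_angles number of projection angles over pi.
#' @param n_radial number of radial bins.
#' @param radial_mm radial bin spacing (mm).
#' @param n_slices number of axial slices.
#' @param slice_mm axial slice spacing (mm).
#' @return a `sino_geom` list with an `angles` vector (radians).
#' @export
sinogram_geometry <- function(n_angles = 168, n_radial = 137,
                              radial_mm = 2, n_slices = 1,
                              slice_mm = radial_mm) {
  stopifnot(n_angles >= 1, n_radial >= 1, radial_mm > 0, n_slices >= 1)
  structure(list(n_angles = as.integer(n_angles),
                 angles = (seq_len(n_angles) - 1) * pi / n_angles,
                 n_radial = as.integer(n_radial),
                 radial_mm = radial_mm,
                 n_slices = as.integer(n_slices),
                 slice_mm = slice_mm,
                 fov_mm = n_radial * radial_mm),
            class = "sino_geom")
}

new_sinogram <- function(values, geom, role, calib = NA_real_) {
  structure(list(values = values, geom = geom, role = role, calib = calib),
            class = "pvc_sinogram")
}

#' @export
print.pvc_sinogram <- function(x, ...) {
  g <- x$geom
  cat(sprintf("<pvc_sinogram:%s> %d radial x %d angles x %d slices, sum %.4g\n",
              x$role, g$n_radial, g$n_angles, g$n_slices, sum(x$values)))
  invisible(x)
}

#' Gaussian camera / post-reconstruction resolution model
#' @param fwhm_trans transaxial FWHM (mm).
#' @param fwhm_axial axial FWHM (mm).
#' @return a `psf_model` list.
#' @export
psf_model <- function(fwhm_trans = 4.3, fwhm_axial = 4.5) {
  stopifnot(fwhm_trans >= 0, fwhm_axial >= 0)
  structure(list(fwhm_trans = fwhm_trans, fwhm_axial = fwhm_axial),
            class = "psf_model")
}

#' Convert a Gaussian FWHM to its standard deviation
#' @param fwhm_mm full width at half maximum (mm).
#' @return sigma in mm (`fwhm / sqrt(8 log 2)`).
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  stopifnot(all(fwhm_mm >= 0))
  fwhm_mm / sqrt(8 * log(2))
}

#' Separable Gaussian smoothing in physical units
#'
#' Convolves the image with a separable Gaussian whose per-axis FWHM is
#' given in mm (converted to voxels through the image spacing). With
#' `renormalize = TRUE` (default) the kernel is renormalized over in-bounds
#' taps, so constant images are preserved exactly; with `FALSE` the plain
#' zero-padded convolution is used, which is a symmetric operator and is
#' what the reconstruction system model employs.
#'
#' @param img a [pvc_image].
#' @param psf a [psf_model], or a length-1/2/3 numeric FWHM (mm) recycled
#'   as (transaxial, transaxial, axial).
#' @param renormalize preserve constants at the boundary.
#' @return blurred [pvc_image].
#' @export
gaussian_blur <- function(img, psf, renormalize = TRUE) {
  s <- img_spacing(img)
  fw <- if (inherits(psf, "psf_model"))
    c(psf$fwhm_trans, psf$fwhm_trans, psf$fwhm_axial)
  else if (length(psf) == 2) c(psf[1], psf[1], psf[2])
  else rep_len(as.numeric(psf), 3L)
  sig <- fwhm_to_sigma(fw) / s
  if (all(sig <= 0)) return(img)
  a <- img_data(img)
  d <- dim(a)
  out <- gauss_blur_cpp(a, d[1], d[2], d[3], sig[1], sig[2], sig[3])
  if (renormalize) {
    ones <- gauss_blur_cpp(array(1, d), d[1], d[2], d[3],
                           sig[1], sig[2], sig[3])
    out <- out / ones
  }
  pvc_image(array(out, d), s)
}

check_fov <- function(img, geom) {
  s <- img_spacing(img)
  d <- dim(img_data(img))
  corner <- sqrt((d[1] * s[1])^2 + (d[2] * s[2])^2) / 2
  if (corner > geom$fov_mm / 2 + geom$radial_mm)
    stop("image extends outside the sinogram field of view")
  if (d[3] != geom$n_slices)
    stop("image has ", d[3], " slices but the geometry expects ",
         geom$n_slices, "; rebin axially first")
}

#' Forward projection (line integrals)
#'
#' Ray-driven Joseph projection of a multi-slice image onto the
#' parallel-beam geometry. Values are line integrals in (image unit) x mm.
#' Linear in the image and the exact adjoint of [back_project].
#'
#' @param img a [pvc_image]; axial slice count and spacing must match the
#'   geometry.
#' @param geom a [sinogram_geometry].
#' @param angle_idx optional subset of angle indices (1-based).
#' @return a `pvc_sinogram` of role "line_integral" (over the angle subset
#'   if given).
#' @export
forward_project <- function(img, geom, angle_idx = NULL) {
  check_fov(img, geom)
  s <- img_spacing(img)
  a <- img_data(img)
  d <- dim(a)
  ang <- if (is.null(angle_idx)) geom$angles else geom$angles[angle_idx]
  v <- joseph_fwd(a, d[1], d[2], d[3], s[1], s[2],
                  ang, geom$n_radial, geom$radial_mm)
  new_sinogram(v, geom, "line_integral")
}

#' Back projection (adjoint of [forward_project])
#'
#' @param sino a `pvc_sinogram` or a bare array `(n_radial, n_angles,
#'   n_slices)`.
#' @param geom a [sinogram_geometry].
#' @param img_dim,img_spacing_mm target image grid.
#' @param angle_idx optional subset of angle indices matching the sinogram's
#'   second dimension.
#' @return a [pvc_image].
#' @export
back_project <- function(sino, geom, img_dim, img_spacing_mm,
                         angle_idx = NULL) {
  v <- if (inherits(sino, "pvc_sinogram")) sino$values else sino
  img_dim <- rep_len(as.integer(img_dim), 3L)
  sp <- rep_len(as.numeric(img_spacing_mm), 3L)
  ang <- if (is.null(angle_idx)) geom$angles else geom$angles[angle_idx]
  out <- joseph_back(v, img_dim[1], img_dim[2], img_dim[3], sp[1], sp[2],
                     ang, geom$n_radial, geom$radial_mm)
  pvc_image(array(out, img_dim), sp)
}

#' Per-ray photon survival factors from an attenuation map
#'
#' exp(-integral of mu along the ray), with mu in 1/cm and path lengths in
#' mm. The attenuation correction factor is the reciprocal; simulation and
#' reconstruction both use these factors so attenuation cancels exactly in
#' the matched-model limit.
#'
#' @param mu_map attenuation [pvc_image] (1/cm, non-negative).
#' @param geom a [sinogram_geometry].
#' @return a `pvc_sinogram` of role "attenuation" with values in (0, 1].
#' @export
attenuation_factors <- function(mu_map, geom) {
  if (min(img_data(mu_map)) < 0) stop("attenuation coefficients must be >= 0")
  li <- forward_project(mu_map, geom)
  new_sinogram(exp(-0.1 * li$values), geom, "attenuation")
}

#' Simulate a noise-free PET acquisition
#'
#' Expected-counts sinogram: the activity is smoothed with the camera
#' resolution model in image space, forward projected, attenuated with the
#' per-ray survival factors, and globally scaled so the total equals
#' `total_counts`. The same resolution kernel and attenuation sinogram are
#' reused by matched-model reconstruction.
#'
#' @param activity activity [pvc_image] (kBq/cc).
#' @param mu attenuation [pvc_image] (1/cm), same grid.
#' @param geom a [sinogram_geometry]; images are rebinned axially to the
#'   geometry's slices if needed.
#' @param psf a [psf_model] (camera resolution).
#' @param total_counts expected total counts of the acquisition.
#' @return a `pvc_sinogram` of role "expected" with fields `att` (the
#'   survival-factor sinogram) and `calib` (counts per kBq/cc x mm).
#' @export
simulate_acquisition <- function(activity, mu, geom, psf = psf_model(),
                                 total_counts) {
  stopifnot(total_counts > 0)
  activity <- rebin_axial(activity, geom)
  mu <- rebin_axial(mu, geom)
  blurred <- gaussian_blur(activity, psf, renormalize = FALSE)
  li <- forward_project(blurred, geom)
  att <- attenuation_factors(mu, geom)
  raw <- att$values * li$values
  tot <- sum(raw)
  if (tot <= 0) stop("zero total expected signal; nothing to simulate")
  calib <- total_counts / tot
  out <- new_sinogram(raw * calib, geom, "expected", calib = calib)
  out$att <- att
  out
}

rebin_axial <- function(img, geom) {
  d <- dim(img_data(img))
  s <- img_spacing(img)
  if (d[3] == geom$n_slices && isTRUE(all.equal(s[3], geom$slice_mm)))
    return(img)
  resample_image(img, c(d[1], d[2], geom$n_slices),
                 c(s[1], s[2], geom$slice_mm))
}

#' Poisson noise realizations of an expected sinogram
#'
#' Independent seeded Poisson draws; realization `i` is reproducible from
#' `(seed, i)` alone.
#'
#' @param expected a `pvc_sinogram` of non-negative expected counts.
#' @param n number of realizations.
#' @param seed integer base seed.
#' @return list of `pvc_sinogram`s of role "counts" (integer-valued).
#' @export
poisson_realizations <- function(expected, n, seed = 1L) {
  ev <- expected$values
  if (min(ev) < 0) stop("expected counts must be >= 0")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seed + 7919L * i)
    v <- array(stats::rpois(length(ev), ev), dim(ev))
    s <- new_sinogram(v, expected$geom, "counts", calib = expected$calib)
    s$att <- expected$att
    out[[i]] <- s
  }
  out
}

#' Per-gate scan time under different gating modes
#'
#' A doubly gated scan (`DUAL`) divides the scan among respiratory x
#' cardiac gates (30 min with 5 x 10 gates gives 36 s per gate). ECG-only
#' modes combine all respiratory phases, so a cardiac gate keeps
#' `n_resp` times more counts: `ECG` retains the respiratory motion blur
#' (the expected sinogram must average the respiratory-state sinograms)
#' while `ECG+R` assumes ideal list-mode respiratory motion correction and
#' uses the reference state only.
#'
#' @param scan_minutes total scan duration (minutes).
#' @param n_resp,n_card respiratory and cardiac gate counts.
#' @param mode one of `"DUAL"`, `"ECG"`, `"ECG+R"`.
#' @return list with `seconds`, `count_scale` (relative to DUAL) and
#'   `average_resp_states` (logical).
#' @export
gate_budget <- function(scan_minutes, n_resp, n_card,
                        mode = c("DUAL", "ECG", "ECG+R")) {
  mode <- match.arg(mode)
  stopifnot(scan_minutes > 0, n_resp >= 1, n_card >= 1)
  if (mode == "DUAL") {
    list(seconds = scan_minutes * 60 / (n_resp * n_card),
         count_scale = 1, average_resp_states = FALSE)
  } else {
    list(seconds = scan_minutes * 60 / n_card,
         count_scale = n_resp,
         average_resp_states = (mode == "ECG"))
  }
}
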