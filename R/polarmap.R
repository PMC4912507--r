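#' 17-segment layout of the left-ventricular polar map
#'
#' Longitudinal ring boundaries are fractions of the apex-to-base axis
#' (`t = 0` apex tip, `t = 1` base): apical cap below `t_cap`, apical ring
#' to `t_apical`, mid ring to `t_mid`, basal ring to the base. Angles are
#' measured in the short-axis plane with the lateral wall at 0 degrees and
#' the anterior wall at 90 degrees. Mid and basal rings use the standard
#' 60-degree sectors (anterior, anteroseptal, inferoseptal, inferior,
#' inferolateral, anterolateral). The apical ring is numbered starting at
#' the inferior sector (13 inferior, 14 lateral, 15 anterior, 16 septal),
#' which places the apical-inferior transmural lesion in segment 13 and
#' the mid-inferolateral non-transmural lesion in segment 11; the mapping
#' is fixed here and used everywhere.
#'
#' @param t_cap,t_apical,t_mid ring boundaries (fractions of the axis).
#' @return a `pm_layout` list.
#' @export
pm_layout_17 <- function(t_cap = 0.155, t_apical = 0.222, t_mid = 0.65) {
  stopifnot(0 < t_cap, t_cap < t_apical, t_apical < t_mid, t_mid < 1)
  structure(list(t_cap = t_cap, t_apical = t_apical, t_mid = t_mid,
                 lesion_segments = c(l1 = 11L, l2 = 13L)),
            class = "pm_layout")
}

# segment id for polar coordinates (t in [0,1], phi_deg in [0,360))
segment_of <- function(t, phi_deg, layout) {
  phi <- phi_deg %% 360
  sector6 <- function(phi) {
    # 60-degree sectors: 1 anterior [60,120), 2 anteroseptal [120,180),
    # 3 inferoseptal [180,240), 4 inferior [240,300),
    # 5 inferolateral [300,360), 6 anterolateral [0,60)
    br <- (floor((phi - 60) %% 360 / 60)) + 1
    br
  }
  sector4 <- function(phi) {
    # 90-degree sectors from the inferior wall: 1 inferior [225,315),
    # 2 lateral [315,45), 3 anterior [45,135), 4 septal [135,225)
    (floor((phi - 225) %% 360 / 90)) + 1
  }
  ifelse(t < layout$t_cap, 17L,
  ifelse(t < layout$t_apical, 12L + sector4(phi),
  ifelse(t < layout$t_mid, 6L + sector6(phi), sector6(phi))))
}

#' Delineate the LV wall with an imposed thickness
#'
#' Builds the wall model used for polar-map sampling: a mid-wall surface
#' (truncated prolate ellipsoid) with endo- and epicardial surfaces offset
#' by half the imposed thickness along the local surface normal. For a
#' `phantom_set` the mid-wall surface comes from the analytic geometry;
#' for a logical LV mask it is estimated from the mask (axis from the
#' centroid and axial extent, mid-wall radius from the equatorial band),
#' which is the entry point for real data.
#'
#' @param source a `phantom_set`, or a logical LV mask array with a
#'   `spacing` attribute (a [pvc_image] of 0/1 works).
#' @param thickness_mm imposed wall thickness (mm; 6 by default).
#' @return a `wall_model` list (centre, mid-wall semi-axes, base plane,
#'   thickness).
#' @export
delineate_lv <- function(source, thickness_mm = 6) {
  if (inherits(source, "phantom_set")) {
    g <- source$geom
    wm <- list(centre = g$centre, a_mid = g$a_mid, b_mid = g$b_mid,
               base_z = g$base_z, apex_z = g$apex_z,
               thickness = thickness_mm)
  } else {
    m <- img_data_any(source) > 0.5
    if (sum(m) == 0) stop("empty LV mask; cannot delineate")
    s <- if (inherits(source, "pvc_image")) img_spacing(source)
         else attr(source, "spacing")
    if (is.null(s)) stop("mask needs a spacing attribute")
    d <- dim(m)
    xs <- axis_coords(d[1], s[1]); ys <- axis_coords(d[2], s[2])
    zs <- axis_coords(d[3], s[3])
    idx <- which(m, arr.ind = TRUE)
    ctr <- c(mean(xs[idx[, 1]]), mean(ys[idx[, 2]]), NA)
    zv <- zs[idx[, 3]]
    apex_z <- min(zv); base_z <- max(zv)
    # mid-wall radius from the band around the widest level
    r <- sqrt((xs[idx[, 1]] - ctr[1])^2 + (ys[idx[, 2]] - ctr[2])^2)
    zq <- stats::quantile(zv, c(0.6, 0.9))
    band <- zv >= zq[1] & zv <= zq[2]
    a_mid <- mean(r[band])
    # ellipse through (a_mid at the band centre) pointing to the apex
    zc <- mean(zv[band])
    b_mid <- zc - apex_z + a_mid * 0.2
    ctr[3] <- apex_z + b_mid
    wm <- list(centre = ctr, a_mid = a_mid, b_mid = b_mid,
               base_z = base_z, apex_z = apex_z, thickness = thickness_mm)
  }
  class(wm) <- "wall_model"
  wm
}

# mid-wall point and in-plane radial sampling direction at (t, phi).
# Sampling across the wall follows the short-axis radial direction (the
# convention of bull's-eye tools working on short-axis stacks), so samples
# at one (t, phi) bin stay in one axial plane.
wall_point <- function(wall, t, phi_rad) {
  z <- wall$apex_z + t * (wall$base_z - wall$apex_z)
  zr <- (z - wall$centre[3]) / wall$b_mid
  r <- wall$a_mid * sqrt(pmax(0, 1 - zr^2))
  p <- cbind(wall$centre[1] + r * cos(phi_rad),
             wall$centre[2] + r * sin(phi_rad),
             z)
  list(p = p, n = cbind(cos(phi_rad), sin(phi_rad), 0 * phi_rad))
}

# trilinear sample of an image at physical points (mm), NA outside
trilinear_sample <- function(img, pts) {
  a <- img_data_any(img)
  s <- if (inherits(img, "pvc_image")) img_spacing(img)
       else attr(img, "spacing")
  d <- dim(a)
  u <- sweep(pts, 2, s, "/")
  u <- sweep(u, 2, (dim(a) + 1) / 2, "+")  # 1-based continuous index
  i0 <- floor(u)
  fr <- u - i0
  out <- numeric(nrow(pts))
  ok <- i0[, 1] >= 1 & i0[, 1] < d[1] & i0[, 2] >= 1 & i0[, 2] < d[2] &
        i0[, 3] >= 1 & i0[, 3] < d[3]
  out[!ok] <- NA_real_
  if (any(ok)) {
    i <- i0[ok, , drop = FALSE]; f <- fr[ok, , drop = FALSE]
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[, 1] else 1 - f[, 1]) *
           (if (dy) f[, 2] else 1 - f[, 2]) *
           (if (dz) f[, 3] else 1 - f[, 3])
      acc <- acc + w * a[cbind(i[, 1] + dx, i[, 2] + dy, i[, 3] + dz)]
    }
    out[ok] <- acc
  }
  out
}

#' Sample the LV wall onto a polar raster
#'
#' For each (longitudinal, angular) bin, samples the image along the local
#' radial ray between the endo- and epicardial surfaces of the wall model
#' (quarter-voxel steps, trilinear interpolation) and takes the maximum or
#' the mean across the wall.
#'
#' @param img a [pvc_image] (reconstruction or resampled ground truth).
#' @param wall a `wall_model` from [delineate_lv].
#' @param mode `"max"` or `"mean"`.
#' @param n_long,n_ang raster size (longitudinal x angular bins).
#' @return matrix (n_long x n_ang) with attributes `t` and `phi_deg`; row
#'   1 is the apex tip.
#' @export
wall_samples <- function(img, wall, mode = c("max", "mean"),
                         n_long = 36, n_ang = 72) {
  mode <- match.arg(mode)
  s <- img_spacing(img)
  step <- min(s) / 4
  half <- wall$thickness / 2
  us <- seq(-half, half, by = step)
  t_grid <- (seq_len(n_long) - 0.5) / n_long
  phi_grid <- (seq_len(n_ang) - 0.5) * 2 * pi / n_ang
  raster <- matrix(NA_real_, n_long, n_ang)
  for (it in seq_len(n_long)) {
    wp <- wall_point(wall, t_grid[it], phi_grid)
    vals <- matrix(NA_real_, length(us), n_ang)
    for (k in seq_along(us)) {
      vals[k, ] <- trilinear_sample(img, wp$p + us[k] * wp$n)
    }
    raster[it, ] <- if (mode == "max") {
      suppressWarnings(apply(vals, 2, max, na.rm = TRUE))
    } else {
      colMeans(vals, na.rm = TRUE)
    }
  }
  raster[!is.finite(raster)] <- NA_real_
  attr(raster, "t") <- t_grid
  attr(raster, "phi_deg") <- phi_grid * 180 / pi
  attr(raster, "mode") <- mode
  raster
}

#' Collapse a polar raster to the 17 segment means
#'
#' Assigns every raster pixel to exactly one segment of the layout and
#' averages within segments.
#' @param raster output of [wall_samples].
#' @param layout a [pm_layout_17].
#' @return numeric vector of length 17 (named `seg1` ... `seg17`).
#' @export
to_17_segments <- function(raster, layout = pm_layout_17()) {
  t_grid <- attr(raster, "t")
  phi <- attr(raster, "phi_deg")
  seg <- outer(t_grid, phi, function(t, p) segment_of(t, p, layout))
  out <- vapply(1:17, function(k) mean(raster[seg == k], na.rm = TRUE),
                numeric(1))
  names(out) <- paste0("seg", 1:17)
  out
}

#' Polar map of one image (raster + segment means)
#' @inheritParams wall_samples
#' @param layout a [pm_layout_17].
#' @return list with `raster`, `segments`, `mode`, `layout`.
#' @export
polar_map <- function(img, wall, mode = c("max", "mean"),
                      layout = pm_layout_17(), n_long = 36, n_ang = 72) {
  mode <- match.arg(mode)
  raster <- wall_samples(img, wall, mode, n_long, n_ang)
  list(raster = raster, segments = to_17_segments(raster, layout),
       mode = mode, layout = layout)
}

#' Normal / lesion summaries of segment means across realizations
#'
#' Splits the 17 segment means into the lesion segments (11 for the
#' non-transmural, 13 for the transmural lesion) and the normal tissue
#' (all other segments), and reports mean, min and max over realizations.
#'
#' @param segment_means matrix (realizations x 17) or a single length-17
#'   vector.
#' @param layout a [pm_layout_17].
#' @return data.frame with rows `normal`, `l1`, `l2`.
#' @export
lesion_summary <- function(segment_means, layout = pm_layout_17()) {
  m <- if (is.matrix(segment_means)) segment_means
       else matrix(segment_means, nrow = 1)
  ls <- layout$lesion_segments
  normal_idx <- setdiff(1:17, ls)
  per_real <- cbind(normal = rowMeans(m[, normal_idx, drop = FALSE]),
                    l1 = m[, ls[["l1"]]],
                    l2 = m[, ls[["l2"]]])
  data.frame(region = colnames(per_real),
             mean = colMeans(per_real),
             min = apply(per_real, 2, min),
             max = apply(per_real, 2, max),
             row.names = NULL)
}
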