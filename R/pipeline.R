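#' Study configuration
#'
#' Desk-scale defaults: 96^3 phantom at 2 mm, reconstruction 64^3 at 3 mm,
#' 84 angles, 10 noise realizations, 3.9e6 expected counts for the 36-s
#' doubly gated frame. The default scheme 3i42s + 2i21s + 2i1s keeps the
#' full-scale scheme's effective iteration count (which the noise
#' behaviour of unregularized resolution recovery depends on) with subset
#' sizes that divide 84 angles. The full-scale setting (0.8 mm phantom,
#' 1.35 mm reconstruction, 168 angles, scheme 3i42s+2i24s+2i1s, 20-25
#' realizations) is reached by overriding these fields.
#'
#' The default roster covers the five algorithm families: OSEM3D (+5 mm
#' post-smoothing), OSEM3D+RR (+5 mm post-smoothing), MAP-RD (beta 4,
#' gamma 10), MAP-TV (beta 0.005) and MAP-Bowsher (beta 10, n 9, MR
#' anatomy) — the selected "clinical" parameter sets.
#'
#' @param phantom a [phantom_params] (desk default at 2 mm).
#' @param n_angles,radial_mm,n_radial sinogram geometry.
#' @param recon_dim,recon_voxel_mm reconstruction grid (axial spacing =
#'   `recon_voxel_mm`).
#' @param scheme iteration scheme (list of `c(iterations, subsets)`).
#' @param gate_mode `"DUAL"`, `"ECG"` or `"ECG+R"`.
#' @param counts_dual expected counts of the 36-s doubly gated frame; other
#'   modes scale it by their count ratio.
#' @param n_realizations,base_seed noise ensemble controls.
#' @param algorithms named list of algorithm descriptors (see
#'   [algorithm_spec]).
#' @param threshold_fraction region-mask threshold.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return a `study_config` list.
#' @export
study_config <- function(phantom = phantom_params(voxel_mm = 2),
                         n_angles = 84, radial_mm = 2, n_radial = 137,
                         recon_dim = 64, recon_voxel_mm = 3,
                         scheme = list(c(3, 42), c(2, 21), c(2, 1)),
                         gate_mode = "DUAL", counts_dual = 3.9e6,
                         n_realizations = 10, base_seed = 1L,
                         algorithms = default_roster(),
                         threshold_fraction = 0.7, out_dir = NULL) {
  structure(list(phantom = phantom, n_angles = n_angles,
                 radial_mm = radial_mm, n_radial = n_radial,
                 recon_dim = recon_dim, recon_voxel_mm = recon_voxel_mm,
                 scheme = scheme, gate_mode = gate_mode,
                 counts_dual = counts_dual,
                 n_realizations = n_realizations,
                 base_seed = as.integer(base_seed),
                 algorithms = algorithms,
                 threshold_fraction = threshold_fraction,
                 out_dir = out_dir),
            class = "study_config")
}

#' Algorithm descriptor for the study roster
#'
#' @param algo one of `"osem"`, `"osem-rr"`, `"map-rd"`, `"map-tv"`,
#'   `"map-bowsher"`.
#' @param post_fwhm Gaussian post-smoothing FWHM (mm) or `NULL`.
#' @param beta,gamma,n prior parameters (as applicable).
#' @param anatomy `"mr"`, `"hrct"` or `"mr_aniso"` (Bowsher only).
#' @param variant `"perf"`, `"shift"`, `"mism"` (Bowsher only).
#' @param shift_mm anatomy shift vector (mm) for `variant = "shift"`.
#' @param heart_scale,phase_delta mismatch surrogates for
#'   `variant = "mism"`.
#' @return an `algorithm_spec` list.
#' @export
algorithm_spec <- function(algo, post_fwhm = NULL, beta = NULL,
                           gamma = 0, n = 9, anatomy = "mr",
                           variant = "perf", shift_mm = c(0, 0, 0),
                           heart_scale = 1, phase_delta = 0) {
  structure(list(algo = algo, post_fwhm = post_fwhm, beta = beta,
                 gamma = gamma, n = n, anatomy = anatomy,
                 variant = variant, shift_mm = shift_mm,
                 heart_scale = heart_scale, phase_delta = phase_delta),
            class = "algorithm_spec")
}

#' @rdname study_config
#' @export
default_roster <- function() {
  list(
    osem = algorithm_spec("osem", post_fwhm = 5),
    osem_rr = algorithm_spec("osem-rr", post_fwhm = 5),
    map_rd = algorithm_spec("map-rd", beta = 4, gamma = 10),
    map_tv = algorithm_spec("map-tv", beta = 0.005),
    bowsher_mr_perf = algorithm_spec("map-bowsher", beta = 10, n = 9,
                                     anatomy = "mr", variant = "perf")
  )
}

#' Enumerate the planned runs of a study
#' @param config a [study_config].
#' @return data.frame manifest (one row per algorithm).
#' @export
study_manifest <- function(config) {
  rows <- lapply(names(config$algorithms), function(nm) {
    a <- config$algorithms[[nm]]
    data.frame(name = nm, algo = a$algo,
               family = algo_family(a$algo),
               post_fwhm = if (is.null(a$post_fwhm)) NA else a$post_fwhm,
               beta = if (is.null(a$beta)) NA else a$beta,
               gamma = a$gamma, n = a$n,
               anatomy = if (a$algo == "map-bowsher") a$anatomy else NA,
               variant = if (a$algo == "map-bowsher") a$variant else NA,
               n_realizations = config$n_realizations,
               seed = config$base_seed)
  })
  do.call(rbind, rows)
}

algo_family <- function(algo) {
  c("osem" = "OSEM3D", "osem-rr" = "OSEM3D+RR", "map-rd" = "MAP-RD",
    "map-tv" = "MAP-TV", "map-bowsher" = "MAP-Bowsher")[[algo]]
}

# build the recon_spec and (if needed) Bowsher graph for one algorithm
prepare_algorithm <- function(aspec, config, phantom, geom) {
  prior <- switch(aspec$algo,
    "osem" = NULL, "osem-rr" = NULL,
    "map-rd" = prior_spec("RD", beta = aspec$beta, gamma = aspec$gamma),
    "map-tv" = prior_spec("TV", beta = aspec$beta),
    "map-bowsher" = prior_spec("BOWSHER", beta = aspec$beta, n = aspec$n),
    stop("unknown algorithm: ", aspec$algo))
  rr <- aspec$algo != "osem"
  spec <- recon_spec(scheme = config$scheme, rr = rr,
                     prior = prior, post_fwhm = aspec$post_fwhm,
                     dim = config$recon_dim,
                     voxel_mm = config$recon_voxel_mm)
  graph <- NULL
  if (aspec$algo == "map-bowsher") {
    anat_set <- phantom
    if (aspec$variant == "mism")
      anat_set <- mismatch_phantom(phantom$params, aspec$heart_scale,
                                   aspec$phase_delta)
    anat <- anat_set[[aspec$anatomy]]
    if (aspec$variant == "shift")
      anat <- shift_image(anat, aspec$shift_mm)
    rd <- c(spec$dim, geom$n_slices)
    rs <- c(spec$voxel_mm, spec$voxel_mm, geom$slice_mm)
    anat_r <- resample_image(anat, rd, rs)
    graph <- bowsher_select(anat_r, prior$n, prior$offsets)
  }
  list(spec = spec, graph = graph)
}

#' Run the full simulation study
#'
#' Generates the phantom, simulates the acquisition for the configured
#' gate mode, draws the Poisson noise ensemble, reconstructs every
#' realization with every algorithm in the roster, and evaluates figures
#' of merit, polar-map summaries (both modes) and the septal-lateral
#' profile through the non-transmural lesion. Deterministic given
#' `base_seed`; per-run provenance is recorded in the manifest. When a run
#' fails its error is recorded and the run is skipped in aggregation.
#'
#' @param config a [study_config].
#' @return list with `metrics` (data.frame), `polar` (per-algorithm
#'   [lesion_summary] tables, both modes), `profiles`, `manifest`,
#'   `masks`, `truth`, and `errors`.
#' @export
run_study <- function(config = study_config()) {
  phantom <- build_phantom(config$phantom)
  geom <- sinogram_geometry(n_angles = config$n_angles,
                            n_radial = config$n_radial,
                            radial_mm = config$radial_mm,
                            n_slices = as.integer(round(
                              config$phantom$extent_mm /
                              config$recon_voxel_mm)),
                            slice_mm = config$recon_voxel_mm)
  masks <- region_masks(phantom, c(rep(config$recon_dim, 2), geom$n_slices),
                        c(rep(config$recon_voxel_mm, 2), geom$slice_mm),
                        config$threshold_fraction)
  budget <- gate_budget(config$phantom$scan_minutes,
                        config$phantom$resp_gates,
                        config$phantom$card_gates, config$gate_mode)
  counts <- config$counts_dual * budget$count_scale
  if (budget$average_resp_states) {
    states <- respiratory_states(config$phantom, config$phantom$resp_gates)
    sinos <- lapply(states, function(st)
      simulate_acquisition(st$activity, st$mu_map, geom,
                           total_counts = counts))
    expected <- sinos[[1]]
    expected$values <- Reduce(`+`, lapply(sinos, `[[`, "values")) /
      length(sinos)
    expected$values <- expected$values * counts / sum(expected$values)
  } else {
    expected <- simulate_acquisition(phantom$activity, phantom$mu_map,
                                     geom, total_counts = counts)
  }
  realizations <- poisson_realizations(expected, config$n_realizations,
                                       config$base_seed)
  wall <- delineate_lv(phantom, thickness_mm = 6)
  line <- study_profile_line(phantom)

  metrics <- list(); polar <- list(); profiles <- list(); errors <- list()
  for (nm in names(config$algorithms)) {
    res <- tryCatch({
      prep <- prepare_algorithm(config$algorithms[[nm]], config, phantom,
                                geom)
      recons <- lapply(realizations, function(d) {
        if (is.null(prep$spec$prior)) osem(d, geom = geom, spec = prep$spec)
        else map_osem(d, geom = geom, spec = prep$spec, graph = prep$graph)
      })
      rep0 <- metrics_report(recons, masks)
      rep0$algorithm <- nm
      segs <- list(
        max = t(vapply(recons, function(r)
          to_17_segments(wall_samples(r, wall, "max")), numeric(17))),
        mean = t(vapply(recons, function(r)
          to_17_segments(wall_samples(r, wall, "mean")), numeric(17))))
      avg <- pvc_image(Reduce(`+`, lapply(recons, img_data_any)) /
                         length(recons), img_spacing(recons[[1]]))
      prof <- profile_extract(avg, line$p0, line$p1)
      list(metrics = rep0,
           polar = list(max = lesion_summary(segs$max),
                        mean = lesion_summary(segs$mean)),
           profile = prof)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("run '", nm, "' failed: ", conditionMessage(res))
      errors[[nm]] <- conditionMessage(res)
    } else {
      metrics[[nm]] <- res$metrics
      polar[[nm]] <- res$polar
      profiles[[nm]] <- res$profile
    }
  }
  out <- list(metrics = do.call(rbind, metrics),
              polar = polar, profiles = profiles,
              manifest = study_manifest(config),
              masks = masks, truth = masks$truth,
              expected = expected, errors = errors)
  if (!is.null(config$out_dir)) write_study(out, config)
  out
}

write_study <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(out$manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(gate_mode = config$gate_mode, counts = config$counts_dual,
         n_realizations = config$n_realizations,
         base_seed = config$base_seed,
         algorithms = lapply(config$algorithms, unclass),
         errors = out$errors),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  md <- c("# Study summary", "",
          sprintf("- gate mode: %s", config$gate_mode),
          sprintf("- realizations: %d", config$n_realizations),
          sprintf("- algorithms: %s",
                  paste(names(config$algorithms), collapse = ", ")), "",
          "See metrics.csv / manifest.csv for the full tables.")
  writeLines(md, file.path(config$out_dir, "summary.md"))
  invisible(config$out_dir)
}

#' Septal-lateral profile line through the non-transmural lesion
#' @param phantom a `phantom_set`.
#' @return list with endpoints `p0`, `p1` (mm) at the lesion's y/z level.
#' @export
study_profile_line <- function(phantom) {
  m <- phantom$masks$l1
  s <- img_spacing(phantom$activity)
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  yc <- mean(axis_coords(d[2], s[2])[idx[, 2]])
  zc <- mean(axis_coords(d[3], s[3])[idx[, 3]])
  g <- phantom$geom
  reach <- g$epi[1] + 15
  list(p0 = c(g$centre[1] - reach, yc, zc),
       p1 = c(g$centre[1] + reach, yc, zc))
}

#' Extract a 1-D intensity profile along a line segment
#'
#' Samples the image at `n` evenly spaced points between two physical
#' endpoints (mm), with trilinear or nearest-voxel interpolation.
#' @param img a [pvc_image].
#' @param p0,p1 endpoints (mm, length 3).
#' @param n number of samples.
#' @param method `"linear"` or `"nearest"`.
#' @return data.frame with `s_mm` (distance from `p0`) and `value`.
#' @export
profile_extract <- function(img, p0, p1, n = 128,
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  tt <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]),
               p0[2] + tt * (p1[2] - p0[2]),
               p0[3] + tt * (p1[3] - p0[3]))
  v <- if (method == "linear") trilinear_sample(img, pts)
  else {
    a <- img_data(img)
    s <- img_spacing(img)
    u <- round(sweep(sweep(pts, 2, s, "/"), 2, (dim(a) + 1) / 2, "+"))
    ok <- u[, 1] >= 1 & u[, 1] <= dim(a)[1] & u[, 2] >= 1 &
          u[, 2] <= dim(a)[2] & u[, 3] >= 1 & u[, 3] <= dim(a)[3]
    out <- rep(NA_real_, n)
    out[ok] <- a[u[ok, , drop = FALSE]]
    out
  }
  data.frame(s_mm = tt * sqrt(sum((p1 - p0)^2)), value = v)
}
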