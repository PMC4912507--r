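#' Region means across noise realizations
#' @param recons list of reconstructed [pvc_image]s (or arrays).
#' @param mask logical mask on the reconstruction grid.
#' @return per-realization region means (numeric vector).
#' @export
region_means <- function(recons, mask) {
  if (sum(mask) == 0) stop("empty region mask")
  vapply(recons, function(r) mean(img_data_any(r)[mask]), numeric(1))
}

img_data_any <- function(x) if (inherits(x, "pvc_image")) img_data(x) else x

#' LV bias: mean reconstructed activity minus the true value
#'
#' Mean over realizations of the region-mean activity, minus the true
#' piecewise-constant value (kBq/cc).
#' @param recons list of reconstructions (>= 1).
#' @param mask LV mask.
#' @param true_value true LV activity (kBq/cc).
#' @return scalar bias (kBq/cc).
#' @export
bias_lv <- function(recons, mask, true_value) {
  mean(region_means(recons, mask)) - true_value
}

#' Ensemble noise over a region
#'
#' Voxelwise sample standard deviation (n-1) across realizations, averaged
#' over the mask. Invariant under adding a common image to every
#' realization.
#' @param recons list of reconstructions (>= 2).
#' @param mask region mask.
#' @return scalar noise in image units.
#' @export
noise_region <- function(recons, mask) {
  if (length(recons) < 2) stop("noise needs at least 2 realizations")
  m <- vapply(recons, function(r) img_data_any(r)[mask],
              numeric(sum(mask)))
  mean(apply(m, 1, stats::sd))
}

#' Region contrast against its background
#'
#' `mean_r / mean_BP - 1` for the ventricles (hot regions against the
#' blood pool) and `1 - mean_r / mean_LV` for the lesions (cold regions
#' against the LV wall).
#' @param region_mean,background_mean mean activities of the region and of
#'   its background (blood pool for LV/RV, LV for L1/L2).
#' @param type `"hot"` (LV, RV) or `"cold"` (L1, L2).
#' @return scalar contrast.
#' @export
region_contrast <- function(region_mean, background_mean,
                            type = c("hot", "cold")) {
  type <- match.arg(type)
  if (type == "hot") region_mean / background_mean - 1
  else 1 - region_mean / background_mean
}

#' Recovery coefficient
#'
#' Mean reconstructed activity in the region (region mean first, then
#' averaged over realizations) divided by the true value. Undefined when
#' the true value is zero (e.g. a fully transmural scar) and refuses to
#' return a number in that case.
#' @param recons list of reconstructions.
#' @param mask region mask.
#' @param true_value true activity (non-zero).
#' @return scalar RC.
#' @export
rc <- function(recons, mask, true_value) {
  if (true_value == 0)
    stop("RC is undefined for a region with true mean zero")
  mean(region_means(recons, mask)) / true_value
}

#' Contrast recovery coefficient
#'
#' Reconstructed contrast divided by the true contrast; flagged `NA` when
#' the true contrast is zero.
#' @param recon_contrast,true_contrast contrasts from [region_contrast].
#' @return scalar CRC, or `NA` with attribute `undefined` when the true
#'   contrast is zero.
#' @export
crc <- function(recon_contrast, true_contrast) {
  if (true_contrast == 0) {
    warning("true contrast is zero; CRC undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  recon_contrast / true_contrast
}

#' Contrast-to-noise ratio
#'
#' Reconstructed contrast divided by the relative noise of the background
#' region (ensemble stddev / mean over the background: blood pool for the
#' ventricles, LV for the lesions).
#' @param recon_contrast contrast of the region.
#' @param recons list of reconstructions.
#' @param background_mask background region mask.
#' @return scalar CNR.
#' @export
cnr <- function(recon_contrast, recons, background_mask) {
  noise_b <- noise_region(recons, background_mask) /
    mean(region_means(recons, background_mask))
  recon_contrast / noise_b
}

#' Paired significance test between two algorithms
#'
#' Two-sided paired t test on per-realization values, with a significance
#' decision at the stated level.
#' @param a,b equal-length paired samples (>= 2 pairs).
#' @param alpha significance level (default 0.01).
#' @return list with `statistic`, `p.value`, `significant`, `alpha`.
#' @export
paired_test <- function(a, b, alpha = 0.01) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  ht <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       significant = ht$p.value < alpha, alpha = alpha)
}

#' Full figure-of-merit report for one set of reconstructions
#'
#' Per region: RC (where defined), contrast, CRC, CNR with min/max of the
#' per-realization values, plus LV bias and LV noise. Region means are
#' computed region-first, then averaged over realizations. True region
#' values are the region means of the resampled ground truth on the
#' reconstruction grid (the reference the evaluation is defined against),
#' so a reconstruction identical to the resampled truth reaches the exact
#' fixed points bias 0, RC 1, CRC 1.
#'
#' @param recons list of reconstructions of the same data under one
#'   algorithm.
#' @param masks region masks (as from [region_masks]).
#' @param truth resampled ground-truth [pvc_image] on the reconstruction
#'   grid (defaults to `masks$truth`).
#' @return data.frame, one row per region x metric.
#' @export
metrics_report <- function(recons, masks, truth = masks$truth) {
  nreal <- length(recons)
  mLV <- region_means(recons, masks$lv)
  mRV <- region_means(recons, masks$rv)
  mBP <- region_means(recons, masks$bp)
  mL1 <- region_means(recons, masks$l1)
  mL2 <- region_means(recons, masks$l2)
  tv <- img_data_any(truth)
  activities <- list(lv = mean(tv[masks$lv]), rv = mean(tv[masks$rv]),
                     blood = mean(tv[masks$bp]), l1 = mean(tv[masks$l1]),
                     l2 = mean(tv[masks$l2]))
  true_c <- c(
    lv = region_contrast(activities[["lv"]], activities[["blood"]], "hot"),
    rv = region_contrast(activities[["rv"]], activities[["blood"]], "hot"),
    l1 = region_contrast(activities[["l1"]], activities[["lv"]], "cold"),
    l2 = region_contrast(activities[["l2"]], activities[["lv"]], "cold"))
  rec_c <- c(
    lv = region_contrast(mean(mLV), mean(mBP), "hot"),
    rv = region_contrast(mean(mRV), mean(mBP), "hot"),
    l1 = region_contrast(mean(mL1), mean(mLV), "cold"),
    l2 = region_contrast(mean(mL2), mean(mLV), "cold"))
  # per-realization contrasts for the min/max columns and paired tests
  per_c <- list(
    lv = region_contrast(mLV, mBP, "hot"),
    rv = region_contrast(mRV, mBP, "hot"),
    l1 = region_contrast(mL1, mLV, "cold"),
    l2 = region_contrast(mL2, mLV, "cold"))
  noise_bp <- if (nreal >= 2) noise_region(recons, masks$bp) / mean(mBP)
              else NA_real_
  noise_lv <- if (nreal >= 2) noise_region(recons, masks$lv) / mean(mLV)
              else NA_real_
  noise_of <- c(lv = noise_bp, rv = noise_bp, l1 = noise_lv, l2 = noise_lv)

  rows <- lapply(names(true_c), function(r) {
    rc_val <- if (r == "l2") NA_real_
              else mean(get(paste0("m", toupper(r)))) / activities[[r]]
    data.frame(
      region = r,
      rc = rc_val,
      contrast = unname(rec_c[r]),
      crc = unname(rec_c[r] / true_c[r]),
      cnr = unname(rec_c[r] / noise_of[r]),
      cnr_min = min(per_c[[r]] / noise_of[r]),
      cnr_max = max(per_c[[r]] / noise_of[r]),
      n_realizations = nreal)
  })
  out <- do.call(rbind, rows)
  out$bias_lv <- mean(mLV) - activities[["lv"]]
  out$noise_lv_abs <- if (nreal >= 2) noise_region(recons, masks$lv)
                      else NA_real_
  out
}

#' Per-realization CNR values for paired comparisons
#'
#' CNR of one region for each realization (per-realization contrast over
#' the shared ensemble background noise), as used by the paired t test
#' between algorithms.
#' @param recons list of reconstructions.
#' @param masks region masks.
#' @param region `"lv"`, `"rv"`, `"l1"` or `"l2"`.
#' @return numeric vector, one CNR per realization.
#' @export
cnr_per_realization <- function(recons, masks, region) {
  hot <- region %in% c("lv", "rv")
  bmask <- if (hot) masks$bp else masks$lv
  mR <- region_means(recons, masks[[region]])
  mB <- region_means(recons, bmask)
  noise_b <- noise_region(recons, bmask) / mean(mB)
  ctr <- if (hot) mR / mean(region_means(recons, masks$bp)) - 1
         else 1 - mR / mean(region_means(recons, masks$lv))
  ctr / noise_b
}

#' Assemble bias-noise and contrast-noise curves over a parameter grid
#'
#' Orders one (noise, bias) and one (noise, contrast) point per run,
#' grouped by algorithm, as used for penalty-weight selection plots.
#' @param runs data.frame with columns `algorithm`, `param_id`, `noise`,
#'   `bias`, `contrast` (one row per run).
#' @param path optional CSV output path.
#' @return list of data.frames `bias_noise` and `contrast_noise`, ordered
#'   by noise within algorithm.
#' @export
curve_assembly <- function(runs, path = NULL) {
  need <- c("algorithm", "param_id", "noise", "bias", "contrast")
  stopifnot(all(need %in% names(runs)))
  ord <- order(runs$algorithm, runs$noise)
  bn <- runs[ord, c("algorithm", "param_id", "noise", "bias")]
  cn <- runs[ord, c("algorithm", "param_id", "noise", "contrast")]
  if (!is.null(path)) {
    utils::write.csv(runs[ord, need], path, row.names = FALSE)
  }
  list(bias_noise = bn, contrast_noise = cn)
}
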