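#' Approximately spherical 18-neighbour offset set
#'
#' The 26 offsets of the 3 x 3 x 3 cube minus the centre and minus the 8
#' corner offsets, i.e. all neighbours at distance 1 or sqrt(2) in voxel
#' units. Returned in canonical order (increasing squared distance, then
#' lexicographic in dz, dy, dx), which is also the tie-break order of the
#' Bowsher selection. Closed under sign flip.
#'
#' @return integer matrix (18 x 3) of voxel offsets.
#' @export
neighbourhood_18 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d2 <- rowSums(g^2)
  g <- g[d2 > 0 & d2 < 3, , drop = FALSE]
  d2 <- rowSums(g^2)
  ord <- order(d2, g[, 3], g[, 2], g[, 1])
  out <- g[ord, , drop = FALSE]
  dimnames(out) <- list(NULL, c("dx", "dy", "dz"))
  storage.mode(out) <- "integer"
  out
}

#' Penalty specification for MAP reconstruction
#'
#' @param kind one of `"RD"` (relative difference), `"TV"` (total
#'   variation), `"BOWSHER"` (anatomically selected relative difference
#'   with `gamma = 0`).
#' @param beta penalty weight (>= 0).
#' @param gamma edge-preservation parameter of the RD penalty (0 = no edge
#'   preservation).
#' @param n number of selected neighbours for the Bowsher prior.
#' @param offsets neighbourhood offset matrix (default [neighbourhood_18]).
#' @param epsilon numerical floor; `NULL` means 1e-6 x image maximum,
#'   evaluated per image.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(kind = c("RD", "TV", "BOWSHER"), beta,
                       gamma = 0, n = 9, offsets = neighbourhood_18(),
                       epsilon = NULL) {
  kind <- match.arg(kind)
  stopifnot(beta >= 0, gamma >= 0, n >= 1, n <= nrow(offsets),
            is.null(epsilon) || epsilon > 0)
  structure(list(kind = kind, beta = beta, gamma = gamma, n = as.integer(n),
                 offsets = offsets, epsilon = epsilon),
            class = "prior_spec")
}

#' Bowsher neighbour selection from an anatomical image
#'
#' For every voxel, selects the `n` in-bounds neighbours (within the offset
#' neighbourhood) whose anatomical value is closest to the voxel's own,
#' ties broken by the canonical offset order. The selection depends only on
#' the anatomy and is asymmetric: voxel j may select k without k selecting
#' j. Boundary voxels with fewer than `n` in-bounds neighbours select all
#' available ones and are flagged.
#'
#' @param anatomy anatomical [pvc_image] on the reconstruction grid.
#' @param n neighbours to select per voxel.
#' @param offsets offset matrix (default [neighbourhood_18]).
#' @return a `neighbour_graph`: 0-based linear neighbour indices
#'   (`idx`, -1 = none), pair weights `w` (1/offset length in voxel
#'   units), the grid `dim`, `n`, and `short_voxels` (count of flagged
#'   boundary voxels).
#' @export
bowsher_select <- function(anatomy, n, offsets = neighbourhood_18()) {
  if (n > nrow(offsets))
    stop("n exceeds the neighbourhood size (", nrow(offsets), ")")
  a <- img_data(anatomy)
  d <- dim(a)
  sel <- bowsher_select_cpp(as.double(a), d[1], d[2], d[3], offsets,
                            as.integer(n))
  short <- sum(sel$idx[, n] < 0)
  structure(list(idx = sel$idx, w = sel$w, dim = d, n = as.integer(n),
                 short_voxels = short),
            class = "neighbour_graph")
}

# non-selective graph over the full neighbourhood (used by RD)
full_neighbour_graph <- function(dim, offsets = neighbourhood_18()) {
  g <- full_graph_cpp(dim[1], dim[2], dim[3], offsets)
  structure(list(idx = g$idx, w = g$w, dim = dim, n = nrow(offsets),
                 short_voxels = NA_integer_),
            class = "neighbour_graph")
}

prior_epsilon <- function(spec, img_max) {
  if (!is.null(spec$epsilon)) return(spec$epsilon)
  if (img_max > 0) 1e-6 * img_max else 1e-12
}

resolve_graph <- function(img_dim, spec, graph) {
  if (!is.null(graph)) {
    if (!all(graph$dim == img_dim))
      stop("neighbour graph grid does not match the image")
    return(graph)
  }
  if (spec$kind == "BOWSHER")
    stop("the Bowsher prior needs a neighbour graph (see bowsher_select)")
  full_neighbour_graph(img_dim, spec$offsets)
}

penalty_pair <- function(img, spec, graph = NULL) {
  a <- img_data(img)
  d <- dim(a)
  if (spec$kind %in% c("RD", "BOWSHER") && min(a) < 0)
    stop("the relative-difference penalty requires a non-negative image")
  eps <- prior_epsilon(spec, max(a))
  if (spec$kind == "TV") {
    d3 <- dim(a)
    out <- tv_penalty_cpp(as.double(a), d3[1], d3[2], d3[3], eps, spec$beta)
    return(list(value = out$value, grad = array(out$grad, d3),
                curv = array(out$curv, d3)))
  }
  g <- resolve_graph(d, spec, graph)
  gam <- if (spec$kind == "BOWSHER") 0 else spec$gamma
  out <- rd_penalty_cpp(as.double(a), g$idx, g$w, gam, eps, spec$beta)
  list(value = out$value, grad = array(out$grad, d),
       curv = array(out$curv, d))
}

#' Penalty value of an image under a prior
#'
#' RD / Bowsher: `(beta/2) * sum over voxel-neighbour pairs of
#' w (f_j - f_k)^2 / (f_j + f_k + gamma |f_j - f_k| + eps)`, with the
#' Bowsher neighbour set taken from the anatomical selection and
#' `gamma = 0`. TV: `beta * sum_j sqrt(|forward difference|^2 + eps^2)`
#' (smoothed isotropic total variation; a constant image returns the
#' eps floor `beta * nvox * eps`).
#'
#' @param img a [pvc_image] (non-negative for RD/Bowsher).
#' @param spec a [prior_spec].
#' @param graph a `neighbour_graph` (required for Bowsher).
#' @return scalar penalty value.
#' @export
penalty_value <- function(img, spec, graph = NULL) {
  penalty_pair(img, spec, graph)$value
}

#' Analytic gradient of [penalty_value]
#' @inheritParams penalty_value
#' @return gradient [pvc_image] (same grid as `img`).
#' @export
penalty_gradient <- function(img, spec, graph = NULL) {
  pvc_image(penalty_pair(img, spec, graph)$grad, img_spacing(img))
}
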