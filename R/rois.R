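# Chebyshev dilation of a logical volume by r voxels (separable box filter)
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  v <- array(as.numeric(mask), dim = dim(mask))
  k <- rep(1, 2 * r + 1)
  for (ax in 1:3) v <- conv_axis(v, k, ax)
  v > 1e-9
}

# sum of the frames whose span lies inside the window, weighted by duration
early_summed <- function(image, window = c(0, 2)) {
  keep <- image$schedule$start >= window[1] - 1e-9 &
    image$schedule$end <= window[2] + 1e-9
  assert_that(any(keep), "no frames inside the early window")
  d <- dim(image$voxels)
  out <- array(0, dim = d[1:3])
  for (fr in which(keep)) {
    out <- out + image$voxels[, , , fr] * image$schedule$duration[fr]
  }
  out
}

# connected components (26-connectivity) of a set of voxel coordinates
connected_clusters <- function(coords) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  idx <- stats::setNames(seq_len(n), key(coords))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[i, ], "+")
    hit <- idx[key(nb)]
    ok <- !is.na(hit)
    if (any(ok)) edges[[length(edges) + 1]] <- cbind(which(ok), unname(hit[ok]))
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, c(edges, list(cbind(seq_len(n), seq_len(n))))),
                                   directed = FALSE)
  igraph::components(g)$membership[seq_len(n)]
}

#' Automatically delineate carotid and background ROIs
#'
#' Emulates the manual drawing of carotid ROIs on the summed early frames:
#' sums the frames of the first `early_window_min` minutes, restricts to the
#' lower-third axial slab (where the carotids run through the neck), selects
#' connected clusters among the top-`top_fraction` voxels as the carotid
#' mask, and builds the background ("surround") mask as a shell 2-4 voxels
#' away from the carotids — near, but not adjacent, mirroring the
#' comma-shaped background region of the original method.
#'
#' @param image a [dynamic_image()].
#' @param early_window_min summation window in minutes (default `c(0, 2)`).
#' @param top_fraction fraction of slab voxels considered carotid-candidate
#'   (default 0.004).
#' @param max_clusters keep at most this many largest clusters (default 4,
#'   two carotid pairs).
#' @param min_cluster_voxels discard clusters smaller than this (default 8).
#' @param slab_fraction fraction of the axial extent, from the bottom, to
#'   search (default 1/3: the lower axial slab containing the carotids;
#'   planes near the skull base pick up scalp spill, as clinical ROIs do).
#' @return a `carotid_roi_set`: logical arrays `carotid_mask`,
#'   `background_mask`, integer `plane_ids`, and per-cluster voxel
#'   coordinates `clusters`.
#' @export
auto_carotid_rois <- function(image, early_window_min = c(0, 2),
                              top_fraction = 0.004, max_clusters = 4,
                              min_cluster_voxels = 8, slab_fraction = 1 / 3) {
  summed <- early_summed(image, early_window_min)
  d <- dim(summed)
  slab_z <- seq_len(floor(d[3] * slab_fraction))
  slab <- summed[, , slab_z]
  assert_that(any(slab > 0), "image carries no early signal", "petidif_detection_error")
  thr <- stats::quantile(slab, 1 - top_fraction)
  assert_that(thr > 0 && any(slab > thr), "no suprathreshold carotid cluster",
              "petidif_detection_error")
  cand <- which(slab > thr, arr.ind = TRUE)
  memb <- connected_clusters(cand)
  sizes <- sort(table(memb), decreasing = TRUE)
  keep_ids <- as.integer(names(sizes)[sizes >= min_cluster_voxels])
  keep_ids <- head(keep_ids, max_clusters)
  assert_that(length(keep_ids) > 0, "no suprathreshold carotid cluster",
              "petidif_detection_error")
  mask <- array(FALSE, dim = d)
  clusters <- list()
  for (id in keep_ids) {
    cc <- cand[memb == id, , drop = FALSE]
    mask[cc] <- TRUE
    clusters[[length(clusters) + 1]] <- cc
  }
  background <- dilate_mask(mask, 4) & !dilate_mask(mask, 1)
  structure(list(carotid_mask = mask, background_mask = background,
                 plane_ids = sort(unique(which(mask, arr.ind = TRUE)[, 3])),
                 clusters = clusters),
            class = "carotid_roi_set")
}

# mean TAC over a logical 3D mask
mask_tac <- function(image, mask) {
  nf <- nrow(image$schedule)
  idx <- which(mask)
  assert_that(length(idx) > 0, "empty mask")
  nvox <- prod(dim(image$voxels)[1:3])
  vapply(seq_len(nf), function(fr) {
    mean(image$voxels[idx + (fr - 1) * nvox])
  }, numeric(1))
}

#' Hottest-pixels carotid curve
#'
#' For each axial plane intersecting the mask, picks the `n_per_plane`
#' voxels that are hottest in the early-summed image (a fixed cluster reused
#' for every frame) and averages the time-activity curves of all selected
#' voxels.
#'
#' @param image a [dynamic_image()].
#' @param mask logical 3D carotid mask.
#' @param n_per_plane voxels kept per plane (default 4).
#' @param early_window_min summation window defining "hottest".
#' @param planes restrict to these axial plane indices (default: all planes
#'   in the mask).
#' @return numeric curve on the frame grid (kBq/mL).
#' @export
hottest_pixels_curve <- function(image, mask, n_per_plane = 4,
                                 early_window_min = c(0, 2), planes = NULL) {
  summed <- early_summed(image, early_window_min)
  vox <- which(mask, arr.ind = TRUE)
  assert_that(nrow(vox) > 0, "empty mask")
  if (!is.null(planes)) vox <- vox[vox[, 3] %in% planes, , drop = FALSE]
  assert_that(nrow(vox) > 0, "mask has no voxels in the requested planes")
  sel <- list()
  for (z in sort(unique(vox[, 3]))) {
    pz <- vox[vox[, 3] == z, , drop = FALSE]
    if (nrow(pz) < n_per_plane) {
      warn(sprintf("plane %d has only %d mask voxels (< %d); using all",
                   z, nrow(pz), n_per_plane))
      sel[[length(sel) + 1]] <- pz
    } else {
      vals <- summed[pz]
      sel[[length(sel) + 1]] <- pz[order(vals, decreasing = TRUE)[seq_len(n_per_plane)], ,
                                   drop = FALSE]
    }
  }
  sel <- do.call(rbind, sel)
  selmask <- array(FALSE, dim = dim(summed))
  selmask[sel] <- TRUE
  mask_tac(image, selmask)
}

#' Square carotid ROIs (Backes-style)
#'
#' Builds square ROIs centered on each detected carotid cluster over
#' `n_slices` adjacent axial planes around the cluster's hottest plane.
#'
#' @param image a [dynamic_image()].
#' @param rois a `carotid_roi_set` from [auto_carotid_rois()].
#' @param half_side half the square side, in voxels (default 2 -> 5x5).
#' @param n_slices adjacent slices per carotid (default 4).
#' @return logical 3D mask.
#' @export
square_carotid_rois <- function(image, rois, half_side = 2, n_slices = 4) {
  summed <- early_summed(image)
  d <- dim(summed)
  mask <- array(FALSE, dim = d)
  for (cc in rois$clusters) {
    vals <- summed[cc]
    hot <- cc[which.max(vals), ]
    ctr <- round(colMeans(cc[, 1:2, drop = FALSE]))
    zs <- hot[3] + seq(0, n_slices - 1) - floor((n_slices - 1) / 2)
    zs <- zs[zs >= 1 & zs <= d[3]]
    xs <- max(1, ctr[1] - half_side):min(d[1], ctr[1] + half_side)
    ys <- max(1, ctr[2] - half_side):min(d[2], ctr[2] + half_side)
    mask[xs, ys, zs] <- TRUE
  }
  mask
}
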