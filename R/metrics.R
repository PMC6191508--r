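#' Overlap metrics between a manual label A and an automatic result B
#'
#' Voxel-count ratios: Dice = 2|A∩B| / (|A|+|B|), Jaccard = |A∩B| / |A∪B|,
#' Precision = |A∩B| / |B|, Recall = |A∩B| / |A|.  A is the reference
#' (manual) mask, B the automatic result.
#'
#' @param A,B [label_volume()] objects on a common grid, both non-empty.
#' @return named numeric vector `(dice, jaccard, precision, recall)`.
#' @export
overlap_metrics <- function(A, B) {
  check_common_grid(list(A, B), ids = c("A", "B"))
  va <- sum(A$data); vb <- sum(B$data)
  if (va == 0) af_error("mask A is empty", "atlasfuse_empty_mask")
  if (vb == 0) af_error("mask B is empty", "atlasfuse_empty_mask")
  inter <- sum(A$data & B$data)
  c(dice = 2 * inter / (va + vb),
    jaccard = inter / (va + vb - inter),
    precision = inter / vb,
    recall = inter / va)
}

#' Boundary voxels of a mask, in mm
#'
#' The surface is the set of foreground voxels having at least one
#' background 6-neighbor, with the image border counting as background.
#' Coordinates are 0-based voxel indices scaled by the voxel spacing.
#'
#' @param M a non-empty [label_volume()].
#' @return numeric matrix of boundary coordinates (mm), one row per
#'   boundary voxel, with the 0-based voxel indices in attribute
#'   `"index"`.
#' @export
extract_surface <- function(M) {
  stopifnot(inherits(M, "label_volume"))
  m <- M$data == 1L
  if (!any(m)) af_error("empty mask has no surface", "atlasfuse_empty_mask")
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  all_nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- core & !all_nb
  idx <- which(surf, arr.ind = TRUE) - 1L
  out <- sweep(idx, 2, M$spacing, `*`)
  attr(out, "index") <- idx
  out
}

#' Surface-distance metrics between a manual label A and a result B
#'
#' All distances are Euclidean in mm between boundary voxels.  With
#' `d(e, ∂B) = min_f d(e, f)`:
#' * MD: mean over e in ∂A of d(e, ∂B) — directed, manual to automatic.
#' * HD: max of the two directed maxima.
#' * HD95: like HD after discarding, within each directed distance set,
#'   its `ceil(0.05 n)` largest values (at least one value is kept).
#' * ASSD: average of the two directed means.
#' * RMSD: sqrt((sum of squared directed distances both ways) /
#'   (|∂A| + |∂B|)).
#'
#' @param A,B non-empty [label_volume()] objects on a common grid.
#' @return named numeric vector `(md, hd, hd95, assd, rmsd)` in mm.
#' @export
distance_metrics <- function(A, B) {
  check_common_grid(list(A, B), ids = c("A", "B"))
  sa <- extract_surface(A)
  sb <- extract_surface(B)
  da <- cpp_directed_min_dists(sa, sb)
  db <- cpp_directed_min_dists(sb, sa)
  trim_max <- function(x) {
    drop <- min(ceiling(0.05 * length(x)), length(x) - 1L)
    if (drop > 0L) max(sort(x, decreasing = TRUE)[-seq_len(drop)]) else max(x)
  }
  c(md = mean(da),
    hd = max(max(da), max(db)),
    hd95 = max(trim_max(da), trim_max(db)),
    assd = (mean(da) + mean(db)) / 2,
    rmsd = sqrt((sum(da^2) + sum(db^2)) / (length(da) + length(db))))
}

#' All nine evaluation metrics
#'
#' @inheritParams distance_metrics
#' @return one-row data.frame with columns `dice`, `jaccard`,
#'   `precision`, `recall` (unitless) and `md`, `hd`, `hd95`, `assd`,
#'   `rmsd` (mm).
#' @export
evaluate_segmentation <- function(A, B) {
  as.data.frame(t(c(overlap_metrics(A, B), distance_metrics(A, B))))
}
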