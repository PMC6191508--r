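#' Patch and training-neighborhood parameters
#'
#' `r_s` is the radius of the image patch used for feature extraction: a
#' voxel is described by its (2*r_s+1)^3 neighborhood.  `r` is the radius
#' of the training neighborhood: for each voxel to be segmented, the
#' corresponding (2*r+1)^3 voxels of every atlas supply training samples.
#'
#' @param r_s patch radius in voxels (default 3, i.e. 7x7x7 patches).
#' @param r training-neighborhood radius in voxels (default 1).
#' @export
patch_params <- function(r_s = 3L, r = 1L) {
  r_s <- as.integer(r_s); r <- as.integer(r)
  stopifnot(r_s >= 1L, r >= 0L)
  structure(list(r_s = r_s, r = r), class = "patch_params")
}

#' Feature vector layout
#'
#' The feature vector concatenates, block by block, the z-scored patch
#' intensities and the filter-bank responses evaluated at every patch
#' voxel.  The layout (block names, lengths, offsets) is fixed by `r_s`
#' alone, so every voxel under the same parameters yields a vector of
#' identical length: 15 * (2*r_s+1)^3.
#'
#' @param r_s patch radius in voxels.
#' @return data.frame with columns `block`, `length`, `offset`.
#' @export
feature_layout <- function(r_s = 3L) {
  s3 <- (2L * as.integer(r_s) + 1L)^3
  blocks <- c("intensity", "d1_x", "d1_y", "d1_z", "d2_x", "d2_y", "d2_z",
              "hyperplane_x", "hyperplane_y", "hyperplane_z",
              "sobel_x", "sobel_y", "sobel_z", "laplacian", "range")
  data.frame(block = blocks, length = rep(s3, length(blocks)),
             offset = s3 * (seq_along(blocks) - 1L))
}

#' Extract a cubic patch around a voxel
#'
#' Out-of-volume positions are filled by edge replication (clamped
#' indices), so patches at the border keep the full (2*r_s+1)^3 size.
#'
#' @param vol a [volume()].
#' @param center 0-based voxel index, length 3.
#' @param r_s patch radius in voxels.
#' @return a (2*r_s+1)^3 numeric array.
#' @export
extract_patch <- function(vol, center, r_s) {
  stopifnot(inherits(vol, "volume"), length(center) == 3L)
  d <- dim(vol$data)
  center <- as.integer(center)
  if (any(center < 0L) || any(center >= d))
    af_error("patch center outside the volume", "atlasfuse_bad_voxel")
  idx <- lapply(1:3, function(a)
    pmin(pmax(center[a] + (-r_s:r_s), 0L), d[a] - 1L) + 1L)
  vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' z-score a patch
#'
#' Subtracts the patch mean and divides by the patch standard deviation
#' (sample sd).  Constant patches (sd below 1e-12) map to all zeros: they
#' carry no texture information and the guard avoids division by zero.
#' The result is invariant to positive affine intensity transforms of the
#' input.
#'
#' @param patch numeric array.
#' @return array of the same shape with mean 0 and sd 1 (or all zeros).
#' @export
normalize_patch <- function(patch) {
  s <- stats::sd(patch)
  if (!is.finite(s) || s < 1e-12) return(array(0, dim(patch)))
  (patch - mean(patch)) / s
}

# clamped shift of a 3D array: value at x is a[clamp(x + off)]
shift_rep <- function(a, off) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax)
    pmin(pmax(seq_len(d[ax]) + off[ax], 1L), d[ax]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Texture filter bank (reference implementation)
#'
#' Applies the filter families to a (z-scored) patch with edge replication
#' at the patch border and returns one response array per family and
#' orientation.  The concrete kernels: 1st-order central differences and
#' (1,-2,1) second differences along each axis; hyperplane filters (mean
#' over the 3x3 plane normal to each axis, minus the center); 3D Sobel
#' ([1,2,1] smoothing in the two transverse axes times [-1,0,1]); the
#' 27-point Laplacian (neighbor sum minus 27x center); and the range
#' filter (max minus min over 3x3x3).  This plain-R version defines the
#' semantics; the compiled path used by [extract_features()] matches it
#' exactly and is covered by an equivalence test.
#'
#' @param patch numeric 3D array with side >= 3 (typically the output of
#'   [normalize_patch()]).
#' @return named list of response arrays, in [feature_layout()] order
#'   (without the intensity block).
#' @export
filter_bank <- function(patch) {
  stopifnot(length(dim(patch)) == 3L, all(dim(patch) >= 3L))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifted <- lapply(seq_len(nrow(offs)), function(i)
    shift_rep(patch, as.integer(offs[i, ])))
  at <- function(dx, dy, dz)
    shifted[[which(offs$dx == dx & offs$dy == dy & offs$dz == dz)]]
  w <- c(1, 2, 1)
  sobel <- function(axis) {
    r <- array(0, dim(patch))
    for (i in seq_len(nrow(offs))) {
      o <- as.numeric(offs[i, ])
      tr <- setdiff(1:3, axis)
      r <- r + o[axis] * w[o[tr[1]] + 2] * w[o[tr[2]] + 2] * shifted[[i]]
    }
    r
  }
  plane_mean <- function(axis) {
    keep <- offs[[axis]] == 0
    Reduce(`+`, shifted[keep]) / 9 - patch
  }
  lap <- Reduce(`+`, shifted) - 27 * patch
  rng <- Reduce(pmax, shifted) - Reduce(pmin, shifted)
  list(
    d1_x = at(1, 0, 0) - at(-1, 0, 0),
    d1_y = at(0, 1, 0) - at(0, -1, 0),
    d1_z = at(0, 0, 1) - at(0, 0, -1),
    d2_x = at(1, 0, 0) - 2 * patch + at(-1, 0, 0),
    d2_y = at(0, 1, 0) - 2 * patch + at(0, -1, 0),
    d2_z = at(0, 0, 1) - 2 * patch + at(0, 0, -1),
    hyperplane_x = plane_mean(1),
    hyperplane_y = plane_mean(2),
    hyperplane_z = plane_mean(3),
    sobel_x = sobel(1), sobel_y = sobel(2), sobel_z = sobel(3),
    laplacian = lap, range = rng
  )
}

#' Feature vectors for a set of voxels
#'
#' The per-voxel pipeline is: extract the (2*r_s+1)^3 patch (edge
#' replication at the volume border), z-score it, run the filter bank, and
#' concatenate `[intensity | responses]` in [feature_layout()] order.  The
#' identical pipeline is applied to target and atlas volumes, and the
#' output is invariant to positive affine rescalings of the input
#' intensities.
#'
#' @param vol a [volume()].
#' @param voxels integer matrix of 0-based voxel indices, one row per
#'   voxel (a single index may be given as a length-3 vector).
#' @param params a [patch_params()].
#' @return numeric matrix, one row per voxel, `15 * (2*r_s+1)^3` columns.
#' @export
extract_features <- function(vol, voxels, params = patch_params()) {
  stopifnot(inherits(vol, "volume"))
  if (is.null(dim(voxels))) voxels <- matrix(voxels, nrow = 1L)
  f <- cpp_patch_features(as.numeric(vol$data), dim(vol$data),
                          matrix(as.integer(voxels), ncol = 3L), params$r_s)
  t(f)
}

#' @rdname extract_features
#' @param voxel single 0-based voxel index (length 3).
#' @return `extract_feature_vector()` returns one numeric vector.
#' @export
extract_feature_vector <- function(vol, voxel, params = patch_params()) {
  drop(extract_features(vol, matrix(voxel, nrow = 1L), params))
}

# internal: features-in-columns (p x n), avoiding the transpose copy on
# the hot path
extract_features_cols <- function(vol, voxels, params) {
  cpp_patch_features(as.numeric(vol$data), dim(vol$data),
                     matrix(as.integer(voxels), ncol = 3L), params$r_s)
}
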