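#' Volume and label containers
#'
#' A `volume` is a 3D scalar grid with per-axis voxel spacing in mm; a
#' `label_volume` is a volume whose data are strictly 0/1 integers.  An
#' `atlas_pair` bundles an intensity volume with its label volume.  Voxel
#' indices are 0-based everywhere in this package; physical coordinates are
#' index times spacing (mm).  Orientation information read from NIfTI
#' headers is carried along untouched and written back as-is.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param header optional NIfTI header (from [RNifti::niftiHeader()]) to
#'   carry geometry through a read/write round trip.
#' @return `volume()` returns an object of class `volume`; `label_volume()`
#'   an object of class `c("label_volume", "volume")`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), header = NULL) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L)
    af_error("volume data must be a 3D array", "atlasfuse_non_3d_image")
  if (any(dim(data) <= 0L))
    af_error("volume extents must be positive", "atlasfuse_bad_geometry")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    af_error("spacing must be three positive values (mm)",
             "atlasfuse_bad_geometry")
  if (anyNA(data))
    af_error("volume contains NaN/NA values", "atlasfuse_nan_data")
  structure(list(data = data, spacing = spacing, header = header),
            class = "volume")
}

#' @rdname volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), header = NULL) {
  v <- volume(data, spacing, header)
  d <- v$data
  if (!all(d == 0L | d == 1L))
    af_error("label data must be exactly 0/1", "atlasfuse_non_binary_label")
  storage.mode(d) <- "integer"
  v$data <- d
  class(v) <- c("label_volume", "volume")
  v
}

#' @rdname volume
#' @param intensity,label a `volume` and its `label_volume` on the same grid.
#' @param id free-text identifier.
#' @export
atlas_pair <- function(intensity, label, id = "") {
  stopifnot(inherits(intensity, "volume"), inherits(label, "label_volume"))
  check_common_grid(list(intensity, label), ids = c(id, paste0(id, ":label")))
  structure(list(intensity = intensity, label = label, id = id),
            class = "atlas_pair")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Spacing is taken from the header's pixdim; the full header is retained
#' so that writing the volume back preserves orientation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    af_error(sprintf("file not found: %s", path), "atlasfuse_missing_file")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    af_error(sprintf("unreadable NIfTI header: %s (%s)",
                                     path, conditionMessage(e)),
                             "atlasfuse_bad_header"))
  if (length(dim(img)) != 3L)
    af_error(sprintf("non-3D image: %s has %d dimensions",
                     path, length(dim(img))), "atlasfuse_non_3d_image")
  dat <- array(as.numeric(img), dim = dim(img))
  if (anyNA(dat))
    af_error(sprintf("volume contains NaN values: %s", path),
             "atlasfuse_nan_data")
  volume(dat, spacing = RNifti::pixdim(img),
         header = RNifti::niftiHeader(img))
}

#' Read a binary label volume from a NIfTI-1 file
#'
#' Stored values must sit within `tol` of 0 or 1; anything else raises a
#' `non-binary label` error naming the offending values.
#'
#' @inheritParams read_volume
#' @param tol rounding tolerance around 0 and 1 (default `1e-3`).
#' @return a [label_volume()].
#' @export
read_label <- function(path, tol = 1e-3) {
  v <- read_volume(path)
  d <- v$data
  bad <- abs(d) > tol & abs(d - 1) > tol
  if (any(bad)) {
    offenders <- unique(d[bad])
    af_error(sprintf("non-binary label: %s contains value(s) %s", path,
                     paste(head(signif(offenders, 6), 5), collapse = ", ")),
             "atlasfuse_non_binary_label")
  }
  label_volume(array(as.integer(round(d)), dim(d)), spacing = v$spacing,
               header = v$header)
}

#' Write volumes to NIfTI-1
#'
#' Intensities and probability maps are written as float32, labels as
#' unsigned 8-bit.  When the volume was read from disk its header (and so
#' its orientation) is reused; otherwise an identity orientation with the
#' volume's spacing is written.
#'
#' @param vol a [volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  dtype <- if (inherits(vol, "label_volume")) "uint8" else "float"
  img <- if (!is.null(vol$header))
    RNifti::asNifti(vol$data, reference = vol$header)
  else {
    i <- RNifti::asNifti(vol$data)
    RNifti::pixdim(i) <- vol$spacing
    i
  }
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Check that volumes share one voxel grid
#'
#' Shapes must match exactly; spacings within `tol` mm.  The error message
#' names the first offending pair.
#'
#' @param volumes non-empty list of [volume()]/[label_volume()] objects.
#' @param ids optional identifiers used in error messages.
#' @param tol spacing tolerance in mm.
#' @return `TRUE`, invisibly.
#' @export
check_common_grid <- function(volumes, ids = NULL, tol = 1e-4) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  if (is.null(ids)) ids <- paste0("volume", seq_along(volumes))
  ref <- volumes[[1]]
  for (i in seq_along(volumes)[-1]) {
    v <- volumes[[i]]
    if (!identical(dim(ref$data), dim(v$data)))
      af_error(sprintf("grid mismatch between %s (%s) and %s (%s)",
                       ids[1], paste(dim(ref$data), collapse = "x"),
                       ids[i], paste(dim(v$data), collapse = "x")),
               "atlasfuse_grid_mismatch")
    if (any(abs(ref$spacing - v$spacing) > tol))
      af_error(sprintf("spacing mismatch between %s and %s", ids[1], ids[i]),
               "atlasfuse_grid_mismatch")
  }
  invisible(TRUE)
}
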