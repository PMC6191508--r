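#' Phantom specification
#'
#' Describes a smooth blob-shaped foreground structure (an ellipsoid with
#' a low-frequency radial perturbation) in a noisy two-class intensity
#' volume: foreground and background means on a 0-255-like grayscale, an
#' optional smooth multiplicative bias field, and i.i.d. Gaussian noise.
#' The defaults (background 80, foreground 160, noise sd 10) keep the
#' method's default intensity-similarity scale `sigma = 10` directly
#' meaningful on generated data.
#'
#' @param shape grid extents in voxels (default 32^3).
#' @param center blob center, 0-based voxel coordinates (default the grid
#'   center).
#' @param radii ellipsoid semi-axes in voxels (default `c(8, 6, 5)`).
#' @param fg_mean,bg_mean class intensity means (defaults 160 / 80).
#' @param noise_sd additive Gaussian noise sd (default 10).
#' @param bias_amp relative amplitude of the smooth multiplicative bias
#'   field (default 0.05; 0 disables it).
#' @param bias_smooth Gaussian smoothing sd of the bias field, voxels.
#' @param perturb_amp relative amplitude of the smooth radial boundary
#'   perturbation (default 0.12).
#' @param perturb_smooth smoothing sd of the perturbation field, voxels.
#' @param spacing voxel size in mm.
#' @param seed RNG seed.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), center = NULL,
                         radii = c(8, 6, 5), fg_mean = 160, bg_mean = 80,
                         noise_sd = 10, bias_amp = 0.05, bias_smooth = 8,
                         perturb_amp = 0.12, perturb_smooth = 6,
                         spacing = c(1, 1, 1), seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape - 1) / 2
  stopifnot(length(shape) == 3L, all(shape > 0L), noise_sd >= 0,
            fg_mean != bg_mean, all(radii > 0))
  structure(list(shape = shape, center = center, radii = radii,
                 fg_mean = fg_mean, bg_mean = bg_mean, noise_sd = noise_sd,
                 bias_amp = bias_amp, bias_smooth = bias_smooth,
                 perturb_amp = perturb_amp, perturb_smooth = perturb_smooth,
                 spacing = spacing, seed = seed),
            class = "phantom_spec")
}

#' Atlas library specification
#'
#' Each atlas is the ground-truth phantom warped by an independent smooth
#' random displacement field (standing in for residual registration
#' error) with a per-atlas affine intensity perturbation and fresh noise
#' (standing in for inter-subject intensity discrepancy).
#'
#' @param n_atlases library size (default 10).
#' @param deform_amp root-mean-square displacement per component in
#'   voxels (default 2; 0 yields atlases identical to the truth up to
#'   intensity changes).
#' @param deform_smooth Gaussian smoothing sd of the displacement fields,
#'   voxels (default 4).
#' @param gain_range,offset_range per-atlas affine intensity perturbation
#'   `gain * I + offset`, drawn uniformly (defaults `c(0.9, 1.1)` and
#'   `c(-10, 10)`).
#' @param noise_sd per-atlas additive noise sd (default 5).
#' @param seed RNG seed.
#' @export
atlas_library_spec <- function(n_atlases = 10L, deform_amp = 2,
                               deform_smooth = 4, gain_range = c(0.9, 1.1),
                               offset_range = c(-10, 10), noise_sd = 5,
                               seed = 1L) {
  stopifnot(n_atlases >= 1L, deform_amp >= 0, noise_sd >= 0)
  structure(list(n_atlases = as.integer(n_atlases), deform_amp = deform_amp,
                 deform_smooth = deform_smooth, gain_range = gain_range,
                 offset_range = offset_range, noise_sd = noise_sd,
                 seed = seed),
            class = "atlas_library_spec")
}

# separable Gaussian smoothing with replicate padding
gaussian_smooth_3d <- function(a, sd) {
  if (sd <= 0) return(a)
  r <- ceiling(3 * sd)
  w <- exp(-((-r:r)^2) / (2 * sd^2))
  w <- w / sum(w)
  for (ax in 1:3) {
    out <- array(0, dim(a))
    n <- dim(a)[ax]
    for (t in -r:r) {
      off <- integer(3); off[ax] <- t
      out <- out + w[t + r + 1] * shift_rep(a, off)
    }
    a <- out
  }
  a
}

coord_grids <- function(shape) {
  list(x = array(rep(0:(shape[1] - 1), times = shape[2] * shape[3]), shape),
       y = array(rep(rep(0:(shape[2] - 1), each = shape[1]), shape[3]), shape),
       z = array(rep(0:(shape[3] - 1), each = shape[1] * shape[2]), shape))
}

# smooth zero-mean random field scaled to unit max-abs
smooth_unit_field <- function(shape, sd_smooth) {
  f <- gaussian_smooth_3d(array(rnorm(prod(shape)), shape), sd_smooth)
  f <- f - mean(f)
  m <- max(abs(f))
  if (m > 0) f / m else f
}

#' Generate a phantom target and its ground-truth label
#'
#' The label is the perturbed ellipsoid `sum(((c - center)/radii)^2) <=
#' (1 + amp * field)^2` with a smooth unit-amplitude random field; the
#' intensity is the two-class mean image, optionally modulated by a
#' smooth multiplicative bias field, plus Gaussian noise.  Fully
#' deterministic given `spec$seed`.  The blob must lie strictly inside
#' the grid.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [volume()]) and `label` (a
#'   [label_volume()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    g <- coord_grids(spec$shape)
    u <- ((g$x - spec$center[1]) / spec$radii[1])^2 +
      ((g$y - spec$center[2]) / spec$radii[2])^2 +
      ((g$z - spec$center[3]) / spec$radii[3])^2
    pert <- if (spec$perturb_amp > 0)
      spec$perturb_amp * smooth_unit_field(spec$shape, spec$perturb_smooth)
    else array(0, spec$shape)
    mask <- u <= (1 + pert)^2
    if (!any(mask))
      af_error("phantom blob is empty", "atlasfuse_bad_phantom")
    idx <- which(mask, arr.ind = TRUE)
    if (any(idx == 1L) || any(sweep(idx, 2, spec$shape, `==`)))
      af_error("phantom blob exits the grid", "atlasfuse_bad_phantom")
    inten <- array(spec$bg_mean, spec$shape)
    inten[mask] <- spec$fg_mean
    if (spec$bias_amp > 0)
      inten <- inten *
        (1 + spec$bias_amp * smooth_unit_field(spec$shape, spec$bias_smooth))
    if (spec$noise_sd > 0)
      inten <- inten + array(rnorm(prod(spec$shape), sd = spec$noise_sd),
                             spec$shape)
    list(volume = volume(inten, spacing = spec$spacing),
         label = label_volume(array(as.integer(mask), spec$shape),
                              spacing = spec$spacing))
  })
}

# backward warp: out(x) = src(x + disp(x)); trilinear for intensities,
# nearest-neighbor for labels, clamped at the border
warp_volume <- function(src, dx, dy, dz, nearest = FALSE) {
  d <- dim(src)
  g <- coord_grids(d)
  sx <- pmin(pmax(g$x + dx, 0), d[1] - 1)
  sy <- pmin(pmax(g$y + dy, 0), d[2] - 1)
  sz <- pmin(pmax(g$z + dz, 0), d[3] - 1)
  if (nearest) {
    idx <- cbind(as.integer(round(sx)), as.integer(round(sy)),
                 as.integer(round(sz))) + 1L
    return(array(src[idx], d))
  }
  x0 <- pmin(floor(sx), d[1] - 2); y0 <- pmin(floor(sy), d[2] - 2)
  z0 <- pmin(floor(sz), d[3] - 2)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  at <- function(ox, oy, oz)
    src[cbind(as.integer(x0 + ox), as.integer(y0 + oy),
              as.integer(z0 + oz)) + 1L]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(0, 0, 0) +
    fx * (1 - fy) * (1 - fz) * at(1, 0, 0) +
    (1 - fx) * fy * (1 - fz) * at(0, 1, 0) +
    fx * fy * (1 - fz) * at(1, 1, 0) +
    (1 - fx) * (1 - fy) * fz * at(0, 0, 1) +
    fx * (1 - fy) * fz * at(1, 0, 1) +
    (1 - fx) * fy * fz * at(0, 1, 1) +
    fx * fy * fz * at(1, 1, 1)
  array(v, d)
}

# smooth random displacement component with root-mean-square amplitude
# `amp` voxels; peak scaling would leave typical displacements sub-voxel
# on small grids and degenerate to near-identical atlases
displacement_field <- function(shape, amp, sd_smooth) {
  if (amp <= 0) return(array(0, shape))
  f <- gaussian_smooth_3d(array(rnorm(prod(shape)), shape), sd_smooth)
  f <- f - mean(f)
  s <- stats::sd(f)
  if (s > 0) f * (amp / s) else f
}

#' Generate an atlas library from a ground-truth phantom
#'
#' Each atlas pair is the truth warped by an independent smooth random
#' displacement field (trilinear interpolation for the intensity,
#' nearest-neighbor for the label), followed by a per-atlas affine
#' intensity perturbation and fresh additive noise.  Deterministic given
#' `spec$seed`.
#'
#' @param phantom output of [make_phantom()] (or a list with `volume` and
#'   `label`).
#' @param spec an [atlas_library_spec()].
#' @return list of [atlas_pair()] with per-atlas truth Dice scores in
#'   attribute `"dice_to_truth"`.
#' @export
make_atlas_library <- function(phantom, spec) {
  stopifnot(inherits(spec, "atlas_library_spec"))
  truth_v <- phantom$volume; truth_l <- phantom$label
  shape <- dim(truth_v$data)
  out <- vector("list", spec$n_atlases)
  dice <- numeric(spec$n_atlases)
  for (i in seq_len(spec$n_atlases)) {
    out[[i]] <- with_seed(derive_seed(spec$seed, i), {
      dx <- displacement_field(shape, spec$deform_amp, spec$deform_smooth)
      dy <- displacement_field(shape, spec$deform_amp, spec$deform_smooth)
      dz <- displacement_field(shape, spec$deform_amp, spec$deform_smooth)
      inten <- warp_volume(truth_v$data, dx, dy, dz)
      lab <- warp_volume(truth_l$data, dx, dy, dz, nearest = TRUE)
      gain <- runif(1, spec$gain_range[1], spec$gain_range[2])
      offset <- runif(1, spec$offset_range[1], spec$offset_range[2])
      inten <- gain * inten + offset
      if (spec$noise_sd > 0)
        inten <- inten + array(rnorm(prod(shape), sd = spec$noise_sd), shape)
      atlas_pair(volume(inten, spacing = truth_v$spacing),
                 label_volume(lab, spacing = truth_v$spacing),
                 id = sprintf("atlas%02d", i))
    })
    dice[i] <- if (any(out[[i]]$label$data == 1L))
      unname(overlap_metrics(truth_l, out[[i]]$label)["dice"]) else 0
  }
  attr(out, "dice_to_truth") <- dice
  out
}

#' Generate a full synthetic study
#'
#' `n_subjects` independent (target, truth, atlas library) triples,
#' reproducible from the master seed.  Per-subject blob geometry is
#' jittered (radii by up to 10 percent, center by up to 1 voxel) so truth
#' labels differ across subjects.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param phantom a [phantom_spec()] template.
#' @param library an [atlas_library_spec()] template.
#' @param master_seed master RNG seed.
#' @return list of subjects, each a list with `target`, `truth`,
#'   `atlases`.
#' @export
make_dataset <- function(n_subjects, phantom = phantom_spec(),
                         library = atlas_library_spec(), master_seed = 1L) {
  stopifnot(n_subjects >= 1L)
  lapply(seq_len(n_subjects), function(s) {
    sseed <- derive_seed(master_seed, 1000L + s)
    jit <- with_seed(sseed, list(radii = runif(3, 0.9, 1.1),
                                 center = runif(3, -1, 1)))
    ps <- phantom
    ps$radii <- phantom$radii * jit$radii
    ps$center <- phantom$center + jit$center
    ps$seed <- derive_seed(sseed, 1L)
    ph <- make_phantom(ps)
    ls <- library
    ls$seed <- derive_seed(sseed, 2L)
    list(target = ph$volume, truth = ph$label,
         atlases = make_atlas_library(ph, ls))
  })
}
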