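#' Bounding boxes
#'
#' A bounding box is stored as 0-based voxel indices: `lower` inclusive,
#' `upper` exclusive, so the box spans `lower[a] <= i < upper[a]` on each
#' axis.
#'
#' @param lower,upper integer length-3 corners (0-based; `lower < upper`).
#' @param dim optional grid extents used to validate containment.
#' @export
bounding_box <- function(lower, upper, dim = NULL) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  stopifnot(length(lower) == 3L, length(upper) == 3L)
  if (any(lower < 0L) || any(upper <= lower))
    af_error("invalid bounding box corners", "atlasfuse_bad_box")
  if (!is.null(dim) && any(upper > dim))
    af_error("bounding box exceeds the image extent", "atlasfuse_bad_box")
  structure(list(lower = lower, upper = upper), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> [%s) x [%s) x [%s)\n",
              paste(c(x$lower[1], x$upper[1]), collapse = ","),
              paste(c(x$lower[2], x$upper[2]), collapse = ","),
              paste(c(x$lower[3], x$upper[3]), collapse = ",")))
  invisible(x)
}

box_ranges <- function(box) {
  lapply(1:3, function(a) (box$lower[a] + 1L):box$upper[a])
}

box_volume <- function(box) prod(box$upper - box$lower)

box_mask <- function(box, dim) {
  m <- array(FALSE, dim)
  r <- box_ranges(box)
  m[r[[1]], r[[2]], r[[3]]] <- TRUE
  m
}

#' Working bounding box from registered atlas labels
#'
#' The tight box of the union of all atlas foregrounds, dilated by `margin`
#' voxels on every axis and clipped to the image extent.  With atlases
#' registered to the target this covers any plausible target foreground.
#'
#' @param atlas_labels list of [label_volume()] on a common grid.
#' @param margin dilation in voxels (default 10).
#' @return a [bounding_box()].
#' @export
compute_bounding_box <- function(atlas_labels, margin = 10L) {
  stopifnot(length(atlas_labels) >= 1L, margin >= 0L)
  u <- atlas_labels[[1]]$data == 1L
  for (l in atlas_labels[-1]) u <- u | l$data == 1L
  if (!any(u))
    af_error("all atlas labels are empty", "atlasfuse_empty_labels")
  idx <- which(u, arr.ind = TRUE)  # 1-based
  lo <- pmax(apply(idx, 2, min) - 1L - margin, 0L)
  hi <- pmin(apply(idx, 2, max) + margin, dim(u))
  bounding_box(lo, hi, dim = dim(u))
}

#' Normalized mutual information between two volumes inside a box
#'
#' NMI = (H(A) + H(B)) / H(A, B), computed in nats from a joint histogram
#' of `bins` equal-width bins per image spanning each image's min-max range
#' inside the box.  Equals 2 for identical (non-constant) inputs and tends
#' to 1 in the independence limit.  A constant image carries no
#' information; its NMI is defined as 1 and flagged with a message.
#'
#' @param a,b [volume()] objects on a common grid.
#' @param box a [bounding_box()]; `NULL` means the whole grid.
#' @param bins histogram bins per image (default 32).
#' @return a single numeric score.
#' @export
normalized_mutual_information <- function(a, b, box = NULL, bins = 32L) {
  stopifnot(bins >= 2L)
  check_common_grid(list(a, b), ids = c("a", "b"))
  if (is.null(box))
    box <- bounding_box(c(0L, 0L, 0L), dim(a$data))
  r <- box_ranges(box)
  va <- as.numeric(a$data[r[[1]], r[[2]], r[[3]]])
  vb <- as.numeric(b$data[r[[1]], r[[2]], r[[3]]])
  if (max(va) == min(va) || max(vb) == min(vb)) {
    message("constant image inside the box; NMI defined as 1")
    return(1)
  }
  ia <- bin_index(va, bins)
  ib <- bin_index(vb, bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  pj <- joint / sum(joint)
  pa <- tabulate(ia, nbins = bins) / length(ia)
  pb <- tabulate(ib, nbins = bins) / length(ib)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (ent(pa) + ent(pb)) / ent(pj)
}

bin_index <- function(v, bins) {
  cuts <- seq(min(v), max(v), length.out = bins + 1L)
  pmin(pmax(findInterval(v, cuts, all.inside = TRUE), 1L), bins)
}

#' Select the atlases most similar to the target
#'
#' Ranks the library by decreasing NMI against the target inside the box
#' and returns the top `n_select` pairs.  Ties keep library order (stable
#' sort).  A library smaller than `n_select` is returned whole with a
#' warning.
#'
#' @param target target [volume()].
#' @param library list of [atlas_pair()].
#' @param box a [bounding_box()] or `NULL`.
#' @param n_select number of atlases to keep (default 20).
#' @param bins histogram bins for the NMI.
#' @return list of [atlas_pair()], most similar first, with the scores in
#'   attribute `"nmi"`.
#' @export
select_atlases <- function(target, library, box = NULL, n_select = 20L,
                           bins = 32L) {
  stopifnot(length(library) >= 1L, n_select >= 1L)
  scores <- vapply(library, function(ap)
    normalized_mutual_information(target, ap$intensity, box, bins), numeric(1))
  if (length(library) < n_select)
    warning(sprintf("library has %d atlases, fewer than n_select = %d",
                    length(library), n_select))
  ord <- order(-scores)  # stable: ties keep library order
  keep <- ord[seq_len(min(n_select, length(library)))]
  out <- library[keep]
  attr(out, "nmi") <- scores[keep]
  out
}

#' Majority voting over registered atlas labels
#'
#' The vote map holds, per voxel, the fraction of atlases labelling it
#' foreground.  Inside the box, voxels split into unanimously-foreground
#' (fraction 1), unanimously-background (fraction 0) and ambiguous
#' (anything in between); only the ambiguous ones are re-decided by the
#' learned fusion.  The hard majority-voting segmentation thresholds the
#' vote at 0.5, ties going to foreground.
#'
#' @param atlas_labels list of [label_volume()] on a common grid.
#' @param box a [bounding_box()].
#' @return an object of class `vote_partition`: the vote map (a
#'   [volume()]), the three disjoint masks covering the box, the box, and
#'   the atlas count.
#' @export
majority_vote <- function(atlas_labels, box) {
  stopifnot(length(atlas_labels) >= 1L, inherits(box, "bounding_box"))
  check_common_grid(atlas_labels)
  n <- length(atlas_labels)
  acc <- array(0, dim(atlas_labels[[1]]$data))
  for (l in atlas_labels) acc <- acc + l$data
  vote <- acc / n
  inbox <- box_mask(box, dim(vote))
  structure(list(
    vote = volume(vote, spacing = atlas_labels[[1]]$spacing),
    unanimous_fg = inbox & vote == 1,
    unanimous_bg = inbox & vote == 0,
    ambiguous    = inbox & vote > 0 & vote < 1,
    box = box, n_atlases = n
  ), class = "vote_partition")
}

#' @export
print.vote_partition <- function(x, ...) {
  cat(sprintf(
    "<vote_partition> %d atlases; box %d voxels: %d fg / %d bg / %d ambiguous\n",
    x$n_atlases, box_volume(x$box), sum(x$unanimous_fg), sum(x$unanimous_bg),
    sum(x$ambiguous)))
  invisible(x)
}

#' Hard majority-voting segmentation from a vote partition
#'
#' @param partition a `vote_partition` from [majority_vote()].
#' @return a [label_volume()] (vote fraction >= 0.5 is foreground).
#' @export
mv_segmentation <- function(partition) {
  v <- partition$vote$data
  label_volume(array(as.integer(v >= 0.5), dim(v)),
               spacing = partition$vote$spacing)
}
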