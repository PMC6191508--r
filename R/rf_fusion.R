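#' Random-forest fusion parameters
#'
#' @param k per-class training subset size: the `k` positive and `k`
#'   negative atlas samples most similar to the target voxel are kept
#'   (default 100).
#' @param n_tree number of trees per voxel forest (default 200).
#' @param n_split number of candidate predictors sampled uniformly at
#'   random at each node split (mtry; default 20).
#' @param seed master RNG seed; per-voxel forests derive their own seeds
#'   deterministically from it and the voxel's linear index, so results do
#'   not depend on scheduling.
#' @export
rf_params <- function(k = 100L, n_tree = 200L, n_split = 20L, seed = 1L) {
  stopifnot(k >= 1L, n_tree >= 1L, n_split >= 1L)
  structure(list(k = as.integer(k), n_tree = as.integer(n_tree),
                 n_split = as.integer(n_split), seed = as.numeric(seed)),
            class = "rf_params")
}

neighborhood_offsets <- function(r) {
  as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))  # dx fastest
}

#' Assemble candidate training samples for one target voxel
#'
#' For voxel `x`, every atlas contributes its (2r+1)^3 neighborhood: the
#' feature vector of each (clamped) neighbor voxel of the atlas intensity,
#' labelled by the atlas label at that voxel — `(2r+1)^3 * N` candidates
#' in atlas-major, offset-minor order.
#'
#' @param atlases list of [atlas_pair()].
#' @param x 0-based voxel index (length 3).
#' @param params a [patch_params()].
#' @return a `training_set`: list with `features` (samples in rows),
#'   `labels` (0/1 integer), and `provenance` (atlas id and voxel index
#'   per sample).
#' @export
assemble_candidates <- function(atlases, x, params = patch_params()) {
  stopifnot(length(atlases) >= 1L)
  d <- dim(atlases[[1]]$intensity$data)
  offs <- neighborhood_offsets(params$r)
  centers <- sweep(offs, 2, as.integer(x), `+`)
  for (a in 1:3) centers[, a] <- pmin(pmax(centers[, a], 0L), d[a] - 1L)
  feats <- vector("list", length(atlases))
  labs <- vector("list", length(atlases))
  prov <- vector("list", length(atlases))
  for (i in seq_along(atlases)) {
    ap <- atlases[[i]]
    feats[[i]] <- extract_features(ap$intensity, centers, params)
    labs[[i]] <- ap$label$data[centers + 1L]
    prov[[i]] <- data.frame(atlas = if (nzchar(ap$id)) ap$id else as.character(i),
                            i = centers[, 1], j = centers[, 2], k = centers[, 3])
  }
  structure(list(features = do.call(rbind, feats),
                 labels = as.integer(unlist(labs)),
                 provenance = do.call(rbind, prov)),
            class = "training_set")
}

#' Balanced most-similar training subset
#'
#' Keeps, per class, the `k` candidates with the smallest Euclidean
#' feature distance to the target voxel's feature vector (all of a class
#' if it has fewer than `k`; the forest then trains on the imbalanced
#' set).  Ties are broken stably by candidate order.  If one class is
#' entirely absent the result is flagged degenerate and [train_forest()]
#' must not be called on it.
#'
#' @param candidates a `training_set` from [assemble_candidates()].
#' @param target_feature feature vector of the voxel to be segmented.
#' @param k per-class subset size.
#' @return a `training_set` (positives first, then negatives, each by
#'   increasing distance) with attributes `degenerate` (logical) and
#'   `present_class` (the surviving class when degenerate).
#' @export
select_balanced_subset <- function(candidates, target_feature, k) {
  stopifnot(inherits(candidates, "training_set"),
            nrow(candidates$features) >= 1L, k >= 1L)
  sel <- cpp_balanced_subset(t(candidates$features),
                             as.integer(candidates$labels),
                             as.numeric(target_feature), as.integer(k))
  keep <- c(sel$pos, sel$neg)
  out <- structure(list(features = candidates$features[keep, , drop = FALSE],
                        labels = candidates$labels[keep],
                        provenance = candidates$provenance[keep, , drop = FALSE]),
                   class = "training_set")
  attr(out, "degenerate") <- length(sel$pos) == 0L || length(sel$neg) == 0L
  attr(out, "present_class") <-
    if (length(sel$pos) == 0L && length(sel$neg) > 0L) 0L
    else if (length(sel$neg) == 0L && length(sel$pos) > 0L) 1L
    else NA_integer_
  out
}

#' Train a per-voxel random forest
#'
#' Classification trees grown on bootstrap resamples of the training set
#' with `n_split` predictors sampled uniformly at random as split
#' candidates per node; Gini impurity, unlimited depth, minimum leaf size
#' 1.  Deterministic for a given seed.
#'
#' @param training a `training_set` containing both classes.
#' @param params an [rf_params()]; `params$seed` seeds the forest.
#' @return a `forest_model`.
#' @export
train_forest <- function(training, params = rf_params()) {
  stopifnot(inherits(training, "training_set"))
  y <- training$labels
  if (length(unique(y)) < 2L)
    af_error("single-class training set; use the degenerate path",
             "atlasfuse_degenerate_training")
  X <- training$features  # samples in rows
  if (any(!is.finite(X)))
    af_error("non-finite feature values", "atlasfuse_bad_features")
  n_split <- min(params$n_split, ncol(X))
  trees <- cpp_rf_train(X, as.integer(y), params$n_tree, n_split, 1L,
                        params$seed)
  structure(list(trees = trees, n_feat = ncol(X), params = params,
                 class_counts = c(bg = sum(y == 0L), fg = sum(y == 1L))),
            class = "forest_model")
}

#' Forest vote fraction for feature vectors
#'
#' The foreground probability is the exact fraction of trees voting
#' foreground, so values lie on the `{0, 1/n_tree, ..., 1}` lattice.
#'
#' @param model a `forest_model` from [train_forest()].
#' @param f a feature vector, or a matrix of them (one per row).
#' @param votes if `TRUE`, return the 0/1 per-tree vote matrix instead.
#' @return probability vector (or vote matrix).
#' @export
predict_probability <- function(model, f, votes = FALSE) {
  stopifnot(inherits(model, "forest_model"))
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
  if (ncol(f) != model$n_feat)
    af_error(sprintf("feature dimension %d does not match the model (%d)",
                     ncol(f), model$n_feat), "atlasfuse_dim_mismatch")
  v <- cpp_rf_votes(model$trees, t(f))
  if (votes) return(v)
  rowMeans(v)
}

#' Probabilistic segmentation by per-voxel random-forest label fusion
#'
#' Unanimously voted voxels short-circuit (probability 1 or 0); every
#' ambiguous voxel gets its own forest, trained on the balanced
#' most-similar subset of its atlas neighborhood candidates, and receives
#' the tree-vote fraction as its foreground probability.  Voxels outside
#' the bounding box get 0.  Voxels whose candidate pool is single-class
#' take that class's probability (with a note in the returned counts).
#' Per-voxel seeds derive from `rf_params$seed` and the voxel's linear
#' index, so the run is bit-reproducible for a fixed seed and atlas order.
#'
#' @param target target [volume()].
#' @param atlases list of [atlas_pair()] registered to the target.
#' @param partition a `vote_partition` from [majority_vote()] on the same
#'   atlases.
#' @param patch a [patch_params()].
#' @param rf an [rf_params()].
#' @return a [volume()] of foreground probabilities with attribute
#'   `"fusion_counts"` (ambiguous / degenerate voxel counts); threshold at
#'   0.5 for the hard segmentation (ties to foreground).
#' @export
rf_segment <- function(target, atlases, partition, patch = patch_params(),
                       rf = rf_params()) {
  stopifnot(inherits(partition, "vote_partition"))
  check_common_grid(c(list(target), lapply(atlases, `[[`, "intensity")))
  d <- dim(target$data)
  prob <- array(0, d)
  prob[partition$unanimous_fg] <- 1
  amb <- which(partition$ambiguous)
  counts <- c(ambiguous = length(amb), only_fg = 0L, only_bg = 0L)
  if (length(amb) == 0L) {
    out <- volume(prob, spacing = target$spacing)
    attr(out, "fusion_counts") <- counts
    return(out)
  }
  amb_ijk <- arrayInd(amb, d) - 1L  # 0-based
  offs <- neighborhood_offsets(patch$r)
  n_off <- nrow(offs)
  n_atlas <- length(atlases)

  # process ambiguous voxels in chunks: neighboring voxels share most of
  # their candidate features, so per-chunk precomputation keeps the reuse
  # while bounding memory to a few hundred MB
  chunk_size <- 1024L
  n_amb <- nrow(amb_ijk)
  atlas_data <- lapply(atlases, function(a) as.numeric(a$intensity$data))
  for (c0 in seq(1L, n_amb, by = chunk_size)) {
    c1 <- min(c0 + chunk_size - 1L, n_amb)
    sel <- c0:c1
    blk <- amb_ijk[sel, , drop = FALSE]
    nb <- blk[rep(seq_along(sel), each = n_off), , drop = FALSE] +
      offs[rep(seq_len(n_off), times = length(sel)), , drop = FALSE]
    for (a in 1:3) nb[, a] <- pmin(pmax(nb[, a], 0L), d[a] - 1L)
    nb_lin <- nb[, 1] + d[1] * (nb[, 2] + d[2] * nb[, 3])
    needed <- sort(unique(nb_lin))
    pos_in_needed <- match(nb_lin, needed)
    needed_ijk <- arrayInd(needed + 1L, d) - 1L
    n_needed <- length(needed)

    candF <- cpp_patch_features_multi(atlas_data, d,
                                      matrix(as.integer(needed_ijk),
                                             ncol = 3L), patch$r_s)
    candLab <- unlist(lapply(atlases, function(a)
      as.integer(a$label$data[needed_ijk + 1L])))

    # per-voxel candidate columns, atlas-major then offset order (matching
    # assemble_candidates())
    cand_idx <- vector("list", length(sel))
    for (v in seq_along(sel)) {
      loc <- pos_in_needed[((v - 1L) * n_off + 1L):(v * n_off)] - 1L
      cand_idx[[v]] <- as.integer(outer(loc,
                                        (seq_len(n_atlas) - 1L) * n_needed,
                                        `+`))
    }

    targetF <- extract_features_cols(target, blk, patch)
    lin0 <- amb[sel] - 1L  # 0-based linear index
    seeds <- derive_voxel_seed(rf$seed, lin0)  # vectorized, exact in doubles
    n_split <- min(rf$n_split, nrow(targetF))
    res <- cpp_rf_fuse(targetF, candF, candLab, cand_idx, rf$k, rf$n_tree,
                       n_split, 1L, seeds)
    prob[amb[sel]] <- res$prob
    counts["only_fg"] <- counts["only_fg"] + sum(res$status == 1L)
    counts["only_bg"] <- counts["only_bg"] + sum(res$status == 2L)
  }
  out <- volume(prob, spacing = target$spacing)
  attr(out, "fusion_counts") <- counts
  out
}
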