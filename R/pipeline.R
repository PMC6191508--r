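#' Pipeline configuration
#'
#' Bundles everything one segmentation run needs: the method variant, the
#' patch / forest / propagation parameters, atlas selection size and
#' bounding-box margin, and the master seed.
#'
#' Method variants: `"MV"` (thresholded majority vote), `"MV-SSLP"`
#' (propagation-refined vote map), `"RF"` (thresholded forest
#' probability map) and `"RF-SSLP"` (propagation-refined forest map, the
#' full method).
#'
#' @param method one of `"MV"`, `"MV-SSLP"`, `"RF"`, `"RF-SSLP"`.
#' @param patch a [patch_params()].
#' @param rf an [rf_params()].
#' @param sslp an [sslp_params()].
#' @param n_select atlases kept by NMI ranking (default 20).
#' @param margin bounding-box margin in voxels (default 10).
#' @param seed master seed; forest seeds derive from it.
#' @export
run_config <- function(method = c("RF-SSLP", "RF", "MV-SSLP", "MV"),
                       patch = patch_params(), rf = rf_params(),
                       sslp = sslp_params(), n_select = 20L, margin = 10L,
                       seed = 1L) {
  structure(list(method = match.arg(method), patch = patch, rf = rf,
                 sslp = sslp, n_select = as.integer(n_select),
                 margin = as.integer(margin), seed = as.numeric(seed)),
            class = "run_config")
}

#' Run the full segmentation pipeline on one target
#'
#' Stages: bounding box from the registered atlas labels, NMI-based atlas
#' selection, majority voting with the unanimous/ambiguous partition,
#' then the method variant: forest fusion of the ambiguous voxels (RF
#' variants) and/or label-propagation refinement (SSLP variants).  When a
#' truth label is supplied the nine evaluation metrics are computed.
#' Runs are bit-reproducible for a fixed config, seed, and atlas order.
#'
#' @param config a [run_config()].
#' @param target target [volume()].
#' @param atlases list of [atlas_pair()] registered to the target.
#' @param truth optional manual [label_volume()] for evaluation.
#' @return list with `label` (the segmentation), `prob` (the
#'   probabilistic map the variant thresholds or refines), `partition`,
#'   `box`, `metrics` (or `NULL`), and a `manifest` of resolved
#'   parameters and voxel counts.
#' @export
run_pipeline <- function(config, target, atlases, truth = NULL) {
  stopifnot(inherits(config, "run_config"), length(atlases) >= 1L)
  check_common_grid(c(list(target), lapply(atlases, `[[`, "intensity")),
                    ids = c("target", vapply(atlases, `[[`, "", "id")))
  rf <- config$rf
  rf$seed <- config$seed
  box <- compute_bounding_box(lapply(atlases, `[[`, "label"),
                              margin = config$margin)
  selected <- if (length(atlases) > config$n_select)
    select_atlases(target, atlases, box, config$n_select)
  else atlases
  partition <- majority_vote(lapply(selected, `[[`, "label"), box)

  prob <- if (config$method %in% c("RF", "RF-SSLP"))
    rf_segment(target, selected, partition, config$patch, rf)
  else partition$vote

  label <- if (config$method %in% c("MV-SSLP", "RF-SSLP"))
    sslp_refine(prob, target, box, config$sslp)
  else label_volume(array(as.integer(prob$data >= 0.5), dim(prob$data)),
                    spacing = target$spacing)

  metrics <- if (!is.null(truth)) evaluate_segmentation(truth, label)
  manifest <- list(
    method = config$method, seed = config$seed,
    n_atlases = length(selected), margin = config$margin,
    box = list(lower = box$lower, upper = box$upper),
    voxels = c(box = box_volume(box),
               unanimous_fg = sum(partition$unanimous_fg),
               unanimous_bg = sum(partition$unanimous_bg),
               ambiguous = sum(partition$ambiguous)),
    patch = unclass(config$patch), rf = unclass(rf),
    sslp = unclass(config$sslp))
  list(label = label, prob = prob, partition = partition, box = box,
       metrics = metrics, manifest = manifest)
}

#' Enumerate a parameter grid
#'
#' Full Cartesian product of the candidate lists, in deterministic
#' odometer order (the first named parameter varies fastest).
#'
#' @param grid named list of non-empty candidate-value vectors.
#' @return data.frame with one row per configuration.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(is.list(grid), length(grid) >= 1L, !is.null(names(grid)),
            all(lengths(grid) >= 1L))
  expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

apply_grid_row <- function(config, row) {
  for (nm in names(row)) {
    val <- row[[nm]]
    if (nm %in% names(config$rf)) config$rf[[nm]] <- val
    else if (nm %in% names(config$sslp)) config$sslp[[nm]] <- val
    else if (nm %in% names(config$patch)) config$patch[[nm]] <- val
    else if (nm %in% c("n_select", "margin", "method")) config[[nm]] <- val
    else stop(sprintf("unknown grid parameter '%s'", nm))
  }
  config
}

#' Cross-validated parameter sweep
#'
#' For every grid configuration, runs the pipeline on each subject of the
#' dataset (leave-one-out style: every subject is a held-out target
#' segmented from its own atlas library) and ranks configurations by mean
#' held-out Dice.  Deterministic for a fixed master seed.
#'
#' @param dataset a list of subjects as produced by [make_dataset()]
#'   (each with `target`, `truth`, `atlases`).
#' @param grid named list of candidate values; names must match fields of
#'   [rf_params()], [sslp_params()], [patch_params()] or the config
#'   itself.
#' @param base_config the [run_config()] the grid rows are applied to.
#' @return data.frame: one row per configuration with its parameters,
#'   `mean_dice`, per-subject Dice in attribute `"folds"`, ranked by
#'   decreasing mean Dice (stable in grid order for ties).
#' @export
cross_validated_sweep <- function(dataset, grid,
                                  base_config = run_config()) {
  stopifnot(length(dataset) >= 2L)
  rows <- enumerate_grid(grid)
  folds <- matrix(NA_real_, nrow(rows), length(dataset))
  for (g in seq_len(nrow(rows))) {
    cfg <- apply_grid_row(base_config, rows[g, , drop = FALSE])
    for (s in seq_along(dataset)) {
      sub <- dataset[[s]]
      res <- run_pipeline(cfg, sub$target, sub$atlases, truth = sub$truth)
      folds[g, s] <- res$metrics$dice
    }
  }
  out <- rows
  out$mean_dice <- rowMeans(folds)
  ord <- order(-out$mean_dice)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "folds") <- folds[ord, , drop = FALSE]
  out
}

#' Compare the four method variants on a synthetic study
#'
#' Generates (or accepts) a synthetic dataset and runs MV, MV-SSLP, RF
#' and RF-SSLP on every subject with shared upstream computation,
#' returning the per-subject Dice of each variant.  This is the package's
#' workhorse for the ordering property that propagation refinement
#' improves both baselines and that the forest + propagation combination
#' ranks first.
#'
#' @param n_subjects subjects to simulate (default 20).
#' @param master_seed master RNG seed for the dataset.
#' @param config a [run_config()] whose parameters (other than `method`)
#'   are shared by all four variants.
#' @param phantom,library generator specs passed to [make_dataset()].
#' @param dataset optionally, an existing dataset (overrides the
#'   generator arguments).
#' @return data.frame with columns `subject`, `method`, `dice`.
#' @export
benchmark_variants <- function(n_subjects = 20L, master_seed = 1L,
                               config = run_config(),
                               phantom = phantom_spec(),
                               library = atlas_library_spec(),
                               dataset = NULL) {
  if (is.null(dataset))
    dataset <- make_dataset(n_subjects, phantom, library, master_seed)
  methods <- c("MV", "MV-SSLP", "RF", "RF-SSLP")
  res <- vector("list", length(dataset) * length(methods))
  at <- 0L
  for (s in seq_along(dataset)) {
    sub <- dataset[[s]]
    cfg <- config
    cfg$seed <- derive_seed(master_seed, 5000L + s)
    box <- compute_bounding_box(lapply(sub$atlases, `[[`, "label"),
                                margin = cfg$margin)
    partition <- majority_vote(lapply(sub$atlases, `[[`, "label"), box)
    rf <- cfg$rf; rf$seed <- cfg$seed
    rf_prob <- rf_segment(sub$target, sub$atlases, partition, cfg$patch, rf)
    maps <- list("MV" = partition$vote, "MV-SSLP" = partition$vote,
                 "RF" = rf_prob, "RF-SSLP" = rf_prob)
    for (m in methods) {
      lab <- if (grepl("SSLP", m))
        sslp_refine(maps[[m]], sub$target, box, cfg$sslp)
      else label_volume(array(as.integer(maps[[m]]$data >= 0.5),
                              dim(maps[[m]]$data)),
                        spacing = sub$target$spacing)
      at <- at + 1L
      res[[at]] <- data.frame(
        subject = s, method = m,
        dice = unname(overlap_metrics(sub$truth, lab)["dice"]))
    }
  }
  do.call(rbind, res)
}
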