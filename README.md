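# atlasfuse

Multi-atlas segmentation of compact anatomical structures (the
motivating case is the hippocampus in T1-weighted MRI) from a library of
co-registered, expert-labelled reference images.  Registration is
assumed done; `atlasfuse` takes a target volume plus atlas
intensity/label pairs on the target's grid (NIfTI-1) and fuses the atlas
labels into a segmentation.

## The method

Majority voting decides the easy voxels: wherever all registered atlases
agree, their common label is accepted.  The contested shell of
*ambiguous* voxels is re-decided in two learned stages:

1. **Voxelwise random-forest fusion.**  Each ambiguous voxel `x` gets
   its own classifier.  Training samples are the atlas voxels in the
   `(2r+1)^3` neighborhood of `x`, described by z-scored patch
   intensities concatenated with a texture filter bank (difference,
   hyperplane, Sobel, Laplacian and range filters over the `(2r_s+1)^3`
   patch).  The `k` most similar samples per class (Euclidean feature
   distance) train a forest of `N_tree` trees with `N_split` candidate
   predictors per node, and

       p(f_x) = (1/N_tree) * sum_i T_i(f_x)

   is the exact fraction of trees voting foreground.

2. **Semi-supervised label propagation.**  The probability map is
   encoded as an n×2 coding `p_i1 = max(2(p_i - 0.5), 0)`,
   `p_i2 = max(2(0.5 - p_i), 0)`; reliable background entries (above the
   threshold `T`) are rescaled by the reliable-count ratio `N_f/N_b`
   (floored at `T`) and each reliable side is normalized to mean 1.
   On the intensity affinity `W_xy = exp(-(I_x - I_y)^2 / sigma^2)` with
   symmetric normalization `S = D^{-1/2} W D^{-1/2}`, the coding is
   iterated to the fixed point of

       L <- (1 - beta) S L + beta P

   and binarized (foreground iff column 1 exceeds column 2).

Four variants are exposed: `MV`, `MV-SSLP`, `RF`, and the full
`RF-SSLP`.  Defaults are `r_s = 3`, `r = 1`, `k = 100`, `N_tree = 200`,
`N_split = 20`, `T = 0.5`, `sigma = 10`, `beta = 0.6`.  The package also
ships NMI-based atlas selection, a nine-metric evaluation suite (Dice,
Jaccard, precision, recall, MD, HD, HD95, ASSD, RMSD), a cross-validated
grid-sweep driver, and a synthetic phantom generator so everything can
be run and tested without imaging data.

## Worked example

```r
library(atlasfuse)

# a synthetic subject: blob phantom + 10 imperfectly registered atlases
set.seed(1)
phantom <- make_phantom(phantom_spec(seed = 7))
atlases <- make_atlas_library(phantom, atlas_library_spec(n_atlases = 10,
                                                          seed = 8))
round(attr(atlases, "dice_to_truth"), 3)
#>  [1] 0.756 0.886 0.858 0.844 0.692 0.749 0.827 0.791 0.782 0.855

cfg <- run_config(method = "RF-SSLP", rf = rf_params(n_tree = 50),
                  n_select = 10, seed = 1)
res <- run_pipeline(cfg, phantom$volume, atlases, truth = phantom$label)
res$manifest$voxels
#>          box unanimous_fg unanimous_bg    ambiguous
#>        32768          302        30899         1567
round(res$metrics, 4)
#>   dice jaccard precision recall md hd hd95 assd rmsd
#> 1    1       1         1      1  0  0    0    0    0
```

The individual atlases overlap the truth at Dice ≈ 0.8; majority voting
leaves 1567 voxels contested, and the forest + propagation pipeline
recovers the exact truth label on this phantom (all nine metrics at
their ideal values).  `benchmark_variants()` runs all four variants on a
multi-subject synthetic study and returns per-subject Dice for
comparisons like MV vs MV-SSLP vs RF vs RF-SSLP.

A thin command-line wrapper with `segment`, `evaluate`, `synthesize` and
`sweep` subcommands is installed at
`system.file("cli", "atlasfuse.R", package = "atlasfuse")`.

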