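---
title: "Multi-atlas label fusion with voxelwise forests and label propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas label fusion with voxelwise forests and label propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasfuse)
```

## The problem

Multi-atlas image segmentation (MAIS) delineates a compact structure —
the motivating application is the hippocampus in T1-weighted MRI — by
registering a library of expert-labelled reference images (*atlases*) to
the target scan and fusing their propagated labels.  Registration is
never perfect: residual geometric error and inter-subject intensity
differences leave a shell of voxels on which the registered atlases
disagree.  Everything in this package is about deciding those voxels
well.  Registration itself is out of scope; all inputs are assumed
resampled to the target's voxel grid.

The pipeline is

1. **Bounding box** — the union of the registered atlas foregrounds,
   dilated by a margin (default 10 voxels) and clipped to the grid.  All
   further work is restricted to this box.
2. **Atlas selection** — the `n_select` (default 20) atlases most similar
   to the target by normalized mutual information (NMI) inside the box.
3. **Majority voting (MV)** — the per-voxel foreground vote fraction.
   Voxels with unanimous votes are accepted outright; only *ambiguous*
   voxels (vote strictly between 0 and 1) move on.
4. **Per-voxel random-forest fusion (RF)** — each ambiguous voxel gets
   its own classifier trained on patch-texture features of the atlas
   voxels around it, and receives the fraction of trees voting
   foreground as its probability.
5. **Semi-supervised label propagation (SSLP)** — the probabilistic map
   is refined on an intensity-affinity graph so that reliable labels
   spread into unreliable regions under a local-and-global consistency
   objective.

The MV and RF maps can each be thresholded directly or refined, giving
the four variants `MV`, `MV-SSLP`, `RF`, `RF-SSLP` exposed by
`run_config()`.

## Feature extraction

A voxel is described by its $(2r_s+1)^3$ patch (default $r_s = 3$, i.e.
$7^3$).  The patch is z-scored (mean subtracted, divided by the sample
standard deviation), which makes every downstream feature invariant to
positive affine intensity changes — the first line of defence against
inter-subject intensity discrepancy.  A texture filter bank is then
applied to the normalized patch and all responses are concatenated with
the normalized intensities.

The filter families are named conventions of the patch-classification
literature; their concrete kernels are this package's own documented
choices (`feature_layout()` freezes the order):

* first-order central differences and $(1,-2,1)$ second differences
  along each axis;
* *hyperplane* filters: the mean over the $3\times3$ plane normal to
  each axis, minus the center;
* $3\times3\times3$ Sobel derivatives along each axis
  ($[1,2,1]\otimes[1,2,1]$ smoothing times $[-1,0,1]$);
* the 27-point Laplacian (neighbor sum minus $27\times$ center);
* the range filter ($\max - \min$ over $3^3$).

Responses are kept at every patch voxel, so the vector length is
$15(2r_s+1)^3$ (5145 at the default radius).  Edge replication is used
both against the volume border and at the patch border, so no position
yields NaNs.  Because no subsampling rule is imposed, keeping the full
response maps is the least arbitrary completion; numeric parity with any
particular historical implementation of these filter families is not
claimed, and the layout test exists precisely to freeze *this* package's
definition.

## Per-voxel random forests

For an ambiguous voxel $x$, every atlas contributes its $(2r+1)^3$
neighborhood (default $r = 1$): each neighbor's feature vector, labelled
by that atlas's label at the neighbor.  With $N$ atlases this yields
$(2r+1)^3 N$ candidates.  To balance the classes, the $k$ (default 100)
candidates *per class* nearest to the target voxel's own feature vector
in Euclidean distance are kept; a class with fewer than $k$ candidates
is taken whole and the forest trains on the imbalanced set (the minimal
completion of the per-class rule).  If one class is absent entirely the
voxel takes that degenerate probability (0 or 1) and is flagged in the
run counts.

The forest is `n_tree` (default 200) CART trees grown on bootstrap
resamples of the selected subset with `n_split` (default 20) predictors
sampled uniformly at random per node — Gini impurity, midpoint
thresholds, unlimited depth, minimum leaf size 1, the canonical settings
for this model family.  Bootstrap resampling is applied on top of the
balanced subset rather than the full candidate pool; the alternative
scope would blur the per-class balance that the subset selection just
established.  The foreground probability is the exact fraction of trees
voting foreground, so probabilities live on the $1/\texttt{n\_tree}$
lattice; the hard segmentation thresholds at 0.5 with ties to
foreground.

The per-voxel forests are trained by compiled code inside the package.
At the default dimensions (hundreds of samples, thousands of features,
tens of thousands of voxels per scan) the per-voxel loop is the hot path
of the whole method, and the implementation keeps each feature column
contiguous in memory and sorts raw doubles per class during the split
search; an equivalence test pins the fused fast path to the composed
single-voxel operations bit for bit.  Reproducibility is by
construction: every voxel derives its own RNG seed deterministically
from the master seed and its linear index, so results are independent of
chunking or scheduling; a deterministic splitmix64 generator is used
because the C++ standard library's distributions are
implementation-defined.

## Label propagation

The probability map $p$ over the working region is encoded as an
$n\times2$ coding with rows
$(\max(2(p_i-0.5),0),\ \max(2(0.5-p_i),0))$ — foreground evidence in
column 1, background in column 2, indifference at $p=0.5$ coding to
$(0,0)$.  Entries above the reliability threshold $T$ (default 0.5) are
*reliable*.

Because background voxels far outnumber foreground ones, reliable
background entries are rescaled by $N_f/N_b$ (the reliable-count ratio)
and floored at $T$, so a reliable entry never drops below the threshold;
each reliable side is then divided by its own mean so both sides average
1.  Entries floored to exactly $T$ fall outside the strictly-above-$T$
normalization set and stay put — the literal reading of the
normalization rule, which also avoids dividing by the mean of an empty
set.  Unreliable entries are left unchanged by default
(`zero_unreliable` exposes the stated alternative).  The transform is
monotone in the input coding over the reliable range, which the suite
checks.

The affinity between voxels $x,y$ is
$W_{xy} = \exp(-(I_x-I_y)^2/\sigma^2)$ on target intensities (default
$\sigma = 10$, matched to raw-grayscale data on a 0–255-like scale),
zero diagonal, and $S = D^{-1/2} W D^{-1/2}$.  The refined coding is the
fixed point of $L^{(t+1)} = (1-\beta)\,S L^{(t)} + \beta P$ (default
$\beta = 0.6$), which exists because the spectral radius of
$(1-\beta)S$ is below 1; the iteration converges geometrically at rate
$1-\beta$.  Up to `direct_cap` (512) nodes the fixed point
$\beta(I-(1-\beta)S)^{-1}P$ is obtained by a direct solve; beyond that
the iteration (tolerance $10^{-6}$ on the max-abs change, cap 1000) is
used — above a few hundred nodes a dozen matrix-vector products are far
cheaper than a dense factorization, and an oracle test holds the two
routes together.  Binarization takes foreground iff column 1 strictly
exceeds column 2, ties to background.

Two choices are genuinely open in this construction and are resolved as
follows:

* **Node set.** Propagating over every voxel of the box is wasteful when
  most are reliably decided.  By default the graph nodes are the
  unreliable voxels plus a 1-voxel dilation ring of reliable neighbors,
  so reliable evidence borders every unreliable component
  (`graph_nodes = "box"` selects the whole box).
* **Edge set.** The literal all-pairs affinity is quadratic in the node
  count; it is used (`mode = "dense"`) up to 20000 nodes and serves as
  the reference in tests.  Beyond that, each node keeps its 26 spatial
  neighbors plus its 10 nearest-intensity nodes, symmetrized — keeping
  both the local and the global (intensity-based, spatially unbounded)
  consistency channels at tractable cost.

## Evaluation metrics

`evaluate_segmentation()` computes, between a manual label $A$ and a
result $B$: Dice $2|A\cap B|/(|A|+|B|)$, Jaccard, precision
$|A\cap B|/|B|$, recall $|A\cap B|/|A|$, and five surface distances in
mm.  The boundary $\partial M$ is the set of foreground voxels with a
background 6-neighbor, the image border counting as background — the
most common convention, frozen here since nothing in the metric
definitions pins it down.  With $d(e,\partial B)=\min_{f\in\partial B}
d(e,f)$:

* MD $= \operatorname{mean}_{e\in\partial A} d(e,\partial B)$ —
  deliberately directed, manual to automatic, exactly as defined;
* HD $= \max$ of the two directed maxima;
* HD95: within *each* directed distance set the
  $\lceil 0.05 n\rceil$ largest values are discarded (always keeping at
  least one) before taking the max of the two maxima — the trimming is
  per direction, not pooled, reading "removed before calculation"
  literally;
* ASSD: mean of the two directed means;
* RMSD $= \sqrt{(D_A^2 + D_B^2)/(|\partial A|+|\partial B|)}$ with
  $D_A^2$ the sum of squared directed distances.

Distances are computed by an exhaustive pairwise scan in compiled code
(surfaces of compact structures are small, and exactness beats a
distance-transform approximation on anisotropic grids); a plain-R
double-loop oracle checks all nine metrics on random mask pairs.

## The synthetic phantom family

The generator exists so that the full pipeline can be exercised, and its
claims tested, without any imaging data.  A phantom is an ellipsoid
(default semi-axes $8\times6\times5$ voxels in a $32^3$ grid) whose
boundary is modulated by a smooth random radial field (amplitude 12 % of
the radius), with foreground mean 160, background mean 80, an optional
smooth multiplicative bias field (±5 %), and Gaussian noise of sd 10 —
intensities on a 0–255-like scale precisely so that the default
$\sigma = 10$ is meaningful on generated data.  Each atlas is the truth
warped by an independent Gaussian-smoothed random displacement field
(smoothing sd 4 voxels; root-mean-square amplitude 2 voxels per
component — peak-amplitude scaling would leave typical displacements
sub-voxel on these grids and collapse the library onto the truth),
followed by a random affine intensity change (gain 0.9–1.1, offset ±10)
and fresh noise of sd 5.  At these settings the atlases overlap the
truth at Dice ≈ 0.8, a realistic level of post-registration
disagreement, and every downstream stage is exercised: ambiguous sets
are non-empty and both classes appear in every boundary neighborhood.

What the phantoms deliberately do *not* model: anatomy (a hippocampus is
not an ellipsoid), MRI physics (no Rician noise, no partial-volume
model beyond linear interpolation), or registration failure modes beyond
smooth small-amplitude warps.  Passing the packaged studies therefore
shows that the implementation is correct and that the method's internal
ordering (propagation refines both baselines; forest fusion beats
voting) holds under its own assumptions — not that any particular
accuracy will be reached on clinical data.

## Study sizes and numerical choices

The packaged end-to-end study runs 20 subjects at reduced scale — $32^3$
grids (which the margin-10 bounding box covers), 10 atlases per subject,
50 trees — sizes chosen so a complete run stays a desk-scale computation
while every stage still does real work; the acceptance script runs the
same study at 8 subjects.  Sweeps over the documented candidate grids
(12 forest settings, 27 propagation settings) use the same machinery via
`cross_validated_sweep()`, which evaluates every configuration on every
held-out subject.

Degenerate inputs are handled explicitly rather than by accident:
constant patches z-score to zero; a constant image inside the box has
NMI defined as 1 (no information) with a message; a probability map with
no reliable labels on one side raises a named error naming that side; an
empty mask cannot produce a surface.  Label codings at exactly the MV
tie (vote fraction 0.5) binarize to foreground in the MV baseline — a
fixed convention that never affects the learned variants, which re-decide
all non-unanimous voxels anyway.

## Limitations

* Multi-class structures are out of scope; the coding is strictly
  foreground/background.
* $\sigma$ is a fixed intensity scale, not estimated from the data; on
  inputs whose intensity range differs wildly from 0–255 it must be set
  by the caller.
* The per-voxel forests do not share computation across voxels, which is
  faithful to the method but leaves obvious headroom (feature reuse is
  exploited, tree reuse is not).
* The sparse graph mode approximates the literal all-pairs affinity; the
  dense mode is the reference and the default whenever it fits.
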