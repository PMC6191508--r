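#' Semi-supervised label-propagation parameters
#'
#' @param T_rel reliability threshold on the label coding: entries above
#'   it count as reliable (default 0.5).
#' @param sigma intensity-similarity scale of the affinity kernel, in the
#'   image's intensity units (default 10, meaningful for raw-grayscale
#'   0-255-like data).
#' @param beta trade-off between the graph term and fidelity to the input
#'   coding, in (0, 1) (default 0.6).
#' @param tol convergence tolerance on the max-abs iterate change
#'   (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @param graph_nodes `"ring"` (default): graph nodes are the unreliable
#'   voxels plus a 1-voxel dilation ring of reliable neighbors, so
#'   reliable information borders every unreliable component; `"box"`:
#'   every voxel of the bounding box.
#' @param mode `"auto"` (dense pairwise affinities up to `dense_cap`
#'   nodes, sparse beyond), `"dense"`, or `"sparse"`.
#' @param dense_cap node count up to which the literal all-pairs affinity
#'   matrix is built (default 20000).
#' @param m_intensity in sparse mode, number of nearest-intensity
#'   neighbors retained per node besides the 26 spatial ones (default 10).
#' @param direct_cap node count up to which the propagation fixed point is
#'   obtained by a direct linear solve instead of iteration (default 512;
#'   the iterative route converges geometrically at rate `1 - beta` and
#'   is much cheaper on larger graphs); both routes agree to within
#'   `tol`.
#' @export
sslp_params <- function(T_rel = 0.5, sigma = 10, beta = 0.6, tol = 1e-6,
                        max_iter = 1000L, graph_nodes = c("ring", "box"),
                        mode = c("auto", "dense", "sparse"),
                        dense_cap = 20000L, m_intensity = 10L,
                        direct_cap = 512L) {
  stopifnot(T_rel >= 0, T_rel < 1, sigma > 0, beta > 0, beta < 1, tol > 0,
            max_iter >= 1L)
  structure(list(T_rel = T_rel, sigma = sigma, beta = beta, tol = tol,
                 max_iter = as.integer(max_iter),
                 graph_nodes = match.arg(graph_nodes),
                 mode = match.arg(mode), dense_cap = as.integer(dense_cap),
                 m_intensity = as.integer(m_intensity),
                 direct_cap = as.integer(direct_cap)),
            class = "sslp_params")
}

#' Encode foreground probabilities as a two-column label coding
#'
#' Row i is `(max(2*(p_i - 0.5), 0), max(2*(0.5 - p_i), 0))`: the first
#' column codes foreground evidence, the second background evidence, and
#' probabilities at exactly 0.5 code as (0, 0).
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return an n x 2 nonnegative matrix.
#' @export
encode_probabilities <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    af_error("probabilities must lie in [0, 1]", "atlasfuse_bad_probability")
  cbind(fg = pmax(2 * (p - 0.5), 0), bg = pmax(2 * (0.5 - p), 0))
}

#' Information-balance weighting of reliable labels
#'
#' Background voxels usually outnumber foreground ones, so reliable
#' background evidence is rescaled by the reliable-count ratio N_f/N_b,
#' floored at `T_rel` so a reliable entry never drops below the
#' reliability threshold; entries at or below `T_rel` are untouched.  With
#' `normalize = TRUE` (the default) each reliable side is then divided by
#' its own mean, so the reliable foreground and (weighted) background
#' entries both average 1; unreliable entries are left unchanged.
#'
#' @param P an n x 2 coding from [encode_probabilities()].
#' @param T_rel reliability threshold in \[0, 1).
#' @param normalize apply the reliable-mean normalization (default TRUE).
#' @param zero_unreliable if TRUE, zero the unreliable entries instead of
#'   leaving them unchanged.
#' @return the weighted (and normalized) n x 2 coding, with the reliable
#'   counts in attribute `"reliable_counts"`.
#' @export
balance_weighting <- function(P, T_rel = 0.5, normalize = TRUE,
                              zero_unreliable = FALSE) {
  stopifnot(is.matrix(P), ncol(P) == 2L, T_rel >= 0, T_rel < 1)
  rel_f <- P[, 1] > T_rel
  rel_b <- P[, 2] > T_rel
  n_f <- sum(rel_f); n_b <- sum(rel_b)
  if (n_f == 0L || n_b == 0L)
    af_error(sprintf("no reliable labels on the %s side",
                     if (n_f == 0L) "foreground" else "background"),
             "atlasfuse_no_reliable_labels")
  out <- P
  out[rel_b, 2] <- pmax((n_f / n_b) * P[rel_b, 2], T_rel)
  if (normalize) {
    # re-evaluated on the weighted values: entries floored to exactly
    # T_rel fall outside the strict threshold and stay as they are
    nf_set <- out[, 1] > T_rel
    nb_set <- out[, 2] > T_rel
    if (any(nf_set)) out[nf_set, 1] <- out[nf_set, 1] / mean(out[nf_set, 1])
    if (any(nb_set)) out[nb_set, 2] <- out[nb_set, 2] / mean(out[nb_set, 2])
  }
  if (zero_unreliable) {
    out[!rel_f, 1] <- 0
    out[!rel_b, 2] <- 0
  }
  attr(out, "reliable_counts") <- c(n_f = n_f, n_b = n_b)
  out
}

#' Intensity-affinity graph with symmetric normalization
#'
#' Pairwise similarity `W_xy = exp(-(I_x - I_y)^2 / sigma^2)` with zero
#' diagonal, and its symmetric normalization `S = D^-1/2 W D^-1/2` where D
#' is the diagonal degree matrix.  The spectral radius of S is at most 1,
#' which guarantees convergence of the propagation.  In dense mode all
#' pairs are retained (the literal reference construction); in sparse
#' mode each node keeps its 26-connected spatial neighbors plus its
#' `m_intensity` nearest-intensity nodes, symmetrized.
#'
#' @param intensities numeric vector of node intensities.
#' @param sigma similarity scale (> 0).
#' @param mode `"dense"` or `"sparse"`.
#' @param coords 0-based n x 3 voxel indices of the nodes; required in
#'   sparse mode.
#' @param m_intensity nearest-intensity neighbors per node (sparse mode).
#' @return list with `W`, `S` (base matrices in dense mode, `Matrix`
#'   sparse matrices otherwise), the degree vector `d`, and `mode`.
#' @export
build_affinity <- function(intensities, sigma, mode = c("dense", "sparse"),
                           coords = NULL, m_intensity = 10L) {
  mode <- match.arg(mode)
  n <- length(intensities)
  stopifnot(n >= 2L, sigma > 0)
  if (mode == "dense") {
    dif <- outer(intensities, intensities, `-`)
    W <- exp(-(dif * dif) / sigma^2)
    diag(W) <- 0
    d <- rowSums(W)
    inv <- 1 / sqrt(d)
    S <- W * (inv %o% inv)
    return(list(W = W, S = S, d = d, mode = "dense"))
  }
  if (is.null(coords))
    af_error("sparse affinity mode needs node coordinates",
             "atlasfuse_missing_coords")
  key <- coords[, 1] + 4096 * (coords[, 2] + 4096 * coords[, 3])
  offs <- neighborhood_offsets(1L)
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ei <- integer(0); ej <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb_key <- (coords[, 1] + offs[o, 1]) +
      4096 * ((coords[, 2] + offs[o, 2]) + 4096 * (coords[, 3] + offs[o, 3]))
    hit <- match(nb_key, key)
    ok <- !is.na(hit)
    ei <- c(ei, which(ok)); ej <- c(ej, hit[ok])
  }
  # nearest-intensity neighbors via the sorted order
  ord <- order(intensities)
  rank <- integer(n); rank[ord] <- seq_len(n)
  m <- min(m_intensity, n - 1L)
  for (s in seq_len(m)) {
    lo <- seq_len(n - s)
    ei <- c(ei, ord[lo]); ej <- c(ej, ord[lo + s])
  }
  both_i <- c(ei, ej); both_j <- c(ej, ei)
  keep <- !duplicated(both_i + n * both_j) & both_i != both_j
  i <- both_i[keep]; j <- both_j[keep]
  w <- exp(-((intensities[i] - intensities[j])^2) / sigma^2)
  W <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  d <- Matrix::rowSums(W)
  if (any(d == 0)) {
    # isolated nodes: reconnect to the nearest spatial neighbor
    iso <- which(d == 0)
    message(sprintf("reconnecting %d isolated node(s)", length(iso)))
    for (v in iso) {
      dd <- rowSums(sweep(coords, 2, coords[v, ])^2)
      dd[v] <- Inf
      u <- which.min(dd)
      w0 <- exp(-((intensities[v] - intensities[u])^2) / sigma^2)
      W[v, u] <- w0; W[u, v] <- w0
    }
    d <- Matrix::rowSums(W)
  }
  inv <- Matrix::Diagonal(x = 1 / sqrt(d))
  S <- inv %*% W %*% inv
  list(W = W, S = S, d = d, mode = "sparse")
}

#' Propagate a label coding over the affinity graph
#'
#' Iterates `L^(n+1) = (1 - beta) S L^(n) + beta P` from `L^(0) = P` until
#' the max-abs change falls below `tol` (or `max_iter`); the fixed point
#' is `beta (I - (1 - beta) S)^-1 P`, which the direct route computes by a
#' linear solve for graphs up to `direct_cap` nodes.  Convergence is
#' guaranteed because the spectral radius of `(1 - beta) S` is below 1.
#'
#' @param S normalized affinity from [build_affinity()].
#' @param P an n x 2 label coding.
#' @param beta trade-off in (0, 1).
#' @param tol,max_iter stopping rule for the iterative route.
#' @param method `"auto"`, `"iterative"`, or `"direct"`.
#' @param direct_cap size cap for the direct solve under `"auto"`.
#' @return the converged n x 2 coding, with attributes `iterations`,
#'   `converged`, and `method`.
#' @export
propagate_labels <- function(S, P, beta, tol = 1e-6, max_iter = 1000L,
                             method = c("auto", "iterative", "direct"),
                             direct_cap = 512L) {
  method <- match.arg(method)
  stopifnot(beta > 0, beta < 1, is.matrix(P) || inherits(P, "Matrix"),
            ncol(P) == 2L)
  n <- nrow(P)
  if (method == "auto")
    method <- if (n <= direct_cap) "direct" else "iterative"
  if (method == "direct") {
    A <- diag(n) - (1 - beta) * as.matrix(S)
    L <- beta * solve(A, as.matrix(P))
    attr(L, "iterations") <- 0L
    attr(L, "converged") <- TRUE
    attr(L, "method") <- "direct"
    return(L)
  }
  L <- as.matrix(P)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    L2 <- (1 - beta) * as.matrix(S %*% L) + beta * P
    delta <- max(abs(L2 - L))
    L <- L2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("propagation did not converge in %d iterations", max_iter))
  attr(L, "iterations") <- it
  attr(L, "converged") <- converged
  attr(L, "method") <- "iterative"
  L
}

#' Binarize a propagated label coding
#'
#' Foreground iff the foreground coding strictly exceeds the background
#' coding; ties go to background.
#'
#' @param L an n x 2 coding.
#' @return integer 0/1 vector.
#' @export
binarize_coding <- function(L) {
  as.integer(L[, 1] > L[, 2])
}

#' Refine a probabilistic segmentation by label propagation
#'
#' Pipeline: encode the probabilities of the working region as a
#' two-column coding, apply information-balance weighting and
#' normalization of the reliable entries, build the intensity-affinity
#' graph on the target intensities of the graph nodes, propagate to
#' convergence, and binarize.  Voxels outside the node set keep their
#' thresholded input label (probability >= 0.5 is foreground).  With no
#' unreliable voxel there is nothing to refine and the thresholded input
#' is returned directly.
#'
#' @param prob_map a [volume()] of foreground probabilities.
#' @param target the target intensity [volume()].
#' @param box a [bounding_box()] delimiting the working region; `NULL`
#'   means the whole grid.
#' @param params an [sslp_params()].
#' @return a [label_volume()] with attribute `"sslp_info"` (node count,
#'   iterations, reliable counts).
#' @export
sslp_refine <- function(prob_map, target, box = NULL,
                        params = sslp_params()) {
  check_common_grid(list(prob_map, target), ids = c("prob_map", "target"))
  d <- dim(prob_map$data)
  if (is.null(box)) box <- bounding_box(c(0L, 0L, 0L), d)
  hard <- prob_map$data >= 0.5
  inbox <- box_mask(box, d)
  p_all <- prob_map$data
  P_all <- encode_probabilities(as.numeric(p_all))
  reliable <- array(pmax(P_all[, 1], P_all[, 2]) > params$T_rel, d)
  unreliable <- inbox & !reliable
  if (!any(unreliable)) {
    out <- label_volume(array(as.integer(hard), d),
                        spacing = prob_map$spacing)
    attr(out, "sslp_info") <- list(n_nodes = 0L, iterations = 0L)
    return(out)
  }
  node_mask <- if (params$graph_nodes == "box") inbox
  else unreliable | (reliable & inbox & dilate_mask(unreliable, 1L))
  nodes <- which(node_mask)
  coords <- arrayInd(nodes, d) - 1L
  P <- encode_probabilities(p_all[nodes])
  Pw <- balance_weighting(P, params$T_rel)
  n <- length(nodes)
  mode <- if (params$mode == "auto") {
    if (n <= params$dense_cap) "dense" else "sparse"
  } else params$mode
  g <- build_affinity(target$data[nodes], params$sigma, mode = mode,
                      coords = coords, m_intensity = params$m_intensity)
  L <- propagate_labels(g$S, Pw, params$beta, tol = params$tol,
                        max_iter = params$max_iter,
                        direct_cap = params$direct_cap)
  lab <- as.integer(hard)
  lab[nodes] <- binarize_coding(L)
  out <- label_volume(array(lab, d), spacing = prob_map$spacing)
  attr(out, "sslp_info") <- list(
    n_nodes = n, iterations = attr(L, "iterations"),
    reliable_counts = attr(Pw, "reliable_counts"), mode = g$mode)
  out
}

# binary dilation by a (2r+1)^3 cube, clamped at the border
dilate_mask <- function(mask, r = 1L) {
  out <- mask
  offs <- neighborhood_offsets(r)
  for (o in seq_len(nrow(offs))) {
    if (all(offs[o, ] == 0L)) next
    out <- out | shift_rep(mask, -as.integer(offs[o, ]))
  }
  out
}
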