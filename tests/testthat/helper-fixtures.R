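# Fixtures are built in code; nothing is read from disk except round-trip
# temporaries created by the io tests themselves.

rand_volume <- function(dim = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  volume(array(rnorm(prod(dim), mean = 100, sd = 20), dim), spacing = spacing)
}

rand_mask <- function(dim = c(12, 12, 12), n_fg = 30, seed = 1,
                      spacing = c(1, 1, 1)) {
  set.seed(seed)
  m <- array(0L, dim)
  m[sample(prod(dim), n_fg)] <- 1L
  label_volume(m, spacing = spacing)
}

# mask from explicit 0-based index ranges (inclusive)
box_label <- function(dim, lo, hi, spacing = c(1, 1, 1)) {
  m <- array(0L, dim)
  m[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
    (lo[3] + 1):(hi[3] + 1)] <- 1L
  label_volume(m, spacing = spacing)
}

# small synthetic subject shared by the fusion and pipeline tests;
# built once per test run
tiny_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- phantom_spec(shape = c(20, 20, 20), radii = c(5, 4, 4),
                        perturb_amp = 0.08, seed = 11)
      lib <- atlas_library_spec(n_atlases = 4, deform_amp = 1.5, seed = 12)
      p <- make_phantom(ph)
      cache <<- list(target = p$volume, truth = p$label,
                     atlases = make_atlas_library(p, lib))
    }
    cache
  }
})

tiny_patch <- function() patch_params(r_s = 1, r = 1)

# training set straight from matrices, bypassing image feature extraction
mk_training_set <- function(features, labels) {
  structure(list(features = features, labels = as.integer(labels),
                 provenance = data.frame(atlas = as.character(seq_along(labels)),
                                         i = 0L, j = 0L, k = 0L)),
            class = "training_set")
}

# --- independent oracles -------------------------------------------------

# NMI from scratch via table(): joint histogram, entropies in nats
oracle_nmi <- function(a, b, bins = 32L) {
  cut_idx <- function(v) {
    br <- seq(min(v), max(v), length.out = bins + 1L)
    pmin(pmax(findInterval(v, br, all.inside = TRUE), 1L), bins)
  }
  ia <- factor(cut_idx(a), levels = 1:bins)
  ib <- factor(cut_idx(b), levels = 1:bins)
  pj <- as.numeric(table(ia, ib)) / length(a)
  pa <- as.numeric(table(ia)) / length(a)
  pb <- as.numeric(table(ib)) / length(b)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (H(pa) + H(pb)) / H(pj)
}

# exhaustive double-loop surface distances (mm)
oracle_distance_metrics <- function(A, B) {
  surf <- function(M) {
    d <- dim(M$data)
    idx <- which(M$data == 1L, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- v; nb[ax] <- nb[ax] + s
        if (any(nb < 1L) || any(nb > d) ||
            M$data[nb[1], nb[2], nb[3]] == 0L) {
          keep[r] <- TRUE
        }
      }
    }
    sweep(idx[keep, , drop = FALSE] - 1L, 2, M$spacing, `*`)
  }
  sa <- surf(A); sb <- surf(B)
  dmin <- function(from, to) {
    vapply(seq_len(nrow(from)), function(i)
      sqrt(min(colSums((t(to) - from[i, ])^2))), numeric(1))
  }
  da <- dmin(sa, sb); db <- dmin(sb, sa)
  trim <- function(x) {
    drop <- min(ceiling(0.05 * length(x)), length(x) - 1L)
    if (drop > 0L) max(sort(x, decreasing = TRUE)[-seq_len(drop)]) else max(x)
  }
  c(md = mean(da), hd = max(max(da), max(db)),
    hd95 = max(trim(da), trim(db)), assd = (mean(da) + mean(db)) / 2,
    rmsd = sqrt((sum(da^2) + sum(db^2)) / (length(da) + length(db))))
}

# full exhaustive sort of all candidate distances, per class
oracle_balanced_subset <- function(features, labels, target, k) {
  d <- sqrt(colSums((t(features) - target)^2))
  pos <- which(labels == 1L)[order(d[labels == 1L])]
  neg <- which(labels == 0L)[order(d[labels == 0L])]
  list(pos = pos[seq_len(min(k, length(pos)))],
       neg = neg[seq_len(min(k, length(neg)))])
}

# traverse the forest's trees in R, one query at a time
oracle_tree_votes <- function(model, f) {
  vapply(model$trees, function(tr) {
    node <- 1L
    while (tr$feat[node] >= 0L) {
      node <- if (f[tr$feat[node] + 1L] <= tr$thr[node])
        tr$left[node] + 1L else tr$right[node] + 1L
    }
    tr$pred[node]
  }, integer(1))
}

# random graph + label coding for the propagation oracle
rand_sslp_instance <- function(n, seed) {
  set.seed(seed)
  intens <- runif(n, 0, 255)
  g <- build_affinity(intens, sigma = runif(1, 5, 40), mode = "dense")
  p <- runif(n)
  list(g = g, P = encode_probabilities(p), beta = runif(1, 0.3, 0.8))
}
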