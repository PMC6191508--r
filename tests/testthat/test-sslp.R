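test_that("probability encoding maps to the two-column coding", {
  P <- encode_probabilities(c(0.5, 0.9, 0, 1, 0.25))
  expect_equal(P[1, ], c(fg = 0, bg = 0))
  expect_equal(P[2, ], c(fg = 0.8, bg = 0), tolerance = 1e-12)
  expect_equal(P[3, ], c(fg = 0, bg = 1))
  expect_equal(P[4, ], c(fg = 1, bg = 0))
  expect_equal(P[5, ], c(fg = 0, bg = 0.5))
  expect_true(all(P >= 0))
  expect_error(encode_probabilities(c(0.2, 1.3)),
               class = "atlasfuse_bad_probability")
})

test_that("information-balance weighting reproduces the worked example", {
  # 100 reliable foreground rows, 300 reliable background rows at 0.8:
  # the weighted value (100/300) * 0.8 = 0.2667 is floored at T = 0.5
  P <- rbind(matrix(c(0.8, 0), 100, 2, byrow = TRUE),
             matrix(c(0, 0.8), 300, 2, byrow = TRUE))
  W <- balance_weighting(P, T_rel = 0.5, normalize = FALSE)
  expect_equal(unique(W[101:400, 2]), 0.5, tolerance = 1e-12)
  expect_equal(attr(W, "reliable_counts"), c(n_f = 100L, n_b = 300L))
  # foreground untouched by the background enhancement
  expect_equal(W[1:100, 1], P[1:100, 1])

  # equal reliable counts with equal background values: normalization
  # turns every reliable entry into exactly 1
  Q <- rbind(matrix(c(0.7, 0), 50, 2, byrow = TRUE),
             matrix(c(0, 0.6), 50, 2, byrow = TRUE))
  Wn <- balance_weighting(Q, T_rel = 0.5)
  expect_true(all(Wn[1:50, 1] == 1))
  expect_true(all(Wn[51:100, 2] == 1))
})

test_that("post-normalization reliable-class means equal one", {
  # more reliable foreground than background, so the weighted background
  # entries stay above the threshold and both sides get normalized
  set.seed(3)
  p <- c(runif(120, 0.8, 1), runif(40, 0, 0.2), runif(40, 0.3, 0.7))
  P <- encode_probabilities(p)
  W <- balance_weighting(P, T_rel = 0.5)
  expect_equal(mean(W[W[, 1] > 0.5, 1]), 1, tolerance = 1e-12)
  expect_equal(mean(W[W[, 2] > 0.5, 2]), 1, tolerance = 1e-12)

  # with many more reliable background rows the weighting floors every
  # reliable background entry at exactly T, and normalization skips the
  # then-empty strictly-above-threshold set
  p2 <- c(runif(20, 0.8, 1), runif(200, 0, 0.2))
  W2 <- balance_weighting(encode_probabilities(p2), T_rel = 0.5)
  expect_true(all(W2[21:220, 2] == 0.5))
})

test_that("weighting errors without reliable labels and stays monotone", {
  err <- expect_error(balance_weighting(encode_probabilities(rep(0.5, 10)),
                                        0.5),
                      class = "atlasfuse_no_reliable_labels")
  expect_match(conditionMessage(err), "foreground")

  # monotonicity of the background transform over the reliable range
  for (seed in 1:10) {
    set.seed(seed)
    n_f <- sample(5:200, 1)
    bg <- sort(runif(80, 0.51, 1))
    P <- rbind(cbind(runif(n_f, 0.6, 1), 0), cbind(0, bg))
    W <- balance_weighting(P, T_rel = 0.5)
    expect_true(all(diff(W[(n_f + 1):(n_f + 80), 2]) >= -1e-12))
  }
})

test_that("affinity weights follow the Gaussian kernel of intensity", {
  g <- build_affinity(c(10, 10, 30), sigma = 20, mode = "dense")
  expect_equal(g$W[1, 2], 1)            # equal intensities
  expect_equal(g$W[1, 3], exp(-1), tolerance = 1e-12)  # |dI| = sigma
  expect_equal(diag(g$W), rep(0, 3))
  expect_equal(g$W, t(g$W))

  set.seed(12)
  g5 <- build_affinity(runif(5, 0, 255), sigma = 10, mode = "dense")
  ev <- eigen(g5$S, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(abs(max(abs(ev)) - 1), 1e-8)
})

test_that("sparse affinity keeps symmetry and a unit spectral bound", {
  set.seed(13)
  coords <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  intens <- runif(64, 0, 255)
  g <- build_affinity(intens, sigma = 10, mode = "sparse", coords = coords,
                      m_intensity = 4)
  W <- as.matrix(g$W)
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_true(all(g$d > 0))
  ev <- eigen(as.matrix(g$S), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(ev)), 1 + 1e-8)
})

test_that("propagation agrees with the closed-form fixed point", {
  # no edges: the iteration lands on beta * P immediately
  P <- encode_probabilities(c(0.9, 0.1, 0.6))
  S0 <- matrix(0, 3, 3)
  L0 <- propagate_labels(S0, P, beta = 0.6, method = "iterative")
  expect_equal(unclass(L0)[, ], 0.6 * P, tolerance = 1e-9,
               ignore_attr = TRUE)

  # zero coding propagates to zero
  inst <- rand_sslp_instance(20, seed = 5)
  Lz <- propagate_labels(inst$g$S, matrix(0, 20, 2), beta = 0.5)
  expect_true(all(Lz == 0))

  for (seed in 1:10) {
    inst <- rand_sslp_instance(sample(10:50, 1), seed = seed)
    n <- nrow(inst$P)
    it <- propagate_labels(inst$g$S, inst$P, inst$beta, method = "iterative")
    closed <- inst$beta *
      solve(diag(n) - (1 - inst$beta) * inst$g$S, inst$P)
    expect_lt(max(abs(it - closed)), 1e-6)
    dir <- propagate_labels(inst$g$S, inst$P, inst$beta, method = "direct")
    expect_lt(max(abs(dir - closed)), 1e-10)
    expect_true(attr(it, "converged"))
  }
})

test_that("binarization is strict on the foreground column", {
  L <- rbind(c(0.7, 0.2), c(0.3, 0.3), c(0, 0.1))
  expect_identical(binarize_coding(L), c(1L, 0L, 0L))
})

test_that("refinement preserves a reliable map aligned with an edge", {
  d <- c(12, 12, 12)
  inten <- array(80, d)
  inten[7:12, , ] <- 160
  prob <- array(0, d)
  prob[7:12, , ] <- 1
  tgt <- volume(inten)
  out <- sslp_refine(volume(prob), tgt, params = sslp_params())
  expect_identical(out$data, array(as.integer(prob >= 0.5), d))
  expect_equal(attr(out, "sslp_info")$n_nodes, 0L)
})

test_that("refinement repairs weak salt-and-pepper flips", {
  sub <- tiny_subject()
  d <- dim(sub$truth$data)
  prob <- array(as.numeric(sub$truth$data), d)
  set.seed(21)
  fg <- which(sub$truth$data == 1L)
  bg <- which(sub$truth$data == 0L)
  flips_fg <- sample(fg, 8)
  flips_bg <- sample(bg, 8)
  prob[flips_fg] <- 0.45   # thresholds to background, wrongly
  prob[flips_bg] <- 0.55   # thresholds to foreground, wrongly
  noisy <- label_volume(array(as.integer(prob >= 0.5), d))
  dice_in <- overlap_metrics(sub$truth, noisy)["dice"]
  refined <- sslp_refine(volume(prob), sub$target, params = sslp_params())
  dice_out <- overlap_metrics(sub$truth, refined)["dice"]
  expect_gte(dice_out, dice_in)
  expect_gt(dice_out, 0.98)

  expect_error(sslp_refine(volume(array(0.5, d)), sub$target),
               class = "atlasfuse_no_reliable_labels")
})
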