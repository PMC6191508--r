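test_that("candidate assembly yields (2r+1)^3 samples per atlas", {
  lab1 <- label_volume(array(1L, c(8, 8, 8)))
  atl <- lapply(1:20, function(i)
    atlas_pair(rand_volume(c(8, 8, 8), seed = i), lab1, id = as.character(i)))
  ts <- assemble_candidates(atl, c(4, 4, 4), patch_params(r_s = 1, r = 1))
  expect_equal(nrow(ts$features), 540)  # 27 x 20
  expect_length(ts$labels, 540)
  expect_true(all(ts$labels == 1L))  # every neighborhood voxel is fg

  one <- assemble_candidates(atl[1], c(4, 4, 4), patch_params(r_s = 1, r = 0))
  expect_equal(nrow(one$features), 1)
  expect_equal(one$labels, 1L)
})

test_that("balanced subset selection matches the exhaustive sort", {
  for (case in 1:100) {
    set.seed(case)
    m <- sample(20:120, 1)
    p <- 10
    k <- sample(3:30, 1)
    feats <- matrix(rnorm(m * p), m, p)
    labs <- rbinom(m, 1, 0.5)
    if (length(unique(labs)) < 2) labs[1:2] <- c(0L, 1L)
    target <- rnorm(p)
    ts <- mk_training_set(feats, labs)
    got <- select_balanced_subset(ts, target, k)
    ora <- oracle_balanced_subset(feats, labs, target, k)
    expect_identical(got$features,
                     feats[c(ora$pos, ora$neg), , drop = FALSE])
    expect_identical(got$labels,
                     c(rep(1L, length(ora$pos)), rep(0L, length(ora$neg))))
  }
})

test_that("subset selection truncates scarce classes and flags degeneracy", {
  set.seed(9)
  feats <- matrix(rnorm(540 * 8), 540, 8)
  labs <- c(rep(1L, 40), rep(0L, 500))
  got <- select_balanced_subset(mk_training_set(feats, labs), rnorm(8), 100)
  expect_equal(sum(got$labels == 1L), 40)
  expect_equal(sum(got$labels == 0L), 100)
  expect_false(attr(got, "degenerate"))

  # a candidate identical to the target is always kept (distance 0)
  feats2 <- matrix(rnorm(50 * 8), 50, 8)
  labs2 <- rep(c(1L, 0L), 25)
  target <- feats2[7, ]
  got2 <- select_balanced_subset(mk_training_set(feats2, labs2), target, 3)
  expect_true(any(apply(got2$features, 1, identical, target)))

  only_fg <- select_balanced_subset(mk_training_set(feats2, rep(1L, 50)),
                                    target, 5)
  expect_true(attr(only_fg, "degenerate"))
  expect_equal(attr(only_fg, "present_class"), 1L)
})

test_that("forests separate separable data and are seed-deterministic", {
  set.seed(31)
  n <- 60; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(0L, 1L), each = n / 2)
  X[y == 1L, 1:3] <- X[y == 1L, 1:3] + 4
  ts <- mk_training_set(X, y)
  fit <- train_forest(ts, rf_params(n_tree = 25, n_split = 4, seed = 5))
  expect_equal(predict_probability(fit, X) >= 0.5, y == 1L)

  fit2 <- train_forest(ts, rf_params(n_tree = 25, n_split = 4, seed = 5))
  q <- matrix(rnorm(20 * p), 20, p)
  expect_identical(predict_probability(fit, q), predict_probability(fit2, q))

  fit3 <- train_forest(ts, rf_params(n_tree = 25, n_split = 4, seed = 6))
  expect_false(identical(fit$trees, fit3$trees))

  expect_error(train_forest(mk_training_set(X, rep(1L, n)), rf_params()),
               class = "atlasfuse_degenerate_training")
})

test_that("under permuted labels holdout accuracy hovers at chance", {
  set.seed(77)
  n <- 40; p <- 8
  acc <- replicate(100, {
    X <- matrix(rnorm(2 * n * p), 2 * n, p)
    y <- sample(rep(c(0L, 1L), n))  # labels independent of X
    fit <- train_forest(mk_training_set(X[1:n, ], y[1:n]),
                        rf_params(n_tree = 15, n_split = 3,
                                  seed = sample.int(1e6, 1)))
    ph <- predict_probability(fit, X[(n + 1):(2 * n), ]) >= 0.5
    mean(ph == (y[(n + 1):(2 * n)] == 1L))
  })
  expect_gt(mean(acc), 0.44)
  expect_lt(mean(acc), 0.56)
})

test_that("forest probability is the exact per-tree vote fraction", {
  set.seed(55)
  n <- 50; p <- 9
  X <- matrix(rnorm(n * p), n, p)
  y <- as.integer(X[, 1] + 0.4 * rnorm(n) > 0)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  fit <- train_forest(mk_training_set(X, y),
                      rf_params(n_tree = 20, n_split = 3, seed = 2))
  q <- matrix(rnorm(15 * p), 15, p)
  probs <- predict_probability(fit, q)
  votes <- predict_probability(fit, q, votes = TRUE)
  for (i in 1:15) {
    manual <- oracle_tree_votes(fit, q[i, ])
    expect_identical(as.integer(votes[i, ]), manual)
    expect_equal(probs[i], mean(manual))
  }
  expect_true(all(probs * 20 == round(probs * 20)))

  expect_error(predict_probability(fit, rnorm(p + 1)),
               class = "atlasfuse_dim_mismatch")
})

test_that("rf_segment short-circuits unanimity and stays on the vote lattice", {
  sub <- tiny_subject()
  d <- dim(sub$target$data)

  # atlases identical to the truth: nothing ambiguous, output is the label
  same <- lapply(1:4, function(i)
    atlas_pair(sub$target, sub$truth, id = as.character(i)))
  bb <- compute_bounding_box(list(sub$truth), margin = 3)
  vp0 <- majority_vote(rep(list(sub$truth), 4), bb)
  pm0 <- rf_segment(sub$target, same, vp0, tiny_patch(),
                    rf_params(n_tree = 10, seed = 4))
  expect_identical(array(as.integer(pm0$data >= 0.5), d), sub$truth$data)
  expect_equal(attr(pm0, "fusion_counts")[["ambiguous"]], 0L)

  # real fixture: probabilities live on the 1/n_tree lattice inside the
  # ambiguous set and at {0,1} elsewhere
  labs <- lapply(sub$atlases, `[[`, "label")
  bb <- compute_bounding_box(labs, margin = 3)
  vp <- majority_vote(labs, bb)
  pm <- rf_segment(sub$target, sub$atlases, vp, tiny_patch(),
                   rf_params(n_tree = 10, seed = 4))
  expect_true(all(pm$data >= 0 & pm$data <= 1))
  expect_true(all(abs(pm$data * 10 - round(pm$data * 10)) < 1e-9))
  expect_true(all(pm$data[vp$unanimous_fg] == 1))
  expect_true(all(pm$data[vp$unanimous_bg] == 0))
  expect_true(all(pm$data[!atlasfuse:::box_mask(bb, d)] == 0))
})

test_that("the fused fast path equals the composed per-voxel operations", {
  sub <- tiny_subject()
  labs <- lapply(sub$atlases, `[[`, "label")
  bb <- compute_bounding_box(labs, margin = 3)
  vp <- majority_vote(labs, bb)
  rfp <- rf_params(k = 10, n_tree = 10, n_split = 5, seed = 99)
  pm <- rf_segment(sub$target, sub$atlases, vp, tiny_patch(), rfp)

  d <- dim(sub$target$data)
  amb <- which(vp$ambiguous)
  for (ai in amb[c(1, length(amb) %/% 2, length(amb))]) {
    x <- as.integer(arrayInd(ai, d)) - 1L
    cand <- assemble_candidates(sub$atlases, x, tiny_patch())
    f_x <- extract_feature_vector(sub$target, x, tiny_patch())
    sel <- select_balanced_subset(cand, f_x, rfp$k)
    vseed <- atlasfuse:::derive_voxel_seed(rfp$seed, ai - 1L)
    fit <- train_forest(sel, rf_params(k = rfp$k, n_tree = rfp$n_tree,
                                       n_split = rfp$n_split, seed = vseed))
    expect_identical(unname(predict_probability(fit, f_x)), pm$data[ai])
  }

  # bit-reproducible under a fixed seed
  pm2 <- rf_segment(sub$target, sub$atlases, vp, tiny_patch(), rfp)
  expect_identical(pm$data, pm2$data)
})
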