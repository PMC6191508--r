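test_that("bounding box dilates the label union and clips to the grid", {
  lab <- box_label(c(64, 64, 64), lo = c(10, 10, 10), hi = c(19, 19, 19))
  bb <- compute_bounding_box(list(lab), margin = 5)
  expect_equal(bb$lower, rep(5L, 3))
  expect_equal(bb$upper, rep(25L, 3))

  tight <- compute_bounding_box(list(lab), margin = 0)
  expect_equal(tight$lower, rep(10L, 3))
  expect_equal(tight$upper, rep(20L, 3))

  huge <- compute_bounding_box(list(lab), margin = 100)
  expect_equal(huge$lower, rep(0L, 3))
  expect_equal(huge$upper, rep(64L, 3))

  empty <- label_volume(array(0L, c(4, 4, 4)))
  expect_error(compute_bounding_box(list(empty)),
               class = "atlasfuse_empty_labels")
})

test_that("NMI matches an independent table()-based computation", {
  a <- rand_volume(c(8, 8, 8), seed = 21)
  set.seed(22)
  # independent permutation of the same intensities
  b <- volume(array(sample(a$data), dim(a$data)))
  nmi_ab <- normalized_mutual_information(a, b)
  expect_equal(nmi_ab, oracle_nmi(as.numeric(a$data), as.numeric(b$data)),
               tolerance = 1e-12)

  # identity and monotone (linear, gain > 0) rescaling both give 2
  expect_equal(normalized_mutual_information(a, a), 2, tolerance = 1e-12)
  resc <- volume(2.5 * a$data + 17)
  expect_equal(normalized_mutual_information(a, resc), 2, tolerance = 1e-12)
  # a shuffled copy carries far less mutual information than the image
  expect_lt(nmi_ab, 1.5)

  cst <- volume(array(7, c(8, 8, 8)))
  expect_message(val <- normalized_mutual_information(a, cst), "constant")
  expect_equal(val, 1)
})

test_that("atlas selection ranks by NMI with stable ties", {
  target <- rand_volume(c(8, 8, 8), seed = 30)
  lab <- label_volume(array(rep(0:1, length.out = 512), c(8, 8, 8)))
  lib <- lapply(1:35, function(i)
    atlas_pair(rand_volume(c(8, 8, 8), seed = 100 + i), lab,
               id = sprintf("a%02d", i)))
  top <- select_atlases(target, lib, n_select = 20)
  expect_length(top, 20)
  expect_true(all(diff(attr(top, "nmi")) <= 0))

  expect_warning(few <- select_atlases(target, lib[1:5], n_select = 20),
                 "fewer")
  expect_length(few, 5)

  # a library containing the target itself ranks it first
  lib2 <- append(lib[1:10], list(atlas_pair(target, lab, id = "self")), 4)
  top2 <- select_atlases(target, lib2, n_select = 3)
  expect_equal(top2[[1]]$id, "self")
})

test_that("majority voting partitions the box and counts votes exactly", {
  d <- c(10, 10, 10)
  base <- box_label(d, lo = c(3, 3, 3), hi = c(6, 6, 6))
  # 20 atlases: 13 vote an extra voxel foreground
  extra <- base
  extra$data[8, 8, 8] <- 1L
  labs <- c(rep(list(extra), 13), rep(list(base), 7))
  bb <- compute_bounding_box(labs, margin = 2)
  vp <- majority_vote(labs, bb)
  expect_equal(vp$vote$data[8, 8, 8], 0.65)
  expect_true(vp$ambiguous[8, 8, 8])
  expect_true(vp$unanimous_fg[4, 4, 4])
  expect_true(vp$unanimous_bg[1 + vp$box$lower[1], 1 + vp$box$lower[2],
                              1 + vp$box$lower[3]])

  # unanimity: identical atlases leave nothing ambiguous and MV recovers
  # the common label
  vp1 <- majority_vote(rep(list(base), 20), bb)
  expect_equal(sum(vp1$ambiguous), 0)
  expect_true(all(vp1$vote$data %in% c(0, 1)))
  expect_identical(mv_segmentation(vp1)$data, base$data)

  # vote map is invariant to atlas order
  set.seed(41)
  vp2 <- majority_vote(sample(labs), bb)
  expect_equal(vp2$vote$data, vp$vote$data)
})

test_that("vote partition masks are disjoint and cover the box", {
  for (seed in 1:5) {
    set.seed(seed)
    labs <- lapply(1:5, function(i) rand_mask(c(9, 9, 9), n_fg = 60,
                                              seed = seed * 10 + i))
    bb <- compute_bounding_box(labs, margin = 1)
    vp <- majority_vote(labs, bb)
    total <- vp$unanimous_fg + vp$unanimous_bg + vp$ambiguous
    inbox <- atlasfuse:::box_mask(bb, c(9, 9, 9))
    expect_true(all(total[inbox] == 1))
    expect_true(all(total[!inbox] == 0))
  }
})
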