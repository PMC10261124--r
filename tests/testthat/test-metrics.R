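test_that("IoU matrix matches brute-force voxel counting", {
  cubes <- shifted_cube_pair()
  iou <- instance_iou_matrix(cubes$gt, cubes$pred)
  expect_equal(iou["1", "1"], 1 / 3)   # |I| = 4, |U| = 12

  lab <- random_box_labels(c(12L, 12L, 12L), 4L, seed = 5)
  perm <- lab
  mx <- max(lab)
  perm[lab > 0] <- (mx + 1L) - lab[lab > 0]   # reversed labels
  iou2 <- instance_iou_matrix(lab, perm)
  for (g in rownames(iou2))
    expect_equal(sum(iou2[g, ] == 1), 1)

  disj <- array(0L, c(4, 4, 4)); disj[1, 1, 1] <- 1L
  disj2 <- array(0L, c(4, 4, 4)); disj2[4, 4, 4] <- 1L
  expect_true(all(instance_iou_matrix(disj, disj2) == 0))
  expect_error(instance_iou_matrix(lab, array(0L, c(4, 4, 4))), "shape")
})

test_that("threshold matching: shifted cube, one-to-one rule", {
  cubes <- shifted_cube_pair()
  iou <- instance_iou_matrix(cubes$gt, cubes$pred)
  m25 <- match_at_threshold(iou, 0.25)
  expect_identical(c(m25$tp, m25$fp, m25$fn), c(1L, 0L, 0L))
  m50 <- match_at_threshold(iou, 0.5)
  expect_identical(c(m50$tp, m50$fp, m50$fn), c(0L, 1L, 1L))

  # two predictions over one GT: exactly one TP, one FP
  gt <- array(0L, c(8, 8, 4)); gt[2:7, 2:7, ] <- 1L
  pr <- array(0L, c(8, 8, 4)); pr[2:4, 2:7, ] <- 1L; pr[5:7, 2:7, ] <- 2L
  m <- match_at_threshold(instance_iou_matrix(gt, pr), 0.25)
  expect_identical(c(m$tp, m$fp, m$fn), c(1L, 1L, 0L))
})

test_that("greedy matching equals exhaustive assignment on small fixtures", {
  for (seed in 1:6) {
    gt <- random_box_labels(c(14L, 14L, 14L), 5L, seed = seed)
    set.seed(seed + 100)
    f <- make_deformation_field(dim(gt), d = 4L, sigma = 1.2)
    pred <- apply_deformation(gt, f)
    pred <- remove_small(pred, 1L)
    iou <- instance_iou_matrix(gt, pred)
    if (nrow(iou) > 6 || ncol(iou) > 6) next
    for (t in c(0.25, 0.4, 0.6)) {
      greedy <- match_at_threshold(iou, t)$tp
      expect_identical(greedy, brute_best_matching(iou, t))
      expect_identical(greedy, match_at_threshold(iou, t, "optimal")$tp)
    }
  }
})

test_that("detection metrics: perfect, empty and closed-form cases", {
  lab <- random_box_labels(c(12L, 12L, 12L), 4L, seed = 3)
  rep <- detection_metrics(lab, lab)
  expect_equal(c(rep$mP, rep$mR, rep$mF1, rep$mAP), rep(100, 4))

  empty <- array(0L, dim(lab))
  rep0 <- detection_metrics(lab, empty)
  expect_equal(c(rep0$mP, rep0$mR, rep0$mF1), c(0, 0, 0))
  expect_message(rep_ee <- detection_metrics(empty, empty), "empty")
  expect_equal(rep_ee$mAP, 100)

  # 10 GT, 8 matched, 1 spurious prediction -> P 8/9, R 8/10, F1 16/19
  gt <- random_box_labels(c(24L, 24L, 24L), 10L, seed = 10)
  expect_identical(max(gt), 10L)
  pred <- gt
  pred[gt %in% c(9L, 10L)] <- 0L    # drop two
  pred[22:23, 22:23, 22:23] <- 11L  # spurious
  rep2 <- detection_metrics(gt, pred)
  expect_equal(rep2$mP, 100 * 8 / 9)
  expect_equal(rep2$mR, 100 * 8 / 10)
  expect_equal(rep2$mF1, 100 * 16 / 19)
  expect_equal(rep2$mAP, 100 * 8 / 11)  # TP/(TP+FP+FN) = 8/(8+1+2)
})

test_that("AJI: identity, emptiness, shifted cube, permutation invariance", {
  lab <- random_box_labels(c(12L, 12L, 12L), 4L, seed = 6)
  expect_equal(aji(lab, lab), 1)
  expect_equal(aji(lab, array(0L, dim(lab))), 0)

  cubes <- shifted_cube_pair()
  expect_equal(aji(cubes$gt, cubes$pred), 1 / 3)

  perm <- lab
  perm[lab > 0] <- (max(lab) + 1L) - lab[lab > 0]
  expect_equal(aji(lab, perm), 1)
  expect_true(aji(lab, perm) >= 0 && aji(lab, perm) <= 1)
})

test_that("F1 equals the harmonic mean of precision and recall per threshold", {
  gt <- random_box_labels(c(16L, 16L, 16L), 6L, seed = 12)
  set.seed(12)
  f <- make_deformation_field(dim(gt), d = 4L, sigma = 1)
  pred <- remove_small(apply_deformation(gt, f), 1L)
  rep <- detection_metrics(gt, pred)
  for (r in seq_len(nrow(rep$per_threshold))) {
    row <- rep$per_threshold[r, ]
    hm <- if (row$precision + row$recall > 0)
      2 * row$precision * row$recall / (row$precision + row$recall) else 0
    expect_equal(row$f1, hm, tolerance = 1e-9)
  }
})
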