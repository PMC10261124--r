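test_that("gradient map: constants, converging interiors, touching boundary", {
  vf <- array(2.5, c(8, 8, 8, 3))
  expect_true(all(abs(gradient_map(vf)) < 1e-12))

  # single nucleus: strictly negative inside, away from the boundary
  lab <- array(0L, c(20, 20, 20))
  co <- rasterize_ellipsoid(list(a = c(6, 6, 6), theta = c(0, 0, 0),
                                 center = c(9.5, 9.5, 9.5)), dim(lab))
  lab[co[, 1] + 20 * co[, 2] + 400 * co[, 3] + 1] <- 1L
  G <- gradient_map(generate_vector_field(lab))
  interior <- nucsplit3d:::erode3(lab > 0, se_ellipsoid(2, 2, 2))
  expect_true(all(G[interior] < 0))

  # two side-by-side nuclei: global maximum on the plane between them
  lab2 <- array(0L, c(24, 16, 16))
  lab2[2:11, 5:12, 5:12] <- 1L    # centroid x ~ 5.5 (0-based)
  lab2[12:21, 5:12, 5:12] <- 2L   # centroid x ~ 15.5
  G2 <- gradient_map(generate_vector_field(lab2))
  peak <- arrayInd(which.max(G2), dim(G2))
  expect_true(peak[1] %in% c(11L, 12L))

  # brute-force convolution oracle at one interior voxel
  vf2 <- generate_vector_field(lab2)
  sx <- c(-1, 0, 1); sm <- c(1, 2, 1)
  at <- c(8L, 8L, 8L)
  acc <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    acc <- acc + sx[i] * sm[j] * sm[k] *
      vf2[at[1] + i - 2L, at[2] + j - 2L, at[3] + k - 2L, 1]
  expect_equal(G2[at[1], at[2], at[3]],
               max(acc, local({
                 a2 <- 0
                 for (i in 1:3) for (j in 1:3) for (k in 1:3)
                   a2 <- a2 + sm[i] * sx[j] * sm[k] *
                     vf2[at[1] + i - 2L, at[2] + j - 2L, at[3] + k - 2L, 2]
                 a2
               }), local({
                 a3 <- 0
                 for (i in 1:3) for (j in 1:3) for (k in 1:3)
                   a3 <- a3 + sm[i] * sm[j] * sx[k] *
                     vf2[at[1] + i - 2L, at[2] + j - 2L, at[3] + k - 2L, 3]
                 a3
               })))
})

test_that("blob map thresholding follows the rectified difference", {
  mask <- array(c(TRUE, FALSE), c(6, 6, 6))
  G <- array(seq(-2, 2, length.out = 216), c(6, 6, 6))
  expect_identical(blob_map(mask, G, T_m = 3), mask)        # above max
  expect_true(!any(blob_map(mask, G, T_m = -3)))            # below min
  b <- blob_map(mask, G, T_m = 0)
  expect_identical(as.vector(b), as.vector(mask & G < 0))
  expect_error(blob_map(mask, array(0, c(2, 2, 2)), 1), "shape")
})

test_that("conditional erosion shrinks blobs into markers per the rules", {
  p <- seg_params(t_c = 200L, t_f = 60L)
  # below all thresholds: unchanged
  small <- array(FALSE, c(10, 10, 10)); small[4:6, 4:6, 4:6] <- TRUE
  mk <- conditional_erosion(small, p)
  expect_identical(mk > 0, small)

  # solid ball, eroded below t_c then t_f, stays nonempty
  ball <- array(FALSE, c(16, 16, 16))
  co <- rasterize_ellipsoid(list(a = c(5, 5, 5), theta = c(0, 0, 0),
                                 center = c(7, 7, 7)), dim(ball))
  ball[co[, 1] + 16 * co[, 2] + 256 * co[, 3] + 1] <- TRUE
  # brute count of integer points with x^2+y^2+z^2 < 25 (strict inequality)
  expect_equal(sum(ball), 485)
  mk2 <- conditional_erosion(ball, p)
  expect_gte(sum(mk2 > 0), 1)
  expect_lt(sum(mk2 > 0), 60)
  expect_identical(max(mk2), 1L)
  # oracle: direct iterative erosion with the same elements
  ref <- ball
  while (sum(ref) >= p$t_c) {
    er <- nucsplit3d:::erode3(ref, p$B_c)
    if (!any(er)) break
    ref <- er
  }
  while (sum(ref) >= p$t_f) {
    er <- nucsplit3d:::erode3(ref, p$B_f)
    if (!any(er)) break
    ref <- er
  }
  expect_identical(which(mk2 > 0), which(ref))

  # dumbbell: two balls joined by a thin bridge -> at least 2 markers
  db <- array(FALSE, c(30, 14, 14))
  for (ctr in list(c(6, 6.5, 6.5), c(22, 6.5, 6.5))) {
    co <- rasterize_ellipsoid(list(a = c(4.5, 4.5, 4.5), theta = c(0, 0, 0),
                                   center = ctr), dim(db))
    db[co[, 1] + 30 * co[, 2] + 30 * 14 * co[, 3] + 1] <- TRUE
  }
  db[7:23, 7:8, 7:8] <- TRUE
  mk3 <- conditional_erosion(db, seg_params(t_c = 300L, t_f = 100L))
  expect_gte(max(mk3), 2L)
})

test_that("watershed assigns each foreground voxel to the nearest basin", {
  # single marker, single component
  mask <- array(FALSE, c(12, 12, 12)); mask[3:10, 3:10, 3:10] <- TRUE
  mk <- array(0L, dim(mask)); mk[6, 6, 6] <- 1L
  seg <- watershed_split(mk, mask)
  expect_identical(seg > 0, mask)
  expect_identical(max(seg), 1L)

  # fused spheres, one seed each: labels split near the geometric middle
  fused <- array(FALSE, c(36, 18, 18))
  for (ctr in list(c(10, 8.5, 8.5), c(24, 8.5, 8.5))) {
    co <- rasterize_ellipsoid(list(a = c(8, 6, 6), theta = c(0, 0, 0),
                                   center = ctr), dim(fused))
    fused[co[, 1] + 36 * co[, 2] + 36 * 18 * co[, 3] + 1] <- TRUE
  }
  mk2 <- array(0L, dim(fused))
  mk2[11, 9, 9] <- 1L; mk2[25, 9, 9] <- 2L
  seg2 <- watershed_split(mk2, fused)
  for (k in 1:2) {
    ctr <- compute_centroids(seg2)[as.character(k), ]
    seeds <- rbind(c(10, 8, 8), c(24, 8, 8))
    d <- sqrt(rowSums(sweep(seeds, 2, ctr)^2))
    expect_identical(which.min(d), as.integer(k))
  }

  # marker-free component rescued as one instance
  mask3 <- array(FALSE, c(10, 10, 10))
  mask3[2:6, 2:6, 2:3] <- TRUE   # 50 voxels, no marker
  seg3 <- watershed_split(array(0L, dim(mask3)), mask3)
  expect_identical(max(seg3), 1L)
  expect_identical(sum(seg3 > 0), 50L)

  # markers outside the mask are clipped with a warning
  bad <- array(0L, dim(mask3)); bad[9, 9, 9] <- 5L
  expect_warning(watershed_split(bad, mask3), "clipped")
})

test_that("small-object removal follows the strict 20-voxel rule", {
  seg <- array(0L, c(10, 10, 10))
  seg[1:19 + 100] <- 1L           # 19 voxels
  expect_identical(max(remove_small(seg, 20L)), 0L)
  seg[1:20 + 300] <- 2L           # 20 voxels survive
  out <- remove_small(seg, 20L)
  expect_identical(max(out), 1L)
  expect_identical(sum(out > 0), 20L)
  expect_identical(remove_small(out, 20L), out)      # idempotent
  expect_identical(remove_small(seg, 0L), seg)       # disabled filter
})

test_that("segment_instances: partition property and empty input", {
  expect_identical(max(segment_instances(array(0, c(8, 8, 8)),
                                         array(0, c(8, 8, 8, 3)))), 0L)
  fx <- make_fixture("dense", c(48L, 48L, 48L), seed = 2)
  seg <- segment_instances(fx$labels > 0, fx$vec, seg_params())
  expect_true(all(seg[fx$labels == 0L] == 0L))   # union within the mask
  # monotonicity: raising T_m weakly decreases carved voxels
  G <- gradient_map(fx$vec)
  carved_lo <- sum((fx$labels > 0) & !blob_map(fx$labels > 0, G, 40))
  carved_hi <- sum((fx$labels > 0) & !blob_map(fx$labels > 0, G, 80))
  expect_gte(carved_lo, carved_hi)
})
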