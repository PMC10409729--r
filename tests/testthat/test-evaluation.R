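test_that("contour extraction marks foreground pixels with background
           4-neighbours", {
  m <- matrix(0, 7, 7)
  m[3:5, 3:5] <- 1
  ct <- extractContour(m, spacing = 1)
  expect_equal(contourSize(ct), 8)           # all but the centre pixel
  expect_false(any(ct@pixels[, 1] == 4 & ct@pixels[, 2] == 4))
  # full-frame mask: border pixels only
  full <- extractContour(matrix(1, 6, 8), spacing = 1)
  expect_equal(contourSize(full), 2 * 6 + 2 * 8 - 4)
  # empty after threshold: flagged empty contour
  expect_equal(contourSize(extractContour(matrix(0.2, 5, 5))), 0)
  # erosion oracle on random blobs
  for (s in 1:5) {
    b <- random_blob(24, 30, seed = s)
    ct <- extractContour(b, spacing = 1)
    er <- b
    n1 <- nrow(b); n2 <- ncol(b)
    pad <- matrix(0, n1 + 2, n2 + 2)
    pad[2:(n1 + 1), 2:(n2 + 1)] <- b
    eroded <- pad[1:n1, 2:(n2 + 1)] * pad[3:(n1 + 2), 2:(n2 + 1)] *
      pad[2:(n1 + 1), 1:n2] * pad[2:(n1 + 1), 3:(n2 + 2)] * b
    oracle <- which(b - eroded == 1, arr.ind = TRUE)
    expect_equal(contourSize(ct), nrow(oracle))
    expect_setequal(paste(ct@pixels[, 1], ct@pixels[, 2]),
                    paste(oracle[, 1], oracle[, 2]))
  }
})

test_that("distance-map HD and MCD match the all-pairs oracle", {
  # identical contours
  b <- random_blob(20, 20, seed = 9)
  c1 <- extractContour(b, spacing = 1)
  expect_equal(hausdorffDistance(c1, c1), 0)
  expect_equal(meanContourDistance(c1, c1), 0)
  # two parallel segments one pixel apart at 0.8 mm spacing
  m1 <- matrix(0, 8, 8); m1[4, 2:7] <- 1
  m2 <- matrix(0, 8, 8); m2[5, 2:7] <- 1
  s1 <- extractContour(m1, spacing = 0.8)
  s2 <- extractContour(m2, spacing = 0.8)
  expect_equal(hausdorffDistance(s1, s2), 0.8)
  expect_equal(meanContourDistance(s1, s2), 0.8)
  # random pairs against the brute-force oracle
  for (s in 1:10) {
    a <- extractContour(random_blob(26, 32, seed = 100 + s), spacing = 0.8)
    b2 <- extractContour(random_blob(26, 32, seed = 200 + s), spacing = 0.8)
    ref <- brute_contour_metrics(a, b2)
    expect_equal(hausdorffDistance(a, b2), ref$hd, tolerance = 0.4)
    expect_equal(meanContourDistance(a, b2), ref$mcd, tolerance = 0.4)
    expect_gte(hausdorffDistance(a, b2), meanContourDistance(a, b2))
    # symmetry
    expect_equal(hausdorffDistance(a, b2), hausdorffDistance(b2, a))
    expect_equal(meanContourDistance(a, b2), meanContourDistance(b2, a))
  }
  expect_error(hausdorffDistance(extractContour(matrix(0, 4, 4)), c1),
               "empty")
})

test_that("concentric circles are separated by their radius difference", {
  mk <- function(r) {
    g <- expand.grid(x = 1:60, y = 1:60)
    matrix(as.numeric((g$x - 30)^2 + (g$y - 30)^2 <= r^2), 60, 60)
  }
  ci <- extractContour(mk(12), spacing = 1)
  co <- extractContour(mk(17), spacing = 1)
  expect_equal(meanContourDistance(ci, co), 5, tolerance = 0.6)
})

test_that("pose errors are the L2 norms of the component differences", {
  expect_equal(unname(poseError(rigidTransform(), rigidTransform())),
               c(0, 0))
  est <- rigidTransform(rotation = c(3, 4, 0) * pi / 180)
  expect_equal(unname(poseError(est, rigidTransform())[1]), 5)
  est2 <- rigidTransform(translation = c(1, 2, 2))
  expect_equal(unname(poseError(est2, rigidTransform())[2]), 3)
})

test_that("sequence evaluation closes at the ground truth and reports
           per-frame rows", {
  px <- local_phantom()
  sm <- px$sample
  res <- evaluateSequence(sm, sm@gtPoses[3:6], frames = 3:6)
  expect_equal(nrow(res$perFrame), 4)
  expect_true(all(res$perFrame$mcdCTCT == 0))
  expect_true(all(res$perFrame$hdCTCT == 0))
  expect_true(all(res$perFrame$hdCTUS >= res$perFrame$mcdCTUS))
  expect_equal(res$summary$mean[res$summary$metric == "mcdCTCT"], 0)
  # frames without ground truth are skipped
  res2 <- evaluateSequence(sm, sm@gtPoses[c(3, 4)], frames = c(3, 99))
  expect_equal(nrow(res2$perFrame), 1)
})

test_that("an in-plane IS offset appears in the CT-CT distance and
           out-of-plane errors are under-reported by CT-US", {
  px <- local_phantom()
  sm <- px$sample
  sp <- voxelSpacing(px$ct)
  delta <- 2 * sp[3]                        # two voxels along IS
  off <- lapply(3:5, function(t)
    composeTransforms(rigidTransform(translation = c(0, 0, delta),
                                     centre = gridCentre(px$ct)),
                      sm@gtPoses[[t]]))
  res <- evaluateSequence(sm, off, frames = 3:5)
  # re-slicing oracle: contours of the two planes, brute-force distance
  t <- 3
  wEst <- resampleRigid(sm@ctMask, off[[1]], "nearest")
  wGt <- resampleRigid(sm@ctMask, sm@gtPoses[[t]], "nearest")
  cEst <- extractContour(voxels(wEst)[sm@slicePlaneRL, , ],
                         spacing = sp[2])
  cGt <- extractContour(voxels(wGt)[sm@slicePlaneRL, , ],
                        spacing = sp[2])
  ref <- brute_contour_metrics(cEst, cGt)
  expect_equal(res$perFrame$mcdCTCT[1], ref$mcd, tolerance = 1e-9)
  expect_gt(res$perFrame$mcdCTCT[1], 0)
  expect_lte(res$perFrame$mcdCTCT[1], delta + sp[2])
  # pure out-of-plane (RL) error: the 2D CT-US distance stays well
  # below the 3D displacement magnitude
  offRL <- lapply(3:5, function(t)
    composeTransforms(rigidTransform(translation = c(delta, 0, 0),
                                     centre = gridCentre(px$ct)),
                      sm@gtPoses[[t]]))
  resRL <- evaluateSequence(sm, offRL, frames = 3:5)
  expect_lt(median(resRL$perFrame$mcdCTUS), delta)
})
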