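ns <- asNamespace("SliceVolReg")

test_that("MIND agrees with the brute-force patch oracle", {
  set.seed(30)
  for (i in 1:5) {
    v <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
    expect_lt(max(abs(mindDescriptor(v) - brute_mind(v))), 1e-6)
  }
  # constant image: all channels 1 on the interior (zero-padded patches
  # touch the boundary ring only)
  mc <- mindDescriptor(array(3, c(7, 7, 7)))
  expect_equal(max(abs(mc[3:5, 3:5, 3:5, ] - 1)), 0)
  # per-voxel max channel is exactly 1 everywhere
  v <- array(rnorm(6^3), c(6, 6, 6))
  m <- mindDescriptor(v)
  expect_equal(max(abs(apply(m, 1:3, max) - 1)), 0)
  expect_true(all(m > 0 & m <= 1))
})

test_that("elementwise Dice hits its closed forms", {
  ones <- array(1, c(10, 10))
  zeros <- array(0, c(10, 10))
  expect_equal(elementwiseDice(ones, ones), 2 / (2 + 1e-6))
  expect_equal(elementwiseDice(ones, zeros), 0, tolerance = 1e-9)
  # binary x = y with fraction p of ones tends to p
  set.seed(31)
  x <- array(rbinom(400, 1, 0.3), c(20, 20))
  expect_equal(elementwiseDice(x, x), mean(x), tolerance = 1e-5)
})

test_that("feature loss reaches its degenerate values", {
  sp <- c(3.2, 3.2, 3.2)
  dm <- c(16L, 16L, 16L)
  Wid <- windowTransformSet(replicate(5, rigidTransform(
    centre = (dm - 1) / 2 * sp), simplify = FALSE))
  # all-ones maps, perfect alignment: -1 + O(eps)
  onesV <- featureMap(array(1, dm), spacing = sp)
  expect_equal(featureLoss(onesV, onesV, Wid), -2 / (2 + 1e-6),
               tolerance = 1e-9)
  # disjoint masks: 0
  a <- array(0, dm); a[2:4, , ] <- 1
  b <- array(0, dm); b[10:12, , ] <- 0   # empty fixed side
  expect_equal(featureLoss(featureMap(b, spacing = sp),
                           featureMap(a, spacing = sp), Wid), 0,
               tolerance = 1e-9)
  # Nw = 1 reduces to a single negated slice Dice
  W1 <- windowTransformSet(list(rigidTransform(centre = (dm - 1) / 2 * sp)))
  mid <- dm[1] %/% 2L + 1L
  v <- array(runif(prod(dm)), dm)
  f <- featureMap(v, spacing = sp)
  expect_equal(featureLoss(f, f, W1),
               -elementwiseDice(v[mid, , ], v[mid, , ]),
               tolerance = 1e-12)
})

test_that("image loss vanishes for identical inputs and is invariant to
           affine intensity remapping", {
  wp <- local_window_pair()
  px <- local_phantom()
  sp <- voxelSpacing(px$ct)
  dm <- dim(wp@movingCT)
  ctr <- (dm - 1) / 2 * sp
  Wid <- windowTransformSet(replicate(5, rigidTransform(centre = ctr),
                                      simplify = FALSE))
  # fixed window identical to the masked moving volume: loss 0
  masked <- wp@movingCT * pmin(pmax(wp@movingFmap, 0), 1)
  expect_equal(imageLoss(volume3D(masked, spacing = sp),
                         volume3D(wp@movingCT, spacing = sp),
                         featureMap(pmin(pmax(wp@movingFmap, 0), 1),
                                    spacing = sp), Wid),
               0, tolerance = 1e-12)
  # MIND is intensity-normalised: affine remap changes the loss < 5%
  l0 <- imageLoss(volume3D(wp@fixedUS, spacing = sp),
                  volume3D(wp@movingCT, spacing = sp),
                  featureMap(pmin(pmax(wp@movingFmap, 0), 1),
                             spacing = sp), Wid)
  l1 <- imageLoss(volume3D(2.5 * wp@fixedUS + 0.3, spacing = sp),
                  volume3D(2.5 * wp@movingCT + 0.3, spacing = sp),
                  featureMap(pmin(pmax(wp@movingFmap, 0), 1),
                             spacing = sp), Wid)
  expect_lt(abs(l1 - l0) / l0, 0.05)
  # composition oracle: warp + MIND + slice + mean-abs, assembled by hand
  set.seed(32)
  W <- windowTransformSet(replicate(5, rigidTransform(
    rotation = rnorm(3, 0, 0.05), translation = rnorm(3, 0, 2),
    centre = ctr), simplify = FALSE))
  li <- imageLoss(volume3D(wp@fixedUS, spacing = sp),
                  volume3D(wp@movingCT, spacing = sp),
                  featureMap(pmin(pmax(wp@movingFmap, 0), 1),
                             spacing = sp), W)
  mid <- dm[1] %/% 2L + 1L
  wmid <- resampleRigid(volume3D(masked, spacing = sp),
                        W@transforms[[3]], "linear")
  mW <- mindDescriptor(voxels(wmid))
  mF <- mindDescriptor(wp@fixedUS)
  ref <- mean(abs(mW[mid, , , ] - mF[mid, , , ]))
  expect_equal(li, ref, tolerance = 1e-10)
})

test_that("transform loss follows the printed magnitude/smoothness mix", {
  Wid <- windowTransformSet(replicate(5, rigidTransform(),
                                      simplify = FALSE))
  expect_equal(transformLoss(Wid), 0)
  # constant velocity: second differences vanish
  Wcv <- windowTransformSet(lapply(1:5, function(i)
    rigidTransform(translation = c(i, 0, 0))))
  ms <- vapply(1:5, function(i) sqrt(i^2), numeric(1))
  expect_equal(transformLoss(Wcv, refLength = 1), 0.01 * mean(ms))
  # random window against a loop oracle
  set.seed(33)
  W <- windowTransformSet(replicate(5, rand_transform(),
                                    simplify = FALSE))
  mats <- lapply(W@transforms, toMatrix, translationScale = 0.8)
  dist <- mean(vapply(mats, function(M) sqrt(sum((M - diag(4))^2)),
                      numeric(1)))
  sec <- vapply(2:4, function(i)
    sqrt(sum((mats[[i + 1]] + mats[[i - 1]] - 2 * mats[[i]])^2)),
    numeric(1))
  expect_equal(transformLoss(W, refLength = 0.8),
               0.01 * dist + 0.99 * mean(sec))
  expect_error(transformLoss(windowTransformSet(list(rigidTransform()))),
               "window")
})

test_that("the FIM loss combines its terms with the printed weights and
           is differentiable", {
  wp <- local_window_pair()
  px <- local_phantom()
  sp <- voxelSpacing(px$ct)
  dm <- dim(wp@movingCT)
  ctr <- (dm - 1) / 2 * sp
  Ifix <- volume3D(wp@fixedUS, spacing = sp)
  Imov <- volume3D(wp@movingCT, spacing = sp)
  Mfix <- featureMap(pmin(pmax(wp@fixedFmap, 0), 1), spacing = sp)
  Mmov <- featureMap(pmin(pmax(wp@movingFmap, 0), 1), spacing = sp)
  set.seed(34)
  W <- windowTransformSet(replicate(5, rigidTransform(
    rotation = rnorm(3, 0, 0.03), translation = rnorm(3, 0, 1.5),
    centre = ctr), simplify = FALSE))
  r <- fimLoss(Ifix, Imov, Mfix, Mmov, W)
  expect_equal(r$total,
               r$feature + 0.01 * r$image + 0.001 * r$transform,
               tolerance = 1e-12)
  # lambda ablation reduces the total to the feature term
  r0 <- fimLoss(Ifix, Imov, Mfix, Mmov, W,
                weights = fimWeights(lambda1 = 0, lambda2 = 0))
  expect_equal(r0$total, r0$feature)
  # gradient check against central differences
  rg <- fimLoss(Ifix, Imov, Mfix, Mmov, W, gradient = TRUE)
  p0 <- as.vector(vapply(W@transforms, function(t)
    c(t@rotation, t@translation), numeric(6)))
  idx <- c(1, 4, 9, 14, 21, 28)
  h <- 1e-4
  fd <- vapply(idx, function(i) {
    pp <- p0; pp[i] <- pp[i] + h
    pm <- p0; pm[i] <- pm[i] - h
    mk <- function(pv) windowTransformSet(lapply(1:5, function(k)
      rigidTransform(pv[(k - 1) * 6 + 1:3], pv[(k - 1) * 6 + 4:6],
                     centre = ctr)))
    (fimLoss(Ifix, Imov, Mfix, Mmov, mk(pp))$total -
       fimLoss(Ifix, Imov, Mfix, Mmov, mk(pm))$total) / (2 * h)
  }, numeric(1))
  an <- as.vector(t(rg$gradient))[idx]
  expect_lt(max(abs(fd - an)) / max(abs(fd)), 1e-2)
})

test_that("perfectly aligned identical-modality pairs sit at the global
           optimum", {
  # all-ones masks, identity window: Lf ~ -1, Li ~ 0, Ld = 0
  dm <- c(16L, 16L, 16L)
  sp <- c(1, 1, 1)
  ctr <- (dm - 1) / 2
  set.seed(35)
  tex <- array(runif(prod(dm), 0.5, 1), dm)
  ones <- featureMap(array(1, dm), spacing = sp)
  Wid <- windowTransformSet(replicate(5, rigidTransform(centre = ctr),
                                      simplify = FALSE))
  r <- fimLoss(volume3D(tex, spacing = sp), volume3D(tex, spacing = sp),
               ones, ones, Wid)
  expect_equal(r$feature, -2 / (2 + 1e-6), tolerance = 1e-9)
  expect_equal(r$image, 0, tolerance = 1e-12)
  expect_equal(r$transform, 0, tolerance = 1e-12)
  expect_equal(r$total, r$feature, tolerance = 1e-9)
})

test_that("the FIM landscape dips at the true IS offset", {
  # noise-free phantom pair: sweep IS translation, minimum within 1 voxel
  wp <- local_window_pair()
  px <- local_phantom()
  sp <- voxelSpacing(px$ct)
  dm <- dim(wp@movingCT)
  ctr <- (dm - 1) / 2 * sp
  Ifix <- volume3D(wp@fixedUS, spacing = sp)
  Imov <- volume3D(wp@movingCT, spacing = sp)
  Mfix <- featureMap(pmin(pmax(wp@fixedFmap, 0), 1), spacing = sp)
  Mmov <- featureMap(pmin(pmax(wp@movingFmap, 0), 1), spacing = sp)
  offs <- seq(-8, 8, by = 1.6)
  losses <- vapply(offs, function(d) {
    W <- windowTransformSet(replicate(5, rigidTransform(
      translation = c(0, 0, d), centre = ctr), simplify = FALSE))
    fimLoss(Ifix, Imov, Mfix, Mmov, W)$total
  }, numeric(1))
  # the window pair is centroid pre-aligned, so truth is at ~0
  expect_lt(abs(offs[which.min(losses)]), sp[3] + 1e-9)
})

test_that("the feature term dominates the weighted image term at
           initialisation-scale misalignments", {
  wp <- local_window_pair()
  px <- local_phantom()
  sp <- voxelSpacing(px$ct)
  dm <- dim(wp@movingCT)
  ctr <- (dm - 1) / 2 * sp
  Ifix <- volume3D(wp@fixedUS, spacing = sp)
  Imov <- volume3D(wp@movingCT, spacing = sp)
  Mfix <- featureMap(pmin(pmax(wp@fixedFmap, 0), 1), spacing = sp)
  Mmov <- featureMap(pmin(pmax(wp@movingFmap, 0), 1), spacing = sp)
  set.seed(36)
  dominates <- vapply(1:10, function(i) {
    W <- windowTransformSet(replicate(5, rigidTransform(
      rotation = rnorm(3, 0, 0.1), translation = rnorm(3, 0, 3),
      centre = ctr), simplify = FALSE))
    r <- fimLoss(Ifix, Imov, Mfix, Mmov, W)
    abs(r$feature) > 0.01 * r$image
  }, logical(1))
  expect_gte(mean(dominates), 0.9)
})
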