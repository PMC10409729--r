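ns <- asNamespace("SliceVolReg")

test_that("transform distributions are fitted with sample statistics", {
  same <- replicate(5, rigidTransform(rotation = c(0.1, 0, 0),
                                      translation = c(1, 2, 3)),
                    simplify = FALSE)
  d <- fitTransformDistribution(same)
  expect_equal(d@sd, rep(0, 6))
  two <- list(rigidTransform(translation = c(0, 0, 2)),
              rigidTransform(translation = c(0, 0, 4)))
  d2 <- fitTransformDistribution(two)
  expect_equal(d2@mean[6], 3)
  expect_equal(d2@sd[6], sqrt(2))
  expect_error(fitTransformDistribution(two[1]), "two")
  # parameter recovery from 200 known-Gaussian draws
  set.seed(60)
  refs <- replicate(200, rigidTransform(
    rotation = rnorm(3, 0.02, 0.05), translation = rnorm(3, 1, 2)),
    simplify = FALSE)
  d3 <- fitTransformDistribution(refs)
  expect_lt(max(abs(d3@sd[4:6] - 2) / 2), 0.15)
  expect_lt(max(abs(d3@mean[4:6] - 1)), 3 * 2 / sqrt(200))
})

test_that("two-sigma sampling is truncated, unbiased and seeded", {
  d <- new("TransformDistribution", mean = c(1, -2, 0, 5, 0, -3),
           sd = c(2, 1, 0.5, 3, 0.1, 2))
  s1 <- sampleTransforms(d, 200, seed = 61)
  s2 <- sampleTransforms(d, 200, seed = 61)
  expect_identical(poseTable(s1), poseTable(s2))
  par <- t(vapply(s1, function(t) c(t@rotation * 180 / pi,
                                    t@translation), numeric(6)))
  for (j in 1:6) {
    expect_true(all(abs(par[, j] - d@mean[j]) <= 2 * d@sd[j] + 1e-9))
  }
  # zero-sd distribution collapses to the mean
  d0 <- new("TransformDistribution", mean = c(1, 2, 3, 4, 5, 6),
            sd = rep(0, 6))
  s0 <- sampleTransforms(d0, 3, seed = 62)
  expect_equal(s0[[1]]@translation, c(4, 5, 6))
  expect_equal(s0[[1]]@rotation * 180 / pi, c(1, 2, 3))
})

test_that("generated pairs close under their ground-truth transforms", {
  px <- local_phantom()
  wp <- local_window_pair()
  sp <- voxelSpacing(px$ct)
  aligned <- volume3D(wp@movingCT, spacing = sp)
  alignedF <- featureMap(pmin(pmax(wp@movingFmap, 0), 1), spacing = sp)
  dist <- groupATransformDistribution()
  pairs <- generateTrainingPairs(aligned, alignedF,
                                 volume3D(wp@fixedUS, spacing = sp),
                                 featureMap(pmin(pmax(wp@fixedFmap, 0), 1),
                                            spacing = sp),
                                 dist, Nt = 6, seed = 63)
  expect_length(pairs, 6)
  expect_true(attr(pairs, "resampled") >= 0)
  mid <- dim(wp@movingCT)[1] %/% 2L + 1L
  for (pr in pairs[1:3]) {
    restored <- resampleRigid(
      volume3D(pr@movingFmap, spacing = sp), pr@gtTransform, "linear")
    c1 <- extractContour(voxels(restored)[mid, , ] , spacing = sp[2])
    c2 <- extractContour(voxels(alignedF)[mid, , ], spacing = sp[2])
    expect_lt(meanContourDistance(c1, c2), sp[2])
  }
  # an identity-only distribution reproduces the aligned optimum
  d0 <- new("TransformDistribution", mean = rep(0, 6), sd = rep(0, 6))
  p0 <- generateTrainingPairs(aligned, alignedF,
                              volume3D(wp@fixedUS, spacing = sp),
                              featureMap(pmin(pmax(wp@fixedFmap, 0), 1),
                                         spacing = sp),
                              d0, Nt = 1, seed = 64)
  expect_equal(p0[[1]]@movingFmap, voxels(alignedF), tolerance = 1e-12)
})

test_that("pretraining descends, is seeded, and never reads the
           ground-truth poses", {
  px <- local_phantom()
  wp <- local_window_pair()
  sp <- voxelSpacing(px$ct)
  pairs <- generateTrainingPairs(
    volume3D(wp@movingCT, spacing = sp),
    featureMap(pmin(pmax(wp@movingFmap, 0), 1), spacing = sp),
    volume3D(wp@fixedUS, spacing = sp),
    featureMap(pmin(pmax(wp@fixedFmap, 0), 1), spacing = sp),
    groupATransformDistribution(), Nt = 4, seed = 65)
  cfg <- regNetConfig(maxTranslation = 4)
  model <- buildRegNet(cfg, seed = 8)
  # epochs = 0 leaves the model bitwise unchanged
  expect_identical(pretrainRegNet(model, pairs, epochs = 0L)@params,
                   model@params)
  m1 <- pretrainRegNet(model, pairs, epochs = 3L, seed = 66,
                       learningRate = 0.01, valFraction = 0)
  expect_equal(nrow(m1@lossHistory), 3)
  expect_lt(m1@lossHistory$train[3], m1@lossHistory$train[1])
  # seeded rerun reproduces the loss history exactly
  m2 <- pretrainRegNet(model, pairs, epochs = 3L, seed = 66,
                       learningRate = 0.01, valFraction = 0)
  expect_identical(m1@lossHistory, m2@lossHistory)
  # unsupervised contract: wiping the diagnostic gt changes nothing
  pairsWiped <- lapply(pairs, function(p) {
    p@gtTransform <- rigidTransform()
    p
  })
  m3 <- pretrainRegNet(model, pairsWiped, epochs = 3L, seed = 66,
                       learningRate = 0.01, valFraction = 0)
  expect_identical(m1@params, m3@params)
})

test_that("one-cycle transfer refines a copy for exactly two epochs", {
  px <- local_phantom()
  wp <- local_window_pair()
  cfg <- regNetConfig(maxTranslation = 4)
  model <- buildRegNet(cfg, seed = 9)
  tm <- oneCycleTransfer(model, list(wp, wp), epochs = 2L, seed = 67,
                         learningRate = 0.01)
  expect_equal(nrow(tm@lossHistory), 2)
  # the input model is untouched
  expect_identical(model@params[["head1.b"]],
                   numeric(30))
  # continued optimisation does not increase the loss on its own data
  l0 <- ns$regnet_fim_pass(model@params, cfg, wp, fimWeights(),
                           withGrad = FALSE)$loss
  l1 <- ns$regnet_fim_pass(tm@params, cfg, wp, fimWeights(),
                           withGrad = FALSE)$loss
  expect_lte(l1, l0 + 1e-3)
  expect_error(oneCycleTransfer(model, list()), "window")
})

test_that("respiration-cycle detection finds the second zero crossing", {
  # synthetic sinusoidal IS centroid trajectory, period 10
  mk <- function(shift) {
    m <- matrix(0, 8, 40)
    m[3:5, round(18 + shift)] <- 1
    m
  }
  fmaps <- lapply(1:30, function(t) mk(6 * sin(2 * pi * (t - 1) / 10)))
  n <- detectFirstCycle(fmaps)
  expect_true(abs(n - 11) <= 1)
  expect_equal(detectFirstCycle(fmaps, override = 7), 7L)
  expect_error(detectFirstCycle(fmaps[1:3]), "cycle")
})

test_that("sequence inference assigns middle-frame poses with the
           expected bookkeeping", {
  # static, aligned phantom: all poses near identity
  ph <- makeCTPhantom(phantomSpec(), seed = 21)
  resp <- respirationModel(translationAmplitude = c(0, 0, 0),
                           rotationAmplitude = c(0, 0, 0), period = 5)
  sm <- simulateUSSequence(ph$ct, ph$mask, resp, nFrames = 9,
                           noise = list(speckleSigma = 0, blurSigma = 0,
                                        gamma = 1), seed = 22)
  ctF <- featureMap(voxels(ph$mask), spacing = voxelSpacing(ph$mask),
                    modality = "CT")
  model <- buildRegNet(regNetConfig(), seed = 10)
  inf <- inferSequence(model, ph$ct, ctF, sm@usFrames, sm@usMasks)
  expect_length(inf$poses, 9 - 4)         # F - Nw + 1 posed frames
  expect_equal(inf$frames, 3:7)
  expect_length(inf$planes, 5)
  for (p in inf$poses) {
    pe <- poseError(p, rigidTransform(centre = p@centre))
    expect_lt(pe["translation"], max(voxelSpacing(ph$ct)))
    expect_lt(pe["rotation"], 1)
  }
  expect_error(inferSequence(model, ph$ct, ctF, sm@usFrames[1:3],
                             sm@usMasks[1:3]), "shorter")
})
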