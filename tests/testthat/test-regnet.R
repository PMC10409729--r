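ns <- asNamespace("SliceVolReg")

test_that("configuration enforces the printed translation-weight rule", {
  cfg <- regNetConfig()
  expect_equal(cfg@translationWeights, c(2, 1, 0.5, 0.25))
  expect_error(new("RegNetConfig", encoderFilters = c(8, 16, 16),
                   decoderFilters = c(16, 16, 16, 16, 8, 8),
                   nScales = 4L, scaleFactors = c(1 / 8, 1 / 4, 1 / 2, 1),
                   translationWeights = c(1, 1, 1, 1), Nw = 5L,
                   maxRotation = 0.5, maxTranslation = 16,
                   learningRate = 3e-4, inputDims = c(32L, 56L, 72L),
                   spacing = rep(3.2, 3), refLength = 3.2),
               "weights")
  expect_error(regNetConfig(inputDims = c(30L, 56L, 72L)), "divisible")
})

test_that("a zero-initialised head predicts the identity and a no-op
           warp", {
  cfg <- regNetConfig()
  model <- buildRegNet(cfg, seed = 1)
  set.seed(50)
  cf <- array(runif(prod(cfg@inputDims)), cfg@inputDims)
  uf <- array(runif(prod(cfg@inputDims)), cfg@inputDims)
  reg <- registerWindow(model, cf, uf)
  expect_equal(windowSize(reg$transforms), 5L)
  for (t in reg$transforms@transforms)
    expect_true(isIdentityTransform(t))
  expect_identical(reg$warped[[3]], cf)
  # all per-scale tanh outputs lie strictly inside (-1, 1) pre-scaling
  tape <- ns$td_tape()
  P <- ns$param_nodes(tape, model@params, leaf = FALSE)
  heads <- ns$regnet_graph(tape, P, cfg, ns$td_const(cf),
                           ns$td_const(uf))
  expect_length(heads, 4)
  for (h in heads) {
    expect_length(h$value, 30)
    expect_true(all(abs(h$value / rep(c(rep(cfg@maxRotation, 3),
                                        rep(cfg@maxTranslation, 3)),
                                      5)) < 1))
  }
  expect_error(registerWindow(model, array(0, c(16, 16, 16)), uf),
               "dims")
})

test_that("the parameter count matches the analytic layer-by-layer sum", {
  cfg <- regNetConfig()
  model <- buildRegNet(cfg, seed = 2)
  expect_equal(sum(vapply(model@params, length, integer(1))),
               regNetParameterCount(cfg))
})

test_that("hierarchical combination applies the printed weight rules", {
  cfg <- regNetConfig()
  # only the 1/8 scale predicts a unit translation -> 2 full-res voxels
  zero <- matrix(0, 5, 6)
  coarse <- zero; coarse[, 4] <- 1
  stack <- scaleTransformStack(list(coarse, zero, zero, zero))
  W <- combineHierarchical(stack, cfg)
  for (t in W@transforms)
    expect_equal(t@translation, c(2 * cfg@spacing[1], 0, 0))
  # equal rotations average to themselves
  rots <- zero; rots[, 1:3] <- rep(c(0.1, -0.2, 0.3), each = 5)
  stack2 <- scaleTransformStack(list(rots, rots, rots, rots))
  W2 <- combineHierarchical(stack2, cfg)
  for (t in W2@transforms)
    expect_equal(t@rotation, c(0.1, -0.2, 0.3))
  # random stacks against a loop oracle
  set.seed(51)
  for (i in 1:100) {
    mats <- replicate(4, matrix(rnorm(30), 5, 6), simplify = FALSE)
    W3 <- combineHierarchical(scaleTransformStack(mats), cfg)
    for (f in 1:5) {
      rot <- (mats[[1]][f, 1:3] + mats[[2]][f, 1:3] +
                mats[[3]][f, 1:3] + mats[[4]][f, 1:3]) / 4
      tr <- (2 * mats[[1]][f, 4:6] + 1 * mats[[2]][f, 4:6] +
               0.5 * mats[[3]][f, 4:6] + 0.25 * mats[[4]][f, 4:6]) *
        cfg@spacing
      expect_equal(W3@transforms[[f]]@rotation, rot, tolerance = 1e-12)
      expect_equal(W3@transforms[[f]]@translation, tr,
                   tolerance = 1e-12)
    }
  }
})

test_that("a coarse-scale translation induces the combined full-res
           displacement of the warped volume", {
  cfg <- regNetConfig()
  zero <- matrix(0, 5, 6)
  coarse <- zero; coarse[, 6] <- 1           # 1 coarse voxel along IS
  W <- combineHierarchical(scaleTransformStack(
    list(coarse, zero, zero, zero)), cfg)
  # expected displacement: 2 full-res voxels along IS
  v <- array(0, cfg@inputDims)
  v[13:20, 21:36, 30:45] <- 1
  vol <- volume3D(v, spacing = cfg@spacing)
  w <- resampleRigid(vol, W@transforms[[3]], "nearest")
  ref <- array(0, cfg@inputDims)
  ref[13:20, 21:36, 32:47] <- 1
  expect_equal(voxels(w), ref)
})

test_that("hierarchical combination converges faster than the
           single-scale ablation", {
  # fixed desk task: a misaligned training pair, same number of updates
  px <- local_phantom()
  wp <- local_window_pair()
  sp <- voxelSpacing(px$ct)
  pairs <- generateTrainingPairs(
    volume3D(wp@movingCT, spacing = sp),
    featureMap(pmin(pmax(wp@movingFmap, 0), 1), spacing = sp),
    volume3D(wp@fixedUS, spacing = sp),
    featureMap(pmin(pmax(wp@fixedFmap, 0), 1), spacing = sp),
    groupATransformDistribution(), Nt = 1, seed = 90)
  tp <- pairs[[1]]
  cfg <- regNetConfig(maxTranslation = 4)
  run <- function(scales, nsteps = 16) {
    model <- buildRegNet(cfg, seed = 7)
    params <- model@params
    st <- ns$adam_state(params)
    losses <- numeric(nsteps)
    for (i in seq_len(nsteps)) {
      ps <- ns$regnet_fim_pass(params, cfg, tp, fimWeights(),
                               scales = scales)
      upd <- ns$adam_step(params, ps$grads, st, lr = 0.02)
      params <- upd$params; st <- upd$state
      losses[i] <- ps$loss
    }
    losses
  }
  full <- run(1:4)
  single <- run(4L)
  expect_lt(tail(full, 1), tail(single, 1))
})
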