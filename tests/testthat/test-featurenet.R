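ns <- asNamespace("SliceVolReg")

desk_cfg <- function(dropout = 0.2)
  ulbnetConfig("CT", encoderFilters = c(4, 8, 16, 32, 64),
               patchShape = c(32, 48, 64), dropout = dropout,
               lbcFilters = 8L)

test_that("the fixed LBC filter bank is seeded, sparse and ternary", {
  b1 <- lbcFilterBank(8L, 0.5, seed = 42L)
  b2 <- lbcFilterBank(8L, 0.5, seed = 42L)
  expect_identical(b1, b2)
  expect_true(all(b1 %in% c(-1, 0, 1)))
  # expected 13.5 nonzeros per 3^3 filter; 99% binomial bounds
  nz <- apply(b1, 5, function(f) sum(f != 0))
  bounds <- qbinom(c(0.005, 0.995), 27, 0.5)
  expect_true(all(nz >= bounds[1] & nz <= bounds[2]))
  # zero input maps to zero output
  x <- array(0, c(6, 6, 6, 3))
  comb <- array(rnorm(8 * 3), c(1, 1, 1, 8, 3))
  expect_equal(max(abs(lbcLayer(x, b1, comb))), 0)
})

test_that("the network maps patches to same-shape probability maps", {
  cfg <- desk_cfg()
  net <- buildULBNet(cfg, seed = 1)
  set.seed(40)
  x <- array(runif(32 * 48 * 64), c(32, 48, 64))
  pr <- predictFeatureMap(net, x)
  expect_equal(dim(voxels(pr)), c(32, 48, 64))
  expect_true(all(voxels(pr) >= 0 & voxels(pr) <= 1))
  expect_true(all(is.finite(voxels(pr))))
  # US-style config never downsamples the time axis
  us <- ulbnetConfig("US", encoderFilters = c(4, 8, 16, 32, 64),
                     patchShape = c(32L, 48L, 5L))
  netus <- buildULBNet(us, seed = 1)
  prus <- predictFeatureMap(netus, array(runif(32 * 48 * 5),
                                         c(32, 48, 5)))
  expect_equal(dim(voxels(prus)), c(32, 48, 5))
  # indivisible patch shapes are rejected with a shape message
  expect_error(buildULBNet(ulbnetConfig("CT",
    encoderFilters = c(4, 8, 16, 32, 64), patchShape = c(30, 48, 64))),
    "divisible")
})

test_that("a residual block with zeroed branch weights is the identity", {
  set.seed(41)
  p <- ns$block_params("blk", 4, 4)
  for (nm in grep("conv", names(p), value = TRUE)) {
    p[[nm]] <- if (is.null(dim(p[[nm]]))) numeric(length(p[[nm]]))
               else array(0, dim(p[[nm]]))
  }
  tape <- ns$td_tape()
  P <- lapply(p, function(v) ns$td_const(v))
  x <- array(runif(6 * 6 * 6 * 4), c(6, 6, 6, 4))   # non-negative input
  y <- ns$res_block_graph(tape, P, "blk", ns$td_const(x))
  expect_equal(y$value, x)
})

test_that("tiling reproduces single-patch inference and preserves
           constant outputs", {
  cfg <- desk_cfg()
  net <- buildULBNet(cfg, seed = 2)
  set.seed(42)
  x <- array(runif(32 * 48 * 64), c(32, 48, 64))
  # volume equal to one patch: tiling = direct forward pass
  tape <- ns$td_tape()
  P <- ns$param_nodes(tape, net@params, leaf = FALSE)
  FX <- lapply(net@fixedFilters, ns$td_const)
  direct <- ns$ulbnet_graph(tape, P, FX, cfg, ns$td_const(x))$value
  dim(direct) <- dim(x)
  expect_equal(voxels(predictFeatureMap(net, x)), direct,
               tolerance = 1e-12)
  # constant-output model: zero all weights -> sigmoid(bias) everywhere;
  # overlapping-tile blending must preserve the constant
  net0 <- net
  net0@params <- lapply(net@params, function(p)
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p)))
  net0@params[["out.b"]] <- 0.4
  big <- array(runif(40 * 60 * 80), c(40, 60, 80))
  pr <- voxels(predictFeatureMap(net0, big))
  expect_lt(max(abs(pr - 1 / (1 + exp(-0.4)))), 1e-12)
})

test_that("training reduces the negative Dice and keeps its books", {
  px <- local_phantom()
  v <- voxels(px$ct)[, 5:52, 5:68]
  m <- voxels(px$mask)[, 5:52, 5:68]
  cfg <- desk_cfg()
  net <- buildULBNet(cfg, seed = 3)
  trained <- trainFeatureNet(net, list(v), list(m), epochs = 5,
                             seed = 4, learningRate = 1e-3)
  expect_length(trained@lossHistory, 5)
  expect_lt(trained@lossHistory[5], trained@lossHistory[1])
  expect_error(trainFeatureNet(net, list(v), list(array(0, dim(m)))),
               "empty|degenerate")
  expect_error(trainFeatureNet(net, list(), list(), epochs = 1),
               "empty")
})

test_that("integer shifts of input and mask barely change the Dice", {
  # convolutional equivariance smoke test on a lightly trained net
  px <- local_phantom()
  v <- voxels(px$ct)[, 5:52, 5:68]
  m <- voxels(px$mask)[, 5:52, 5:68]
  cfg <- desk_cfg(dropout = 0)
  net <- trainFeatureNet(buildULBNet(cfg, seed = 5), list(v), list(m),
                         epochs = 12, seed = 6, learningRate = 3e-3)
  dice0 <- segMetrics(voxels(predictFeatureMap(net, v)) >= 0.5,
                      m)["dice"]
  sh <- function(a) {
    out <- array(0, dim(a))
    out[, , 1:(dim(a)[3] - 4)] <- a[, , 5:dim(a)[3]]
    out
  }
  dice1 <- segMetrics(voxels(predictFeatureMap(net, sh(v))) >= 0.5,
                      sh(m))["dice"]
  expect_lt(abs(dice1 - dice0), 0.05)
})

test_that("segmentation metrics implement the printed formulas", {
  m <- array(0, c(10, 10, 2))
  m[1:5, , ] <- 1                     # |Y| = 100
  # |Y*| = 80 with |Y n Y*| = 60: 60 inside Y plus 20 outside
  p <- array(0, c(10, 10, 2))
  p[1:3, , ] <- 1                     # 60 inside Y
  p[6:7, , 1] <- 1                    # 20 outside Y
  sm <- segMetrics(p, m)
  expect_equal(unname(sm["dice"]), 2 * 60 / 180)
  expect_equal(unname(sm["sensitivity"]), 0.60)
  expect_equal(unname(sm["specificity"]), 0.75)
  expect_equal(unname(segMetrics(m, m)), c(1, 1, 1))
  d <- array(0, c(4, 4, 1)); d[1, 1, 1] <- 1
  e <- array(0, c(4, 4, 1)); e[4, 4, 1] <- 1
  expect_equal(unname(segMetrics(d, e)), c(0, 0, 0))
  expect_warning(res <- segMetrics(array(0, c(2, 2)), array(0, c(2, 2))),
                 "empty")
  expect_true(all(is.nan(res)))
})

test_that("models survive a save/load round trip bit-exactly", {
  net <- buildULBNet(desk_cfg(), seed = 9)
  f <- tempfile(fileext = ".rds")
  saveModel(net, f)
  back <- loadModel(f)
  expect_identical(back@fixedFilters, net@fixedFilters)
  expect_identical(back@params, net@params)
  expect_identical(back@config@lbcSeed, net@config@lbcSeed)
})
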