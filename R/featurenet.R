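## Feature networks: a 5-level residual U-Net with local binary
## convolution (LBC) skip layers, producing per-voxel kidney
## probability maps for CT volumes and 5-frame US windows. Trained on
## binary segmentation with a negative set-Dice loss.

#' Configuration of a feature U-Net
#'
#' @slot levels number of resolution levels (5).
#' @slot encoderFilters,decoderFilters per-level filter counts; the
#'   first decoder entry is the bottleneck width.
#' @slot dropout dropout rate at the bottleneck and decoder blocks.
#' @slot lbcFilters number of fixed ternary LBC filters per skip.
#' @slot lbcSparsity probability that an LBC filter tap is nonzero.
#' @slot lbcSeed seed of the fixed filter bank (serialised with the
#'   model).
#' @slot timeAxisDownsample FALSE for US configs: the third (time)
#'   axis is never pooled.
#' @slot patchShape input patch shape; axes that are downsampled must
#'   be divisible by 2^(levels - 1).
#' @slot learningRate Adam learning rate (1e-4).
#' @slot batchSize fixed at 1.
#' @slot modality "CT" or "US".
#' @export
setClass("ULBNetConfig",
  representation(levels = "integer", encoderFilters = "numeric",
                 decoderFilters = "numeric", dropout = "numeric",
                 lbcFilters = "integer", lbcSparsity = "numeric",
                 lbcSeed = "integer", timeAxisDownsample = "logical",
                 patchShape = "integer", learningRate = "numeric",
                 batchSize = "integer", modality = "character"))

setValidity("ULBNetConfig", function(object) {
  if (length(object@encoderFilters) != object@levels ||
      length(object@decoderFilters) != object@levels)
    return("encoder and decoder filter lists must have length = levels")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  if (object@lbcSparsity <= 0 || object@lbcSparsity > 1)
    return("lbcSparsity must be in (0, 1]")
  if (length(object@patchShape) != 3L)
    return("patchShape must have length 3")
  TRUE
})

#' Construct a feature-network configuration
#'
#' Defaults follow the full-scale networks (encoder 16, 32, 64, 128,
#' 256; CT patches 160 x 160 x 80; US windows 256 x 192 x 5 with no
#' time-axis downsampling). Tests and desk-scale runs pass smaller
#' filter lists and patches.
#'
#' @param modality "CT" or "US".
#' @param encoderFilters,decoderFilters per-level filter counts.
#' @param patchShape input patch shape; default by modality.
#' @param dropout dropout rate (default 0.2).
#' @param lbcFilters,lbcSparsity,lbcSeed fixed LBC bank settings.
#' @param timeAxisDownsample default TRUE for CT, FALSE for US.
#' @param learningRate Adam learning rate (default 1e-4).
#' @return A [ULBNetConfig-class].
#' @export
ulbnetConfig <- function(modality = c("CT", "US"),
                         encoderFilters = c(16, 32, 64, 128, 256),
                         decoderFilters = rev(encoderFilters),
                         patchShape = NULL,
                         dropout = 0.2, lbcFilters = 8L,
                         lbcSparsity = 0.5, lbcSeed = 42L,
                         timeAxisDownsample = NULL,
                         learningRate = 1e-4) {
  modality <- match.arg(modality)
  if (is.null(patchShape))
    patchShape <- if (modality == "CT") c(160L, 160L, 80L)
                  else c(256L, 192L, 5L)
  if (is.null(timeAxisDownsample)) timeAxisDownsample <- modality == "CT"
  new("ULBNetConfig", levels = 5L,
      encoderFilters = encoderFilters, decoderFilters = decoderFilters,
      dropout = dropout, lbcFilters = as.integer(lbcFilters),
      lbcSparsity = lbcSparsity, lbcSeed = as.integer(lbcSeed),
      timeAxisDownsample = timeAxisDownsample,
      patchShape = as.integer(patchShape), learningRate = learningRate,
      batchSize = 1L, modality = modality)
}

#' A feature U-Net model
#'
#' @slot config the [ULBNetConfig-class].
#' @slot params named list of trainable parameter arrays.
#' @slot fixedFilters per-level fixed ternary LBC filter banks
#'   (non-trainable, seeded).
#' @slot lossHistory per-epoch training loss.
#' @export
setClass("ULBNet",
  representation(config = "ULBNetConfig", params = "list",
                 fixedFilters = "list", lossHistory = "numeric"))

setMethod("show", "ULBNet", function(object) {
  cat(sprintf("ULBNet (%s): %d levels, filters %s, %d parameters\n",
              object@config@modality, object@config@levels,
              paste(object@config@encoderFilters, collapse = "/"),
              sum(vapply(object@params, length, integer(1)))))
})

## ---------------------------------------------------------------------
## construction

he_init <- function(k, cin, cout) {
  array(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
        dim = c(k, k, k, cin, cout))
}

#' Fixed sparse ternary LBC filter bank
#'
#' Each of `nFilters` 3x3x3 filters has taps that are nonzero with
#' probability `sparsity` and take values -1 or +1 with equal
#' probability. The bank is deterministic given `seed` and is stored
#' (not trained) with the model.
#'
#' @param nFilters number of filters.
#' @param sparsity nonzero probability per tap.
#' @param seed RNG seed.
#' @return array `[3, 3, 3, 1, nFilters]`.
#' @export
lbcFilterBank <- function(nFilters = 8L, sparsity = 0.5, seed = 42L) {
  with_seed(seed, {
    nz <- array(runif(27 * nFilters) < sparsity,
                dim = c(3, 3, 3, 1, nFilters))
    sg <- array(sign(runif(27 * nFilters) - 0.5),
                dim = c(3, 3, 3, 1, nFilters))
    nz * sg
  })
}

## parameter set of one residual block; the identity skip is projected
## only when the channel counts differ (or the block downsamples)
block_params <- function(prefix, cin, cout, proj = cin != cout) {
  p <- list()
  p[[paste0(prefix, ".conv1.w")]] <- he_init(3, cin, cout)
  p[[paste0(prefix, ".conv1.b")]] <- numeric(cout)
  p[[paste0(prefix, ".n1.g")]] <- rep(1, cout)
  p[[paste0(prefix, ".n1.b")]] <- numeric(cout)
  p[[paste0(prefix, ".conv2.w")]] <- he_init(3, cout, cout)
  p[[paste0(prefix, ".conv2.b")]] <- numeric(cout)
  p[[paste0(prefix, ".n2.g")]] <- rep(1, cout)
  p[[paste0(prefix, ".n2.b")]] <- numeric(cout)
  if (proj)
    p[[paste0(prefix, ".proj.w")]] <- he_init(1, cin, cout)
  p
}

ulbnet_down_stride <- function(cfg) {
  if (cfg@timeAxisDownsample) c(2L, 2L, 2L) else c(2L, 2L, 1L)
}

#' Build a feature U-Net
#'
#' Residual blocks are (conv - instance norm - ReLU) x 2 with an
#' additive identity skip (1x1x1 projection when the channel counts or
#' strides differ). Downsampling uses stride-2 convolutions in the
#' first conv of each encoder level; upsampling is nearest-neighbour.
#' Skip connections pass through an LBC layer (fixed ternary filters
#' on the channel mean, ReLU, zero-initialised trainable 1x1x1
#' combination added residually). The output layer is a 1x1x1
#' convolution with sigmoid activation.
#'
#' @param cfg a [ULBNetConfig-class].
#' @param seed RNG seed for the trainable-parameter initialisation.
#' @return An untrained [ULBNet-class].
#' @export
buildULBNet <- function(cfg, seed = 1L) {
  validObject(cfg)
  ds <- ulbnet_down_stride(cfg)
  ndown <- 2^(cfg@levels - 1L)
  bad <- (cfg@patchShape %% ndown != 0L) & (ds == 2L)
  if (any(bad))
    stop(sprintf(
      "patch shape (%s) must be divisible by %d on downsampled axes",
      paste(cfg@patchShape, collapse = "x"), ndown))
  f <- cfg@encoderFilters
  dfl <- cfg@decoderFilters
  L <- cfg@levels
  params <- with_seed(seed, {
    p <- block_params("enc1", 1, f[1])
    for (l in 2:L)
      p <- c(p, block_params(paste0("enc", l), f[l - 1], f[l],
                             proj = TRUE))         # strided skip
    prevc <- f[L]
    for (l in (L - 1):1) {
      dc <- dfl[L - l + 1L]
      p <- c(p, block_params(paste0("dec", l), prevc + f[l], dc))
      ## zero-initialised trainable LBC combination (bias-free)
      p[[paste0("lbc", l, ".w")]] <-
        array(0, dim = c(1, 1, 1, cfg@lbcFilters, f[l]))
      prevc <- dc
    }
    p[["out.w"]] <- he_init(1, prevc, 1)
    p[["out.b"]] <- 0
    p
  })
  fixed <- lapply((L - 1):1, function(l)
    lbcFilterBank(cfg@lbcFilters, cfg@lbcSparsity, cfg@lbcSeed + l))
  names(fixed) <- paste0("lbc", (L - 1):1)
  new("ULBNet", config = cfg, params = params, fixedFilters = fixed,
      lossHistory = numeric(0))
}

## ---------------------------------------------------------------------
## forward graph

res_block_graph <- function(tape, P, prefix, x, stride = c(1L, 1L, 1L)) {
  g <- function(nm) P[[paste0(prefix, ".", nm)]]
  y <- td_conv3d(tape, x, g("conv1.w"), g("conv1.b"), stride)
  y <- td_relu(tape, td_instnorm(tape, y, g("n1.g"), g("n1.b")))
  y <- td_conv3d(tape, y, g("conv2.w"), g("conv2.b"))
  y <- td_instnorm(tape, y, g("n2.g"), g("n2.b"))
  s <- if (!is.null(g("proj.w"))) {
    zb <- td_const(numeric(dim(g("proj.w")$value)[5]))
    td_conv3d(tape, x, g("proj.w"), zb, stride)
  } else x
  td_relu(tape, td_add(tape, y, s))
}

#' Apply a local binary convolution layer
#'
#' The channel mean of the input is convolved with the fixed ternary
#' filter bank, passed through ReLU, combined by a trainable bias-free
#' 1x1x1 convolution, and added to the input.
#'
#' @param x input array `[X, Y, Z, C]` (or a tape node).
#' @param bank fixed filter bank from [lbcFilterBank()].
#' @param combineW trainable combination weights
#'   `[1, 1, 1, nFilters, C]`.
#' @return same-shape array (or node).
#' @export
lbcLayer <- function(x, bank, combineW) {
  tape <- td_tape()
  node <- if (inherits(x, "td_node")) x else td_const(td_as4d(x))
  out <- lbc_graph(tape, node, td_const(bank), td_const(combineW))
  if (inherits(x, "td_node")) out else out$value
}

lbc_graph <- function(tape, x, bank, combineW) {
  m <- td_chan_mean(tape, x)
  h <- td_relu(tape, td_conv3d(tape, m, bank,
                               td_const(numeric(dim(bank$value)[5]))))
  comb <- td_conv3d(tape, h, combineW,
                    td_const(numeric(dim(combineW$value)[5])))
  td_add(tape, x, comb)
}

td_dropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) return(x)
  mask <- array(stats::rbinom(length(x$value), 1L, 1 - rate) /
                  (1 - rate), dim = dim(x$value))
  td_mul(tape, x, td_const(mask))
}

## Full U-Net graph: x is a [p1,p2,p3] node; returns the sigmoid map
## node of the same shape (single channel).
ulbnet_graph <- function(tape, P, FX, cfg, x, training = FALSE) {
  L <- cfg@levels
  ds <- ulbnet_down_stride(cfg)
  enc <- vector("list", L)
  enc[[1]] <- res_block_graph(tape, P, "enc1", x)
  for (l in 2:L)
    enc[[l]] <- res_block_graph(tape, P, paste0("enc", l), enc[[l - 1]],
                                stride = ds)
  h <- td_dropout(tape, enc[[L]], cfg@dropout, training)
  for (l in (L - 1):1) {
    h <- td_upsample_nn(tape, h, ds)
    skip <- lbc_graph(tape, enc[[l]], FX[[paste0("lbc", l)]],
                      P[[paste0("lbc", l, ".w")]])
    h <- td_concat_c(tape, list(h, skip))
    h <- res_block_graph(tape, P, paste0("dec", l), h)
    h <- td_dropout(tape, h, cfg@dropout, training)
  }
  out <- td_conv3d(tape, h, P[["out.w"]], P[["out.b"]])
  td_reshape(tape, td_sigmoid(tape, out), dim(out$value)[1:3])
}

## wrap params/fixed filters as nodes
param_nodes <- function(tape, params, leaf = TRUE) {
  mk <- if (leaf) function(v) td_leaf(tape, v) else td_const
  lapply(params, mk)
}

## ---------------------------------------------------------------------
## training and inference

soft_dice_graph <- function(tape, p, mask, eps = 1e-6) {
  num <- td_sadd(tape, td_smul(tape, td_sum(tape,
    td_mul(tape, p, td_const(mask))), 2), eps)
  den <- td_sadd(tape, td_sum(tape, p), sum(mask) + eps)
  td_div(tape, num, den)
}

#' Train a feature network on paired images and masks
#'
#' Optimises the negative set soft-Dice with Adam (batch size 1).
#' Deterministic given `seed`.
#'
#' @param net a [ULBNet-class].
#' @param images list of arrays (or [Volume3D-class]) matching the
#'   configured patch shape.
#' @param masks list of binary arrays of the same shapes.
#' @param epochs number of passes over the data.
#' @param seed RNG seed (shuffling and dropout).
#' @param learningRate Adam step size; default from the config.
#' @return The trained [ULBNet-class] with `lossHistory` extended by
#'   one mean loss per epoch.
#' @export
trainFeatureNet <- function(net, images, masks, epochs, seed = 1L,
                            learningRate = NULL) {
  if (length(images) == 0L) stop("empty training set")
  if (length(images) != length(masks))
    stop("images and masks must pair up")
  images <- lapply(images, function(v)
    if (is(v, "Volume3D")) v@voxels else v)
  masks <- lapply(masks, function(v)
    if (is(v, "Volume3D")) v@voxels else v)
  if (all(vapply(masks, function(m) sum(m) == 0, logical(1))))
    stop("all masks are empty: Dice is degenerate")
  cfg <- net@config
  lr <- learningRate %||% cfg@learningRate
  params <- net@params
  st <- adam_state(params)
  hist <- numeric(epochs)
  if (epochs > 0) with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(images))
      losses <- numeric(length(ord))
      for (j in seq_along(ord)) {
        i <- ord[j]
        tape <- td_tape()
        P <- param_nodes(tape, params)
        FX <- lapply(net@fixedFilters, td_const)
        p <- ulbnet_graph(tape, P, FX, cfg, td_const(images[[i]]),
                          training = TRUE)
        loss <- td_neg(tape, soft_dice_graph(tape, p, masks[[i]]))
        td_backward(tape, loss)
        grads <- lapply(P, function(nd) nd$grad)
        upd <- adam_step(params, grads, st, lr = lr)
        params <- upd$params
        st <- upd$state
        losses[j] <- loss$value
      }
      hist[ep] <- mean(losses)
    }
  })
  new("ULBNet", config = cfg, params = params,
      fixedFilters = net@fixedFilters,
      lossHistory = c(net@lossHistory, hist))
}

## tile start positions covering [1, n] with patches of size p
tile_starts <- function(n, p) {
  if (p >= n) return(1L)
  s <- seq(1L, n - p + 1L, by = max(1L, p %/% 2L))
  if (s[length(s)] != n - p + 1L) s <- c(s, n - p + 1L)
  s
}

#' Predict a feature map for a whole volume
#'
#' The volume is tiled into patches of the configured shape with 50%
#' overlap; patch predictions are blended with separable triangular
#' weights (a constant-output model therefore yields a constant map).
#' Volumes smaller than one patch are zero-padded and cropped back.
#'
#' @param net a [ULBNet-class].
#' @param vol a [Volume3D-class] or 3D array.
#' @return A [FeatureMap-class] on the input grid.
#' @export
predictFeatureMap <- function(net, vol) {
  v <- if (is(vol, "Volume3D")) vol@voxels else vol
  cfg <- net@config
  ps <- cfg@patchShape
  dm0 <- dim(v)
  dm <- pmax(dm0, ps)
  if (!identical(dm, dm0)) {
    vv <- array(0, dim = dm)
    vv[seq_len(dm0[1]), seq_len(dm0[2]), seq_len(dm0[3])] <- v
    v <- vv
  }
  acc <- array(0, dim = dm)
  wacc <- array(0, dim = dm)
  wpatch <- outer(outer(pmin(seq_len(ps[1]), rev(seq_len(ps[1]))),
                        pmin(seq_len(ps[2]), rev(seq_len(ps[2])))),
                  pmin(seq_len(ps[3]), rev(seq_len(ps[3]))))
  tape <- td_tape()
  P <- param_nodes(tape, net@params, leaf = FALSE)
  FX <- lapply(net@fixedFilters, td_const)
  for (sx in tile_starts(dm[1], ps[1]))
    for (sy in tile_starts(dm[2], ps[2]))
      for (sz in tile_starts(dm[3], ps[3])) {
        patch <- v[sx:(sx + ps[1] - 1L), sy:(sy + ps[2] - 1L),
                   sz:(sz + ps[3] - 1L)]
        pr <- ulbnet_graph(tape, P, FX, cfg, td_const(patch))$value
        dim(pr) <- ps
        ix <- sx:(sx + ps[1] - 1L); iy <- sy:(sy + ps[2] - 1L)
        iz <- sz:(sz + ps[3] - 1L)
        acc[ix, iy, iz] <- acc[ix, iy, iz] + pr * wpatch
        wacc[ix, iy, iz] <- wacc[ix, iy, iz] + wpatch
      }
  out <- acc / wacc
  out <- out[seq_len(dm0[1]), seq_len(dm0[2]), seq_len(dm0[3])]
  dim(out) <- dm0
  if (is(vol, "Volume3D"))
    featureMap(out, spacing = vol@spacing, origin = vol@origin,
               modality = cfg@modality)
  else
    featureMap(out, modality = cfg@modality)
}

#' Segmentation metrics (set Dice, sensitivity, specificity)
#'
#' Computed exactly as printed for a predicted mask Y* against ground
#' truth Y: Dice = 2|Y n Y*| / (|Y| + |Y*|), sensitivity =
#' |Y n Y*| / |Y|, specificity = |Y n Y*| / |Y*|.
#'
#' @param predMask,gtMask same-shape binary arrays (Y* and Y).
#' @return named numeric c(dice, sensitivity, specificity); all NaN
#'   (with a warning) when both masks are empty.
#' @export
segMetrics <- function(predMask, gtMask) {
  stopifnot(identical(dim(predMask), dim(gtMask)))
  ySz <- sum(gtMask > 0)
  pSz <- sum(predMask > 0)
  if (ySz == 0 && pSz == 0) {
    warning("both masks empty: metrics undefined")
    return(c(dice = NaN, sensitivity = NaN, specificity = NaN))
  }
  inter <- sum(predMask > 0 & gtMask > 0)
  c(dice = 2 * inter / (ySz + pSz),
    sensitivity = if (ySz > 0) inter / ySz else NaN,
    specificity = if (pSz > 0) inter / pSz else NaN)
}

#' Save / load a model
#'
#' Serialises the full model object (configuration, trainable
#' parameters and the fixed LBC filter banks) so a reloaded model is
#' bit-identical.
#'
#' @param model a [ULBNet-class] or [RegNet-class].
#' @param path file path (.rds).
#' @return `saveModel` returns `path` invisibly; `loadModel` returns
#'   the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
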