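## The 3D-2D registration network: an encoder-decoder CNN consuming
## the concatenated CT and US feature volumes, emitting one set of
## 6 Nw rigid transform parameters per decoder resolution scale
## through tanh-activated dense heads, combined hierarchically
## (rotations averaged, translations weighted by resolution) and
## applied through the differentiable rigid resampler.

#' Configuration of the registration network
#'
#' @slot encoderFilters filter counts of the stride-2 encoder convs
#'   (8, 16, 16).
#' @slot decoderFilters filter counts of the six decoder convs
#'   (16, 16, 16, 16, 8, 8); transforms are emitted after the 2nd,
#'   4th, 5th and 6th (scales 1/8, 1/4, 1/2, 1).
#' @slot nScales number of transform-emitting scales (4).
#' @slot scaleFactors resolutions of the emitting scales, coarsest
#'   first (1/8, 1/4, 1/2, 1).
#' @slot translationWeights per-scale translation weights
#'   (8, 4, 2, 1)/4 = (2, 1, 0.5, 0.25), coarsest first.
#' @slot Nw window size (5).
#' @slot maxRotation tanh output range for rotations, radians.
#' @slot maxTranslation tanh output range for translations, in voxels
#'   of the emitting scale.
#' @slot learningRate Adam step size (3e-4).
#' @slot inputDims canonical paired-volume dims.
#' @slot spacing voxel spacing of the canonical grid, mm.
#' @slot refLength reference length (mm) used by the transform-loss
#'   matrix norm.
#' @export
setClass("RegNetConfig",
  representation(encoderFilters = "numeric", decoderFilters = "numeric",
                 nScales = "integer", scaleFactors = "numeric",
                 translationWeights = "numeric", Nw = "integer",
                 maxRotation = "numeric", maxTranslation = "numeric",
                 learningRate = "numeric", inputDims = "integer",
                 spacing = "numeric", refLength = "numeric"))

setValidity("RegNetConfig", function(object) {
  if (length(object@encoderFilters) != 3L)
    return("encoderFilters must have length 3")
  if (length(object@decoderFilters) != 6L)
    return("decoderFilters must have length 6")
  if (length(object@translationWeights) != object@nScales)
    return("one translation weight per emitting scale is required")
  if (max(abs(object@translationWeights -
                (1 / object@scaleFactors) / 4)) > 1e-9)
    return("translation weights must equal (1/scaleFactors)/4")
  if (object@Nw %% 2L == 0L) return("Nw must be odd")
  dv <- 2^(object@nScales - 1L)
  if (any(object@inputDims %% dv != 0L))
    return(sprintf("input dims must be divisible by %d", dv))
  TRUE
})

#' Construct a registration-network configuration
#'
#' The defaults give the desk profile (canonical grid 32 x 56 x 72 at
#' 3.2 mm); pass `inputDims = c(128, 224, 288)` and
#' `spacing = rep(0.8, 3)` for the full profile.
#'
#' @param inputDims canonical paired-volume dims (RL, AP, IS).
#' @param spacing canonical voxel spacing, mm.
#' @param encoderFilters,decoderFilters conv filter counts.
#' @param Nw window size (odd, default 5).
#' @param maxRotation rotation range of the tanh heads, radians.
#' @param maxTranslation translation range, voxels at emitting scale.
#' @param learningRate Adam step size.
#' @param refLength reference length for the transform-loss norm; one
#'   voxel by default.
#' @return A [RegNetConfig-class].
#' @export
regNetConfig <- function(inputDims = c(32L, 56L, 72L),
                         spacing = c(3.2, 3.2, 3.2),
                         encoderFilters = c(8, 16, 16),
                         decoderFilters = c(16, 16, 16, 16, 8, 8),
                         Nw = 5L, maxRotation = 30 * pi / 180,
                         maxTranslation = 16,
                         learningRate = 3e-4, refLength = NULL) {
  sf <- c(1 / 8, 1 / 4, 1 / 2, 1)
  new("RegNetConfig", encoderFilters = encoderFilters,
      decoderFilters = decoderFilters, nScales = 4L, scaleFactors = sf,
      translationWeights = (1 / sf) / 4, Nw = as.integer(Nw),
      maxRotation = maxRotation, maxTranslation = maxTranslation,
      learningRate = learningRate, inputDims = as.integer(inputDims),
      spacing = as.numeric(spacing),
      refLength = refLength %||% spacing[1])
}

#' A registration-network model
#' @slot config the [RegNetConfig-class].
#' @slot params named list of trainable parameter arrays.
#' @slot lossHistory data.frame of per-epoch training/validation loss.
#' @export
setClass("RegNet",
  representation(config = "RegNetConfig", params = "list",
                 lossHistory = "data.frame"))

setMethod("show", "RegNet", function(object) {
  cat(sprintf(
    "RegNet: grid %s, Nw=%d, %d parameters, %d training epochs\n",
    paste(object@config@inputDims, collapse = "x"), object@config@Nw,
    sum(vapply(object@params, length, integer(1))),
    nrow(object@lossHistory)))
})

#' Per-scale transform predictions of the registration network
#'
#' @slot params list of nScales matrices `[Nw, 6]` (3 rotations in
#'   radians, 3 translations in voxels of that scale), coarsest first.
#' @slot scaleFactors resolutions, coarsest first.
#' @export
setClass("ScaleTransformStack",
  representation(params = "list", scaleFactors = "numeric"))

setValidity("ScaleTransformStack", function(object) {
  if (length(object@params) != length(object@scaleFactors))
    return("one parameter matrix per scale is required")
  nw <- vapply(object@params, nrow, integer(1))
  if (length(unique(nw)) != 1L)
    return("all scales must share the same Nw")
  TRUE
})

#' Construct a ScaleTransformStack
#' @param params list of `[Nw, 6]` matrices, coarsest scale first.
#' @param scaleFactors resolutions of the scales (default 1/8..1).
#' @return A [ScaleTransformStack-class].
#' @export
scaleTransformStack <- function(params,
                                scaleFactors = c(1 / 8, 1 / 4, 1 / 2,
                                                 1)) {
  new("ScaleTransformStack", params = params,
      scaleFactors = scaleFactors)
}

## ---------------------------------------------------------------------
## construction

#' Build a registration network
#'
#' Stride-2 convolutions encode the concatenated (CT, US) feature
#' pair to 1/8 resolution; the decoder convs (with encoder skip
#' concatenation and nearest-neighbour upsampling) emit a 6 Nw
#' parameter vector at each of the four scales through a global-
#' average-pool + dense head with tanh activation. The dense heads
#' are zero-initialised so the untrained network predicts the
#' identity transform exactly.
#'
#' @param cfg a [RegNetConfig-class].
#' @param seed RNG seed for conv initialisation.
#' @return An untrained [RegNet-class].
#' @export
buildRegNet <- function(cfg, seed = 1L) {
  validObject(cfg)
  ef <- cfg@encoderFilters
  df <- cfg@decoderFilters
  np <- 6L * cfg@Nw
  headC <- c(df[2], df[4], df[5], df[6])
  params <- with_seed(seed, {
    p <- list(
      e1.w = he_init(3, 2, ef[1]), e1.b = numeric(ef[1]),
      e2.w = he_init(3, ef[1], ef[2]), e2.b = numeric(ef[2]),
      e3.w = he_init(3, ef[2], ef[3]), e3.b = numeric(ef[3]),
      d1.w = he_init(3, ef[3], df[1]), d1.b = numeric(df[1]),
      d2.w = he_init(3, df[1], df[2]), d2.b = numeric(df[2]),
      d3.w = he_init(3, df[2] + ef[2], df[3]), d3.b = numeric(df[3]),
      d4.w = he_init(3, df[3], df[4]), d4.b = numeric(df[4]),
      d5.w = he_init(3, df[4] + ef[1], df[5]), d5.b = numeric(df[5]),
      d6.w = he_init(3, df[5] + 2, df[6]), d6.b = numeric(df[6]))
    for (s in 1:4) {
      p[[paste0("head", s, ".W")]] <- matrix(0, np, headC[s])
      p[[paste0("head", s, ".b")]] <- numeric(np)
    }
    p
  })
  new("RegNet", config = cfg, params = params,
      lossHistory = data.frame())
}

#' Analytic parameter count of a registration network
#' @param cfg a [RegNetConfig-class].
#' @return integer: total trainable parameter count.
#' @export
regNetParameterCount <- function(cfg) {
  ef <- cfg@encoderFilters
  df <- cfg@decoderFilters
  conv <- function(cin, cout) 27 * cin * cout + cout
  np <- 6L * cfg@Nw
  heads <- c(df[2], df[4], df[5], df[6])
  sum(conv(2, ef[1]), conv(ef[1], ef[2]), conv(ef[2], ef[3]),
      conv(ef[3], df[1]), conv(df[1], df[2]),
      conv(df[2] + ef[2], df[3]), conv(df[3], df[4]),
      conv(df[4] + ef[1], df[5]), conv(df[5] + 2, df[6]),
      sum(heads * np + np))
}

## ---------------------------------------------------------------------
## forward graph

conv_relu <- function(tape, P, nm, x, stride = c(1L, 1L, 1L)) {
  td_relu(tape, td_conv3d(tape, x, P[[paste0(nm, ".w")]],
                          P[[paste0(nm, ".b")]], stride))
}

head_graph <- function(tape, P, s, x, cfg) {
  g <- td_gap(tape, x)
  v <- td_tanh(tape, td_dense(tape, g, P[[paste0("head", s, ".W")]],
                              P[[paste0("head", s, ".b")]]))
  ## scale tanh outputs: rotations to radians, translations to voxels
  ## of the emitting scale (frame-major layout: rot1..3, trans1..3)
  sc <- rep(c(rep(cfg@maxRotation, 3), rep(cfg@maxTranslation, 3)),
            cfg@Nw)
  td_mul(tape, v, td_const(sc))
}

## forward pass; returns list of 4 scaled head vectors ([6 Nw] nodes)
regnet_graph <- function(tape, P, cfg, ctFeat, usFeat) {
  s2 <- c(2L, 2L, 2L)
  x0 <- td_concat_c(tape, list(ctFeat, usFeat))
  x1 <- conv_relu(tape, P, "e1", x0, s2)
  x2 <- conv_relu(tape, P, "e2", x1, s2)
  x3 <- conv_relu(tape, P, "e3", x2, s2)
  h <- conv_relu(tape, P, "d1", x3)
  h <- conv_relu(tape, P, "d2", h)
  v1 <- head_graph(tape, P, 1L, h, cfg)
  h <- td_concat_c(tape, list(td_upsample_nn(tape, h, s2), x2))
  h <- conv_relu(tape, P, "d3", h)
  h <- conv_relu(tape, P, "d4", h)
  v2 <- head_graph(tape, P, 2L, h, cfg)
  h <- td_concat_c(tape, list(td_upsample_nn(tape, h, s2), x1))
  h <- conv_relu(tape, P, "d5", h)
  v3 <- head_graph(tape, P, 3L, h, cfg)
  h <- td_concat_c(tape, list(td_upsample_nn(tape, h, s2), x0))
  h <- conv_relu(tape, P, "d6", h)
  v4 <- head_graph(tape, P, 4L, h, cfg)
  list(v1, v2, v3, v4)
}

## hierarchical combination as graph nodes: returns per-frame theta
## nodes (rotations in radians, translations in mm). `scales` selects
## the emitting scales (all four by default; a single entry gives the
## non-hierarchical ablation).
combine_graph <- function(tape, heads, cfg, scales = seq_along(heads)) {
  S <- length(scales)
  wrot <- 1 / S
  comb <- NULL
  for (s in scales) {
    sc <- rep(c(rep(wrot, 3), cfg@translationWeights[s] * cfg@spacing),
              cfg@Nw)
    term <- td_mul(tape, heads[[s]], td_const(sc))
    comb <- if (is.null(comb)) term else td_add(tape, comb, term)
  }
  lapply(seq_len(cfg@Nw), function(i)
    td_slice_vec(tape, comb, (i - 1L) * 6L + 1:6))
}

#' Hierarchically combine per-scale transform predictions
#'
#' Rotation is scale invariant and is averaged across scales;
#' translation is inversely proportional to resolution and is combined
#' with weights (2, 1, 0.5, 0.25) from the 1/8 scale to full
#' resolution, yielding full-resolution voxel displacements that are
#' converted to mm through the canonical spacing.
#'
#' @param stack a [ScaleTransformStack-class].
#' @param cfg a [RegNetConfig-class].
#' @param centre rotation centre (mm) for the resulting transforms;
#'   default the canonical grid centre.
#' @return A [WindowTransformSet-class] (rotations radians,
#'   translations mm).
#' @export
combineHierarchical <- function(stack, cfg, centre = NULL) {
  validObject(stack)
  if (length(stack@params) != cfg@nScales)
    stop("stack scale count does not match the configuration")
  if (is.null(centre))
    centre <- (cfg@inputDims - 1) / 2 * cfg@spacing
  S <- cfg@nScales
  Nw <- nrow(stack@params[[1]])
  transforms <- lapply(seq_len(Nw), function(i) {
    rot <- Reduce(`+`, lapply(stack@params, function(m) m[i, 1:3])) / S
    tvox <- Reduce(`+`, lapply(seq_len(S), function(s)
      cfg@translationWeights[s] * stack@params[[s]][i, 4:6]))
    rigidTransform(rotation = rot, translation = tvox * cfg@spacing,
                   centre = centre)
  })
  windowTransformSet(transforms)
}

## head vectors (plain values) -> ScaleTransformStack
heads_to_stack <- function(heads, cfg) {
  scaleTransformStack(lapply(heads, function(v)
    matrix(v, nrow = cfg@Nw, ncol = 6L, byrow = TRUE)),
    cfg@scaleFactors)
}

#' Register one US window against the CT feature volume
#'
#' Runs the network forward on the (CT feature, US window feature)
#' pair, combines the per-scale predictions, and warps the CT feature
#' volume by each frame's transform. The returned transforms are
#' relative to the pre-aligned CT pose.
#'
#' @param model a [RegNet-class].
#' @param ctFeat CT feature volume ([FeatureMap-class] or array) on
#'   the canonical grid.
#' @param usFeat embedded US window feature volume on the same grid.
#' @param warpVolumes if FALSE, skip the per-frame warps and return
#'   only the transforms.
#' @return list(transforms = [WindowTransformSet-class],
#'   stack = [ScaleTransformStack-class], warped = list of Nw warped
#'   CT feature arrays (NULL when `warpVolumes` is FALSE)).
#' @export
registerWindow <- function(model, ctFeat, usFeat, warpVolumes = TRUE) {
  cfg <- model@config
  cf <- if (is(ctFeat, "Volume3D")) ctFeat@voxels else ctFeat
  uf <- if (is(usFeat, "Volume3D")) usFeat@voxels else usFeat
  if (!identical(dim(cf), cfg@inputDims) ||
      !identical(dim(uf), cfg@inputDims))
    stop("inputs must match the configured canonical dims")
  tape <- td_tape()
  P <- param_nodes(tape, model@params, leaf = FALSE)
  heads <- regnet_graph(tape, P, cfg, td_const(cf), td_const(uf))
  stack <- heads_to_stack(lapply(heads, function(h) h$value), cfg)
  W <- combineHierarchical(stack, cfg)
  warped <- NULL
  if (warpVolumes) {
    vol <- volume3D(cf, spacing = cfg@spacing)
    warped <- lapply(W@transforms, function(t)
      voxels(resampleRigid(vol, t, "linear")))
  }
  list(transforms = W, stack = stack, warped = warped)
}
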