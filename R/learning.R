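## Training strategy: truncated-Gaussian transform sampling fitted to
## reference alignments, training-pair generation by inverse-warping a
## reference CT, unsupervised pretraining of the registration network
## under the FIM loss, one-cycle transfer learning, and sequential
## inference over a breathing sequence.

#' One generated CT-US training pair
#'
#' The moving side is the reference CT (and feature map) warped by the
#' inverse of a sampled transform; the fixed side is the embedded US
#' window. `gtTransform` restores the reference alignment and is kept
#' for diagnostics only -- it never enters the training loss.
#'
#' @slot movingCT,movingFmap moving CT intensity / feature arrays.
#' @slot fixedUS,fixedFmap embedded US window intensity / feature
#'   arrays.
#' @slot mindFixMid precomputed MIND channels of the fixed middle
#'   slice `[AP, IS, 6]`.
#' @slot gtTransform diagnostic ground-truth [RigidTransform-class].
#' @slot prealign the centroid pre-alignment applied to the moving CT.
#' @export
setClass("TrainingPair",
  representation(movingCT = "array", movingFmap = "array",
                 fixedUS = "array", fixedFmap = "array",
                 mindFixMid = "array", gtTransform = "RigidTransform",
                 prealign = "RigidTransform"))

setMethod("show", "TrainingPair", function(object) {
  cat(sprintf("TrainingPair on %s grid\n",
              paste(dim(object@movingCT), collapse = "x")))
})

#' Fit a per-parameter transform distribution
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of
#' each of the 6 rigid parameters over a set of reference transforms,
#' for two-sigma truncated Gaussian sampling.
#'
#' @param referenceTransforms list of at least two
#'   [RigidTransform-class] objects.
#' @return A [TransformDistribution-class] (rotations in degrees,
#'   translations in mm).
#' @export
fitTransformDistribution <- function(referenceTransforms) {
  if (length(referenceTransforms) < 2L)
    stop("at least two reference transforms are required")
  m <- t(vapply(referenceTransforms, function(t)
    c(t@rotation * 180 / pi, t@translation), numeric(6)))
  new("TransformDistribution", mean = colMeans(m),
      sd = apply(m, 2, sd))
}

#' Group-A-like transform distribution from L2 magnitudes
#'
#' Converts target L2-norm magnitudes of the rotation and translation
#' component vectors into per-axis zero-mean Gaussian widths: for
#' three iid N(0, sigma) components the expected L2 norm is
#' sigma * 2 * sqrt(2 / pi) (chi distribution, 3 df), so
#' sigma = L2mean / 1.5958.
#'
#' @param rotL2Mean,transL2Mean target mean L2 norms (degrees, mm);
#'   defaults are the small-transformation group statistics (10.37
#'   degrees, 3.69 mm).
#' @return A [TransformDistribution-class].
#' @export
groupATransformDistribution <- function(rotL2Mean = 10.37,
                                        transL2Mean = 3.69) {
  chi3 <- 2 * sqrt(2 / pi)
  new("TransformDistribution", mean = numeric(6),
      sd = c(rep(rotL2Mean / chi3, 3), rep(transL2Mean / chi3, 3)))
}

#' Sample rigid transforms from a truncated Gaussian
#'
#' Parameter-wise independent Gaussian draws, redrawn by rejection
#' until every parameter lies within two standard deviations of its
#' mean (preserving the Gaussian shape inside the band).
#'
#' @param dist a [TransformDistribution-class].
#' @param Nt number of transforms.
#' @param seed RNG seed.
#' @param centre rotation centre (mm) of the returned transforms.
#' @return list of Nt [RigidTransform-class] objects.
#' @export
sampleTransforms <- function(dist, Nt, seed = 1L, centre = c(0, 0, 0)) {
  stopifnot(Nt >= 1L)
  with_seed(seed, {
    lapply(seq_len(Nt), function(i) {
      p <- numeric(6)
      for (j in 1:6) {
        repeat {
          x <- rnorm(1, dist@mean[j], dist@sd[j])
          if (abs(x - dist@mean[j]) <= 2 * dist@sd[j]) break
        }
        p[j] <- x
      }
      rigidTransform(rotation = p[1:3] * pi / 180, translation = p[4:6],
                     centre = centre)
    })
  })
}

## mass retained by a warp (kidney kept inside the grid)
warp_retention <- function(fmapVol, transform) {
  w <- resampleRigid(fmapVol, transform, "linear")
  sum(w@voxels) / sum(fmapVol@voxels)
}

#' Generate training pairs by inverse-transform warping
#'
#' For each sampled transform T, the verified-aligned reference CT and
#' its feature map are warped by the inverse of T to a new initial
#' pose; warping back by T restores the alignment, so T is stored as
#' the pair's diagnostic ground truth. Transforms that push the kidney
#' outside the grid (feature-map mass retention below
#' `minRetention`) are resampled; the count is attached as attribute
#' "resampled".
#'
#' @param alignedCT,alignedFmap reference CT [Volume3D-class] and
#'   [FeatureMap-class] at the verified alignment (canonical grid).
#' @param fixedUS,fixedFmap embedded US window intensity and feature
#'   volumes.
#' @param dist a [TransformDistribution-class].
#' @param Nt number of pairs.
#' @param seed RNG seed.
#' @param minRetention minimum warped feature-mass fraction.
#' @return list of [TrainingPair-class] with attribute "resampled".
#' @export
generateTrainingPairs <- function(alignedCT, alignedFmap, fixedUS,
                                  fixedFmap, dist, Nt, seed = 1L,
                                  minRetention = 0.99) {
  ctr <- gridCentre(alignedCT)
  mindFix <- mindDescriptor(fixedUS@voxels)
  dm <- dim(fixedUS@voxels)
  mid <- dm[1] %/% 2L + 1L
  mindFixMid <- array(mindFix[mid, , , ], dim = c(dm[2:3], 6L))
  resampled <- 0L
  pairs <- vector("list", Nt)
  for (k in seq_len(Nt)) {
    tk <- NULL
    for (try in 1:100) {
      tk <- sampleTransforms(dist, 1L, seed = seed * 1000L + k * 101L +
                               try, centre = ctr)[[1]]
      if (warp_retention(alignedFmap, invertTransform(tk)) >=
            minRetention) break
      resampled <- resampled + 1L
      tk <- NULL
    }
    if (is.null(tk)) stop("could not sample a transform keeping the ",
                          "kidney inside the grid")
    inv <- invertTransform(tk)
    pairs[[k]] <- new("TrainingPair",
      movingCT = voxels(resampleRigid(alignedCT, inv, "linear")),
      movingFmap = voxels(resampleRigid(alignedFmap, inv, "linear")),
      fixedUS = fixedUS@voxels, fixedFmap = fixedFmap@voxels,
      mindFixMid = mindFixMid, gtTransform = tk,
      prealign = rigidTransform(centre = ctr))
  }
  attr(pairs, "resampled") <- resampled
  pairs
}

## ---------------------------------------------------------------------
## training steps

## one FIM training/evaluation step on a pair; returns loss (+ grads)
regnet_fim_pass <- function(params, cfg, pair, weights,
                            withGrad = TRUE,
                            scales = 1:4) {
  geom <- loss_geometry(cfg@inputDims, cfg@spacing,
                        refLength = cfg@refLength, Nw = cfg@Nw)
  tape <- td_tape()
  P <- param_nodes(tape, params, leaf = withGrad)
  heads <- regnet_graph(tape, P, cfg, td_const(pair@movingFmap),
                        td_const(pair@fixedFmap))
  thetas <- combine_graph(tape, heads, cfg, scales = scales)
  frames <- window_frame_slices(pair@fixedFmap, cfg@Nw)
  fim <- fim_graph(tape, thetas, td_const(pair@movingFmap), frames,
                   td_const(pair@movingCT * pair@movingFmap),
                   pair@mindFixMid, geom, weights)
  out <- list(loss = fim$total$value, feature = fim$feature$value,
              image = fim$image$value, transform = fim$transform$value)
  if (withGrad) {
    td_backward(tape, fim$total)
    out$grads <- lapply(P, function(nd) nd$grad)
  }
  out
}

#' Unsupervised pretraining of the registration network
#'
#' Minimises the FIM loss with Adam over generated training pairs.
#' Ground-truth transforms never enter the objective. A fraction of
#' the pairs is held out for early stopping (patience on the
#' validation loss); the best-validation parameters are returned.
#'
#' @param model a [RegNet-class].
#' @param pairs list of [TrainingPair-class].
#' @param epochs maximum number of epochs; 0 returns the model
#'   unchanged.
#' @param seed RNG seed (shuffling).
#' @param weights a [FimWeights-class].
#' @param learningRate Adam step size; default from the config.
#' @param valFraction held-out fraction for early stopping.
#' @param patience epochs without validation improvement before
#'   stopping.
#' @return The trained [RegNet-class] with `lossHistory` rows
#'   (epoch, train, val).
#' @export
pretrainRegNet <- function(model, pairs, epochs, seed = 1L,
                           weights = fimWeights(), learningRate = NULL,
                           valFraction = 0.1, patience = 10L) {
  if (length(pairs) == 0L) stop("no training pairs")
  if (epochs == 0L) return(model)
  cfg <- model@config
  lr <- learningRate %||% cfg@learningRate
  params <- model@params
  st <- adam_state(params)
  nval <- floor(valFraction * length(pairs))
  hist <- data.frame()
  best <- params
  bestVal <- Inf
  bad <- 0L
  with_seed(seed, {
    idx <- sample.int(length(pairs))
    vIdx <- head(idx, nval)
    tIdx <- setdiff(idx, vIdx)
    for (ep in seq_len(epochs)) {
      losses <- numeric(length(tIdx))
      for (j in seq_along(sh <- sample(tIdx))) {
        ps <- regnet_fim_pass(params, cfg, pairs[[sh[j]]], weights)
        if (!is.finite(ps$loss))
          stop(sprintf(
            "training diverged at epoch %d (loss=%g, Lf=%g, Li=%g)",
            ep, ps$loss, ps$feature, ps$image))
        upd <- adam_step(params, ps$grads, st, lr = lr)
        params <- upd$params
        st <- upd$state
        losses[j] <- ps$loss
      }
      val <- if (nval > 0)
        mean(vapply(vIdx, function(i)
          regnet_fim_pass(params, cfg, pairs[[i]], weights,
                          withGrad = FALSE)$loss, numeric(1)))
      else mean(losses)
      hist <- rbind(hist, data.frame(epoch = ep, train = mean(losses),
                                     val = val))
      if (val < bestVal - 1e-6) {
        bestVal <- val
        best <- params
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
  })
  new("RegNet", config = cfg, params = best,
      lossHistory = rbind(model@lossHistory, hist))
}

#' One-cycle transfer learning
#'
#' Continues unsupervised FIM optimisation on the windows of one
#' patient's first respiration cycle for exactly `epochs` (default 2)
#' passes, all weights trainable. Returns a refined copy; the
#' pretrained model is left untouched.
#'
#' @param model a pretrained [RegNet-class].
#' @param windows list of [TrainingPair-class] built from the first
#'   cycle's windows (e.g. via [makeWindowPair()]).
#' @param epochs transfer epochs, fixed at 2 in the standard protocol.
#' @param seed RNG seed (shuffling).
#' @param weights a [FimWeights-class].
#' @param learningRate Adam step size; default from the config.
#' @return The refined [RegNet-class].
#' @export
oneCycleTransfer <- function(model, windows, epochs = 2L, seed = 1L,
                             weights = fimWeights(),
                             learningRate = NULL) {
  if (length(windows) == 0L) stop("no first-cycle windows found")
  cfg <- model@config
  lr <- learningRate %||% cfg@learningRate
  params <- model@params
  st <- adam_state(params)
  hist <- data.frame()
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      losses <- numeric(length(windows))
      for (j in seq_along(sh <- sample.int(length(windows)))) {
        ps <- regnet_fim_pass(params, cfg, windows[[sh[j]]], weights)
        if (!is.finite(ps$loss)) stop("transfer diverged")
        upd <- adam_step(params, ps$grads, st, lr = lr)
        params <- upd$params
        st <- upd$state
        losses[j] <- ps$loss
      }
      hist <- rbind(hist, data.frame(epoch = ep, train = mean(losses),
                                     val = NA_real_))
    }
  })
  new("RegNet", config = cfg, params = params,
      lossHistory = rbind(model@lossHistory, hist))
}

## ---------------------------------------------------------------------
## window assembly and sequential inference

#' Assemble the canonical pair data for one US window
#'
#' Embeds the window's intensity frames and feature maps into the
#' canonical zero-padded volume, centroid-aligns the CT, and packages
#' everything (with the precomputed fixed MIND slice) as a
#' [TrainingPair-class] whose `prealign` slot records the centroid
#' alignment.
#'
#' @param ct CT [Volume3D-class] on the canonical grid.
#' @param ctFmap CT [FeatureMap-class].
#' @param usWin intensity [USWindow-class].
#' @param usFmapWin feature [USWindow-class] (same frames).
#' @param prealign logical; apply centroid pre-alignment.
#' @return A [TrainingPair-class].
#' @export
makeWindowPair <- function(ct, ctFmap, usWin, usFmapWin,
                           prealign = TRUE) {
  dm <- dim(ct@voxels)
  fixUS <- embedUSWindow(usWin, dm)
  fixFmap <- embedUSWindow(usFmapWin, dm)
  fixUS@spacing <- ct@spacing
  fixFmap@spacing <- ct@spacing
  pre <- if (prealign)
    centroidAlign(ctFmap, fixFmap) else
      rigidTransform(centre = gridCentre(ct))
  movCT <- resampleRigid(ct, pre, "linear")
  movFmap <- resampleRigid(ctFmap, pre, "linear")
  mindFix <- mindDescriptor(fixUS@voxels)
  mid <- dm[1] %/% 2L + 1L
  new("TrainingPair",
      movingCT = movCT@voxels, movingFmap = movFmap@voxels,
      fixedUS = fixUS@voxels, fixedFmap = fixFmap@voxels,
      mindFixMid = array(mindFix[mid, , , ], dim = c(dm[2:3], 6L)),
      gtTransform = rigidTransform(centre = gridCentre(ct)),
      prealign = pre)
}

#' Detect the first respiration cycle
#'
#' The first cycle spans the frames up to the second zero-crossing of
#' the mean-centred inferior-superior centroid trajectory of the US
#' feature maps. An explicit `override` frame count takes precedence.
#'
#' @param usFmaps list of 2D feature maps (AP x IS).
#' @param override explicit number of first-cycle frames, or NULL.
#' @return integer: number of frames in the first cycle.
#' @export
detectFirstCycle <- function(usFmaps, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  cis <- vapply(usFmaps, function(m) {
    s <- sum(m)
    if (s <= 0) return(NA_real_)
    sum(colSums(m) * (seq_len(ncol(m)) - 1)) / s
  }, numeric(1))
  x <- cis - mean(cis, na.rm = TRUE)
  sgn <- ifelse(x >= 0, 1, -1)
  crossings <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(crossings) < 2L)
    stop("no full respiration cycle found in the sequence")
  as.integer(crossings[2L] + 1L)
}

#' Register a full US sequence frame by frame
#'
#' Windows the sequence, registers each window (with per-window
#' centroid pre-alignment), and assigns each frame the pose from the
#' window in which it is the middle frame: the estimated pose is the
#' window transform composed with the pre-alignment. Edge frames
#' without a centred window are left unposed.
#'
#' @param model a trained [RegNet-class].
#' @param ct CT [Volume3D-class] on the canonical grid.
#' @param ctFmap CT [FeatureMap-class].
#' @param usFrames,usFmaps lists of 2D intensity frames and feature
#'   maps (AP x IS, canonical in-plane dims).
#' @param prealign logical; apply centroid pre-alignment per window.
#' @return list(frames = posed frame indices, poses = list of
#'   [RigidTransform-class], planes = list of middle-RL CT slices).
#' @export
inferSequence <- function(model, ct, ctFmap, usFrames, usFmaps,
                          prealign = TRUE) {
  cfg <- model@config
  Nw <- cfg@Nw
  if (length(usFrames) < Nw)
    stop("sequence shorter than the window size")
  sp <- ct@spacing[2:3]
  wins <- windowUS(usFrames, Nw, spacing = sp)
  fwins <- windowUS(usFmaps, Nw, spacing = sp)
  mid <- dim(ct@voxels)[1] %/% 2L + 1L
  out <- lapply(seq_along(wins), function(k) {
    pair <- makeWindowPair(ct, ctFmap, wins[[k]], fwins[[k]],
                           prealign = prealign)
    movFmap <- featureMap(pair@movingFmap, spacing = ct@spacing,
                          modality = "CT")
    reg <- registerWindow(model, movFmap,
                          volume3D(pair@fixedFmap,
                                   spacing = ct@spacing),
                          warpVolumes = FALSE)
    D <- reg$transforms@transforms[[middleIndex(reg$transforms)]]
    pose <- composeTransforms(D, pair@prealign)
    plane <- voxels(resampleRigid(ct, pose, "linear"))[mid, , ]
    list(frame = windowMiddleFrame(wins[[k]]), pose = pose,
         plane = plane)
  })
  list(frames = vapply(out, `[[`, integer(1), "frame"),
       poses = lapply(out, `[[`, "pose"),
       planes = lapply(out, `[[`, "plane"))
}
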