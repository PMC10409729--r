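## Desk-scale end-to-end benchmark: synthetic patients on the
## 32 x 56 x 72 canonical grid, misaligned by draws from the
## small-transformation group distribution, registered by the full
## two-step pipeline (shared unsupervised pretraining + per-patient
## one-cycle transfer), and scored by pose recovery and contour
## distances against the phantom ground truth.

## one synthetic patient: phantom, misaligned CT, sequence, ground truth
desk_patient <- function(seed, dims = c(32L, 56L, 72L), spacing = 3.2,
                         nFrames = 20L, period = 12) {
  with_seed(seed, {
    semi <- c(25, 30, 55) * runif(3, 0.9, 1.1)
    poseT <- runif(3, -4, 4)
    lesionCentre <- c(0.3, 0.35, 0.35) * semi * sample(c(-1, 1), 3,
                                                       replace = TRUE)
    resp <- respirationModel(
      period = period,
      translationAmplitude = c(0.5, 2, 6) * runif(3, 0.8, 1.2),
      rotationAmplitude = c(1.5, 0.5, 0.5) * runif(3, 0.8, 1.2),
      phase = runif(1, 0, 2 * pi))
  })
  spec <- phantomSpec(dim = dims, spacing = rep(spacing, 3),
                      semiAxes = semi,
                      pose = rigidTransform(translation = poseT),
                      textureAmplitude = 0.3,
                      backgroundIntensity = 0.25,
                      lesion = list(centre = lesionCentre, radius = 8,
                                    intensityOffset = -0.35))
  ph <- makeCTPhantom(spec, seed = seed)
  sample <- simulateUSSequence(ph$ct, ph$mask, resp, nFrames,
                               seed = seed + 1L)
  ## static misalignment of the presented CT, drawn from the
  ## small-transformation group distribution
  ctr <- gridCentre(ph$ct)
  maskF <- featureMap(ph$mask@voxels, spacing = ph$mask@spacing,
                      modality = "CT")
  tmis <- NULL
  for (try in 1:50) {
    cand <- sampleTransforms(groupATransformDistribution(), 1L,
                             seed = seed * 7L + try, centre = ctr)[[1]]
    if (warp_retention(maskF, invertTransform(cand)) >= 0.99) {
      tmis <- cand
      break
    }
  }
  ctMis <- resampleRigid(ph$ct, invertTransform(tmis), "linear")
  maskMis <- resampleRigid(ph$mask, invertTransform(tmis), "nearest")
  gtPoses <- lapply(sample@gtPoses, function(p)
    composeTransforms(p, tmis))
  evalSample <- new("PhantomSample", ct = ctMis, ctMask = maskMis,
                    usFrames = sample@usFrames,
                    usMasks = sample@usMasks, gtPoses = gtPoses,
                    resp = resp, slicePlaneRL = sample@slicePlaneRL)
  list(sample = evalSample,
       ctFmap = featureMap(maskMis@voxels, spacing = maskMis@spacing,
                           modality = "CT"),
       usFmaps = sample@usMasks, misalignment = tmis)
}

## first-cycle window pairs (full TrainingPair, for transfer and pair
## generation) + reference residual transforms
desk_patient_windows <- function(pat, Nw = 5L) {
  sm <- pat$sample
  sp <- sm@ct@spacing[2:3]
  nCycle <- detectFirstCycle(pat$usFmaps)
  nCycle <- min(max(nCycle, Nw), length(sm@usFrames))
  wins <- windowUS(sm@usFrames[seq_len(nCycle)], Nw, spacing = sp)
  fwins <- windowUS(pat$usFmaps[seq_len(nCycle)], Nw, spacing = sp)
  pairs <- lapply(seq_along(wins), function(k)
    makeWindowPair(sm@ct, pat$ctFmap, wins[[k]], fwins[[k]]))
  refs <- lapply(seq_along(wins), function(k) {
    mid <- windowMiddleFrame(wins[[k]])
    composeTransforms(sm@gtPoses[[mid]],
                      invertTransform(pairs[[k]]@prealign))
  })
  list(pairs = pairs, refs = refs, nCycle = nCycle,
       middleFrames = vapply(wins, windowMiddleFrame, integer(1)))
}

## light per-window inference data: embedded feature volume, centroid
## pre-alignment and the pre-aligned CT feature map (no intensities)
desk_inference_windows <- function(pat, Nw = 5L) {
  sm <- pat$sample
  dm <- dim(sm@ct@voxels)
  sp <- sm@ct@spacing
  fwins <- windowUS(pat$usFmaps, Nw, spacing = sp[2:3])
  lapply(fwins, function(fw) {
    fixFmap <- embedUSWindow(fw, dm)
    fixFmap@spacing <- sp
    pre <- centroidAlign(pat$ctFmap, fixFmap)
    list(fixFmap = fixFmap@voxels,
         movFmap = voxels(resampleRigid(pat$ctFmap, pre, "linear")),
         pre = pre, frame = windowMiddleFrame(fw))
  })
}

## register all windows of one patient with one model
desk_infer <- function(model, infWins) {
  lapply(infWins, function(wd) {
    reg <- registerWindow(model, wd$movFmap, wd$fixFmap,
                          warpVolumes = FALSE)
    D <- reg$transforms@transforms[[middleIndex(reg$transforms)]]
    list(frame = wd$frame, pose = composeTransforms(D, wd$pre))
  })
}

## frame-level scoring against ground truth, reusing the ground-truth
## plane contour across models
desk_score <- function(pat, results, tag) {
  sm <- pat$sample
  sp <- sm@ct@spacing[2]
  rows <- lapply(results, function(rr) {
    f <- rr$frame
    gt <- sm@gtPoses[[f]]
    wEst <- resampleRigid(sm@ctMask, rr$pose, "nearest")
    cEst <- extractContour(wEst@voxels[sm@slicePlaneRL, , ],
                           spacing = sp)
    wGt <- resampleRigid(sm@ctMask, gt, "nearest")
    cGt <- extractContour(wGt@voxels[sm@slicePlaneRL, , ],
                          spacing = sp)
    cUS <- extractContour(sm@usMasks[[f]], spacing = sp)
    if (contourSize(cEst) == 0L || contourSize(cGt) == 0L ||
        contourSize(cUS) == 0L) return(NULL)
    pe <- poseError(rr$pose, gt)
    data.frame(frame = f, model = tag,
               mcdCTUS = meanContourDistance(cEst, cUS),
               mcdCTCT = meanContourDistance(cEst, cGt),
               hdCTUS = hausdorffDistance(cEst, cUS),
               hdCTCT = hausdorffDistance(cEst, cGt),
               rotErr = unname(pe["rotation"]),
               transErr = unname(pe["translation"]))
  })
  do.call(rbind, rows)
}

#' Run the desk-scale two-step registration benchmark
#'
#' Builds `nPatients` synthetic breathing patients on the desk grid,
#' misaligns each CT by a draw from the small-transformation group
#' distribution, fits the per-parameter reference-transform
#' distribution from the phantom reference alignments, generates
#' training pairs by inverse-transform warping, pretrains one shared
#' registration model (unsupervised FIM loss), refines it per patient
#' with one-cycle transfer learning (2 epochs), infers per-frame poses
#' with both the pretrained-only and the transferred model, and scores
#' pose recovery and contour distances.
#'
#' The desk schedule runs orders of magnitude fewer optimisation steps
#' than a full-scale training, so its Adam step sizes are scaled up
#' correspondingly (see the methods vignette); the model defaults keep
#' the full-scale value.
#'
#' @param seed base RNG seed.
#' @param nPatients number of synthetic patients (default 20).
#' @param nFrames frames per patient sequence.
#' @param period breathing period in frames (desk scaling of a
#'   clinical cycle).
#' @param pairsPerPatient generated training pairs per patient.
#' @param pretrainEpochs pretraining epochs.
#' @param transferEpochs one-cycle transfer epochs (2).
#' @param pretrainLearningRate,transferLearningRate desk Adam step
#'   sizes for the shared pretraining and the per-patient transfer.
#' @param recoveryTransMM,recoveryRotDeg recovery thresholds: 2
#'   full-resolution desk voxels (6.4 mm) and 5 degrees.
#' @param verbose print progress.
#' @return list(perFrame, summary, pretrainHistory); `summary` holds
#'   the frame recovery rate after transfer, median CT-CT and CT-US
#'   mask MCDs for both models, and the misalignment magnitudes.
#' @export
runDeskBenchmark <- function(seed = 1L, nPatients = 20L, nFrames = 20L,
                             period = 12, pairsPerPatient = 2L,
                             pretrainEpochs = 4L, transferEpochs = 2L,
                             pretrainLearningRate = 0.01,
                             transferLearningRate = 0.04,
                             recoveryTransMM = 6.4, recoveryRotDeg = 5,
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("building %d synthetic patients", nPatients)
  patients <- lapply(seq_len(nPatients), function(p)
    desk_patient(seed * 1000L + p * 13L, nFrames = nFrames,
                 period = period))
  winsets <- lapply(patients, desk_patient_windows)

  ## reference-transform distribution pooled over patients
  refs <- unlist(lapply(winsets, `[[`, "refs"), recursive = FALSE)
  dist <- fitTransformDistribution(refs)

  ## training pairs: inverse-transform warps of per-patient reference
  ## alignments, fixed side = first-cycle windows
  say("generating training pairs")
  pairs <- list()
  for (p in seq_len(nPatients)) {
    ws <- winsets[[p]]
    sm <- patients[[p]]$sample
    pick <- unique(round(seq(1, length(ws$pairs),
                             length.out = min(2L, length(ws$pairs)))))
    nper <- max(1L, pairsPerPatient %/% length(pick))
    for (k in pick) {
      wp <- ws$pairs[[k]]
      mid <- ws$middleFrames[k]
      aligned <- resampleRigid(sm@ct, sm@gtPoses[[mid]], "linear")
      alignedF <- resampleRigid(patients[[p]]$ctFmap,
                                sm@gtPoses[[mid]], "linear")
      pr <- generateTrainingPairs(
        aligned, alignedF,
        volume3D(wp@fixedUS, spacing = sm@ct@spacing),
        featureMap(pmin(pmax(wp@fixedFmap, 0), 1),
                   spacing = sm@ct@spacing, modality = "US"),
        dist, Nt = nper, seed = seed * 100L + p * 17L + k)
      pairs <- c(pairs, pr)
    }
  }
  say("pretraining on %d pairs", length(pairs))
  ## quarter-scale grid, quarter translation range of the tanh heads
  cfg <- regNetConfig(maxTranslation = 4)
  model0 <- buildRegNet(cfg, seed = seed)
  model <- pretrainRegNet(model0, pairs, epochs = pretrainEpochs,
                          seed = seed + 2L,
                          learningRate = pretrainLearningRate,
                          valFraction = 0.1, patience = pretrainEpochs)

  say("per-patient transfer + inference")
  perFrame <- list()
  for (p in seq_len(nPatients)) {
    pat <- patients[[p]]
    tmodel <- oneCycleTransfer(model, winsets[[p]]$pairs,
                               epochs = transferEpochs,
                               seed = seed + 3L + p,
                               learningRate = transferLearningRate)
    infWins <- desk_inference_windows(pat)
    perFrame[[length(perFrame) + 1L]] <-
      desk_score(pat, desk_infer(model, infWins), "pretrained")
    perFrame[[length(perFrame) + 1L]] <-
      desk_score(pat, desk_infer(tmodel, infWins), "transfer")
    perFrame[[length(perFrame)]]$patient <- p
    perFrame[[length(perFrame) - 1L]]$patient <- p
    say("patient %d done", p)
  }
  perFrame <- do.call(rbind, perFrame)
  rownames(perFrame) <- NULL
  tr <- perFrame[perFrame$model == "transfer", ]
  pre <- perFrame[perFrame$model == "pretrained", ]
  mis <- vapply(patients, function(pat) {
    c(rot = sqrt(sum((pat$misalignment@rotation * 180 / pi)^2)),
      trans = sqrt(sum(pat$misalignment@translation^2)))
  }, numeric(2))
  summary <- list(
    recoveryRate = mean(tr$transErr <= recoveryTransMM &
                          tr$rotErr <= recoveryRotDeg),
    recoveryRatePretrained = mean(pre$transErr <= recoveryTransMM &
                                    pre$rotErr <= recoveryRotDeg),
    medianMcdCTCTTransfer = median(tr$mcdCTCT),
    medianMcdCTCTPretrained = median(pre$mcdCTCT),
    medianMcdCTUSTransfer = median(tr$mcdCTUS),
    medianMcdCTUSPretrained = median(pre$mcdCTUS),
    medianRotErrTransfer = median(tr$rotErr),
    medianTransErrTransfer = median(tr$transErr),
    meanMisalignmentRotDeg = mean(mis["rot", ]),
    meanMisalignmentTransMM = mean(mis["trans", ]),
    nFramesScored = nrow(tr))
  list(perFrame = perFrame, summary = summary,
       pretrainHistory = model@lossHistory)
}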