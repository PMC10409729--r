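## Synthetic breathing phantoms: a textured ellipsoidal "kidney" in a
## darker background volume, and an ultrasound-like sagittal slice
## sequence of it under periodic rigid breathing motion with known
## per-frame poses. These stand in for clinical CT/US pairs.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## smooth unit-variance random field: white noise + repeated 3^3 box
## filtering (approximately Gaussian smoothing, sigma ~ sqrt(2k/3) vox)
smooth_field <- function(dm, passes = 5L) {
  f <- array(rnorm(prod(dm)), dim = dm)
  for (i in seq_len(passes)) f <- cpp_boxfilter3(f, dm)
  s <- sd(f)
  if (s > 0) f <- f / s
  f
}

## 0-based voxel index grids in world mm
world_coords <- function(dm, spacing, origin) {
  list(x = origin[1] + (seq_len(dm[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(dm[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(dm[3]) - 1) * spacing[3])
}

#' Build a synthetic CT kidney phantom
#'
#' Creates a textured volume containing a posed ellipsoidal kidney of
#' intensity 1 (plus a smooth internal texture field and an optional
#' lesion-like blob) over a darker background, together with the exact
#' analytic ellipsoid mask. Deterministic given `seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer RNG seed.
#' @return list(ct = [Volume3D-class], mask = binary [Volume3D-class]).
#' @examples
#' ph <- makeCTPhantom(phantomSpec(), seed = 1)
#' range(voxels(ph$mask))
#' @export
makeCTPhantom <- function(spec, seed = 1L) {
  validObject(spec)
  dm <- spec@dim
  sp <- spec@spacing
  origin <- c(0, 0, 0)
  ctr <- origin + (dm - 1) / 2 * sp
  pose <- spec@pose
  ## pose the ellipsoid: mask(x) = || R^T (x - c_k) / a || <= 1 where
  ## c_k = pose centre translated; rotation about the grid centre
  R <- eulerToRotation(pose@rotation)
  ck <- ctr + pose@translation
  ## bounding half-extent of the rotated ellipsoid along each axis
  ext <- sqrt(colSums((R * spec@semiAxes)^2))
  lo <- ck - ext
  hi <- ck + ext
  if (any(lo < origin) || any(hi > origin + (dm - 1) * sp))
    stop("posed ellipsoid exceeds the grid")

  wc <- world_coords(dm, sp, origin)
  ## coordinates relative to the kidney centre, rotated back
  gx <- array(wc$x, dim = dm)
  gy <- array(rep(wc$y, each = dm[1]), dim = dm)
  gz <- array(rep(wc$z, each = dm[1] * dm[2]), dim = dm)
  px <- gx - ck[1]; py <- gy - ck[2]; pz <- gz - ck[3]
  Rt <- t(R)
  ux <- Rt[1, 1] * px + Rt[1, 2] * py + Rt[1, 3] * pz
  uy <- Rt[2, 1] * px + Rt[2, 2] * py + Rt[2, 3] * pz
  uz <- Rt[3, 1] * px + Rt[3, 2] * py + Rt[3, 3] * pz
  q <- (ux / spec@semiAxes[1])^2 + (uy / spec@semiAxes[2])^2 +
    (uz / spec@semiAxes[3])^2
  mask <- array(as.numeric(q <= 1), dim = dm)

  vox <- with_seed(seed, {
    v <- array(spec@backgroundIntensity, dim = dm)
    kid <- array(1, dim = dm) + if (spec@textureAmplitude > 0)
      spec@textureAmplitude * smooth_field(dm) else 0
    if (length(spec@lesion)) {
      les <- spec@lesion
      lc <- ck + les$centre
      d2 <- (gx - lc[1])^2 + (gy - lc[2])^2 + (gz - lc[3])^2
      kid <- kid + les$intensityOffset * exp(-d2 / les$radius^2)
    }
    v[mask > 0] <- kid[mask > 0]
    v
  })
  list(ct = volume3D(vox, spacing = sp, origin = origin),
       mask = volume3D(mask, spacing = sp, origin = origin))
}

## per-frame breathing pose (t is the 1-based frame number)
breathing_pose <- function(resp, t, centre) {
  s <- sin(2 * pi * (t - 1) / resp@period + resp@phase)
  rigidTransform(rotation = resp@rotationAmplitude * pi / 180 * s,
                 translation = resp@translationAmplitude * s,
                 centre = centre)
}

## 2D binomial blur, applied `k` times (3x3 kernel [1 2 1]/4 per axis)
blur2d <- function(m, k) {
  if (k <= 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  for (i in seq_len(k)) {
    up <- rbind(m[1, ], m[1:(n1 - 1), , drop = FALSE])
    dn <- rbind(m[2:n1, , drop = FALSE], m[n1, ])
    m <- (up + 2 * m + dn) / 4
    lf <- cbind(m[, 1], m[, 1:(n2 - 1), drop = FALSE])
    rt <- cbind(m[, 2:n2, drop = FALSE], m[, n2])
    m <- (lf + 2 * m + rt) / 4
  }
  m
}

#' Simulate an ultrasound-like breathing slice sequence
#'
#' Each frame is the constant-RL sagittal slice of the CT phantom
#' rigidly moved by a sinusoidal breathing pose, remapped through a
#' gamma curve (so CT and US intensities are not linearly related),
#' blurred, and corrupted with multiplicative log-normal speckle. Mask
#' frames are sliced from the warped exact mask without noise, and the
#' exact poses are recorded.
#'
#' @param ct,mask [Volume3D-class] phantom volume and binary mask, as
#'   from [makeCTPhantom()].
#' @param resp a [RespirationModel-class].
#' @param nFrames number of frames (>= resp period).
#' @param slicePlaneRL 1-based RL index of the imaging plane; default
#'   the middle plane.
#' @param noise list(speckleSigma, blurSigma, gamma).
#' @param seed integer RNG seed.
#' @return A [PhantomSample-class].
#' @export
simulateUSSequence <- function(ct, mask, resp, nFrames,
                               slicePlaneRL = NULL,
                               noise = list(speckleSigma = 0.3,
                                            blurSigma = 0.8,
                                            gamma = 0.7),
                               seed = 1L) {
  dm <- dim(ct@voxels)
  if (is.null(slicePlaneRL)) slicePlaneRL <- dm[1] %/% 2L + 1L
  if (slicePlaneRL < 1L || slicePlaneRL > dm[1])
    stop("slice plane outside grid")
  if (nFrames < resp@period) stop("nFrames must be >= resp period")
  ctr <- gridCentre(ct)
  speckle <- noise$speckleSigma %||% 0
  blurk <- max(0L, as.integer(round((noise$blurSigma %||% 0) /
                                      0.7071)))
  gam <- noise$gamma %||% 1

  frames <- vector("list", nFrames)
  masks <- vector("list", nFrames)
  poses <- vector("list", nFrames)
  with_seed(seed, {
    for (t in seq_len(nFrames)) {
      pose <- breathing_pose(resp, t, ctr)
      wct <- resampleRigid(ct, pose, "linear")
      wmk <- resampleRigid(mask, pose, "nearest")
      sl <- wct@voxels[slicePlaneRL, , ]
      sl <- pmax(sl, 0)^gam
      sl <- blur2d(sl, blurk)
      if (speckle > 0)
        sl <- sl * exp(matrix(rnorm(length(sl), -speckle^2 / 2, speckle),
                              nrow(sl)))
      frames[[t]] <- sl
      masks[[t]] <- wmk@voxels[slicePlaneRL, , ]
      poses[[t]] <- pose
    }
  })
  new("PhantomSample", ct = ct, ctMask = mask, usFrames = frames,
      usMasks = masks, gtPoses = poses, resp = resp,
      slicePlaneRL = as.integer(slicePlaneRL))
}

#' Write a phantom sample to disk
#'
#' CT and mask as NIfTI, US frames (and masks) as a 3D NIfTI stack with
#' the frame axis mapped to RL, the ground-truth pose table as CSV, and
#' a YAML manifest describing the sample.
#'
#' @param sample a [PhantomSample-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantomSample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(sample@ct, file.path(dir, "ct.nii.gz"))
  writeVolume(sample@ctMask, file.path(dir, "ct_mask.nii.gz"))
  us <- aperm(simplify2array(sample@usFrames), c(3, 1, 2))
  sp <- sample@ct@spacing
  writeVolume(volume3D(us, spacing = sp), file.path(dir, "us.nii.gz"))
  um <- aperm(simplify2array(sample@usMasks), c(3, 1, 2))
  writeVolume(volume3D(um, spacing = sp),
              file.path(dir, "us_masks.nii.gz"))
  writePoseTable(sample@gtPoses, file.path(dir, "gt_poses.csv"))
  yaml::write_yaml(list(
    n_frames = length(sample@usFrames),
    slice_plane_rl = sample@slicePlaneRL,
    period = sample@resp@period,
    translation_amplitude_mm = sample@resp@translationAmplitude,
    rotation_amplitude_deg = sample@resp@rotationAmplitude,
    spacing_mm = sp), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
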