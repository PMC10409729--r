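#' @import methods
#' @importFrom stats rnorm runif sd median rbinom
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib SliceVolReg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Rigid transform in RAI world coordinates
#'
#' A 6-parameter rigid pose: three Euler angles (radians, intrinsic
#' rotations applied in axis order RL, AP, IS) and three translations
#' (mm, ordered RL, AP, IS), rotating about `centre` (mm). The mapping
#' is \eqn{T(x) = R (x - c) + c + t} on world coordinates.
#'
#' @slot rotation numeric(3), Euler angles in radians (RL, AP, IS).
#' @slot translation numeric(3), mm (RL, AP, IS).
#' @slot centre numeric(3), rotation centre in mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric",
                 centre = "numeric"),
  prototype(rotation = c(0, 0, 0), translation = c(0, 0, 0),
            centre = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  if (length(object@rotation) != 3L) return("rotation must have length 3")
  if (length(object@translation) != 3L)
    return("translation must have length 3")
  if (length(object@centre) != 3L) return("centre must have length 3")
  if (!all(is.finite(c(object@rotation, object@translation,
                       object@centre))))
    return("transform parameters must be finite")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation Euler angles in radians (RL, AP, IS order).
#' @param translation translation in mm (RL, AP, IS order).
#' @param centre rotation centre in mm; use [gridCentre()] to rotate
#'   about a volume's centre.
#' @return A [RigidTransform-class] object.
#' @examples
#' rigidTransform(rotation = c(pi / 2, 0, 0), translation = c(1, 2, 3))
#' @export
rigidTransform <- function(rotation = c(0, 0, 0),
                           translation = c(0, 0, 0),
                           centre = c(0, 0, 0)) {
  new("RigidTransform", rotation = as.numeric(rotation),
      translation = as.numeric(translation), centre = as.numeric(centre))
}

#' Windowed set of per-frame rigid transforms
#'
#' Holds the Nw rigid transforms predicted for one ultrasound window
#' (one per frame; the middle frame is the registration target).
#'
#' @slot transforms list of [RigidTransform-class], length Nw (odd).
#' @export
setClass("WindowTransformSet",
  representation(transforms = "list"))

setValidity("WindowTransformSet", function(object) {
  n <- length(object@transforms)
  if (n < 1L) return("at least one transform required")
  if (n %% 2L == 0L) return("window size must be odd")
  ok <- vapply(object@transforms, function(t) is(t, "RigidTransform"),
               logical(1))
  if (!all(ok)) return("all elements must be RigidTransform")
  TRUE
})

#' Construct a WindowTransformSet
#' @param transforms list of [RigidTransform-class] objects, odd length.
#' @return A [WindowTransformSet-class].
#' @export
windowTransformSet <- function(transforms) {
  new("WindowTransformSet", transforms = transforms)
}

#' @describeIn windowTransformSet number of frames in the window.
#' @param W a WindowTransformSet.
#' @export
windowSize <- function(W) length(W@transforms)

#' @describeIn windowTransformSet 1-based index of the middle frame.
#' @export
middleIndex <- function(W) (length(W@transforms) + 1L) %/% 2L

#' 3D scalar volume on a regular RAI grid
#'
#' Axis order is (RL, AP, IS); sagittal planes are constant-RL slices.
#' World coordinates are `origin + index * spacing` with 0-based
#' indices at voxel centres.
#'
#' @slot voxels 3D numeric array (RL, AP, IS).
#' @slot spacing numeric(3), mm per voxel.
#' @slot origin numeric(3), mm world coordinate of voxel (0,0,0).
#' @slot orientation fixed tag, "RAI".
#' @export
setClass("Volume3D",
  representation(voxels = "array", spacing = "numeric",
                 origin = "numeric", orientation = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
            orientation = "RAI"))

setValidity("Volume3D", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be 3D")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (!identical(object@orientation, "RAI"))
    return("orientation must be 'RAI'")
  TRUE
})

#' Construct a Volume3D
#' @param voxels 3D numeric array in (RL, AP, IS) axis order.
#' @param spacing mm per voxel, length 3.
#' @param origin world mm coordinate of voxel (0,0,0).
#' @return A [Volume3D-class].
#' @export
volume3D <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume3D", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = "RAI")
}

#' Per-voxel kidney probability map
#'
#' A [Volume3D-class] whose voxels are probabilities in \[0, 1\]
#' (sigmoid output of a feature network, or an exact phantom mask),
#' tagged with the source modality.
#'
#' @slot modality "CT" or "US".
#' @export
setClass("FeatureMap", contains = "Volume3D",
  representation(modality = "character"),
  prototype(modality = "CT"))

setValidity("FeatureMap", function(object) {
  if (!object@modality %in% c("CT", "US"))
    return("modality must be 'CT' or 'US'")
  rng <- range(object@voxels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("feature map values must lie in [0, 1]")
  TRUE
})

#' Construct a FeatureMap
#' @param values 3D array of probabilities in \[0, 1\].
#' @param spacing,origin grid geometry, as for [volume3D()].
#' @param modality "CT" or "US".
#' @return A [FeatureMap-class].
#' @export
featureMap <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       modality = "CT") {
  new("FeatureMap", voxels = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = "RAI",
      modality = modality)
}

#' Specification of a synthetic CT kidney phantom
#'
#' @slot dim integer(3) grid size (RL, AP, IS).
#' @slot spacing numeric(3) mm.
#' @slot semiAxes numeric(3) ellipsoid semi-axes in mm (RL, AP, IS).
#' @slot pose [RigidTransform-class] posing the ellipsoid in the grid.
#' @slot textureAmplitude fraction of the kidney intensity used for the
#'   smooth internal texture field.
#' @slot backgroundIntensity background level (kidney level is 1).
#' @slot lesion list(centre, radius, intensityOffset) or empty list; an
#'   off-centre intensity blob emulating internal renal structure
#'   (affects intensities only, never the mask).
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric",
                 semiAxes = "numeric", pose = "RigidTransform",
                 textureAmplitude = "numeric",
                 backgroundIntensity = "numeric", lesion = "list"))

setValidity("PhantomSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 4L))
    return("dim must be 3 values >= 4")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
    return("semiAxes must be 3 positive lengths (mm)")
  if (object@textureAmplitude < 0 || object@textureAmplitude > 1)
    return("textureAmplitude must be in [0, 1]")
  TRUE
})

#' Construct a PhantomSpec
#' @param dim grid size in voxels (RL, AP, IS).
#' @param spacing voxel spacing in mm.
#' @param semiAxes kidney ellipsoid semi-axes in mm.
#' @param pose kidney pose; default centred, unrotated.
#' @param textureAmplitude internal texture amplitude (fraction of the
#'   kidney intensity).
#' @param backgroundIntensity background level relative to kidney = 1.
#' @param lesion optional list(centre = mm offsets from the kidney
#'   centre, radius = mm, intensityOffset = signed fraction).
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(32L, 56L, 72L), spacing = c(3.2, 3.2, 3.2),
                        semiAxes = c(25, 30, 55),
                        pose = rigidTransform(),
                        textureAmplitude = 0.3,
                        backgroundIntensity = 0.25,
                        lesion = list()) {
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      semiAxes = as.numeric(semiAxes), pose = pose,
      textureAmplitude = textureAmplitude,
      backgroundIntensity = backgroundIntensity, lesion = lesion)
}

#' Periodic breathing-motion model
#'
#' Sinusoidal per-axis translation and rotation with a common period,
#' dominant inferior-superior translation by default.
#'
#' @slot period frames per breathing cycle (>= 4).
#' @slot translationAmplitude numeric(3) mm (RL, AP, IS).
#' @slot rotationAmplitude numeric(3) degrees.
#' @slot phase phase offset in radians.
#' @export
setClass("RespirationModel",
  representation(period = "numeric", translationAmplitude = "numeric",
                 rotationAmplitude = "numeric", phase = "numeric"))

setValidity("RespirationModel", function(object) {
  if (object@period < 4) return("period must be >= 4 frames")
  if (any(object@translationAmplitude < 0) ||
      any(object@rotationAmplitude < 0))
    return("amplitudes must be >= 0")
  TRUE
})

#' Construct a RespirationModel
#' @param period frames per breathing cycle.
#' @param translationAmplitude per-axis translation amplitude in mm.
#' @param rotationAmplitude per-axis rotation amplitude in degrees.
#' @param phase phase offset in radians.
#' @return A [RespirationModel-class].
#' @export
respirationModel <- function(period = 16,
                             translationAmplitude = c(0.5, 2, 6),
                             rotationAmplitude = c(1.5, 0.5, 0.5),
                             phase = 0) {
  new("RespirationModel", period = period,
      translationAmplitude = as.numeric(translationAmplitude),
      rotationAmplitude = as.numeric(rotationAmplitude), phase = phase)
}

#' One synthetic CT + breathing ultrasound sample
#'
#' The test fixture standing in for a clinical CT/US pair: a textured
#' CT volume with its exact ellipsoid mask, a sequence of speckled
#' US-like sagittal frames with noise-free mask frames, and the exact
#' per-frame rigid poses that generated them.
#'
#' @slot ct,ctMask [Volume3D-class] CT volume and binary mask.
#' @slot usFrames list of 2D matrices (AP x IS).
#' @slot usMasks list of 2D binary matrices.
#' @slot gtPoses list of [RigidTransform-class] (CT to frame alignment).
#' @slot resp the [RespirationModel-class] used.
#' @slot slicePlaneRL 1-based RL index of the imaging plane.
#' @export
setClass("PhantomSample",
  representation(ct = "Volume3D", ctMask = "Volume3D",
                 usFrames = "list", usMasks = "list", gtPoses = "list",
                 resp = "RespirationModel", slicePlaneRL = "integer"))

setValidity("PhantomSample", function(object) {
  n <- length(object@usFrames)
  if (length(object@usMasks) != n || length(object@gtPoses) != n)
    return("usFrames, usMasks and gtPoses must have equal length")
  TRUE
})

#' A window of Nw consecutive ultrasound frames
#'
#' @slot frames list of Nw 2D matrices sharing shape and spacing.
#' @slot spacing in-plane spacing, mm (AP, IS).
#' @slot frameIndices 1-based indices of the source frames.
#' @export
setClass("USWindow",
  representation(frames = "list", spacing = "numeric",
                 frameIndices = "integer"))

setValidity("USWindow", function(object) {
  n <- length(object@frames)
  if (n %% 2L == 0L) return("window size must be odd")
  if (length(object@frameIndices) != n)
    return("frameIndices must match the number of frames")
  d <- dim(object@frames[[1]])
  same <- vapply(object@frames, function(f) identical(dim(f), d),
                 logical(1))
  if (!all(same)) return("all frames must share the same shape")
  TRUE
})

#' Per-parameter truncated-Gaussian transform distribution
#'
#' Parameter order: 3 rotations (degrees), 3 translations (mm). Samples
#' are rejected outside the two-sigma band around the mean.
#'
#' @slot mean numeric(6).
#' @slot sd numeric(6), all >= 0.
#' @export
setClass("TransformDistribution",
  representation(mean = "numeric", sd = "numeric"))

setValidity("TransformDistribution", function(object) {
  if (length(object@mean) != 6L || length(object@sd) != 6L)
    return("mean and sd must have length 6")
  if (any(object@sd < 0)) return("sd must be >= 0")
  TRUE
})

#' Weights of the feature-image-motion loss
#'
#' `lambda1` scales the MIND image term, `lambda2` the transform term;
#' `distMix` are the (magnitude, smoothness) weights inside the
#' transform term.
#'
#' @slot lambda1,lambda2 non-negative scalars.
#' @slot distMix numeric(2), non-negative.
#' @export
setClass("FimWeights",
  representation(lambda1 = "numeric", lambda2 = "numeric",
                 distMix = "numeric"),
  prototype(lambda1 = 0.01, lambda2 = 0.001, distMix = c(0.01, 0.99)))

setValidity("FimWeights", function(object) {
  if (object@lambda1 < 0 || object@lambda2 < 0 || any(object@distMix < 0))
    return("all weights must be >= 0")
  TRUE
})

#' Construct FIM loss weights
#' @param lambda1 weight of the MIND image loss (default 0.01).
#' @param lambda2 weight of the transform loss (default 0.001).
#' @param distMix magnitude/smoothness mix inside the transform loss
#'   (default c(0.01, 0.99)).
#' @return A [FimWeights-class].
#' @export
fimWeights <- function(lambda1 = 0.01, lambda2 = 0.001,
                       distMix = c(0.01, 0.99)) {
  new("FimWeights", lambda1 = lambda1, lambda2 = lambda2,
      distMix = as.numeric(distMix))
}

## ---------------------------------------------------------------------
## show methods

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n")
  cat("  rotation (deg, RL/AP/IS):",
      paste(sprintf("%.3f", object@rotation * 180 / pi), collapse = ", "),
      "\n")
  cat("  translation (mm):       ",
      paste(sprintf("%.3f", object@translation), collapse = ", "), "\n")
  cat("  centre (mm):            ",
      paste(sprintf("%.2f", object@centre), collapse = ", "), "\n")
})

setMethod("show", "WindowTransformSet", function(object) {
  cat(sprintf("WindowTransformSet of %d transforms (middle index %d)\n",
              windowSize(object), middleIndex(object)))
})

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("%s %dx%dx%d (RL x AP x IS), spacing %s mm\n",
              class(object), d[1], d[2], d[3],
              paste(sprintf("%.2f", object@spacing), collapse = "x")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf(
    "PhantomSample: %d US frames, CT %s voxels, period %.1f frames\n",
    length(object@usFrames),
    paste(dim(object@ct@voxels), collapse = "x"), object@resp@period))
})

## ---------------------------------------------------------------------
## small accessors

#' Voxel array of a volume
#' @param vol a [Volume3D-class].
#' @return The 3D numeric array.
#' @export
voxels <- function(vol) vol@voxels

#' Voxel spacing of a volume (mm)
#' @param vol a [Volume3D-class].
#' @return numeric(3).
#' @export
voxelSpacing <- function(vol) vol@spacing

#' World coordinate (mm) of a volume's grid centre
#' @param vol a [Volume3D-class].
#' @return numeric(3), the world position of the grid centre.
#' @export
gridCentre <- function(vol) {
  vol@origin + (dim(vol@voxels) - 1) / 2 * vol@spacing
}
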