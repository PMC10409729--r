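## Contour-based alignment metrics: kidney outlines extracted from 2D
## mask slices, Hausdorff and mean contour distance computed through a
## Euclidean distance transform, pose-error summaries and the per-
## sequence evaluation driver.

#' 2D contour extracted from a binary mask slice
#'
#' @slot points n x 2 matrix of contour coordinates in mm.
#' @slot pixels n x 2 integer matrix of 1-based pixel indices.
#' @slot maskDim dim of the source slice.
#' @slot spacing in-plane pixel spacing (mm), isotropic.
#' @export
setClass("Contour2D",
  representation(points = "matrix", pixels = "matrix",
                 maskDim = "integer", spacing = "numeric"))

setMethod("show", "Contour2D", function(object) {
  cat(sprintf("Contour2D: %d boundary points, %.2f mm pixels\n",
              nrow(object@points), object@spacing))
})

#' Number of points on a contour
#' @param contour a [Contour2D-class].
#' @return integer.
#' @export
contourSize <- function(contour) nrow(contour@points)

#' Extract the boundary contour of a 2D mask
#'
#' Boundary pixels are foreground pixels (after thresholding) with at
#' least one background 4-neighbour; pixels on the image border count
#' as boundary. Coordinates are reported in mm (0-based pixel index
#' times spacing).
#'
#' @param maskSlice 2D map with values in \[0, 1\].
#' @param threshold foreground threshold (default 0.5).
#' @param spacing isotropic in-plane pixel spacing in mm.
#' @return A [Contour2D-class]; empty (0 points) if nothing survives
#'   the threshold.
#' @export
extractContour <- function(maskSlice, threshold = 0.5, spacing = 1) {
  m <- maskSlice >= threshold
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- matrix(FALSE, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1L), 2:(n2 + 1L)] <- m
  core <- pad[2:(n1 + 1L), 2:(n2 + 1L)]
  bg4 <- !pad[1:n1, 2:(n2 + 1L)] | !pad[3:(n1 + 2L), 2:(n2 + 1L)] |
    !pad[2:(n1 + 1L), 1:n2] | !pad[2:(n1 + 1L), 3:(n2 + 2L)]
  bd <- which(core & bg4, arr.ind = TRUE)
  new("Contour2D",
      points = (bd - 1) * spacing,
      pixels = matrix(as.integer(bd), ncol = 2),
      maskDim = c(n1, n2), spacing = as.numeric(spacing))
}

## distance (mm) from each of U's points to the nearest point of C,
## via the Euclidean distance transform of C's contour raster
contour_distances <- function(U, C) {
  if (contourSize(U) == 0L || contourSize(C) == 0L)
    stop("empty contour")
  if (abs(U@spacing - C@spacing) > 1e-9)
    stop("contours must share pixel spacing")
  nd <- pmax(U@maskDim, C@maskDim)
  m <- matrix(1, nd[1], nd[2])
  m[C@pixels] <- 0
  dm <- EBImage::imageData(EBImage::distmap(m))
  dm[U@pixels] * U@spacing
}

#' Hausdorff distance between two contours
#'
#' Symmetric max-min point distance in mm, computed by sampling each
#' contour's Euclidean distance transform at the other contour's
#' points.
#'
#' @param U,C [Contour2D-class] objects (nonempty, same spacing).
#' @return distance in mm.
#' @export
hausdorffDistance <- function(U, C) {
  max(max(contour_distances(U, C)), max(contour_distances(C, U)))
}

#' Mean contour distance (MCD) between two contours
#'
#' Symmetric mean of point-to-other-contour distances pooled over both
#' contours; always less than or equal to the Hausdorff distance.
#'
#' @param U,C [Contour2D-class] objects (nonempty, same spacing).
#' @return distance in mm.
#' @export
meanContourDistance <- function(U, C) {
  mean(c(contour_distances(U, C), contour_distances(C, U)))
}

#' Rotation and translation error between two poses
#'
#' Component-wise parameter differences summarised as the L2 norm of
#' the three rotation components (degrees) and of the three
#' translation components (mm).
#'
#' @param estimated,truth [RigidTransform-class] objects sharing the
#'   same convention.
#' @return c(rotation = degrees, translation = mm).
#' @export
poseError <- function(estimated, truth) {
  dr <- (estimated@rotation - truth@rotation) * 180 / pi
  dt <- estimated@translation - truth@translation
  c(rotation = sqrt(sum(dr^2)), translation = sqrt(sum(dt^2)))
}

#' Evaluate an estimated pose sequence against phantom ground truth
#'
#' For each estimated frame pose, the CT mask is warped by the
#' estimated pose and sliced at the imaging plane; its contour is
#' compared against the US frame's mask contour (CT-US) and against
#' the contour of the plane obtained with the ground-truth pose
#' (CT-CT), by Hausdorff and mean contour distance. Frames without
#' ground truth are skipped.
#'
#' @param sample a [PhantomSample-class].
#' @param poses named or indexed list of [RigidTransform-class]; names
#'   (or the `frame` attribute) give 1-based frame numbers, otherwise
#'   positions are used.
#' @param frames integer vector of frame numbers matching `poses`.
#' @return list(perFrame = data.frame, summary = data.frame of
#'   mean +/- sd per metric).
#' @export
evaluateSequence <- function(sample, poses,
                             frames = seq_along(poses)) {
  sp <- sample@ct@spacing[2]
  rows <- lapply(seq_along(poses), function(k) {
    f <- frames[k]
    if (f < 1L || f > length(sample@gtPoses)) return(NULL)
    est <- poses[[k]]
    gt <- sample@gtPoses[[f]]
    wEst <- resampleRigid(sample@ctMask, est, "nearest")
    wGt <- resampleRigid(sample@ctMask, gt, "nearest")
    cEst <- extractContour(wEst@voxels[sample@slicePlaneRL, , ],
                           spacing = sp)
    cGt <- extractContour(wGt@voxels[sample@slicePlaneRL, , ],
                          spacing = sp)
    cUS <- extractContour(sample@usMasks[[f]], spacing = sp)
    if (contourSize(cEst) == 0L || contourSize(cUS) == 0L ||
        contourSize(cGt) == 0L)
      return(NULL)
    pe <- poseError(est, gt)
    data.frame(frame = f,
               hdCTUS = hausdorffDistance(cEst, cUS),
               mcdCTUS = meanContourDistance(cEst, cUS),
               hdCTCT = hausdorffDistance(cEst, cGt),
               mcdCTCT = meanContourDistance(cEst, cGt),
               rotErr = pe["rotation"], transErr = pe["translation"])
  })
  per <- do.call(rbind, rows)
  metrics <- c("hdCTUS", "mcdCTUS", "hdCTCT", "mcdCTCT", "rotErr",
               "transErr")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) sd(per[[m]]), numeric(1)))
  list(perFrame = per, summary = summ)
}
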