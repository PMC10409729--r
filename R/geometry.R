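## Rigid-transform algebra and rigid resampling (the STN contract).
##
## Euler convention: R = R_RL(a1) %*% R_AP(a2) %*% R_IS(a3), i.e.
## intrinsic rotations applied in axis order RL -> AP -> IS, acting on
## column vectors. Transforms act on world coordinates (mm) as
## T(x) = R (x - c) + c + t about the centre c.

rotAxis <- function(theta, axis) {
  c_ <- cos(theta); s_ <- sin(theta)
  ## right-handed rotations: cyclic axis pairs (2,3), (3,1), (1,2)
  ij <- switch(axis, c(2L, 3L), c(3L, 1L), c(1L, 2L))
  R <- diag(3)
  i <- ij[1]; j <- ij[2]
  R[i, i] <- c_; R[i, j] <- -s_
  R[j, i] <- s_; R[j, j] <- c_
  R
}

eulerToRotation <- function(angles) {
  rotAxis(angles[1], 1) %*% rotAxis(angles[2], 2) %*% rotAxis(angles[3], 3)
}

## inverse of eulerToRotation (gimbal-safe away from |a2| = pi/2)
rotationToEuler <- function(R) {
  a2 <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(a2)) > 1e-9) {
    a1 <- atan2(-R[2, 3], R[3, 3])
    a3 <- atan2(-R[1, 2], R[1, 1])
  } else {
    a1 <- atan2(R[2, 1], R[2, 2])
    a3 <- 0
  }
  c(a1, a2, a3)
}

#' Homogeneous 4x4 matrix view of a rigid transform
#'
#' Returns the matrix of \eqn{T(x) = R (x - c) + c + t}: the rotation
#' block is `R` and the translation column is `c + t - R c`. With
#' `translationScale` the translation column is divided by a reference
#' length so rotation and translation entries are commensurate (used by
#' the transform-loss norm).
#'
#' @param transform a [RigidTransform-class].
#' @param translationScale reference length (mm) dividing the
#'   translation column; default 1 (translations in mm).
#' @return 4x4 numeric matrix, last row (0, 0, 0, 1).
#' @examples
#' toMatrix(rigidTransform(translation = c(1, 2, 3)))
#' @export
toMatrix <- function(transform, translationScale = 1) {
  R <- eulerToRotation(transform@rotation)
  cc <- transform@centre
  b <- cc + transform@translation - as.vector(R %*% cc)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- b / translationScale
  M
}

## Recover (rotation, translation) from a 4x4 matrix, keeping a centre.
matrixToTransform <- function(M, centre = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  b <- M[1:3, 4]
  t <- b - centre + as.vector(R %*% centre)
  rigidTransform(rotation = rotationToEuler(R), translation = t,
                 centre = centre)
}

#' Compose two rigid transforms
#'
#' Returns the transform whose matrix is `toMatrix(A) %*% toMatrix(B)`
#' (apply `B` first, then `A`). Both transforms must share the same
#' centre convention; the result keeps `A`'s centre.
#'
#' @param A,B [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(A, B) {
  matrixToTransform(toMatrix(A) %*% toMatrix(B), centre = A@centre)
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return The inverse transform (same centre).
#' @export
invertTransform <- function(transform) {
  matrixToTransform(solve(toMatrix(transform)),
                    centre = transform@centre)
}

#' Whether a transform is the identity
#' @param transform a [RigidTransform-class].
#' @param tol tolerance on parameters.
#' @return logical.
#' @export
isIdentityTransform <- function(transform, tol = 1e-9) {
  all(abs(transform@rotation) < tol) &&
    all(abs(transform@translation) < tol)
}

## Voxel-space sampling map of resampleRigid: output voxel index i
## (0-based) samples input voxel coordinate A[,1:3] i + A[,4]. This is
## the matrix of T^{-1} expressed in index space.
samplingMap <- function(vol, transform) {
  R <- eulerToRotation(transform@rotation)
  cc <- transform@centre
  tt <- transform@translation
  S <- vol@spacing
  o <- vol@origin
  Rt <- t(R)
  ## T^{-1}(w) = Rt (w - c - t) + c; w = o + S * i
  Alin <- Rt * rep(S, each = 3) / S            # diag(1/S) %*% Rt %*% diag(S)
  b <- as.vector(Rt %*% (o - cc - tt) + cc - o) / S
  cbind(Alin, b)
}

#' Rigidly resample a volume (spatial-transformer contract)
#'
#' Applies `transform` to the image content: a structure at world
#' position `x` in the input appears at `T(x)` in the output. The
#' output grid is identical to the input grid; samples falling outside
#' the input are filled with zero (the neutral background of the
#' zero-padded ultrasound window volume).
#'
#' @param vol a [Volume3D-class] (finite voxels).
#' @param transform a [RigidTransform-class].
#' @param interpolation "linear" or "nearest".
#' @return A [Volume3D-class] on the same grid.
#' @examples
#' v <- volume3D(array(rnorm(8^3), c(8, 8, 8)))
#' identical(voxels(resampleRigid(v, rigidTransform())), voxels(v))
#' @export
resampleRigid <- function(vol, transform, interpolation = c("linear",
                                                            "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!all(is.finite(vol@voxels)))
    stop("volume contains non-finite voxels")
  A <- samplingMap(vol, transform)
  out <- cpp_warp_affine(vol@voxels, A, dim(vol@voxels), dim(vol@voxels),
                         as.integer(interpolation == "nearest"))
  new(class(vol)[1], vol, voxels = out)
}

#' Mean matrix distance of a transform window from the identity
#'
#' Computes \eqn{\frac{1}{N_w} \sum_i \lVert D_i - I_{4\times4}\rVert_F}
#' over the window, with the translation column of each matrix divided
#' by `refLength` so rotation and translation entries are commensurate.
#'
#' @param W a [WindowTransformSet-class].
#' @param refLength reference length in mm (default one voxel at
#'   0.8 mm).
#' @return non-negative scalar; 0 iff every transform is the identity.
#' @export
transformDistance <- function(W, refLength = 0.8) {
  ms <- vapply(W@transforms, function(t) {
    M <- toMatrix(t, translationScale = refLength)
    sqrt(sum((M - diag(4))^2))
  }, numeric(1))
  mean(ms)
}

## ---------------------------------------------------------------------
## Plain-text serialisation

#' Pose table of a list of transforms
#'
#' One row per frame: rotations in degrees, translations in mm.
#'
#' @param transforms list of [RigidTransform-class].
#' @return data.frame with columns frame, rotRL/rotAP/rotIS (deg),
#'   transRL/transAP/transIS (mm).
#' @export
poseTable <- function(transforms) {
  rot <- t(vapply(transforms, function(t) t@rotation * 180 / pi,
                  numeric(3)))
  tra <- t(vapply(transforms, function(t) t@translation, numeric(3)))
  data.frame(frame = seq_along(transforms),
             rotRL = rot[, 1], rotAP = rot[, 2], rotIS = rot[, 3],
             transRL = tra[, 1], transAP = tra[, 2], transIS = tra[, 3])
}

#' Write / read a pose table as CSV
#' @param transforms list of [RigidTransform-class].
#' @param path output CSV path.
#' @return `writePoseTable` returns `path` invisibly; `readPoseTable`
#'   returns a list of [RigidTransform-class] (centre not stored).
#' @export
writePoseTable <- function(transforms, path) {
  write.csv(poseTable(transforms), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePoseTable
#' @param centre rotation centre assigned to the read transforms.
#' @export
readPoseTable <- function(path, centre = c(0, 0, 0)) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    rigidTransform(
      rotation = as.numeric(df[i, c("rotRL", "rotAP", "rotIS")]) * pi / 180,
      translation = as.numeric(df[i, c("transRL", "transAP", "transIS")]),
      centre = centre)
  })
}

#' Write a transform's 4x4 matrix as a text file
#' @param transform a [RigidTransform-class].
#' @param path output path (whitespace-separated 4x4 matrix).
#' @return `path`, invisibly.
#' @export
writeTransformMatrix <- function(transform, path) {
  write(t(toMatrix(transform)), path, ncolumns = 4)
  invisible(path)
}
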