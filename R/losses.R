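## The feature-image-motion (FIM) loss: a windowed elementwise-Dice
## feature term on kidney probability maps, a masked MIND image term,
## and a motion-regularised transform term. Each loss exists in two
## forms: a plain evaluation on arrays, and a tape-graph form
## (fim_graph) through which the registration network backpropagates
## into its predicted transform parameters.

## face-neighbour displacement set N, in (RL, AP, IS) voxel steps
MIND_DISPLACEMENTS <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L),
                           c(0L, -1L, 0L), c(0L, 1L, 0L),
                           c(0L, 0L, -1L), c(0L, 0L, 1L))

mind_eps <- function(vals) {
  dr <- diff(range(vals))
  max(1e-6 * dr * dr, 1e-12)
}

## MIND graph on a volume node: [X,Y,Z] -> [X,Y,Z,6].
## D_p(x, r) = 3x3x3 patch mean of (I - shift(I, r))^2 (zero-padded),
## channel = exp(-D_p / V) with V = per-voxel mean of the six D_p
## floored at eps, then divided by the per-voxel max channel.
mind_graph <- function(tape, vol, eps = NULL) {
  if (is.null(eps)) eps <- mind_eps(vol$value)
  ## pad by 2 so the patch sums see the zero-padded image rather than
  ## truncated patches, then crop back after the box filter
  vp <- td_pad3(tape, vol, 2L)
  dps <- lapply(MIND_DISPLACEMENTS, function(r) {
    d <- td_sub(tape, vp, td_shift3d(tape, vp, r))
    td_square(tape, d)
  })
  D <- td_crop3(tape, td_boxfilter3(tape, td_concat_c(tape, dps)), 2L)
  V <- td_clamp_min(tape, td_chan_mean(tape, D), eps)
  E <- td_exp(tape, td_neg(tape, td_div_bc(tape, D, V)))
  td_div_bc(tape, E, td_chan_max(tape, E))
}

#' Modality-independent neighbourhood descriptor (MIND)
#'
#' Six channels per voxel, one per face-neighbour displacement (-RL,
#' +RL, -AP, +AP, -IS, +IS). Each channel is a Gaussian function of the
#' mean squared difference between the 3x3x3 patch at the voxel and the
#' patch at the displaced position (zero-padded at boundaries),
#' variance-normalised by the per-voxel mean of the six patch distances
#' (floored at `eps`), then divided by the per-voxel maximum so the
#' strongest channel is exactly 1.
#'
#' @param vol a [Volume3D-class] or 3D array with finite values.
#' @param eps variance floor; default `1e-6 * dynamicRange^2`.
#' @return numeric array `[X, Y, Z, 6]` with values in (0, 1].
#' @examples
#' m <- mindDescriptor(array(rnorm(6^3), c(6, 6, 6)))
#' range(apply(m, 1:3, max))  # per-voxel max channel is exactly 1
#' @export
mindDescriptor <- function(vol, eps = NULL) {
  v <- if (is(vol, "Volume3D")) vol@voxels else vol
  if (!all(is.finite(v))) stop("volume contains non-finite values")
  tape <- td_tape()
  mind_graph(tape, td_const(v), eps)$value
}

#' Elementwise (soft) Dice of two maps
#'
#' The mean over elements of \eqn{2xy / (x + y + \epsilon)}. This is
#' the elementwise formula used inside the feature loss; it is distinct
#' from the set Dice used to score segmentations ([segMetrics()]).
#'
#' @param x,y same-shape arrays with values in \[0, 1\].
#' @param eps stabiliser keeping (0, 0) background elements at 0.
#' @return scalar in \[0, 1\].
#' @export
elementwiseDice <- function(x, y, eps = 1e-6) {
  stopifnot(identical(dim(x), dim(y)) || length(x) == length(y))
  mean(2 * x * y / (x + y + eps))
}

dice_graph <- function(tape, a, bconst, eps = 1e-6) {
  num <- td_smul(tape, td_mul(tape, a, bconst), 2)
  den <- td_sadd(tape, td_add(tape, a, bconst), eps)
  td_mean(tape, td_div(tape, num, den))
}

## ---------------------------------------------------------------------
## transform parameter nodes -> matrices

## rotation node (3x3) from a 6-parameter theta node (rot rad, trans mm)
theta_rotation <- function(tape, theta) {
  a1 <- td_index(tape, theta, 1L)
  a2 <- td_index(tape, theta, 2L)
  a3 <- td_index(tape, theta, 3L)
  R1 <- td_rot3(tape, a1, 1L)
  R2 <- td_rot3(tape, a2, 2L)
  R3 <- td_rot3(tape, a3, 3L)
  td_matmul(tape, td_matmul(tape, R1, R2), R3)
}

## 3x4 voxel-space sampling map node of resampleRigid for theta
theta_sampling_map <- function(tape, theta, geom) {
  R <- theta_rotation(tape, theta)
  Rt <- td_transpose(tape, R)
  S <- geom$spacing
  o <- geom$origin
  cc <- geom$centre
  tvec <- td_node(tape, matrix(theta$value[4:6], 3, 1), list(theta),
                  function(g) {
                    gt <- numeric(6)
                    gt[4:6] <- as.vector(g)
                    td_acc(theta, gt)
                  })
  Alin <- td_mul(tape, Rt, td_const(outer(1 / S, S)))
  w <- td_sub(tape, td_const(matrix(o - cc, 3, 1)), tvec)
  b <- td_mul(tape,
              td_add(tape, td_matmul(tape, Rt, w),
                     td_const(matrix(cc - o, 3, 1))),
              td_const(matrix(1 / S, 3, 1)))
  td_affine_pack(tape, Alin, b)
}

## 3x4 homogeneous-matrix view node [R | (c + t - R c)/refLength]
theta_matrix_view <- function(tape, theta, centre, refLength) {
  R <- theta_rotation(tape, theta)
  tvec <- td_node(tape, matrix(theta$value[4:6], 3, 1), list(theta),
                  function(g) {
                    gt <- numeric(6)
                    gt[4:6] <- as.vector(g)
                    td_acc(theta, gt)
                  })
  Rc <- td_matmul(tape, R, td_const(matrix(centre, 3, 1)))
  col <- td_smul(tape,
                 td_add(tape, td_sub(tape, td_const(matrix(centre, 3, 1)),
                                     Rc), tvec),
                 1 / refLength)
  td_affine_pack(tape, R, col)
}

## Frobenius norm node; the value is exact and the gradient uses a
## floored denominator so it stays finite at exactly zero
frob_graph <- function(tape, M) {
  ss <- td_sum(tape, td_square(tape, M))
  v <- sqrt(ss$value)
  td_node(tape, v, list(ss), function(g) {
    td_acc(ss, g / (2 * max(v, 1e-8)))
  })
}

## ---------------------------------------------------------------------
## the three loss terms as graphs

## geometry descriptor shared by the graph losses
loss_geometry <- function(dims, spacing, origin = c(0, 0, 0),
                          centre = NULL, refLength = NULL, Nw = 5L) {
  if (is.null(centre)) centre <- origin + (dims - 1) / 2 * spacing
  if (is.null(refLength)) refLength <- spacing[1]
  list(dims = as.integer(dims), spacing = spacing, origin = origin,
       centre = centre, refLength = refLength, Nw = as.integer(Nw),
       middleRL = dims[1] %/% 2L + 1L,
       frameRL = embed_rl_indices(dims[1], Nw) + 1L)
}

## feature term: mean negative elementwise Dice between the middle RL
## slice of the per-frame warped CT feature map and each US frame map
feature_graph <- function(tape, thetas, Mmov, MfixFrames, geom,
                          eps = 1e-6) {
  ds <- lapply(seq_along(thetas), function(i) {
    A <- theta_sampling_map(tape, thetas[[i]], geom)
    w <- td_warp(tape, Mmov, A)
    sl <- td_slice_x(tape, w, geom$middleRL)
    dice_graph(tape, sl, td_const(MfixFrames[[i]]), eps)
  })
  acc <- ds[[1]]
  for (i in seq_along(ds)[-1]) acc <- td_add(tape, acc, ds[[i]])
  td_smul(tape, acc, -1 / length(ds))
}

## image term: mean absolute MIND difference on the middle RL slice
## between the fixed US window volume and the warped masked CT
image_graph <- function(tape, thetaMid, maskedCT, mindFixMid, geom) {
  A <- theta_sampling_map(tape, thetaMid, geom)
  w <- td_warp(tape, maskedCT, A)
  mw <- mind_graph(tape, w)
  sl <- td_slice_x(tape, mw, geom$middleRL)
  td_mean(tape, td_abs(tape, td_sub(tape, sl, td_const(mindFixMid))))
}

## transform term: distMix[1] * mean ||D_i - I|| + distMix[2] * gradD
transform_graph <- function(tape, thetas, geom,
                            distMix = c(0.01, 0.99)) {
  Nw <- length(thetas)
  if (Nw < 3L) stop("transform loss needs a window of at least 3")
  Ms <- lapply(thetas, theta_matrix_view, tape = tape,
               centre = geom$centre, refLength = geom$refLength)
  I34 <- td_const(cbind(diag(3), c(0, 0, 0)))
  dist <- NULL
  for (M in Ms) {
    n <- frob_graph(tape, td_sub(tape, M, I34))
    dist <- if (is.null(dist)) n else td_add(tape, dist, n)
  }
  dist <- td_smul(tape, dist, 1 / Nw)
  grad <- NULL
  for (i in 2:(Nw - 1L)) {
    sec <- td_sub(tape, td_add(tape, Ms[[i + 1L]], Ms[[i - 1L]]),
                  td_smul(tape, Ms[[i]], 2))
    n <- frob_graph(tape, sec)
    grad <- if (is.null(grad)) n else td_add(tape, grad, n)
  }
  grad <- td_smul(tape, grad, 1 / (Nw - 2L))
  td_add(tape, td_smul(tape, dist, distMix[1]),
         td_smul(tape, grad, distMix[2]))
}

## full FIM graph; returns the term nodes
fim_graph <- function(tape, thetas, Mmov, MfixFrames, maskedCT,
                      mindFixMid, geom, weights) {
  lf <- feature_graph(tape, thetas, Mmov, MfixFrames, geom)
  li <- image_graph(tape, thetas[[(length(thetas) + 1L) %/% 2L]],
                    maskedCT, mindFixMid, geom)
  ld <- transform_graph(tape, thetas, geom, weights@distMix)
  total <- td_add(tape, lf,
                  td_add(tape, td_smul(tape, li, weights@lambda1),
                         td_smul(tape, ld, weights@lambda2)))
  list(total = total, feature = lf, image = li, transform = ld)
}

## ---------------------------------------------------------------------
## exported plain evaluations

## theta vectors (rot rad, trans mm) from a WindowTransformSet
window_thetas <- function(W) {
  lapply(W@transforms, function(t) c(t@rotation, t@translation))
}

## US frame feature slices from an embedded window feature volume
window_frame_slices <- function(MfixVol, Nw) {
  dm <- dim(MfixVol)
  rl <- embed_rl_indices(dm[1], Nw) + 1L
  lapply(rl, function(i) array(MfixVol[i, , ], dim = dm[2:3]))
}

#' Windowed feature loss (negative mean elementwise Dice)
#'
#' For each frame i, the moving CT feature map is warped by the frame's
#' transform, its middle RL slice is taken, and the elementwise Dice
#' against frame i's US feature map is computed; the loss is the
#' negative mean over the window, in \[-1, 0\].
#'
#' @param Mfix embedded US window feature volume ([FeatureMap-class] or
#'   [Volume3D-class]).
#' @param Mmov CT feature map on the same canonical grid.
#' @param W a [WindowTransformSet-class].
#' @param eps Dice stabiliser.
#' @return scalar in \[-1, 0\].
#' @export
featureLoss <- function(Mfix, Mmov, W, eps = 1e-6) {
  Nw <- windowSize(W)
  dm <- dim(Mfix@voxels)
  if (!identical(dm, dim(Mmov@voxels)))
    stop("fixed and moving volumes must share the canonical grid")
  geom <- loss_geometry(dm, Mfix@spacing, Mfix@origin,
                        centre = W@transforms[[1]]@centre, Nw = Nw)
  frames <- window_frame_slices(Mfix@voxels, Nw)
  tape <- td_tape()
  feature_graph(tape, lapply(window_thetas(W), td_const), # constants
                td_const(Mmov@voxels), frames, geom, eps)$value
}

#' Masked MIND image loss
#'
#' The moving CT is masked by elementwise multiplication with its
#' feature map, warped by the middle frame's transform, and compared to
#' the fixed US window volume through the mean absolute MIND channel
#' difference on the middle RL slice.
#'
#' @param Ifix embedded US window intensity volume.
#' @param Imov CT intensity volume.
#' @param Mmov CT feature map (mask) on the same grid.
#' @param W a [WindowTransformSet-class].
#' @return non-negative scalar.
#' @export
imageLoss <- function(Ifix, Imov, Mmov, W) {
  dm <- dim(Ifix@voxels)
  Nw <- windowSize(W)
  geom <- loss_geometry(dm, Ifix@spacing, Ifix@origin,
                        centre = W@transforms[[1]]@centre, Nw = Nw)
  mindFix <- mindDescriptor(Ifix@voxels)
  mindFixMid <- array(mindFix[geom$middleRL, , , ], dim = c(dm[2:3], 6L))
  masked <- Imov@voxels * Mmov@voxels
  tape <- td_tape()
  image_graph(tape, td_const(c(W@transforms[[middleIndex(W)]]@rotation,
                               W@transforms[[middleIndex(W)]]@translation)),
              td_const(masked), mindFixMid, geom)$value
}

#' Motion-regularised transform loss
#'
#' `distMix[1]` times the mean Frobenius distance of the window's
#' matrices from the identity ([transformDistance()]) plus `distMix[2]`
#' times the mean second-difference norm over interior frames (zero for
#' constant-velocity motion).
#'
#' @param W a [WindowTransformSet-class] with at least 3 frames.
#' @param distMix magnitude/smoothness weights, default c(0.01, 0.99).
#' @param refLength reference length (mm) making translations
#'   commensurate with rotations in the matrix norm.
#' @return non-negative scalar.
#' @export
transformLoss <- function(W, distMix = c(0.01, 0.99), refLength = 0.8) {
  Nw <- windowSize(W)
  if (Nw < 3L) stop("gradD undefined for windows smaller than 3")
  mats <- lapply(W@transforms, toMatrix, translationScale = refLength)
  dist <- mean(vapply(mats, function(M) sqrt(sum((M - diag(4))^2)),
                      numeric(1)))
  sec <- vapply(2:(Nw - 1L), function(i) {
    sqrt(sum((mats[[i + 1L]] + mats[[i - 1L]] - 2 * mats[[i]])^2))
  }, numeric(1))
  distMix[1] * dist + distMix[2] * mean(sec)
}

#' Feature-image-motion (FIM) loss
#'
#' The composite registration objective: feature term plus
#' `lambda1` times the image term plus `lambda2` times the transform
#' term. Optionally returns the gradient with respect to the 6 Nw
#' transform parameters (rotations in radians, translations in mm,
#' frame-major order).
#'
#' @param Ifix,Imov fixed US window and moving CT intensity volumes.
#' @param Mfix,Mmov fixed and moving feature maps on the same grid.
#' @param W a [WindowTransformSet-class].
#' @param weights a [FimWeights-class].
#' @param gradient if TRUE, also return the parameter gradient.
#' @return list(total, feature, image, transform, gradient?).
#' @export
fimLoss <- function(Ifix, Imov, Mfix, Mmov, W, weights = fimWeights(),
                    gradient = FALSE) {
  dm <- dim(Ifix@voxels)
  Nw <- windowSize(W)
  geom <- loss_geometry(dm, Ifix@spacing, Ifix@origin,
                        centre = W@transforms[[1]]@centre, Nw = Nw)
  mindFix <- mindDescriptor(Ifix@voxels)
  mindFixMid <- array(mindFix[geom$middleRL, , , ], dim = c(dm[2:3], 6L))
  frames <- window_frame_slices(Mfix@voxels, Nw)
  masked <- Imov@voxels * Mmov@voxels
  tape <- td_tape()
  mk <- if (gradient) function(v) td_leaf(tape, v) else td_const
  thetas <- lapply(window_thetas(W), mk)
  gr <- fim_graph(tape, thetas, td_const(Mmov@voxels), frames,
                  td_const(masked), mindFixMid, geom, weights)
  out <- list(total = gr$total$value, feature = gr$feature$value,
              image = gr$image$value, transform = gr$transform$value)
  if (gradient) {
    td_backward(tape, gr$total)
    out$gradient <- do.call(rbind, lapply(thetas, function(th)
      th$grad %||% numeric(6)))
  }
  out
}
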