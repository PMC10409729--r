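## Canonicalisation of CT volumes and US frame sequences into the
## fixed-size paired volumes the registration network consumes: 0.8 mm
## isotropic resampling, centroid cropping, sliding time windows and
## zero-padded embedding of windows along the RL axis.

#' Resample a volume to isotropic spacing
#'
#' Linear interpolation; the world extent is preserved to within one
#' voxel. A volume already at the target spacing is returned
#' voxel-identical.
#'
#' @param vol a [Volume3D-class].
#' @param targetSpacing isotropic spacing in mm (default 0.8).
#' @return A [Volume3D-class] at the requested spacing.
#' @export
resampleIsotropic <- function(vol, targetSpacing = 0.8) {
  if (targetSpacing <= 0) stop("target spacing must be positive")
  dm <- dim(vol@voxels)
  if (all(abs(vol@spacing - targetSpacing) < 1e-12)) return(vol)
  ## keep every output sample inside the input extent (shrink by at
  ## most one voxel rather than extrapolating into zero padding)
  odim <- pmax(1L, as.integer(floor((dm - 1) * vol@spacing /
                                      targetSpacing + 1e-9)) + 1L)
  A <- cbind(diag(targetSpacing / vol@spacing, 3), c(0, 0, 0))
  out <- cpp_warp_affine(vol@voxels, A, dm, odim, 0L)
  new(class(vol)[1], vol, voxels = out,
      spacing = rep(targetSpacing, 3))
}

## weighted centroid of a feature map, in 0-based voxel indices
fmap_centroid_vox <- function(values) {
  s <- sum(values)
  if (s <= 0) stop("empty feature map")
  dm <- dim(values)
  ix <- array(seq_len(dm[1]) - 1, dim = dm)
  iy <- array(rep(seq_len(dm[2]) - 1, each = dm[1]), dim = dm)
  iz <- array(rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2]), dim = dm)
  c(sum(ix * values), sum(iy * values), sum(iz * values)) / s
}

#' World-coordinate centroid of a feature map
#' @param fmap a [FeatureMap-class] (or any [Volume3D-class] with
#'   non-negative values summing above zero).
#' @return numeric(3), mm.
#' @export
featureCentroid <- function(fmap) {
  fmap@origin + fmap_centroid_vox(fmap@voxels) * fmap@spacing
}

#' Crop a volume about a feature-map centroid
#'
#' Produces a volume of exactly `dims` voxels whose centre coincides
#' (to the nearest voxel) with the feature-map centroid, zero-padding
#' wherever the crop exceeds the input. The world origin is adjusted so
#' voxel world coordinates are preserved.
#'
#' @param vol a [Volume3D-class].
#' @param fmap a [FeatureMap-class] on the same grid.
#' @param dims target dims (RL, AP, IS), default c(128, 224, 288).
#' @return A [Volume3D-class] of size `dims`.
#' @export
cropAboutCentroid <- function(vol, fmap, dims = c(128L, 224L, 288L)) {
  dm <- dim(vol@voxels)
  if (!identical(dim(fmap@voxels), dm))
    stop("feature map must be on the volume's grid")
  dims <- as.integer(dims)
  cen <- fmap_centroid_vox(fmap@voxels)             # 0-based
  shift <- as.integer(round(cen - (dims - 1) / 2))   # input idx of out 0
  out <- array(0, dim = dims)
  ## overlap ranges in output (0-based)
  lo <- pmax(0L, -shift)
  hi <- pmin(dims - 1L, dm - 1L - shift)
  if (all(lo <= hi)) {
    out[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L] <-
      vol@voxels[(lo[1]:hi[1]) + shift[1] + 1L,
                 (lo[2]:hi[2]) + shift[2] + 1L,
                 (lo[3]:hi[3]) + shift[3] + 1L]
  }
  new(class(vol)[1], vol, voxels = out,
      origin = vol@origin + shift * vol@spacing)
}

#' Sliding time windows over an ultrasound frame sequence
#'
#' Window k covers frames k .. k+Nw-1; its middle frame is frame
#' k+(Nw-1)/2. With F frames there are F-Nw+1 windows.
#'
#' @param frames list of 2D matrices (AP x IS), shared shape.
#' @param Nw odd window size (default 5).
#' @param spacing in-plane spacing in mm.
#' @return list of [USWindow-class].
#' @export
windowUS <- function(frames, Nw = 5L, spacing = c(0.8, 0.8)) {
  Nw <- as.integer(Nw)
  if (Nw %% 2L == 0L) stop("Nw must be odd")
  if (length(frames) < Nw) stop("too few frames for the window size")
  lapply(seq_len(length(frames) - Nw + 1L), function(k) {
    new("USWindow", frames = frames[k:(k + Nw - 1L)],
        spacing = as.numeric(spacing),
        frameIndices = as.integer(k:(k + Nw - 1L)))
  })
}

#' Middle frame index of a US window
#' @param w a [USWindow-class].
#' @return 1-based index into the source sequence.
#' @export
windowMiddleFrame <- function(w) {
  w@frameIndices[(length(w@frames) + 1L) %/% 2L]
}

## 0-based RL indices occupied by the Nw frames of an embedded window
embed_rl_indices <- function(dimRL, Nw) {
  centre <- dimRL %/% 2L                      # 0-based
  (centre - (Nw - 1L) %/% 2L):(centre + (Nw - 1L) %/% 2L)
}

#' Embed a US window into a zero-padded 3D volume
#'
#' The Nw frames are stacked along the RL (time) axis, centred at RL
#' index `dims[1] %/% 2` (0-based; e.g. frames at 62..66 with the
#' middle frame at 64 for Nw = 5, dims = 128), and centred in-plane;
#' all other voxels are zero.
#'
#' @param w a [USWindow-class].
#' @param dims target volume dims, default c(128, 224, 288).
#' @return A [Volume3D-class].
#' @export
embedUSWindow <- function(w, dims = c(128L, 224L, 288L)) {
  dims <- as.integer(dims)
  Nw <- length(w@frames)
  fd <- dim(w@frames[[1]])
  if (fd[1] > dims[2] || fd[2] > dims[3])
    stop("frame larger than the target plane")
  out <- array(0, dim = dims)
  rl <- embed_rl_indices(dims[1], Nw) + 1L          # 1-based
  o2 <- (dims[2] - fd[1]) %/% 2L
  o3 <- (dims[3] - fd[2]) %/% 2L
  for (i in seq_len(Nw)) {
    out[rl[i], (o2 + 1L):(o2 + fd[1]), (o3 + 1L):(o3 + fd[2])] <-
      w@frames[[i]]
  }
  volume3D(out, spacing = c(w@spacing[1], w@spacing))
}

#' Centroid pre-alignment of CT to the US window volume
#'
#' Returns the pure translation moving the CT kidney-feature centroid
#' onto the US kidney-feature centroid (both in world mm), applied to
#' the CT before the registration network.
#'
#' @param ctFmap CT [FeatureMap-class].
#' @param usFmapVol US window feature volume (a [FeatureMap-class] or
#'   [Volume3D-class] of the embedded window feature maps).
#' @return A pure-translation [RigidTransform-class] centred on the CT
#'   grid centre.
#' @export
centroidAlign <- function(ctFmap, usFmapVol) {
  ctc <- featureCentroid(ctFmap)
  usc <- featureCentroid(usFmapVol)
  rigidTransform(translation = usc - ctc, centre = gridCentre(ctFmap))
}
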