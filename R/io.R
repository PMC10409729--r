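## NIfTI input/output. Volumes are stored with their voxel spacing in
## the NIfTI pixdim; axis order on disk matches the in-memory (RL, AP,
## IS) array order and images are assumed already in RAI orientation.

#' Write a volume as NIfTI
#' @param vol a [Volume3D-class].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@voxels, internal = FALSE)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path NIfTI file path.
#' @return A [Volume3D-class] with spacing from the header.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) stop("expected a 3D NIfTI image")
  volume3D(array(as.numeric(img), dim = dm),
           spacing = RNifti::pixdim(img)[1:3])
}
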