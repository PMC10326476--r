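#' Read a template-space volume from NIfTI
#'
#' Loads a single 3-D NIfTI volume (`.nii` or `.nii.gz`) together with its
#' voxel-to-world affine. Non-finite voxels are treated as missing and a
#' warning reports their count. 4-D files are rejected: the framework
#' operates on single static frames / SUVR-ready volumes only.
#'
#' @param path path to a NIfTI file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3-D volume, got ", length(d), "-D in ", path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- template_grid(d, affine = aff)
  values <- array(as.numeric(img), dim = d)
  n_missing <- sum(!is.finite(values))
  if (n_missing > 0L) {
    values[!is.finite(values)] <- NaN
    warning(n_missing, " non-finite voxel(s) flagged missing in ", path)
  }
  volume_image(values, grid)
}

#' Write a volume to NIfTI
#'
#' @param image a [volume_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "volume_image"))
  img <- RNifti::asNifti(image$values)
  RNifti::`sform<-`(img, structure(image$grid$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Any voxel with a finite, nonzero value is inside the mask; probabilistic
#' maps should be binarized explicitly first (see [universal_mask()] for
#' the gray-matter convention).
#'
#' @param path path to a NIfTI file storing the mask as a 0/1 volume.
#' @param threshold voxels strictly above this value are in the mask
#'   (default 0.5, so 0/1 masks load exactly and probability maps are
#'   binarized at > 0.5).
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, threshold = 0.5) {
  vol <- suppressWarnings(read_volume(path))
  m <- vol$values > threshold
  m[!is.finite(vol$values)] <- FALSE
  binary_mask(m, vol$grid)
}

#' Write a binary mask to NIfTI as an integer 0/1 volume
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$membership),
                               dim = mask$grid$shape),
                         datatype = "uint8")
  RNifti::`sform<-`(img, structure(mask$grid$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}
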