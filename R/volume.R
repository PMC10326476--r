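#' Scalar volume on a template grid
#'
#' A `volume_image` pairs a 3-D numeric array with its `template_grid`.
#' Values may be tracer uptake (arbitrary units) or a derived unitless
#' quantity (SUVR, CTRz). Missing voxels are represented as `NaN`/`NA` and
#' are excluded from all region means.
#'
#' @param values numeric array whose dimension equals `grid$shape`.
#' @param grid a [template_grid()].
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, grid) {
  stopifnot(inherits(grid, "template_grid"))
  values <- as.array(values)
  if (!is.numeric(values) || length(dim(values)) != 3L)
    stop("'values' must be a numeric 3-D array")
  if (!all(dim(values) == grid$shape))
    stop("'values' dimension does not match grid shape")
  structure(list(values = values, grid = grid), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  v <- x$values
  cat("volume_image:", paste(dim(v), collapse = " x "),
      sprintf("voxels, range [%.4g, %.4g], %d missing\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              sum(!is.finite(v))))
  invisible(x)
}

#' Binary mask on a template grid
#'
#' @param membership logical (or 0/1 numeric) array matching `grid$shape`.
#'   `NA` voxels are treated as outside the mask.
#' @param grid a [template_grid()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(membership, grid) {
  stopifnot(inherits(grid, "template_grid"))
  membership <- as.array(membership)
  if (length(dim(membership)) != 3L || !all(dim(membership) == grid$shape))
    stop("'membership' dimension does not match grid shape")
  m <- array(as.logical(membership), dim = grid$shape)
  m[is.na(m)] <- FALSE
  structure(list(membership = m, grid = grid), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask:", mask_size(x), "of", prod(x$grid$shape), "voxels\n")
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask a `binary_mask`.
#' @return integer voxel count.
#' @export
mask_size <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$membership)
}

# mean of image values over a mask, missing voxels excluded
mask_mean <- function(image, mask) {
  stopifnot(inherits(image, "volume_image"), inherits(mask, "binary_mask"))
  check_grids(image$grid, mask$grid, what = "image and mask")
  if (mask_size(mask) == 0L) stop("mask is empty")
  v <- image$values[mask$membership]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("all voxels in mask are missing")
  mean(v)
}
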