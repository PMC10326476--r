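#' Template-space voxel grid
#'
#' A `template_grid` describes the common sampling grid that every volume
#' and mask in an analysis must share: the array dimensions, and the 4x4
#' affine mapping 0-based voxel indices to world (template) coordinates in
#' millimetres. All multi-image operations in the package check grid
#' compatibility and refuse to mix grids; no resampling is ever performed.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric vector of length 3 (or scalar), voxel edge
#'   lengths in mm (all > 0). Ignored when `affine` is given.
#' @param affine optional 4x4 voxel-to-world matrix. When omitted, an
#'   axis-aligned affine is built from `voxel_size` with the world origin
#'   at the grid centre, so the template is symmetric about x = 0.
#'
#' @return An object of class `template_grid` with elements `shape`,
#'   `affine` and derived `voxel_size`.
#' @examples
#' g <- template_grid(c(91, 109, 91), 2)
#' g$voxel_size
#' @export
template_grid <- function(shape, voxel_size = NULL, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  if (is.null(affine)) {
    if (is.null(voxel_size)) voxel_size <- 1
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
      stop("'voxel_size' must be positive")
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size
    # voxel centres symmetric about the world origin
    affine[1:3, 4] <- -voxel_size * (shape - 1L) / 2
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
      stop("'affine' must be a finite 4x4 matrix")
    if (abs(det(affine)) < .Machine$double.eps)
      stop("'affine' must be invertible")
  }
  structure(
    list(shape = shape, affine = affine,
         voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))),
    class = "template_grid")
}

#' @export
print.template_grid <- function(x, ...) {
  cat("template_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Test whether two grids can be used together
#'
#' Two grids are compatible when their shapes are identical and their
#' affines agree elementwise within `tol` millimetres. Every operation that
#' combines images calls this and fails fast on a mismatch rather than
#' silently resampling.
#'
#' @param a,b `template_grid` objects.
#' @param tol elementwise affine tolerance in mm (default 1e-3).
#' @return `TRUE` or `FALSE`.
#' @export
grids_compatible <- function(a, b, tol = 1e-3) {
  stopifnot(inherits(a, "template_grid"), inherits(b, "template_grid"))
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

# stop unless all grids match the first
check_grids <- function(..., tol = 1e-3, what = "inputs") {
  grids <- list(...)
  for (i in seq_along(grids)[-1])
    if (!grids_compatible(grids[[1]], grids[[i]], tol))
      stop("incompatible grids among ", what,
           " (shapes/affines differ); inputs must share a template grid")
  invisible(TRUE)
}

#' World coordinates of every voxel along one axis
#'
#' Returns a 3-D array (same shape as the grid) holding the world
#' x, y or z coordinate, in mm, of each voxel centre. Used for the
#' slice-bounded reference region and for left-right reflection.
#'
#' @param grid a `template_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z) in world space.
#' @return numeric array of dimension `grid$shape`.
#' @export
world_coordinates <- function(grid, axis = 3L) {
  stopifnot(inherits(grid, "template_grid"), axis %in% 1:3)
  A <- grid$affine
  s <- grid$shape
  # 0-based indices per NIfTI convention
  cx <- A[axis, 1] * (seq_len(s[1]) - 1)
  cy <- A[axis, 2] * (seq_len(s[2]) - 1)
  cz <- A[axis, 3] * (seq_len(s[3]) - 1)
  arr <- outer(outer(cx, cy, `+`), cz, `+`) + A[axis, 4]
  array(arr, dim = s)
}
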