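#' Slice-restricted cerebellar reference region
#'
#' Restricts a cerebellar cortex mask to an axial slab of template space,
#' keeping voxels whose world z lies in `[z_lower, z_upper]` (bounds
#' inclusive). The defaults exclude the upper cerebellum (z > -37 mm),
#' where vermis off-target binding is common, and the lower edge
#' (z < -47 mm), where partial volume, low axial sensitivity and
#' out-of-field scatter degrade quantification.
#'
#' @param base_mask cerebellar cortex [binary_mask()]; must be nonempty.
#' @param z_upper upper world-z bound in mm (default -37).
#' @param z_lower lower world-z bound in mm (default -47).
#' @return A [binary_mask()], the sub-cerebellar reference region.
#' @export
build_reference_region <- function(base_mask, z_upper = -37, z_lower = -47) {
  stopifnot(inherits(base_mask, "binary_mask"))
  if (z_lower >= z_upper) stop("'z_lower' must be below 'z_upper'")
  if (mask_size(base_mask) == 0L) stop("base mask is empty")
  z <- world_coordinates(base_mask$grid, axis = 3L)
  keep <- base_mask$membership & z >= z_lower & z <= z_upper
  if (!any(keep))
    stop(sprintf(
      "base mask has no voxels in the z-range [%g, %g] mm", z_lower, z_upper))
  binary_mask(keep, base_mask$grid)
}

#' Intersection of two or more masks
#'
#' Voxelwise logical AND. The result may be empty; operations that need a
#' nonempty mask reject empties themselves.
#'
#' @param masks list of at least two [binary_mask()]s on one grid.
#' @return A [binary_mask()].
#' @export
mask_intersect <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("need a list of at least two masks")
  stopifnot(all(vapply(masks, inherits, logical(1), "binary_mask")))
  do.call(check_grids, c(lapply(masks, `[[`, "grid"), what = "masks"))
  m <- Reduce(`&`, lapply(masks, `[[`, "membership"))
  binary_mask(m, masks[[1]]$grid)
}

#' Union of two or more masks
#'
#' Voxelwise logical OR; companion to [mask_intersect()].
#'
#' @param masks list of at least two [binary_mask()]s on one grid.
#' @return A [binary_mask()].
#' @export
mask_union <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("need a list of at least two masks")
  stopifnot(all(vapply(masks, inherits, logical(1), "binary_mask")))
  do.call(check_grids, c(lapply(masks, `[[`, "grid"), what = "masks"))
  m <- Reduce(`|`, lapply(masks, `[[`, "membership"))
  binary_mask(m, masks[[1]]$grid)
}

# voxel axis aligned with world x, its step and origin; errors if none
lr_axis <- function(grid, tol = 1e-6) {
  R <- grid$affine[1:3, 1:3]
  axis <- NA_integer_
  for (a in 1:3) {
    if (abs(R[1, a]) > tol && all(abs(R[2:3, a]) <= tol)) {
      # the other columns must not contribute to world x
      if (all(abs(R[1, setdiff(1:3, a)]) <= tol)) { axis <- a; break }
    }
  }
  if (is.na(axis))
    stop("affine has no voxel axis aligned with world x; cannot reflect")
  list(axis = axis, step = R[1, axis], origin = grid$affine[1, 4])
}

#' Left-right reflection of a mask across world x = 0
#'
#' Maps each voxel to its mirror across the template midsagittal plane
#' (world x = 0), with nearest-voxel assignment when the plane bisects a
#' voxel column. Voxels whose reflection falls outside the grid are
#' dropped. Requires an affine with a voxel axis aligned to world x.
#'
#' @param mask a [binary_mask()].
#' @return The reflected [binary_mask()].
#' @export
reflect_lr <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  ax <- lr_axis(mask$grid)
  n <- mask$grid$shape[ax$axis]
  # world x of 0-based index i is origin + step*i; reflection x -> -x.
  # Half-up rounding keeps the index map an involution when the midplane
  # bisects a voxel column.
  idx0 <- seq_len(n) - 1L
  ridx <- as.integer(floor(-2 * ax$origin / ax$step - idx0 + 0.5)) + 1L
  out <- array(FALSE, dim = mask$grid$shape)
  ok <- ridx >= 1L & ridx <= n
  src <- which(ok)          # 1-based positions along the LR axis
  dst <- ridx[ok]
  perm <- switch(ax$axis,
                 `1` = function(m, i, j) { m[j, , ] <- mask$membership[i, , ]; m },
                 `2` = function(m, i, j) { m[, j, ] <- mask$membership[, i, ]; m },
                 `3` = function(m, i, j) { m[, , j] <- mask$membership[, , i]; m })
  out <- perm(out, src, dst)
  binary_mask(out, mask$grid)
}

#' Symmetrize a mask about the template midline
#'
#' Returns the union of a mask and its left-right reflection across world
#' x = 0, removing hemispheric asymmetry without discarding any observed
#' topography. Idempotent, and the output is mirror-invariant.
#'
#' @param mask a [binary_mask()].
#' @return A mirror-symmetric [binary_mask()].
#' @export
symmetrize <- function(mask) {
  mask_union(list(mask, reflect_lr(mask)))
}

#' Dice similarity index between two masks
#'
#' `2 |A & B| / (|A| + |B|)`, the standard overlap agreement between two
#' binary masks on one grid. Symmetric, in `[0, 1]`, 1 for identical
#' nonempty masks. Undefined (error) when both masks are empty.
#'
#' @param a,b [binary_mask()]s on compatible grids.
#' @return numeric in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_grids(a$grid, b$grid, what = "masks")
  na <- mask_size(a); nb <- mask_size(b)
  if (na + nb == 0L) stop("Dice undefined: both masks are empty")
  2 * sum(a$membership & b$membership) / (na + nb)
}
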