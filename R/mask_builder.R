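#' Voxelwise mean of a group of images
#'
#' Arithmetic mean over non-missing values at each voxel; a voxel missing
#' in every input is missing in the output. Used to form the group-mean
#' uptake images (e.g. all CU amyloid-negative scans, all AD
#' amyloid-positive scans) from which tracer masks are derived.
#'
#' @param images list of at least one [volume_image()] on one grid.
#' @return A [volume_image()].
#' @export
mean_image <- function(images) {
  if (!is.list(images) || length(images) < 1L)
    stop("need a list of at least one image")
  stopifnot(all(vapply(images, inherits, logical(1), "volume_image")))
  do.call(check_grids, c(lapply(images, `[[`, "grid"), what = "images"))
  shape <- images[[1]]$grid$shape
  total <- array(0, dim = shape)
  count <- array(0L, dim = shape)
  for (im in images) {
    ok <- is.finite(im$values)
    total[ok] <- total[ok] + im$values[ok]
    count <- count + ok
  }
  out <- total / count   # count 0 -> NaN, i.e. missing everywhere
  volume_image(out, images[[1]]$grid)
}

#' Group difference image
#'
#' Voxelwise `ad_mean - cu_mean`: the AD-vs-CU contrast image that seeds
#' the tracer-specific tau mask.
#'
#' @param ad_mean,cu_mean [volume_image()]s on one grid.
#' @return A [volume_image()].
#' @export
difference_image <- function(ad_mean, cu_mean) {
  stopifnot(inherits(ad_mean, "volume_image"), inherits(cu_mean, "volume_image"))
  check_grids(ad_mean$grid, cu_mean$grid, what = "mean images")
  volume_image(ad_mean$values - cu_mean$values, ad_mean$grid)
}

#' Tracer-specific tau mask from a difference image
#'
#' Thresholds the AD-minus-CU difference image at a fraction (default one
#' third) of its summary value over an inferior temporal anchor mask,
#' keeping voxels with `diff >= threshold`. The anchor summary is the mean
#' by default (median available). The absolute threshold used is attached
#' as attribute `"threshold"` and reported via `message()`.
#'
#' @param diff difference [volume_image()]; must be finite over `it_mask`.
#' @param it_mask inferior temporal anchor [binary_mask()]; nonempty.
#' @param fraction fraction of the anchor summary used as threshold,
#'   in (0, 1); default `1/3`.
#' @param summary `"mean"` (default) or `"median"` anchor summary.
#' @return A [binary_mask()] with attribute `threshold`.
#' @export
tracer_mask <- function(diff, it_mask, fraction = 1/3,
                        summary = c("mean", "median")) {
  stopifnot(inherits(diff, "volume_image"), inherits(it_mask, "binary_mask"))
  summary <- match.arg(summary)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must be a single value in (0, 1)")
  check_grids(diff$grid, it_mask$grid, what = "difference image and anchor mask")
  if (mask_size(it_mask) == 0L) stop("inferior temporal anchor mask is empty")
  v <- diff$values[it_mask$membership]
  if (any(!is.finite(v)))
    stop("difference image has missing voxels inside the anchor mask")
  anchor <- if (summary == "mean") mean(v) else stats::median(v)
  if (anchor <= 0)
    stop("no AD>CU contrast in anchor region (anchor ", summary,
         " difference = ", signif(anchor, 4), ")")
  tau <- fraction * anchor
  message(sprintf("tracer_mask: threshold = %g (%.4g x anchor %s %g)",
                  tau, fraction, summary, anchor))
  keep <- diff$values >= tau
  keep[!is.finite(diff$values)] <- FALSE
  out <- binary_mask(keep, diff$grid)
  attr(out, "threshold") <- tau
  out
}

#' Universal tau mask from tracer-specific masks
#'
#' Intersects the tracer-specific masks (spatial overlap across tracers),
#' restricts the result to gray matter, then symmetrizes it about the
#' template midline — in that fixed order. Probabilistic gray-matter maps
#' should be binarized at > 0.5 (see [read_mask()]) before use.
#'
#' @param tracer_masks list of at least two [binary_mask()]s.
#' @param gm_mask gray-matter [binary_mask()]; nonempty.
#' @return A mirror-symmetric [binary_mask()].
#' @export
universal_mask <- function(tracer_masks, gm_mask) {
  stopifnot(inherits(gm_mask, "binary_mask"))
  if (mask_size(gm_mask) == 0L) stop("gray matter mask is empty")
  core <- mask_intersect(c(tracer_masks, list(gm_mask)))
  if (mask_size(core) == 0L)
    stop("universal mask is empty: tracer masks and gray matter do not overlap")
  out <- symmetrize(core)
  if (mask_size(out) == 0L) stop("universal mask is empty")
  out
}

#' Subregion of the universal mask
#'
#' Restricts the universal mask to an anatomical extent (mesial temporal,
#' meta temporal, temporo-parietal or frontal). Subregions are carved
#' within the constraints of the universal mask and need not be disjoint
#' from one another.
#'
#' @param universal the universal [binary_mask()].
#' @param anatomical anatomical extent [binary_mask()].
#' @param name optional subregion name, used in error messages.
#' @return A [binary_mask()].
#' @export
subregion_mask <- function(universal, anatomical, name = "subregion") {
  out <- mask_intersect(list(universal, anatomical))
  if (mask_size(out) == 0L)
    stop("subregion '", name, "' does not intersect the universal mask")
  out
}
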