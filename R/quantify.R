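#' Linear SUVR-to-CTRz conversion for one tracer and ROI
#'
#' A `tracer_scale` holds one affine conversion `CTRz = slope * SUVR +
#' intercept`. The slope is `1/sd` and the intercept `-mean/sd` of the
#' calibration population (cognitively unimpaired, amyloid-negative), so
#' CTRz is the z-score of SUVR on that population's scale. Slope must be
#' positive: tau burden increases with uptake.
#'
#' @param tracer tracer identifier (e.g. `"MK6240"`, `"FTP"`).
#' @param roi ROI identifier (e.g. `"meta_temporal"`, `"universal"`).
#' @param slope conversion slope, CTRz per SUVR unit; > 0.
#' @param intercept conversion intercept, CTRz units.
#' @param pipeline spatial-normalization pipeline the scale belongs to.
#' @return An object of class `tracer_scale`.
#' @export
tracer_scale <- function(tracer, roi, slope, intercept, pipeline = "CL-SPM") {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope <= 0)
    stop("'slope' must be a single positive number")
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("'intercept' must be a single finite number")
  structure(list(tracer = as.character(tracer), roi = as.character(roi),
                 slope = slope, intercept = intercept,
                 pipeline = as.character(pipeline)),
            class = "tracer_scale")
}

#' @export
print.tracer_scale <- function(x, ...) {
  cat(sprintf("tracer_scale [%s, %s, %s]: CTRz = %.4g * SUVR %s %.4g\n",
              x$tracer, x$roi, x$pipeline, x$slope,
              ifelse(x$intercept < 0, "-", "+"), abs(x$intercept)))
  invisible(x)
}

#' Region SUVR from a PET volume
#'
#' Standardized uptake value ratio: mean uptake over the target mask
#' divided by mean uptake over the reference mask, missing voxels
#' excluded from both means.
#'
#' @param pet a [volume_image()].
#' @param target target-region [binary_mask()]; nonempty.
#' @param reference reference-region [binary_mask()]; nonempty with
#'   positive mean uptake.
#' @return A single unitless SUVR.
#' @export
compute_suvr <- function(pet, target, reference) {
  ref_mean <- mask_mean(pet, reference)
  if (ref_mean <= 0)
    stop("reference region mean is nonpositive (", signif(ref_mean, 4), ")")
  mask_mean(pet, target) / ref_mean
}

#' Calibrate a CTRz scale from a CU amyloid-negative cohort
#'
#' Computes the sample mean and sample (n-1) standard deviation of the
#' calibration SUVRs and returns the scale with `slope = 1/sd`,
#' `intercept = -mean/sd`, so that `CTRz = (SUVR - mean) / sd`.
#'
#' @param cu_suvrs numeric vector of SUVRs from the CU amyloid-negative
#'   calibration population; length >= 2, nonzero variance.
#' @param tracer,roi identifiers recorded on the returned scale.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param pipeline pipeline label recorded on the scale.
#' @return A [tracer_scale()].
#' @examples
#' calibrate_scale(c(0.9, 1.0, 1.1), "MK6240", "meta_temporal")
#' @export
calibrate_scale <- function(cu_suvrs, tracer = "custom", roi = "custom",
                            sd_type = c("sample", "population"),
                            pipeline = "custom") {
  sd_type <- match.arg(sd_type)
  x <- as.numeric(cu_suvrs)
  if (length(x) < 2L) stop("need at least 2 calibration SUVRs")
  if (any(!is.finite(x))) stop("calibration SUVRs must be finite")
  mu <- mean(x)
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (s <= 0) stop("zero variance in calibration SUVRs")
  tracer_scale(tracer, roi, slope = 1 / s, intercept = -mu / s,
               pipeline = pipeline)
}

#' Convert SUVR to CTRz
#'
#' Exactly affine: `slope * x + intercept`. Defined for any real SUVR;
#' negative CTRz (below the CU mean) is meaningful and never clamped.
#'
#' @param x numeric vector of SUVR values.
#' @param scale a [tracer_scale()].
#' @return numeric vector of CTRz values.
#' @export
suvr_to_ctrz <- function(x, scale) {
  stopifnot(inherits(scale, "tracer_scale"))
  scale$slope * as.numeric(x) + scale$intercept
}

#' Published SUVR-to-CTRz conversion table
#'
#' The packaged coefficient table: six tracers (RO948, FTP, MK6240, GTP1,
#' PM-PBB3, PI2620) by five ROIs (universal, mesial_temporal,
#' meta_temporal, temporo_parietal, frontal), with intercepts stored
#' signed. This file is the single source of truth for the published
#' conversions.
#'
#' @param pipeline pipeline to filter on (default `"CL-SPM"`); `NULL`
#'   returns all rows.
#' @return data.frame with columns `tracer`, `roi`, `slope`, `intercept`,
#'   `pipeline`, `source`.
#' @export
published_scales <- function(pipeline = "CL-SPM") {
  path <- system.file("extdata", "centaur_scales.csv", package = "centaurz",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(pipeline)) tab <- tab[tab$pipeline == pipeline, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Look up one published conversion
#'
#' @param tracer tracer identifier, one of the six published tracers.
#' @param roi ROI identifier; default `"temporo_parietal"`, the equation
#'   suggested for global/voxelwise transformation.
#' @param pipeline pipeline of the coefficient set (default `"CL-SPM"`).
#' @return A [tracer_scale()].
#' @examples
#' ctrz_scale("MK6240", "universal")
#' @export
ctrz_scale <- function(tracer, roi = "temporo_parietal", pipeline = "CL-SPM") {
  tab <- published_scales(pipeline)
  row <- tab[tab$tracer == tracer & tab$roi == roi, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no published scale for tracer '", tracer, "', ROI '", roi,
         "' (pipeline '", pipeline, "'); see published_scales()")
  tracer_scale(row$tracer, row$roi, row$slope, row$intercept, row$pipeline)
}

#' Voxelwise CTRz parametric image
#'
#' Divides every voxel by the reference-region mean (a voxelwise SUVR
#' image) and applies the conversion, yielding a CTRz parametric image.
#' For a global transformation the tracer's temporo-parietal equation is
#' the suggested default (see [ctrz_scale()]).
#'
#' @param pet a [volume_image()].
#' @param reference reference-region [binary_mask()]; nonempty, positive
#'   mean uptake.
#' @param scale a [tracer_scale()].
#' @return A [volume_image()] of CTRz values; missing voxels stay missing.
#' @export
ctrz_image <- function(pet, reference, scale) {
  stopifnot(inherits(pet, "volume_image"), inherits(scale, "tracer_scale"))
  ref_mean <- mask_mean(pet, reference)
  if (ref_mean <= 0)
    stop("reference region mean is nonpositive (", signif(ref_mean, 4), ")")
  volume_image(scale$slope * (pet$values / ref_mean) + scale$intercept,
               pet$grid)
}
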