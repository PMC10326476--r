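cortical_regions <- c("mesial_temporal", "meta_temporal",
                      "temporo_parietal", "frontal")

# regions elevated by each topographic subtype
subtype_elevation <- list(
  tau_negative = character(0),
  limbic_predominant = "mesial_temporal",
  hippocampal_sparing = c("meta_temporal", "temporo_parietal", "frontal"),
  typical = cortical_regions)

#' Specification of a synthetic template-space phantom
#'
#' Defines the grid, region layout and signal model of a simulated tau-PET
#' cohort with known ground truth. Per cortical region, a subject's true
#' SUVR is drawn `Normal(cu_suvr_mean, cu_suvr_sd)` plus `ad_effect` in
#' the regions its subtype elevates; the image is
#' `reference_level * (background + region SUVR)` plus additive Gaussian
#' voxel noise, optionally smoothed.
#'
#' Defaults emulate the published MK6240-like calibration population
#' (CU SUVR mean 1.0, SD 0.1, so the conversion slope is about 10) with an
#' AD meta-temporal elevation of 1.0 SUVR, i.e. a mean meta-temporal CTRz
#' near 10, within the reported AD range.
#'
#' @param shape,voxel_size grid geometry (default 32 x 38 x 32 at 4 mm,
#'   world origin at the grid centre).
#' @param tracer tracer label written to simulated cohort tables.
#' @param reference_level mean uptake in the reference region, arbitrary
#'   units (default 1).
#' @param cu_suvr_mean,cu_suvr_sd CU-population SUVR mean and SD, a scalar
#'   or a named vector over the four cortical regions.
#' @param ad_effect SUVR elevation added in subtype-elevated regions,
#'   scalar or named vector (defaults: mesial 1.0, meta 1.0,
#'   temporo-parietal 0.9, frontal 0.6).
#' @param noise_sd additive Gaussian voxel noise SD, uptake units.
#' @param smoothing_fwhm isotropic Gaussian smoothing FWHM in mm
#'   (default 0, off, so unit tests are exact).
#' @return An object of class `phantom_spec` including the grid and the
#'   region layout from [make_layout()].
#' @export
phantom_spec <- function(shape = c(32L, 38L, 32L), voxel_size = 4,
                         tracer = "MK6240", reference_level = 1.0,
                         cu_suvr_mean = 1.0, cu_suvr_sd = 0.1,
                         ad_effect = c(mesial_temporal = 1.0,
                                       meta_temporal = 1.0,
                                       temporo_parietal = 0.9,
                                       frontal = 0.6),
                         noise_sd = 0.1, smoothing_fwhm = 0) {
  grid <- template_grid(shape, voxel_size)
  per_region <- function(x, name) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, 4L), cortical_regions)
    if (!all(cortical_regions %in% names(x)))
      stop("'", name, "' must name all four cortical regions")
    x <- x[cortical_regions]
    if (any(!is.finite(x))) stop("'", name, "' must be finite")
    x
  }
  cu_suvr_mean <- per_region(cu_suvr_mean, "cu_suvr_mean")
  cu_suvr_sd <- per_region(cu_suvr_sd, "cu_suvr_sd")
  ad_effect <- per_region(ad_effect, "ad_effect")
  if (any(cu_suvr_sd < 0) || noise_sd < 0 || smoothing_fwhm < 0)
    stop("standard deviations and smoothing FWHM must be >= 0")
  if (reference_level <= 0) stop("'reference_level' must be positive")
  structure(
    list(grid = grid, layout = make_layout(grid), tracer = tracer,
         reference_level = reference_level,
         cu_suvr_mean = cu_suvr_mean, cu_suvr_sd = cu_suvr_sd,
         ad_effect = ad_effect, noise_sd = noise_sd,
         smoothing_fwhm = smoothing_fwhm),
    class = "phantom_spec")
}

#' Deterministic phantom region layout
#'
#' Places mirror-symmetric box regions in world coordinates on the given
#' grid: an inferior cerebellar slab (spanning well below z = -20 mm so
#' the -47..-37 mm reference slab is nonempty), four disjoint cortical
#' regions (mesial temporal, meta temporal, temporo-parietal, frontal),
#' an inferior temporal anchor nested inside the meta-temporal region,
#' and a gray-matter envelope containing every cortical region and
#' disjoint from the cerebellum.
#'
#' @param grid a [template_grid()].
#' @return Named list of [binary_mask()]s: `cerebellar_cortex`,
#'   `gray_matter`, `inferior_temporal`, `mesial_temporal`,
#'   `meta_temporal`, `temporo_parietal`, `frontal`.
#' @export
make_layout <- function(grid) {
  stopifnot(inherits(grid, "template_grid"))
  X <- world_coordinates(grid, 1L)
  Y <- world_coordinates(grid, 2L)
  Z <- world_coordinates(grid, 3L)
  box <- function(xr, yr, zr, lateral = FALSE) {
    xs <- if (lateral) abs(X) else X
    m <- xs >= xr[1] & xs <= xr[2] &
      Y >= yr[1] & Y <= yr[2] & Z >= zr[1] & Z <= zr[2]
    binary_mask(m, grid)
  }
  layout <- list(
    cerebellar_cortex = box(c(-30, 30), c(-50, -10), c(-56, -24)),
    gray_matter       = box(c(-56, 56), c(-70, 70), c(-12, 44)),
    mesial_temporal   = box(c(6, 22),  c(-20, 10), c(-8, 8),  lateral = TRUE),
    meta_temporal     = box(c(30, 54), c(-20, 10), c(-8, 16), lateral = TRUE),
    inferior_temporal = box(c(34, 50), c(-16, 4),  c(-8, 4),  lateral = TRUE),
    temporo_parietal  = box(c(-40, 40), c(-66, -30), c(8, 40)),
    frontal           = box(c(-40, 40), c(30, 66),  c(0, 32)))
  empty <- names(layout)[vapply(layout, mask_size, 1L) == 0L]
  if (length(empty))
    stop("grid too small to place nonempty regions: ",
         paste(empty, collapse = ", "))
  layout
}

#' Isotropic Gaussian smoothing of a volume
#'
#' Separable 1-D Gaussian convolution along each axis, with edge
#' renormalization so flat regions stay flat at the boundary. Used by the
#' phantom generator to emulate PET resolution.
#'
#' @param image a [volume_image()] with no missing voxels.
#' @param fwhm full width at half maximum in mm; 0 returns the input.
#' @return A smoothed [volume_image()].
#' @export
gaussian_smooth <- function(image, fwhm) {
  stopifnot(inherits(image, "volume_image"), fwhm >= 0)
  if (fwhm == 0) return(image)
  v <- image$values
  if (any(!is.finite(v))) stop("cannot smooth a volume with missing voxels")
  for (axis in 1:3) {
    sigma <- fwhm / (2 * sqrt(2 * log(2))) / image$grid$voxel_size[axis]
    r <- max(1L, ceiling(3 * sigma))
    kern <- stats::dnorm(-r:r, sd = sigma)
    kern <- kern / sum(kern)
    v <- aperm(v, c(axis, setdiff(1:3, axis)))
    d <- dim(v)
    m <- rbind(matrix(0, r, prod(d[2:3])),
               matrix(v, nrow = d[1]),
               matrix(0, r, prod(d[2:3])))
    sm <- stats::filter(m, kern, sides = 2)[(r + 1):(r + d[1]), , drop = FALSE]
    w <- stats::filter(c(rep(0, r), rep(1, d[1]), rep(0, r)),
                       kern, sides = 2)[(r + 1):(r + d[1])]
    v <- array(as.numeric(sm / w), dim = d)
    v <- aperm(v, order(c(axis, setdiff(1:3, axis))))
  }
  volume_image(v, image$grid)
}

#' Simulate one phantom subject
#'
#' Draws per-region true SUVRs, paints the phantom image, adds voxel
#' noise and optional smoothing, and records the ground truth. Draws come
#' from R's current RNG stream; seed it (or use [simulate_cohort()],
#' which seeds once) for reproducibility.
#'
#' @param spec a [phantom_spec()].
#' @param group `"CU"` or `"AD"` (metadata; the signal is driven by
#'   `subtype`).
#' @param subtype topographic subtype to simulate; defaults to
#'   `"tau_negative"` for CU and `"typical"` for AD.
#' @param id subject identifier recorded in the truth.
#' @return list with `image` (a [volume_image()]) and `truth` (group,
#'   abeta status, subtype, and named per-region true SUVR including the
#'   `universal` composite).
#' @export
simulate_subject <- function(spec, group = c("CU", "AD"), subtype = NULL,
                             id = "s1") {
  stopifnot(inherits(spec, "phantom_spec"))
  group <- match.arg(group)
  if (is.null(subtype))
    subtype <- if (group == "CU") "tau_negative" else "typical"
  subtype <- match.arg(subtype, subtype_levels)
  elevated <- subtype_elevation[[subtype]]
  suvr <- stats::rnorm(4L, spec$cu_suvr_mean, spec$cu_suvr_sd)
  names(suvr) <- cortical_regions
  suvr[elevated] <- suvr[elevated] + spec$ad_effect[elevated]

  values <- array(spec$reference_level, dim = spec$grid$shape)
  for (r in cortical_regions)
    values[spec$layout[[r]]$membership] <- spec$reference_level * suvr[[r]]

  # universal composite truth: voxel-weighted mean over the union
  counts <- vapply(spec$layout[cortical_regions], mask_size, 1L)
  truth_suvr <- c(suvr, universal = sum(suvr * counts) / sum(counts))

  if (spec$noise_sd > 0)
    values <- values + stats::rnorm(length(values), 0, spec$noise_sd)
  image <- volume_image(values, spec$grid)
  if (spec$smoothing_fwhm > 0)
    image <- gaussian_smooth(image, spec$smoothing_fwhm)

  list(image = image,
       truth = list(id = id, group = group,
                    abeta = if (group == "AD") "pos" else "neg",
                    subtype = subtype, suvr = truth_suvr))
}

#' Simulate a phantom cohort and quantify it end to end
#'
#' Generates `n_cu` cognitively-unimpaired amyloid-negative subjects
#' (tau-negative) and `n_ad` AD amyloid-positive subjects, measures SUVR
#' in every region against the slice-restricted cerebellar reference,
#' calibrates a per-region CTRz scale on the CU subjects, and returns the
#' cohort table with measured SUVR/CTRz alongside the ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param n_cu number of CU subjects (>= 2, needed for calibration).
#' @param n_ad number of AD subjects (>= 0).
#' @param seed integer seed; all randomness flows from it.
#' @param ad_subtype subtype(s) simulated for the AD group, recycled to
#'   `n_ad` (default `"typical"`).
#' @return list of class `phantom_cohort` with elements `subjects` (per
#'   subject: image + truth), `table` (data.frame: subject_id, tracer,
#'   group, abeta, `suvr_*`, `ctrz_*`, `truth_subtype`, `truth_suvr_*`),
#'   `scales` (per-ROI calibrated [tracer_scale()]s), `reference` (the
#'   reference-region mask) and `rois` (the measured ROI masks).
#' @export
simulate_cohort <- function(spec, n_cu, n_ad = 0, seed = 1L,
                            ad_subtype = "typical") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_cu < 2L) stop("need n_cu >= 2 for CTRz calibration")
  set.seed(seed)

  groups <- c(rep("CU", n_cu), rep("AD", n_ad))
  subtypes <- c(rep("tau_negative", n_cu),
                rep_len(ad_subtype, if (n_ad > 0) n_ad else 0L))
  subjects <- lapply(seq_along(groups), function(i)
    simulate_subject(spec, groups[i], subtypes[i],
                     id = sprintf("sub%03d", i)))

  reference <- build_reference_region(spec$layout$cerebellar_cortex)
  rois <- spec$layout[cortical_regions]
  rois$universal <- mask_union(rois)
  roi_names <- names(rois)

  suvr <- t(vapply(subjects, function(s)
    vapply(roi_names, function(r)
      compute_suvr(s$image, rois[[r]], reference), numeric(1)),
    numeric(length(roi_names))))
  colnames(suvr) <- roi_names

  cu <- groups == "CU"
  scales <- lapply(roi_names, function(r)
    calibrate_scale(suvr[cu, r], tracer = spec$tracer, roi = r,
                    pipeline = "phantom"))
  names(scales) <- roi_names
  ctrz <- vapply(roi_names, function(r) suvr_to_ctrz(suvr[, r], scales[[r]]),
                 numeric(length(groups)))

  truth_suvr <- t(vapply(subjects, function(s) s$truth$suvr,
                         numeric(length(roi_names))))
  tab <- data.frame(
    subject_id = vapply(subjects, function(s) s$truth$id, character(1)),
    tracer = spec$tracer, group = groups,
    abeta = ifelse(cu, "neg", "pos"),
    stringsAsFactors = FALSE)
  colnames(suvr) <- paste0("suvr_", roi_names)
  colnames(ctrz) <- paste0("ctrz_", roi_names)
  colnames(truth_suvr) <- paste0("truth_suvr_", roi_names)
  tab <- cbind(tab, suvr, ctrz,
               truth_subtype = subtypes, truth_suvr)
  rownames(tab) <- NULL

  structure(list(subjects = subjects, table = tab, scales = scales,
                 reference = reference, rois = rois, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("phantom_cohort:", sum(x$table$group == "CU"), "CU +",
      sum(x$table$group == "AD"), "AD subjects,",
      length(x$rois), "ROIs, tracer", x$spec$tracer, "\n")
  invisible(x)
}
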