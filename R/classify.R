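#' Tau positivity at a CTRz threshold
#'
#' A scan is tau-positive when its CTRz is strictly above the threshold
#' (default 2, the meta-temporal operating point). The boundary value
#' counts as negative.
#'
#' @param ctrz numeric vector of CTRz values.
#' @param threshold CTRz cut-off (default 2).
#' @return logical vector.
#' @export
tau_positive <- function(ctrz, threshold = 2) {
  as.numeric(ctrz) > threshold
}

subtype_levels <- c("tau_negative", "limbic_predominant",
                    "hippocampal_sparing", "typical")

#' Topographic tau subtype from two regional CTRz values
#'
#' 2x2 partition on mesial-temporal versus meta-temporal CTRz at one
#' threshold: both at or below threshold is tau-negative; mesial above
#' with meta at or below is limbic-predominant; meta above with mesial at
#' or below is hippocampal-sparing; both above is typical. Every pair of
#' real values receives exactly one label.
#'
#' @param mesial_ctrz,meta_ctrz numeric vectors (recycled to a common
#'   length) of mesial-temporal and meta-temporal CTRz.
#' @param threshold CTRz cut-off (default 2); ties count as below.
#' @return factor with levels `tau_negative`, `limbic_predominant`,
#'   `hippocampal_sparing`, `typical`.
#' @examples
#' tau_subtype(c(1, 3, 1, 3), c(1, 1, 3, 3))
#' @export
tau_subtype <- function(mesial_ctrz, meta_ctrz, threshold = 2) {
  n <- max(length(mesial_ctrz), length(meta_ctrz))
  mtl <- rep_len(as.numeric(mesial_ctrz), n) > threshold
  meta <- rep_len(as.numeric(meta_ctrz), n) > threshold
  lab <- ifelse(mtl,
                ifelse(meta, "typical", "limbic_predominant"),
                ifelse(meta, "hippocampal_sparing", "tau_negative"))
  factor(lab, levels = subtype_levels)
}

#' Binary diagnostic metrics
#'
#' Accuracy, sensitivity and specificity of a binary prediction against a
#' binary truth, with the underlying confusion counts.
#'
#' @param predicted logical vector of predicted positives.
#' @param truth logical vector of true positives, same length; must
#'   contain at least one positive and one negative.
#' @return list with `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
diagnostic_metrics <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (length(predicted) != length(truth) || length(truth) < 1L)
    stop("'predicted' and 'truth' must be nonempty and of equal length")
  if (anyNA(predicted) || anyNA(truth)) stop("NA in predictions or truth")
  if (!any(truth)) stop("sensitivity undefined: no positives in truth")
  if (all(truth)) stop("specificity undefined: no negatives in truth")
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth)
  fn <- sum(!predicted & truth)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' Prevalence of CTRz above a threshold
#'
#' Fraction of values strictly above the threshold (ties excluded),
#' e.g. the proportion of a group with meta-temporal CTRz > 2.
#'
#' @param ctrz nonempty numeric vector of CTRz values.
#' @param threshold CTRz cut-off (default 2).
#' @return proportion in `[0, 1]`.
#' @export
prevalence <- function(ctrz, threshold = 2) {
  x <- as.numeric(ctrz)
  if (length(x) == 0L) stop("empty CTRz vector")
  mean(x > threshold)
}
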