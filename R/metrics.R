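## Image-quality and segmentation-quality metrics.
##
## Image quality: contrast-to-noise ratio (CNR) and equivalent number of
## looks (ENL), each averaged over the supplied homogeneous regions of
## interest. Segmentation quality: pixelwise confusion counts and the seven
## standard scores (accuracy, precision, sensitivity, specificity, Dice,
## IoU, Cohen's kappa). Region variances are sample variances.

validate_rois <- function(rois, background, image) {
  if (!is.list(rois) || length(rois) == 0L)
    stop_octedema("at least one ROI is required", class = "octedema_roi_error")
  for (r in rois) {
    assert_same_shape(image, r, "image and ROI")
    if (!any(r))
      stop_octedema("empty ROI", class = "octedema_roi_error")
    if (!is.null(background) && any(r & background))
      stop_octedema("ROI overlaps the background region", class = "octedema_roi_error")
  }
  if (!is.null(background) && !any(background))
    stop_octedema("empty background region", class = "octedema_roi_error")
  invisible(NULL)
}

#' Contrast-to-noise ratio
#'
#' `CNR = (1/R) * sum_r (mu_r - mu_b) / sqrt(sigma_r^2 + sigma_b^2)` over
#' the `R` homogeneous regions of interest, where `mu_b`, `sigma_b^2` are
#' the mean and variance of the background region. The raw (linear) value
#' is returned; use `as_db = TRUE` for the `10*log10` decibel view.
#'
#' @param image Numeric matrix.
#' @param rois List of logical ROI masks, each non-empty and disjoint from
#'   the background.
#' @param background Logical background mask.
#' @param as_db Return `10*log10(CNR)` instead of the raw ratio.
#' @return A single number.
#' @export
cnr <- function(image, rois, background, as_db = FALSE) {
  assert_gray(image)
  validate_rois(rois, background, image)
  mu_b <- mean(image[background]); var_b <- var(image[background])
  vals <- vapply(rois, function(r) {
    v <- var(image[r])
    if (!is.finite(v + var_b) || v + var_b <= 0)
      stop_octedema("degenerate ROI: zero joint variance", class = "octedema_roi_error")
    (mean(image[r]) - mu_b) / sqrt(v + var_b)
  }, numeric(1))
  out <- mean(vals)
  if (as_db) 10 * log10(out) else out
}

#' Equivalent number of looks
#'
#' `ENL = (1/H) * sum_h mu_h^2 / sigma_h^2` over the `H` homogeneous
#' regions of interest. Larger values indicate smoother speckle.
#'
#' @inheritParams cnr
#' @return A single number.
#' @export
enl <- function(image, rois) {
  assert_gray(image)
  validate_rois(rois, NULL, image)
  vals <- vapply(rois, function(r) {
    v <- var(image[r])
    if (!is.finite(v) || v <= 0)
      stop_octedema("degenerate ROI: zero variance", class = "octedema_roi_error")
    mean(image[r])^2 / v
  }, numeric(1))
  mean(vals)
}

#' Pixelwise confusion counts
#'
#' Counts true/false positives/negatives of a predicted binary mask against
#' a ground-truth mask (positive = structure present).
#'
#' @param pred,truth Logical (or 0/1) matrices of identical shape.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  assert_same_shape(pred, truth, "pred and truth")
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' Segmentation scores from confusion counts
#'
#' Computes accuracy, precision, sensitivity, specificity, Dice similarity,
#' intersection-over-union and Cohen's kappa (chance agreement from the
#' product of the marginals). Ratios with a zero denominator are reported as
#' `NA`, not as 0. A Dice value above 0.70 is conventionally read as
#' excellent agreement; [print.metrics_scores()] surfaces that label.
#'
#' @param counts A `confusion_counts` object (or list with `tp`, `fp`,
#'   `fn`, `tn`).
#' @return A list of class `metrics_scores` with the seven scores.
#' @export
scores <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total <= 0)
    stop_octedema("no pixels to score", class = "octedema_roi_error")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (abs(1 - pe) > .Machine$double.eps) (acc - pe) / (1 - pe) else NA_real_
  structure(list(accuracy = acc,
                 precision = ratio(tp, tp + fp),
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 dice = ratio(2 * tp, 2 * tp + fp + fn),
                 iou = ratio(tp, tp + fp + fn),
                 kappa = kappa),
            class = "metrics_scores")
}

#' @export
print.metrics_scores <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-12s %s\n", nm,
                if (is.na(x[[nm]])) "NA (undefined)" else sprintf("%.4f", x[[nm]])))
  if (!is.na(x$dice) && x$dice > 0.70)
    cat("dice > 0.70: excellent agreement\n")
  invisible(x)
}

#' Evaluate a segmentation against ground truth
#'
#' Convenience wrapper producing per-structure scores (retina and edema)
#' and, when an image and ROIs are supplied, the CNR/ENL image-quality
#' metrics.
#'
#' @param result A `segmentation_result` (or list with `retina_mask` and
#'   `edema_mask`).
#' @param truth List with logical `retina_mask` and `edema_mask`.
#' @param image Optional image for CNR/ENL.
#' @param rois Optional ROI list as in [cnr()].
#' @param background Optional background mask for CNR.
#' @return A list of class `metrics_report` with elements `retina`, `edema`
#'   (each a `metrics_scores`) and optionally `cnr`, `cnr_db`, `enl`.
#' @export
evaluate_segmentation <- function(result, truth, image = NULL, rois = NULL,
                                  background = NULL) {
  rep <- list(retina = scores(confusion(result$retina_mask, truth$retina_mask)),
              edema = scores(confusion(result$edema_mask, truth$edema_mask)))
  if (!is.null(image) && !is.null(rois)) {
    rep$enl <- enl(image, rois)
    if (!is.null(background)) {
      rep$cnr <- cnr(image, rois, background)
      rep$cnr_db <- 10 * log10(rep$cnr)
    }
  }
  structure(rep, class = "metrics_report")
}
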