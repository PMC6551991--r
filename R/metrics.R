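#' Voxel-overlap agreement between two segmentations
#'
#' Dice = 2TP/(2TP + FP + FN), sensitivity = TP/(TP + FN), precision =
#' TP/(TP + FP), computed from the voxelwise confusion counts between a
#' reference and a predicted binary segmentation.  Empty-mask conventions:
#' both masks empty gives Dice = precision = sensitivity = 1 (perfect
#' agreement); an empty reference with a non-empty prediction gives
#' sensitivity NaN, precision 0, Dice 0; the converse gives precision NaN,
#' sensitivity 0, Dice 0.
#'
#' @param ref,pred logical arrays on the same grid (reference first).
#' @return list with `dice`, `precision`, `sensitivity` and the confusion
#'   counts `tp`, `fp`, `fn`.
#' @export
overlap_metrics <- function(ref, pred) {
  check_same_dim(ref, pred)
  tp <- sum(ref & pred)
  fp <- sum(!ref & pred)
  fn <- sum(ref & !pred)
  if (tp + fp + fn == 0) {
    return(list(dice = 1, precision = 1, sensitivity = 1, tp = 0, fp = 0, fn = 0))
  }
  list(dice = 2 * tp / (2 * tp + fp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
       tp = tp, fp = fp, fn = fn)
}

#' Volume agreement between two segmentations
#'
#' Volume difference (mL) is reference minus prediction: positive values
#' indicate undersegmentation by the automated method, negative values
#' oversegmentation.
#'
#' @param ref,pred logical arrays on the same grid.
#' @param spacing voxel spacing in mm.
#' @return list with `volume_diff_ml` and `abs_volume_diff_ml`.
#' @export
volume_agreement <- function(ref, pred, spacing) {
  check_same_dim(ref, pred)
  d <- mask_volume_ml(ref, spacing) - mask_volume_ml(pred, spacing)
  list(volume_diff_ml = d, abs_volume_diff_ml = abs(d))
}

#' Intraclass correlation, absolute agreement
#'
#' Two-way, single-rater, absolute-agreement intraclass correlation
#' (ICC(2,1)) between two measurement series, from the standard
#' mean-squares decomposition of the two-way ANOVA:
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#'
#' @param x,y paired measurement series (length >= 3, finite).
#' @return the ICC in [-1, 1].
#' @export
icc_absolute <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired measurements")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  if (sum((dat - grand)^2) < 1e-24) stop("zero total variance")
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Cutoff classification agreement
#'
#' Binarizes both series at the cutoff (values above the cutoff are the
#' positive class; values exactly at the cutoff count as the low class) and
#' reports the agreement fraction plus Cohen's kappa on the 2x2 table.
#' With a degenerate table (all cases in one agreeing class) kappa is
#' undefined and reported as NaN with a warning.
#'
#' @param ref_vals,pred_vals paired measurement series.
#' @param cutoff classification cutoff in the series' units (25 mL for
#'   largest-lesion volume, 5 mm for midline shift).
#' @return list with `accuracy` and `kappa`.
#' @export
classification_accuracy <- function(ref_vals, pred_vals, cutoff) {
  if (length(ref_vals) != length(pred_vals)) stop("series must have equal length")
  if (!length(ref_vals)) stop("need at least 1 case")
  hr <- ref_vals > cutoff
  hp <- pred_vals > cutoff
  acc <- mean(hr == hp)
  po <- acc
  pe <- mean(hr) * mean(hp) + mean(!hr) * mean(!hp)
  kappa <- if (abs(1 - pe) < 1e-12) {
    warning("degenerate classification table: kappa undefined")
    NaN
  } else (po - pe) / (1 - pe)
  list(accuracy = acc, kappa = kappa)
}

#' Midline-shift measurement agreement
#'
#' Difference in shift (mm) is reference minus prediction, with its
#' absolute value.
#'
#' @param ref_mm,pred_mm shift measurements in mm.
#' @return list with `difference_in_shift_mm` and
#'   `abs_difference_in_shift_mm`.
#' @export
shift_agreement <- function(ref_mm, pred_mm) {
  if (any(!is.finite(ref_mm)) || any(!is.finite(pred_mm)))
    stop("shift values must be finite")
  d <- ref_mm - pred_mm
  list(difference_in_shift_mm = d, abs_difference_in_shift_mm = abs(d))
}
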