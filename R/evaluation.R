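#' Pixelwise confusion counts
#'
#' Vein is the positive class: TP = vein predicted vein, TN = tissue
#' predicted tissue, FP = tissue predicted vein, FN = vein predicted
#' tissue.
#'
#' @param pred,truth 0/1 matrices of equal dimensions.
#' @return Named list `TP`, `TN`, `FP`, `FN`, `P`, `N`.
#' @export
confusion <- function(pred, truth) {
  check_binary(pred); check_binary(truth)
  if (!all(dim(pred) == dim(truth)))
    stop_validation("prediction and truth dims differ")
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  list(TP = tp, TN = tn, FP = fp, FN = fn, P = tp + fn, N = tn + fp)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' \deqn{\mathrm{sensitivity} = \frac{TP}{TP+FN},\quad
#'       \mathrm{specificity} = \frac{TN}{TN+FP},\quad
#'       \mathrm{accuracy} = \frac{TP+TN}{P+N}.}
#'
#' @param counts A [confusion()] result.
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)`.
#' @export
scores <- function(counts) {
  if (counts$P == 0 || counts$N == 0)
    stop_validation("undefined metric: one class is absent (P = ",
                    counts$P, ", N = ", counts$N, ")")
  c(sensitivity = counts$TP / counts$P,
    specificity = counts$TN / counts$N,
    accuracy = (counts$TP + counts$TN) / (counts$P + counts$N))
}

#' ROC sweep over the segmentation threshold
#'
#' Binarizes the enhanced image at every threshold t in \code{0 .. L-2}
#' (bypassing entropy-based selection), optionally applies the configured
#' morphological postprocessing, and scores each operating point against
#' the ground truth. The degenerate all-vein and all-background endpoints
#' (FPR, TPR) = (1, 1) and (0, 0) are appended.
#'
#' @param enh Enhanced image in \code{[0, 1]} (matrix or
#'   `enhanced_image`).
#' @param truth 0/1 ground-truth mask.
#' @param L Number of quantization levels.
#' @param postprocess Apply dilation + majority cleanup at each threshold?
#' @param Y,max_iter Postprocessing parameters (see [dilate_line_x()],
#'   [majority_fixpoint()]).
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, `acc`.
#' @export
roc_sweep <- function(enh, truth, L = 256L, postprocess = TRUE,
                      Y = 5L, max_iter = 100L) {
  if (inherits(enh, "enhanced_image")) enh <- enh$values
  check_binary(truth)
  q <- quantize(enh, L)
  pts <- lapply(0:(L - 2), function(t) {
    mask <- (q > t) * 1L
    storage.mode(mask) <- "integer"
    if (postprocess)
      mask <- majority_fixpoint(dilate_line_x(mask, Y), max_iter)
    cts <- confusion(mask, truth)
    sc <- scores(cts)
    data.frame(threshold = t, fpr = 1 - sc[["specificity"]],
               tpr = sc[["sensitivity"]], acc = sc[["accuracy"]])
  })
  out <- do.call(rbind, pts)
  rbind(data.frame(threshold = -1L, fpr = 1, tpr = 1,
                   acc = mean(truth == 1)),
        out,
        data.frame(threshold = L - 1L, fpr = 0, tpr = 0,
                   acc = mean(truth == 0)))
}

#' Trapezoidal area under an ROC polyline
#'
#' @param roc A [roc_sweep()] data frame.
#' @return Scalar AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
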