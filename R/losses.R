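#' Mean-squared reconstruction error (L2 loss)
#'
#' Mean over all cells and genes of the squared difference between predicted
#' and actual expression.
#'
#' @param predicted,actual numeric matrices of identical shape
#' @return non-negative scalar
#' @export
l2_loss <- function(predicted, actual) {
  if (!identical(dim(predicted), dim(actual))) {
    stop("shape mismatch: predicted ", paste(dim(predicted), collapse = "x"),
         " vs actual ", paste(dim(actual), collapse = "x"))
  }
  mean((predicted - actual)^2)
}

# gradient of l2_loss w.r.t. predicted
l2_loss_grad <- function(predicted, actual) {
  2 * (predicted - actual) / length(predicted)
}

macro_f1_soft <- function(probabilities, onehot, warn = TRUE) {
  # soft confusion counts per class: TP = sum p*y, FP = sum p*(1-y),
  # FN = sum (1-p)*y; F1 = 2*pr*rc/(pr+rc) = 2TP / (2TP + FP + FN)
  y <- onehot
  p <- probabilities
  tp <- colSums(p * y)
  fp <- colSums(p * (1 - y))
  fn <- colSums((1 - p) * y)
  denom <- 2 * tp + fp + fn
  degenerate <- (tp + fp == 0) | (tp + fn == 0)
  f1 <- ifelse(denom > 0 & !degenerate, 2 * tp / denom, 0)
  if (warn && any(degenerate)) {
    warning("class(es) with zero soft TP+FP or TP+FN: ",
            paste(which(degenerate), collapse = ", "),
            "; their F1 is taken as 0")
  }
  list(tp = tp, fp = fp, fn = fn, denom = denom, f1 = f1,
       degenerate = degenerate)
}

#' Differentiable macro F1 loss
#'
#' One minus the unweighted mean over classes of the per-class F1 score, where
#' the confusion counts are soft (probability-weighted): TP = sum(p y),
#' FP = sum(p (1 - y)), FN = sum((1 - p) y). Precision is TP/(TP+FP), recall
#' TP/(TP+FN), F1 their harmonic mean. A class whose soft TP+FP or TP+FN is
#' zero contributes F1 = 0 (loss contribution 1) with a warning. On hard 0/1
#' probabilities this equals one minus the standard hard-count macro F1.
#'
#' @param probabilities cells x classes matrix with entries in `[0, 1]`
#' @param onehot a `LabelMatrix` or a binary cells x classes matrix
#' @param warn warn on degenerate classes
#' @return scalar loss in `[0, 1]`
#' @export
macro_f1_loss <- function(probabilities, onehot, warn = TRUE) {
  if (inherits(onehot, "LabelMatrix")) onehot <- onehot$onehot
  if (!identical(dim(probabilities), dim(onehot))) {
    stop("shape mismatch between probabilities and one-hot labels")
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  s <- macro_f1_soft(probabilities, onehot, warn = warn)
  1 - mean(s$f1)
}

# gradient of macro_f1_loss w.r.t. probabilities.
# dF1_c/dp_ic = 2 (y_ic * D_c - TP_c) / D_c^2 with D = 2TP + FP + FN
# (dTP = y, dD = 1), so dLoss/dp_ic = -dF1_c/dp_ic / n_classes.
macro_f1_loss_grad <- function(probabilities, onehot) {
  s <- macro_f1_soft(probabilities, onehot, warn = FALSE)
  n_classes <- ncol(onehot)
  d <- s$denom
  safe <- d > 0 & !s$degenerate
  scale_y <- ifelse(safe, 2 / d, 0)               # coefficient of y_ic
  scale_c <- ifelse(safe, 2 * s$tp / d^2, 0)      # constant per class
  grad_f1 <- sweep(onehot, 2, scale_y, "*")
  grad_f1 <- sweep(grad_f1, 2, scale_c, "-")
  -grad_f1 / n_classes
}

#' Hard-count macro F1 score
#'
#' Standard macro F1 from binarized predictions; the evaluation-side
#' counterpart of [macro_f1_loss()].
#'
#' @param binary binary cells x classes matrix (or a `LabelMatrix`)
#' @param onehot binary truth matrix (or a `LabelMatrix`)
#' @return scalar macro F1 in `[0, 1]`
#' @export
macro_f1_score <- function(binary, onehot) {
  if (inherits(binary, "LabelMatrix")) binary <- binary$onehot
  if (inherits(onehot, "LabelMatrix")) onehot <- onehot$onehot
  1 - macro_f1_loss(binary, onehot, warn = FALSE)
}
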