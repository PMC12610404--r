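#' Per-class precision, recall and F1 from thresholded predictions
#'
#' Hard confusion counts per output node, treating each of the classes as an
#' independent binary problem. A class that is never predicted and never true
#' has undefined precision and recall; by convention both are reported as 1.0
#' with `degenerate = TRUE` so macro averages stay defined.
#'
#' @param binary binary cells x classes prediction matrix (or the `binary`
#'   element of [predict.dxg_classifier()] output)
#' @param truth a `LabelMatrix` or binary truth matrix
#' @return list with `per_class` (data.frame: class, tp, fp, fn, tn,
#'   precision, recall, f1, degenerate) and `macro` (named vector of macro
#'   precision/recall/f1)
#' @export
per_class_metrics <- function(binary, truth) {
  if (is.list(binary) && !is.null(binary$binary)) binary <- binary$binary
  class_names <- colnames(binary)
  if (inherits(truth, "LabelMatrix")) {
    if (is.null(class_names)) class_names <- truth$class_names
    truth <- truth$onehot
  }
  if (!identical(dim(binary), dim(truth))) {
    stop("shape mismatch between predictions and truth")
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(ncol(binary)))
  n <- nrow(binary)
  tp <- colSums(binary == 1 & truth == 1)
  fp <- colSums(binary == 1 & truth == 0)
  fn <- colSums(binary == 0 & truth == 1)
  tn <- n - tp - fp - fn
  degenerate <- (tp + fp + fn) == 0
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), ifelse(degenerate, 1, 0))
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), ifelse(degenerate, 1, 0))
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = class_names, tp = tp, fp = fp, fn = fn,
                          tn = tn, precision = precision, recall = recall,
                          f1 = f1, degenerate = degenerate,
                          row.names = NULL, stringsAsFactors = FALSE)
  list(per_class = per_class,
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)))
}

#' Per-category confusion matrices from block-wise argmax
#'
#' Within each category block (species, cell type, disease) the predicted
#' label is the node with the highest probability in that block — the
#' thresholded multi-label output can yield zero or two positives per block,
#' so confusion matrices use the argmax reading. Ties resolve to the first
#' node in block order (logged). Rows are truth, columns are predictions.
#'
#' @param probabilities cells x classes probability matrix
#' @param truth a `LabelMatrix` aligned with the rows
#' @return named list of confusion objects, one per category, each a list with
#'   `category`, `labels`, `counts`
#' @export
confusion_by_category <- function(probabilities, truth) {
  stopifnot(inherits(truth, "LabelMatrix"))
  if (nrow(probabilities) != nrow(truth$onehot)) {
    stop("probability rows != truth rows")
  }
  out <- list()
  for (cat in names(truth$blocks)) {
    block <- truth$blocks[[cat]]
    levels_cat <- truth$schema[[cat]]
    p_block <- probabilities[, block, drop = FALSE]
    ties <- apply(p_block, 1, function(r) sum(r == max(r)) > 1)
    if (any(ties)) {
      message("confusion_by_category: ", sum(ties), " argmax tie(s) in '",
              cat, "' resolved to first node in block order")
    }
    pred <- max.col(p_block, ties.method = "first")
    true <- max.col(truth$onehot[, block, drop = FALSE], ties.method = "first")
    counts <- table(factor(levels_cat[true], levels = levels_cat),
                    factor(levels_cat[pred], levels = levels_cat))
    counts <- matrix(as.integer(counts), length(levels_cat),
                     dimnames = list(truth = levels_cat,
                                     predicted = levels_cat))
    out[[cat]] <- list(category = cat, labels = levels_cat, counts = counts)
  }
  out
}

#' Correct classification rate per category
#'
#' The unweighted mean over a category's classes of the per-class correct
#' fraction (diagonal count over that truth label's cell count).
#'
#' @param confusions output of [confusion_by_category()] (or a single
#'   confusion object)
#' @return named numeric vector of per-category rates in `[0, 1]`
#' @export
correct_classification_rate <- function(confusions) {
  if (!is.null(confusions$counts)) confusions <- list(confusions)
  vapply(confusions, function(cm) {
    totals <- rowSums(cm$counts)
    if (all(totals == 0)) stop("category '", cm$category, "' has no cells")
    rates <- diag(cm$counts)[totals > 0] / totals[totals > 0]
    mean(rates)
  }, numeric(1))
}

#' Write evaluation outputs as TSV files
#'
#' @param metrics output of [per_class_metrics()]
#' @param confusions output of [confusion_by_category()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_evaluation <- function(metrics, confusions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(metrics$per_class, file.path(dir, "per_class_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cat in names(confusions)) {
    utils::write.table(confusions[[cat]]$counts,
                       file.path(dir, paste0("confusion_", cat, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}
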