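#' Barcode quality-control filtering
#'
#' Removes cells whose detected-gene count (genes with count > 0) falls outside
#' `[min_genes, max_genes]` or whose mitochondrial count fraction exceeds
#' `max_mt_pct` percent. Mitochondrial genes are recognized by case-insensitive
#' `"MT-"` name prefix. Boundary cells (exactly `min_genes` or `max_genes`
#' detected genes, exactly `max_mt_pct` percent) are retained; removal uses
#' strict inequalities. The gene set is unchanged and the operation is
#' idempotent.
#'
#' @param ds raw-count `ExpressionDataset`
#' @param min_genes,max_genes detected-gene bounds (defaults 300 and 6000)
#' @param max_mt_pct maximum mitochondrial percentage of total counts
#'   (default 5)
#' @param verbose log per-criterion removal counts
#' @return the filtered `ExpressionDataset`; the removal counts are attached as
#'   attribute `"qc_log"`
#' @export
qc_filter <- function(ds, min_genes = 300, max_genes = 6000, max_mt_pct = 5,
                      verbose = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$normalized) stop("qc_filter expects raw counts (normalized = FALSE)")
  detected <- rowSums(ds$values > 0)
  totals <- rowSums(ds$values)
  mt <- is_mito_gene(ds$gene_names)
  mt_frac <- if (any(mt)) {
    rowSums(ds$values[, mt, drop = FALSE]) / pmax(totals, 1e-300)
  } else {
    rep(0, nrow(ds$values))
  }
  low <- detected < min_genes
  high <- detected > max_genes
  mito <- mt_frac > max_mt_pct / 100
  keep <- !(low | high | mito)
  log <- c(n_low_genes = sum(low), n_high_genes = sum(high),
           n_high_mt = sum(mito), n_kept = sum(keep))
  if (verbose) {
    message(sprintf(
      "qc_filter: removed %d (<%d genes), %d (>%d genes), %d (>%g%% MT); kept %d/%d cells",
      log[["n_low_genes"]], min_genes, log[["n_high_genes"]], max_genes,
      log[["n_high_mt"]], max_mt_pct, log[["n_kept"]], nrow(ds$values)))
  }
  if (!any(keep)) {
    stop("qc_filter removed every cell; review min_genes/max_genes/max_mt_pct ",
         "against this dataset's depth")
  }
  out <- subset_cells(ds, cells = which(keep))
  attr(out, "qc_log") <- log
  out
}

#' Log-normalize counts (counts-per-scale, natural log1p)
#'
#' Each count v in a cell with total T becomes `ln(1 + v * scale / T)` — the
#' counts-per-10,000 convention with natural-log pseudocount.
#'
#' @param ds raw-count `ExpressionDataset`
#' @param scale library-size target (default 1e4)
#' @return normalized `ExpressionDataset` (`normalized = TRUE`)
#' @export
lognormalize <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$normalized) stop("dataset is already normalized")
  totals <- rowSums(ds$values)
  if (any(totals == 0)) {
    stop(sum(totals == 0), " cell(s) have zero total counts; ",
         "they should have been removed by qc_filter")
  }
  v <- log1p(ds$values * (scale / totals))
  expression_dataset(v, ds$gene_names, ds$cell_ids, ds$cell_meta,
                     normalized = TRUE)
}

#' Stratified train/validation split
#'
#' Cells are split within each stratum (the joint values of `stratify_by`
#' metadata columns) so every stratum's training share is within one cell of
#' `train_frac`. Strata with fewer than 2 cells go entirely to training with a
#' warning. Deterministic for a fixed seed.
#'
#' @param ds `ExpressionDataset` with metadata
#' @param train_frac training fraction in (0, 1); default 0.8
#' @param stratify_by metadata columns defining strata
#' @param seed integer RNG seed
#' @return list with integer `train_indices`, `val_indices` and the `seed`
#' @export
stratified_split <- function(ds, train_frac = 0.8,
                             stratify_by = c("species", "cell_type", "disease"),
                             seed = 1L) {
  stopifnot(inherits(ds, "ExpressionDataset"), !is.null(ds$cell_meta))
  if (!(train_frac > 0 && train_frac < 1)) stop("train_frac must be in (0, 1)")
  missing_cols <- setdiff(stratify_by, names(ds$cell_meta))
  if (length(missing_cols)) {
    stop("stratify_by columns absent from metadata: ",
         paste(missing_cols, collapse = ", "))
  }
  strata <- interaction(ds$cell_meta[stratify_by], drop = TRUE)
  train <- integer(0)
  withr::with_seed(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      if (length(idx) < 2L) {
        warning("stratum '", s, "' has ", length(idx),
                " cell(s); placed in training")
        train <- c(train, idx)
        next
      }
      n_train <- round(train_frac * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_train))
    }
  })
  train <- sort(train)
  val <- setdiff(seq_len(nrow(ds$values)), train)
  list(train_indices = train, val_indices = val, seed = seed)
}

#' Default 13-class label schema
#'
#' Two species, seven cell types and four disease states — the one-hot scheme
#' in which every cell carries exactly three positive labels.
#'
#' @param species,cell_type,disease level vectors per category
#' @return named list of category levels, class `label_schema`
#' @export
label_schema <- function(species = c("human", "mouse"),
                         cell_type = c("CM", "EC", "FB", "IC", "NC", "PC", "SMC"),
                         disease = c("healthy", "AS", "HFrEF", "HFpEF")) {
  schema <- list(species = species, cell_type = cell_type, disease = disease)
  structure(schema, class = "label_schema")
}

#' One-hot encode per-cell labels
#'
#' Builds the cells x classes binary matrix in schema column order; each row
#' sums to the number of categories (one positive per category block).
#'
#' @param meta per-cell data.frame with one column per schema category
#' @param schema a [label_schema()]
#' @return list of class `LabelMatrix`: `onehot` (cells x classes binary
#'   matrix), `class_names`, and `blocks` (named list of column indices per
#'   category)
#' @export
encode_labels <- function(meta, schema = label_schema()) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  cats <- names(schema)
  missing_cols <- setdiff(cats, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks label columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(meta)
  class_names <- unlist(lapply(cats, function(cat) {
    paste(cat, schema[[cat]], sep = ":")
  }), use.names = FALSE)
  onehot <- matrix(0L, n, length(class_names),
                   dimnames = list(rownames(meta), class_names))
  offset <- 0L
  blocks <- list()
  cell_label <- function(i) {
    if (!is.null(rownames(meta))) rownames(meta)[i] else paste("row", i)
  }
  for (cat in cats) {
    levels_cat <- schema[[cat]]
    vals <- as.character(meta[[cat]])
    bad <- which(is.na(vals) | !(vals %in% levels_cat))
    if (length(bad)) {
      stop("cell '", cell_label(bad[1]), "' has unknown ", cat, " value '",
           vals[bad[1]], "'")
    }
    pos <- match(vals, levels_cat)
    onehot[cbind(seq_len(n), offset + pos)] <- 1L
    blocks[[cat]] <- offset + seq_along(levels_cat)
    offset <- offset + length(levels_cat)
  }
  structure(list(onehot = onehot, class_names = class_names, blocks = blocks,
                 schema = schema),
            class = "LabelMatrix")
}

#' Decode a LabelMatrix back to a per-cell label table
#'
#' @param labels a `LabelMatrix`
#' @return data.frame with one column per category
#' @export
decode_labels <- function(labels) {
  stopifnot(inherits(labels, "LabelMatrix"))
  out <- lapply(names(labels$blocks), function(cat) {
    block <- labels$onehot[, labels$blocks[[cat]], drop = FALSE]
    labels$schema[[cat]][max.col(block, ties.method = "first")]
  })
  names(out) <- names(labels$blocks)
  res <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(res) <- rownames(labels$onehot)
  res
}
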