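#' Construct an ExpressionDataset
#'
#' The universal carrier between pipeline stages: a dense cells x genes
#' expression matrix together with per-cell annotations. Values are raw counts
#' (`normalized = FALSE`) or log-normalized expression (`normalized = TRUE`).
#'
#' @param values numeric matrix, cells as rows and genes as columns. Sparse
#'   `Matrix` input is densified.
#' @param gene_names character vector of unique gene identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param cell_ids character vector of unique cell barcodes, one per row.
#'   Defaults to `rownames(values)`.
#' @param cell_meta data.frame with one row per cell carrying the columns
#'   `species`, `cell_type`, `disease` and `sample` (character). May be `NULL`
#'   for label-free data; most downstream stages require it.
#' @param normalized logical flag; `FALSE` for raw counts.
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, gene_names = colnames(values),
                               cell_ids = rownames(values), cell_meta = NULL,
                               normalized = FALSE) {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (cells x genes)")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty expression matrix: ", nrow(values), " cells x ",
         ncol(values), " genes")
  }
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != ncol(values)) {
    stop("length(gene_names) != number of gene columns")
  }
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) != number of cell rows")
  }
  dup <- unique(gene_names[duplicated(gene_names)])
  if (length(dup)) {
    stop("duplicate gene names: ", paste(utils::head(dup, 10), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (!normalized && any(values < 0)) {
    stop("raw counts must be non-negative")
  }
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
    if (nrow(cell_meta) != nrow(values)) {
      stop("cell_meta rows (", nrow(cell_meta), ") != number of cells (",
           nrow(values), ")")
    }
    missing_cols <- setdiff(c("species", "cell_type", "disease", "sample"),
                            names(cell_meta))
    if (length(missing_cols)) {
      stop("cell_meta lacks required columns: ",
           paste(missing_cols, collapse = ", "))
    }
    rownames(cell_meta) <- cell_ids
  }
  dimnames(values) <- list(cell_ids, gene_names)
  structure(
    list(values = values, gene_names = gene_names, cell_ids = cell_ids,
         cell_meta = cell_meta, normalized = normalized),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw counts"))
  if (!is.null(x$cell_meta)) {
    for (col in c("species", "cell_type", "disease", "sample")) {
      lv <- unique(x$cell_meta[[col]])
      cat(sprintf("  %-9s %s\n", paste0(col, ":"),
                  paste(utils::head(lv, 8), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Subset an ExpressionDataset by cells and/or genes
#'
#' @param x an `ExpressionDataset`
#' @param cells integer/logical/character index over cells
#' @param genes integer/logical/character index over genes
#' @return the subsetted `ExpressionDataset`
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "ExpressionDataset"))
  if (is.null(cells)) cells <- seq_len(nrow(x$values))
  if (is.null(genes)) genes <- seq_len(ncol(x$values))
  v <- x$values[cells, genes, drop = FALSE]
  expression_dataset(
    v,
    gene_names = colnames(v),
    cell_ids = rownames(v),
    cell_meta = if (!is.null(x$cell_meta)) x$cell_meta[cells, , drop = FALSE] else NULL,
    normalized = x$normalized
  )
}

#' Identify mitochondrial genes by name prefix
#'
#' Case-insensitive `"MT-"` prefix, the hg38/mm10 naming convention.
#'
#' @param gene_names character vector
#' @return logical vector
#' @export
is_mito_gene <- function(gene_names) {
  grepl("^mt-", gene_names, ignore.case = TRUE)
}
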