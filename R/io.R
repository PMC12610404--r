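#' Load an expression matrix from disk
#'
#' Supported layouts:
#' * `mtx_dir` — a directory in the 10x triplet convention: `matrix.mtx`
#'   (genes x cells, Matrix Market), `genes.tsv` (or `features.tsv`) and
#'   `barcodes.tsv`. The orientation is transposed on load so the returned
#'   dataset is always cells x genes.
#' * `csv` / `tsv` — a dense table with a header row of gene names and a first
#'   column of cell ids (cells x genes). Set `orientation = "genes_by_cells"`
#'   for the transposed layout (genes as rows, cells as columns).
#'
#' @param path file (csv/tsv) or directory (mtx_dir)
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`
#' @param meta_path optional TSV of per-cell metadata with columns `cell_id`,
#'   `species`, `cell_type`, `disease`, `sample`; matched to the matrix by
#'   `cell_id`
#' @param orientation dense-table orientation, `"cells_by_genes"` (default) or
#'   `"genes_by_cells"`
#' @return an [expression_dataset()] with `normalized = FALSE`
#' @export
load_expression <- function(path, format = c("mtx_dir", "csv", "tsv"),
                            meta_path = NULL,
                            orientation = c("cells_by_genes", "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (format == "mtx_dir") {
    ds <- read_mtx_dir(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(tab) == 0L || ncol(tab) < 2L) {
      stop("dense expression table is empty or lacks a value column: ", path)
    }
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (orientation == "genes_by_cells") m <- t(m)
    ds <- expression_dataset(m, normalized = FALSE)
  }
  if (!is.null(meta_path)) ds <- attach_cell_meta(ds, meta_path)
  ds
}

read_mtx_dir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("missing file: ", mtx)
  feat <- file.path(dir, "genes.tsv")
  if (!file.exists(feat)) feat <- file.path(dir, "features.tsv")
  if (!file.exists(feat)) {
    stop("missing file: ", file.path(dir, "genes.tsv"), " (or features.tsv)")
  }
  bc <- file.path(dir, "barcodes.tsv")
  if (!file.exists(bc)) stop("missing file: ", bc)
  m <- Matrix::readMM(mtx)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty matrix file: ", mtx)
  genes <- utils::read.table(feat, sep = "\t", stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(bc, sep = "\t", stringsAsFactors = FALSE)[[1]]
  if (length(genes) != nrow(m)) {
    stop("gene file rows (", length(genes), ") != matrix rows (", nrow(m), ")")
  }
  if (length(cells) != ncol(m)) {
    stop("barcode file rows (", length(cells), ") != matrix columns (",
         ncol(m), ")")
  }
  m <- t(as.matrix(m))  # 10x stores genes x cells; internal layout is cells x genes
  dimnames(m) <- list(cells, genes)
  expression_dataset(m, normalized = FALSE)
}

#' Attach per-cell metadata from a TSV file
#'
#' @param ds an `ExpressionDataset`
#' @param meta_path TSV with columns `cell_id`, `species`, `cell_type`,
#'   `disease`, `sample`
#' @return the dataset with `cell_meta` populated
#' @export
attach_cell_meta <- function(ds, meta_path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!file.exists(meta_path)) stop("missing file: ", meta_path)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(meta)) stop("metadata lacks a cell_id column")
  idx <- match(ds$cell_ids, meta$cell_id)
  if (anyNA(idx)) {
    stop("metadata missing for cells: ",
         paste(utils::head(ds$cell_ids[is.na(idx)], 5), collapse = ", "))
  }
  meta <- meta[idx, setdiff(names(meta), "cell_id"), drop = FALSE]
  expression_dataset(ds$values, ds$gene_names, ds$cell_ids, meta,
                     normalized = ds$normalized)
}

#' Write an ExpressionDataset as an mtx directory
#'
#' Writes `matrix.mtx` (genes x cells triplets), `genes.tsv`, `barcodes.tsv`
#' and, when metadata is present, `meta.tsv`. Round-trips with
#' [load_expression()].
#'
#' @param ds an `ExpressionDataset`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_expression_mtx <- function(ds, dir) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(ds$values), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$gene_names, file.path(dir, "genes.tsv"))
  writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
  if (!is.null(ds$cell_meta)) {
    meta <- cbind(cell_id = ds$cell_ids, ds$cell_meta)
    utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write an ExpressionDataset as a dense delimited table
#'
#' Cells as rows, genes as columns, first column `cell_id`.
#'
#' @param ds an `ExpressionDataset`
#' @param path output file
#' @param sep field separator (`","` for csv, `"\t"` for tsv)
#' @return `path`, invisibly
#' @export
write_expression_table <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  tab <- data.frame(cell_id = ds$cell_ids, ds$values, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an mtx directory written by [write_expression_mtx()], with metadata
#'
#' @param dir directory containing matrix.mtx, genes.tsv, barcodes.tsv and
#'   optionally meta.tsv
#' @return an `ExpressionDataset`
#' @export
load_expression_dir <- function(dir) {
  ds <- read_mtx_dir(dir)
  meta <- file.path(dir, "meta.tsv")
  if (file.exists(meta)) ds <- attach_cell_meta(ds, meta)
  ds
}
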