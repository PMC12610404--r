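test_that("mtx triplet directories load with the documented orientation", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 2"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  ds <- load_expression(dir, "mtx_dir")
  expect_equal(unname(ds$values), rbind(c(5, 0, 0), c(0, 0, 2)))
  expect_equal(ds$gene_names, c("g1", "g2", "g3"))
  expect_equal(ds$cell_ids, c("c1", "c2"))
  expect_false(ds$normalized)
})

test_that("degenerate and malformed inputs raise validation errors", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "0 0 0"), file.path(dir, "matrix.mtx"))
  writeLines(character(0), file.path(dir, "genes.tsv"))
  writeLines(character(0), file.path(dir, "barcodes.tsv"))
  expect_error(load_expression(dir, "mtx_dir"), "empty")

  expect_error(load_expression(file.path(dir, "nope.csv"), "csv"),
               "does not exist")
  dir2 <- withr::local_tempdir()
  expect_error(load_expression(dir2, "mtx_dir"), "matrix.mtx")

  m <- matrix(1:4, 2, 2)
  expect_error(expression_dataset(m, gene_names = c("a", "a"),
                                  cell_ids = c("c1", "c2")),
               "duplicate gene names.*a")
})

test_that("dense tables round-trip and genes-as-rows transposition matches", {
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_table(ds, path, sep = ",")
  back <- load_expression(path, "csv")
  expect_equal(back$values, ds$values)
  expect_equal(back$gene_names, ds$gene_names)

  # same data stored genes x cells loads identically when declared as such
  path2 <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(gene = ds$gene_names, t(ds$values), check.names = FALSE)
  utils::write.table(tab, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- load_expression(path2, "tsv", orientation = "genes_by_cells")
  expect_equal(unname(back2$values), unname(ds$values))
})

test_that("mtx writer round-trips values, names and metadata", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_expression_mtx(ds, dir)
  back <- load_expression_dir(dir)
  expect_equal(back$values, ds$values)
  expect_equal(back$cell_meta$disease, ds$cell_meta$disease)
  expect_equal(back$cell_meta$sample, ds$cell_meta$sample)
})

test_that("qc_filter applies strict boundary rules per criterion", {
  n_genes <- 400
  counts <- rbind(
    c(rep(1, 299), rep(0, n_genes - 299)),   # 299 detected -> removed
    c(rep(1, 300), rep(0, n_genes - 300)),   # exactly 300 -> retained
    rep(1, n_genes)                          # 400 detected -> retained
  )
  ds <- expression_dataset(counts,
                           gene_names = sprintf("g%03d", seq_len(n_genes)),
                           cell_ids = c("low", "edge", "high"))
  kept <- suppressMessages(qc_filter(ds, min_genes = 300, max_genes = 6000))
  expect_setequal(kept$cell_ids, c("edge", "high"))
  log <- attr(kept, "qc_log")
  expect_equal(unname(log["n_low_genes"]), 1)
})

test_that("qc_filter removes cells above 5% mitochondrial content", {
  # 100 total counts each; 6% vs exactly 5% on MT-CO1
  counts <- matrix(0, 2, 300)
  counts[1, 1:48] <- c(6, rep(2, 47))
  counts[2, 1:49] <- c(5, rep(2, 47), 1)
  genes <- c("MT-CO1", sprintf("g%03d", 1:299))
  ds <- expression_dataset(counts, gene_names = genes,
                           cell_ids = c("high_mt", "edge_mt"))
  kept <- suppressMessages(qc_filter(ds, min_genes = 10, max_genes = 6000,
                                     max_mt_pct = 5))
  expect_setequal(kept$cell_ids, "edge_mt")

  # without MT-prefixed genes the criterion is vacuous
  ds2 <- expression_dataset(counts[, -1],
                            gene_names = sprintf("g%03d", 1:299),
                            cell_ids = c("a", "b"))
  kept2 <- suppressMessages(qc_filter(ds2, min_genes = 10, max_genes = 6000,
                                      max_mt_pct = 5))
  expect_equal(nrow(kept2$values), 2)
})

test_that("qc_filter is idempotent and errors when nothing survives", {
  ds <- tiny_dataset()
  once <- suppressMessages(qc_filter(ds, min_genes = 2, max_genes = 1000))
  twice <- suppressMessages(qc_filter(once, min_genes = 2, max_genes = 1000))
  expect_equal(once$values, twice$values)
  expect_error(suppressMessages(qc_filter(ds, min_genes = 1000)),
               "removed every cell")
})

test_that("lognormalize implements counts-per-scale natural log1p", {
  ds <- expression_dataset(matrix(c(1, 3), 1, 2),
                           gene_names = c("a", "b"), cell_ids = "c1")
  norm <- lognormalize(ds, scale = 1e4)
  expect_equal(unname(norm$values[1, ]), c(log(2501), log(7501)),
               tolerance = 1e-12)
  expect_true(norm$normalized)

  # scale invariance: doubling a cell's counts leaves its profile unchanged
  ds2 <- expression_dataset(matrix(c(2, 6), 1, 2),
                            gene_names = c("a", "b"), cell_ids = "c1")
  expect_equal(lognormalize(ds2)$values, norm$values, tolerance = 1e-12)

  # all-equal counts map to all-equal values
  ds3 <- expression_dataset(matrix(4, 1, 5), cell_ids = "c1")
  expect_equal(length(unique(lognormalize(ds3)$values[1, ])), 1L)

  zero <- expression_dataset(matrix(c(1, 0, 0, 0), 2, 2), cell_ids = c("a", "b"))
  expect_error(lognormalize(zero), "zero total")
})

test_that("lognormalize round-trips back to count proportions", {
  ds <- tiny_dataset(seed = 5)
  norm <- lognormalize(ds, scale = 1e4)
  recovered <- expm1(norm$values) / 1e4      # proportions of library size
  expected <- ds$values / rowSums(ds$values)
  expect_equal(recovered, expected, tolerance = 1e-10)
})

test_that("stratified_split divides exactly and deterministically", {
  counts <- matrix(rpois(100 * 5, 2), 100, 5)
  meta <- data.frame(species = "human",
                     cell_type = rep(c("CM", "EC"), each = 50),
                     disease = "healthy", sample = "s1")
  ds <- expression_dataset(counts, cell_meta = meta)
  sp <- stratified_split(ds, 0.8, stratify_by = "cell_type", seed = 42)
  expect_equal(length(sp$train_indices), 80)
  expect_equal(sum(sp$train_indices <= 50), 40)
  expect_equal(sort(c(sp$train_indices, sp$val_indices)), 1:100)
  sp2 <- stratified_split(ds, 0.8, stratify_by = "cell_type", seed = 42)
  expect_identical(sp, sp2)
})

test_that("stratified_split holds per-stratum shares within one cell", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- 1000
      meta <- data.frame(
        species = sample(c("human", "mouse"), n, TRUE),
        cell_type = sample(c("CM", "EC", "FB"), n, TRUE),
        disease = sample(c("healthy", "HFpEF"), n, TRUE),
        sample = "s1"
      )
      ds <- expression_dataset(matrix(1, n, 3), cell_meta = meta)
      sp <- stratified_split(ds, 0.8, seed = rep)
      expect_equal(sort(c(sp$train_indices, sp$val_indices)), seq_len(n))
      strata <- interaction(meta[c("species", "cell_type", "disease")],
                            drop = TRUE)
      for (s in levels(strata)) {
        idx <- which(strata == s)
        share <- sum(sp$train_indices %in% idx)
        expect_lte(abs(share - 0.8 * length(idx)), 1)
      }
    }
  })
})

test_that("small strata go to training with a warning", {
  meta <- data.frame(species = "human", cell_type = c("CM", "EC", "EC"),
                     disease = "healthy", sample = "s1")
  ds <- expression_dataset(matrix(1, 3, 2), cell_meta = meta)
  expect_warning(sp <- stratified_split(ds, 0.8, stratify_by = "cell_type",
                                        seed = 1),
                 "placed in training")
  expect_true(which(meta$cell_type == "CM") %in% sp$train_indices)
})

test_that("encode_labels builds the one-hot scheme and round-trips", {
  schema <- label_schema()
  meta <- data.frame(species = "human", cell_type = "CM", disease = "HFpEF",
                     sample = "s1")
  lab <- encode_labels(meta, schema)
  expect_equal(ncol(lab$onehot), 13)
  expect_equal(sum(lab$onehot[1, ]), 3)
  expect_equal(unname(which(lab$onehot[1, ] == 1)),
               c(which(lab$class_names == "species:human"),
                 which(lab$class_names == "cell_type:CM"),
                 which(lab$class_names == "disease:HFpEF")))
  # within each category block exactly one positive
  for (block in lab$blocks) expect_equal(sum(lab$onehot[1, block]), 1)

  ds <- tiny_dataset()
  lab2 <- encode_labels(ds$cell_meta, tiny_schema())
  expect_equal(decode_labels(lab2),
               ds$cell_meta[c("species", "cell_type", "disease")],
               ignore_attr = TRUE)
})

test_that("encode_labels names the offending cell on bad values", {
  meta <- data.frame(species = c("human", "human"),
                     cell_type = c("CM", "CM"),
                     disease = c("HFpEF", NA),
                     sample = "s1",
                     row.names = c("cellA", "cellB"))
  expect_error(encode_labels(meta, label_schema()), "cellB")
  meta$disease <- c("HFpEF", "gout")
  expect_error(encode_labels(meta, label_schema()), "gout")
})
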