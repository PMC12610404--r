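# Small in-code fixtures shared across test files.

# a tiny raw-count dataset with full annotations
tiny_dataset <- function(n_cells = 20, n_genes = 12, seed = 1,
                         mito_first = TRUE) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_cells * n_genes, 3), n_cells, n_genes)
    genes <- sprintf("g%03d", seq_len(n_genes))
    if (mito_first) genes[1] <- "MT-CO1"
    meta <- data.frame(
      species = rep(c("human", "mouse"), length.out = n_cells),
      cell_type = rep(c("CM", "EC"), each = n_cells / 2),
      disease = rep(c("healthy", "HFpEF"), length.out = n_cells),
      sample = rep(c("s1", "s2"), length.out = n_cells),
      stringsAsFactors = FALSE
    )
    expression_dataset(counts, gene_names = genes,
                       cell_ids = sprintf("c%03d", seq_len(n_cells)),
                       cell_meta = meta)
  })
}

tiny_schema <- function() {
  label_schema(species = c("human", "mouse"),
               cell_type = c("CM", "EC"),
               disease = c("healthy", "HFpEF"))
}

# small separable synthetic configuration for fast network tests
small_separable_config <- function(seed = 1, marker_effect = 3) {
  synthetic_config(
    n_genes = 60, cells_per_group = 100,
    species = "human", cell_type = c("CM", "EC"),
    disease = c("healthy", "HFpEF"),
    markers_per_label = 6, marker_effect = marker_effect,
    dropout_rate = 0.05, n_mito_genes = 2, seed = seed
  )
}

# an independent macro F1 implementation from hard confusion counts,
# used as the oracle for the differentiable loss
hard_macro_f1 <- function(binary, onehot) {
  f1 <- vapply(seq_len(ncol(onehot)), function(c) {
    tp <- sum(binary[, c] == 1 & onehot[, c] == 1)
    fp <- sum(binary[, c] == 1 & onehot[, c] == 0)
    fn <- sum(binary[, c] == 0 & onehot[, c] == 1)
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  }, numeric(1))
  mean(f1)
}

# simple random 2-layer network as a black-box model for attribution tests
random_mlp_model <- function(d, seed, hidden = 8) {
  withr::with_seed(seed, {
    W1 <- matrix(rnorm(d * hidden), d, hidden)
    b1 <- rnorm(hidden)
    W2 <- rnorm(hidden)
    b2 <- rnorm(1)
  })
  function(X) {
    if (is.null(dim(X))) X <- matrix(X, 1)
    H <- pmax(X %*% W1 + rep(b1, each = nrow(X)), 0)
    drop(1 / (1 + exp(-(H %*% W2 + b2))))
  }
}

random_linear_model <- function(d, seed) {
  w <- withr::with_seed(seed, rnorm(d))
  list(model = function(X) {
    if (is.null(dim(X))) X <- matrix(X, 1)
    drop(X %*% w)
  }, w = w)
}
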