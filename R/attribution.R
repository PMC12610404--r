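#' Select the background distribution for attribution
#'
#' Draws up to `n` distinct training cells (without replacement) whose
#' expression stands in for "absent" features during interventional Shapley
#' attribution. If fewer than `n` cells are available all are used, with a
#' warning.
#'
#' @param train normalized (typically DAE-reconstructed) `ExpressionDataset`
#'   or matrix of training cells
#' @param n background size, default 1000
#' @param seed integer seed
#' @return list of class `BackgroundSet`: `cells` (matrix), `source_indices`,
#'   `seed`
#' @export
select_background <- function(train, n = 1000L, seed = 1L) {
  X <- dataset_matrix(train)
  if (nrow(X) == 0L) stop("training set is empty")
  stopifnot(n >= 1)
  if (nrow(X) < n) {
    warning("requested ", n, " background cells but only ", nrow(X),
            " available; using all of them")
    n <- nrow(X)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(X), n))
  structure(list(cells = X[idx, , drop = FALSE], source_indices = idx,
                 seed = seed),
            class = "BackgroundSet")
}

#' Select cells to explain, capped per group
#'
#' Draws up to `per_group` cells from every group defined by the joint values
#' of `group_by` metadata columns (default cell type x biological sample);
#' smaller groups contribute all their cells.
#'
#' @param ds `ExpressionDataset` with metadata
#' @param per_group cap per group, default 200
#' @param group_by metadata columns defining the groups
#' @param seed integer seed
#' @return sorted integer vector of cell indices
#' @export
select_explained_cells <- function(ds, per_group = 200L,
                                   group_by = c("cell_type", "sample"),
                                   seed = 1L) {
  stopifnot(inherits(ds, "ExpressionDataset"), !is.null(ds$cell_meta),
            per_group >= 1)
  groups <- interaction(ds$cell_meta[group_by], drop = TRUE)
  idx <- withr::with_seed(seed, {
    unlist(lapply(levels(groups), function(g) {
      members <- which(groups == g)
      if (length(members) <= per_group) members
      else sample(members, per_group)
    }), use.names = FALSE)
  })
  sort(idx)
}

#' Exact interventional Shapley values by subset enumeration
#'
#' For every coalition S the value is `v(S) = mean_b f(x_S, b_otherwise)` over
#' the background rows; attributions are the Shapley-weighted average of
#' marginal contributions over all `2^d` coalitions. Exact, so it satisfies
#' the efficiency, null-player, symmetry and linearity axioms to machine
#' precision; feasible only for small feature counts and used as the oracle
#' for [shapley_sampled()].
#'
#' @param model function mapping a (rows x features) numeric matrix to a
#'   numeric vector of outputs, one per row
#' @param x numeric feature vector for the instance to explain
#' @param background a [select_background()] result or plain matrix
#' @param max_features guard on the enumeration size (default 15)
#' @return numeric vector of per-feature attributions
#' @export
shapley_exact <- function(model, x, background, max_features = 15L) {
  B <- if (inherits(background, "BackgroundSet")) background$cells else background
  d <- length(x)
  if (ncol(B) != d) stop("background feature count != length(x)")
  if (d > max_features) {
    stop("exact enumeration over 2^", d, " coalitions refused; ",
         "use shapley_sampled() for more than ", max_features, " features")
  }
  nb <- nrow(B)
  n_sets <- 2^d
  membership <- matrix(FALSE, n_sets, d)
  for (j in seq_len(d)) {
    membership[, j] <- bitwAnd(seq_len(n_sets) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  # value of every coalition, averaged over the background
  eval_mat <- matrix(0, n_sets * nb, d)
  for (s in seq_len(n_sets)) {
    rows <- (s - 1L) * nb + seq_len(nb)
    block <- B
    members <- membership[s, ]
    if (any(members)) {
      block[, members] <- matrix(x[members], nb, sum(members), byrow = TRUE)
    }
    eval_mat[rows, ] <- block
  }
  fx <- model(eval_mat)
  v <- colMeans(matrix(fx, nb, n_sets))
  sizes <- rowSums(membership)
  # Shapley kernel weight for adding j to S: |S|! (d - |S| - 1)! / d!
  wt <- exp(lfactorial(0:(d - 1)) + lfactorial(d - 1 - (0:(d - 1))) - lfactorial(d))
  phi <- numeric(d)
  for (j in seq_len(d)) {
    without_j <- which(!membership[, j])
    with_j <- without_j + as.integer(2^(j - 1))
    w <- wt[sizes[without_j] + 1L]
    phi[j] <- sum(w * (v[with_j] - v[without_j]))
  }
  names(phi) <- colnames(B)
  phi
}

# one cell's permutation-chain evaluation through an arbitrary model
# closure; `perms` is a d x n_perm matrix, `bg_rows` picks one background
# row per permutation. Returns chains x d per-chain attribution vectors
# (antithetic partner chains interleaved).
eval_chains_r <- function(model, x, B, perms, bg_rows, antithetic) {
  d <- length(x)
  n_permutations <- ncol(perms)
  n_chains <- n_permutations * (if (antithetic) 2L else 1L)
  tri <- (row(matrix(0, d + 1L, d)) > col(matrix(0, d + 1L, d)))
  rep_times <- d:1
  chain_list <- vector("list", n_chains)
  chain_perms <- vector("list", n_chains)
  k <- 0L
  for (p in seq_len(n_permutations)) {
    b <- B[bg_rows[p], ]
    base_perm <- perms[, p]
    for (pi in if (antithetic) list(base_perm, rev(base_perm)) else list(base_perm)) {
      M <- matrix(b[pi], d + 1L, d, byrow = TRUE)
      M[tri] <- rep(x[pi], times = rep_times)
      M[, pi] <- M
      k <- k + 1L
      chain_list[[k]] <- M
      chain_perms[[k]] <- pi
    }
  }
  fx <- model(do.call(rbind, chain_list))
  phi_chains <- matrix(0, n_chains, d)
  for (c_ in seq_len(n_chains)) {
    o <- fx[(c_ - 1L) * (d + 1L) + seq_len(d + 1L)]
    phi_chains[c_, chain_perms[[c_]]] <- diff(o)
  }
  phi_chains
}

#' Permutation-sampling interventional Shapley attribution
#'
#' The production estimator: for each explained cell it samples random feature
#' permutations, each paired with one background cell, and walks the chain
#' from background to instance recording every feature's marginal contribution
#' to the model output. With `antithetic = TRUE` (default) each permutation is
#' paired with its reversal, which cancels first-order position noise. The
#' estimate is unbiased for the exact interventional Shapley value and its
#' Monte-Carlo standard error shrinks as `1/sqrt(n_permutations)`; agreement
#' with [shapley_exact()] is the estimator's contract.
#'
#' @param model function mapping a (rows x genes) matrix to one output node's
#'   numeric value per row (see [class_model()])
#' @param X cells x genes matrix (or `ExpressionDataset`) of cells to explain
#' @param background a [select_background()] result or matrix
#' @param n_permutations permutations per cell (default 8)
#' @param antithetic pair each permutation with its reversal (default TRUE)
#' @param seed integer seed
#' @param class_name label of the explained output node
#' @param cell_meta optional per-cell annotations to carry along
#' @param return_se also estimate per-cell per-gene Monte-Carlo standard
#'   errors (over permutation draws)
#' @return an `AttributionSet`: list with `scores` (cells x genes),
#'   `class_name`, `cell_meta`, `z_transformed = FALSE`, `excluded_genes`,
#'   and optionally `se`
#' @export
shapley_sampled <- function(model, X, background, n_permutations = 8L,
                            antithetic = TRUE, seed = 1L, class_name = "node",
                            cell_meta = NULL, return_se = FALSE) {
  if (inherits(X, "ExpressionDataset")) {
    if (is.null(cell_meta)) cell_meta <- X$cell_meta
    X <- X$values
  }
  if (is.null(dim(X))) X <- matrix(X, 1L)
  B <- if (inherits(background, "BackgroundSet")) background$cells else background
  if (nrow(B) == 0L) stop("background is empty")
  if (ncol(B) != ncol(X)) stop("background and X gene dimensions differ")
  stopifnot(n_permutations >= 1)
  n <- nrow(X)
  d <- ncol(X)
  scores <- matrix(0, n, d, dimnames = dimnames(X))
  se <- if (return_se) matrix(0, n, d, dimnames = dimnames(X)) else NULL
  stack <- attr(model, "stack")  # compiled fast path for network stacks
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      perms <- matrix(replicate(n_permutations, sample.int(d)), nrow = d)
      bg_rows <- sample.int(nrow(B), n_permutations, replace = TRUE)
      chains <- if (!is.null(stack)) {
        .cpp_shapley_cell(stack$W, stack$b, stack$acts, stack$node,
                          X[i, ], B, perms, bg_rows, antithetic)
      } else {
        eval_chains_r(model, X[i, ], B, perms, bg_rows, antithetic)
      }
      if (antithetic) {
        # average antithetic partners first; pairs are the independent draws
        chains <- (chains[seq(1L, nrow(chains), 2L), , drop = FALSE] +
                     chains[seq(2L, nrow(chains), 2L), , drop = FALSE]) / 2
      }
      scores[i, ] <- colMeans(chains)
      if (return_se) {
        if (nrow(chains) > 1L) {
          se[i, ] <- apply(chains, 2, stats::sd) / sqrt(nrow(chains))
        } else {
          se[i, ] <- NA_real_
        }
      }
    }
  })
  attribution_set(scores, class_name = class_name, cell_meta = cell_meta,
                  se = se)
}

#' Construct an AttributionSet
#'
#' @param scores cells x genes matrix of attribution scores for one output
#'   node
#' @param class_name the explained node's label
#' @param cell_meta optional per-cell annotation data.frame
#' @param z_transformed whether rows are already Z-standardized
#' @param excluded_genes gene names removed (e.g. mitochondrial)
#' @param se optional matching matrix of Monte-Carlo standard errors
#' @return an `AttributionSet`
#' @export
attribution_set <- function(scores, class_name = "node", cell_meta = NULL,
                            z_transformed = FALSE,
                            excluded_genes = character(0), se = NULL) {
  stopifnot(is.matrix(scores))
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
    stopifnot(nrow(cell_meta) == nrow(scores))
  }
  structure(list(scores = scores, class_name = class_name,
                 cell_meta = cell_meta, z_transformed = z_transformed,
                 excluded_genes = excluded_genes, se = se),
            class = "AttributionSet")
}

#' @export
print.AttributionSet <- function(x, ...) {
  cat(sprintf("AttributionSet '%s': %d cells x %d genes (%s)\n",
              x$class_name, nrow(x$scores), ncol(x$scores),
              if (x$z_transformed) "Z-transformed" else "raw"))
  if (length(x$excluded_genes)) {
    cat("  excluded genes:", length(x$excluded_genes), "\n")
  }
  invisible(x)
}

#' Remove mitochondrial genes from an AttributionSet
#'
#' Drops columns with case-insensitive `MT-` name prefix, before
#' Z-standardization so excluded scores cannot influence row means and
#' standard deviations. Idempotent.
#'
#' @param att a raw (not yet Z-transformed) `AttributionSet`
#' @return the `AttributionSet` without mitochondrial columns; removed names
#'   accumulate in `excluded_genes`
#' @export
exclude_mito <- function(att) {
  stopifnot(inherits(att, "AttributionSet"))
  if (att$z_transformed) stop("exclude mitochondrial genes before Z-transforming")
  mito <- is_mito_gene(colnames(att$scores))
  if (!any(mito)) return(att)
  removed <- colnames(att$scores)[mito]
  att$scores <- att$scores[, !mito, drop = FALSE]
  if (!is.null(att$se)) att$se <- att$se[, !mito, drop = FALSE]
  att$excluded_genes <- union(att$excluded_genes, removed)
  att
}

#' Z-standardize attribution scores rowwise
#'
#' Each cell's scores are centered on that cell's mean attribution and scaled
#' by its population standard deviation (divide by the number of genes, no
#' Bessel correction). Rows with zero spread become all zeros with a warning.
#'
#' @param att a raw `AttributionSet` with at least 2 genes
#' @return the `AttributionSet` with `z_transformed = TRUE`
#' @export
z_transform_rows <- function(att) {
  stopifnot(inherits(att, "AttributionSet"))
  if (att$z_transformed) stop("AttributionSet is already Z-transformed")
  x <- att$scores
  if (ncol(x) < 2L) stop("Z-transform needs at least 2 genes per row")
  mu <- rowMeans(x)
  centered <- x - mu
  sigma <- sqrt(rowMeans(centered^2))
  zero <- sigma == 0
  if (any(zero)) {
    warning(sum(zero), " row(s) with zero standard deviation set to all zeros")
    sigma[zero] <- 1
  }
  z <- centered / sigma
  z[zero, ] <- 0
  att$scores <- z
  att$se <- NULL
  att$z_transformed <- TRUE
  att
}

#' Build the explained-model closure for one classifier output node
#'
#' Returns a function mapping an expression matrix to the chosen node's
#' sigmoid probability. By default the classifier is explained directly on its
#' own (reconstructed) input space; pass `dae` to explain the composite
#' `classifier(reconstruct(.))` on raw normalized expression instead.
#'
#' @param classifier a trained `dxg_classifier`
#' @param node output node index or class name
#' @param dae optional trained `dxg_dae` to prepend
#' @return function(matrix) -> numeric vector
#' @export
class_model <- function(classifier, node, dae = NULL) {
  stopifnot(inherits(classifier, "dxg_classifier"))
  if (is.character(node)) {
    idx <- match(node, classifier$class_names)
    if (is.na(idx)) stop("unknown class name: ", node)
    node <- idx
  }
  stopifnot(node >= 1, node <= classifier$spec$n_classes)
  force(classifier); force(dae)
  f <- function(X) {
    if (is.null(dim(X))) X <- matrix(X, 1L)
    if (!is.null(dae)) X <- nn_forward(dae$net, X)
    nn_forward(classifier$net, X)[, node]
  }
  # the stacked weight list lets shapley_sampled() evaluate permutation
  # chains in compiled code; the closure remains the reference semantics
  stack <- if (is.null(dae)) {
    list(W = classifier$net$W, b = classifier$net$b,
         acts = unname(activation_codes[classifier$net$activations]),
         node = as.integer(node))
  } else {
    list(W = c(dae$net$W, classifier$net$W),
         b = c(dae$net$b, classifier$net$b),
         acts = unname(activation_codes[c(dae$net$activations,
                                          classifier$net$activations)]),
         node = as.integer(node))
  }
  structure(f, class = c("dxg_class_model", "function"), stack = stack)
}

#' Concatenate per-class AttributionSets into one annotated collection
#'
#' All sets must share gene columns; each keeps its own cells and ground-truth
#' annotations, keyed by class name.
#'
#' @param sets list of `AttributionSet` objects
#' @return an `AttributionCollection` (named list)
#' @export
assemble_class_sets <- function(sets) {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, logical(1),
                                          "AttributionSet")))
  ref <- colnames(sets[[1]]$scores)
  for (s in sets[-1]) {
    if (!identical(colnames(s$scores), ref)) {
      diff <- union(setdiff(ref, colnames(s$scores)),
                    setdiff(colnames(s$scores), ref))
      stop("gene columns differ between class sets: ",
           paste(utils::head(diff, 10), collapse = ", "))
    }
  }
  names(sets) <- vapply(sets, function(s) s$class_name, character(1))
  structure(sets, class = "AttributionCollection")
}

#' Persist / restore attribution sets as plain-text TSVs with a JSON manifest
#'
#' One `scores_<class>.tsv` and `meta_<class>.tsv` per class plus
#' `manifest.json`; round-trips through [read_attribution()].
#'
#' @param collection an `AttributionCollection` (or single `AttributionSet`)
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_attribution <- function(collection, dir) {
  if (inherits(collection, "AttributionSet")) {
    collection <- assemble_class_sets(list(collection))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(classes = names(collection),
                   z_transformed = vapply(collection, `[[`, logical(1),
                                          "z_transformed"),
                   excluded_genes = lapply(collection, `[[`, "excluded_genes"))
  for (cls in names(collection)) {
    att <- collection[[cls]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", cls)
    tab <- data.frame(cell_id = if (!is.null(rownames(att$scores)))
      rownames(att$scores) else paste0("cell", seq_len(nrow(att$scores))),
      att$scores, check.names = FALSE)
    utils::write.table(tab, file.path(dir, paste0("scores_", safe, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(att$cell_meta)) {
      utils::write.table(att$cell_meta,
                         file.path(dir, paste0("meta_", safe, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$files[[cls]] <- paste0("scores_", safe, ".tsv")
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_attribution
#' @param dir directory written by [write_attribution()]
#' @export
read_attribution <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sets <- lapply(seq_along(manifest$classes), function(i) {
    cls <- manifest$classes[i]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", cls)
    tab <- utils::read.table(file.path(dir, paste0("scores_", safe, ".tsv")),
                             header = TRUE, sep = "\t", check.names = FALSE)
    scores <- as.matrix(tab[, -1, drop = FALSE])
    rownames(scores) <- tab[[1]]
    meta_path <- file.path(dir, paste0("meta_", safe, ".tsv"))
    meta <- if (file.exists(meta_path)) {
      utils::read.table(meta_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else NULL
    attribution_set(scores, class_name = cls, cell_meta = meta,
                    z_transformed = manifest$z_transformed[[i]],
                    excluded_genes = unlist(manifest$excluded_genes[[i]]))
  })
  assemble_class_sets(sets)
}
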