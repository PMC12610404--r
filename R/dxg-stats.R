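#' Signed cube root
#'
#' `sign(x) * |x|^(1/3)` — odd, defined for negative, zero and positive
#' values, and skew-reducing much like a log transform. Used for the cube-root
#' fold change of attribution-score group means.
#'
#' @param x numeric vector
#' @return numeric vector
#' @export
signed_cuberoot <- function(x) sign(x) * abs(x)^(1 / 3)

#' Define the two cell groups of a comparison
#'
#' Each group is a set of equality filters over the annotation columns
#' (species, cell_type, disease, sample); `class_node` names the attribution
#' class set the scores are drawn from.
#'
#' @param A,B named lists of filters, e.g.
#'   `list(species = "human", cell_type = "CM", disease = "HFpEF")`
#' @param class_node attribution class to test (defaults to the first set)
#' @return a `group_spec` list
#' @export
group_spec <- function(A, B, class_node = NULL) {
  stopifnot(is.list(A), is.list(B), length(A) >= 1, length(B) >= 1)
  structure(list(A = A, B = B, class_node = class_node), class = "group_spec")
}

match_group <- function(meta, filters) {
  keep <- rep(TRUE, nrow(meta))
  for (col in names(filters)) {
    if (!col %in% names(meta)) stop("unknown annotation column: ", col)
    keep <- keep & meta[[col]] %in% filters[[col]]
  }
  keep
}

#' Shapiro-Wilk normality screen over per-gene score samples
#'
#' Tests each gene's pooled values with the Shapiro-Wilk test (subsampled to
#' `max_n`, the standard implementation limit) and summarizes how often
#' normality is rejected at `alpha`. The global recommendation is the t-test
#' when the median gene's p-value is consistent with normality (median p >
#' alpha), otherwise the Wilcoxon rank-sum test. Constant or too-short samples
#' are skipped with a warning.
#'
#' @param scores cells x genes matrix (or `AttributionSet`) of values
#' @param alpha rejection level, default 0.05
#' @param max_n subsampling cap per gene, default 5000
#' @param seed integer seed for the subsampling
#' @return list with `p_values` (per gene), `frac_rejected`,
#'   `recommendation` (`"t"` or `"wilcoxon"`), `skipped` (gene names)
#' @export
normality_check <- function(scores, alpha = 0.05, max_n = 5000L, seed = 1L) {
  if (inherits(scores, "AttributionSet")) scores <- scores$scores
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("gene", seq_len(ncol(scores)))
  }
  p <- rep(NA_real_, ncol(scores))
  names(p) <- colnames(scores)
  withr::with_seed(seed, {
    for (j in seq_len(ncol(scores))) {
      x <- scores[, j]
      x <- x[is.finite(x)]
      if (length(x) > max_n) x <- sample(x, max_n)
      if (length(x) < 3L || stats::sd(x) == 0) next
      p[j] <- stats::shapiro.test(x)$p.value
    }
  })
  skipped <- names(p)[is.na(p)]
  if (length(skipped)) {
    warning(length(skipped), " gene(s) skipped in normality check ",
            "(constant or fewer than 3 values)")
  }
  tested <- p[!is.na(p)]
  frac_rejected <- if (length(tested)) mean(tested < alpha) else NA_real_
  recommendation <- if (length(tested) && stats::median(tested) > alpha) "t" else "wilcoxon"
  list(p_values = p, frac_rejected = frac_rejected,
       recommendation = recommendation, skipped = skipped)
}

# vectorized two-sided Welch t-test over the columns of two matrices
welch_t_cols <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- colSums((A - rep(mA, each = nA))^2) / (nA - 1)
  vB <- colSums((B - rep(mB, each = nB))^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t_stat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  zero <- se2 == 0
  if (any(zero)) {
    # no variance at all: identical constants => no evidence of difference
    p[zero] <- ifelse(mA[zero] == mB[zero], 1, 0)
    t_stat[zero] <- ifelse(mA[zero] == mB[zero], 0, Inf * sign(mA - mB)[zero])
  }
  list(statistic = t_stat, p = p, mean_A = mA, mean_B = mB, df = df)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Input validation plus the standard step-up adjustment with monotonicity
#' enforcement, capped at 1 (delegates to `stats::p.adjust`).
#'
#' @param p_values numeric vector in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differentially explained genes: test attribution scores between two groups
#'
#' The core of the method: for every gene, the Z-standardized Shapley scores
#' of group A are compared with those of group B using Welch's t-test (or the
#' Wilcoxon rank-sum test); p-values are BH-adjusted across all genes of the
#' comparison, and the effect size is the cube-root fold change
#' `FC3 = signed_cuberoot(mean_A) - signed_cuberoot(mean_B)` on the group
#' means of the tested scores. `method = "auto"` resolves the test once for
#' the whole comparison through [normality_check()] on the pooled groups.
#'
#' Standardization: by default each gene's scores are Z-standardized across
#' the pooled cells (`"gene"`), which leaves the test's inference identical to
#' testing raw attributions. `"row"` instead consumes per-cell (rowwise)
#' Z-scores as produced by [z_transform_rows()]. The two readings differ
#' materially on small gene panels: by the efficiency axiom a cell's
#' attributions sum to the difference between its prediction and the mean
#' background prediction, so rowwise centering injects a between-group offset
#' of that difference divided by the gene count into every gene; with few
#' hundred genes this makes unrelated genes test significant. The methods
#' vignette derives the size of the effect. An already row-transformed
#' `AttributionSet` is tested as-is.
#'
#' @param att an `AttributionSet` or `AttributionCollection` (the
#'   `groups$class_node` set is drawn from it)
#' @param groups a [group_spec()]
#' @param method `"auto"`, `"t"` or `"wilcoxon"`
#' @param standardization `"gene"` (default), `"row"` or `"none"`; ignored
#'   with a message if the set is already Z-transformed
#' @param normality_seed seed for the auto normality screen
#' @return data.frame of class `dxg_table`, one row per gene: `gene`,
#'   `mean_A`, `mean_B`, `fc3`, `p_raw`, `p_adj`, `test_used`, `n_A`, `n_B`,
#'   sorted by `p_adj` then decreasing `|fc3|`
#' @export
dxg_test <- function(att, groups, method = c("auto", "t", "wilcoxon"),
                     standardization = c("gene", "row", "none"),
                     normality_seed = 1L) {
  method <- match.arg(method)
  standardization <- match.arg(standardization)
  stopifnot(inherits(groups, "group_spec"))
  if (inherits(att, "AttributionCollection")) {
    if (is.null(groups$class_node)) {
      stop("groups$class_node must name the attribution class to test")
    }
    if (!groups$class_node %in% names(att)) {
      stop("class node '", groups$class_node, "' not in the collection")
    }
    att <- att[[groups$class_node]]
  }
  stopifnot(inherits(att, "AttributionSet"))
  if (is.null(att$cell_meta)) stop("AttributionSet carries no cell annotations")
  in_A <- match_group(att$cell_meta, groups$A)
  in_B <- match_group(att$cell_meta, groups$B)
  if (!any(in_A)) stop("group A filter matches no cells: ",
                       paste(names(groups$A), unlist(groups$A),
                             sep = "=", collapse = ", "))
  if (!any(in_B)) stop("group B filter matches no cells: ",
                       paste(names(groups$B), unlist(groups$B),
                             sep = "=", collapse = ", "))
  if (any(in_A & in_B)) stop("groups A and B overlap; they must be disjoint")
  if (sum(in_A) < 2L || sum(in_B) < 2L) stop("both groups need >= 2 cells")
  scores <- att$scores
  if (att$z_transformed) {
    if (standardization != "none") {
      message("dxg_test: AttributionSet is already rowwise Z-transformed; ",
              "testing it as-is")
    }
  } else if (standardization == "gene") {
    pooled <- scores[in_A | in_B, , drop = FALSE]
    mu <- colMeans(pooled)
    sd_g <- sqrt(colMeans(sweep(pooled, 2, mu)^2))
    sd_g[sd_g == 0] <- 1
    scores <- sweep(sweep(scores, 2, mu), 2, sd_g, "/")
  } else if (standardization == "row") {
    scores <- z_transform_rows(att)$scores
  }
  A <- scores[in_A, , drop = FALSE]
  B <- scores[in_B, , drop = FALSE]
  if (method == "auto") {
    method <- normality_check(rbind(A, B), seed = normality_seed)$recommendation
  }
  if (method == "t") {
    res <- welch_t_cols(A, B)
    p_raw <- res$p
  } else {
    p_raw <- vapply(seq_len(ncol(A)), function(j) {
      if (stats::sd(A[, j]) == 0 && stats::sd(B[, j]) == 0 &&
          A[1, j] == B[1, j]) return(1)
      stats::wilcox.test(A[, j], B[, j], exact = FALSE)$p.value
    }, numeric(1))
  }
  mean_A <- colMeans(A)
  mean_B <- colMeans(B)
  tab <- data.frame(
    gene = colnames(att$scores),
    mean_A = mean_A, mean_B = mean_B,
    fc3 = signed_cuberoot(mean_A) - signed_cuberoot(mean_B),
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    test_used = method,
    n_A = sum(in_A), n_B = sum(in_B),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$p_adj, -abs(tab$fc3), tab$gene), ]
  rownames(tab) <- NULL
  class(tab) <- c("dxg_table", "data.frame")
  tab
}

#' Differentially expressed genes by Wilcoxon rank-sum (the DEG comparator)
#'
#' Classical expression-based testing on normalized values: per gene a
#' two-sided Wilcoxon rank-sum test between the groups, pre-filtered by
#' detection fraction and natural-log fold change of group mean
#' `expm1`-expression (+1 pseudocount), BH adjustment across the tested
#' genes. Set `min_pct = 0, min_abs_logfc = 0` for the unfiltered ranking
#' used by preranked enrichment.
#'
#' @param expr normalized `ExpressionDataset`
#' @param groups a [group_spec()] over the expression metadata
#' @param min_pct minimum detection fraction in at least one group
#'   (default 0.1)
#' @param min_abs_logfc minimum absolute natural-log fold change
#'   (default 0.25)
#' @return data.frame of class `deg_table`: `gene`, `log_fc`, `p_raw`,
#'   `p_adj`, `pct_A`, `pct_B`, `n_A`, `n_B`
#' @export
deg_wilcoxon <- function(expr, groups, min_pct = 0.1, min_abs_logfc = 0.25) {
  stopifnot(inherits(expr, "ExpressionDataset"), inherits(groups, "group_spec"))
  if (!expr$normalized) stop("deg_wilcoxon expects a normalized dataset")
  in_A <- match_group(expr$cell_meta, groups$A)
  in_B <- match_group(expr$cell_meta, groups$B)
  if (!any(in_A) || !any(in_B)) stop("a group filter matches no cells")
  if (any(in_A & in_B)) stop("groups A and B overlap; they must be disjoint")
  A <- expr$values[in_A, , drop = FALSE]
  B <- expr$values[in_B, , drop = FALSE]
  pct_A <- colMeans(A > 0)
  pct_B <- colMeans(B > 0)
  log_fc <- log(colMeans(expm1(A)) + 1) - log(colMeans(expm1(B)) + 1)
  keep <- pmax(pct_A, pct_B) >= min_pct & abs(log_fc) >= min_abs_logfc
  if (!any(keep)) {
    out <- data.frame(gene = character(0), log_fc = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      pct_A = numeric(0), pct_B = numeric(0),
                      n_A = integer(0), n_B = integer(0))
    class(out) <- c("deg_table", "data.frame")
    return(out)
  }
  idx <- which(keep)
  p_raw <- vapply(idx, function(j) {
    stats::wilcox.test(A[, j], B[, j], exact = FALSE)$p.value
  }, numeric(1))
  tab <- data.frame(gene = expr$gene_names[idx], log_fc = log_fc[idx],
                    p_raw = p_raw, p_adj = bh_adjust(p_raw),
                    pct_A = pct_A[idx], pct_B = pct_B[idx],
                    n_A = sum(in_A), n_B = sum(in_B),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_adj, -abs(tab$log_fc), tab$gene), ]
  rownames(tab) <- NULL
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Overlap of significant DXGs and DEGs
#'
#' Set algebra on the genes significant (BH-adjusted p < alpha) under each
#' method.
#'
#' @param dxg a `dxg_table`
#' @param deg a `deg_table`
#' @param alpha significance level, default 0.05
#' @return list with counts `n_common`, `n_dxg_only`, `n_deg_only` and the
#'   corresponding gene vectors
#' @export
compare_gene_sets <- function(dxg, deg, alpha = 0.05) {
  if (!length(intersect(dxg$gene, deg$gene))) {
    warning("DXG and DEG tables share no genes; were they computed on the ",
            "same universe?")
  }
  sig_dxg <- dxg$gene[dxg$p_adj < alpha]
  sig_deg <- deg$gene[deg$p_adj < alpha]
  common <- intersect(sig_dxg, sig_deg)
  list(n_common = length(common),
       n_dxg_only = length(setdiff(sig_dxg, sig_deg)),
       n_deg_only = length(setdiff(sig_deg, sig_dxg)),
       common = common,
       dxg_only = setdiff(sig_dxg, sig_deg),
       deg_only = setdiff(sig_deg, sig_dxg))
}
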