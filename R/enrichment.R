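#' Per-gene ranking score for preranked enrichment
#'
#' `score = sign(FC) * log10(|FC / p_bin| + 1)` where `p_bin` is a binned
#' p-value: 0.1 when the raw p is (strictly) below 0.05, otherwise 1. The
#' binning boosts significant genes by one decade while keeping the fold
#' change in the ranking. Odd in FC; `sign(0) = 0`.
#'
#' @param fc fold change (cube-root fold change for DXGs, log fold change for
#'   DEGs); vectorized
#' @param p_raw raw p-value in `[0, 1]`; vectorized
#' @return numeric score(s)
#' @export
gsea_gene_score <- function(fc, p_raw) {
  if (any(!is.finite(fc))) stop("fold changes must be finite")
  if (any(!is.finite(p_raw)) || any(p_raw < 0 | p_raw > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p_bin <- ifelse(p_raw < 0.05, 0.1, 1)
  sign(fc) * log10(abs(fc / p_bin) + 1)
}

#' Rank genes by enrichment score
#'
#' Accepts a `dxg_table` (uses `fc3`) or `deg_table` (uses `log_fc`), or any
#' data.frame with `gene`, a fold-change column and `p_raw`. Descending score
#' order; exact ties break lexicographically by gene name (logged).
#'
#' @param records per-gene test results, one row per gene
#' @return data.frame with `gene` and `score`, ranked
#' @export
rank_genes <- function(records) {
  stopifnot(is.data.frame(records), "gene" %in% names(records),
            "p_raw" %in% names(records))
  if (anyDuplicated(records$gene)) {
    stop("duplicate genes in ranking input: ",
         paste(utils::head(unique(records$gene[duplicated(records$gene)]), 5),
               collapse = ", "))
  }
  fc_col <- intersect(c("fc3", "log_fc", "fc"), names(records))[1]
  if (is.na(fc_col)) stop("no fold-change column (fc3/log_fc/fc) found")
  score <- gsea_gene_score(records[[fc_col]], records$p_raw)
  ord <- order(-score, records$gene)
  n_ties <- sum(duplicated(score))
  if (n_ties > 0) {
    message("rank_genes: ", n_ties,
            " tied score(s) broken lexicographically by gene name")
  }
  data.frame(gene = records$gene[ord], score = score[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

# weighted Kolmogorov-Smirnov running-sum enrichment statistic.
# ranking_scores must be in ranked (descending) order; hit_positions indexes
# into that order.
gsea_running_sum <- function(ranking_scores, hit_positions, weight = 1) {
  n <- length(ranking_scores)
  hits <- logical(n)
  hits[hit_positions] <- TRUE
  w <- abs(ranking_scores)^weight
  w_hit <- ifelse(hits, w, 0)
  total_hit <- sum(w_hit)
  if (total_hit == 0) {
    # all-zero hit weights: fall back to unweighted hit steps
    w_hit <- ifelse(hits, 1, 0)
    total_hit <- sum(w_hit)
  }
  n_miss <- n - sum(hits)
  p_hit <- cumsum(w_hit) / total_hit
  p_miss <- cumsum(!hits) / n_miss
  running <- p_hit - p_miss
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running)
}

#' Preranked gene set enrichment with a permutation null
#'
#' The standard weighted running-sum statistic: walking down the ranked list,
#' hits advance the sum proportionally to `|score|^weight`, misses retreat it
#' uniformly; the enrichment score is the maximum signed deviation. The
#' p-value comes from `n_perm` seeded gene-label permutations (random sets of
#' the same size), two-sided on `|ES|`, with BH adjustment across sets.
#'
#' @param ranking output of [rank_genes()] (or data.frame gene/score in
#'   ranked order)
#' @param gene_sets named list of gene-identifier vectors (e.g. from
#'   [read_gmt()])
#' @param weight running-sum weight exponent, default 1
#' @param n_perm number of permutations, default 1000
#' @param min_size,max_size set-size bounds after intersecting the ranking
#'   (defaults 5 and 500)
#' @param seed integer seed
#' @return data.frame of class `enrichment_table`: `term`, `size`, `es`,
#'   `p_raw`, `p_adj`, `leading_edge` (comma-joined genes)
#' @export
preranked_gsea <- function(ranking, gene_sets, weight = 1, n_perm = 1000L,
                           min_size = 5L, max_size = 500L, seed = 1L) {
  stopifnot(is.data.frame(ranking), all(c("gene", "score") %in% names(ranking)))
  scores <- ranking$score
  genes <- ranking$gene
  n <- length(genes)
  sizes <- vapply(gene_sets, function(g) length(intersect(g, genes)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    stop("no gene set within [", min_size, ", ", max_size,
         "] after intersecting the ranking")
  }
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]
  withr::with_seed(seed, {
    # the permutation null depends only on the set size, so one pool of
    # permuted enrichment scores is shared by all sets of the same size
    null_pools <- lapply(sort(unique(sizes)), function(m) {
      vapply(seq_len(n_perm), function(b) {
        gsea_running_sum(scores, sample.int(n, m), weight)$es
      }, numeric(1))
    })
    names(null_pools) <- as.character(sort(unique(sizes)))
    res <- lapply(seq_along(gene_sets), function(k) {
      hit_pos <- which(genes %in% gene_sets[[k]])
      obs <- gsea_running_sum(scores, hit_pos, weight)
      m <- length(hit_pos)
      null_es <- null_pools[[as.character(m)]]
      p_raw <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
      le <- if (obs$es >= 0) {
        genes[intersect(hit_pos, seq_len(obs$peak))]
      } else {
        genes[intersect(hit_pos, obs$peak:n)]
      }
      data.frame(term = names(gene_sets)[k], size = m, es = obs$es,
                 p_raw = p_raw,
                 leading_edge = paste(le, collapse = ","),
                 row.names = NULL, stringsAsFactors = FALSE)
    })
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab <- tab[, c("term", "size", "es", "p_raw", "p_adj", "leading_edge")]
  tab <- tab[order(tab$p_adj, -abs(tab$es)), ]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (term, description, genes...)
#' @return named list of gene vectors
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of gene vectors
#' @param path output file
#' @param descriptions optional term descriptions (second GMT column)
#' @return `path`, invisibly
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(gene_sets)
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a truth set of pathway terms by keyword matching
#'
#' A term belongs to the truth set iff any keyword is a case-insensitive
#' substring of its description. Duplicate keywords are harmless.
#'
#' @param keywords character vector of keywords (e.g. read from a plain-text
#'   file, one per line)
#' @param term_names named character vector mapping term id -> description
#' @return list of class `TruthSet`: `keywords`, `matched_terms`, `universe`
#' @export
build_truth_set <- function(keywords, term_names) {
  stopifnot(length(keywords) >= 1)
  keywords <- unique(keywords[nzchar(keywords)])
  if (is.null(names(term_names))) stop("term_names must be named by term id")
  desc <- tolower(term_names)
  matched <- vapply(desc, function(d) {
    any(vapply(tolower(keywords), grepl, logical(1), x = d, fixed = TRUE))
  }, logical(1))
  if (!any(matched)) warning("no term description matched any keyword")
  structure(list(keywords = keywords,
                 matched_terms = names(term_names)[matched],
                 universe = names(term_names)),
            class = "TruthSet")
}

#' Benchmark F1 of significant terms against a truth set
#'
#' True positives are significant terms inside the truth set, false positives
#' significant terms outside it, false negatives truth terms not found
#' significant.
#'
#' @param significant_terms character vector of term ids called significant
#' @param truth a [build_truth_set()] result
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#' @export
benchmark_f1 <- function(significant_terms, truth) {
  stopifnot(inherits(truth, "TruthSet"))
  if (!length(truth$matched_terms)) stop("truth set is empty")
  outside <- setdiff(significant_terms, truth$universe)
  if (length(outside)) {
    warning(length(outside), " significant term(s) outside the truth-set ",
            "universe are counted as false positives")
  }
  tp <- length(intersect(significant_terms, truth$matched_terms))
  fp <- length(setdiff(significant_terms, truth$matched_terms))
  fn <- length(setdiff(truth$matched_terms, significant_terms))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}

#' Construct benchmark gene-set collections from planted truth
#'
#' For an end-to-end benchmark on synthetic data: each marker-carrying label
#' contributes its marker genes split into `sets_per_label` "marker program"
#' sets, plus `n_random` decoy sets of non-marker genes. Term descriptions
#' embed the label so keyword matching (e.g. on the disease name) defines the
#' truth set.
#'
#' @param truth a `PlantedTruth` from [generate_dataset()]
#' @param gene_names all gene names of the dataset
#' @param sets_per_label how many sets each label's markers are split into
#'   (default 2)
#' @param n_random number of random decoy sets (default 40)
#' @param random_size_range decoy size bounds (default c(5, 30))
#' @param min_set_size smallest program emitted (default 5, matching the
#'   usual enrichment size filter — a program too small to be testable would
#'   be an unconditional false negative in the benchmark)
#' @param seed integer seed
#' @return list with `gene_sets` (named list) and `term_names` (id ->
#'   description)
#' @export
marker_gene_sets <- function(truth, gene_names, sets_per_label = 2L,
                             n_random = 40L, random_size_range = c(5L, 30L),
                             min_set_size = 5L, seed = 1L) {
  stopifnot(inherits(truth, "PlantedTruth"))
  withr::with_seed(seed, {
    gene_sets <- list()
    term_names <- character(0)
    for (lab in names(truth$markers)) {
      parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
      # direction-pure programs: a gene set mixing up- and down-regulated
      # members spreads its hits over both ends of a ranking and loses power
      for (dir in unique(truth$markers[[lab]]$direction)) {
        markers <- truth$markers[[lab]]$gene[
          truth$markers[[lab]]$direction == dir]
        n_chunks <- min(sets_per_label,
                        max(1L, length(markers) %/% min_set_size))
        chunks <- split(markers, rep(seq_len(n_chunks),
                                     length.out = length(markers)))
        chunks <- chunks[lengths(chunks) >= min_set_size]
        for (k in seq_along(chunks)) {
          id <- sprintf("SET:%s_%s_%s%d", parts[1], parts[2], dir, k)
          gene_sets[[id]] <- chunks[[k]]
          term_names[id] <- sprintf("%s %s %s-regulated program %d",
                                    parts[2], parts[1], dir, k)
        }
      }
    }
    non_markers <- setdiff(gene_names,
                           unlist(lapply(truth$markers, `[[`, "gene")))
    for (k in seq_len(n_random)) {
      size <- sample(random_size_range[1]:random_size_range[2], 1)
      id <- sprintf("SET:random%02d", k)
      gene_sets[[id]] <- sample(non_markers, min(size, length(non_markers)))
      term_names[id] <- sprintf("random background set %02d", k)
    }
    list(gene_sets = gene_sets, term_names = term_names)
  })
}
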