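#' Configuration for the synthetic single-cell generator
#'
#' The generator emulates droplet-style count data: negative-binomial counts
#' with log-normal gene- and cell-level size variation, Bernoulli dropout, and
#' class-specific marker genes planted on a species x cell-type x disease label
#' grid. The first disease level is treated as the unaffected reference and
#' receives no markers of its own.
#'
#' @param n_genes number of genes
#' @param cells_per_group cells per (species, cell type, disease) combination
#' @param species,cell_type,disease label levels (defaults: the 2 x 7 x 4 grid
#'   giving 13 classes)
#' @param markers_per_label marker genes planted per non-reference label
#' @param marker_effect natural-log fold shift applied to a marker's mean in
#'   cells carrying its label (up-markers multiply by `exp(marker_effect)`,
#'   down-markers by `exp(-marker_effect)`)
#' @param down_marker_frac fraction of each label's markers planted as
#'   down-regulated (default 0.25)
#' @param disease_marker_celltypes optional character vector: restrict disease
#'   markers to act only in these cell types (cell-type-specific disease
#'   signatures); `NULL` means disease markers act in all cell types
#' @param baseline_mean mean count of a non-marker gene
#' @param gene_sd,cell_sd standard deviations of the log-normal gene- and
#'   cell-level size factors
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2)
#' @param dropout_rate probability that any count is zeroed (technical dropout)
#' @param samples_per_condition biological samples per (species, disease)
#'   combination
#' @param n_mito_genes how many non-marker genes get an `MT-` name, to exercise
#'   mitochondrial handling
#' @param seed integer RNG seed
#' @return a validated `synthetic_config` list
#' @export
synthetic_config <- function(n_genes = 300, cells_per_group = 200,
                             species = c("human", "mouse"),
                             cell_type = c("CM", "EC", "FB", "IC", "NC", "PC", "SMC"),
                             disease = c("healthy", "AS", "HFrEF", "HFpEF"),
                             markers_per_label = 15, marker_effect = 1.5,
                             down_marker_frac = 0.25,
                             disease_marker_celltypes = NULL,
                             baseline_mean = 1, gene_sd = 0.3, cell_sd = 0.2,
                             dispersion = 0.3, dropout_rate = 0.1,
                             samples_per_condition = 2, n_mito_genes = 5,
                             seed = 1L) {
  cfg <- list(n_genes = n_genes, cells_per_group = cells_per_group,
              species = species, cell_type = cell_type, disease = disease,
              markers_per_label = markers_per_label,
              marker_effect = marker_effect,
              down_marker_frac = down_marker_frac,
              disease_marker_celltypes = disease_marker_celltypes,
              baseline_mean = baseline_mean, gene_sd = gene_sd,
              cell_sd = cell_sd, dispersion = dispersion,
              dropout_rate = dropout_rate,
              samples_per_condition = samples_per_condition,
              n_mito_genes = n_mito_genes, seed = as.integer(seed))
  n_labels <- length(species) + length(cell_type) + max(length(disease) - 1L, 0L)
  if (markers_per_label * n_labels + n_mito_genes > n_genes) {
    stop("markers_per_label x number of marker-carrying labels (",
         markers_per_label * n_labels, ") plus MT genes exceeds n_genes (",
         n_genes, ")")
  }
  stopifnot(n_genes > 0, cells_per_group > 0, baseline_mean > 0,
            dispersion > 0, marker_effect >= 0,
            dropout_rate >= 0, dropout_rate <= 1,
            length(species) >= 1, length(cell_type) >= 1, length(disease) >= 2)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic dataset with planted marker structure
#'
#' Counts are drawn per cell from a negative binomial whose mean is
#' `baseline_mean * gene_factor * cell_factor`, multiplied by
#' `exp(+/- marker_effect)` for the markers of the cell's own labels, then
#' zeroed with probability `dropout_rate`. Bit-identical for a fixed seed.
#'
#' @param config a [synthetic_config()]
#' @return list with `dataset` (raw-count [expression_dataset()] with full
#'   metadata) and `truth` (a `PlantedTruth`: per-label marker gene names and
#'   directions)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    gene_names <- sprintf("gene%04d", seq_len(cfg$n_genes))
    if (cfg$n_mito_genes > 0) {
      mito_idx <- seq_len(cfg$n_mito_genes)
      gene_names[mito_idx] <- sprintf("MT-G%02d", mito_idx)
    } else {
      mito_idx <- integer(0)
    }

    # disjoint marker assignment; the reference disease gets no markers
    labels <- c(paste0("species:", cfg$species),
                paste0("cell_type:", cfg$cell_type),
                paste0("disease:", cfg$disease[-1]))
    assignable <- setdiff(seq_len(cfg$n_genes), mito_idx)
    picks <- sample(assignable, cfg$markers_per_label * length(labels))
    truth <- list()
    n_down <- round(cfg$down_marker_frac * cfg$markers_per_label)
    for (i in seq_along(labels)) {
      idx <- picks[(i - 1L) * cfg$markers_per_label + seq_len(cfg$markers_per_label)]
      dir <- rep("up", cfg$markers_per_label)
      if (n_down > 0) dir[seq_len(n_down)] <- "down"
      truth[[labels[i]]] <- data.frame(gene = gene_names[idx],
                                       direction = dir,
                                       stringsAsFactors = FALSE)
    }

    grid <- expand.grid(species = cfg$species, cell_type = cfg$cell_type,
                        disease = cfg$disease, stringsAsFactors = FALSE)
    n_cells <- nrow(grid) * cfg$cells_per_group
    meta <- grid[rep(seq_len(nrow(grid)), each = cfg$cells_per_group), ]
    rownames(meta) <- NULL
    meta$sample <- paste0(meta$species, "-", meta$disease, "-s",
                          sample.int(cfg$samples_per_condition, n_cells,
                                     replace = TRUE))

    gene_factor <- exp(stats::rnorm(cfg$n_genes, 0, cfg$gene_sd))
    cell_factor <- exp(stats::rnorm(n_cells, 0, cfg$cell_sd))
    base_mu <- outer(cell_factor, cfg$baseline_mean * gene_factor)

    # per-label multiplicative marker shift
    log_shift <- matrix(0, n_cells, cfg$n_genes)
    for (lab in names(truth)) {
      parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
      in_group <- meta[[parts[1]]] == parts[2]
      if (parts[1] == "disease" && !is.null(cfg$disease_marker_celltypes)) {
        in_group <- in_group & meta$cell_type %in% cfg$disease_marker_celltypes
      }
      g_idx <- match(truth[[lab]]$gene, gene_names)
      sign <- ifelse(truth[[lab]]$direction == "up", 1, -1)
      log_shift[in_group, g_idx] <- log_shift[in_group, g_idx] +
        rep(cfg$marker_effect * sign, each = sum(in_group))
    }
    mu <- base_mu * exp(log_shift)

    size <- 1 / cfg$dispersion
    counts <- matrix(stats::rnbinom(length(mu), size = size, mu = mu),
                     n_cells, cfg$n_genes)
    if (cfg$dropout_rate > 0) {
      counts[stats::runif(length(counts)) < cfg$dropout_rate] <- 0L
    }
    storage.mode(counts) <- "double"
    dimnames(counts) <- list(sprintf("cell%05d", seq_len(n_cells)), gene_names)

    ds <- expression_dataset(counts, cell_meta = meta, normalized = FALSE)
    truth_obj <- structure(list(markers = truth, config = cfg),
                           class = "PlantedTruth")
    list(dataset = ds, truth = truth_obj)
  })
}

#' Marker genes differential for a contrast of two labels
#'
#' For a contrast (A, B) within one category, returns the genes planted as
#' markers of either label, with the direction expected for A relative to B
#' (B's up-markers appear as "down" for A). Contrasting a label with itself
#' yields an empty table. Labels are written `"category:level"` or, when
#' unambiguous, just `"level"`.
#'
#' @param truth a `PlantedTruth` from [generate_dataset()]
#' @param contrast character vector of two labels
#' @return data.frame with columns `gene`, `direction`
#' @export
truth_table <- function(truth, contrast) {
  stopifnot(inherits(truth, "PlantedTruth"), length(contrast) == 2)
  resolve <- function(lab) {
    if (lab %in% names(truth$markers)) return(lab)
    hits <- grep(paste0(":", lab, "$"), names(truth$markers), value = TRUE)
    if (length(hits) == 1) return(hits)
    # reference labels (e.g. the healthy disease level) carry no markers
    all_levels <- unlist(lapply(c("species", "cell_type", "disease"),
                                function(cat) paste0(cat, ":", truth$config[[cat]])))
    if (lab %in% all_levels ||
        lab %in% unlist(truth$config[c("species", "cell_type", "disease")])) {
      return(NA_character_)
    }
    stop("unknown label: ", lab)
  }
  a <- resolve(contrast[1]); b <- resolve(contrast[2])
  if (identical(a, b) || identical(contrast[1], contrast[2])) {
    return(data.frame(gene = character(0), direction = character(0)))
  }
  flip <- c(up = "down", down = "up")
  out <- list()
  if (!is.na(a)) out[[1]] <- truth$markers[[a]]
  if (!is.na(b)) {
    tb <- truth$markers[[b]]
    tb$direction <- unname(flip[tb$direction])
    out[[length(out) + 1]] <- tb
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), direction = character(0)))
  }
  do.call(rbind, out)
}

#' Write the planted truth as a TSV (gene, label, direction)
#'
#' @param truth a `PlantedTruth`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "PlantedTruth"))
  rows <- do.call(rbind, lapply(names(truth$markers), function(lab) {
    data.frame(gene = truth$markers[[lab]]$gene, label = lab,
               direction = truth$markers[[lab]]$direction,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
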