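#' Read and validate a pipeline configuration from YAML
#'
#' The YAML mirrors [study_config()] with two extra top-level fields:
#' `out_dir` (where stage artifacts and manifests go) and optional `paths`
#' (pre-existing inputs: `matrix_dir`, `gene_sets_gmt`, `keywords`). Missing
#' or invalid fields raise errors naming the field.
#'
#' @param path YAML file
#' @return a validated `pipeline_config` list
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- yaml::read_yaml(path)
  validate_pipeline_config(raw, dir = dirname(normalizePath(path)))
}

#' Construct a pipeline configuration in code
#'
#' @param out_dir output directory for stage artifacts
#' @param seed master seed
#' @param ... overrides passed to [study_config()]
#' @param paths optional named list of pre-existing input paths
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1L, ..., paths = NULL) {
  cfg <- study_config(seed = seed, ...)
  cfg$out_dir <- out_dir
  cfg$paths <- paths
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(raw, dir = ".") {
  if (is.null(raw$out_dir)) stop("config field 'out_dir' is required")
  seed <- raw$seed
  if (is.null(seed)) stop("config field 'seed' is required")
  build_args <- list(seed = seed)
  for (f in c("n_genes", "cells_per_group", "marker_effect",
              "markers_per_label", "dropout_rate", "n_permutations",
              "background_n", "gsea_n_perm", "alpha")) {
    if (!is.null(raw[[f]])) build_args[[f]] <- raw[[f]]
  }
  cfg <- do.call(study_config, build_args)
  # allow nested overrides of the structured sections
  for (section in c("synthetic", "qc", "split", "dae", "mlp", "attribution",
                    "contrast", "enrichment")) {
    if (!is.null(raw[[section]])) {
      for (k in names(raw[[section]])) cfg[[section]][[k]] <- raw[[section]][[k]]
    }
  }
  for (f in c("holdout_sample", "fit_subsample")) {
    if (!is.null(raw[[f]])) cfg[[f]] <- raw[[f]]
  }
  cfg$out_dir <- raw$out_dir
  cfg$paths <- raw$paths
  if (!is.null(cfg$paths)) {
    for (k in names(cfg$paths)) {
      p <- cfg$paths[[k]]
      if (!file.exists(p) && !file.exists(file.path(dir, p))) {
        stop("config field 'paths.", k, "' points to a missing path: ", p)
      }
      if (!file.exists(p)) cfg$paths[[k]] <- file.path(dir, p)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stages <- c("simulate", "preprocess", "train", "evaluate", "explain",
                     "dxg", "enrich", "benchmark")

stage_manifest_path <- function(out_dir, stage) {
  file.path(out_dir, paste0("manifest_", stage, ".json"))
}

write_stage_manifest <- function(out_dir, stage, params, outputs,
                                 started, seed) {
  params <- lapply(params, function(x) if (is.list(x)) unclass(x) else x)
  hashes <- vapply(outputs, function(f) {
    if (file.exists(f) && !dir.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(stage = stage, seed = seed, params = params,
                   outputs = as.list(stats::setNames(hashes, outputs)),
                   elapsed_sec = round(as.numeric(Sys.time()) - started, 2),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, stage_manifest_path(out_dir, stage),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the DXG pipeline stage by stage with on-disk artifacts
#'
#' Disk-backed orchestration of [run_dxg_study()]'s steps: every stage reads
#' its inputs from `config$out_dir` (or `config$paths`), writes plain-text
#' artifacts plus a JSON manifest (parameters, seeds, output checksums,
#' timing), and completed stages are skipped on re-runs unless `force`.
#' Identical configs and seeds reproduce byte-identical tables.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()])
#' @param stages subset of
#'   `c("simulate", "preprocess", "train", "evaluate", "explain", "dxg",
#'   "enrich", "benchmark")`, run in canonical order
#' @param force re-run stages whose manifest already exists
#' @param verbose log stage progress
#' @return named list of the manifests of the stages that ran (invisibly)
#' @export
run_pipeline <- function(config, stages = pipeline_stages, force = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say <- function(...) if (verbose) {
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
  }
  env <- new.env(parent = emptyenv())  # lazily loaded inter-stage state
  manifests <- list()

  need <- function(stage) {
    if (force) return(TRUE)
    !file.exists(stage_manifest_path(out, stage))
  }
  get_norm <- function() {
    if (is.null(env$norm)) {
      env$norm <- load_expression_dir(file.path(out, "normalized"))
    }
    env$norm
  }
  get_split <- function() {
    if (is.null(env$split)) {
      env$split <- jsonlite::read_json(file.path(out, "split.json"),
                                       simplifyVector = TRUE)
    }
    env$split
  }
  get_truth <- function() {
    if (is.null(env$truth)) {
      tab <- utils::read.table(file.path(out, "truth.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
      markers <- lapply(split(tab, tab$label), function(d) {
        data.frame(gene = d$gene, direction = d$direction,
                   stringsAsFactors = FALSE)
      })
      env$truth <- structure(list(markers = markers,
                                  config = config$synthetic),
                             class = "PlantedTruth")
    }
    env$truth
  }
  get_models <- function() {
    if (is.null(env$dae)) env$dae <- load_model(file.path(out, "dae.rds"))
    if (is.null(env$mlp)) env$mlp <- load_model(file.path(out, "mlp.rds"))
    list(dae = env$dae, mlp = env$mlp)
  }
  contrast_groups <- function() {
    ct <- config$contrast
    group_spec(
      A = list(species = ct$species, cell_type = ct$cell_type,
               disease = ct$disease),
      B = list(species = ct$species, cell_type = ct$cell_type,
               disease = ct$reference),
      class_node = paste0("disease:", ct$disease)
    )
  }

  for (stage in stages) {
    if (!need(stage)) {
      say("stage %-10s already complete, skipping (use force = TRUE to redo)",
          stage)
      next
    }
    started <- as.numeric(Sys.time())
    say("stage %-10s starting", stage)
    outputs <- switch(stage,
      simulate = {
        gen <- generate_dataset(config$synthetic)
        write_expression_mtx(gen$dataset, file.path(out, "raw"))
        write_truth_tsv(gen$truth, file.path(out, "truth.tsv"))
        env$raw <- gen$dataset
        env$truth <- gen$truth
        c(file.path(out, "raw", "matrix.mtx"), file.path(out, "truth.tsv"))
      },
      preprocess = {
        raw <- if (!is.null(env$raw)) {
          env$raw
        } else if (!is.null(config$paths$matrix_dir)) {
          load_expression_dir(config$paths$matrix_dir)
        } else {
          load_expression_dir(file.path(out, "raw"))
        }
        filtered <- qc_filter(raw, min_genes = config$qc$min_genes,
                              max_genes = config$qc$max_genes,
                              max_mt_pct = config$qc$max_mt_pct,
                              verbose = verbose)
        norm <- lognormalize(filtered)
        write_expression_mtx(norm, file.path(out, "normalized"))
        qc_log <- attr(filtered, "qc_log")
        utils::write.table(data.frame(criterion = names(qc_log),
                                      cells = as.integer(qc_log)),
                           file.path(out, "qc_report.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        # one biological sample per condition is the held-out test set;
        # the 80/20 split applies to the remaining pool
        test_idx <- which(endsWith(norm$cell_meta$sample,
                                   paste0("-s", config$holdout_sample)))
        pool_idx <- setdiff(seq_len(nrow(norm$values)), test_idx)
        pool_split <- stratified_split(subset_cells(norm, pool_idx),
                                       train_frac = config$split$train_frac,
                                       stratify_by = config$split$stratify_by,
                                       seed = stage_seed(seed, 1L))
        split <- list(train_indices = pool_idx[pool_split$train_indices],
                      val_indices = pool_idx[pool_split$val_indices],
                      test_indices = test_idx, seed = pool_split$seed)
        jsonlite::write_json(split, file.path(out, "split.json"),
                             auto_unbox = TRUE, digits = NA)
        env$norm <- norm
        env$split <- split
        c(file.path(out, "normalized", "matrix.mtx"),
          file.path(out, "qc_report.tsv"), file.path(out, "split.json"))
      },
      train = {
        norm <- get_norm()
        split <- get_split()
        train <- subset_cells(norm, split$train_indices)
        val <- subset_cells(norm, split$val_indices)
        fit_frac <- if (is.null(config$fit_subsample)) 1 else config$fit_subsample
        if (fit_frac < 1) {
          sub <- stratified_split(train, train_frac = fit_frac,
                                  stratify_by = config$split$stratify_by,
                                  seed = stage_seed(seed, 10L))
          train <- subset_cells(train, sub$train_indices)
        }
        schema <- label_schema(species = config$synthetic$species,
                               cell_type = config$synthetic$cell_type,
                               disease = config$synthetic$disease)
        dspec <- dae_spec(ncol(norm$values),
                          encoder_sizes = config$dae$encoder_sizes,
                          decoder_sizes = config$dae$decoder_sizes,
                          batch_size = config$dae$batch_size,
                          max_epochs = config$dae$max_epochs)
        dae <- train_dae(dspec, train, val, seed = stage_seed(seed, 2L))
        mspec <- mlp_spec(ncol(norm$values),
                          hidden_sizes = config$mlp$hidden_sizes,
                          n_classes = sum(lengths(schema)),
                          batch_size = config$mlp$batch_size,
                          max_epochs = config$mlp$max_epochs)
        mlp <- train_mlp(mspec, reconstruct(dae, train),
                         encode_labels(train$cell_meta, schema),
                         reconstruct(dae, val),
                         encode_labels(val$cell_meta, schema),
                         seed = stage_seed(seed, 3L))
        save_model(dae, file.path(out, "dae.rds"))
        save_model(mlp, file.path(out, "mlp.rds"))
        env$dae <- dae
        env$mlp <- mlp
        c(file.path(out, "dae.rds.json"), file.path(out, "mlp.rds.json"))
      },
      evaluate = {
        norm <- get_norm()
        split <- get_split()
        models <- get_models()
        val <- subset_cells(norm, split$val_indices)
        schema <- label_schema(species = config$synthetic$species,
                               cell_type = config$synthetic$cell_type,
                               disease = config$synthetic$disease)
        val_labels <- encode_labels(val$cell_meta, schema)
        pred <- predict(models$mlp, reconstruct(models$dae, val))
        metrics <- per_class_metrics(pred$binary, val_labels)
        confusions <- confusion_by_category(pred$probabilities, val_labels)
        write_evaluation(metrics, confusions, file.path(out, "evaluation"))
        rates <- correct_classification_rate(confusions)
        jsonlite::write_json(
          list(val_macro_f1 = macro_f1_score(pred$binary, val_labels),
               rates = as.list(rates)),
          file.path(out, "evaluation", "summary.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        c(file.path(out, "evaluation", "per_class_metrics.tsv"),
          file.path(out, "evaluation", "summary.json"))
      },
      explain = {
        norm <- get_norm()
        split <- get_split()
        models <- get_models()
        groups <- contrast_groups()
        train <- subset_cells(norm, split$train_indices)
        background <- select_background(train,
                                        n = config$attribution$background_n,
                                        seed = stage_seed(seed, 4L))
        test <- subset_cells(norm, split$test_indices)
        idx <- which(match_group(test$cell_meta, groups$A) |
                       match_group(test$cell_meta, groups$B))
        if (!length(idx)) stop("contrast filters match no held-out cells")
        env$explained_global <- split$test_indices[idx]
        att <- shapley_sampled(
          class_model(models$mlp, groups$class_node, dae = models$dae),
          subset_cells(test, idx), background,
          n_permutations = config$attribution$n_permutations,
          antithetic = config$attribution$antithetic,
          seed = stage_seed(seed, 5L), class_name = groups$class_node)
        att <- exclude_mito(att)
        write_attribution(att, file.path(out, "attribution"))
        env$att <- att
        file.path(out, "attribution", "manifest.json")
      },
      dxg = {
        if (is.null(env$att)) {
          env$att <- read_attribution(file.path(out, "attribution"))[[1]]
        }
        norm <- get_norm()
        split <- get_split()
        groups <- contrast_groups()
        dxg <- dxg_test(env$att, groups, method = "t",
                        standardization = "gene")
        # expression comparator on the same held-out cells
        test <- subset_cells(norm, split$test_indices)
        idx <- which(match_group(test$cell_meta, groups$A) |
                       match_group(test$cell_meta, groups$B))
        explained <- subset_cells(test, idx)
        deg <- deg_wilcoxon(explained, groups)
        deg_unf <- deg_wilcoxon(explained, groups, min_pct = 0,
                                min_abs_logfc = 0)
        utils::write.table(dxg, file.path(out, "dxg_table.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(deg, file.path(out, "deg_table.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(deg_unf, file.path(out, "deg_unfiltered.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ov <- compare_gene_sets(dxg, deg, alpha = config$alpha)
        jsonlite::write_json(ov[c("n_common", "n_dxg_only", "n_deg_only")],
                             file.path(out, "overlap.json"),
                             auto_unbox = TRUE, digits = NA)
        env$dxg <- dxg
        env$deg_unf <- deg_unf
        c(file.path(out, "dxg_table.tsv"), file.path(out, "deg_table.tsv"),
          file.path(out, "deg_unfiltered.tsv"), file.path(out, "overlap.json"))
      },
      enrich = {
        if (is.null(env$dxg)) {
          env$dxg <- utils::read.table(file.path(out, "dxg_table.tsv"),
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
          env$deg_unf <- utils::read.table(file.path(out, "deg_unfiltered.tsv"),
                                           header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE)
        }
        norm <- get_norm()
        en <- config$enrichment
        if (!is.null(config$paths$gene_sets_gmt)) {
          gene_sets <- read_gmt(config$paths$gene_sets_gmt)
          term_names <- stats::setNames(names(gene_sets), names(gene_sets))
        } else {
          sets <- marker_gene_sets(get_truth(), norm$gene_names,
                                   sets_per_label = en$sets_per_label,
                                   n_random = en$n_random,
                                   random_size_range = en$random_size_range,
                                   min_set_size = en$min_size,
                                   seed = stage_seed(seed, 7L))
          gene_sets <- sets$gene_sets
          term_names <- sets$term_names
          write_gmt(gene_sets, file.path(out, "gene_sets.gmt"),
                    descriptions = term_names)
        }
        env$term_names <- term_names
        for (which_tab in c("dxg", "deg")) {
          tab <- if (which_tab == "dxg") env$dxg else env$deg_unf
          gs <- preranked_gsea(rank_genes(tab), gene_sets,
                               weight = en$weight, n_perm = en$n_perm,
                               min_size = en$min_size, max_size = en$max_size,
                               seed = stage_seed(seed, if (which_tab == "dxg") 8L else 9L))
          utils::write.table(gs,
                             file.path(out, paste0("gsea_", which_tab, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          env[[paste0("gsea_", which_tab)]] <- gs
        }
        c(file.path(out, "gsea_dxg.tsv"), file.path(out, "gsea_deg.tsv"))
      },
      benchmark = {
        if (is.null(env$gsea_dxg)) {
          env$gsea_dxg <- utils::read.table(file.path(out, "gsea_dxg.tsv"),
                                            header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE)
          env$gsea_deg <- utils::read.table(file.path(out, "gsea_deg.tsv"),
                                            header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE)
        }
        keywords <- if (!is.null(config$paths$keywords)) {
          readLines(config$paths$keywords)
        } else {
          tolower(config$contrast$disease)
        }
        if (is.null(env$term_names)) {
          norm <- get_norm()
          en <- config$enrichment
          sets <- marker_gene_sets(get_truth(), norm$gene_names,
                                   sets_per_label = en$sets_per_label,
                                   n_random = en$n_random,
                                   random_size_range = en$random_size_range,
                                   min_set_size = en$min_size,
                                   seed = stage_seed(seed, 7L))
          env$term_names <- sets$term_names
        }
        truth_set <- build_truth_set(keywords, env$term_names)
        res <- list(
          dxg = benchmark_f1(
            env$gsea_dxg$term[env$gsea_dxg$p_adj < config$alpha], truth_set),
          deg = benchmark_f1(
            env$gsea_deg$term[env$gsea_deg$p_adj < config$alpha], truth_set)
        )
        jsonlite::write_json(res, file.path(out, "benchmark.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        file.path(out, "benchmark.json")
      }
    )
    write_stage_manifest(out, stage, params = config[
      intersect(c("synthetic", "qc", "split", "dae", "mlp", "attribution",
                  "contrast", "enrichment", "alpha"), names(config))],
      outputs = outputs, started = started, seed = seed)
    manifests[[stage]] <- stage_manifest_path(out, stage)
    say("stage %-10s done (%.1fs)", stage, as.numeric(Sys.time()) - started)
  }
  invisible(manifests)
}
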