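#' Default configuration of the scaled-down synthetic study
#'
#' One seeded end-to-end experiment: generate a 13-class synthetic dataset
#' (full 2 species x 7 cell types x 4 diseases grid), preprocess, train the
#' autoencoder and classifier, attribute one disease node, and test a disease
#' contrast within one cell type against the planted truth. Network and
#' estimator sizes are scaled to a 300-gene panel; the vignette discusses the
#' choices.
#'
#' @param seed master integer seed; per-stage seeds are derived from it
#' @param n_genes,cells_per_group,marker_effect,markers_per_label,dropout_rate
#'   generator conditions (see [synthetic_config()])
#' @param contrast_disease,contrast_reference,contrast_celltype,contrast_species
#'   the tested contrast: disease vs reference within one cell type and
#'   species
#' @param n_permutations Shapley permutations per explained cell
#' @param background_n background distribution size
#' @param gsea_n_perm permutations for the enrichment null
#' @param alpha significance level for DXG/DEG/enrichment calls
#' @return a nested configuration list
#' @export
study_config <- function(seed = 1L, n_genes = 300L, cells_per_group = 200L,
                         marker_effect = 1.5, markers_per_label = 15L,
                         dropout_rate = 0.1,
                         contrast_disease = "HFpEF",
                         contrast_reference = "healthy",
                         contrast_celltype = "CM",
                         contrast_species = "human",
                         n_permutations = 6L, background_n = 1000L,
                         gsea_n_perm = 2000L, alpha = 0.05) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    synthetic = synthetic_config(
      n_genes = n_genes, cells_per_group = cells_per_group,
      markers_per_label = markers_per_label, marker_effect = marker_effect,
      dropout_rate = dropout_rate, seed = seed
    ),
    qc = list(min_genes = 50L, max_genes = n_genes, max_mt_pct = 25),
    split = list(train_frac = 0.8,
                 stratify_by = c("species", "cell_type", "disease")),
    # one complete biological sample per condition is held out as the test
    # set; attribution is computed on those cells only, with the background
    # drawn from the training data. The remaining sample(s) are split 80/20
    # into training and validation.
    holdout_sample = 2L,
    fit_subsample = 1,
    dae = list(encoder_sizes = c(128L, 64L), decoder_sizes = 128L,
               batch_size = 128L, max_epochs = 150L),
    mlp = list(hidden_sizes = c(64L, 32L), batch_size = 128L,
               max_epochs = 150L),
    attribution = list(n_permutations = n_permutations,
                       background_n = background_n, antithetic = TRUE),
    contrast = list(disease = contrast_disease,
                    reference = contrast_reference,
                    cell_type = contrast_celltype,
                    species = contrast_species),
    enrichment = list(sets_per_label = 2L, n_random = 40L,
                      random_size_range = c(5L, 30L), weight = 1,
                      n_perm = gsea_n_perm, min_size = 5L, max_size = 500L),
    alpha = alpha
  )
}

# derive stage seeds from the master seed, keeping them in 32-bit range
stage_seed <- function(seed, offset) (as.integer(seed) * 97L + offset) %% 2000000000L

#' Run the full synthetic DXG study
#'
#' Executes the complete method on one seeded synthetic dataset: simulate,
#' QC + log-normalize, hold out one biological sample per condition as the
#' test set, split the rest 80/20 stratified, train the denoising
#' autoencoder and the macro-F1 classifier on reconstructed expression,
#' evaluate on the validation cells, compute permutation-sampling Shapley
#' attributions of the contrast disease node for the held-out cells of the
#' contrast groups, run the DXG test (per-gene standardization, Welch t)
#' and the Wilcoxon DEG comparator on those same cells, rank both tables,
#' run preranked enrichment against marker-program + decoy gene sets, and
#' benchmark both rankings against the keyword-derived truth set.
#'
#' @param config a [study_config()]
#' @param verbose log stage progress
#' @return list with the fitted models, tables, per-stage metrics and the
#'   planted truth (see the README walkthrough)
#' @export
run_dxg_study <- function(config = study_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  say("simulating synthetic dataset (seed %d)", seed)
  gen <- generate_dataset(config$synthetic)
  ds <- gen$dataset
  truth <- gen$truth

  ds <- qc_filter(ds, min_genes = config$qc$min_genes,
                  max_genes = config$qc$max_genes,
                  max_mt_pct = config$qc$max_mt_pct, verbose = verbose)
  norm <- lognormalize(ds)

  # sample-level holdout: the designated biological sample per condition is
  # the test set and takes no part in training or validation
  test_mask <- endsWith(norm$cell_meta$sample,
                        paste0("-s", config$holdout_sample))
  pool <- subset_cells(norm, which(!test_mask))
  test <- subset_cells(norm, which(test_mask))
  split <- stratified_split(pool, train_frac = config$split$train_frac,
                            stratify_by = config$split$stratify_by,
                            seed = stage_seed(seed, 1L))
  train <- subset_cells(pool, split$train_indices)
  val <- subset_cells(pool, split$val_indices)
  fit_frac <- if (is.null(config$fit_subsample)) 1 else config$fit_subsample
  fit_train <- if (fit_frac < 1) {
    sub <- stratified_split(train, train_frac = fit_frac,
                            stratify_by = config$split$stratify_by,
                            seed = stage_seed(seed, 10L))
    subset_cells(train, sub$train_indices)
  } else {
    train
  }
  schema <- label_schema(species = config$synthetic$species,
                         cell_type = config$synthetic$cell_type,
                         disease = config$synthetic$disease)
  fit_labels <- encode_labels(fit_train$cell_meta, schema)
  val_labels <- encode_labels(val$cell_meta, schema)

  say("training autoencoder (%d of %d train cells)",
      nrow(fit_train$values), nrow(train$values))
  dspec <- dae_spec(ncol(norm$values),
                    encoder_sizes = config$dae$encoder_sizes,
                    decoder_sizes = config$dae$decoder_sizes,
                    batch_size = config$dae$batch_size,
                    max_epochs = config$dae$max_epochs)
  dae <- train_dae(dspec, fit_train, val, seed = stage_seed(seed, 2L))
  recon_fit <- reconstruct(dae, fit_train)
  recon_val <- reconstruct(dae, val)

  say("training classifier")
  mspec <- mlp_spec(ncol(norm$values),
                    hidden_sizes = config$mlp$hidden_sizes,
                    n_classes = ncol(fit_labels$onehot),
                    batch_size = config$mlp$batch_size,
                    max_epochs = config$mlp$max_epochs)
  mlp <- train_mlp(mspec, recon_fit, fit_labels, recon_val, val_labels,
                   seed = stage_seed(seed, 3L))

  pred <- predict(mlp, recon_val)
  metrics <- per_class_metrics(pred$binary, val_labels)
  confusions <- confusion_by_category(pred$probabilities, val_labels)
  rates <- correct_classification_rate(confusions)
  val_macro_f1 <- macro_f1_score(pred$binary, val_labels)
  say("validation macro F1 = %.4f", val_macro_f1)

  # the explained model is the DAE-MLP composite on raw normalized
  # expression, so background and explained cells live in measured-gene space
  background <- select_background(train,
                                  n = config$attribution$background_n,
                                  seed = stage_seed(seed, 4L))
  ct <- config$contrast
  node <- paste0("disease:", ct$disease)
  groups <- group_spec(
    A = list(species = ct$species, cell_type = ct$cell_type,
             disease = ct$disease),
    B = list(species = ct$species, cell_type = ct$cell_type,
             disease = ct$reference),
    class_node = node
  )
  # attribution scores are computed for the held-out test sample only
  explain_idx <- which(match_group(test$cell_meta, groups$A) |
                         match_group(test$cell_meta, groups$B))
  explained <- subset_cells(test, explain_idx)
  say("attributing %d held-out cells for node %s", nrow(explained$values),
      node)
  att <- shapley_sampled(class_model(mlp, node, dae = dae),
                         explained, background,
                         n_permutations = config$attribution$n_permutations,
                         antithetic = config$attribution$antithetic,
                         seed = stage_seed(seed, 5L), class_name = node)
  att <- exclude_mito(att)

  # the attribution-score normality screen is reported; the test itself is
  # the t-test (rank tests also react to group differences in score
  # dispersion, which is not the question being asked)
  normality <- normality_check(att$scores, seed = stage_seed(seed, 6L))
  dxg <- dxg_test(att, groups, method = "t", standardization = "gene")
  # the expression comparator runs on the same held-out cells so both
  # methods see identical group sizes
  deg <- deg_wilcoxon(explained, groups)
  deg_unfiltered <- deg_wilcoxon(explained, groups, min_pct = 0,
                                 min_abs_logfc = 0)
  overlap <- compare_gene_sets(dxg, deg, alpha = config$alpha)

  planted <- truth_table(truth, c(ct$disease, ct$reference))
  sig_dxg <- dxg$gene[dxg$p_adj < config$alpha]
  recovery <- list(
    n_planted = nrow(planted),
    n_sig = length(sig_dxg),
    recall = if (nrow(planted)) mean(planted$gene %in% sig_dxg) else NA_real_,
    precision = if (length(sig_dxg)) mean(sig_dxg %in% planted$gene) else NA_real_
  )
  say("DXG recovery: recall %.2f precision %.2f",
      recovery$recall, recovery$precision)

  en <- config$enrichment
  sets <- marker_gene_sets(truth, norm$gene_names,
                           sets_per_label = en$sets_per_label,
                           n_random = en$n_random,
                           random_size_range = en$random_size_range,
                           min_set_size = en$min_size,
                           seed = stage_seed(seed, 7L))
  truth_set <- build_truth_set(tolower(ct$disease), sets$term_names)
  gsea_dxg <- preranked_gsea(rank_genes(dxg), sets$gene_sets,
                             weight = en$weight, n_perm = en$n_perm,
                             min_size = en$min_size, max_size = en$max_size,
                             seed = stage_seed(seed, 8L))
  gsea_deg <- preranked_gsea(rank_genes(deg_unfiltered), sets$gene_sets,
                             weight = en$weight, n_perm = en$n_perm,
                             min_size = en$min_size, max_size = en$max_size,
                             seed = stage_seed(seed, 9L))
  bench_dxg <- benchmark_f1(gsea_dxg$term[gsea_dxg$p_adj < config$alpha],
                            truth_set)
  bench_deg <- benchmark_f1(gsea_deg$term[gsea_deg$p_adj < config$alpha],
                            truth_set)
  say("benchmark F1: DXG %.3f vs DEG %.3f", bench_dxg$f1, bench_deg$f1)

  list(config = config, dataset = norm, truth = truth, split = split,
       dae = dae, classifier = mlp, normality = normality,
       evaluation = list(metrics = metrics, confusions = confusions,
                         rates = rates, val_macro_f1 = val_macro_f1),
       attribution = att, groups = groups,
       dxg = dxg, deg = deg, deg_unfiltered = deg_unfiltered,
       overlap = overlap, recovery = recovery,
       gene_sets = sets, truth_set = truth_set,
       gsea = list(dxg = gsea_dxg, deg = gsea_deg),
       benchmark = list(dxg = bench_dxg, deg = bench_deg))
}
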