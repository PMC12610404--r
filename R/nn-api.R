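#' Denoising autoencoder specification
#'
#' Defaults are the tuned production sizes (encoder 5000/2400/350, decoder
#' 2200/5150); for small gene panels pass proportionally smaller layers. The
#' last encoder size is the latent dimension; the decoder's final (output)
#' layer of width `input_dim` is appended automatically and is linear, the
#' standard pairing with the mean-squared-error objective.
#'
#' @param input_dim number of genes
#' @param encoder_sizes widths of the encoding layers
#' @param decoder_sizes widths of the decoding layers (excluding the output
#'   layer)
#' @param batch_size minibatch size (default 10240)
#' @param initial_lr Adam starting learning rate (default 0.001)
#' @param max_epochs epoch cap (default 500)
#' @param weight_decay decoupled (AdamW-style) weight decay; default 0
#' @return a `dae_spec` list
#' @export
dae_spec <- function(input_dim, encoder_sizes = c(5000, 2400, 350),
                     decoder_sizes = c(2200, 5150), batch_size = 10240L,
                     initial_lr = 1e-3, max_epochs = 500L,
                     weight_decay = 0) {
  stopifnot(input_dim >= 1, length(encoder_sizes) >= 1, all(encoder_sizes >= 1),
            all(decoder_sizes >= 1))
  structure(list(input_dim = input_dim, encoder_sizes = encoder_sizes,
                 decoder_sizes = decoder_sizes, batch_size = batch_size,
                 initial_lr = initial_lr, max_epochs = max_epochs,
                 weight_decay = weight_decay),
            class = "dae_spec")
}

#' Multi-label MLP classifier specification
#'
#' Hidden ReLU layers (tuned production sizes 795/230/105) followed by a
#' sigmoid output layer with one node per class; a cell's predicted labels are
#' the nodes whose probability exceeds `threshold` (strictly).
#'
#' @param input_dim number of input features (genes)
#' @param hidden_sizes hidden layer widths
#' @param n_classes number of output nodes (default 13: 2 species + 7 cell
#'   types + 4 disease states)
#' @param threshold binarization threshold in (0, 1), default 0.5
#' @param batch_size,initial_lr,max_epochs training parameters as in
#'   [dae_spec()]
#' @param weight_decay decoupled weight decay, default 1e-4
#' @param warmup_epochs epochs of binary cross-entropy warm-up before the
#'   macro F1 objective takes over (default 10). The soft-count F1 loss has
#'   vanishing gradients at saturated sigmoids, so a node pushed to an exact
#'   0/1 output early in training can never recover; the cross-entropy
#'   gradient does not vanish there and steers the network into a healthy
#'   region first
#' @return an `mlp_spec` list
#' @export
mlp_spec <- function(input_dim, hidden_sizes = c(795, 230, 105),
                     n_classes = 13L, threshold = 0.5, batch_size = 10240L,
                     initial_lr = 1e-3, max_epochs = 500L,
                     weight_decay = 1e-4, warmup_epochs = 10L) {
  stopifnot(input_dim >= 1, all(hidden_sizes >= 1), n_classes >= 1,
            threshold > 0, threshold < 1)
  structure(list(input_dim = input_dim, hidden_sizes = hidden_sizes,
                 n_classes = n_classes, threshold = threshold,
                 batch_size = batch_size, initial_lr = initial_lr,
                 max_epochs = max_epochs, weight_decay = weight_decay,
                 warmup_epochs = warmup_epochs),
            class = "mlp_spec")
}

dataset_matrix <- function(x) {
  if (inherits(x, "ExpressionDataset")) x$values else x
}

#' Train the denoising autoencoder
#'
#' Minimizes the L2 reconstruction loss on the training cells while monitoring
#' the validation loss. The learning rate starts at `spec$initial_lr` and is
#' multiplied by 0.1 after 25 epochs without validation improvement (floored at
#' 1e-7); training stops after `spec$max_epochs` epochs or 50 epochs without
#' improvement, and the best-validation weights are kept.
#'
#' @param spec a [dae_spec()]
#' @param train,val normalized `ExpressionDataset`s (or plain matrices)
#' @param seed integer seed controlling initialization and batch order
#' @param verbose log per-epoch losses
#' @return a `dxg_dae` model with `net`, `history`, `latent_dim`
#' @export
train_dae <- function(spec, train, val, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "dae_spec"))
  X <- dataset_matrix(train)
  V <- dataset_matrix(val)
  if (ncol(X) != spec$input_dim) {
    stop("spec input_dim (", spec$input_dim, ") != gene count (", ncol(X), ")")
  }
  sizes <- c(spec$encoder_sizes, spec$decoder_sizes, spec$input_dim)
  fit <- train_network(spec$input_dim, sizes, "linear", "mse",
                       X, X, V, V,
                       batch_size = spec$batch_size,
                       initial_lr = spec$initial_lr,
                       max_epochs = spec$max_epochs,
                       weight_decay = spec$weight_decay,
                       seed = seed, verbose = verbose)
  structure(list(net = fit$net, spec = spec, history = fit$history,
                 best_val_loss = fit$best_val_loss,
                 latent_dim = spec$encoder_sizes[length(spec$encoder_sizes)]),
            class = "dxg_dae")
}

#' Reconstruct (denoise) expression through a trained autoencoder
#'
#' @param dae a trained `dxg_dae`
#' @param ds normalized `ExpressionDataset` or matrix with matching gene
#'   dimension
#' @return object of the same kind with reconstructed values; metadata passes
#'   through untouched
#' @export
reconstruct <- function(dae, ds) {
  stopifnot(inherits(dae, "dxg_dae"))
  X <- dataset_matrix(ds)
  if (ncol(X) != dae$spec$input_dim) {
    stop("gene dimension (", ncol(X), ") != autoencoder input_dim (",
         dae$spec$input_dim, ")")
  }
  R <- nn_forward(dae$net, X)
  dimnames(R) <- dimnames(X)
  if (inherits(ds, "ExpressionDataset")) {
    expression_dataset(R, ds$gene_names, ds$cell_ids, ds$cell_meta,
                       normalized = TRUE)
  } else {
    R
  }
}

#' Train the multi-label MLP classifier
#'
#' Minimizes the differentiable [macro_f1_loss()] with the same Adam strategy,
#' learning-rate plateau schedule and early stopping as [train_dae()].
#'
#' @param spec an [mlp_spec()]
#' @param train,val normalized (typically DAE-reconstructed)
#'   `ExpressionDataset`s or matrices
#' @param train_labels,val_labels `LabelMatrix` objects (or binary matrices)
#'   aligned with the cells
#' @param seed integer seed
#' @param verbose log per-epoch losses
#' @return a `dxg_classifier` with `net`, `history`, `threshold`,
#'   `class_names`
#' @export
train_mlp <- function(spec, train, train_labels, val, val_labels, seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(spec, "mlp_spec"))
  X <- dataset_matrix(train)
  V <- dataset_matrix(val)
  class_names <- NULL
  if (inherits(train_labels, "LabelMatrix")) {
    class_names <- train_labels$class_names
    blocks <- train_labels$blocks
    schema <- train_labels$schema
    train_labels <- train_labels$onehot
  } else {
    blocks <- NULL
    schema <- NULL
  }
  if (inherits(val_labels, "LabelMatrix")) val_labels <- val_labels$onehot
  if (ncol(train_labels) != spec$n_classes) {
    stop("label width (", ncol(train_labels), ") != spec n_classes (",
         spec$n_classes, ")")
  }
  init_net <- NULL
  warmup <- if (is.null(spec$warmup_epochs)) 0L else spec$warmup_epochs
  if (warmup > 0L) {
    warm <- train_network(spec$input_dim, c(spec$hidden_sizes, spec$n_classes),
                          "sigmoid", "bce",
                          X, train_labels, V, val_labels,
                          batch_size = spec$batch_size,
                          initial_lr = spec$initial_lr,
                          max_epochs = warmup,
                          patience_lr = warmup + 1L,
                          patience_stop = warmup + 1L,
                          weight_decay = spec$weight_decay,
                          seed = seed, verbose = verbose)
    init_net <- warm$net
  }
  fit <- train_network(spec$input_dim, c(spec$hidden_sizes, spec$n_classes),
                       "sigmoid", "macro_f1",
                       X, train_labels, V, val_labels,
                       batch_size = spec$batch_size,
                       initial_lr = spec$initial_lr,
                       max_epochs = spec$max_epochs,
                       weight_decay = spec$weight_decay,
                       seed = seed, verbose = verbose,
                       init_net = init_net)
  structure(list(net = fit$net, spec = spec, history = fit$history,
                 best_val_loss = fit$best_val_loss,
                 threshold = spec$threshold, class_names = class_names,
                 blocks = blocks, schema = schema),
            class = "dxg_classifier")
}

#' Predict class probabilities and thresholded labels
#'
#' @param object a trained `dxg_classifier`
#' @param newdata normalized `ExpressionDataset` or matrix
#' @param ... unused
#' @return list with `probabilities` (cells x classes, in `[0, 1]`) and
#'   `binary` (1 where probability strictly exceeds the threshold)
#' @export
predict.dxg_classifier <- function(object, newdata, ...) {
  X <- dataset_matrix(newdata)
  if (ncol(X) != object$spec$input_dim) {
    stop("gene dimension (", ncol(X), ") != classifier input_dim (",
         object$spec$input_dim, ")")
  }
  p <- nn_forward(object$net, X)
  colnames(p) <- object$class_names
  rownames(p) <- rownames(X)
  binary <- (p > object$threshold) * 1L
  list(probabilities = p, binary = binary)
}

#' Save / load a trained model with a JSON sidecar
#'
#' The model is written with `saveRDS`; a JSON sidecar records the spec and
#' training history for provenance.
#'
#' @param model a `dxg_dae` or `dxg_classifier`
#' @param path output `.rds` path (sidecar gets `.json` appended)
#' @return `path`, invisibly
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(class = class(model), spec = unclass(model$spec),
                  best_val_loss = model$best_val_loss,
                  history = model$history)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
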