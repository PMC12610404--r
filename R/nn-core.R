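# Minimal dense feed-forward network engine: ReLU hidden layers, linear or
# sigmoid output, Adam, minibatch training with plateau lr decay and early
# stopping. Kept deliberately small; all heavy lifting is BLAS matrix algebra.

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

new_network <- function(input_dim, layer_sizes, output_activation = "linear") {
  # He (fan-in scaled) init; caller controls the RNG state
  dims <- c(input_dim, layer_sizes)
  n_layers <- length(layer_sizes)
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                  sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  activations <- c(rep("relu", n_layers - 1L), output_activation)
  structure(list(W = W, b = b, activations = activations,
                 input_dim = input_dim, layer_sizes = layer_sizes),
            class = "dxg_network")
}

nn_forward <- function(net, X, keep_cache = FALSE) {
  A <- X
  cache <- if (keep_cache) list(A0 = X) else NULL
  for (l in seq_along(net$W)) {
    Z <- A %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))  # recycled column-major bias add
    A <- switch(net$activations[l],
                relu = relu(Z),
                sigmoid = sigmoid(Z),
                linear = Z,
                stop("unknown activation: ", net$activations[l]))
    if (keep_cache) {
      cache[[paste0("Z", l)]] <- Z
      cache[[paste0("A", l)]] <- A
    }
  }
  if (keep_cache) list(out = A, cache = cache) else A
}

nn_backward <- function(net, cache, dA_out) {
  # dA_out: gradient of the loss w.r.t. the output activations
  n_layers <- length(net$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  dA <- dA_out
  for (l in rev(seq_len(n_layers))) {
    A_cur <- cache[[paste0("A", l)]]
    dZ <- switch(net$activations[l],
                 relu = dA * (cache[[paste0("Z", l)]] > 0),
                 sigmoid = dA * A_cur * (1 - A_cur),
                 linear = dA)
    A_prev <- if (l == 1L) cache$A0 else cache[[paste0("A", l - 1L)]]
    gW[[l]] <- crossprod(A_prev, dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) dA <- tcrossprod(dZ, net$W[[l]])
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  zeros_like <- function(p) {
    lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x)))
  }
  list(mW = zeros_like(net$W), vW = zeros_like(net$W),
       mb = zeros_like(net$b), vb = zeros_like(net$b), t = 0L)
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$W[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$mW[[l]] / c1) / (sqrt(opt$vW[[l]] / c2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$b[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + eps)
    if (weight_decay > 0) {
      # decoupled weight decay; biases are not decayed
      net$W[[l]] <- net$W[[l]] - lr * weight_decay * net$W[[l]]
    }
  }
  list(net = net, opt = opt)
}

#' Initialize the training schedule state
#'
#' @param initial_lr starting learning rate
#' @param patience_lr epochs without improvement before the learning rate is
#'   multiplied by `lr_factor` (default 25)
#' @param patience_stop epochs without improvement before training stops
#'   (default 50)
#' @param lr_factor multiplicative decay (default 0.1)
#' @param lr_floor lowest admissible learning rate (default 1e-7)
#' @return a `train_state` list
#' @export
train_state <- function(initial_lr = 1e-3, patience_lr = 25L,
                        patience_stop = 50L, lr_factor = 0.1,
                        lr_floor = 1e-7) {
  list(lr = initial_lr, best_loss = Inf, epochs_since_improvement = 0L,
       lr_wait = 0L, stop = FALSE, lr_dropped = FALSE,
       patience_lr = patience_lr, patience_stop = patience_stop,
       lr_factor = lr_factor, lr_floor = lr_floor)
}

#' Advance the learning-rate / early-stopping schedule by one epoch
#'
#' Improvement is a strictly lower monitored loss. After `patience_lr`
#' consecutive non-improving epochs the learning rate is multiplied by
#' `lr_factor` (floored at `lr_floor`) and the decay counter resets; after
#' `patience_stop` non-improving epochs `state$stop` is set.
#'
#' @param state a [train_state()]
#' @param monitored_loss this epoch's monitored (validation) loss
#' @return the updated state
#' @export
lr_schedule_step <- function(state, monitored_loss) {
  state$lr_dropped <- FALSE
  if (monitored_loss < state$best_loss) {
    state$best_loss <- monitored_loss
    state$epochs_since_improvement <- 0L
    state$lr_wait <- 0L
    return(state)
  }
  state$epochs_since_improvement <- state$epochs_since_improvement + 1L
  state$lr_wait <- state$lr_wait + 1L
  if (state$epochs_since_improvement >= state$patience_stop) {
    state$stop <- TRUE
    return(state)
  }
  if (state$lr_wait >= state$patience_lr) {
    state$lr <- max(state$lr * state$lr_factor, state$lr_floor)
    state$lr_wait <- 0L
    state$lr_dropped <- TRUE
  }
  state
}

activation_codes <- c(linear = 0L, relu = 1L, sigmoid = 2L)

bce_loss <- function(p, y) {
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

# gradient w.r.t. probabilities; the 1/(p(1-p)) factor cancels against the
# sigmoid derivative downstream, yielding the stable (p - y) logit gradient
bce_grad <- function(p, y) {
  (p - y) / pmax(p * (1 - p), 1e-12) / length(p)
}

# run one epoch of minibatch Adam in pure R (reference engine)
r_epoch <- function(net, opt, loss_fun, grad_fun, X, Y, order, batch_size,
                    lr, weight_decay = 0) {
  starts <- seq(1L, nrow(X), by = batch_size)
  train_losses <- numeric(length(starts))
  for (k in seq_along(starts)) {
    idx <- order[starts[k]:min(starts[k] + batch_size - 1L, nrow(X))]
    fw <- nn_forward(net, X[idx, , drop = FALSE], keep_cache = TRUE)
    train_losses[k] <- loss_fun(fw$out, Y[idx, , drop = FALSE])
    if (!is.finite(train_losses[k])) {
      stop("non-finite training loss (lr = ", lr,
           "); inputs may be unscaled or lr too high")
    }
    grads <- nn_backward(net, fw$cache,
                         grad_fun(fw$out, Y[idx, , drop = FALSE]))
    upd <- adam_step(net, grads, opt, lr, weight_decay = weight_decay)
    net <- upd$net
    opt <- upd$opt
  }
  list(net = net, opt = opt, train_loss = mean(train_losses))
}

train_network <- function(input_dim, layer_sizes, output_activation,
                          loss = c("mse", "macro_f1", "bce"),
                          X, Y, val_X, val_Y,
                          batch_size = 10240L, initial_lr = 1e-3,
                          max_epochs = 500L, patience_lr = 25L,
                          patience_stop = 50L, lr_factor = 0.1,
                          lr_floor = 1e-7, weight_decay = 0, seed = 1L,
                          verbose = FALSE, engine = c("cpp", "r"),
                          init_net = NULL) {
  loss <- match.arg(loss)
  engine <- match.arg(engine)
  loss_fun <- switch(loss,
                     mse = l2_loss,
                     macro_f1 = function(p, y) macro_f1_loss(p, y, warn = FALSE),
                     bce = bce_loss)
  grad_fun <- switch(loss, mse = l2_loss_grad, macro_f1 = macro_f1_loss_grad,
                     bce = bce_grad)
  loss_code <- switch(loss, mse = 0L, macro_f1 = 1L, bce = 2L)
  n <- nrow(X)
  if (engine == "cpp") {
    return(withr::with_seed(seed, {
      net <- if (is.null(init_net)) {
        new_network(input_dim, layer_sizes, output_activation)
      } else {
        init_net
      }
      acts <- unname(activation_codes[net$activations])
      orders <- vapply(seq_len(max_epochs), function(e) sample.int(n),
                       integer(n))
      fit <- .cpp_train(net$W, net$b, acts, loss_code, X, Y, identical(X, Y),
                        val_X, val_Y, orders, as.integer(batch_size),
                        initial_lr, as.integer(patience_lr),
                        as.integer(patience_stop), lr_factor, lr_floor,
                        0.9, 0.999, 1e-8, weight_decay)
      net$W <- fit$W
      net$b <- lapply(fit$b, as.numeric)
      history <- data.frame(epoch = seq_len(fit$epochs_run), lr = fit$lr,
                            train_loss = fit$train_loss,
                            val_loss = fit$val_loss)
      if (verbose) {
        message(sprintf("  trained %d epochs, best val loss %.5f",
                        fit$epochs_run, fit$best_val_loss))
      }
      state <- train_state(initial_lr, patience_lr, patience_stop, lr_factor,
                           lr_floor)
      state$lr <- fit$final_lr
      state$best_loss <- fit$best_val_loss
      list(net = net, history = history, best_val_loss = fit$best_val_loss,
           state = state)
    }))
  }
  withr::with_seed(seed, {
    net <- if (is.null(init_net)) {
      new_network(input_dim, layer_sizes, output_activation)
    } else {
      init_net
    }
    opt <- adam_init(net)
    state <- train_state(initial_lr, patience_lr, patience_stop, lr_factor,
                         lr_floor)
    best_net <- net
    history <- vector("list", max_epochs)
    for (epoch in seq_len(max_epochs)) {
      order <- sample.int(n)
      upd <- r_epoch(net, opt, loss_fun, grad_fun, X, Y, order,
                     batch_size, state$lr, weight_decay)
      net <- upd$net
      opt <- upd$opt
      train_loss <- upd$train_loss
      val_loss <- loss_fun(nn_forward(net, val_X), val_Y)
      if (!is.finite(val_loss)) {
        stop("non-finite validation loss at epoch ", epoch)
      }
      improved <- val_loss < state$best_loss
      state <- lr_schedule_step(state, val_loss)
      if (improved) best_net <- net
      history[[epoch]] <- data.frame(epoch = epoch, lr = state$lr,
                                     train_loss = train_loss,
                                     val_loss = val_loss)
      if (verbose && (epoch %% 10L == 0L || epoch == 1L)) {
        message(sprintf("  epoch %3d  train %.5f  val %.5f  lr %.1e",
                        epoch, train_loss, val_loss, state$lr))
      }
      if (state$stop) break
    }
    history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
    list(net = best_net, history = history, best_val_loss = state$best_loss,
         state = state)
  })
}
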