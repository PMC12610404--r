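test_that("l2_loss is the element mean squared difference", {
  a <- matrix(rnorm(12), 3, 4)
  expect_equal(l2_loss(a, a), 0)
  expect_equal(l2_loss(matrix(1, 5, 7), matrix(0, 5, 7)), 1)
  b <- matrix(rnorm(12), 3, 4)
  brute <- sum((a - b)^2) / 12   # explicit elementwise evaluation
  expect_equal(l2_loss(a, b), brute, tolerance = 1e-12)
  expect_error(l2_loss(a, matrix(0, 2, 2)), "shape mismatch")
})

test_that("macro F1 loss reproduces hand-worked soft counts", {
  # one class, two cells, y = [1,0], p = [1,1]:
  # TP 1, FP 1, FN 0 -> pr 0.5, rc 1, F1 2/3, loss 1/3
  expect_equal(macro_f1_loss(matrix(c(1, 1), 2, 1), matrix(c(1, 0), 2, 1)),
               1 / 3, tolerance = 1e-12)
  withr::with_seed(1, {
    y <- matrix(rbinom(40, 1, 0.4), 10, 4)
    y[1, ] <- 1   # every class occurs at least once
    p <- matrix(runif(40), 10, 4)
    perm <- sample(10)
  })
  expect_equal(macro_f1_loss(y, y, warn = FALSE), 0)
  expect_equal(macro_f1_loss(p, y, warn = FALSE),
               macro_f1_loss(p[perm, ], y[perm, ], warn = FALSE))
  expect_error(macro_f1_loss(p * 2, y), "\\[0, 1\\]")
})

test_that("macro F1 loss on hard labels equals hard-count macro F1 exactly", {
  withr::with_seed(5, {
    for (i in 1:10) {
      y <- matrix(rbinom(60, 1, 0.5), 12, 5)
      b <- matrix(rbinom(60, 1, 0.5), 12, 5)
      # avoid classes that are empty in both (loss takes F1 = 0 there by
      # contract, the evaluation convention reports 1)
      keep <- colSums(y) + colSums(b) > 0
      y <- y[, keep, drop = FALSE]; b <- b[, keep, drop = FALSE]
      expect_equal(1 - macro_f1_loss(b, y, warn = FALSE), hard_macro_f1(b, y))
    }
  })
})

test_that("degenerate classes contribute loss 1 with a warning", {
  y <- cbind(c(1, 0), c(0, 0))
  p <- cbind(c(1, 0), c(0, 0))  # second class: zero soft TP+FP and TP+FN
  expect_warning(loss <- macro_f1_loss(p, y), "zero soft")
  expect_equal(loss, 0.5)  # perfect first class (0) + degenerate second (1)
})

test_that("analytic macro F1 gradient matches finite differences", {
  withr::with_seed(8, {
    p <- matrix(runif(24, 0.05, 0.95), 6, 4)
    y <- matrix(rbinom(24, 1, 0.4), 6, 4)
    g <- dxgenes:::macro_f1_loss_grad(p, y)
    eps <- 1e-6
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(ncol(p))) {
        up <- p; up[i, j] <- up[i, j] + eps
        dn <- p; dn[i, j] <- dn[i, j] - eps
        fd <- (macro_f1_loss(up, y, warn = FALSE) -
                 macro_f1_loss(dn, y, warn = FALSE)) / (2 * eps)
        expect_lt(abs(fd - g[i, j]), 1e-4)
      }
    }
  })
})

test_that("the plateau schedule drops lr exactly once per patience window", {
  st <- train_state(initial_lr = 0.001, patience_lr = 25, patience_stop = 50)
  st <- lr_schedule_step(st, 1.0)           # first epoch improves vs Inf
  for (i in 1:26) st <- lr_schedule_step(st, 2.0)
  expect_equal(st$lr, 1e-4, tolerance = 1e-15)
  expect_false(st$stop)
  # improvement resets both counters
  st <- lr_schedule_step(st, 0.5)
  expect_equal(st$epochs_since_improvement, 0L)
  for (i in 1:50) st <- lr_schedule_step(st, 2.0)
  expect_true(st$stop)
})

test_that("lr sequence is non-increasing, decays by 0.1 and floors at 1e-7", {
  st <- train_state()
  st <- lr_schedule_step(st, 1.0)
  lrs <- st$lr
  for (i in 1:200) {
    st <- lr_schedule_step(st, 2.0)
    if (st$stop) break
    lrs <- c(lrs, st$lr)
  }
  expect_true(all(diff(lrs) <= 0))
  drops <- unique(lrs)
  expect_equal(drops[2] / drops[1], 0.1, tolerance = 1e-12)
  st2 <- train_state(initial_lr = 1e-7)
  st2 <- lr_schedule_step(st2, 1)
  for (i in 1:25) st2 <- lr_schedule_step(st2, 2)
  expect_gte(st2$lr, 1e-7)
})

test_that("compiled and reference training engines agree", {
  withr::with_seed(2, {
    X <- matrix(rnorm(300 * 20), 300, 20)
    Y <- matrix(rbinom(300 * 5, 1, 0.3), 300, 5)
  })
  a <- dxgenes:::train_network(20, c(10, 5), "sigmoid", "macro_f1",
                               X, Y, X[1:50, ], Y[1:50, ],
                               batch_size = 64, max_epochs = 8, seed = 7,
                               engine = "r")
  b <- dxgenes:::train_network(20, c(10, 5), "sigmoid", "macro_f1",
                               X, Y, X[1:50, ], Y[1:50, ],
                               batch_size = 64, max_epochs = 8, seed = 7,
                               engine = "cpp")
  expect_equal(a$history$val_loss, b$history$val_loss, tolerance = 1e-12)
  expect_equal(a$history$lr, b$history$lr)
})

test_that("the autoencoder learns a trivial constant target quickly", {
  X <- matrix(0, 64, 8)
  spec <- dae_spec(8, encoder_sizes = 4, decoder_sizes = 4, batch_size = 32,
                   max_epochs = 50)
  fit <- train_dae(spec, X, X, seed = 1)
  expect_lt(fit$best_val_loss, 1e-4)
})

test_that("training is deterministic for a fixed seed", {
  withr::with_seed(3, X <- matrix(rnorm(200 * 10), 200, 10))
  spec <- dae_spec(10, encoder_sizes = 4, decoder_sizes = 4, batch_size = 64,
                   max_epochs = 5)
  f1 <- train_dae(spec, X, X[1:40, ], seed = 9)
  f2 <- train_dae(spec, X, X[1:40, ], seed = 9)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$history$train_loss[1], f2$history$train_loss[1])
})

test_that("reconstruct preserves shape and metadata and beats a zero baseline", {
  gen <- generate_dataset(small_separable_config(seed = 6))
  norm <- lognormalize(gen$dataset)
  sp <- stratified_split(norm, seed = 1)
  tr <- subset_cells(norm, sp$train_indices)
  va <- subset_cells(norm, sp$val_indices)
  spec <- dae_spec(60, encoder_sizes = c(24, 12), decoder_sizes = 24,
                   batch_size = 128, max_epochs = 40)
  dae <- train_dae(spec, tr, va, seed = 2)
  rec <- reconstruct(dae, va)
  expect_equal(dim(rec$values), dim(va$values))
  expect_identical(rec$cell_meta, va$cell_meta)
  expect_lt(l2_loss(rec$values, va$values),
            l2_loss(matrix(0, nrow(va$values), ncol(va$values)), va$values))
  expect_error(reconstruct(dae, va$values[, 1:10]), "input_dim")
})

test_that("classifier reaches high validation F1 on separable data and chance on shuffled labels", {
  gen <- generate_dataset(small_separable_config(seed = 4, marker_effect = 3))
  norm <- lognormalize(gen$dataset)
  sp <- stratified_split(norm, seed = 2)
  tr <- subset_cells(norm, sp$train_indices)
  va <- subset_cells(norm, sp$val_indices)
  schema <- label_schema(species = "human", cell_type = c("CM", "EC"),
                         disease = c("healthy", "HFpEF"))
  tl <- encode_labels(tr$cell_meta, schema)
  vl <- encode_labels(va$cell_meta, schema)
  spec <- mlp_spec(60, hidden_sizes = c(32, 16), n_classes = 5,
                   batch_size = 64, max_epochs = 120)
  mlp <- train_mlp(spec, tr, tl, va, vl, seed = 3)
  pred <- predict(mlp, va)
  expect_gte(macro_f1_score(pred$binary, vl), 0.95)

  # negative control: shuffled labels destroy the mapping
  shuf <- tl
  perm <- withr::with_seed(13, sample(nrow(shuf$onehot)))
  shuf$onehot <- shuf$onehot[perm, ]
  mlp0 <- train_mlp(spec, tr, shuf, va, vl, seed = 3)
  f1_shuffled <- macro_f1_score(predict(mlp0, va)$binary, vl)
  expect_lt(f1_shuffled, 0.75)

  # determinism of the full history
  mlp2 <- train_mlp(spec, tr, tl, va, vl, seed = 3)
  expect_identical(mlp$history, mlp2$history)
})

test_that("prediction thresholds strictly above 0.5", {
  # hand-built single-layer classifier: logits fixed by the bias alone
  spec <- mlp_spec(2, hidden_sizes = 2, n_classes = 3, threshold = 0.5)
  net <- list(W = list(matrix(0, 2, 2), matrix(0, 2, 3)),
              b = list(c(0, 0),
                       c(qlogis(0.51), qlogis(0.5), qlogis(0.49))),
              activations = c("relu", "sigmoid"),
              input_dim = 2, layer_sizes = c(2, 3))
  clf <- structure(list(net = net, spec = spec, threshold = 0.5,
                        class_names = c("a", "b", "c")),
                   class = "dxg_classifier")
  pred <- predict(clf, matrix(0, 4, 2))
  expect_equal(unname(pred$probabilities[1, ]), c(0.51, 0.5, 0.49),
               tolerance = 1e-12)
  expect_equal(unname(pred$binary[1, ]), c(1, 0, 0))

  # monotone: raising one output's bias never lowers its binary call
  net$b[[2]][2] <- qlogis(0.9)
  clf$net <- net
  expect_equal(unname(predict(clf, matrix(0, 1, 2))$binary[1, ]), c(1, 1, 0))
})

test_that("models persist with a JSON sidecar", {
  X <- matrix(rnorm(80), 20, 4)
  spec <- dae_spec(4, encoder_sizes = 2, decoder_sizes = 2, batch_size = 20,
                   max_epochs = 3)
  dae <- train_dae(spec, X, X, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(dae, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_equal(back$net$W, dae$net$W)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$spec$input_dim, 4)
})
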