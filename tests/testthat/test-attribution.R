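test_that("background selection clamps, deduplicates and is seeded", {
  X <- matrix(rnorm(500 * 4), 500, 4)
  expect_warning(bg <- select_background(X, n = 1000, seed = 1),
                 "only 500 available")
  expect_equal(nrow(bg$cells), 500)
  expect_equal(anyDuplicated(bg$source_indices), 0)

  bg1 <- select_background(X, n = 100, seed = 5)
  bg2 <- select_background(X, n = 100, seed = 5)
  expect_identical(bg1$source_indices, bg2$source_indices)
  expect_equal(anyDuplicated(bg1$source_indices), 0)
  expect_error(select_background(X[0, , drop = FALSE], 10, 1), "empty")
})

test_that("explained-cell selection caps per cell type x sample group", {
  withr::with_seed(2, {
    n <- 1200
    meta <- data.frame(species = "human",
                       cell_type = rep(c("CM", "EC"), each = n / 2),
                       disease = "healthy",
                       sample = rep(c("s1", "s2"), n / 2))
    ds <- expression_dataset(matrix(1, n, 2), cell_meta = meta)
  })
  idx <- select_explained_cells(ds, per_group = 200, seed = 3)
  expect_equal(length(idx), 800)   # 2 types x 2 samples x 200
  expect_equal(anyDuplicated(idx), 0)

  small <- subset_cells(ds, 1:50)   # one group with 50 cells only
  expect_equal(length(select_explained_cells(small, per_group = 200, seed = 1)),
               50)
})

test_that("exact Shapley matches the linear closed form and axioms", {
  withr::with_seed(10, {
    d <- 8
    B <- matrix(rnorm(30 * d), 30, d)
    x <- rnorm(d)
  })
  lin <- random_linear_model(d, seed = 3)
  phi <- shapley_exact(lin$model, x, B)
  expect_equal(unname(phi), lin$w * (x - colMeans(B)), tolerance = 1e-10)
  # efficiency
  expect_equal(sum(phi), lin$model(x) - mean(lin$model(B)), tolerance = 1e-10)
  # constant model
  expect_equal(unname(shapley_exact(function(X) rep(2, nrow(X)), x, B)),
               rep(0, d))
  expect_error(shapley_exact(lin$model, rnorm(20), matrix(rnorm(200), 10, 20)),
               "shapley_sampled")
})

test_that("exact Shapley satisfies symmetry and linearity", {
  withr::with_seed(11, {
    d <- 6
    B <- matrix(rnorm(20 * d), 20, d)
    B[, 2] <- B[, 1]                 # identical marginals for features 1, 2
    x <- rnorm(d); x[2] <- x[1]
  })
  f_sym <- function(X) (X[, 1] + X[, 2])^2 + X[, 3]
  phi <- shapley_exact(f_sym, x, B)
  expect_equal(phi[1], phi[2], tolerance = 1e-10)

  f <- function(X) sin(X[, 1]) + X[, 2] * X[, 3]
  g <- function(X) exp(X[, 4] / 2) - X[, 1]
  phi_sum <- shapley_exact(function(X) f(X) + g(X), x, B)
  expect_equal(phi_sum, shapley_exact(f, x, B) + shapley_exact(g, x, B),
               tolerance = 1e-10)
})

test_that("sampled Shapley converges to the exact oracle within MC error", {
  d <- 6
  withr::with_seed(21, {
    B <- matrix(rnorm(15 * d), 15, d)
    x <- rnorm(d)
  })
  model <- random_mlp_model(d, seed = 4)
  exact <- shapley_exact(model, x, B)
  att <- shapley_sampled(model, matrix(x, 1), B, n_permutations = 2000,
                         seed = 31, return_se = TRUE)
  dev <- abs(att$scores[1, ] - exact)
  expect_true(all(dev < 3 * att$se[1, ] + 1e-12))
})

test_that("sampled Shapley honors null-player and efficiency axioms", {
  d <- 5
  withr::with_seed(41, {
    B <- matrix(rnorm(10 * d), 10, d)
    x <- rnorm(d)
  })
  B[, 3] <- 1; x[3] <- 1    # feature 3 identical everywhere -> null player
  model <- random_mlp_model(d, seed = 6)
  att <- shapley_sampled(model, matrix(x, 1), B, n_permutations = 200,
                         seed = 8, return_se = TRUE)
  expect_equal(unname(att$scores[1, 3]), 0)

  # efficiency in Monte-Carlo form
  total <- sum(att$scores[1, ])
  target <- model(matrix(x, 1)) - mean(model(B))
  se_total <- sqrt(sum(att$se[1, ]^2, na.rm = TRUE)) + 1e-8
  expect_lt(abs(total - target), 6 * se_total)

  att2 <- shapley_sampled(model, matrix(x, 1), B, n_permutations = 200,
                          seed = 8)
  expect_equal(att$scores, att2$scores)
})

test_that("mitochondrial exclusion precedes standardization and is idempotent", {
  scores <- matrix(rnorm(6), 2, 3,
                   dimnames = list(NULL, c("MT-CO1", "ACTB", "mt-nd1")))
  att <- attribution_set(scores, class_name = "disease:HFpEF")
  out <- exclude_mito(att)
  expect_equal(colnames(out$scores), "ACTB")
  expect_setequal(out$excluded_genes, c("MT-CO1", "mt-nd1"))
  expect_equal(exclude_mito(out)$scores, out$scores)

  no_mt <- attribution_set(scores[, 2, drop = FALSE])
  expect_identical(exclude_mito(no_mt)$scores, no_mt$scores)
  expect_error(exclude_mito(z_transform_rows(att)), "before Z-transform")
})

test_that("rowwise Z-transform matches the printed equation", {
  att <- attribution_set(matrix(c(1, 2, 3), 1, 3,
                                dimnames = list(NULL, c("a", "b", "c"))))
  z <- z_transform_rows(att)
  expect_equal(unname(z$scores[1, ]), c(-1, 0, 1) / sqrt(2 / 3),
               tolerance = 1e-4)
  expect_equal(unname(z$scores[1, ]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_true(z$z_transformed)

  withr::with_seed(3, big <- matrix(rnorm(50 * 20), 50, 20))
  zb <- z_transform_rows(attribution_set(big))
  expect_true(all(abs(rowMeans(zb$scores)) < 1e-8))
  pop_sd <- sqrt(rowMeans(zb$scores^2))
  expect_true(all(abs(pop_sd - 1) < 1e-6))
  # rank order within each row is preserved
  for (i in 1:5) {
    expect_equal(order(zb$scores[i, ]), order(big[i, ]))
  }

  const <- attribution_set(matrix(1, 2, 4))
  expect_warning(zc <- z_transform_rows(const), "zero standard deviation")
  expect_true(all(zc$scores == 0))
  expect_error(z_transform_rows(attribution_set(matrix(1, 2, 1))),
               "at least 2 genes")
})

test_that("class sets assemble, query and round-trip through disk", {
  withr::with_seed(9, {
    meta <- data.frame(species = "human", cell_type = "CM",
                       disease = rep(c("healthy", "HFpEF"), 5),
                       sample = "s1")
    sets <- lapply(c("disease:HFpEF", "cell_type:CM"), function(cls) {
      attribution_set(matrix(rnorm(30), 10, 3,
                             dimnames = list(sprintf("c%02d", 1:10),
                                             c("g1", "g2", "g3"))),
                      class_name = cls, cell_meta = meta)
    })
  })
  coll <- assemble_class_sets(sets)
  expect_equal(names(coll), c("disease:HFpEF", "cell_type:CM"))
  expect_equal(coll[["disease:HFpEF"]]$class_name, "disease:HFpEF")
  expect_equal(sum(vapply(coll, function(s) nrow(s$scores), numeric(1))), 20)

  dir <- withr::local_tempdir()
  write_attribution(coll, dir)
  back <- read_attribution(dir)
  expect_equal(back[["cell_type:CM"]]$scores, coll[["cell_type:CM"]]$scores)
  expect_equal(back[["disease:HFpEF"]]$cell_meta$disease, meta$disease)

  bad <- sets
  colnames(bad[[2]]$scores) <- c("g1", "g2", "gX")
  expect_error(assemble_class_sets(bad), "gene columns differ.*gX")
})

test_that("class_model explains single nodes, optionally through the DAE", {
  gen <- generate_dataset(small_separable_config(seed = 12))
  norm <- lognormalize(gen$dataset)
  schema <- label_schema(species = "human", cell_type = c("CM", "EC"),
                         disease = c("healthy", "HFpEF"))
  labels <- encode_labels(norm$cell_meta, schema)
  spec <- mlp_spec(60, hidden_sizes = 8, n_classes = 5, batch_size = 256,
                   max_epochs = 5)
  mlp <- train_mlp(spec, norm, labels, norm, labels, seed = 1)
  f <- class_model(mlp, "disease:HFpEF")
  out <- f(norm$values[1:4, ])
  expect_length(out, 4)
  expect_equal(out, predict(mlp, norm$values[1:4, ])$probabilities[, 5],
               ignore_attr = TRUE)
  expect_error(class_model(mlp, "disease:gout"), "unknown class")

  dspec <- dae_spec(60, encoder_sizes = 8, decoder_sizes = 8,
                    batch_size = 256, max_epochs = 3)
  dae <- train_dae(dspec, norm, norm, seed = 2)
  fc <- class_model(mlp, "disease:HFpEF", dae = dae)
  expect_equal(fc(norm$values[1:2, ]),
               f(reconstruct(dae, norm$values[1:2, ])),
               tolerance = 1e-12)
})
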