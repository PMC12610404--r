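test_that("signed cube root is odd and matches hand values", {
  x <- c(-27, -8, -1, 0, 1, 8, 27, 0.5, -0.5)
  expect_equal(signed_cuberoot(-x), -signed_cuberoot(x))
  expect_equal(signed_cuberoot(8), 2)
  expect_equal(signed_cuberoot(-8), -2)
  expect_equal(signed_cuberoot(0), 0)
  # the FC3 hand examples
  expect_equal(signed_cuberoot(8) - signed_cuberoot(1), 1, tolerance = 1e-12)
  expect_equal(signed_cuberoot(-8) - signed_cuberoot(0), -2, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-worked step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.2), 0.2)
  sorted <- sort(runif(50))
  expect_true(all(diff(bh_adjust(sorted)) >= 0))
  expect_true(all(bh_adjust(sorted) >= sorted))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("normality screen is calibrated on normal and powered on skewed data", {
  withr::with_seed(14, {
    normal_p <- vapply(1:100, function(i) {
      normality_check(matrix(rnorm(500), ncol = 1), seed = i)$p_values[1]
    }, numeric(1))
    expo_p <- vapply(1:100, function(i) {
      normality_check(matrix(rexp(500), ncol = 1), seed = i)$p_values[1]
    }, numeric(1))
  })
  expect_gte(mean(normal_p > 0.05), 0.90)
  expect_gte(mean(expo_p < 0.05), 0.99)

  expect_warning(res <- normality_check(matrix(1, 10, 1)), "skipped")
  expect_true(is.na(res$p_values[1]))

  withr::with_seed(15, m <- matrix(rnorm(300 * 10), 300, 10))
  expect_equal(normality_check(m, seed = 2)$recommendation, "t")
  withr::with_seed(16, e <- matrix(rexp(300 * 10), 300, 10))
  expect_equal(normality_check(e, seed = 2)$recommendation, "wilcoxon")
})

test_that("vectorized Welch t equals stats::t.test to 1e-10", {
  withr::with_seed(18, {
    A <- matrix(rnorm(40 * 25, sd = 2), 40, 25)
    B <- matrix(rnorm(60 * 25), 60, 25)
  })
  res <- dxgenes:::welch_t_cols(A, B)
  for (j in 1:25) {
    ref <- stats::t.test(A[, j], B[, j])
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-10)
    expect_equal(unname(res$statistic[j]), unname(ref$statistic),
                 tolerance = 1e-10)
  }
})

make_att <- function(scores, disease, class_name = "disease:HFpEF") {
  meta <- data.frame(species = "human", cell_type = "CM",
                     disease = disease, sample = "s1")
  attribution_set(scores, class_name = class_name, cell_meta = meta)
}

test_that("dxg_test returns null results on copied groups", {
  withr::with_seed(22, block <- matrix(rnorm(20 * 8), 20, 8))
  scores <- rbind(block, block)   # group B is an exact copy of group A
  colnames(scores) <- sprintf("g%02d", 1:8)
  att <- make_att(scores, rep(c("HFpEF", "healthy"), each = 20))
  gg <- group_spec(A = list(disease = "HFpEF"), B = list(disease = "healthy"))
  tab <- dxg_test(att, gg, method = "t", standardization = "none")
  expect_true(all(tab$p_raw > 1 - 1e-10))
  expect_equal(tab$fc3, rep(0, 8), tolerance = 1e-12)
  expect_equal(unique(tab$n_A), 20)
})

test_that("dxg_test validates groups and orders its output", {
  withr::with_seed(23, scores <- matrix(rnorm(40 * 6), 40, 6,
                                        dimnames = list(NULL, letters[1:6])))
  att <- make_att(scores, rep(c("HFpEF", "healthy"), each = 20))
  gg_bad <- group_spec(A = list(disease = "HFpEF"),
                       B = list(disease = "HFrEF"))
  expect_error(dxg_test(att, gg_bad, method = "t"), "matches no cells")
  gg_overlap <- group_spec(A = list(disease = "HFpEF"),
                           B = list(cell_type = "CM"))
  expect_error(dxg_test(att, gg_overlap, method = "t"), "disjoint")

  gg <- group_spec(A = list(disease = "HFpEF"), B = list(disease = "healthy"))
  tab <- dxg_test(att, gg, method = "t")
  expect_true(all(diff(tab$p_adj) >= 0))
  expect_equal(tab$p_adj, bh_adjust(tab$p_raw)[match(tab$gene, colnames(scores))],
               tolerance = 1e-12)
  expect_equal(tab$fc3,
               signed_cuberoot(tab$mean_A) - signed_cuberoot(tab$mean_B),
               tolerance = 1e-12)

  # wilcoxon branch agrees with stats::wilcox.test
  tabw <- dxg_test(att, gg, method = "wilcoxon", standardization = "none")
  j <- which(colnames(scores) == tabw$gene[1])
  ref <- stats::wilcox.test(scores[1:20, j], scores[21:40, j],
                            exact = FALSE)$p.value
  expect_equal(tabw$p_raw[1], ref, tolerance = 1e-12)
})

test_that("dxg_test on a collection draws the configured class node", {
  withr::with_seed(25, {
    s1 <- make_att(matrix(rnorm(20), 10, 2,
                          dimnames = list(NULL, c("g1", "g2"))),
                   rep(c("HFpEF", "healthy"), 5), "disease:HFpEF")
    s2 <- make_att(matrix(rnorm(20, 5), 10, 2,
                          dimnames = list(NULL, c("g1", "g2"))),
                   rep(c("HFpEF", "healthy"), 5), "disease:HFrEF")
  })
  coll <- assemble_class_sets(list(s1, s2))
  gg <- group_spec(A = list(disease = "HFpEF"), B = list(disease = "healthy"),
                   class_node = "disease:HFpEF")
  tab <- dxg_test(coll, gg, method = "t", standardization = "none")
  expect_equal(nrow(tab), 2)
  gg2 <- group_spec(A = list(disease = "HFpEF"),
                    B = list(disease = "healthy"),
                    class_node = "disease:AS")
  expect_error(dxg_test(coll, gg2, method = "t"), "not in the collection")
})

test_that("deg_wilcoxon filters like the reference tool and finds planted shifts", {
  # identical groups: no gene passes the |logFC| filter
  withr::with_seed(26, vals <- matrix(rexp(40 * 10), 40, 10))
  ds <- expression_dataset(rbind(vals, vals),
                           cell_meta = data.frame(
                             species = "human", cell_type = "CM",
                             disease = rep(c("HFpEF", "healthy"), each = 40),
                             sample = "s1"),
                           normalized = TRUE)
  gg <- group_spec(A = list(disease = "HFpEF"), B = list(disease = "healthy"))
  expect_equal(nrow(deg_wilcoxon(ds, gg)), 0)
  # unfiltered mode tests the full universe
  expect_equal(nrow(deg_wilcoxon(ds, gg, min_pct = 0, min_abs_logfc = 0)), 10)
})

test_that("deg_wilcoxon detects a 4x planted mean shift reliably", {
  detected <- 0
  for (sim in 1:50) {
    withr::with_seed(300 + sim, {
      base <- matrix(rpois(400 * 20, 2), 400, 20)
      base[1:200, 1] <- rpois(200, 8)   # 4x shift in gene 1, group A
    })
    ds <- expression_dataset(base, cell_meta = data.frame(
      species = "human", cell_type = "CM",
      disease = rep(c("HFpEF", "healthy"), each = 200), sample = "s1"))
    norm <- lognormalize(ds)
    gg <- group_spec(A = list(disease = "HFpEF"),
                     B = list(disease = "healthy"))
    tab <- deg_wilcoxon(norm, gg)
    g1 <- tab[tab$gene == norm$gene_names[1], ]
    detected <- detected + (nrow(g1) == 1 && g1$p_adj < 0.05)
  }
  expect_gte(detected / 50, 0.95)
})

test_that("gene-set overlap is plain set algebra", {
  dxg <- data.frame(gene = c("A", "B", "C", "E"),
                    p_adj = c(0.01, 0.01, 0.01, 0.9))
  deg <- data.frame(gene = c("B", "C", "D", "E"),
                    p_adj = c(0.01, 0.01, 0.01, 0.9))
  ov <- compare_gene_sets(dxg, deg)
  expect_equal(ov$n_common, 2)
  expect_equal(ov$n_dxg_only, 1)
  expect_equal(ov$n_deg_only, 1)
  expect_equal(ov$n_common + ov$n_dxg_only, sum(dxg$p_adj < 0.05))

  ov2 <- compare_gene_sets(dxg, dxg)
  expect_equal(ov2$n_common, 3)
  expect_equal(ov2$n_dxg_only, 0)

  disjoint <- data.frame(gene = c("X", "Y"), p_adj = c(0.01, 0.01))
  expect_warning(compare_gene_sets(dxg, disjoint), "share no genes")
})
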