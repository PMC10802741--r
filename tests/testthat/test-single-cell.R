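test_that("diversity indices have their closed-form values", {
  even <- rep(3, 10)
  d <- diversity_indices(even)
  expect_equal(unname(d["simpson_diversity"]), 0.9)   # 1 - 10 * 0.1^2
  expect_equal(unname(d["gini_diversity"]), 1)        # Gini coefficient 0
  one <- c(0, 7, 0)
  d1 <- diversity_indices(one)
  expect_equal(unname(d1["simpson_diversity"]), 0)
  expect_error(diversity_indices(c(0, 0)), "all-zero")
})

test_that("QC removes cells violating any single rule", {
  withr::with_seed(2, {
    counts <- matrix(rpois(300 * 50, 30), 300, 50,
                     dimnames = list(c(sprintf("GENE%03d", 1:280),
                                       sprintf("MT-%02d", 1:10),
                                       sprintf("RPS%02d", 1:10)),
                                     sprintf("C%02d", 1:50)))
  })
  # cell 1: 30% mitochondrial counts
  tot <- sum(counts[, 1])
  counts[281:290, 1] <- round(0.3 * tot / (0.7 * 10) * counts[281:290, 1] /
                                mean(counts[281:290, 1]) * 10)
  m <- sc_qc_metrics(counts)
  stopifnot(m$mito_fraction[1] > 0.25)
  # cell 2: only 150 detected genes
  counts[151:300, 2] <- 0
  qc <- qc_filter(counts, band = NULL, min_diversity = NULL)
  expect_false("C01" %in% qc$kept)
  expect_false("C02" %in% qc$kept)
  # gene filtering drops mito/ribo genes
  expect_false(any(grepl("^MT-|^RPS", rownames(qc$counts))))
})

test_that("QC with all rules disabled keeps every cell", {
  sim <- generate_single_cell(sc_sim_config(n_cells = 100,
                                            fraction_low_quality = 0,
                                            seed = 3))
  qc <- qc_filter(sim$counts, mito_max = NULL, ribo_max = NULL, band = NULL,
                  min_features = NULL, min_diversity = NULL,
                  min_cells_per_gene = NULL)
  expect_setequal(qc$kept, colnames(sim$counts))
})

test_that("QC report evaluates every rule on pre-filter statistics", {
  sim <- generate_single_cell(sc_sim_config(n_cells = 300, seed = 4))
  qc <- qc_filter(sim$counts)
  rules <- grep("^fail_", names(qc$report), value = TRUE)
  expect_gt(length(rules), 3)
  # kept = no rule fails; this is exactly order independence
  fails <- as.matrix(qc$report[, rules])
  expect_identical(qc$report$kept, rowSums(fails) == 0)
})

test_that("normalization fixes totals to 1000 before the log transform", {
  counts <- matrix(c(2, 3, 5, 1, 1, 2), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  norm <- sc_normalize(counts)
  expect_equal(norm[, "c1"], log1p(c(a = 200, b = 300, c = 500)))
  expect_equal(unname(colSums(expm1(norm))), c(1000, 1000), tolerance = 1e-9)
  zero <- cbind(counts, c3 = c(0, 0, 0))
  expect_error(sc_normalize(zero), "c3")
})

test_that("module scores are zero on constant data and seeded", {
  const <- matrix(1, 50, 20, dimnames = list(sprintf("g%02d", 1:50),
                                             sprintf("c%02d", 1:20)))
  ms <- module_score(const, sprintf("g%02d", 1:5), n_bins = 5, n_ctrl = 20,
                     seed = 1)
  expect_true(all(abs(ms$score) < 1e-12))
  sim <- generate_single_cell(sc_sim_config(n_cells = 150, seed = 5))
  norm <- sc_normalize(qc_filter(sim$counts)$counts)
  a <- module_score(norm, rownames(norm)[1:20], seed = 7)
  b <- module_score(norm, rownames(norm)[1:20], seed = 7)
  expect_identical(a$score, b$score)
  expect_error(module_score(norm, c("absent1", "absent2")), "absent")
})

test_that("the planted program scores highest in its cluster", {
  sim <- generate_single_cell(sc_sim_config(n_cells = 600, seed = 6))
  qc <- qc_filter(sim$counts)
  norm <- sc_normalize(qc$counts)
  cl <- sim$cells$cluster[sim$cells$barcode %in% qc$kept]
  ms <- module_score(norm, intersect(sim$truth$program_genes, rownames(norm)),
                     seed = 8)
  means <- tapply(ms$score, cl, mean)
  expect_identical(names(which.max(means)), "cl1")
  p <- stats::wilcox.test(ms$score[cl == "cl1"], ms$score[cl != "cl1"],
                          alternative = "greater")$p.value
  expect_lt(p, 1e-6)
})

test_that("cluster markers rank an exclusive gene first and calibrate under null labels", {
  withr::with_seed(9, {
    norm <- matrix(rnorm(60 * 90), 60, 90,
                   dimnames = list(sprintf("g%02d", 1:60),
                                   sprintf("c%02d", 1:90)))
    labels <- rep(c("A", "B", "C"), each = 30)
    norm["g01", labels == "A"] <- norm["g01", labels == "A"] + 5
  })
  mk <- cluster_markers(norm, labels)
  expect_identical(mk$gene[mk$cluster == "A"][1], "g01")
  # permuted labels: at most ~5% raw p < 0.05
  withr::with_seed(10, perm <- sample(labels))
  mk0 <- cluster_markers(norm[-1, ], perm)
  expect_lte(mean(mk0$p_value < 0.05), 0.08)
  expect_error(cluster_markers(norm, rep("A", 90)), ">= 2 clusters")
})

test_that("marker Wilcoxon agrees with the exact enumeration oracle on small clusters", {
  withr::with_seed(11, {
    x <- matrix(rnorm(3 * 12), 3, 12,
                dimnames = list(c("g1", "g2", "g3"), sprintf("c%02d", 1:12)))
    labels <- rep(c("A", "B"), each = 6)
  })
  mk <- cluster_markers(x, labels)
  for (g in rownames(x)) {
    p_impl <- mk$p_value[mk$cluster == "A" & mk$gene == g]
    p_or <- wilcox_oracle(x[g, labels == "A"], x[g, labels == "B"])
    expect_equal(p_impl, p_or, tolerance = 1e-10)
  }
})

test_that("cluster score summaries take the unclipped maximum of subcluster means", {
  scores <- tibble::tibble(barcode = sprintf("c%d", 1:6),
                           score = c(0.1, 0.1, 0.4, 0.4, -0.2, -0.5))
  labels <- c("s1", "s1", "s2", "s2", "t1", "t2")
  major <- c(s1 = "B", s2 = "B", t1 = "NK", t2 = "NK")
  out <- summarize_cluster_scores(scores, labels, major)
  expect_equal(out$max_score[out$major_type == "B"], 0.4)
  expect_identical(out$top_subcluster[out$major_type == "B"], "s2")
  # negative means: max taken as-is
  expect_equal(out$max_score[out$major_type == "NK"], -0.2)
  # single subcluster reports its own mean
  one <- summarize_cluster_scores(scores[1:2, ], labels[1:2], major)
  expect_equal(one$max_score, 0.1)
})
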