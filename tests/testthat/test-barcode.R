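test_that("enrichment threshold is the max of the averaged baselines", {
  # a table whose averaged-baseline maximum frequency is exactly 0.0077:
  # the top clone holds 77 of 10000 reads, all others fewer
  base <- c(77, rep(49, 201), 74)
  counts <- cbind(baseline_1 = base, baseline_2 = base,
                  drug_rep1 = rev(base))
  tb <- barcode_table(counts, roles = c("baseline", "baseline", "drug"))
  expect_equal(enrichment_threshold(tb), 0.0077)

  # element-wise averaging: [[0.5, 0.5], [0.3, 0.7]] -> [0.4, 0.6] -> 0.6
  counts2 <- cbind(b1 = c(50, 50), b2 = c(30, 70), t1 = c(10, 90))
  tb2 <- barcode_table(counts2, roles = c("baseline", "baseline", "drug"))
  expect_equal(enrichment_threshold(tb2), 0.6)

  # a single baseline: its own maximum
  tb3 <- barcode_table(counts2[, c(1, 3)], roles = c("baseline", "drug"))
  expect_equal(enrichment_threshold(tb3), 0.5)

  tb4 <- barcode_table(counts2, roles = c("drug", "drug", "drug"))
  expect_error(enrichment_threshold(tb4), "baseline")
})

test_that("enrichment calling is strict and depth-invariant", {
  counts <- cbind(b1 = c(60, 40), b2 = c(60, 40), t1 = c(60, 40),
                  t2 = c(80, 20))
  tb <- barcode_table(counts, roles = c("baseline", "baseline", "t", "t"))
  res <- call_enriched(tb)
  # treated sample identical to baseline: nothing enriched; a barcode at
  # exactly the threshold (0.6) is not called
  expect_length(res$enriched$t1, 0)
  expect_identical(res$enriched$t2, rownames(tb)[1])

  # rescaling counts (sequencing depth) changes nothing
  tb10 <- barcode_table(counts * 10, roles = attr(tb, "roles"))
  res10 <- call_enriched(tb10)
  expect_identical(res$enriched, res10$enriched)
})

test_that("planted clones are recovered with high sensitivity", {
  spec <- barcode_sim_spec()
  st <- rowMeans(vapply(1:8, function(s)
    barcode_recovery_stats(generate_barcode_experiment(spec, seed = s)),
    numeric(4)))
  expect_gte(st[["sensitivity"]], 0.85)
  expect_lte(st[["false_call"]], 0.05)
})

test_that("Shannon diversity has its analytic anchors", {
  expect_equal(shannon_diversity(1), 0)
  expect_equal(shannon_diversity(rep(1 / 100, 100)), log(100))
  expect_equal(shannon_diversity(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(round(shannon_diversity(c(2, 1, 1)), 4), 1.0397)
  # invariant to relabeling; zero frequencies contribute nothing
  expect_equal(shannon_diversity(c(0.25, 0.25, 0.5)),
               shannon_diversity(c(0.5, 0, 0.25, 0.25)))
})

test_that("selection depresses diversity below baseline", {
  tb <- generate_barcode_experiment(barcode_sim_spec(), seed = 12)
  f <- barcode_frequencies(tb)
  H <- apply(f, 2, shannon_diversity)
  roles <- attr(tb, "roles")
  expect_gt(mean(H[roles == "baseline"]), mean(H[roles != "baseline"]))
})

test_that("correlation matrix behaves as a rank statistic", {
  tb <- generate_barcode_experiment(barcode_sim_spec(n_barcodes = 800),
                                    seed = 13)
  res <- call_enriched(tb)
  corr <- replicate_correlation(res, tb)
  expect_equal(diag(corr), setNames(rep(1, ncol(tb)), colnames(tb)))
  expect_equal(corr, t(corr))

  # a strictly increasing transform of one sample leaves Spearman at 1
  f <- barcode_frequencies(tb)[res$union, ]
  expect_equal(cor(f[, 3], f[, 3]^3 + f[, 3], method = "spearman"), 1)

  few <- barcode_table(cbind(b = c(60, 40), t = c(90, 10)),
                       roles = c("baseline", "t"))
  resf <- call_enriched(few)
  expect_warning(replicate_correlation(resf, few), "underpowered")
})

test_that("clustering groups samples by condition", {
  # identical samples merge at height zero first
  counts <- cbind(b = c(10, 30, 60), s1 = c(60, 30, 10), s2 = c(60, 30, 10),
                  s3 = c(5, 95, 0))
  tb <- barcode_table(counts, roles = c("baseline", "a", "a", "b"))
  cl <- cluster_enriched(call_enriched(tb, threshold = 0.05), tb)
  expect_equal(min(cl$col_hclust$height), 0)
  first_merge <- cl$col_hclust$merge[1, ]
  expect_setequal(colnames(counts)[-first_merge], c("s1", "s2"))

  # single barcode: single-leaf "tree"
  one <- barcode_table(cbind(b = c(60, 40), t = c(10, 90)),
                       roles = c("baseline", "t"))
  r1 <- call_enriched(one)
  cl1 <- cluster_enriched(r1, one)
  expect_null(cl1$row_hclust)
  expect_identical(cl1$row_order, 1L)

  # planted two-condition experiments split by condition at the top
  spec <- barcode_sim_spec(n_barcodes = 1000, n_conditions = 2,
                           n_replicates_per_condition = 3,
                           selection_overlap = 0)
  hits <- vapply(1:10, function(s) {
    tbx <- generate_barcode_experiment(spec, seed = 100 + s)
    resx <- call_enriched(tbx)
    # cluster the treated samples only (baselines sit apart trivially)
    treated <- grep("cond", colnames(tbx))
    tbt <- barcode_table(unclass(tbx)[, treated],
                         roles = attr(tbx, "roles")[treated])
    clx <- cluster_enriched(resx, tbt)
    sub <- cutree(clx$col_hclust, k = 2)
    cond <- sub("_rep.*", "", colnames(tbt))
    # bijective condition <-> cluster assignment at the top split
    length(unique(sub)) == 2 && length(unique(paste(sub, cond))) == 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
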