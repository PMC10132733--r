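test_that("annotation preserves input order and reports a remainder", {
  cat1 <- simulate_gene_catalog(200, seed = 101)
  ids <- cat1$gene_id[c(5, 2, 9)]
  tab <- annotate_list(ids, cat1)
  expect_equal(tab$gene_id, ids)
  expect_length(attr(tab, "remainder"), 0)
  expect_warning(tab2 <- annotate_list(c(ids, "missing1"), cat1), "missing")
  expect_equal(nrow(tab2), 3L)
  expect_equal(attr(tab2, "remainder"), "missing1")
  expect_warning(tab3 <- annotate_list(c(ids, ids), cat1), "duplicate")
  expect_equal(nrow(tab3), 3L)
  expect_error(annotate_list(c(ids, sprintf("x%d", 1:7)), cat1,
                             strict = TRUE),
               class = "lenbias_unannotated")
})

test_that("sample skewness matches direct moment computation", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0, tolerance = 1e-12)
  expect_equal(sample_skewness(c(1, 1, 4)), 2 / 2^1.5, tolerance = 1e-12)
  set.seed(102)
  x <- rexp(50)
  expect_equal(sample_skewness(-x), -sample_skewness(x), tolerance = 1e-12)
  expect_error(sample_skewness(c(1, 2)), class = "lenbias_invalid_argument")
  expect_error(sample_skewness(rep(3, 10)),
               class = "lenbias_undefined_statistic")
})

test_that("comparing a list with itself is a perfect null", {
  cat1 <- simulate_gene_catalog(300, seed = 103)
  tab <- annotate_list(cat1$gene_id[1:50], cat1)
  rep <- compare_structures(tab, tab)
  expect_true(all(rep$tests$p_value == 1))
  expect_true(all(rep$tests$mean_diff == 0))
})

test_that("background bin fractions sum to one and reconstruct counts", {
  cat1 <- simulate_gene_catalog(2000, seed = 104)
  tab <- annotate_list(cat1$gene_id[1:100], cat1)
  rep <- genome_background_comparison(tab, cat1)
  expect_equal(sum(rep$exon_bins$observed), 1, tolerance = 1e-9)
  expect_equal(sum(rep$exon_bins$expected), 1, tolerance = 1e-9)
  expect_equal(rep$exon_bins$observed * nrow(tab),
               round(rep$exon_bins$observed * nrow(tab)), tolerance = 1e-9)
})

test_that("a degenerate single-bin list is rejected by the chi-square", {
  cat1 <- simulate_gene_catalog(2000, seed = 105)
  minexon <- cat1[which.min(cat1$exon_count), ]
  tab <- minexon[rep(1, 100), ]
  rep <- genome_background_comparison(tab, cat1)
  bin1 <- rep$exon_bins$bin == as.character(minexon$exon_count)
  expect_equal(rep$exon_bins$observed[bin1], 1)
  expect_lt(rep$chisq$p_value, 1e-10)
})

test_that("uniformly drawn lists are unbiased against the background", {
  cat1 <- simulate_gene_catalog(3000, seed = 106)
  set.seed(106)
  ps <- replicate(40, {
    tab <- annotate_list(sample(cat1$gene_id, 120), cat1)
    genome_background_comparison(tab, cat1)$tests$p_value[1]
  })
  # p-values roughly uniform: no mass collapse at either end
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("a small catalog cannot serve as background", {
  cat1 <- simulate_gene_catalog(200, seed = 107)
  tab <- annotate_list(cat1$gene_id[1:50], cat1)
  expect_error(genome_background_comparison(tab, cat1),
               class = "lenbias_insufficient_data")
})

test_that("bias reports survive a JSON round-trip", {
  cat1 <- simulate_gene_catalog(2000, seed = 108)
  taba <- annotate_list(cat1$gene_id[1:80], cat1)
  tabb <- annotate_list(cat1$gene_id[101:180], cat1)
  pair <- compare_structures(taba, tabb)
  bg <- genome_background_comparison(taba, cat1)
  for (rep in list(pair, bg)) {
    path <- withr::local_tempfile(fileext = ".json")
    write_bias_report(rep, path)
    back <- read_bias_report(path)
    expect_equal(back$tests$p_value, rep$tests$p_value, tolerance = 1e-12)
    if (!is.null(rep$exon_bins))
      expect_equal(back$exon_bins$observed, rep$exon_bins$observed,
                   tolerance = 1e-12)
    if (!is.null(rep$summary))
      expect_equal(back$summary$mean, rep$summary$mean, tolerance = 1e-12)
  }
})
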