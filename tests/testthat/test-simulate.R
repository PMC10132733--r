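test_that("recorded per-cell totals equal the realized column sums", {
  sim <- tiny_sim(1)
  exp <- sim$experiment
  expect_silent(validate_paired_experiment(exp))
  expect_identical(exp$cells$total_counts,
                   as.integer(Matrix::colSums(exp$counts)))
  expect_identical(exp$cells$n_features,
                   as.integer(Matrix::colSums(exp$counts > 0)))
})

test_that("mito/ribo genes are absent from every single-nucleus cell", {
  sim <- tiny_sim(2)
  exp <- sim$experiment
  comp <- exp$genes$is_mito | exp$genes$is_ribo
  nuc <- exp$cells$technique == "single_nucleus"
  expect_true(sum(comp) > 0)
  expect_equal(sum(exp$counts[comp, nuc]), 0)
  expect_gt(sum(exp$counts[comp, !nuc]), 0)
})

test_that("capture weights are monotone in exon count when bias is planted", {
  cat1 <- simulate_gene_catalog(500, seed = 3)
  tr <- tiny_truth(3, n_genes = 500)
  w <- capture_weights(cat1, tr)
  keep <- !(cat1$is_mito | cat1$is_ribo)
  ord <- order(cat1$exon_count[keep])
  expect_true(all(diff(w$single_nucleus[keep][ord]) >= 0))
  expect_true(all(w$single_cell == 1))
  # amplitude 1 flattens the curve entirely
  w0 <- capture_weights(cat1, tiny_truth(3, n_genes = 500,
                                         bias_amplitude = 1))
  expect_true(all(w0$single_nucleus[keep] == 1))
})

test_that("simulation is deterministic and seed-isolated", {
  expect_identical(tiny_sim(5)$experiment$counts,
                   tiny_sim(5)$experiment$counts)
  expect_false(identical(tiny_sim(5)$experiment$counts,
                         tiny_sim(6)$experiment$counts))
})

test_that("null generator leaves per-gene count shares balanced", {
  # two-proportion z statistics across genes should look standard normal
  sim <- null_experiment(simulate_gene_catalog(600, seed = 9),
                         tiny_truth(9, n_genes = 600, n_cells = 150))
  exp <- sim$experiment
  comp <- exp$genes$is_mito | exp$genes$is_ribo
  sc <- exp$cells$technique == "single_cell"
  a <- Matrix::rowSums(exp$counts[!comp, sc])
  b <- Matrix::rowSums(exp$counts[!comp, !sc])
  na <- sum(a); nb <- sum(b)
  p <- (a + b) / (na + nb)
  keep <- p > 0 & (a + b) > 20
  z <- (a / na - b / nb)[keep] /
    sqrt((p * (1 - p) * (1 / na + 1 / nb))[keep])
  expect_lt(abs(mean(z)), 0.2)
  expect_gt(sd(z), 0.8)
  expect_lt(sd(z), 1.3)
})

test_that("planted bias enriches long genes in the nucleus pooled share", {
  hits <- 0L
  for (seed in 1:10) {
    sim <- tiny_sim(seed + 40, n_genes = 600, n_cells = 120)
    exp <- sim$experiment
    comp <- exp$genes$is_mito | exp$genes$is_ribo
    sc <- exp$cells$technique == "single_cell"
    a <- Matrix::rowSums(exp$counts[, !sc]) + 0.5  # nucleus
    b <- Matrix::rowSums(exp$counts[, sc]) + 0.5
    ratio <- (a / sum(a)) / (b / sum(b))
    ratio[comp] <- NA
    top <- order(ratio, decreasing = TRUE)[1:100]
    bottom <- order(ratio)[1:100]
    if (mean(exp$genes$exon_count[top]) >
        mean(exp$genes$exon_count[bottom])) hits <- hits + 1L
  }
  expect_gte(hits, 10L * 0.95 - 1L)  # >= 95% of seeds (allowing one miss)
})

test_that("invalid generator arguments are rejected", {
  expect_error(simulation_truth(bias_amplitude = 0.5),
               class = "lenbias_invalid_argument")
  expect_error(simulation_truth(marker_fold = 1),
               class = "lenbias_invalid_argument")
  cat1 <- simulate_gene_catalog(100, seed = 1)
  expect_error(simulate_paired_experiment(cat1, tiny_truth(1, n_genes = 200)),
               class = "lenbias_invalid_argument")
})
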