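test_that("the four-gene worked example gives ES = 2 at alpha = 0", {
  expr <- c(4, 3, 2, 1)
  expect_equal(ssgsea_score(expr, c(TRUE, TRUE, FALSE, FALSE), alpha = 0), 2,
               tolerance = 1e-12)
  # bottom-2 set mirrors to -2
  expect_equal(ssgsea_score(expr, c(FALSE, FALSE, TRUE, TRUE), alpha = 0), -2,
               tolerance = 1e-12)
})

test_that("scores match the brute-force ECDF oracle on random instances", {
  set.seed(91)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    expr <- rnorm(n)
    if (i %% 3 == 0) expr <- round(expr, 1)  # induce ties
    k <- sample(2:(n - 2), 1)
    in_set <- seq_len(n) %in% sample.int(n, k)
    alpha <- sample(c(0, 0.25, 0.5, 1), 1)
    expect_equal(ssgsea_score(expr, in_set, alpha),
                 brute_ssgsea(expr, in_set, alpha), tolerance = 1e-10)
  }
})

test_that("alpha = 0 scores are invariant under monotone transforms", {
  set.seed(92)
  for (i in 1:30) {
    expr <- rnorm(30)
    in_set <- seq_len(30) %in% sample.int(30, 8)
    base <- ssgsea_score(expr, in_set, alpha = 0)
    expect_equal(ssgsea_score(exp(expr), in_set, alpha = 0), base,
                 tolerance = 1e-10)
    expect_equal(ssgsea_score(rank(expr), in_set, alpha = 0), base,
                 tolerance = 1e-10)
  }
})

test_that("degenerate sets are rejected", {
  expect_error(ssgsea_score(1:4, rep(TRUE, 4)),
               class = "lenbias_invalid_argument")
  expect_error(ssgsea_score(1:4, rep(FALSE, 4)),
               class = "lenbias_invalid_argument")
})

test_that("experiment scoring normalizes NES into a width-1 interval", {
  sim <- tiny_sim(93, n_genes = 200, n_cells = 40)
  exp <- sim$experiment
  norm <- log_normalize(exp)
  set <- exp$genes$gene_id[order(exp$genes$exon_count)][1:30]
  res <- score_experiment(norm, exp$cells, set)
  expect_equal(max(res$nes) - min(res$nes), 1, tolerance = 1e-12)
  expect_equal(res$es / (max(res$es) - min(res$es)), res$nes,
               tolerance = 1e-12)
  expect_equal(length(res$es), ncol(exp$counts))
})

test_that("each cell's score ignores the other cells' labels", {
  sim <- tiny_sim(94, n_genes = 150, n_cells = 20)
  exp <- sim$experiment
  norm <- log_normalize(exp)
  set <- exp$genes$gene_id[1:20]
  res1 <- score_experiment(norm, exp$cells, set)
  cells2 <- exp$cells
  set.seed(940)
  cells2$technique <- sample(cells2$technique)
  res2 <- score_experiment(norm, cells2, set)
  expect_equal(res1$es, res2$es, tolerance = 1e-12)
})

test_that("set members absent from the matrix are dropped with a message", {
  sim <- tiny_sim(95, n_genes = 150, n_cells = 20)
  norm <- log_normalize(sim$experiment)
  set <- c(sim$experiment$genes$gene_id[1:10], "NOT_A_GENE")
  expect_message(res <- score_experiment(norm, sim$experiment$cells, set),
                 "absent")
  expect_equal(res$n_set, 10L)
  expect_equal(res$n_dropped, 1L)
})
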