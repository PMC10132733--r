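test_that("depth/feature correlation passes on simulated data", {
  sim <- tiny_sim(51, n_genes = 500, n_cells = 200)
  rep <- linearity_check(sim$experiment, depth_window(250, 650))
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$r > 0.6))
  expect_true(all(rep$pass))
})

test_that("degenerate linearity inputs raise the documented errors", {
  sim <- tiny_sim(52, n_genes = 100, n_cells = 30)
  exp <- sim$experiment
  # collinear toy: force features proportional to depth
  exp$cells$n_features <- exp$cells$total_counts
  expect_equal(linearity_check(exp, depth_window(1, 1e6))$r, c(1, 1))
  exp$cells$n_features <- rep(50L, nrow(exp$cells))
  expect_error(linearity_check(exp, depth_window(1, 1e6)),
               class = "lenbias_insufficient_variation")
  expect_error(linearity_check(sim$experiment, depth_window(1, 2)),
               class = "lenbias_insufficient_data")
})

test_that("balanced subsample returns the exact requested composition", {
  sim <- tiny_sim(53, n_genes = 300, n_cells = 300)
  win <- depth_window(250, 650)
  sub <- balanced_subsample(sim$experiment, win, 100, seed = 9)
  expect_equal(ncol(sub$counts), 200L)
  expect_equal(as.numeric(table(sub$cells$technique)), c(100, 100))
  # totals strictly inside the window
  expect_true(all(sub$cells$total_counts > win$min_counts))
  expect_true(all(sub$cells$total_counts < win$max_counts))
  # gene order untouched
  expect_identical(sub$genes$gene_id, sim$experiment$genes$gene_id)
})

test_that("subsampling is seed-deterministic and identity at full pool size", {
  sim <- tiny_sim(54, n_genes = 300, n_cells = 150)
  win <- depth_window(250, 650)
  s1 <- balanced_subsample(sim$experiment, win, 80, seed = 4)
  s2 <- balanced_subsample(sim$experiment, win, 80, seed = 4)
  expect_identical(s1$cells$cell_id, s2$cells$cell_id)
  pool <- sim$experiment$cells
  n_in <- min(table(pool$technique[pool$total_counts > 250 &
                                     pool$total_counts < 650]))
  sub <- balanced_subsample(sim$experiment, win, n_in, seed = 1)
  # at full pool size the draw per technique is the whole in-window pool
  expect_setequal(
    sub$cells$cell_id[sub$cells$technique == "single_cell"],
    pool$cell_id[pool$technique == "single_cell" &
                   pool$total_counts > 250 & pool$total_counts < 650])
})

test_that("insufficient in-window cells is reported with available counts", {
  sim <- tiny_sim(55, n_genes = 300, n_cells = 50)
  err <- expect_error(
    balanced_subsample(sim$experiment, depth_window(250, 650), 1000),
    class = "lenbias_insufficient_data")
  expect_match(conditionMessage(err), "in-window")
})

test_that("subsampling leaves cluster proportions statistically unchanged", {
  ok <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    sim <- tiny_sim(seed + 60, n_genes = 300, n_cells = 300)
    sub <- balanced_subsample(sim$experiment, depth_window(250, 650), 150,
                              seed = seed)
    ps <- vapply(sort(unique(sim$experiment$cells$cluster)), function(cl) {
      x <- sum(sub$cells$cluster == cl)
      orig <- mean(sim$experiment$cells$cluster == cl)
      stats::binom.test(x, nrow(sub$cells), orig)$p.value
    }, numeric(1))
    if (all(ps > 0.05)) ok <- ok + 1L
  }
  expect_gte(ok, 0.9 * n_seeds - 1L)
})

test_that("window construction validates its bounds", {
  expect_error(depth_window(0, 10), class = "lenbias_invalid_argument")
  expect_error(depth_window(10, 10), class = "lenbias_invalid_argument")
})
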