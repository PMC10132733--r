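biased_markers <- function(seed, ...) {
  sim <- tiny_sim(seed, ...)
  exp <- sim$experiment
  norm <- log_normalize(exp)
  list(sim = sim, exp = exp, norm = norm,
       degs = find_technique_markers(norm, exp$cells, marker_filter(),
                                     genes = exp$genes))
}

test_that("low-expression and low-fold-change genes are never tested", {
  run <- biased_markers(71)
  exp <- run$exp
  norm <- run$norm
  sc <- exp$cells$technique == "single_cell"
  pct_sc <- Matrix::rowMeans(norm$values[, sc] > 0)
  pct_sn <- Matrix::rowMeans(norm$values[, !sc] > 0)
  low <- exp$genes$gene_id[pmax(pct_sc, pct_sn) < 0.25]
  expect_gt(length(low), 0)
  expect_false(any(run$degs$gene_id %in% low))
  expect_true(all(abs(run$degs$log_fc) >= 0.25))
})

test_that("Bonferroni adjustment multiplies by the number of tested genes", {
  run <- biased_markers(72)
  d <- run$degs[run$degs$group == "single_nucleus", ]
  m <- nrow(d)   # one record per tested gene per group
  expect_equal(d$p_adj, pmin(1, d$p_value * m), tolerance = 1e-12)
  expect_true(all(d$p_adj >= d$p_value))
  # sorted by adjusted p then effect size
  expect_true(!is.unsorted(d$p_adj))
})

test_that("a strongly nucleus-biased long gene surfaces as a nucleus marker", {
  run <- biased_markers(73, n_genes = 600, n_cells = 150)
  genes <- run$exp$genes
  long <- genes$gene_id[genes$exon_count >= 20 &
                          !(genes$is_mito | genes$is_ribo)]
  nuc <- run$degs[run$degs$group == "single_nucleus" &
                    run$degs$p_adj < 0.05 & run$degs$log_fc > 0, ]
  expect_gt(length(intersect(nuc$gene_id, long)), 0)
})

test_that("top marker selection honours n, direction and prefix exclusion", {
  run <- biased_markers(74, n_genes = 600, n_cells = 150)
  tops <- suppressWarnings(top_n_markers(run$degs, 50))
  expect_named(tops, c("single_cell", "single_nucleus"))
  expect_true(all(lengths(tops) <= 50))
  # excluded prefixes never appear in the whole-cell list
  sym <- run$exp$genes$symbol[match(tops$single_cell,
                                    run$exp$genes$gene_id)]
  expect_false(any(grepl("^(mt-|Rpl|Rps)", sym)))
  # with exclusion off, compartment genes dominate the whole-cell list
  f_off <- marker_filter(exclude_prefixes = character())
  raw <- suppressWarnings(top_n_markers(run$degs, 50, f_off))
  sym_raw <- run$exp$genes$symbol[match(raw$single_cell,
                                        run$exp$genes$gene_id)]
  expect_gt(sum(grepl("^(mt-|Rpl|Rps)", sym_raw)), 0)
  # positive-only: every selected gene is upregulated in its group
  d <- run$degs
  for (g in names(tops)) {
    lfc <- d$log_fc[d$group == g][match(tops[[g]], d$gene_id[d$group == g])]
    expect_true(all(lfc > 0))
  }
})

test_that("asking for more markers than available warns and truncates", {
  run <- biased_markers(75, n_genes = 100, n_cells = 40)
  w <- testthat::capture_warnings(tops <- top_n_markers(run$degs, 5000))
  expect_match(w, "available", all = TRUE)
  expect_true(all(lengths(tops) < 5000))
})

test_that("a single-technique object cannot be scanned", {
  sim <- tiny_sim(76, n_genes = 100, n_cells = 20)
  exp <- sim$experiment
  keep <- exp$cells$technique == "single_cell"
  sub <- exp[, which(keep)]
  expect_error(find_technique_markers(log_normalize(sub), sub$cells),
               class = "lenbias_invalid_input")
})
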