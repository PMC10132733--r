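# Shared fixtures and independent oracles for the suite.

# Small biased / null experiments used across files. Sizes are kept small
# so each simulation takes well under a second.
tiny_truth <- function(seed, n_genes = 400L, n_cells = 80L,
                       bias_amplitude = 4, ...) {
  simulation_truth(seed = seed, n_genes = n_genes,
                   n_cells_per_technique = n_cells,
                   bias_amplitude = bias_amplitude,
                   libsize_log_mean = log(400), libsize_log_sd = 0.2, ...)
}

tiny_sim <- function(seed, ...) {
  tr <- tiny_truth(seed, ...)
  simulate_paired_experiment(
    simulate_gene_catalog(tr$n_genes, seed = seed + 1000L), tr)
}

# Independent enumeration oracle for the two-sided Wilcoxon rank-sum
# p-value: walks every assignment of nx observations to group x,
# computes the midrank sum with an explicit loop, and applies the
# doubled-tail definition.
enum_wilcoxon_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals); nx <- length(x)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  sums <- numeric(ncol(combos))
  for (k in seq_len(ncol(combos))) sums[k] <- sum(r[combos[, k]])
  lower <- sum(sums <= w_obs + 1e-9) / length(sums)
  upper <- sum(sums >= w_obs - 1e-9) / length(sums)
  min(1, 2 * min(lower, upper))
}

# Independent brute-force single-sample enrichment score: builds both
# weighted ECDFs explicitly, one ranked position at a time.
brute_ssgsea <- function(expr, in_set, alpha) {
  n <- length(expr)
  ord <- order(expr, decreasing = TRUE)
  pos <- rank(-expr)
  es <- 0
  denom_in <- 0
  for (g in which(in_set)) denom_in <- denom_in + (n + 1 - pos[g])^alpha
  cum_in <- 0; cum_out <- 0
  n_out <- n - sum(in_set)
  for (i in seq_len(n)) {
    g <- ord[i]
    if (in_set[g]) cum_in <- cum_in + (n + 1 - pos[g])^alpha
    else cum_out <- cum_out + 1
    es <- es + (cum_in / denom_in - cum_out / n_out)
  }
  es
}
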