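#' Parameters of the paired-experiment generator
#'
#' Collects every knob of the synthetic generator together with the seed,
#' forming the "truth ledger" against which downstream recovery of the
#' planted capture bias is judged. The nucleus technique's per-gene
#' capture weight is `1 + (bias_amplitude - 1) *
#' plogis((exon_count - bias_midpoint) * bias_steepness)`; the whole-cell
#' technique is flat (weight 1) unless `sc_length_tilt > 0`, which adds
#' an inverse-transcript-length preference for short genes.
#' `bias_amplitude = 1` defines the null generator with no technique
#' bias; mitochondrial and ribosomal-protein genes always have weight 0
#' in single-nucleus cells.
#'
#' @param seed Master seed for the whole generator.
#' @param n_genes Catalog size.
#' @param n_cells_per_technique Cells drawn per technique.
#' @param n_clusters Number of shared cell populations.
#' @param bias_midpoint Exon count at which the logistic capture curve is
#'   halfway up (default 10, the operational threshold between "short"
#'   and "long" genes).
#' @param bias_steepness Logistic slope per exon.
#' @param bias_amplitude Maximum nucleus/cell capture ratio for very long
#'   genes; must be >= 1, with 1 meaning no bias.
#' @param markers_per_cluster,marker_fold Number of marker genes planted
#'   per cluster and their expression fold change (> 1) inside their
#'   cluster.
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size
#'   parameters; defaults centre cells near 1,500 counts so most fall in
#'   a 1,100-2,000 depth window.
#' @param baseline_dispersion Gamma shape of the per-gene, per-cell
#'   expression perturbation (negative-binomial-style overdispersion);
#'   `Inf` disables it.
#' @param sc_length_tilt Optional strength of the whole-cell technique's
#'   short-gene preference (0 = flat).
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(seed = 1L,
                             n_genes = 5000L,
                             n_cells_per_technique = 3000L,
                             n_clusters = 3L,
                             bias_midpoint = 10,
                             bias_steepness = 0.7,
                             bias_amplitude = 4,
                             markers_per_cluster = 25L,
                             marker_fold = 4,
                             libsize_log_mean = log(1500),
                             libsize_log_sd = 0.15,
                             baseline_dispersion = 10,
                             sc_length_tilt = 0) {
  check_scalar_count(n_genes, "n_genes", 50L)
  check_scalar_count(n_cells_per_technique, "n_cells_per_technique", 2L)
  check_scalar_count(n_clusters, "n_clusters", 1L)
  if (bias_amplitude < 1)
    stop_lenbias("bias_amplitude must be >= 1 (1 = null generator)",
                 class = "lenbias_invalid_argument")
  if (marker_fold <= 1)
    stop_lenbias("marker_fold must be > 1", class = "lenbias_invalid_argument")
  stopifnot(baseline_dispersion > 0, sc_length_tilt >= 0,
            libsize_log_sd > 0, bias_steepness > 0)
  structure(list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_cells_per_technique = as.integer(n_cells_per_technique),
    n_clusters = as.integer(n_clusters),
    bias_midpoint = bias_midpoint,
    bias_steepness = bias_steepness,
    bias_amplitude = bias_amplitude,
    markers_per_cluster = as.integer(markers_per_cluster),
    marker_fold = marker_fold,
    libsize_log_mean = libsize_log_mean,
    libsize_log_sd = libsize_log_sd,
    baseline_dispersion = baseline_dispersion,
    sc_length_tilt = sc_length_tilt
  ), class = "simulation_truth")
}

#' Per-gene capture weights implied by a truth object
#'
#' The analytic (noise-free) capture-efficiency curve applied by the
#' generator, useful for checking monotonicity of the planted bias
#' without simulating counts.
#'
#' @param catalog A `gene_catalog`.
#' @param truth A `simulation_truth`.
#' @return A list with numeric vectors `single_cell` and
#'   `single_nucleus`, one weight per catalog gene.
#' @export
capture_weights <- function(catalog, truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  w_nuc <- 1 + (truth$bias_amplitude - 1) *
    stats::plogis((catalog$exon_count - truth$bias_midpoint) *
                    truth$bias_steepness)
  w_nuc[catalog$is_mito | catalog$is_ribo] <- 0
  w_cell <- rep(1, nrow(catalog))
  if (truth$sc_length_tilt > 0) {
    rel <- catalog$transcript_length / median(catalog$transcript_length)
    w_cell <- rel^(-truth$sc_length_tilt)
  }
  list(single_cell = w_cell, single_nucleus = w_nuc)
}

#' Simulate a paired single-cell / single-nucleus experiment
#'
#' Generates a sparse count matrix for two techniques sharing the same
#' cell populations. Per-gene base expression is log-normal; cluster
#' markers are multiplied by their fold change inside their cluster;
#' technique-specific capture weights come from [capture_weights()]
#' (logistic in exon count for the nucleus technique, flat for whole
#' cells, zero for mitochondrial/ribosomal genes in nuclei). Each cell's
#' library size is log-normal and its counts are drawn multinomially
#' from the normalized product of base x cluster x capture weights,
#' optionally perturbed per gene and cell by a mean-1 Gamma to emulate
#' negative-binomial overdispersion.
#'
#' @param catalog A `gene_catalog` with at least `truth$n_genes` rows
#'   (extra rows are ignored); usually from [simulate_gene_catalog()].
#' @param truth A `simulation_truth`.
#' @return A list with elements `experiment` (a `paired_experiment`) and
#'   `truth` (the input truth augmented with the planted
#'   `marker_table`).
#' @examples
#' tr <- simulation_truth(seed = 7, n_genes = 300,
#'                        n_cells_per_technique = 50)
#' sim <- simulate_paired_experiment(simulate_gene_catalog(300, 7), tr)
#' sim$experiment
#' @export
simulate_paired_experiment <- function(catalog, truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  validate_gene_catalog(catalog)
  if (nrow(catalog) < truth$n_genes)
    stop_lenbias("catalog has fewer rows than truth$n_genes",
                 class = "lenbias_invalid_argument")
  catalog <- catalog[seq_len(truth$n_genes), , drop = FALSE]
  G <- truth$n_genes

  with_seed(child_seed(truth$seed, 1), {
    base <- rlnorm(G, meanlog = 0, sdlog = 1.3)

    # cluster markers: disjoint gene sets, excluding compartment genes so
    # marker structure never aliases the planted technique bias
    eligible <- which(!(catalog$is_mito | catalog$is_ribo))
    n_mark <- min(truth$markers_per_cluster * truth$n_clusters,
                  length(eligible))
    marker_genes <- sample(eligible, n_mark)
    marker_table <- split(catalog$gene_id[marker_genes],
                          rep_len(seq_len(truth$n_clusters), n_mark))
    names(marker_table) <- sprintf("c%d", seq_len(truth$n_clusters))

    w <- capture_weights(catalog, truth)
    n_per <- truth$n_cells_per_technique
    n_cells <- 2L * n_per
    technique <- rep(c("single_cell", "single_nucleus"), each = n_per)
    cluster <- sprintf("c%d", sample.int(truth$n_clusters, n_cells,
                                         replace = TRUE))
    libsize <- pmax(1, round(rlnorm(n_cells, truth$libsize_log_mean,
                                    truth$libsize_log_sd)))

    # per-cluster expression profiles (base x marker fold change)
    cl_prof <- lapply(names(marker_table), function(cl) {
      p <- base
      idx <- match(marker_table[[cl]], catalog$gene_id)
      p[idx] <- p[idx] * truth$marker_fold
      p
    })
    names(cl_prof) <- names(marker_table)

    counts <- matrix(0L, nrow = G, ncol = n_cells)
    disp <- truth$baseline_dispersion
    for (j in seq_len(n_cells)) {
      pr <- cl_prof[[cluster[j]]] * w[[technique[j]]]
      if (is.finite(disp))
        pr <- pr * rgamma(G, shape = disp, rate = disp)
      counts[, j] <- rmultinom(1, size = libsize[j], prob = pr)
    }

    cells <- data.frame(
      cell_id = sprintf("%s_%04d", ifelse(technique == "single_cell",
                                          "sc", "sn"), seq_len(n_cells)),
      technique = technique,
      cluster = cluster,
      stringsAsFactors = FALSE
    )
    exp <- paired_experiment(counts, catalog, cells)
    truth$marker_table <- marker_table
    list(experiment = exp, truth = truth)
  })
}

#' Simulate a bias-free paired experiment
#'
#' Convenience wrapper around [simulate_paired_experiment()] that forces
#' `bias_amplitude = 1` (and no whole-cell length tilt), so the two
#' techniques are exchangeable up to the compartment-exclusive
#' mitochondrial/ribosomal genes. Used as the type-I-error harness for
#' every downstream between-technique statistic.
#'
#' @inheritParams simulate_paired_experiment
#' @return As [simulate_paired_experiment()].
#' @export
null_experiment <- function(catalog, truth) {
  truth$bias_amplitude <- 1
  truth$sc_length_tilt <- 0
  simulate_paired_experiment(catalog, truth)
}
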