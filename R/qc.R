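#' Quality-control filtering of a paired experiment
#'
#' Applies the standard object-construction filters in a single pass and
#' in a fixed order: first drop genes detected (nonzero) in fewer than
#' `min_cells_per_gene` cells, then drop cells expressing fewer than
#' `min_features_per_cell` of the retained genes. Defaults are the usual
#' 5 cells / 300 features. The order matters and is deliberate: gene
#' removal can lower a cell's feature count below threshold, and the
#' pass is not iterated to a fixed point.
#'
#' @param exp A `paired_experiment`.
#' @param min_cells_per_gene Minimum number of cells in which a gene must
#'   be detected.
#' @param min_features_per_cell Minimum number of detected genes a cell
#'   must retain.
#' @return The filtered `paired_experiment` with metadata re-derived.
#' @examples
#' tr <- simulation_truth(seed = 3, n_genes = 200,
#'                        n_cells_per_technique = 40)
#' sim <- simulate_paired_experiment(simulate_gene_catalog(200, 3), tr)
#' filter_matrix(sim$experiment, 5, 50)
#' @export
filter_matrix <- function(exp, min_cells_per_gene = 5L,
                          min_features_per_cell = 300L) {
  stopifnot(inherits(exp, "paired_experiment"))
  if (min_cells_per_gene < 0 || min_features_per_cell < 0)
    stop_lenbias("QC thresholds must be >= 0",
                 class = "lenbias_invalid_argument")
  keep_g <- Matrix::rowSums(exp$counts > 0) >= min_cells_per_gene
  if (!any(keep_g))
    stop_lenbias("QC removed every gene (min_cells_per_gene = ",
                 min_cells_per_gene, ")", class = "lenbias_empty_result")
  counts <- exp$counts[keep_g, , drop = FALSE]
  keep_c <- Matrix::colSums(counts > 0) >= min_features_per_cell
  if (!any(keep_c))
    stop_lenbias("QC removed every cell (min_features_per_cell = ",
                 min_features_per_cell, ")", class = "lenbias_empty_result")
  paired_experiment(counts[, keep_c, drop = FALSE],
                    exp$genes[keep_g, , drop = FALSE],
                    exp$cells[keep_c, , drop = FALSE])
}
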