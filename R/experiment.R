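#' Construct a paired single-cell / single-nucleus experiment
#'
#' The container every pipeline stage transforms: a sparse gene-by-cell
#' count matrix plus the gene catalog rows and per-cell metadata that
#' describe it. Row order of `counts` matches `genes`, column order
#' matches `cells`; each cell's `total_counts` / `n_features` are
#' recomputed from the matrix so they can never drift out of sync.
#'
#' @param counts A gene-by-cell matrix of non-negative integer counts
#'   (coerced to a sparse `dgCMatrix`).
#' @param genes Gene annotation data frame (see
#'   [simulate_gene_catalog()]); one row per matrix row.
#' @param cells Per-cell metadata with columns `cell_id`, `technique`
#'   (`"single_cell"` or `"single_nucleus"`) and optionally `cluster`;
#'   one row per matrix column.
#' @return A `paired_experiment` object.
#' @export
paired_experiment <- function(counts, genes, cells) {
  if (!inherits(counts, "CsparseMatrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (methods::is(counts, "lMatrix") || methods::is(counts, "nMatrix"))
    counts <- methods::as(counts, "dMatrix")
  if (nrow(counts) != nrow(genes))
    stop_lenbias("counts has ", nrow(counts), " rows but genes has ",
                 nrow(genes), class = "lenbias_format")
  if (ncol(counts) != nrow(cells))
    stop_lenbias("counts has ", ncol(counts), " columns but cells has ",
                 nrow(cells), class = "lenbias_format")
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != trunc(counts@x))))
    stop_lenbias("counts must be non-negative integers",
                 class = "lenbias_format")
  bad <- setdiff(unique(cells$technique), c("single_cell", "single_nucleus"))
  if (length(bad))
    stop_lenbias("unknown technique label: ", paste(bad, collapse = ", "),
                 class = "lenbias_format")
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$cell_id
  cells$total_counts <- as.integer(Matrix::colSums(counts))
  cells$n_features <- as.integer(Matrix::colSums(counts > 0))
  if (!"cluster" %in% names(cells)) cells$cluster <- "c1"
  structure(list(counts = counts,
                 genes = as.data.frame(genes),
                 cells = as.data.frame(cells)),
            class = "paired_experiment")
}

#' @export
dim.paired_experiment <- function(x) dim(x$counts)

#' @export
print.paired_experiment <- function(x, ...) {
  tab <- table(x$cells$technique)
  cat("paired_experiment: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells (", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      ")\n", sep = "")
  cat("  clusters:", paste(sort(unique(x$cells$cluster)), collapse = ", "),
      "\n")
  cat("  median depth:", median(x$cells$total_counts),
      " median features:", median(x$cells$n_features), "\n")
  invisible(x)
}

#' Subset a paired experiment
#'
#' @param x A `paired_experiment`.
#' @param i,j Gene (row) and cell (column) indices.
#' @param ... Ignored.
#' @return A `paired_experiment` restricted to the selected genes/cells,
#'   with per-cell totals re-derived.
#' @export
`[.paired_experiment` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  paired_experiment(x$counts[i, j, drop = FALSE],
                    x$genes[i, , drop = FALSE],
                    x$cells[j, , drop = FALSE])
}

#' Validate a paired experiment
#'
#' Re-checks the container invariants: matrix/metadata dimensions agree,
#' recorded per-cell totals and feature counts equal the column sums of
#' the count matrix, and technique labels are known.
#'
#' @param exp A `paired_experiment`.
#' @return `exp`, invisibly; errors name the violated invariant.
#' @export
validate_paired_experiment <- function(exp) {
  stopifnot(inherits(exp, "paired_experiment"))
  if (nrow(exp$counts) != nrow(exp$genes) ||
      ncol(exp$counts) != nrow(exp$cells))
    stop_lenbias("matrix and metadata dimensions disagree",
                 class = "lenbias_format")
  tc <- as.integer(Matrix::colSums(exp$counts))
  nf <- as.integer(Matrix::colSums(exp$counts > 0))
  if (!identical(tc, as.integer(exp$cells$total_counts)))
    stop_lenbias("recorded total_counts do not match column sums",
                 class = "lenbias_format")
  if (!identical(nf, as.integer(exp$cells$n_features)))
    stop_lenbias("recorded n_features do not match nonzero column counts",
                 class = "lenbias_format")
  validate_gene_catalog(exp$genes)
  invisible(exp)
}
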