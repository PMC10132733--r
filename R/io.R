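#' Write an experiment to Matrix Market + TSV sidecars
#'
#' Persists the standard on-disk exchange format: `matrix.mtx` (1-based
#' coordinate Matrix Market), `genes.tsv` (the full structural
#' annotation), `cells.tsv` (cell metadata) and, when a truth object is
#' supplied, `truth.json` with the generator parameters.
#'
#' @param exp A `paired_experiment`.
#' @param dir Output directory (created if missing).
#' @param truth Optional `simulation_truth` to persist alongside.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir, truth = NULL) {
  stopifnot(inherits(exp, "paired_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(exp$counts, file.path(dir, "matrix.mtx"))
  write.table(exp$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(exp$cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an experiment from Matrix Market + TSV sidecars
#'
#' Counterpart of [write_experiment()]. The three files must be mutually
#' consistent: matrix dimensions must match the sidecar row counts,
#' entries must be non-negative integers, and technique labels must be
#' known. Per-cell totals and feature counts are recomputed from the
#' matrix rather than trusted from `cells.tsv`.
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`,
#'   `cells.tsv`; alternatively pass the three paths explicitly.
#' @param mtx,genes,cells Explicit file paths (override `dir`).
#' @return A validated `paired_experiment`.
#' @export
read_experiment <- function(dir = NULL, mtx = NULL, genes = NULL,
                            cells = NULL) {
  if (!is.null(dir)) {
    mtx <- mtx %||% file.path(dir, "matrix.mtx")
    genes <- genes %||% file.path(dir, "genes.tsv")
    cells <- cells %||% file.path(dir, "cells.tsv")
  }
  for (f in c(mtx, genes, cells)) {
    if (!file.exists(f))
      stop_lenbias("missing input file: ", f, class = "lenbias_format")
  }
  counts <- Matrix::readMM(mtx)
  if (length(counts@x) && any(counts@x < 0))
    stop_lenbias("negative count entry in ", mtx, class = "lenbias_format")
  gtab <- read.delim(genes, stringsAsFactors = FALSE)
  ctab <- read.delim(cells, stringsAsFactors = FALSE)
  if (nrow(gtab) != nrow(counts))
    stop_lenbias(genes, " has ", nrow(gtab), " rows but matrix has ",
                 nrow(counts), " rows", class = "lenbias_format")
  if (nrow(ctab) != ncol(counts))
    stop_lenbias(cells, " has ", nrow(ctab), " rows but matrix has ",
                 ncol(counts), " columns", class = "lenbias_format")
  exp <- paired_experiment(counts, gtab, ctab)
  validate_paired_experiment(exp)
  exp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member gene
#' ids. Empty sets are rejected.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop_lenbias("missing GMT file: ", path, class = "lenbias_format")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L)
      stop_lenbias("GMT line with no members: ", f[1],
                   class = "lenbias_format")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}
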