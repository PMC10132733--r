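#' Log-normalize a count matrix
#'
#' The primary normalization: counts are scaled to a common per-cell
#' total (`scale_factor`, default 10,000) and log-transformed with a
#' pseudocount of one, `ln(1 + count / total * scale_factor)`. Zeros map
#' to zeros, so sparsity is preserved.
#'
#' @param exp A `paired_experiment`; every cell must have positive total
#'   counts.
#' @param scale_factor Common per-cell scale (counts per `scale_factor`).
#' @return A `normalized_matrix`: a list with the sparse gene-by-cell
#'   `values` matrix plus the `method` and `scale_factor` used.
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 2, 0), nrow = 3)
#' # per-cell relative counts scaled to 1e4, then log1p
#' log1p(m[, 1] / sum(m[, 1]) * 1e4)
#' @export
log_normalize <- function(exp, scale_factor = 1e4) {
  normalize_experiment(exp, method = "log_scaled",
                       scale_factor = scale_factor)
}

#' Alternate per-cell normalizations
#'
#' Two monotone alternates used to show that a recovered capture bias is
#' not an artifact of the log transform: `relative` (per-cell relative
#' counts times `scale_factor`, no log) and `sqrt_scaled` (square root
#' of the relative values). Within any cell all three schemes preserve
#' the rank order of genes.
#'
#' @inheritParams log_normalize
#' @param method One of `"log_scaled"`, `"relative"`, `"sqrt_scaled"`.
#' @return A `normalized_matrix`.
#' @export
alternate_normalize <- function(exp, method, scale_factor = 1e4) {
  if (length(method) != 1L ||
      !method %in% c("log_scaled", "relative", "sqrt_scaled"))
    stop_lenbias("unknown normalization method: ",
                 paste(method, collapse = ","),
                 class = "lenbias_invalid_argument")
  normalize_experiment(exp, method = method, scale_factor = scale_factor)
}

normalize_experiment <- function(exp, method, scale_factor) {
  stopifnot(inherits(exp, "paired_experiment"), scale_factor > 0)
  tot <- exp$cells$total_counts
  if (any(tot <= 0))
    stop_lenbias("cell(s) with zero total counts: ",
                 paste(head(exp$cells$cell_id[tot <= 0], 5), collapse = ", "),
                 class = "lenbias_invalid_input")
  m <- exp$counts
  # column-scale the nonzeros only; all three maps send 0 to 0
  j <- rep(seq_len(ncol(m)), diff(m@p))
  rel <- m@x / tot[j] * scale_factor
  m@x <- switch(method,
                log_scaled = log1p(rel),
                relative = rel,
                sqrt_scaled = sqrt(rel))
  structure(list(values = m, method = method, scale_factor = scale_factor),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix (", x$method, ", scale ", x$scale_factor, "): ",
      nrow(x$values), " genes x ", ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)
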