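#' Marker-test filters
#'
#' The standard pre-test filters and list-cleaning rules for marker
#' detection: a gene is tested only if expressed in at least `min_pct`
#' of the cells of one of the two groups and shows at least
#' `logfc_threshold` natural-log fold difference; marker lists keep
#' positive (upregulated) records only; and genes whose symbol matches
#' `exclude_prefixes` (mitochondrial `mt-`, ribosomal-protein
#' `Rpl`/`Rps`) are removed from the lists named in `exclude_from`,
#' because single-nucleus data cannot capture them and they would
#' otherwise dominate the whole-cell list.
#'
#' @param min_pct Minimum expressed fraction in the higher group.
#' @param logfc_threshold Minimum |log fold change| (natural log).
#' @param positive_only Keep only upregulated records when selecting top
#'   markers.
#' @param exclude_prefixes Symbol prefixes removed from marker lists.
#' @param exclude_from Group labels whose lists get the prefix exclusion
#'   (default the whole-cell list, as the nucleus one cannot contain
#'   these genes); use `"all"` to clean every list.
#' @return A `marker_filter` list.
#' @export
marker_filter <- function(min_pct = 0.25, logfc_threshold = 0.25,
                          positive_only = TRUE,
                          exclude_prefixes = c("mt-", "Rpl", "Rps"),
                          exclude_from = "single_cell") {
  if (min_pct < 0 || min_pct > 1)
    stop_lenbias("min_pct must lie in [0, 1]",
                 class = "lenbias_invalid_argument")
  if (logfc_threshold < 0)
    stop_lenbias("logfc_threshold must be >= 0",
                 class = "lenbias_invalid_argument")
  structure(list(min_pct = min_pct, logfc_threshold = logfc_threshold,
                 positive_only = isTRUE(positive_only),
                 exclude_prefixes = exclude_prefixes,
                 exclude_from = exclude_from),
            class = "marker_filter")
}

# Group means of the (back-transformed) normalized values, used for the
# log fold change ln(mean + 1) difference. Log-normalized data is
# exponentiated back (expm1) first, the toolkit convention; the alternate
# monotone normalizations are averaged on their own scale.
.group_expr_mean <- function(values, idx, method) {
  if (method == "log_scaled") {
    sub <- values[, idx, drop = FALSE]
    sub@x <- expm1(sub@x)
    Matrix::rowMeans(sub)
  } else {
    Matrix::rowMeans(values[, idx, drop = FALSE])
  }
}

# One-vs-rest marker scan shared by the Wilcoxon and NB-GLM routes.
# `test_fun(gene_row_counts_or_values, in_idx, out_idx)` returns a p-value
# (or NA to flag non-convergence).
.scan_markers <- function(values, method, groups, filter, test_fun,
                          symbols = NULL) {
  groups <- as.character(groups)
  levels <- sort(unique(groups))
  out <- list()
  for (g in levels) {
    in_idx <- which(groups == g)
    out_idx <- which(groups != g)
    pct_in <- as.numeric(Matrix::rowMeans(values[, in_idx, drop = FALSE] > 0))
    pct_out <- as.numeric(Matrix::rowMeans(values[, out_idx, drop = FALSE] > 0))
    lfc <- log(.group_expr_mean(values, in_idx, method) + 1) -
      log(.group_expr_mean(values, out_idx, method) + 1)
    tested <- which(pmax(pct_in, pct_out) >= filter$min_pct &
                      abs(lfc) >= filter$logfc_threshold)
    if (!length(tested)) next
    p <- vapply(tested, function(i) test_fun(i, in_idx, out_idx), numeric(1))
    ok <- !is.na(p)
    if (any(!ok))
      warning(sum(!ok), " gene(s) failed to converge in group ", g,
              " and were skipped", call. = FALSE)
    tested <- tested[ok]; p <- p[ok]
    rec <- data.frame(
      gene_id = rownames(values)[tested],
      group = g,
      log_fc = as.numeric(lfc[tested]),
      p_value = p,
      p_adj = pmin(1, p * length(p)),
      pct_in = pct_in[tested],
      pct_out = pct_out[tested],
      stringsAsFactors = FALSE
    )
    if (!is.null(symbols)) rec$symbol <- symbols[tested]
    rec <- rec[order(rec$p_adj, -abs(rec$log_fc)), , drop = FALSE]
    out[[g]] <- rec
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), group = character(),
                      log_fc = numeric(), p_value = numeric(),
                      p_adj = numeric(), pct_in = numeric(),
                      pct_out = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("deg_table", "data.frame")
  res
}

#' Wilcoxon marker genes between the two techniques
#'
#' For every gene passing the expressed-fraction and log-fold-change
#' filters, tests the normalized expression of single-cell versus
#' single-nucleus cells with the Wilcoxon rank-sum test
#' ([wilcoxon_rank_sum()]) and Bonferroni-adjusts over the tested genes.
#' Records are produced for both directions (one per group) and sorted
#' by adjusted p then |log fold change|.
#'
#' @param norm A `normalized_matrix` (see [log_normalize()]).
#' @param cells Cell metadata with a `technique` column, aligned with
#'   the matrix columns.
#' @param filter A [marker_filter()].
#' @param genes Optional gene catalog used to attach symbols (needed for
#'   prefix exclusions in [top_n_markers()]).
#' @param group_by Metadata column defining the two-or-more groups to
#'   compare one-vs-rest (default `"technique"`).
#' @return A `deg_table` data frame: `gene_id`, `group`, `log_fc`
#'   (natural log, positive = up in `group`), `p_value`, `p_adj`,
#'   `pct_in`, `pct_out`, and `symbol` when a catalog was given.
#' @export
find_technique_markers <- function(norm, cells, filter = marker_filter(),
                                   genes = NULL, group_by = "technique") {
  stopifnot(inherits(norm, "normalized_matrix"))
  groups <- cells[[group_by]]
  if (length(unique(groups)) < 2L)
    stop_lenbias("need at least two groups in '", group_by, "'",
                 class = "lenbias_invalid_input")
  v <- norm$values
  dense <- as.matrix(v)
  test_fun <- function(i, in_idx, out_idx) {
    wilcoxon_rank_sum(dense[i, in_idx], dense[i, out_idx])$p_value
  }
  .scan_markers(v, norm$method, groups, filter, test_fun,
                symbols = genes$symbol[match(rownames(v), genes$gene_id)])
}

#' Negative-binomial GLM marker genes
#'
#' One-vs-rest differential expression on raw counts: for each tested
#' gene, counts are regressed on the group indicator with an
#' `ln(total_counts)` offset under a negative-binomial GLM. The
#' dispersion is estimated per gene by method of moments on a Poisson
#' full-model fit (floored at theta = 0.01), the model is refit once at
#' that theta, and significance comes from a likelihood-ratio chi-square
#' test with one degree of freedom. Genes failing to converge are
#' skipped with a warning. The same expressed-fraction / log-fold-change
#' prefilters and Bonferroni correction as the Wilcoxon route apply.
#'
#' @param exp A `paired_experiment` (raw counts).
#' @param group_by Metadata column defining the groups (default
#'   `"technique"`; use `"cluster"` for cluster markers).
#' @param filter A [marker_filter()].
#' @param min_cells_per_group Guard on group sizes (default 20).
#' @return A `deg_table` (see [find_technique_markers()]).
#' @export
nb_glm_markers <- function(exp, group_by = "technique",
                           filter = marker_filter(),
                           min_cells_per_group = 20L) {
  stopifnot(inherits(exp, "paired_experiment"))
  groups <- exp$cells[[group_by]]
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop_lenbias("need at least two groups", class = "lenbias_invalid_input")
  if (any(sizes < min_cells_per_group))
    stop_lenbias("every group needs >= ", min_cells_per_group, " cells",
                 class = "lenbias_invalid_input")
  norm <- log_normalize(exp)
  counts <- as.matrix(exp$counts)
  off <- log(exp$cells$total_counts)
  test_fun <- function(i, in_idx, out_idx) {
    .nb_lrt_p(counts[i, ], c(in_idx, out_idx), length(in_idx), off)
  }
  .scan_markers(norm$values, norm$method, groups, filter, test_fun,
                symbols = exp$genes$symbol)
}

# NB LRT p for one gene: cells reordered so the first n_in are the
# in-group. Returns NA on non-convergence.
.nb_lrt_p <- function(y_all, ord, n_in, off_all) {
  y <- y_all[ord]; off <- off_all[ord]
  x <- cbind(1, c(rep(1, n_in), rep(0, length(ord) - n_in)))
  tryCatch({
    fit0 <- suppressWarnings(
      glm.fit(x, y, family = poisson(), offset = off))
    mu <- fit0$fitted.values
    denom <- sum((y - mu)^2 - mu)
    theta <- if (denom <= 0) 1e6 else max(0.01, sum(mu^2) / denom)
    fam <- MASS::negative.binomial(theta)
    full <- suppressWarnings(glm.fit(x, y, family = fam, offset = off))
    null <- suppressWarnings(
      glm.fit(x[, 1, drop = FALSE], y, family = fam, offset = off))
    if (!full$converged || !null$converged) return(NA_real_)
    stat <- max(0, null$deviance - full$deviance)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }, error = function(e) NA_real_)
}

#' Select the top-n markers per group
#'
#' From a sorted `deg_table`, keeps (by default) only positive
#' upregulated records, removes genes whose symbol matches the excluded
#' prefixes from the lists named in the filter, and returns the first
#' `n` gene ids per group. A warning is issued when a group yields fewer
#' than `n`.
#'
#' @param records A `deg_table` from one of the marker scans.
#' @param n Markers to keep per group (default 100).
#' @param filter A [marker_filter()]; `exclude_prefixes`, `exclude_from`
#'   and `positive_only` are honoured.
#' @return Named list (one element per group) of gene-id vectors.
#' @export
top_n_markers <- function(records, n = 100L, filter = marker_filter()) {
  stopifnot(is.data.frame(records))
  if (filter$positive_only)
    records <- records[records$log_fc > 0, , drop = FALSE]
  lists <- split(records, records$group)
  lapply(lists, function(rec) {
    g <- rec$group[1]
    if ((identical(filter$exclude_from, "all") ||
         g %in% filter$exclude_from) &&
        length(filter$exclude_prefixes) && !is.null(rec$symbol)) {
      pat <- paste0("^(", paste(filter$exclude_prefixes, collapse = "|"), ")")
      rec <- rec[!grepl(pat, rec$symbol), , drop = FALSE]
    }
    if (nrow(rec) < n)
      warning("group ", g, ": only ", nrow(rec), " markers available (",
              n, " requested)", call. = FALSE)
    head(rec$gene_id, n)
  })
}
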