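#' Annotate a gene list with structural features
#'
#' Looks each gene id up in the structural catalog. Duplicated input ids
#' are deduplicated with a warning; ids missing from the catalog are
#' returned in a `remainder` attribute rather than silently dropped, and
#' escalate to an error under `strict` mode when they exceed 20% of the
#' input.
#'
#' @param gene_ids Character vector of gene ids.
#' @param catalog A `gene_catalog` indexed by `gene_id`.
#' @param strict Error (instead of warn) when more than 20% of ids are
#'   unannotated.
#' @return The catalog rows for the annotated genes, in input order,
#'   with attribute `remainder` holding the unannotated ids.
#' @export
annotate_list <- function(gene_ids, catalog, strict = FALSE) {
  validate_gene_catalog(catalog)
  if (anyDuplicated(gene_ids)) {
    warning("duplicate gene ids deduplicated", call. = FALSE)
    gene_ids <- unique(gene_ids)
  }
  idx <- match(gene_ids, catalog$gene_id)
  remainder <- gene_ids[is.na(idx)]
  if (length(remainder) > 0.2 * length(gene_ids)) {
    msg <- paste0(length(remainder), "/", length(gene_ids),
                  " gene ids missing from the catalog")
    if (strict) stop_lenbias(msg, class = "lenbias_unannotated")
    warning(msg, call. = FALSE)
  }
  out <- catalog[idx[!is.na(idx)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "remainder") <- remainder
  out
}

#' Sample skewness (adjusted Fisher-Pearson g1)
#'
#' `g1 = m3 / m2^(3/2)` with central-moment estimators
#' `mk = mean((x - mean(x))^k)`. Symmetric samples give 0; mirroring a
#' sample negates g1.
#'
#' @param values Numeric vector, `n >= 3`, nonzero variance.
#' @return The skewness `g1`.
#' @examples
#' sample_skewness(c(1, 1, 4))  # 2 / 2^1.5
#' @export
sample_skewness <- function(values) {
  if (length(values) < 3L)
    stop_lenbias("need at least 3 values", class = "lenbias_invalid_argument")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0)
    stop_lenbias("skewness undefined for zero-variance sample",
                 class = "lenbias_undefined_statistic")
  mean((values - m)^3) / m2^1.5
}

.structure_features <- c("exon_count", "transcript_length", "cds_length",
                         "genomic_span")

# Skewness for report tables: degenerate lists yield NA instead of the
# strict error, so a pathological input cannot abort a whole report.
.skewness_or_na <- function(v) {
  if (length(v) >= 3 && var(v) > 0) sample_skewness(v) else NA_real_
}

.list_summary <- function(tab) {
  do.call(rbind, lapply(.structure_features, function(f) {
    v <- tab[[f]]
    data.frame(feature = f, n = length(v), mean = mean(v),
               median = median(v), skewness = .skewness_or_na(v),
               stringsAsFactors = FALSE)
  }))
}

#' Compare the structural features of two gene lists
#'
#' For each structural feature (exon count, transcript length, CDS
#' length, genomic span): per-list mean, median and skewness, a
#' two-sample Wilcoxon rank-sum test between the lists, and density-
#' curve data for the exon-count distributions (with per-list means) for
#' plotting.
#'
#' @param table_a,table_b Structural tables from [annotate_list()]; by
#'   convention `a` is the single-nucleus list and `b` the single-cell
#'   list.
#' @param labels Length-2 labels for the two lists.
#' @return A `bias_report` with elements `summary` (per list x feature),
#'   `tests` (per feature: Wilcoxon statistic, p, mean difference a-b)
#'   and `density` (exon-count density curves per list).
#' @export
compare_structures <- function(table_a, table_b,
                               labels = c("single_nucleus", "single_cell")) {
  if (!nrow(table_a) || !nrow(table_b))
    stop_lenbias("both tables must be nonempty",
                 class = "lenbias_invalid_argument")
  sa <- .list_summary(table_a); sa$list <- labels[1]
  sb <- .list_summary(table_b); sb$list <- labels[2]
  tests <- do.call(rbind, lapply(.structure_features, function(f) {
    wt <- wilcoxon_rank_sum(table_a[[f]], table_b[[f]])
    data.frame(feature = f, statistic = wt$statistic,
               p_value = wt$p_value,
               mean_diff = mean(table_a[[f]]) - mean(table_b[[f]]),
               stringsAsFactors = FALSE)
  }))
  dens <- lapply(list(table_a, table_b), function(tab) {
    d <- stats::density(tab$exon_count, from = 0)
    list(x = d$x, y = d$y, mean = mean(tab$exon_count))
  })
  names(dens) <- labels
  structure(list(kind = "pairwise", labels = labels,
                 summary = rbind(sa, sb), tests = tests, density = dens),
            class = "bias_report")
}

#' Compare a gene list against the genome background
#'
#' Tests whether a gene list is structurally biased relative to the
#' whole catalog (the "host genome"): per feature, a Wilcoxon rank-sum
#' test of list values against all catalog values plus skewness of both;
#' and an exon-count bin table (default unit bins 1..70 plus a 70+ bin)
#' with the observed list fraction, the expected genome fraction and a
#' chi-square goodness-of-fit statistic.
#'
#' @param table A structural table from [annotate_list()].
#' @param catalog The full `gene_catalog`; must be at least 10x the list
#'   size.
#' @param bin_edges Upper bin edges for exon counts; counts above the
#'   last edge are pooled into an overflow bin.
#' @param exclude_list_from_background Drop the list's own members from
#'   the background before comparing.
#' @return A `bias_report` with elements `tests`, `skewness`,
#'   `exon_bins` (data frame with `bin`, `observed`, `expected`) and
#'   `chisq` (statistic, df, p).
#' @export
genome_background_comparison <- function(table, catalog,
                                         bin_edges = 1:70,
                                         exclude_list_from_background = FALSE) {
  validate_gene_catalog(catalog)
  background <- catalog
  if (exclude_list_from_background)
    background <- catalog[!catalog$gene_id %in% table$gene_id, , drop = FALSE]
  if (nrow(background) < 10L * nrow(table))
    stop_lenbias("catalog must be at least 10x the list size",
                 class = "lenbias_insufficient_data")
  tests <- do.call(rbind, lapply(.structure_features, function(f) {
    wt <- wilcoxon_rank_sum(table[[f]], background[[f]])
    data.frame(feature = f, statistic = wt$statistic, p_value = wt$p_value,
               list_mean = mean(table[[f]]),
               genome_mean = mean(background[[f]]),
               list_skewness = .skewness_or_na(table[[f]]),
               genome_skewness = .skewness_or_na(background[[f]]),
               stringsAsFactors = FALSE)
  }))
  breaks <- c(bin_edges - 0.5, max(bin_edges) + 0.5, Inf)
  labs <- c(sprintf("%d", bin_edges), sprintf("%d+", max(bin_edges) + 1))
  obs_n <- table(cut(table$exon_count, breaks, labels = labs))
  exp_p <- table(cut(background$exon_count, breaks, labels = labs))
  exon_bins <- data.frame(
    bin = labs,
    observed = as.numeric(obs_n) / nrow(table),
    expected = as.numeric(exp_p) / nrow(background),
    stringsAsFactors = FALSE
  )
  nonzero <- exon_bins$expected > 0
  stat <- nrow(table) * sum((exon_bins$observed[nonzero] -
                               exon_bins$expected[nonzero])^2 /
                              exon_bins$expected[nonzero])
  df <- sum(nonzero) - 1L
  structure(list(kind = "background", tests = tests, exon_bins = exon_bins,
                 chisq = list(statistic = stat, df = df,
                              p_value = pchisq(stat, df, lower.tail = FALSE))),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("bias_report (", x$kind, ")\n", sep = "")
  print(x$tests, digits = 4)
  invisible(x)
}

#' Serialize / restore a bias report
#'
#' JSON round-trip for [compare_structures()] /
#' [genome_background_comparison()] output.
#'
#' @param report A `bias_report`.
#' @param path Output / input file path.
#' @return `path` (write) or the restored `bias_report` (read).
#' @export
write_bias_report <- function(report, path) {
  stopifnot(inherits(report, "bias_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_bias_report
#' @export
read_bias_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("summary", "tests", "exon_bins"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.data.frame(obj[[nm]])
  structure(obj, class = "bias_report")
}
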