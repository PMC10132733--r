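#' Simulate a per-gene structural annotation catalog
#'
#' Draws a synthetic gene catalog whose structural features mimic a
#' mammalian genome: exon counts follow 1 + a negative binomial targeting
#' a genome-wide mean of about 8.8 exons per gene, per-exon lengths are
#' log-normal, the genomic span inflates the mature transcript length by
#' log-normal introns, and the CDS is a uniform fraction of the
#' transcript. A configurable fraction of genes is flagged mitochondrial
#' (forced single-exon, so transcript length equals genomic span) or
#' ribosomal-protein (at most 6 exons), carrying the mouse-style symbol
#' prefixes `mt-`, `Rpl`/`Rps` so prefix-based exclusions can be
#' exercised.
#'
#' @param n_genes Number of genes to draw (at least 50).
#' @param seed Integer seed; the same seed reproduces the catalog exactly.
#' @param exon_mean Mean of the negative-binomial draw added to the
#'   obligatory first exon. The default 7.8 targets a mean exon count of
#'   8.8, the mammalian genome-wide average.
#' @param exon_size Negative-binomial size (inverse dispersion) of the
#'   exon-count draw.
#' @param exon_len_meanlog,exon_len_sdlog Log-normal parameters of
#'   per-exon lengths in nucleotides.
#' @param intron_len_meanlog,intron_len_sdlog Log-normal parameters of
#'   per-intron lengths in nucleotides; a gene with `k` exons receives
#'   `k - 1` introns, so span inflation grows with exon count.
#' @param cds_frac_range CDS length as a uniform fraction of transcript
#'   length.
#' @param mito_frac,ribo_frac Fractions of genes flagged mitochondrial /
#'   ribosomal-protein. The flags are mutually exclusive.
#' @param symbol_style `"mouse"` (`mt-`, `Rpl`, `Rps`) or `"human"`
#'   (`MT-`, `RPL`, `RPS`) symbol prefixes.
#'
#' @return A `gene_catalog`: a data frame with one row per gene and
#'   columns `gene_id`, `symbol`, `exon_count`, `transcript_length`,
#'   `cds_length`, `genomic_span`, `is_mito`, `is_ribo`.
#' @examples
#' cat10k <- simulate_gene_catalog(1000, seed = 1)
#' mean(cat10k$exon_count)
#' @export
simulate_gene_catalog <- function(n_genes, seed = 1L,
                                  exon_mean = 7.8, exon_size = 2,
                                  exon_len_meanlog = log(180),
                                  exon_len_sdlog = 0.7,
                                  intron_len_meanlog = log(1500),
                                  intron_len_sdlog = 1,
                                  cds_frac_range = c(0.3, 0.9),
                                  mito_frac = 0.005, ribo_frac = 0.02,
                                  symbol_style = c("mouse", "human")) {
  check_scalar_count(n_genes, "n_genes", min = 50L)
  symbol_style <- match.arg(symbol_style)
  stopifnot(exon_mean > 0, exon_size > 0,
            length(cds_frac_range) == 2L, all(cds_frac_range > 0),
            all(cds_frac_range <= 1), mito_frac >= 0, ribo_frac >= 0,
            mito_frac + ribo_frac < 1)

  with_seed(seed, {
    n_genes <- as.integer(n_genes)
    exon_count <- 1L + rnbinom(n_genes, mu = exon_mean, size = exon_size)

    n_mito <- round(mito_frac * n_genes)
    n_ribo <- round(ribo_frac * n_genes)
    is_mito <- is_ribo <- rep(FALSE, n_genes)
    special <- sample.int(n_genes, n_mito + n_ribo)
    is_mito[special[seq_len(n_mito)]] <- TRUE
    is_ribo[special[n_mito + seq_len(n_ribo)]] <- TRUE
    # mitochondrial genes are intron-less; ribosomal-protein genes short
    exon_count[is_mito] <- 1L
    exon_count[is_ribo] <- pmin(exon_count[is_ribo], 6L)

    # exon/intron lengths drawn per gene; spans grow with exon count
    transcript_length <- vapply(exon_count, function(k) {
      sum(ceiling(rlnorm(k, exon_len_meanlog, exon_len_sdlog)))
    }, numeric(1))
    intron_total <- vapply(exon_count - 1L, function(k) {
      if (k == 0L) 0 else sum(ceiling(rlnorm(k, intron_len_meanlog,
                                             intron_len_sdlog)))
    }, numeric(1))
    genomic_span <- transcript_length + intron_total
    cds_length <- floor(runif(n_genes, cds_frac_range[1], cds_frac_range[2]) *
                          transcript_length)

    symbol <- sprintf("Gene%05d", seq_len(n_genes))
    pre <- if (symbol_style == "mouse") c("mt-", "Rpl", "Rps")
           else c("MT-", "RPL", "RPS")
    symbol[is_mito] <- sprintf("%sNd%d", pre[1], seq_len(sum(is_mito)))
    half <- seq_len(sum(is_ribo)) %% 2 == 0
    symbol[is_ribo] <- ifelse(half,
                              sprintf("%s%d", pre[2], seq_len(sum(is_ribo))),
                              sprintf("%s%d", pre[3], seq_len(sum(is_ribo))))

    out <- data.frame(
      gene_id = sprintf("G%06d", seq_len(n_genes)),
      symbol = symbol,
      exon_count = exon_count,
      transcript_length = as.integer(transcript_length),
      cds_length = as.integer(cds_length),
      genomic_span = as.integer(genomic_span),
      is_mito = is_mito,
      is_ribo = is_ribo,
      stringsAsFactors = FALSE
    )
    class(out) <- c("gene_catalog", "data.frame")
    out
  })
}

#' Validate a gene catalog
#'
#' Checks the structural invariants every catalog must satisfy:
#' `cds_length <= transcript_length <= genomic_span`, single-exon genes
#' have transcript length equal to genomic span, and the mitochondrial /
#' ribosomal flags are mutually exclusive.
#'
#' @param catalog A `gene_catalog` or plain data frame with the catalog
#'   columns.
#' @return The catalog, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_gene_catalog <- function(catalog) {
  need <- c("gene_id", "symbol", "exon_count", "transcript_length",
            "cds_length", "genomic_span", "is_mito", "is_ribo")
  missing <- setdiff(need, names(catalog))
  if (length(missing))
    stop_lenbias("catalog missing columns: ", paste(missing, collapse = ", "),
                 class = "lenbias_format")
  if (anyDuplicated(catalog$gene_id))
    stop_lenbias("duplicate gene_id in catalog", class = "lenbias_format")
  if (any(catalog$exon_count < 1L))
    stop_lenbias("exon_count must be >= 1", class = "lenbias_format")
  if (any(catalog$cds_length > catalog$transcript_length) ||
      any(catalog$transcript_length > catalog$genomic_span))
    stop_lenbias("length ordering violated: need cds <= transcript <= span",
                 class = "lenbias_format")
  one <- catalog$exon_count == 1L
  if (any(catalog$transcript_length[one] != catalog$genomic_span[one]))
    stop_lenbias("single-exon gene with transcript_length != genomic_span",
                 class = "lenbias_format")
  if (any(catalog$is_mito & catalog$is_ribo))
    stop_lenbias("is_mito and is_ribo are mutually exclusive",
                 class = "lenbias_format")
  invisible(catalog)
}
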