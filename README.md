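# lenbias

Single-cell RNA-seq reads the whole-cell mRNA pool; single-nucleus
RNA-seq reads only the nuclear pool. The two techniques capture genes at
systematically different rates: nuclei over-represent long, exon-rich
transcripts (roughly those with more than ~10 exons, which are retained
until splicing completes), under-represent short ones, and miss
mitochondrial and most ribosomal-protein transcripts entirely. This
capture bias propagates into marker lists, structural summaries and
pathway scores, so analyses run on the two techniques disagree for
technical, not biological, reasons.

`lenbias` is an R package for quantifying that bias. It provides:

* a **seeded simulator** of paired single-cell / single-nucleus count
  matrices with a *planted*, parameterized capture-efficiency curve —
  nucleus weight `1 + (A − 1)·logistic((exons − 10)·s)` per gene, zero
  for mitochondrial/ribosomal genes — plus a gene catalog whose exon
  counts target the genome-wide mean of ~8.8 exons per gene;
* the comparison pipeline: QC filtering (genes in ≥ 5 cells, cells with
  ≥ 300 features), log-normalization (`ln(1 + count/total × 10⁴)`) with
  monotone alternates, depth-window linearity diagnostics and a
  balanced 1,000-cells-per-technique subsample;
* **differential expression** between techniques or clusters by
  Wilcoxon rank-sum (exact enumeration for small samples, tie-corrected
  normal approximation otherwise) or a negative-binomial GLM with
  library-size offset and likelihood-ratio test, with the standard
  `min.pct` / log-fold-change prefilters, Bonferroni correction and
  `mt-`/`Rpl`/`Rps` list exclusions;
* **structural bias statistics**: per-list exon count, transcript/CDS
  length and genomic span summaries with Fisher–Pearson skewness,
  list-vs-list and list-vs-genome Wilcoxon tests, and an exon-count bin
  table (unit bins to 70, overflow beyond) with a chi-square
  goodness-of-fit against the genome background;
* per-cell **single-sample gene-set enrichment** (rank-weighted ECDF
  difference, α = 0.25, range-normalized NES) compared between
  techniques.

Because the simulator's bias is known, the pipeline's claims are
checkable: the test-suite verifies that the planted exon-count bias is
recovered in direction and significance, that the machinery has its
nominal type-I error on bias-free data, and that the recovered
direction is invariant to the normalization scheme.

## Worked example

A full default run — simulate 5,000 genes × 6,000 cells with a planted
amplitude-4 bias at 10 exons, QC, normalize, subsample to the balanced
2,000-cell object, Wilcoxon DEG between techniques, top-100 lists, and
the structural bias report:

```r
library(lenbias)
rep <- run_pipeline(run_config(seed = 42))
print(rep)
#> run_report (seed 42)
#>   input: 5000 genes x 6000 cells; after QC: 5000 x 6000
#>   balanced object: 2000 cells
#>   top markers: single_cell=100, single_nucleus=100
#>   planted bias recovery: mean exon diff 14.00 (p = 1.8e-34) -> recovered

print(rep$bias$pairwise)
#> bias_report (pairwise)
#>             feature statistic   p_value mean_diff
#> 1        exon_count     15050 1.804e-34        14
#> 2 transcript_length     15043 3.160e-34      3329
#> 3        cds_length     14949 5.167e-33      1921
#> 4      genomic_span     14893 2.664e-32     38784
```

Reading the output: the balanced object holds exactly 1,000 cells per
technique inside the 1,100–2,000-count depth window; each technique
contributes its top-100 upregulated markers; and the single-nucleus
list's genes average 14 more exons than the single-cell list's (17.6 vs
3.6 in this run), with the same ordering in all three length measures —
the planted length bias, recovered. On a bias-free simulation
(`simulation_truth(bias_amplitude = 1)`) the same report shows a
near-zero difference and a non-significant p.

Individual stages are plain functions (`simulate_gene_catalog()`,
`filter_matrix()`, `log_normalize()`, `balanced_subsample()`,
`find_technique_markers()`, `nb_glm_markers()`, `compare_structures()`,
`genome_background_comparison()`, `score_experiment()`) operating on a
sparse `paired_experiment` container with Matrix-Market/TSV readers and
writers, so the pipeline can also be driven piecewise or pointed at real
data via `read_experiment()`.

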