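---
title: "Quantifying gene-length capture bias between single-cell and single-nucleus RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-length capture bias between single-cell and single-nucleus RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell RNA-seq profiles the whole-cell mRNA pool of dissociated live
cells; single-nucleus RNA-seq profiles only the nuclear pool of isolated
nuclei. The two techniques do not capture the same transcriptome: nuclei
retain long, exon-rich transcripts that are still being spliced and
exported, while short transcripts with few introns exit the nucleus
quickly and are washed out of nuclear preparations. Mitochondrial
transcripts and most ribosomal-protein mRNAs are essentially absent from
nuclei altogether. The practical consequence is that marker lists,
structural summaries and pathway scores computed from the two techniques
disagree systematically, in a way that tracks gene length and exon
count — with a changeover around ten exons — rather than biology.

`lenbias` packages that comparison as a reusable, testable pipeline:
a seeded generator of paired count matrices with a *known, planted*
capture bias, the quality-control / normalization / depth-matching steps
needed for a fair comparison, two differential-expression routes, the
structural-bias statistics, and per-cell gene-set scoring. Because the
generator's bias is known, every downstream claim ("the nucleus list is
exon-rich", "the comparison has its nominal type-I error") can be checked
against ground truth.

## The synthetic generator

### Gene catalog

`simulate_gene_catalog()` draws per-gene structure:

* exon count `1 + NB(mean = 7.8, size = 2)`, targeting the mammalian
  genome-wide average of about 8.8 exons per gene;
* per-exon lengths log-normal (median 180 nt, sdlog 0.7); transcript
  length is their sum;
* genomic span adds one log-normal intron (median 1.5 kb, sdlog 1) per
  internal junction, so span inflation grows with exon count;
* CDS length a uniform 30–90% fraction of transcript length;
* 0.5% of genes flagged mitochondrial (forced single-exon, symbols
  `mt-…`) and 2% ribosomal-protein (at most 6 exons, `Rpl…`/`Rps…`),
  so prefix-based exclusion rules can be exercised verbatim. A
  `symbol_style = "human"` switch produces `MT-`/`RPL`/`RPS`.

The invariants `cds ≤ transcript ≤ span` and
`exon_count = 1 ⟹ transcript = span` hold by construction and are
re-checked by `validate_gene_catalog()`.

### Counts

`simulate_paired_experiment()` plants the bias:

* per-gene base expression is log-normal (sdlog 1.3); cluster markers
  (default 3 clusters × 25 genes, fold change 4) multiply it within
  their cluster;
* the nucleus technique's capture weight is
  `1 + (A − 1)·logistic((exons − m)·s)` with amplitude `A = 4`,
  midpoint `m = 10` exons and steepness `s = 0.7` by default; the
  whole-cell technique is flat (an optional inverse-length tilt exists
  but defaults off, since the whole-cell short-gene preference is the
  relative consequence of the nucleus curve);
* mitochondrial/ribosomal weights are zero in nuclei;
* each cell draws a log-normal library size (median 1,500 counts,
  sdlog 0.15) and its counts come from one multinomial over the
  normalized product of base × cluster × capture weights, with an
  optional mean-1 Gamma perturbation per gene and cell
  (`baseline_dispersion = 10`) supplying negative-binomial-style
  overdispersion.

The multinomial construction makes depth exactly controllable — each
cell's total is its drawn library size — which is what the depth-window
logic downstream assumes. The exon-count logistic (rather than a curve
in length directly) is the primary mechanism because "about ten exons"
is the most operational statement of the effect; transcript length,
CDS length and genomic span are all correlated with exon count through
the catalog, so all four features show the bias.

`bias_amplitude = 1` defines the **null generator**: both techniques
then share identical capture weights for every non-compartment gene.
Note the compartment-exclusive genes are *still* differentially captured
under the null — that is a planted, real difference. Calibration
harnesses that need fully exchangeable techniques therefore use
catalogs with `mito_frac = ribo_frac = 0`; pipelines that keep them rely
on the prefix-exclusion rule to remove them from marker lists.

Default sizes (5,000 genes, 3,000 cells per technique) were chosen so
that at least 1,500 cells per technique fall inside the default
1,100–2,000-count depth window, comfortably covering the 1,000-cell
balanced draw, while a full default pipeline run stays under a minute on
one CPU.

What the generator does **not** emulate: ambient RNA, doublets, UMI
collisions, dissociation-stress signatures, batch effects needing real
integration, or isoform-level structure. A passing recovery test
therefore shows the *statistical machinery* is sound, not that any
particular real tissue behaves like the simulation.

## Pipeline stages

* **QC** (`filter_matrix()`): drop genes detected in fewer than 5 cells,
  then cells expressing fewer than 300 retained genes — a single pass in
  that order, not iterated to a fixed point. The order is deliberate and
  asserted by the tests; re-checking genes after cell removal is a
  different (also defensible) policy that we do not apply.
* **Normalization** (`log_normalize()`, `alternate_normalize()`):
  primary scheme `ln(1 + count/total × 10⁴)`; alternates `relative`
  (no log) and `sqrt_scaled`. Scale factor 10⁴ and pseudocount 1 are the
  standard toolkit defaults. All three are monotone within a cell and
  map zeros to zeros; the robustness property — the recovered bias
  direction is identical under all three — is an acceptance test.
* **Depth matching** (`depth_window()`, `linearity_check()`,
  `balanced_subsample()`): windows are exclusive bounds, treated as
  configuration (the regime where genes/cell grows linearly with
  counts/cell is chosen by inspection, with `linearity_check()` as an
  advisory diagnostic, default pass at Pearson r ≥ 0.6). The balanced
  draw is uniform without replacement, 1,000 cells per technique by
  default, seeded.
* **Differential expression**: both routes test one group versus the
  rest per gene after the same prefilters — expressed fraction
  ≥ `min.pct` 0.25 in the higher group and |natural-log fold change|
  ≥ 0.25, with the fold change computed as the difference of
  `ln(mean + 1)` of back-transformed (expm1) normalized means. The
  Wilcoxon route uses the package's own rank-sum test; the NB route
  fits a negative-binomial GLM with an `ln(total counts)` offset,
  method-of-moments dispersion on a Poisson full-model fit floored at
  θ = 0.01, one refit, and a 1-df likelihood-ratio test. Bonferroni
  correction over the tested genes (the toolkit default; BH is a
  one-line change in user code via `p.adjust`). Records are sorted by
  adjusted p, then |log fold change|; "top-100" means the first 100
  positive records per group after removing `mt-`/`Rpl`/`Rps` symbols
  from the whole-cell list (configurable to both lists).
* **Structural bias** (`annotate_list()`, `compare_structures()`,
  `genome_background_comparison()`): lists are annotated from the local
  catalog (no remote gene-database queries); features are compared
  between lists and against the whole catalog with the same Wilcoxon
  test, with adjusted Fisher–Pearson skewness `g1 = m3/m2^{3/2}`
  summarizing each distribution. The exon-count histogram uses unit
  bins 1…70 plus an overflow bin (genes beyond 70 exons are negligible)
  against the catalog's expected fractions, with a chi-square
  goodness-of-fit statistic. The background includes the list's own
  members unless `exclude_list_from_background = TRUE`.
* **Enrichment** (`ssgsea_score()`, `score_experiment()`): per-cell
  single-sample scores walk the expression-ranked gene list and
  accumulate the difference between the rank-weighted (`rank^alpha`,
  α = 0.25) cumulative fraction of set members and the unweighted
  cumulative fraction of non-members; ties get midrank positions. NES
  divides by the range of scores across all scored cells, so the scored
  population always spans a width-1 interval. At α = 0 the score is
  rank-only and invariant under monotone transforms — a tested
  property. Tie handling and the normalization cohort are the standard
  single-sample GSEA choices; both are exposed as arguments.

## Numerical and design choices

* **Wilcoxon p-values.** The exact branch enumerates all
  `choose(n, n_x)` group assignments of the observed midranked values
  whenever `n ≤ 12` — ties included, where the classic no-tie recursion
  does not apply — and doubles the smaller tail (capped at 1), matching
  the convention of `stats::wilcox.test`. Larger samples use the normal
  approximation with tie correction and continuity correction. On
  tie-free samples at n = 12 the approximation sits within 0.02 of
  enumeration; with heavy ties it can be off by an order of magnitude
  more, which is exactly why tied small samples are routed to the
  exact branch.
* **Two definitions kept apart.** Everywhere a statistic has an
  independent oracle in the test-suite (enumeration for the rank-sum
  test, an explicit double-ECDF walk for the enrichment score), the
  oracle is a separate implementation, not a second call into the same
  code path.
* **Integration surrogate.** Real paired datasets need batch
  alignment before techniques are comparable. Synthetic techniques
  share a coordinate-free gene space, so the pipeline's integration
  stage is an explicit no-op placeholder that keeps the stage order of
  a real analysis and gives real-data users a seam to plug an external
  integration into.
* **Power is conditional on testing.** The expressed-fraction prefilter
  withholds near-zero genes no test could call; the package's power
  checks therefore measure detection among planted genes that enter
  testing (and separately assert that most planted genes do).
* **Seeds.** Every random step flows from one seed through a private
  RNG stream that saves and restores the caller's `.Random.seed`;
  stage seeds are derived with a fixed integer recurrence kept inside
  32-bit range.

## Problem sizes

The shipped tests run the full default pipeline once (5,000 genes,
6,000 cells), the planted-bias recovery on 20 seeds at 2,000 genes ×
600 cells, the top-list type-I calibration on 500 reduced runs
(400 genes × 160 cells, selection filters opened and top-30 lists so
the lists are always full), the NB calibration on 3 seeds of 2,000
genes × 400 cells, and 100 reduced null enrichment runs. These sizes
give the binomial assertions enough resolution (±2% bands at 500 runs)
while keeping the whole suite in a few minutes.

## Known limitations

* The generator's whole-cell technique is flat by default; any
  short-gene preference of whole-cell capture appears only relative to
  the nucleus curve unless `sc_length_tilt` is set.
* The NB dispersion estimator is deliberately simple (per-gene moments,
  floor, one refit); genes with almost all zeros in both groups can
  fail to converge and are skipped with a warning rather than modeled.
* Cluster labels are ground truth from the generator; no clustering or
  embedding is performed, and on real data clusters must be supplied.
* The exon-count bin table compares against whatever catalog is given;
  whether a real analysis should background against all annotated genes
  or protein-coding genes only is the caller's choice of catalog.
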