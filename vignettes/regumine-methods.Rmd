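---
title: "regumine: methods and parameter rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regumine: methods and parameter rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r load}
library(regumine)
```

`regumine` infers the direct regulon of a bacterial transcription factor by
combining two independent lines of evidence: the presence of a predicted
operator (a position-weight-matrix hit in a gene's regulatory window) and
repression visible in expression data (anti-correlation between the gene and
the regulator across conditions). The design follows the workflow of an
iron-dependent DmdR1-type repressor study in *Streptomyces coelicolor*; every
stage can be validated on synthetic genomes with planted regulons, so no
external data are required. This vignette documents what each stage computes
and why the default parameters are what they are.

## 1. Motif model

`build_pfm()` counts aligned binding sites into a position frequency matrix
and `pfm_to_pwm()` turns it into a log-odds matrix:

$$ s_{b,j} = \log_2 \frac{(c_{b,j} + k\,p_b)/(n + k)}{p_b} $$

with pseudocount $k = 0.8$ and a background $p_b$ derived from the genomic
GC content (default GC $= 0.72$, the *Streptomyces* value). The pseudocount is
spread across bases proportionally to the background, so a base that is rare
in the genome is not artificially inflated at positions where it was never
observed. Scores are in bits; `pwm$max_score` is the score of the consensus.

```{r pwm}
sites <- c("TTAGGTTAGGCTAACCTAA", "TTAGGTTAGGCTTACCTAA",
           "ATAGGTAAGGCTAACCTTA", "TTAGGTTGGGCTAACCTAA")
pwm <- pfm_to_pwm(build_pfm(sites), background = gc_background(0.72))
pwm
```

## 2. Genome scanning with an exact p-value floor

`scan_genome()` slides the PWM along both strands of every contig. Rather
than an arbitrary score cut-off, the initial floor is chosen by exact
p-value: `score_threshold_from_pvalue(pwm, p = p)` computes, by dynamic programming over
the per-column score distributions, the smallest score whose tail probability
under the background model is at most `p`.

The DP discretizes each column's scores on a 0.001-bit grid (floor rounding),
so the guarantee is per column, not global: the returned threshold `s`
satisfies

$$ P(S \ge s + 0.001\,L) \le p < P(S \ge s - 0.001), $$

where $L$ is the motif length. Tests verify this against a brute-force
enumeration oracle for short motifs.

Each retained hit is classified as `coding` or `noncoding` by the midpoint of
its window against the merged coding intervals, and hits are associated with
strand-aware regulatory windows (default 350 bp upstream to 50 bp downstream
of each start codon, via `extract_regions()`). These window bounds match the
promoter-proximal operator placement of DmdR1-family repressors, which bind
at or just upstream of the transcription start.

## 3. Threshold refinement from the non-coding/coding ratio

A genuine operator is under selection to sit in intergenic DNA, so as the
score threshold rises the fraction of surviving hits that are non-coding
should rise well above the genomic expectation. `refined_threshold()` computes
the cumulative non-coding percentage over a score grid and takes the first
grid point from which the curve stays at or above the median of the curve
(`method = "ratio_median_crossing"`). Requiring a *sustained* crossing rather
than the first touch makes the threshold robust to jitter in sparsely
populated score bins. The published description admits a second reading — the
plain median of the retained hit scores — which is available as
`method = "median_hit_score"`; the ambiguity is recorded in
`comparison_report()`.

Hits above the refined threshold are deduplicated into *unique locations* by
single-linkage clustering of overlapping windows (`filter_and_dedupe()`):
both strands of a palindromic operator, and staggered windows over the same
site, collapse to one location represented by the best-scoring hit.

## 4. Co-expression with mean-expression bias correction

`coexpression_stack()` prepares a Pearson correlation matrix from an RNA-seq
count matrix:

1. **Filter** — keep genes with ≥ 5 reads in at least half the samples
   (`filter_low_expression()`).
2. **Normalize** — TMM effective library sizes (`edgeR`), then CPM.
3. **Transform** — `asinh` of CPM; identical to `log2(2x)/…` asymptotically
   for large counts but defined and smooth at zero, so low-count genes need
   no pseudocount.
4. **Confounder removal** — subtract the projection onto the first principal
   component (`remove_pcs = 1` by default). In compendium-scale expression
   data PC1 is dominated by technical batch/depth structure; removing it is
   what allows biological anti-correlation to surface.
5. **Correlation** — Pearson across samples, with two-sided p-values.
6. **spqn** — spatial quantile normalization of the correlation matrix
   against gene mean expression. Correlation estimates are systematically
   inflated for lowly expressed genes; spqn equalizes the correlation
   distribution across expression bins by quantile-mapping each bin pair onto
   a high-expression reference window. The running window is floored at 90
   genes so that the reference quantiles are estimated from a stable number
   of gene pairs; with fewer genes the quantile map itself becomes the
   dominant noise source.

`bin_density_diagnostic()` quantifies the bias before/after: per
mean-expression bin, the median off-diagonal correlation should shrink toward
zero after correction.

The significance cut-off for calling a correlation is analytic:
`critical_pcc(n, alpha)` inverts the t-statistic of a Pearson correlation,
$r^\* = t^\*/\sqrt{t^{\*2} + (n-2)}$, and rounds *up* at the requested number
of digits so the printed threshold is itself still significant. For the
paper's 22 samples at $\alpha = 0.05$:

```{r critical}
critical_pcc(22, 0.05, digits = 4)
critical_pcc(22, 0.05, digits = 2)
```

**Scale caveat.** The correction stack's defaults assume genome-scale gene
counts. On toy matrices of a few dozen genes, PC1 removal and spqn remove
genuine signal rather than technical structure (measured on the 40-gene
synthetic scenario: planted anti-correlations of −0.6 to −0.8 shrink to −0.1
to −0.5). For such inputs set `remove_pcs = 0, spqn_passes = 0`.

## 5. Regulon assembly

`build_regulon()` combines the two evidence streams:

- **Target assignment** — each unique location is assigned to the gene whose
  regulatory window contains it; with divergent genes the location can seed
  both. Locations in no window are kept as orphans.
- **Anti-correlation filter** — a candidate target is accepted only if its
  correlation with the regulator is negative and exceeds the
  `critical_pcc()` threshold in magnitude (the regulator is a repressor:
  more regulator, less target).
- **Operon expansion** — accepted targets are extended along the strand to
  downstream same-strand neighbours with intergenic gaps ≤ 200 bp *and*
  significant positive co-expression with the seed gene. The 200 bp bound is
  not stated in the original methods (a documented ambiguity); it is the
  conventional prokaryotic operon gap and the regulon size is sensitive to
  it.
- **Locus grouping** — members within 5 kb on the same contig are grouped
  into loci, mirroring the clustered organization of siderophore pathways.

`regulon_statistics()` reports the median within-regulon correlation, the
median correlation to the regulator, and a one-sided Mann–Whitney test of
within-regulon correlations against the negated regulator correlations. On
real compendia this p-value is the headline coherence statistic. On synthetic
data it is descriptive only: the simulated repression follows inverse mass
action, so member–regulator correlations sit near the Pearson ceiling of −1
and their negation stochastically dominates the within-member correlations —
the test can legitimately return p ≈ 1.

## 6. Domain-rule cluster detection

Independently of expression, `detect_clusters()` finds candidate biosynthetic
loci from declarative rules over protein-domain content: a rule names
required and optional Pfam accessions, a maximum gene gap, and a minimum
number of distinct carrier genes. Genes carrying required domains are chained
along a contig (bipartite matching ensures multi-domain fusion proteins are
not double-counted), and `load_cluster_rules()` ships presets for the
desferrioxamine loci (`desABCD`, `desGH`).

## 7. Synthetic data: what is planted and why

`synthetic_regulon_dataset()` generates a genome, annotation, operonized
regulon with planted operator sites in leader-gene regulatory windows, and an
RNA-seq count matrix:

- **Regulator profile** — log-linear across samples; member means follow
  inverse mass action with `effect_size = 0.85`, producing strong, realistic
  anti-correlation.
- **Confounder** — a step-shaped sample loading with two-level gene loadings
  (1 for high-expression genes, 0.1 for the rest). A uniform loading would be
  a pure library-size shift that CPM normalization silently removes; the
  two-level structure survives normalization, so PC1 removal has real work
  to do and the spqn stage sees genuine mean-expression-dependent inflation.

`run_pipeline()` on a simulated config attaches the ground truth and a
`recovery` block (planted-site recall/precision, member
sensitivity/precision), which is what the acceptance tests assert.

```{r pipeline}
cfg <- regumine_config(simulation = list(), seed = 1)
run <- run_pipeline(cfg)
run
```

## 8. Comparison with the reference study

`paper_reference_values()` pins the quantities printed in the original study;
`run_summary_quantities()` extracts the comparable quantities from a run, and
`comparison_report()` tabulates the deltas, always carrying the two
documented reading ambiguities (threshold method and operon gap). The
original expression compendium is not redistributable, so deviations on
synthetic data are expected and the report exists to make them explicit
rather than to be minimized.

```{r report}
comparison_report(run_summary_quantities(run))
```

## Limitations

- The Mann–Whitney coherence p-value is not meaningful on the synthetic
  scenario (section 5).
- The correction stack requires genome-scale gene counts (section 4).
- The refined threshold and the operon-gap bound each follow one of two
  defensible readings of the published methods; both choices are surfaced in
  every `comparison_report()`.
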