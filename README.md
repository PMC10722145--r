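# chromcord

Innate lymphoid cells (ILC1/2/3) mirror T helper subsets (Th1/2/17) in
effector function, yet the two lineages are wired differently: they diverge
in which genes they commit to, in the chromatin that controls those genes,
and in the transcription factors that read it. **chromcord** implements an
integrative transcriptome + chromatin-accessibility workflow for this kind
of paired-lineage comparison, aimed at computational immunologists who want
to derive conserved marker genesets from heterogeneous public RNA-seq
compendia and then ask how those genesets are regulated.

The pipeline has three analysis stages plus a fully planted synthetic-study
generator, so every rule is testable end to end against a known ground
truth.

## The core rules and statistics

**Conserved marker genesets.** After TPM normalisation, a prevalence filter
(TPM > 10 in more than 80% of the samples of at least one subset) and
design-protected batch removal, paired rank-sum comparisons (ILC1 vs Th1,
ILC2 vs Th2, ILC3 vs Th17) define the lineage genesets by a
minimum-fold-change / maximum-p rule:

    gene ∈ ILC geneset  ⇔  min_k log2FC(ILCk / Thk) > 0.25  and
                           max_k p_k < 0.01

(Th symmetric with the sign flipped). Immune-response genesets (type 1/2/3)
require the same thresholds for subset k against the other two subsets
*within each lineage separately* — conservation across the innate and
adaptive arms.

**Expression-concordant OCRs.** Open chromatin regions are linked to genes
whose TSS lies within 50 kb of the peak midpoint. A peak linked to a
geneset gene is *concordant* when its accessibility (BPM) satisfies all
three parts of

1. mean BPM(up-lineage) / mean BPM(down-lineage) > 1.5,
2. min over up-lineage replicates > max over down-lineage replicates,
3. min over up-lineage replicates > 0.5 BPM,

all strict. Subset-specific OCRs apply the same rule restricted to the
paired subsets' replicates (e.g. ILC2 vs Th2). Peak geometry (width,
distance to TSS) is compared between classes with two-sided Mann-Whitney
tests.

**Motif inference.** PWM log2-odds scores are discretised to a 1e-3 grid
and the exact null score distribution is computed by positionwise
convolution; the scan threshold is the smallest grid score whose tail
probability is ≤ 1e-4 per window. Motif enrichment between OCR classes is
an exact hypergeometric test; *potential TFs* are enriched motifs
(p < 0.01) whose mapped TF gene is expressed (TPM > 50) in the
interrogated subsets, ranked by p-value; occupancy fractions of the top
TFs are compared with a paired two-sided Wilcoxon signed-rank test.

## Worked example

```r
library(chromcord)

bundle <- simulate_bundle(sim_config(seed = 1))   # 294-sample synthetic study
report <- run_pipeline(bundle = bundle, quiet = TRUE)
print(report)
```

```
<run_report> seed 1
  294 samples, 2000 genes (1977 after filtering)
  genesets: ILC=60 Th=60 type1=40 type2=40 type3=40
  clustering ARI: 1
  ILC OCRs: 240 concordant / 120 non-concordant
  Th OCRs: 240 concordant / 120 non-concordant
  top TFs (ILC): gene_0710 gene_0975 gene_0774 gene_0416 gene_1877
  top TFs (Th):  gene_1005 gene_0862 gene_0676 gene_1573 gene_0008
```

The run recovers the five planted genesets exactly (60/60/40/40/40), the
sample clustering agrees perfectly with the cell-type labels (adjusted Rand
index 1), and 240 concordant OCRs per lineage are found — the peaks the
generator planted with the concordant accessibility pattern. The geometry
report shows the planted lineage difference:

```r
print(report$geometry)
```

```
  class          n width_median width_mean frac_width_gt dist_median frac_tss_lt
1 ILC_conco…   240          712       709.         0.921        522.       0.675
2 Th_concor…   240          461       456.         0.329       3653        0.167
tests:
  metric       statistic  p_value
1 width            52756 5.35e-56
2 tss_distance      8005 1.24e-42
```

ILC-class concordant OCRs are broader (median 712 vs 461 bp; 92% vs 33%
above 500 bp) and sit nearer the TSS (68% vs 17% within 1 kb), both
Mann-Whitney p ≪ 0.01. `plot_embedding()`, `plot_peak_geometry()`,
`plot_tf_scatter()` and `plot_occupancy_fractions()` visualise each result;
`glance(report)` and `tidy(report)` return the numbers as tibbles.
`write_bundle()` / `read_bundle()` round-trip a study through plain-text
formats (TSV, BED6, GFF3, FASTA, minimal MEME, JSON).

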