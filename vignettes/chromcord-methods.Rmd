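---
title: "chromcord: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromcord: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

chromcord compares innate lymphoid cell (ILC) subsets with their T helper
(Th) counterparts across three data layers: transcriptome, chromatin
accessibility, and transcription-factor binding motifs. This vignette is
the package's own account of the science behind each stage: the models and
their assumptions, the parameters that matter, what the synthetic-study
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The study design

Six subsets are compared in fixed pairs — ILC1 with Th1, ILC2 with Th2,
ILC3 with Th17 — reflecting the shared type 1/2/3 effector programs of the
innate and adaptive arms. Expression data are a gene × sample matrix
assembled from many studies (hence explicit batch structure); chromatin
data are peak intervals with per-sample BPM (bins per million mapped reads)
accessibility and exactly two replicates per subset, which is what makes
the replicate-separation rule below evaluable.

## Expression stage

**TPM and filtering.** Counts are length-normalised to transcripts per
million. A gene is retained when, in at least one subset, it exceeds 10 TPM
in strictly more than 80% of that subset's samples. Both inequalities are
strict, so boundary genes drop; this is deliberate — the thresholds are
phrased as exceedances, and strictness makes the rule unambiguous at the
boundary.

**Batch removal.** Multi-study compendia carry additive study effects. Per
gene we fit expression on cell-type indicators plus sum-to-zero batch
indicators by ordinary least squares (via `limma::removeBatchEffect` with a
cell-type design) and subtract the fitted batch component. The design
matrix protects the biological structure: on balanced designs cell-type
means are unchanged and purely additive offsets are removed exactly (the
test suite asserts residual between-batch variance below 1e-8). A batch
perfectly confounded with a cell type makes the fit unidentifiable and is
reported as an error naming the batch. Correction is idempotent.

**Clustering QC.** Genes are standardised, samples are projected onto the
top 20 principal components, and k-means with k = 6 (25 restarts, seeded)
is compared to the cell-type labels by the adjusted Rand index. Two design
notes. First, no nonlinear-embedding implementation is available among the
package's dependencies, and none is needed for a QC readout: the 2-d view
returned for plotting is simply the first two PCs. Second, k-means runs on
the full 20-PC scores rather than on the 2-d view — six groups need not be
separable in two dimensions, and the ARI should measure the expression
structure, not the projection. The embedding is QC only; genesets never
depend on it.

**Differential expression and genesets.** Per-gene two-sided Mann-Whitney
(Wilcoxon rank-sum) tests compare groups; the matrix path uses a
vectorised normal approximation with tie and continuity corrections (group
sizes here are 21-64, well inside the approximation's comfort zone), while
the scalar `mwu_test()` switches to the exact null for small tie-free
samples. Fold change is `log2(mean_a + 1) - log2(mean_b + 1)` on the TPM
scale; the pseudocount of 1 TPM stabilises low-expression genes, and log
layers are un-logged before averaging so the fold change is always on one
scale. The lineage genesets apply the conserved-marker rule: log2FC > 0.25
in *every* pairing and p < 0.01 in *every* pairing, with consistent
direction. Combining p-values across pairings (e.g. Fisher) was rejected:
it would admit genes strong in one pairing and absent in another, which is
exactly what "conserved" must exclude. Response genesets apply the same
thresholds to subset-k-versus-rest comparisons run separately within the
ILC samples and within the Th samples, requiring both arms to agree.

**Over-representation.** Term enrichment of a geneset against a universe
is a one-sided hypergeometric tail with Benjamini-Hochberg adjustment
(q < 0.05 flags). Terms are flat gene sets; no ontology DAG handling.

## Chromatin stage

**Annotation.** A peak links to every gene whose TSS lies within 50 kb of
the peak midpoint (`floor((start + end)/2)`, 0-based), boundary inclusive.
Signed distance is midpoint minus TSS, sign-flipped on minus-strand genes,
so positive always means transcriptionally downstream. Coordinates are
BED-style 0-based half-open internally; GFF3 is converted on read.

**The three-part concordance rule.** A geneset-linked peak is concordant
when (i) the ratio of mean BPM in the up-lineage samples to the down-lineage
samples exceeds 1.5, (ii) the minimum across all up-lineage replicates
exceeds the maximum across all down-lineage replicates, and (iii) the
up-lineage minimum exceeds 0.5 BPM — all strict. Part (ii) is the
replicate-aware guard: no amount of averaging can rescue a peak whose
weakest up-replicate dips below the strongest down-replicate. Choices made
where the rule's prose left room: the fold change uses the pooled mean over
all samples of each lineage (means over medians for linearity; pooled
rather than mean-of-subset-means, configurable in principle), and a zero
denominator with positive numerator counts as infinite fold change (passes),
while 0/0 fails. Subset-specific classification is the identical rule
restricted to one paired subset's replicates, evaluated in both directions;
the floor applies to the *up* subset in each direction — the rule is
symmetric under swapping the lineages, and the test suite asserts that
symmetry. Non-concordant is the residual class; the two classes partition
the linked peaks by construction.

**Geometry.** Widths and per-peak minimum |TSS distance| are summarised per
class (fraction wider than 500 bp, fraction within 1 kb of a TSS) and
compared with two-sided Mann-Whitney tests.

## Motif stage

**Exact calibration.** Scanning thresholds come from the exact null
distribution of the PWM score, not from an asymptotic approximation.
Log2-odds scores against a 0-order background are rounded to an integer
grid at 1e-3 log-odds units; the distribution of a random background
window's total score is built by convolving the per-position score
distributions. The threshold is the *smallest* grid score whose tail
probability is at or below the target (1e-4 per window), so the attained
p-value is conservative; the test suite checks the DP tails against full
4^L enumeration to 1e-12. A per-cell pseudocount of 0.1 (renormalised) is
applied at calibration time — motif objects keep their raw probabilities so
file round-trips are lossless — and a zero probability with zero
pseudocount is an error rather than a silent -Inf. The uniform background
is the default because the generator emits uniform-composition sequence,
making the null exact; a background estimated from the scanned sequences
can be supplied instead.

**Scanning.** Every window on both strands is scored on the same integer
grid (the reverse strand scores through the reverse-complemented score
matrix, which is exactly equivalent to scanning the reverse-complement
sequence). Windows containing non-ACGT characters are skipped; sequences
shorter than the motif contribute nothing. Occupancy is binary — at least
one hit per (peak, motif) — matching the "fraction of OCRs with a binding
motif" readout.

**Enrichment and potential TFs.** Enrichment of a motif in one OCR class
against another is an exact hypergeometric test on occupancy counts. Two
p-values are kept: the one-sided enrichment tail drives ranking and the
enrichment score (-log10 p), because enrichment is directional; the
two-sided minimum-likelihood p is also reported for completeness. The
background set is the opposing concordant class (not a GC-matched genomic
background, which would require a reference genome). A motif becomes a
*potential TF* when its mapped gene is expressed above 50 TPM in the
interrogated subsets — in at least one subset by default, or in all of them
(`tpm_mode = "all_subsets"`) for the stricter reading — and its enrichment
p is below 0.01; the top 10 by p-value are reported. Occupancy fractions of
a TF panel between two OCR classes are compared with the *paired* two-sided
Wilcoxon signed-rank test by default (the same TFs are measured in both
classes); all-zero differences return p = 1 with a degeneracy flag rather
than an error, and a single-TF panel falls back to the rank-sum test with a
warning.

## The synthetic-study generator

The generator plants the structure every stage is supposed to find, at the
published study scale: 21/64/41/61/49/58 samples across the six subsets
(294 in total). Its defaults are the package's study conditions and were
chosen once:

| parameter | default | why |
|---|---|---|
| genes | 2,000 | large enough for stable TPM totals, small enough to iterate |
| genesets | 60 ILC / 60 Th / 40 per type | same order as published geneset sizes after scaling to 2,000 genes |
| effects | 2.0 log2 | a four-fold conserved marker — strong but realistic |
| batch sd | 0.5 log2 | multi-study heterogeneity comparable to the effect scale |
| NB dispersion | 0.1 | typical bulk RNA-seq overdispersion |
| baseline | N(6, 1.5) log2 counts | spans silent-to-abundant genes |
| peaks/gene | 6, 60% concordant | a few hundred concordant OCRs per lineage |
| widths | N(700, 150) ILC / N(450, 100) Th bp | the planted geometry difference |
| TSS offsets | exponential, 0.8 kb ILC / 5 kb Th | ILC class promoter-proximal |
| BPM | 3 high / 0.2 low / 1 flat, lognormal sdlog 0.2 | clean separation with replicate noise |
| motifs | 5 ILC + 5 Th + 2 shared, L = 10, consensus 0.97 | high-information motifs whose ≤1-mismatch instances pass the 1e-4 threshold |
| plant rates | 0.8 matched / 0.05 elsewhere | strong but imperfect class association |

Genes are spaced 160 kb apart so planted peaks link only to their own gene;
decoy peaks beyond the 50 kb window exercise the annotation boundary. Motif
instances are consensus-with-noise draws planted at non-overlapping
offsets on random strands, and the emitted PWMs are the generating models.
The whole bundle is a deterministic function of the configuration
(including its seed), byte-identical through the file writers.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: GC content and repeat structure (sequence is
i.i.d. uniform, which is exactly what keeps the scan's null exact),
read-level noise or peak-calling artefacts, correlated genes or co-bound
motifs, unbalanced or missing replicates, and batch effects that are
non-additive or correlated with cell type. Results on real compendia will
be noisier than the planted recovery rates; the planted design is for
verifying the machinery, not for benchmarking sensitivity on real assays.

## Numerical conventions and degenerate inputs

* Strict inequalities at every published threshold; at exact boundaries
  records drop.
* Tests with zero variance (all-tied groups) report p = 1 instead of NaN.
* Zero paired differences are dropped before signed-ranking (error if all
  are zero); tied absolute differences at n ≤ 15 are handled by exact
  sign-pattern enumeration, larger tied samples by the tie-corrected normal
  approximation.
* The two-sided hypergeometric p is the minimum-likelihood sum with a
  1 + 1e-7 relative guard against floating-point pmf comparisons.
* TPM columns with zero total signal return zeros with a warning; TPM
  column sums are 1e6 within 1e-6 relative tolerance otherwise.
* k-means uses 25 restarts under a caller-supplied seed; all generator
  randomness derives from the configuration seed plus fixed per-stage
  offsets.

## Problem sizes in the test suite

The suite exercises the full 294-sample default design across ten seeds for
the recovery, geometry, TF and clustering properties, a matching set of
null simulations (no planted effects), brute-force rule checks on 1,000
random peaks per seed, full 4^8 enumeration for calibration exactness, and
over 10^6 scored null windows for the false-positive rate. Unit tests run
smaller paired designs (8 samples per subset) where the rank-sum
approximation still resolves p < 0.01 on clean separation.

## Known limitations

* The expression model treats samples as exchangeable within subset and
  batch; no covariates beyond batch are modelled.
* Rank-sum DE has no dispersion shrinkage; at two or three samples per
  group it is underpowered compared to count-model alternatives.
* The motif-to-TF map is one-to-one; TF families sharing a motif are not
  collapsed.
* Enrichment against the opposing class answers "which motifs distinguish
  the classes", not "which motifs are enriched against the genome".
* The QC embedding is linear; fine nonlinear structure in real compendia
  will not be visible in it (the ARI does not depend on it).
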