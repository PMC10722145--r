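#' Simulation configuration for the synthetic six-subset study
#'
#' Collects every knob of the synthetic-study generator. The defaults are the
#' study conditions the pipeline is exercised under: the published sample
#' counts per subset (21 ILC1, 64 ILC2, 41 ILC3, 61 Th1, 49 Th2, 58 Th17 —
#' 294 samples in total), 2,000 genes with five planted marker genesets,
#' log2 effect sizes of 2 against a batch standard deviation of 0.5,
#' lineage-distinct peak geometry (ILC-class peaks wider and nearer the TSS),
#' and class-matched motif planting. See the methods vignette for the
#' rationale behind each default.
#'
#' @param n_samples_per_subset Named integer vector over the six subsets.
#' @param n_genes Total number of genes simulated.
#' @param n_batches Number of study batches; samples are assigned round-robin
#'   within each subset.
#' @param geneset_sizes Named counts for the planted `ILC`, `Th`, `type1`,
#'   `type2`, `type3` genesets (disjoint; must sum to at most `n_genes`).
#' @param lineage_effect_log2,response_effect_log2 Planted log2 effects for
#'   lineage and immune-response genesets.
#' @param batch_sd_log2 SD of gene-specific additive batch offsets (log2).
#' @param nb_dispersion Negative-binomial dispersion of counts (0 = Poisson).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-gene
#'   baseline log2 expected counts.
#' @param n_chroms,chrom_len Synthetic genome shape (bp).
#' @param gene_spacing Distance between consecutive TSSs on a chromosome (bp);
#'   kept above twice the annotation window plus decoy range so planted peaks
#'   link only to their own gene.
#' @param peaks_per_gene Peaks planted per geneset gene.
#' @param concordant_fraction Fraction of each gene's peaks planted with the
#'   concordant accessibility pattern.
#' @param n_decoy_peaks Peaks emitted beyond the 50 kb annotation window.
#' @param width_params List with `ILC` and `Th` elements, each `c(mean, sd)`
#'   of the Gaussian peak width (bp, truncated at 50).
#' @param tss_dist_scale Named vector: exponential scale (bp) of the signed
#'   peak-midpoint-to-TSS offset per lineage class.
#' @param bpm_high,bpm_low,bpm_flat Planted accessibility levels (BPM).
#' @param bpm_noise_sdlog Lognormal replicate-noise sdlog applied to BPM.
#' @param n_motifs_per_class,n_shared_motifs Motifs per lineage class and
#'   motifs planted in both classes.
#' @param motif_length,motif_consensus_prob PWM length and per-position
#'   consensus probability of the generating model.
#' @param motif_plant_rate_fg,motif_plant_rate_bg Planting probability per
#'   (motif, peak) in matched vs unmatched peak classes.
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 7)
#' @export
sim_config <- function(n_samples_per_subset = c(ILC1 = 21, ILC2 = 64, ILC3 = 41,
                                                Th1 = 61, Th2 = 49, Th17 = 58),
                       n_genes = 2000,
                       n_batches = 6,
                       geneset_sizes = c(ILC = 60, Th = 60,
                                         type1 = 40, type2 = 40, type3 = 40),
                       lineage_effect_log2 = 2,
                       response_effect_log2 = 2,
                       batch_sd_log2 = 0.5,
                       nb_dispersion = 0.1,
                       baseline_log2_mean = 6,
                       baseline_log2_sd = 1.5,
                       n_chroms = 10,
                       chrom_len = 3.4e7,
                       gene_spacing = 160000,
                       peaks_per_gene = 6,
                       concordant_fraction = 0.6,
                       n_decoy_peaks = 200,
                       width_params = list(ILC = c(mean = 700, sd = 150),
                                           Th = c(mean = 450, sd = 100)),
                       tss_dist_scale = c(ILC = 800, Th = 5000),
                       bpm_high = 3,
                       bpm_low = 0.2,
                       bpm_flat = 1,
                       bpm_noise_sdlog = 0.2,
                       n_motifs_per_class = 5,
                       n_shared_motifs = 2,
                       motif_length = 10,
                       motif_consensus_prob = 0.97,
                       motif_plant_rate_fg = 0.8,
                       motif_plant_rate_bg = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!setequal(names(cfg$n_samples_per_subset), CELL_TYPES)) {
    abort("n_samples_per_subset must be named by the six subsets")
  }
  if (any(cfg$n_samples_per_subset < 1)) abort("each subset needs >= 1 sample")
  if (!setequal(names(cfg$geneset_sizes), c("ILC", "Th", "type1", "type2", "type3"))) {
    abort("geneset_sizes must cover ILC, Th, type1, type2, type3")
  }
  if (any(cfg$geneset_sizes < 1)) abort("geneset sizes must be positive")
  if (sum(cfg$geneset_sizes) > cfg$n_genes) {
    abort("geneset sizes exceed n_genes")
  }
  frac <- c(cfg$concordant_fraction, cfg$motif_plant_rate_fg, cfg$motif_plant_rate_bg)
  if (any(frac < 0 | frac > 1)) abort("fractions and rates must lie in [0, 1]")
  for (cl in c("ILC", "Th")) {
    wp <- cfg$width_params[[cl]]
    if (is.null(wp) || wp[["mean"]] <= 0 || wp[["sd"]] < 0) {
      abort("width_params must give positive means for ILC and Th")
    }
  }
  counts <- c(cfg$n_genes, cfg$n_batches, cfg$n_chroms, cfg$chrom_len,
              cfg$peaks_per_gene, cfg$motif_length, cfg$n_motifs_per_class)
  if (any(counts <= 0)) abort("all counts must be positive")
  if (cfg$motif_consensus_prob <= 0.25 || cfg$motif_consensus_prob >= 1) {
    abort("motif_consensus_prob must lie in (0.25, 1)")
  }
  if (cfg$nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  samples:", sum(x$n_samples_per_subset), "across",
      length(x$n_samples_per_subset), "subsets;",
      x$n_batches, "batches\n")
  cat("  genes:", x$n_genes, "| genesets:",
      paste(sprintf("%s=%d", names(x$geneset_sizes), x$geneset_sizes),
            collapse = " "), "\n")
  cat("  effects (log2): lineage", x$lineage_effect_log2,
      "response", x$response_effect_log2,
      "| batch sd", x$batch_sd_log2, "\n")
  cat("  peaks/gene:", x$peaks_per_gene,
      "| concordant fraction:", x$concordant_fraction, "\n")
  cat("  motifs:", 2 * x$n_motifs_per_class + x$n_shared_motifs,
      sprintf("(L=%d)", x$motif_length), "| seed:", x$seed, "\n")
  invisible(x)
}
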