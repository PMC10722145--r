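# Small in-code fixtures used across test files.

small_config <- function(seed = 1, ...) {
  args <- list(
    n_samples_per_subset = setNames(rep(8L, 6), subsets6),
    n_genes = 300,
    n_batches = 2,
    geneset_sizes = c(ILC = 12, Th = 12, type1 = 6, type2 = 6, type3 = 6),
    peaks_per_gene = 4,
    concordant_fraction = 0.5,
    n_decoy_peaks = 20,
    n_chroms = 4,
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# manifest of six subsets with n samples each, single batch
flat_manifest <- function(n_per_subset = 8, n_batches = 1) {
  m <- tibble::tibble(
    sample_id = unlist(lapply(subsets6, function(ct) {
      sprintf("%s_%02d", ct, seq_len(n_per_subset))
    })),
    cell_type = rep(subsets6, each = n_per_subset)
  )
  m$batch <- sprintf("b%d", ((seq_len(nrow(m)) - 1) %% n_batches) + 1)
  complete_manifest(m)
}

# gene x sample matrix with one constant value per (gene, subset)
subset_matrix <- function(manifest, subset_means, layer = "tpm") {
  genes <- rownames(subset_means)
  mat <- matrix(0, nrow = length(genes), ncol = nrow(manifest),
                dimnames = list(genes, manifest$sample_id))
  for (ct in colnames(subset_means)) {
    cols <- manifest$sample_id[manifest$cell_type == ct]
    mat[, cols] <- matrix(subset_means[, ct], nrow = length(genes),
                          ncol = length(cols))
  }
  attr(mat, "layer") <- layer
  mat
}

# mean value that yields a requested log2 fold change against mean_b on the
# (mean + 1) scale used by differential_expression()
mean_for_lfc <- function(lfc, mean_b = 3) (mean_b + 1) * 2^lfc - 1

# shared pipeline-run cache so acceptance criteria reuse the same seeds
.pipeline_cache <- new.env(parent = emptyenv())

cached_default_run <- function(seed) {
  key <- paste0("default", seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- run_pipeline(config = sim_config(seed = seed),
                                           quiet = TRUE)
  }
  .pipeline_cache[[key]]
}

cached_null_run <- function(seed) {
  key <- paste0("null", seed)
  if (is.null(.pipeline_cache[[key]])) {
    cfg <- sim_config(seed = seed, lineage_effect_log2 = 0,
                      response_effect_log2 = 0)
    man <- simulate_manifest(cfg)
    genes <- simulate_genes(cfg)
    ex <- simulate_expression(cfg, man, genes)
    bundle <- list(config = cfg, manifest = man, genes = genes,
                   gene_lengths = setNames(genes$length, genes$gene_id),
                   counts = ex$counts, truth = ex$truth)
    .pipeline_cache[[key]] <- run_pipeline(bundle = bundle,
                                           stages = "expression",
                                           quiet = TRUE)
  }
  .pipeline_cache[[key]]
}
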