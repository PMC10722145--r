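# Expression stage: TPM, low-expression filtering, batch removal, QC
# embedding, paired differential expression and the five conserved-marker
# genesets.

#' Convert counts to transcripts per million
#'
#' `tpm_gs = (count_gs / length_kb_g) / sum_g(count_gs / length_kb_g) * 1e6`.
#' Columns with zero total signal are returned as all-zero with a warning.
#'
#' @param counts Gene x sample matrix of non-negative counts (layer
#'   `"counts"`).
#' @param gene_lengths Named vector of gene lengths in bp (positive; names
#'   must cover the matrix rows).
#' @return Matrix of the same shape, layer `"tpm"`; non-degenerate columns
#'   sum to 1e6.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  if (any(counts < 0)) abort("counts must be non-negative")
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing) > 0) {
    abort(paste0("gene_lengths missing gene(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  len_kb <- gene_lengths[rownames(counts)] / 1000
  if (any(len_kb <= 0)) abort("gene lengths must be positive")
  rate <- counts / len_kb
  totals <- colSums(rate)
  zero_cols <- totals == 0
  if (any(zero_cols)) {
    warn(paste0("all-zero column(s): ",
                paste(colnames(counts)[zero_cols], collapse = ", ")))
    totals[zero_cols] <- 1
  }
  set_layer(sweep(rate, 2, totals, "/") * 1e6, "tpm")
}

#' Log-transform a TPM matrix
#' @param tpm Matrix with layer `"tpm"`.
#' @return `log2(tpm + 1)`, layer `"log2_tpm1"`.
#' @export
log_tpm <- function(tpm) {
  if (expr_layer(tpm) != "tpm") abort("expected a tpm-layer matrix")
  set_layer(log2(tpm + 1), "log2_tpm1")
}

#' Filter genes by expression prevalence within subsets
#'
#' A gene is kept iff in at least one cell-type subset it exceeds `min_tpm`
#' in strictly more than `min_frac` of that subset's samples (both
#' inequalities strict, so boundary genes drop).
#'
#' @param tpm TPM-layer matrix.
#' @param manifest Sample manifest covering the matrix columns.
#' @param min_tpm TPM threshold (default 10).
#' @param min_frac Prevalence threshold (default 0.8).
#' @return Character vector of retained gene ids.
#' @export
filter_low_expression <- function(tpm, manifest, min_tpm = 10, min_frac = 0.8) {
  manifest <- complete_manifest(manifest)
  assert_samples_match(tpm, manifest, "tpm matrix")
  keep <- rep(FALSE, nrow(tpm))
  for (ct in unique(manifest$cell_type)) {
    cols <- manifest$sample_id[manifest$cell_type == ct]
    if (length(cols) == 0) abort(paste0("subset ", ct, " has zero samples"))
    frac <- rowMeans(tpm[, cols, drop = FALSE] > min_tpm)
    keep <- keep | (frac > min_frac)
  }
  rownames(tpm)[keep]
}

#' Remove additive batch effects while protecting cell-type structure
#'
#' Per gene, an ordinary least-squares fit of expression on cell-type
#' indicators plus sum-to-zero batch indicators; the fitted batch component
#' is subtracted. On balanced designs cell-type means are preserved and
#' noiseless additive offsets are removed exactly. Already-corrected input
#' passes through unchanged.
#'
#' @param log_matrix Gene x sample matrix, layer `"log2_tpm1"` (or
#'   `"corrected"` for idempotent re-application).
#' @param manifest Manifest with `batch` covering the columns.
#' @return Corrected matrix, layer `"corrected"`.
#' @export
remove_batch_effect <- function(log_matrix, manifest) {
  if (!expr_layer(log_matrix) %in% c("log2_tpm1", "corrected")) {
    abort("expected a log2_tpm1 (or corrected) layer matrix")
  }
  manifest <- complete_manifest(manifest)
  if (is.null(manifest$batch)) abort("manifest has no batch column")
  assert_samples_match(log_matrix, manifest, "expression matrix")
  manifest <- manifest[match(colnames(log_matrix), manifest$sample_id), ]
  batch <- factor(manifest$batch)
  if (nlevels(batch) < 2) return(set_layer(log_matrix, "corrected"))

  cell_type <- factor(manifest$cell_type)
  design <- model.matrix(~cell_type)
  contrasts(batch) <- contr.sum(nlevels(batch))
  batch_mat <- model.matrix(~batch)[, -1, drop = FALSE]
  full <- cbind(design, batch_mat)
  if (qr(full)$rank < ncol(full)) {
    tab <- table(manifest$batch, manifest$cell_type)
    nested <- rownames(tab)[rowSums(tab > 0) == 1]
    detail <- if (length(nested) > 0) {
      paste0(" (batch ", nested[1], " occurs only in cell type ",
             colnames(tab)[which(tab[nested[1], ] > 0)], ")")
    } else ""
    abort(paste0("batch is confounded with cell type", detail))
  }
  corrected <- limma::removeBatchEffect(log_matrix, batch = batch,
                                        design = design)
  set_layer(corrected, "corrected")
}

#' PCA embedding and clustering agreement score
#'
#' Standardises genes, projects samples onto the top `n_pcs` principal
#' components, clusters them with k-means (`k` centres, seeded, multiple
#' restarts) and reports the adjusted Rand index against the cell-type
#' labels. The 2-d embedding returned for plotting is the first two PCs;
#' genesets never depend on this step - it is a QC readout.
#'
#' @param corrected Corrected (or log) gene x sample matrix.
#' @param manifest Manifest covering the columns.
#' @param n_pcs Number of principal components (default 20).
#' @param k Number of k-means centres (default 6, one per subset).
#' @param seed Seed for the k-means restarts.
#' @return Object of class `embedding_qc`: list with `embedding` (tibble),
#'   `ari`, and the PC standard deviations.
#' @export
embed_and_score <- function(corrected, manifest, n_pcs = 20, k = 6, seed = 1) {
  manifest <- complete_manifest(manifest)
  assert_samples_match(corrected, manifest, "expression matrix")
  if (ncol(corrected) < n_pcs + 1) {
    abort(paste0("need at least ", n_pcs + 1, " samples for ", n_pcs, " PCs"))
  }
  manifest <- manifest[match(colnames(corrected), manifest$sample_id), ]
  sds <- row_sds(corrected)
  x <- corrected[sds > 0, , drop = FALSE]
  xs <- (x - rowMeans(x)) / row_sds(x)
  pca <- prcomp(t(xs), center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pca$x
  km <- with_seed(seed, kmeans(scores, centers = k, nstart = 25, iter.max = 100))
  ari <- adjusted_rand_index(km$cluster, manifest$cell_type)
  embedding <- tibble(
    sample_id = manifest$sample_id,
    dim1 = scores[, 1], dim2 = scores[, 2],
    cell_type = manifest$cell_type, lineage = manifest$lineage,
    batch = manifest$batch, cluster = factor(km$cluster)
  )
  structure(list(embedding = embedding, ari = ari, sdev = pca$sdev),
            class = "embedding_qc")
}

#' @export
print.embedding_qc <- function(x, ...) {
  cat("<embedding_qc>", nrow(x$embedding), "samples | ARI vs cell type:",
      round(x$ari, 3), "\n")
  invisible(x)
}

#' Rank-sum differential expression between two sample groups
#'
#' Per gene: a two-sided Mann-Whitney test on the matrix values (normal
#' approximation with tie and continuity corrections) and
#' `log2fc = log2(mean_a + 1) - log2(mean_b + 1)` on the TPM scale (log
#' layers are unlogged for the fold change).
#'
#' @param mat Gene x sample matrix (tpm, log2_tpm1 or corrected layer).
#' @param samples_a,samples_b Disjoint sample-id sets, each of size >= 2.
#' @return Tibble with `gene`, `log2fc`, `p_value`, `mean_a`, `mean_b`.
#' @export
differential_expression <- function(mat, samples_a, samples_b) {
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    abort("both groups need at least 2 samples")
  }
  missing <- setdiff(c(samples_a, samples_b), colnames(mat))
  if (length(missing) > 0) {
    abort(paste0("samples absent from matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  layer <- expr_layer(mat)
  tv <- if (layer %in% c("log2_tpm1", "corrected")) pmax(2^mat - 1, 0) else mat
  res <- row_mwu(mat, samples_a, samples_b)
  ma <- unname(rowMeans(tv[, samples_a, drop = FALSE]))
  mb <- unname(rowMeans(tv[, samples_b, drop = FALSE]))
  tibble(
    gene = rownames(mat),
    mean_a = ma, mean_b = mb,
    log2fc = log2(ma + 1) - log2(mb + 1),
    p_value = unname(res$p_value)
  )
}

#' Conserved lineage genesets from paired subset comparisons
#'
#' Runs differential expression for the three pairings (ILC1 vs Th1, ILC2 vs
#' Th2, ILC3 vs Th17). A gene joins the ILC geneset iff its log2 fold change
#' exceeds `lfc_min` in every pairing and its p-value stays below `p_max` in
#' every pairing (minimum-fold-change / maximum-p rule); the Th geneset is
#' symmetric with the sign flipped.
#'
#' @param mat Gene x sample matrix.
#' @param manifest Manifest covering the columns; all six subsets required.
#' @param lfc_min Fold-change threshold, strict (default 0.25).
#' @param p_max P-value threshold, strict (default 0.01).
#' @return List with `sets` (`ILC`, `Th` gene-id vectors) and the per-pairing
#'   `table`.
#' @export
lineage_genesets <- function(mat, manifest, lfc_min = 0.25, p_max = 0.01) {
  manifest <- complete_manifest(manifest)
  missing_ct <- setdiff(CELL_TYPES, unique(manifest$cell_type))
  if (length(missing_ct) > 0) {
    abort(paste0("missing pairing subset(s): ", paste(missing_ct, collapse = ", ")))
  }
  tab <- list_rbind(imap(PAIRINGS, function(pr, label) {
    a <- manifest$sample_id[manifest$cell_type == pr[["ILC"]]]
    b <- manifest$sample_id[manifest$cell_type == pr[["Th"]]]
    differential_expression(mat, a, b) |>
      mutate(pairing = paste0(pr[["ILC"]], "_vs_", pr[["Th"]]))
  }))
  by_gene <- tab |>
    summarise(min_fc = min(.data$log2fc), max_fc = max(.data$log2fc),
              max_p = max(.data$p_value), .by = "gene")
  ilc <- by_gene$gene[by_gene$min_fc > lfc_min & by_gene$max_p < p_max]
  th <- by_gene$gene[by_gene$max_fc < -lfc_min & by_gene$max_p < p_max]
  list(sets = list(ILC = ilc, Th = th), table = tab)
}

#' Conserved immune-response genesets
#'
#' For each response type k: differential expression of subset k against the
#' other two subsets, separately within the ILC samples and within the Th
#' samples. A gene joins the type-k set iff both comparisons pass
#' `log2fc > lfc_min` and `p < p_max` with positive direction (conservation
#' across the innate and adaptive arms).
#'
#' @inheritParams lineage_genesets
#' @return List with `sets` (`type1`, `type2`, `type3`) and the long `table`.
#' @export
response_genesets <- function(mat, manifest, lfc_min = 0.25, p_max = 0.01) {
  manifest <- complete_manifest(manifest)
  missing_ct <- setdiff(CELL_TYPES, unique(manifest$cell_type))
  if (length(missing_ct) > 0) {
    abort(paste0("missing pairing subset(s): ", paste(missing_ct, collapse = ", ")))
  }
  rows <- list()
  for (k in 1:3) {
    for (lin in c("ILC", "Th")) {
      in_lin <- manifest[manifest$lineage == lin, ]
      a <- in_lin$sample_id[in_lin$response_type == k]
      b <- in_lin$sample_id[in_lin$response_type != k]
      rows[[paste(k, lin)]] <- differential_expression(mat, a, b) |>
        mutate(response_type = k, lineage = lin)
    }
  }
  tab <- list_rbind(rows)
  sets <- map(1:3, function(k) {
    sub <- tab[tab$response_type == k, ]
    by_gene <- sub |>
      summarise(min_fc = min(.data$log2fc), max_p = max(.data$p_value),
                .by = "gene")
    by_gene$gene[by_gene$min_fc > lfc_min & by_gene$max_p < p_max]
  })
  names(sets) <- paste0("type", 1:3)
  list(sets = sets, table = tab)
}

#' Hypergeometric over-representation of annotation terms
#'
#' One-sided hypergeometric enrichment of each term within `geneset`
#' against `universe`, Benjamini-Hochberg adjusted. Terms with no universe
#' genes are skipped with a message.
#'
#' @param geneset Gene ids (must be a subset of `universe`).
#' @param universe Background gene ids.
#' @param term_annotation Tibble with `term_id`, `gene_id` and optionally
#'   `description`.
#' @param q_max Significance flag threshold on the q-value (default 0.05).
#' @return Tibble sorted by q then p: `term_id`, `description`, counts,
#'   `p_value` (one-sided), `p_two_sided`, `q_value`, `significant`.
#' @export
go_overrepresentation <- function(geneset, universe, term_annotation,
                                  q_max = 0.05) {
  if (length(setdiff(geneset, universe)) > 0) {
    abort("geneset must be a subset of the universe")
  }
  term_annotation <- as_tibble(term_annotation)
  if (!"description" %in% names(term_annotation)) {
    term_annotation$description <- NA_character_
  }
  N <- length(unique(universe))
  n <- length(unique(geneset))
  terms <- split(term_annotation, term_annotation$term_id)
  skipped <- character(0)
  rows <- map(terms, function(tt) {
    tg <- intersect(unique(tt$gene_id), universe)
    if (length(tg) == 0) {
      skipped <<- c(skipped, tt$term_id[1])
      return(NULL)
    }
    k <- length(intersect(tg, geneset))
    ht <- hypergeom_test(k = k, K = length(tg), n = n, N = N)
    tibble(term_id = tt$term_id[1], description = tt$description[1],
           k = k, term_size = length(tg), geneset_size = n, universe_size = N,
           p_value = ht$one_sided, p_two_sided = ht$two_sided)
  })
  if (length(skipped) > 0) {
    inform(paste0("skipped term(s) with no universe genes: ",
                  paste(head(skipped, 5), collapse = ", ")))
  }
  out <- list_rbind(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(out) == 0) return(out)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < q_max
  arrange(out, .data$q_value, .data$p_value)
}
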