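# Synthetic six-subset study generator. Every stage of the analysis has a
# planted ground truth here: geneset membership, concordant peaks, motif
# occurrences. Each simulate_* function derives its own stream from
# config$seed (plus a fixed offset per stage), so individual calls and the
# composed bundle are both deterministic.

#' Simulate the sample manifest
#'
#' One record per sample across the six subsets, with batches assigned
#' round-robin within each subset and lineage / response type derived from
#' the cell type (ILC3 pairs with Th17).
#'
#' @param config A [sim_config()].
#' @return Tibble with `sample_id`, `cell_type`, `lineage`, `response_type`,
#'   `batch`.
#' @examples
#' nrow(simulate_manifest(sim_config()))  # 294 under the default design
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- imap(config$n_samples_per_subset[CELL_TYPES], function(n, ct) {
    tibble(
      sample_id = sprintf("%s_s%03d", ct, seq_len(n)),
      cell_type = ct,
      batch = sprintf("batch%02d", ((seq_len(n) - 1L) %% config$n_batches) + 1L)
    )
  })
  complete_manifest(list_rbind(rows)) |>
    select("sample_id", "cell_type", "lineage", "response_type", "batch")
}

#' Simulate the gene annotation
#'
#' Places genes at regularly spaced TSSs along synthetic chromosomes with
#' random strand and length. The spacing keeps each planted peak within the
#' annotation window of its own gene only. Coordinates are 0-based
#' half-open; `tss` is `start` on the + strand and `end - 1` on the - strand.
#'
#' @param config A [sim_config()].
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`,
#'   `length`.
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 4L, {
    n <- config$n_genes
    per_chrom <- ceiling(n / config$n_chroms)
    idx <- seq_len(n) - 1L
    chrom_i <- idx %/% per_chrom
    within_i <- idx %% per_chrom
    tss <- 100000 + within_i * config$gene_spacing
    if (max(tss) + 110000 > config$chrom_len) {
      abort("chrom_len too short for n_genes at the requested gene_spacing")
    }
    len <- round(runif(n, 500, 5000))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    start <- ifelse(strand == "+", tss, tss + 1 - len)
    end <- start + len
    tibble(
      gene_id = sprintf("gene_%04d", seq_len(n)),
      chrom = sprintf("chr%02d", chrom_i + 1L),
      start = as.integer(start), end = as.integer(end),
      strand = strand, tss = as.integer(tss), length = as.integer(len)
    )
  })
}

# Partition genes into the five planted genesets and designate TF genes
# (used downstream to map motifs onto expressed genes).
assign_genesets <- function(config, gene_ids) {
  shuffled <- sample(gene_ids)
  sizes <- config$geneset_sizes[c("ILC", "Th", "type1", "type2", "type3")]
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1) + 1L)
  sets <- setNames(map2(starts, stops, function(a, b) shuffled[a:b]), names(sizes))
  background <- shuffled[(stops[length(stops)] + 1L):length(shuffled)]
  tf_genes <- bind_rows(
    tibble(class = "ILC", tf_gene = sets$ILC[seq_len(config$n_motifs_per_class)]),
    tibble(class = "Th", tf_gene = sets$Th[seq_len(config$n_motifs_per_class)]),
    if (config$n_shared_motifs > 0) {
      tibble(class = "shared", tf_gene = background[seq_len(config$n_shared_motifs)])
    }
  )
  list(sets = sets, tf_genes = tf_genes, background = background)
}

#' Simulate the count matrix with planted genesets and batch effects
#'
#' Per gene and sample the log2 expected count is a gene baseline plus the
#' lineage effect (for ILC/Th geneset genes in their lineage), the response
#' effect (for type-k genes in response-k samples), and a gene-by-batch
#' offset drawn N(0, `batch_sd_log2`). Counts are negative-binomial with the
#' configured dispersion (Poisson at dispersion 0). Genes designated as
#' motif-mapped TFs get raised baselines so their TPM clears the
#' potential-TF expression gate in their own lineage.
#'
#' @param config A [sim_config()].
#' @param manifest Manifest from [simulate_manifest()].
#' @param genes Annotation from [simulate_genes()] (supplies gene ids).
#' @return List with `counts` (gene x sample integer matrix, layer
#'   `"counts"`) and `truth` (geneset membership, TF designations, batch
#'   offsets, baselines).
#' @export
simulate_expression <- function(config, manifest, genes) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- complete_manifest(manifest)
  with_seed(config$seed + 1L, {
    gene_ids <- genes$gene_id
    n_g <- length(gene_ids); n_s <- nrow(manifest)
    gs <- assign_genesets(config, gene_ids)

    baseline <- rnorm(n_g, config$baseline_log2_mean, config$baseline_log2_sd)
    names(baseline) <- gene_ids
    lineage_tf <- gs$tf_genes$tf_gene[gs$tf_genes$class %in% c("ILC", "Th")]
    shared_tf <- gs$tf_genes$tf_gene[gs$tf_genes$class == "shared"]
    baseline[lineage_tf] <- pmax(baseline[lineage_tf], config$baseline_log2_mean + 2)
    baseline[shared_tf] <- pmax(baseline[shared_tf], config$baseline_log2_mean + 3)

    batches <- sort(unique(manifest$batch))
    batch_offsets <- matrix(rnorm(length(batches) * n_g, 0, config$batch_sd_log2),
                            nrow = length(batches),
                            dimnames = list(batches, gene_ids))

    log2mu <- matrix(baseline, nrow = n_g, ncol = n_s,
                     dimnames = list(gene_ids, manifest$sample_id))
    for (lin in c("ILC", "Th")) {
      cols <- manifest$lineage == lin
      log2mu[gs$sets[[lin]], cols] <- log2mu[gs$sets[[lin]], cols] +
        config$lineage_effect_log2
    }
    for (k in 1:3) {
      cols <- manifest$response_type == k
      set_k <- gs$sets[[paste0("type", k)]]
      log2mu[set_k, cols] <- log2mu[set_k, cols] + config$response_effect_log2
    }
    log2mu <- log2mu + t(batch_offsets[manifest$batch, , drop = FALSE])

    mu <- 2^log2mu
    counts <- if (config$nb_dispersion > 0) {
      matrix(rnbinom(n_g * n_s, mu = mu, size = 1 / config$nb_dispersion),
             nrow = n_g, dimnames = dimnames(mu))
    } else {
      matrix(rpois(n_g * n_s, lambda = mu), nrow = n_g, dimnames = dimnames(mu))
    }
    list(
      counts = set_layer(counts, "counts"),
      truth = list(genesets = gs$sets, tf_genes = gs$tf_genes,
                   background_genes = gs$background,
                   batch_offsets = batch_offsets, baseline = baseline)
    )
  })
}

# Accessibility manifest: two replicates per subset, the design under which
# the replicate-separation rule is evaluable.
make_acc_manifest <- function() {
  tibble(
    acc_sample = as.vector(t(outer(CELL_TYPES, 1:2, function(ct, r) {
      sprintf("%s_r%d", ct, r)
    }))),
    cell_type = rep(CELL_TYPES, each = 2),
    replicate = rep(1:2, times = length(CELL_TYPES))
  ) |> mutate(lineage = lineage_of(.data$cell_type),
              response_type = response_of(.data$cell_type))
}

#' Simulate peaks with planted concordant accessibility
#'
#' For every geneset gene, `peaks_per_gene` peaks are placed at signed TSS
#' offsets drawn from a lineage-specific exponential, with Gaussian widths
#' truncated at 50 bp. A `concordant_fraction` of each gene's peaks get the
#' planted accessibility pattern: high BPM (times lognormal replicate noise)
#' in the up-lineage samples (lineage genesets) or the up-subset replicates
#' (type genesets, random direction per peak) and low BPM elsewhere. The
#' remaining peaks are flat. Decoy peaks beyond the 50 kb window are also
#' emitted.
#'
#' @param config A [sim_config()].
#' @param genes Annotation from [simulate_genes()].
#' @param truth Truth list from [simulate_expression()].
#' @return List with `peaks` (tibble: `peak_id`, `chrom`, `start`, `end`),
#'   `bpm` (peak x accessibility-sample matrix), `acc_manifest`, and `truth`
#'   gaining a `peaks` table of planted classes.
#' @export
simulate_peaks <- function(config, genes, truth) {
  stopifnot(inherits(config, "sim_config"))
  gene_tbl <- genes
  missing <- setdiff(unlist(truth$genesets), gene_tbl$gene_id)
  if (length(missing) > 0) {
    abort(paste0("gene annotation missing geneset gene(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  with_seed(config$seed + 2L, {
    window <- 50000
    k_conc <- round(config$concordant_fraction * config$peaks_per_gene)
    plan <- list_rbind(imap(truth$genesets, function(set_genes, label) {
      list_rbind(map(set_genes, function(g) {
        conc <- seq_len(config$peaks_per_gene) %in%
          sample(config$peaks_per_gene, k_conc)
        dir <- if (label %in% c("ILC", "Th")) {
          rep(label, config$peaks_per_gene)
        } else {
          sample(c("ILC", "Th"), config$peaks_per_gene, replace = TRUE)
        }
        tibble(gene_id = g, geneset = label, lineage_class = dir,
               concordant = conc, decoy = FALSE)
      }))
    }))
    if (config$n_decoy_peaks > 0) {
      decoy_genes <- sample(unlist(truth$genesets), config$n_decoy_peaks,
                            replace = TRUE)
      plan <- bind_rows(plan, tibble(
        gene_id = decoy_genes, geneset = "decoy",
        lineage_class = sample(c("ILC", "Th"), config$n_decoy_peaks, TRUE),
        concordant = FALSE, decoy = TRUE
      ))
    }
    gene_lookup <- gene_tbl[match(plan$gene_id, gene_tbl$gene_id), ]

    n_pk <- nrow(plan)
    start <- integer(n_pk); end <- integer(n_pk)
    for (i in seq_len(n_pk)) {
      wp <- config$width_params[[plan$lineage_class[i]]]
      scale <- config$tss_dist_scale[[plan$lineage_class[i]]]
      ok <- FALSE
      for (attempt in 1:100) {
        width <- max(50, round(rnorm(1, wp[["mean"]], wp[["sd"]])))
        off <- if (plan$decoy[i]) {
          round(runif(1, window + 5000, window + 55000)) * sample(c(-1L, 1L), 1)
        } else {
          o <- round(rexp(1, 1 / scale)) * sample(c(-1L, 1L), 1)
          if (abs(o) > window) next
          o
        }
        mid <- gene_lookup$tss[i] + off
        s <- mid - floor(width / 2); e <- s + width
        if (s >= 0 && e <= config$chrom_len) { ok <- TRUE; break }
      }
      if (!ok) abort("could not place peak within chromosome bounds in 100 attempts")
      start[i] <- s; end[i] <- e
    }

    acc <- make_acc_manifest()
    planted_class <- rep("nonconcordant", n_pk)
    planted_class[plan$decoy] <- "decoy"
    lin_conc <- plan$concordant & plan$geneset %in% c("ILC", "Th")
    planted_class[lin_conc] <- paste0(plan$geneset[lin_conc], "_concordant")
    type_conc <- plan$concordant & startsWith(plan$geneset, "type")
    if (any(type_conc)) {
      subset_ct <- mapply(function(gs, lc) PAIRINGS[[gs]][[lc]],
                          plan$geneset[type_conc], plan$lineage_class[type_conc])
      planted_class[type_conc] <- paste0(subset_ct, "_specific")
    }

    base <- matrix(config$bpm_flat, nrow = n_pk, ncol = nrow(acc),
                   dimnames = list(sprintf("peak_%05d", seq_len(n_pk)),
                                   acc$acc_sample))
    for (i in seq_len(n_pk)) {
      cls <- planted_class[i]
      if (cls %in% c("ILC_concordant", "Th_concordant")) {
        up <- acc$lineage == sub("_concordant", "", cls)
        base[i, up] <- config$bpm_high
        base[i, !up] <- config$bpm_low
      } else if (grepl("_specific$", cls)) {
        up_ct <- sub("_specific", "", cls)
        base[i, ] <- config$bpm_low
        base[i, acc$cell_type == up_ct] <- config$bpm_high
      }
    }
    noise <- matrix(rlnorm(length(base), 0, config$bpm_noise_sdlog),
                    nrow = n_pk)
    bpm <- base * noise

    peaks <- tibble(
      peak_id = rownames(base),
      chrom = gene_lookup$chrom,
      start = start, end = end
    )
    truth$peaks <- tibble(
      peak_id = peaks$peak_id, gene_id = plan$gene_id,
      geneset = plan$geneset, lineage_class = plan$lineage_class,
      planted_class = planted_class, concordant = plan$concordant
    )
    list(peaks = peaks, bpm = bpm, acc_manifest = acc, truth = truth)
  })
}

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

mutate_consensus <- function(consensus, keep_prob) {
  n <- length(consensus)
  flip <- runif(n) > keep_prob
  out <- consensus
  if (any(flip)) {
    out[flip] <- map_int(consensus[flip], function(b) {
      sample(setdiff(1:4, b), 1)
    })
  }
  out
}

revcomp_idx <- function(idx) rev(5L - idx)

#' Simulate peak sequences and the generating PWMs
#'
#' Uniform-background sequence per peak with motif instances
#' (consensus-with-noise draws from the generating PWM) planted at
#' `motif_plant_rate_fg` in class-matched peaks (ILC-class motifs in
#' ILC-concordant and ILC-subset-specific peaks, Th symmetric, shared motifs
#' in every concordant/specific peak) and `motif_plant_rate_bg` elsewhere.
#' Instances avoid overlapping each other; strand is random. The emitted
#' PWMs are the generating models, and every surviving planting is recorded
#' in the truth.
#'
#' @param config A [sim_config()].
#' @param peaks Peak tibble from [simulate_peaks()].
#' @param truth Truth list (with `peaks` and `tf_genes`).
#' @return List with `sequences` (named character vector), `pwms` (list of
#'   pwm objects), and `truth` gaining `planted_motifs`.
#' @export
simulate_sequences_and_pwms <- function(config, peaks, truth) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    L <- config$motif_length
    widths <- peaks$end - peaks$start
    if (any(widths < L + 2)) abort("all peak widths must be >= motif length + 2")

    classes <- truth$tf_genes$class
    pwms <- vector("list", length(classes))
    consensus <- vector("list", length(classes))
    counters <- c(ILC = 0L, Th = 0L, shared = 0L)
    for (i in seq_along(classes)) {
      cl <- classes[i]
      counters[cl] <- counters[cl] + 1L
      cons <- sample(1:4, L, replace = TRUE)
      m <- matrix((1 - config$motif_consensus_prob) / 3, nrow = L, ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
      m[cbind(seq_len(L), cons)] <- config$motif_consensus_prob
      pwms[[i]] <- new_pwm(
        motif_id = sprintf("motif_%s_%d", cl, counters[cl]),
        tf_name = truth$tf_genes$tf_gene[i],
        matrix = m, pseudocount = 0
      )
      consensus[[i]] <- cons
    }
    names(pwms) <- map_chr(pwms, "motif_id")
    motif_class <- setNames(classes, names(pwms))

    pk_class <- truth$peaks$planted_class[match(peaks$peak_id, truth$peaks$peak_id)]
    matched <- function(m_cl, p_cl) {
      if (p_cl %in% c("nonconcordant", "decoy")) return(FALSE)
      if (m_cl == "shared") return(TRUE)
      startsWith(p_cl, m_cl)
    }

    seqs <- character(nrow(peaks))
    planted <- vector("list", nrow(peaks))
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(peaks))) {
      w <- widths[i]
      sv <- random_bases(w)
      taken <- logical(w)
      recs <- list()
      for (mid in names(pwms)) {
        rate <- if (matched(motif_class[[mid]], pk_class[i])) {
          config$motif_plant_rate_fg
        } else {
          config$motif_plant_rate_bg
        }
        if (rate <= 0 || runif(1) > rate) next
        placed <- FALSE
        for (try in 1:20) {
          off <- sample.int(w - L + 1L, 1) - 1L
          span <- (off + 1L):(off + L)
          if (any(taken[span])) next
          inst <- mutate_consensus(consensus[[which(names(pwms) == mid)]],
                                   config$motif_consensus_prob)
          strand <- sample(c("+", "-"), 1)
          if (strand == "-") inst <- revcomp_idx(inst)
          sv[span] <- bases[inst]
          taken[span] <- TRUE
          recs[[length(recs) + 1L]] <- tibble(
            peak_id = peaks$peak_id[i], motif_id = mid,
            offset = off, strand = strand
          )
          placed <- TRUE
          break
        }
        if (!placed) next
      }
      seqs[i] <- paste(sv, collapse = "")
      planted[[i]] <- if (length(recs)) list_rbind(recs) else NULL
    }
    names(seqs) <- peaks$peak_id
    truth$planted_motifs <- list_rbind(planted[!vapply(planted, is.null, TRUE)])
    list(sequences = seqs, pwms = pwms, truth = truth)
  })
}

#' Simulate a complete study bundle
#'
#' Composes manifest, gene annotation, counts, peaks with accessibility,
#' peak sequences and PWMs into a single object with the full planted truth.
#' Identical configurations (including the seed) reproduce the bundle
#' exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_bundle`.
#' @examples
#' b <- simulate_bundle(sim_config(
#'   n_samples_per_subset = setNames(rep(4, 6), c("ILC1","ILC2","ILC3","Th1","Th2","Th17")),
#'   n_genes = 120, geneset_sizes = c(ILC = 8, Th = 8, type1 = 4, type2 = 4, type3 = 4),
#'   n_decoy_peaks = 10, seed = 1))
#' @export
simulate_bundle <- function(config = sim_config()) {
  manifest <- simulate_manifest(config)
  genes <- simulate_genes(config)
  ex <- simulate_expression(config, manifest, genes)
  pk <- simulate_peaks(config, genes, ex$truth)
  sq <- simulate_sequences_and_pwms(config, pk$peaks, pk$truth)
  structure(list(
    config = config,
    manifest = manifest,
    genes = genes,
    gene_lengths = setNames(genes$length, genes$gene_id),
    counts = ex$counts,
    peaks = pk$peaks,
    bpm = pk$bpm,
    acc_manifest = pk$acc_manifest,
    sequences = sq$sequences,
    pwms = sq$pwms,
    truth = sq$truth
  ), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("<sim_bundle>\n")
  cat(" ", nrow(x$manifest), "samples,", nrow(x$genes), "genes,",
      nrow(x$peaks), "peaks,", length(x$pwms), "motifs\n")
  cat("  planted genesets:",
      paste(sprintf("%s=%d", names(x$truth$genesets),
                    lengths(x$truth$genesets)), collapse = " "), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Score recovered genesets against the planted truth
#'
#' @param sets Named list of recovered gene-id vectors.
#' @param truth Bundle truth (with `genesets`).
#' @return Tibble with per-set `n_true`, `n_called`, `tp`, `sensitivity`,
#'   `fdr` (FDR is 0 when nothing is called).
#' @export
geneset_recovery <- function(sets, truth) {
  list_rbind(imap(sets, function(called, label) {
    planted <- truth$genesets[[label]]
    if (is.null(planted)) abort(paste0("no planted truth for geneset ", label))
    tp <- length(intersect(called, planted))
    tibble(
      geneset = label,
      n_true = length(planted), n_called = length(called), tp = tp,
      sensitivity = tp / length(planted),
      fdr = if (length(called) == 0) 0 else 1 - tp / length(called)
    )
  }))
}
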