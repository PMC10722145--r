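# Orchestration: validate a bundle, run the stages in order, and collect a
# run report with internally consistent counts.

#' Validate a study bundle before running the pipeline
#'
#' Checks sample-id agreement between the manifest and the count matrix,
#' six-subset coverage, accessibility replicate structure (the replicate
#' separation rule needs two repeats per subset), peak coordinate sanity,
#' and PWM well-formedness. Problems are reported, not thrown.
#'
#' @param bundle A `sim_bundle` or the list returned by [read_bundle()].
#' @return Tibble with `check`, `status` (`"ok"`, `"warning"`, `"fatal"`)
#'   and `detail`.
#' @export
validate_bundle <- function(bundle) {
  rows <- list()
  add <- function(check, status, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble(check = check, status = status,
                                         detail = detail)
  }
  missing <- setdiff(bundle$manifest$sample_id, colnames(bundle$counts))
  if (length(missing) > 0) {
    add("counts_samples", "fatal",
        paste("manifest sample(s) missing from counts:",
              paste(head(missing, 5), collapse = ", ")))
  } else add("counts_samples", "ok")

  absent <- setdiff(CELL_TYPES, unique(bundle$manifest$cell_type))
  if (length(absent) > 0) {
    add("six_subsets", "fatal",
        paste("subset(s) absent:", paste(absent, collapse = ", ")))
  } else add("six_subsets", "ok")

  if (!is.null(bundle$peaks) && nrow(bundle$peaks) > 0) {
    bad <- bundle$peaks$end <= bundle$peaks$start
    if (any(bad)) {
      add("peak_coordinates", "fatal",
          paste(sum(bad), "peak(s) with end <= start"))
    } else add("peak_coordinates", "ok")
  }
  if (!is.null(bundle$acc_manifest)) {
    tab <- table(bundle$acc_manifest$cell_type)
    absent_acc <- setdiff(CELL_TYPES, names(tab))
    single <- names(tab)[tab < 2]
    if (length(absent_acc) > 0 || length(single) > 0) {
      add("accessibility_replicates", "fatal",
          paste("subset(s) without both repeats:",
                paste(c(absent_acc, single), collapse = ", ")))
    } else add("accessibility_replicates", "ok")
    missing_acc <- setdiff(bundle$acc_manifest$acc_sample, colnames(bundle$bpm))
    if (length(missing_acc) > 0) {
      add("bpm_samples", "fatal",
          paste("accessibility sample(s) missing from bpm:",
                paste(missing_acc, collapse = ", ")))
    } else add("bpm_samples", "ok")
  }
  if (!is.null(bundle$pwms)) {
    bad_pwm <- names(bundle$pwms)[vapply(bundle$pwms, function(p) {
      any(abs(rowSums(p$matrix) - 1) > 0.01) || nrow(p$matrix) < 4
    }, TRUE)]
    if (length(bad_pwm) > 0) {
      add("pwm_rows", "fatal",
          paste("malformed PWM(s):", paste(bad_pwm, collapse = ", ")))
    } else add("pwm_rows", "ok")
  }
  if (!is.null(bundle$sequences) && !is.null(bundle$peaks)) {
    widths <- bundle$peaks$end - bundle$peaks$start
    seq_lens <- nchar(bundle$sequences[bundle$peaks$peak_id])
    if (any(seq_lens != widths, na.rm = TRUE)) {
      add("sequence_widths", "warning",
          paste(sum(seq_lens != widths, na.rm = TRUE),
                "sequence length(s) differ from peak width"))
    } else add("sequence_widths", "ok")
  }
  list_rbind(rows)
}

#' Run the full analysis pipeline on a bundle
#'
#' Executes the stages in fixed order — expression (TPM, filter, batch
#' removal, clustering QC, genesets), chromatin (annotation, concordant and
#' subset-specific classification, coverage, geometry), motif (calibration,
#' scan, enrichment, potential TFs, occupancy comparison) — and returns a
#' `run_report`. Thresholds default to the values used throughout the
#' package. If `bundle` is omitted it is simulated from `config`, in which
#' case geneset recovery against the planted truth is also reported.
#'
#' @param config A [sim_config()]; used to simulate when `bundle` is NULL
#'   and echoed into the report.
#' @param bundle Optional pre-built bundle (simulated or read from disk).
#' @param stages Character subset of `c("expression", "chromatin", "motif")`;
#'   later stages require the earlier ones.
#' @param min_tpm,min_frac Low-expression filter thresholds.
#' @param lfc_min,p_max Differential-expression thresholds.
#' @param n_pcs Principal components for the clustering QC.
#' @param tss_window Peak-to-TSS annotation window (bp).
#' @param fc_min,bpm_floor Concordance-rule thresholds.
#' @param width_ref,tss_ref Geometry references (bp).
#' @param motif_p Per-window scan p-value target.
#' @param pseudocount PWM pseudocount at calibration.
#' @param tf_tpm_min,top_n Potential-TF gates.
#' @param quiet Suppress stage progress messages.
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config = sim_config(), bundle = NULL,
                         stages = c("expression", "chromatin", "motif"),
                         min_tpm = 10, min_frac = 0.8,
                         lfc_min = 0.25, p_max = 0.01, n_pcs = 20,
                         tss_window = 50000, fc_min = 1.5, bpm_floor = 0.5,
                         width_ref = 500, tss_ref = 1000,
                         motif_p = 1e-4, pseudocount = 0.1,
                         tf_tpm_min = 50, top_n = 10, quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (!quiet) inform(paste0("[", ..1, "] ", ..2))
  thresholds <- list(min_tpm = min_tpm, min_frac = min_frac, lfc_min = lfc_min,
                     p_max = p_max, n_pcs = n_pcs, tss_window = tss_window,
                     fc_min = fc_min, bpm_floor = bpm_floor,
                     width_ref = width_ref, tss_ref = tss_ref,
                     motif_p = motif_p, pseudocount = pseudocount,
                     tf_tpm_min = tf_tpm_min, top_n = top_n)

  if (is.null(bundle)) {
    say("simulate", sprintf("generating bundle (seed %d)", config$seed))
    bundle <- simulate_bundle(config)
  }
  checks <- validate_bundle(bundle)
  fatal <- checks[checks$status == "fatal", ]
  if (nrow(fatal) > 0) {
    abort(paste0("input validation failed: ",
                 paste(fatal$check, fatal$detail, sep = " - ", collapse = "; ")))
  }
  report <- list(config = bundle$config %||% config, thresholds = thresholds,
                 seed = (bundle$config %||% config)$seed, checks = checks,
                 n_samples = nrow(bundle$manifest),
                 n_genes = nrow(bundle$counts))

  if (!"expression" %in% stages) {
    return(structure(report, class = "run_report"))
  }
  say("expression", "TPM, filtering, batch removal")
  tpm <- compute_tpm(bundle$counts, bundle$gene_lengths)
  kept <- filter_low_expression(tpm, bundle$manifest, min_tpm, min_frac)
  tpm_f <- set_layer(tpm[kept, , drop = FALSE], "tpm")
  corrected <- remove_batch_effect(log_tpm(tpm_f), bundle$manifest)
  qc <- embed_and_score(corrected, bundle$manifest, n_pcs = n_pcs,
                        seed = report$seed)
  say("expression", sprintf("%d genes kept; clustering ARI %.3f",
                            length(kept), qc$ari))
  lin <- lineage_genesets(corrected, bundle$manifest, lfc_min, p_max)
  resp <- response_genesets(corrected, bundle$manifest, lfc_min, p_max)
  genesets <- c(lin$sets, resp$sets)
  say("expression", paste("geneset sizes:",
                          paste(sprintf("%s=%d", names(genesets),
                                        lengths(genesets)), collapse = " ")))
  report$tpm <- tpm
  report$filtered_genes <- kept
  report$corrected <- corrected
  report$embedding_qc <- qc
  report$genesets <- genesets
  report$de_tables <- list(lineage = lin$table, response = resp$table)
  if (!is.null(bundle$truth)) {
    report$geneset_recovery <- geneset_recovery(genesets, bundle$truth)
  }

  if (!"chromatin" %in% stages) {
    return(structure(report, class = "run_report"))
  }
  gene_missing <- setdiff(unlist(genesets), bundle$genes$gene_id)
  if (length(gene_missing) > 0) {
    abort(paste0("stage contract violation: geneset gene(s) absent from ",
                 "annotation: ", paste(head(gene_missing, 5), collapse = ", ")))
  }
  say("chromatin", "annotating peaks and classifying OCRs")
  links <- annotate_peaks(bundle$peaks, bundle$genes, window = tss_window)
  classifications <- list(
    ILC = classify_concordant(bundle$bpm, bundle$acc_manifest, links,
                              genesets$ILC, direction = "ILC",
                              geneset_label = "ILC",
                              fc_min = fc_min, bpm_floor = bpm_floor),
    Th = classify_concordant(bundle$bpm, bundle$acc_manifest, links,
                             genesets$Th, direction = "Th",
                             geneset_label = "Th",
                             fc_min = fc_min, bpm_floor = bpm_floor)
  )
  coverage <- list_rbind(imap(classifications, function(cl, label) {
    if (length(genesets[[label]]) == 0 || nrow(cl) == 0) {
      return(tibble(geneset = label, n_genes = length(genesets[[label]]),
                    n_covered = 0L, fraction = NA_real_))
    }
    gene_coverage(cl, links, genesets[[label]]) |>
      mutate(geneset = label, .before = 1)
  }))
  subset_specific <- map(1:3, function(k) {
    classify_subset_specific(bundle$bpm, bundle$acc_manifest, links,
                             genesets[[paste0("type", k)]], pairing = k,
                             fc_min = fc_min, bpm_floor = bpm_floor)
  })
  names(subset_specific) <- paste0("type", 1:3)
  conc_ids <- map(classifications, ~ .x$peak_id[.x$class == "concordant"])
  geometry <- if (all(lengths(conc_ids) > 0)) {
    geometry_stats(bundle$peaks, links, conc_ids$ILC, conc_ids$Th,
                   labels = c("ILC_concordant", "Th_concordant"),
                   width_ref = width_ref, tss_ref = tss_ref)
  } else NULL
  say("chromatin", sprintf("concordant OCRs: ILC %d / Th %d",
                           length(conc_ids$ILC), length(conc_ids$Th)))
  report$links <- links
  report$classifications <- classifications
  report$subset_specific <- subset_specific
  report$coverage <- coverage
  report$geometry <- geometry
  report$concordant_ids <- conc_ids

  if (!"motif" %in% stages) {
    return(structure(report, class = "run_report"))
  }
  if (is.null(bundle$pwms) || is.null(bundle$sequences)) {
    abort("motif stage requires sequences and pwms in the bundle")
  }
  if (any(lengths(conc_ids) == 0)) {
    abort("motif stage requires non-empty concordant OCR sets")
  }
  say("motif", "calibrating and scanning PWMs")
  calibrations <- map(bundle$pwms, calibrate_threshold,
                      p_target = motif_p, pseudocount = pseudocount)
  scan <- scan_peaks(bundle$sequences, bundle$pwms, calibrations)
  tf_map <- tibble(motif_id = map_chr(bundle$pwms, "motif_id"),
                   tf_gene = map_chr(bundle$pwms, "tf_name"))
  enrichment <- list(
    ILC = motif_enrichment(scan, conc_ids$ILC, conc_ids$Th),
    Th = motif_enrichment(scan, conc_ids$Th, conc_ids$ILC)
  )
  subsets_of <- list(ILC = CELL_TYPES[1:3], Th = CELL_TYPES[4:6])
  top_tfs <- imap(enrichment, function(recs, lin) {
    potential_tfs(recs, tpm, bundle$manifest, tf_map,
                  subsets = subsets_of[[lin]], tpm_min = tf_tpm_min,
                  p_max = p_max, top_n = top_n)
  })
  comparisons <- imap(top_tfs, function(tt, lin) {
    if (nrow(tt) == 0) return(NULL)
    sets <- if (lin == "ILC") conc_ids[c("ILC", "Th")] else conc_ids[c("Th", "ILC")]
    occupancy_fraction_comparison(scan, tt$motif_id, sets[[1]], sets[[2]])
  })
  say("motif", sprintf("top TFs: ILC %d / Th %d",
                       nrow(top_tfs$ILC), nrow(top_tfs$Th)))
  report$calibrations <- calibrations
  report$scan <- scan
  report$tf_map <- tf_map
  report$enrichment <- enrichment
  report$top_tfs <- top_tfs
  report$occupancy_comparisons <- comparisons
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  cat(" ", x$n_samples, "samples,", x$n_genes, "genes",
      if (!is.null(x$filtered_genes)) {
        paste0("(", length(x$filtered_genes), " after filtering)")
      } else "", "\n")
  if (!is.null(x$genesets)) {
    cat("  genesets:", paste(sprintf("%s=%d", names(x$genesets),
                                     lengths(x$genesets)), collapse = " "), "\n")
    cat("  clustering ARI:", round(x$embedding_qc$ari, 3), "\n")
  }
  if (!is.null(x$classifications)) {
    for (lab in names(x$classifications)) {
      cl <- x$classifications[[lab]]
      cat(sprintf("  %s OCRs: %d concordant / %d non-concordant\n", lab,
                  sum(cl$class == "concordant"),
                  sum(cl$class == "non_concordant")))
    }
  }
  if (!is.null(x$top_tfs)) {
    cat("  top TFs (ILC):", paste(head(x$top_tfs$ILC$tf_gene, 5), collapse = " "),
        "\n  top TFs (Th): ", paste(head(x$top_tfs$Th$tf_gene, 5), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @rdname glance.run_report
#' @export
tidy.run_report <- function(x, ...) {
  rows <- list(tibble(stage = "input", quantity = "n_samples",
                      value = as.numeric(x$n_samples)),
               tibble(stage = "input", quantity = "n_genes",
                      value = as.numeric(x$n_genes)))
  if (!is.null(x$filtered_genes)) {
    rows <- c(rows, list(
      tibble(stage = "expression", quantity = "n_filtered_genes",
             value = length(x$filtered_genes)),
      tibble(stage = "expression", quantity = "clustering_ari",
             value = x$embedding_qc$ari),
      tibble(stage = "expression",
             quantity = paste0("geneset_", names(x$genesets)),
             value = as.numeric(lengths(x$genesets)))
    ))
  }
  if (!is.null(x$classifications)) {
    rows <- c(rows, list(list_rbind(imap(x$classifications, function(cl, lab) {
      tibble(stage = "chromatin",
             quantity = paste0(lab, c("_concordant", "_non_concordant")),
             value = c(sum(cl$class == "concordant"),
                       sum(cl$class == "non_concordant")))
    })),
    tibble(stage = "chromatin",
           quantity = paste0("coverage_", x$coverage$geneset),
           value = x$coverage$fraction)))
  }
  if (!is.null(x$top_tfs)) {
    rows <- c(rows, list(tibble(
      stage = "motif", quantity = c("n_top_tfs_ILC", "n_top_tfs_Th"),
      value = c(nrow(x$top_tfs$ILC), nrow(x$top_tfs$Th)))))
  }
  list_rbind(rows)
}

#' Summarise a pipeline run
#'
#' `glance()` returns a one-row tibble of the run's headline numbers;
#' `tidy()` a long table of per-stage quantities.
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.run_report <- function(x, ...) {
  out <- tibble(seed = x$seed, n_samples = x$n_samples, n_genes = x$n_genes)
  if (!is.null(x$filtered_genes)) {
    out$n_filtered_genes <- length(x$filtered_genes)
    out$clustering_ari <- x$embedding_qc$ari
    for (nm in names(x$genesets)) {
      out[[paste0("n_", nm)]] <- length(x$genesets[[nm]])
    }
  }
  if (!is.null(x$classifications)) {
    out$n_ilc_concordant <- sum(x$classifications$ILC$class == "concordant")
    out$n_th_concordant <- sum(x$classifications$Th$class == "concordant")
  }
  out
}
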