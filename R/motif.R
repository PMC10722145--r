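# Motif stage: PWM log-odds scanning with exact p-value calibration by
# dynamic programming over a discretised score grid, per-peak occupancy,
# hypergeometric enrichment between OCR classes, expression-gated
# potential-TF calling, and occupancy-fraction comparisons.

BASES <- c("A", "C", "G", "T")

pwm_probs <- function(pwm, pseudocount = NULL) {
  pc <- pseudocount %||% pwm$pseudocount %||% 0
  m <- (pwm$matrix + pc) / (1 + 4 * pc)
  m / rowSums(m)
}

#' Calibrate a PWM score threshold to an exact p-value
#'
#' Log2-odds scores against a 0-order background are discretised to an
#' integer grid at `precision` log-odds units. The exact null score
#' distribution of a random background window is computed by position-wise
#' convolution, and the threshold is the smallest grid score whose tail
#' probability does not exceed `p_target` (so the attained p-value is
#' conservative). Scanning uses the identical integer grid.
#'
#' @param pwm A pwm object (see [read_meme()]); its recorded pseudocount is
#'   applied and renormalised before scoring unless overridden.
#' @param background Background base probabilities (A, C, G, T; sum to 1).
#' @param p_target Per-window p-value target (default 1e-4).
#' @param precision Score grid resolution in log2-odds units (default 1e-3).
#' @param pseudocount Optional override of the motif's pseudocount.
#' @return Object of class `scan_calibration` with the integer score matrix,
#'   `threshold_int`, `threshold_score`, `attained_pvalue` and the full null
#'   score distribution.
#' @export
calibrate_threshold <- function(pwm, background = rep(0.25, 4),
                                p_target = 1e-4, precision = 1e-3,
                                pseudocount = NULL) {
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    abort("background probabilities must be positive and sum to 1")
  }
  m <- pwm_probs(pwm, pseudocount)
  if (any(m <= 0)) {
    abort(paste0("motif ", pwm$motif_id,
                 " has zero probabilities and zero pseudocount (infinite log-odds)"))
  }
  L <- nrow(m)
  lo <- log2(sweep(m, 2, background, "/"))
  ints <- matrix(as.integer(round(lo / precision)), nrow = L)
  colnames(ints) <- BASES

  # exact null distribution by convolution over positions
  cur <- 1; cur_base <- 0L
  for (j in seq_len(L)) {
    mins <- min(ints[j, ]); maxs <- max(ints[j, ])
    new <- numeric(length(cur) + (maxs - mins))
    for (b in 1:4) {
      sh <- ints[j, b] - mins
      idx <- (1L + sh):(length(cur) + sh)
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new
    cur_base <- cur_base + mins
  }
  scores_int <- cur_base + seq_along(cur) - 1L
  tail_p <- rev(cumsum(rev(cur)))
  ok <- which(tail_p <= p_target)
  if (length(ok) == 0) {
    threshold_int <- scores_int[length(scores_int)] + 1L
    attained <- 0
  } else {
    threshold_int <- scores_int[ok[1]]
    attained <- tail_p[ok[1]]
  }
  structure(list(
    motif_id = pwm$motif_id, tf_name = pwm$tf_name,
    background = background, precision = precision, p_target = p_target,
    int_matrix = ints,
    threshold_int = threshold_int,
    threshold_score = threshold_int * precision,
    attained_pvalue = attained,
    null_scores_int = scores_int, null_probs = cur
  ), class = "scan_calibration")
}

#' @export
print.scan_calibration <- function(x, ...) {
  cat("<scan_calibration>", x$motif_id,
      sprintf("threshold %.3f log2-odds (attained p = %.3g <= %.1g)\n",
              x$threshold_score, x$attained_pvalue, x$p_target))
  invisible(x)
}

encode_seq <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES)
  v  # N and anything else -> NA; windows containing NA are skipped
}

#' Scan peak sequences for calibrated PWM hits
#'
#' Scores every window on both strands on the calibration's integer grid; a
#' hit is a window scoring at or above the calibrated threshold. Windows
#' containing non-ACGT characters are skipped. Sequences shorter than a
#' motif contribute no windows for it.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of peak sequences.
#' @param pwms List of pwm objects.
#' @param calibrations List of [calibrate_threshold()] results matching
#'   `pwms` by `motif_id`.
#' @return Object of class `occupancy_scan`: `occupancy` (binary peak x
#'   motif matrix), `hits` (tibble with `peak_id`, `motif_id`, `offset`
#'   0-based, `strand`, `score`), and scan metadata.
#' @export
scan_peaks <- function(seqs, pwms, calibrations) {
  if (is(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    abort("sequences must be named by peak id")
  }
  cal_ids <- map_chr(calibrations, "motif_id")
  names(calibrations) <- cal_ids
  pwm_ids <- map_chr(pwms, "motif_id")
  missing <- setdiff(pwm_ids, cal_ids)
  if (length(missing) > 0) {
    abort(paste0("no calibration for motif(s): ", paste(missing, collapse = ", ")))
  }

  enc <- lapply(seqs, encode_seq)
  lens <- lengths(enc)
  max_l <- max(vapply(pwms, function(p) nrow(p$matrix), 1L))
  spacer <- rep(NA_integer_, max_l)
  big <- unlist(map(enc, function(v) c(v, spacer)), use.names = FALSE)
  starts <- cumsum(c(1L, head(lens + max_l, -1)))  # 1-based start of each peak

  n_windows_total <- 0
  hits <- list()
  occupancy <- matrix(0L, nrow = length(seqs), ncol = length(pwms),
                      dimnames = list(names(seqs), pwm_ids))
  short_count <- 0L
  slice_cache <- list()  # window slices shared across motifs of equal length
  for (pi in seq_along(pwms)) {
    mid <- pwm_ids[pi]
    cal <- calibrations[[mid]]
    ints <- cal$int_matrix
    L <- nrow(ints)
    short_count <- max(short_count, sum(lens < L))
    n_windows_total <- n_windows_total + 2 * sum(pmax(lens - L + 1L, 0L))
    luts <- list("+" = ints, "-" = ints[rev(seq_len(L)), 4:1, drop = FALSE])
    W <- length(big) - L + 1L
    key <- as.character(L)
    if (is.null(slice_cache[[key]])) {
      slice_cache[[key]] <- lapply(seq_len(L), function(j) big[j:(j + W - 1L)])
    }
    slices <- slice_cache[[key]]
    for (strand in c("+", "-")) {
      lut <- luts[[strand]]
      sc <- numeric(W)
      for (j in seq_len(L)) {
        sc <- sc + lut[j, ][slices[[j]]]
      }
      pos <- which(!is.na(sc) & sc >= cal$threshold_int)
      if (length(pos) > 0) {
        pk_idx <- findInterval(pos, starts)
        offset <- pos - starts[pk_idx]
        keep <- offset <= lens[pk_idx] - L  # guard; spacers already NA
        pos <- pos[keep]; pk_idx <- pk_idx[keep]; offset <- offset[keep]
        if (length(pos) > 0) {
          hits[[paste(mid, strand)]] <- tibble(
            peak_id = names(seqs)[pk_idx], motif_id = mid,
            offset = as.integer(offset), strand = strand,
            score = unname(sc[pos]) * cal$precision
          )
          occupancy[cbind(pk_idx, pi)] <- 1L
        }
      }
    }
  }
  if (short_count > 0) {
    inform(paste0(short_count,
                  " sequence(s) shorter than a motif scanned with zero windows"))
  }
  hits_tbl <- if (length(hits)) list_rbind(unname(hits)) else {
    tibble(peak_id = character(), motif_id = character(),
           offset = integer(), strand = character(), score = double())
  }
  structure(list(occupancy = occupancy, hits = hits_tbl,
                 n_windows = n_windows_total),
            class = "occupancy_scan")
}

#' @export
print.occupancy_scan <- function(x, ...) {
  cat("<occupancy_scan>", nrow(x$occupancy), "peaks x",
      ncol(x$occupancy), "motifs;", nrow(x$hits), "hits\n")
  invisible(x)
}

#' Hypergeometric motif enrichment between two peak sets
#'
#' Per motif, tests whether its occupancy concentrates in the foreground:
#' draws of size |fg| from the |fg| + |bg| classified peaks, with the
#' motif's total occupied peaks as the category. Both the one-sided
#' enrichment tail (used for ranking and for the enrichment score
#' `-log10(p)`) and the two-sided minimum-likelihood p-value are reported.
#'
#' @param occupancy Binary peak x motif matrix (or an `occupancy_scan`).
#' @param fg_peaks,bg_peaks Disjoint, non-empty peak-id sets.
#' @return Tibble sorted by the one-sided tail: `motif_id`, hit counts and
#'   totals, `p_value` (one-sided), `p_two_sided`, `enrichment_score`.
#' @export
motif_enrichment <- function(occupancy, fg_peaks, bg_peaks) {
  if (is(occupancy, "occupancy_scan") ||
      (is.list(occupancy) && !is.matrix(occupancy))) {
    occupancy <- occupancy$occupancy
  }
  if (length(fg_peaks) == 0 || length(bg_peaks) == 0) {
    abort("foreground and background must be non-empty")
  }
  if (length(intersect(fg_peaks, bg_peaks)) > 0) {
    abort("foreground and background must be disjoint")
  }
  missing <- setdiff(c(fg_peaks, bg_peaks), rownames(occupancy))
  if (length(missing) > 0) {
    abort(paste0("peak(s) absent from occupancy: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  fg <- occupancy[fg_peaks, , drop = FALSE]
  bg <- occupancy[bg_peaks, , drop = FALSE]
  rows <- map(colnames(occupancy), function(mid) {
    k <- sum(fg[, mid]); bk <- sum(bg[, mid])
    ht <- hypergeom_test(k = k, K = k + bk, n = nrow(fg),
                         N = nrow(fg) + nrow(bg))
    tibble(motif_id = mid,
           fg_hits = k, fg_total = nrow(fg),
           bg_hits = bk, bg_total = nrow(bg),
           p_value = ht$one_sided, p_two_sided = ht$two_sided,
           enrichment_score = -log10(ht$one_sided))
  })
  arrange(list_rbind(rows), .data$p_value)
}

#' Expression-gated potential transcription factors
#'
#' Filters enrichment records to motifs whose mapped TF gene is expressed in
#' the interrogated subsets (`mean TPM > tpm_min`, in at least one subset or
#' in all of them depending on `tpm_mode`) and significantly enriched
#' (`p < p_max`), then ranks by p-value and returns the top `top_n`.
#'
#' @param records Enrichment table from [motif_enrichment()].
#' @param tpm TPM-layer gene x sample matrix.
#' @param manifest Sample manifest covering the TPM columns.
#' @param tf_map Tibble mapping `motif_id` to `tf_gene`.
#' @param subsets Cell types over which the expression gate applies (e.g.
#'   the three ILC subsets).
#' @param tpm_min Expression gate (default 50 TPM).
#' @param p_max Enrichment p-value gate (default 0.01).
#' @param top_n Number of TFs returned (default 10; fewer survivors are all
#'   returned).
#' @param tpm_mode `"any_subset"` (default) or `"all_subsets"`.
#' @return Tibble of the ranked records with `tf_gene`, `mean_tpm` and the
#'   per-subset gate summary attached.
#' @export
potential_tfs <- function(records, tpm, manifest, tf_map, subsets,
                          tpm_min = 50, p_max = 0.01, top_n = 10,
                          tpm_mode = c("any_subset", "all_subsets")) {
  tpm_mode <- match.arg(tpm_mode)
  if (expr_layer(tpm) != "tpm") abort("expected a tpm-layer matrix")
  manifest <- complete_manifest(manifest)
  unmapped <- setdiff(records$motif_id, tf_map$motif_id)
  if (length(unmapped) > 0) {
    abort(paste0("motif(s) without a TF gene mapping: ",
                 paste(unmapped, collapse = ", ")))
  }
  recs <- left_join(records, tf_map[, c("motif_id", "tf_gene")], by = "motif_id")
  missing_gene <- setdiff(recs$tf_gene, rownames(tpm))
  if (length(missing_gene) > 0) {
    abort(paste0("TF gene(s) absent from expression matrix: ",
                 paste(missing_gene, collapse = ", ")))
  }
  subset_means <- vapply(subsets, function(ct) {
    cols <- manifest$sample_id[manifest$cell_type == ct]
    if (length(cols) == 0) abort(paste0("no samples for subset ", ct))
    rowMeans(tpm[recs$tf_gene, cols, drop = FALSE])
  }, numeric(nrow(recs)))
  if (is.null(dim(subset_means))) {
    subset_means <- matrix(subset_means, nrow = nrow(recs))
  }
  all_cols <- manifest$sample_id[manifest$cell_type %in% subsets]
  recs$mean_tpm <- rowMeans(tpm[recs$tf_gene, all_cols, drop = FALSE])
  gate <- if (tpm_mode == "any_subset") {
    apply(subset_means, 1L, max) > tpm_min
  } else {
    apply(subset_means, 1L, min) > tpm_min
  }
  recs |>
    filter(gate, .data$p_value < p_max) |>
    arrange(.data$p_value) |>
    head(top_n)
}

#' Compare motif occupancy fractions between two peak sets
#'
#' For each motif, the fraction of peaks with at least one hit is computed
#' in both sets; the TF-wise fraction pairs are compared with a paired
#' signed-rank test (default) or an unpaired rank-sum test. All-zero
#' differences are reported as p = 1 with a `degenerate` flag; a single TF
#' under pairing falls back to the rank-sum test with a warning.
#'
#' @param occupancy Binary peak x motif matrix (or `occupancy_scan`).
#' @param motif_ids Motifs to compare (non-empty).
#' @param set_a,set_b Disjoint, non-empty peak-id sets.
#' @param paired Use the signed-rank test on fraction differences
#'   (default TRUE).
#' @return Object of class `occupancy_comparison`: `fractions` tibble and a
#'   one-row `test` tibble with a `degenerate` flag.
#' @export
occupancy_fraction_comparison <- function(occupancy, motif_ids, set_a, set_b,
                                          paired = TRUE) {
  if (is(occupancy, "occupancy_scan") ||
      (is.list(occupancy) && !is.matrix(occupancy))) {
    occupancy <- occupancy$occupancy
  }
  if (length(motif_ids) == 0) abort("motif list is empty")
  if (length(set_a) == 0 || length(set_b) == 0) abort("empty peak set")
  if (length(intersect(set_a, set_b)) > 0) abort("peak sets must be disjoint")
  fa <- colMeans(occupancy[set_a, motif_ids, drop = FALSE])
  fb <- colMeans(occupancy[set_b, motif_ids, drop = FALSE])
  fractions <- tibble(motif_id = motif_ids, frac_a = unname(fa),
                      frac_b = unname(fb), diff = unname(fa - fb))
  diffs <- fractions$diff
  degenerate <- FALSE
  if (paired && all(diffs == 0)) {
    test <- test_result(0, 1, "wilcoxon_signed_rank", 0, length(diffs))
    degenerate <- TRUE
  } else if (paired && length(diffs) < 2) {
    warn("n too small for signed-rank; reporting rank-sum fallback")
    test <- mwu_test(fractions$frac_a, fractions$frac_b)
  } else if (paired) {
    test <- signed_rank_test(diffs)
  } else {
    test <- mwu_test(fractions$frac_a, fractions$frac_b)
  }
  test$degenerate <- degenerate
  structure(list(fractions = fractions, test = test, paired = paired),
            class = "occupancy_comparison")
}

#' @export
print.occupancy_comparison <- function(x, ...) {
  cat("<occupancy_comparison>", nrow(x$fractions), "motifs |",
      x$test$method, "p =", signif(x$test$p_value, 3),
      if (isTRUE(x$test$degenerate)) "(degenerate)" else "", "\n")
  invisible(x)
}
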