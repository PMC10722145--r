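# Chromatin stage: peak-to-TSS annotation, the three-part concordance rule,
# subset-specific classification, gene coverage and peak-geometry statistics.

#' Annotate peaks to genes within a TSS window
#'
#' Links every peak whose midpoint (`floor((start + end) / 2)`, 0-based)
#' lies within `window` bp of a gene's TSS (inclusive boundary). A peak may
#' link to several genes and vice versa. Signed distance is midpoint minus
#' TSS, with the sign flipped on minus-strand genes so positive means
#' downstream of the gene.
#'
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `tss`.
#' @param window Maximum |distance| in bp (default 50000).
#' @return Tibble of links: `peak_id`, `gene_id`, `tss_distance`,
#'   `abs_distance`.
#' @export
annotate_peaks <- function(peaks, genes, window = 50000) {
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(tibble(peak_id = character(), gene_id = character(),
                  tss_distance = integer(), abs_distance = integer()))
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  gr_mid <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = mid + 1L, width = 1L))
  gr_tss <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$tss + 1L - window,
                     end = genes$tss + 1L + window))
  ov <- GenomicRanges::findOverlaps(gr_mid, gr_tss)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  raw <- mid[qi] - genes$tss[si]
  signed <- ifelse(genes$strand[si] == "-", -raw, raw)
  tibble(
    peak_id = peaks$peak_id[qi],
    gene_id = genes$gene_id[si],
    tss_distance = as.integer(signed),
    abs_distance = as.integer(abs(raw))
  )
}

# shared validation for accessibility matrices
assert_acc_manifest <- function(bpm, acc_manifest) {
  acc_manifest <- as_tibble(acc_manifest)
  missing <- setdiff(acc_manifest$acc_sample, colnames(bpm))
  if (length(missing) > 0) {
    abort(paste0("bpm matrix lacks accessibility sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab <- table(acc_manifest$cell_type)
  absent <- setdiff(CELL_TYPES, names(tab))
  if (length(absent) > 0) {
    abort(paste0("accessibility manifest missing subset(s): ",
                 paste(absent, collapse = ", ")))
  }
  single <- names(tab)[tab < 2]
  if (length(single) > 0) {
    abort(paste0("subset(s) with fewer than 2 accessibility replicates: ",
                 paste(single, collapse = ", ")))
  }
  acc_manifest
}

# The three-part rule, evaluated row-wise: (i) mean up / mean down > fc_min
# (+Inf when the denominator is 0 and the numerator positive), (ii) min up
# > max down across replicates, (iii) min up > bpm_floor. All strict.
ocr_rule <- function(bpm, up_cols, down_cols, fc_min, bpm_floor) {
  up <- bpm[, up_cols, drop = FALSE]
  down <- bpm[, down_cols, drop = FALSE]
  up_mean <- unname(rowMeans(up)); down_mean <- unname(rowMeans(down))
  fc <- ifelse(down_mean > 0, up_mean / down_mean,
               ifelse(up_mean > 0, Inf, NaN))
  up_min <- unname(apply(up, 1L, min))
  down_max <- unname(apply(down, 1L, max))
  tibble(
    fold_change = fc,
    pass_fc = !is.nan(fc) & fc > fc_min,
    pass_separation = up_min > down_max,
    pass_floor = up_min > bpm_floor
  ) |> mutate(pass_all = .data$pass_fc & .data$pass_separation & .data$pass_floor)
}

#' Classify geneset-linked peaks as expression-concordant or not
#'
#' For every peak linked to at least one gene of the geneset, the
#' concordance rule compares the up-lineage accessibility samples against
#' the down-lineage samples: (i) fold change of means > `fc_min`; (ii)
#' minimum BPM across all up-lineage replicates above the maximum across all
#' down-lineage replicates; (iii) minimum up-lineage BPM above `bpm_floor`.
#' Peaks failing any part are the residual, non-concordant class; the two
#' classes partition the geneset-linked peaks.
#'
#' @param bpm Peak x accessibility-sample BPM matrix.
#' @param acc_manifest Accessibility manifest (`acc_sample`, `cell_type`,
#'   `replicate`); all six subsets with >= 2 replicates required.
#' @param links Peak-gene links from [annotate_peaks()].
#' @param geneset Gene ids whose linked peaks are classified.
#' @param direction `"ILC"` or `"Th"`: the up lineage (must match the
#'   geneset's lineage).
#' @param geneset_label Label recorded on the output rows.
#' @param fc_min Fold-change threshold (default 1.5).
#' @param bpm_floor Accessibility floor (default 0.5).
#' @return Tibble: `peak_id`, `geneset_label`, `class`
#'   (`"concordant"`/`"non_concordant"`), `fold_change`, and the three
#'   `pass_*` flags.
#' @export
classify_concordant <- function(bpm, acc_manifest, links, geneset,
                                direction = c("ILC", "Th"),
                                geneset_label = direction,
                                fc_min = 1.5, bpm_floor = 0.5) {
  direction <- match.arg(direction)
  acc_manifest <- assert_acc_manifest(bpm, acc_manifest)
  peak_ids <- unique(links$peak_id[links$gene_id %in% geneset])
  if (length(peak_ids) == 0) {
    return(tibble(peak_id = character(), geneset_label = character(),
                  class = character(), fold_change = double(),
                  pass_fc = logical(), pass_separation = logical(),
                  pass_floor = logical()))
  }
  lin <- lineage_of(acc_manifest$cell_type)
  up_cols <- acc_manifest$acc_sample[lin == direction]
  down_cols <- acc_manifest$acc_sample[lin != direction]
  rule <- ocr_rule(bpm[peak_ids, , drop = FALSE], up_cols, down_cols,
                   fc_min, bpm_floor)
  tibble(
    peak_id = peak_ids,
    geneset_label = geneset_label[[1]],
    class = ifelse(rule$pass_all, "concordant", "non_concordant"),
    fold_change = rule$fold_change,
    pass_fc = rule$pass_fc,
    pass_separation = rule$pass_separation,
    pass_floor = rule$pass_floor
  )
}

#' Classify peaks linked to a response geneset as subset-specific
#'
#' The same three-part rule, restricted to the paired subsets' replicates
#' (ILCk vs Thk for pairing k) and evaluated in both directions. Each
#' direction is emitted as its own row; a peak is, e.g., `ILC2_specific`
#' when the up-ILC2 rule passes, `Th2_specific` when the up-Th2 rule passes,
#' and `non_specific` otherwise (the two directions cannot both pass).
#'
#' @inheritParams classify_concordant
#' @param type_geneset Gene ids of the type-k response geneset.
#' @param pairing Response type k in 1..3 (ILC3 pairs with Th17).
#' @return Tibble with one row per linked peak and direction: `peak_id`,
#'   `geneset_label`, `direction_subset`, `class`, `fold_change`, flags.
#' @export
classify_subset_specific <- function(bpm, acc_manifest, links, type_geneset,
                                     pairing, fc_min = 1.5, bpm_floor = 0.5) {
  if (!pairing %in% 1:3) abort("pairing must be 1, 2 or 3")
  acc_manifest <- assert_acc_manifest(bpm, acc_manifest)
  pr <- PAIRINGS[[paste0("type", pairing)]]
  peak_ids <- unique(links$peak_id[links$gene_id %in% type_geneset])
  if (length(peak_ids) == 0) {
    return(tibble(peak_id = character(), geneset_label = character(),
                  direction_subset = character(), class = character(),
                  fold_change = double(), pass_fc = logical(),
                  pass_separation = logical(), pass_floor = logical()))
  }
  sub <- bpm[peak_ids, , drop = FALSE]
  cols <- function(ct) acc_manifest$acc_sample[acc_manifest$cell_type == ct]
  out <- list()
  for (up_ct in c(pr[["ILC"]], pr[["Th"]])) {
    down_ct <- setdiff(c(pr[["ILC"]], pr[["Th"]]), up_ct)
    rule <- ocr_rule(sub, cols(up_ct), cols(down_ct), fc_min, bpm_floor)
    out[[up_ct]] <- tibble(
      peak_id = peak_ids,
      geneset_label = paste0("type", pairing),
      direction_subset = up_ct,
      class = ifelse(rule$pass_all, paste0(up_ct, "_specific"), "non_specific"),
      fold_change = rule$fold_change,
      pass_fc = rule$pass_fc,
      pass_separation = rule$pass_separation,
      pass_floor = rule$pass_floor
    )
  }
  list_rbind(out)
}

#' Fraction of geneset genes covered by classified peaks
#'
#' @param classification Output of [classify_concordant()] or
#'   [classify_subset_specific()].
#' @param links Peak-gene links used for the classification.
#' @param geneset The geneset's gene ids (non-empty).
#' @param class_label Class counted as covering (default `"concordant"`; use
#'   e.g. `"ILC2_specific"` for subset classifications).
#' @return One-row tibble: `n_genes`, `n_covered`, `fraction`.
#' @export
gene_coverage <- function(classification, links, geneset,
                          class_label = "concordant") {
  if (length(geneset) == 0) abort("empty geneset")
  hit_peaks <- classification$peak_id[classification$class == class_label]
  covered <- unique(links$gene_id[links$peak_id %in% hit_peaks &
                                    links$gene_id %in% geneset])
  tibble(n_genes = length(geneset), n_covered = length(covered),
         fraction = length(covered) / length(geneset))
}

#' Peak-geometry statistics between two OCR classes
#'
#' Summarises widths and minimum absolute TSS distances per class, reports
#' the fraction of peaks broader than `width_ref` and the fraction with a
#' linked TSS within `tss_ref`, and compares the two classes with two-sided
#' Mann-Whitney tests on widths and distances.
#'
#' @param peaks Peak tibble (`peak_id`, `start`, `end`).
#' @param links Peak-gene links (for TSS distances; per peak the minimum
#'   absolute distance over its links is used).
#' @param peaks_a,peaks_b Peak-id sets of the two classes (non-empty).
#' @param labels Length-2 labels for the classes.
#' @param width_ref Width reference in bp (default 500).
#' @param tss_ref TSS-distance reference in bp (default 1000).
#' @return Object of class `geometry_report`: `summary` (per class),
#'   `tests` (width and distance rows), `data` (per peak).
#' @export
geometry_stats <- function(peaks, links, peaks_a, peaks_b,
                           labels = c("a", "b"),
                           width_ref = 500, tss_ref = 1000) {
  if (length(peaks_a) == 0 || length(peaks_b) == 0) abort("empty peak class")
  min_dist <- links |>
    summarise(min_abs_distance = min(.data$abs_distance), .by = "peak_id")
  build <- function(ids, label) {
    idx <- match(ids, peaks$peak_id)
    if (anyNA(idx)) abort("peak ids absent from the peak table")
    tibble(peak_id = ids, class = label,
           width = peaks$end[idx] - peaks$start[idx]) |>
      left_join(min_dist, by = "peak_id")
  }
  dat <- bind_rows(build(peaks_a, labels[1]), build(peaks_b, labels[2]))
  summary <- dat |>
    summarise(
      n = n(),
      width_median = median(.data$width),
      width_mean = mean(.data$width),
      frac_width_gt = mean(.data$width > width_ref),
      dist_median = median(.data$min_abs_distance, na.rm = TRUE),
      frac_tss_lt = mean(.data$min_abs_distance < tss_ref, na.rm = TRUE),
      .by = "class"
    )
  wa <- dat$width[dat$class == labels[1]]
  wb <- dat$width[dat$class == labels[2]]
  da <- dat$min_abs_distance[dat$class == labels[1]]
  db <- dat$min_abs_distance[dat$class == labels[2]]
  tests <- bind_rows(
    mwu_test(wa, wb) |> mutate(metric = "width", .before = 1),
    mwu_test(da[!is.na(da)], db[!is.na(db)]) |>
      mutate(metric = "tss_distance", .before = 1)
  )
  structure(list(summary = summary, tests = tests, data = dat,
                 width_ref = width_ref, tss_ref = tss_ref),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("<geometry_report>\n")
  print(x$summary)
  cat("tests:\n")
  print(select(x$tests, "metric", "statistic", "p_value"))
  invisible(x)
}
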