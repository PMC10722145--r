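# Readers and writers for the plain-text study formats: TSV matrices and
# manifests, BED6 peaks (0-based half-open), GFF3 gene annotation (1-based,
# converted on read), FASTA peak sequences, minimal MEME motifs, JSON truth.

#' Write a simulated bundle to plain-text files
#'
#' Emits `manifest.tsv`, `counts.tsv`, `gene_annotation.gff3`, `peaks.bed`,
#' `bpm.tsv` (two-line header: accessibility sample id, then
#' `cell_type:replicate`), `peaks.fasta`, `motifs.meme`, and `truth.json`.
#' The files round-trip through [read_bundle()].
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory ", dir))
  }
  p <- function(f) file.path(dir, f)

  readr::write_tsv(bundle$manifest, p("manifest.tsv"))
  counts_tbl <- as_tibble(bundle$counts, rownames = "gene_id")
  readr::write_tsv(counts_tbl, p("counts.tsv"))
  write_gff3_genes(bundle$genes, p("gene_annotation.gff3"))
  write_bed_peaks(bundle$peaks, p("peaks.bed"))
  write_bpm(bundle$bpm, bundle$acc_manifest, p("bpm.tsv"))
  seqs <- Biostrings::DNAStringSet(bundle$sequences)
  Biostrings::writeXStringSet(seqs, p("peaks.fasta"))
  write_meme(bundle$pwms, p("motifs.meme"))
  truth_json <- list(
    genesets = bundle$truth$genesets,
    tf_genes = bundle$truth$tf_genes,
    peaks = bundle$truth$peaks,
    planted_motifs = bundle$truth$planted_motifs,
    seed = bundle$config$seed
  )
  jsonlite::write_json(truth_json, p("truth.json"), digits = NA)
  invisible(c("manifest.tsv", "counts.tsv", "gene_annotation.gff3",
              "peaks.bed", "bpm.tsv", "peaks.fasta", "motifs.meme",
              "truth.json"))
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Directory containing the bundle files.
#' @return A list with the same components as a `sim_bundle` (minus the
#'   config; the truth is restored from `truth.json` if present).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  manifest <- read_manifest(p("manifest.tsv"))
  counts <- read_matrix_tsv(p("counts.tsv"), id_col = "gene_id")
  counts <- set_layer(counts, "counts")
  genes <- read_gff3_genes(p("gene_annotation.gff3"))
  peaks <- read_bed_peaks(p("peaks.bed"))
  bpmr <- read_bpm(p("bpm.tsv"))
  seqs <- Biostrings::readDNAStringSet(p("peaks.fasta"))
  sequences <- setNames(as.character(seqs), names(seqs))
  pwms <- read_meme(p("motifs.meme"), pseudocount = 0)
  truth <- NULL
  if (file.exists(p("truth.json"))) {
    tj <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    truth <- list(genesets = as.list(tj$genesets),
                  tf_genes = as_tibble(tj$tf_genes),
                  peaks = as_tibble(tj$peaks),
                  planted_motifs = as_tibble(tj$planted_motifs))
  }
  list(manifest = manifest, counts = counts, genes = genes,
       gene_lengths = setNames(genes$length, genes$gene_id),
       peaks = peaks, bpm = bpmr$bpm, acc_manifest = bpmr$acc_manifest,
       sequences = sequences, pwms = pwms, truth = truth)
}

#' Read a sample manifest TSV
#' @param path Path to a TSV with `sample_id`, `cell_type`, optional `batch`.
#' @return A completed manifest tibble (see [complete_manifest()]).
#' @export
read_manifest <- function(path) {
  complete_manifest(readr::read_tsv(path, show_col_types = FALSE))
}

read_matrix_tsv <- function(path, id_col) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tbl[, setdiff(names(tbl), id_col), drop = FALSE])
  rownames(m) <- tbl[[id_col]]
  m
}

# BED6: 0-based half-open, written through rtracklayer so the coordinate
# conversion follows the format's convention.
write_bed_peaks <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    name = peaks$peak_id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

read_bed_peaks <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(tibble(peak_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    peak_id = if (!is.null(gr$name)) gr$name else sprintf("peak_%05d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

write_gff3_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  tibble(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0, strand = strand,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    length = end0 - start0
  )
}

# BPM TSV with a two-line header: accessibility sample ids, then
# cell_type:replicate tags.
write_bpm <- function(bpm, acc_manifest, path) {
  acc_manifest <- acc_manifest[match(colnames(bpm), acc_manifest$acc_sample), ]
  header1 <- paste(c("peak_id", colnames(bpm)), collapse = "\t")
  header2 <- paste(c("#cell_type:replicate",
                     paste0(acc_manifest$cell_type, ":", acc_manifest$replicate)),
                   collapse = "\t")
  body <- apply(bpm, 1L, function(v) paste(format(v, digits = 15, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = "\t"))
  writeLines(c(header1, header2, paste(rownames(bpm), body, sep = "\t")), path)
  invisible(path)
}

read_bpm <- function(path) {
  lines <- readLines(path, n = 2)
  samples <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  tags <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  parts <- strsplit(tags, ":", fixed = TRUE)
  acc_manifest <- tibble(
    acc_sample = samples,
    cell_type = map_chr(parts, 1),
    replicate = as.integer(map_chr(parts, 2))
  ) |> mutate(lineage = lineage_of(.data$cell_type),
              response_type = response_of(.data$cell_type))
  tbl <- readr::read_tsv(path, skip = 2, col_names = c("peak_id", samples),
                         show_col_types = FALSE)
  bpm <- as.matrix(tbl[, samples, drop = FALSE])
  rownames(bpm) <- tbl$peak_id
  list(bpm = bpm, acc_manifest = acc_manifest)
}

# minimal MEME motif format ----------------------------------------------

new_pwm <- function(motif_id, tf_name, matrix, pseudocount = 0) {
  structure(list(motif_id = motif_id, tf_name = tf_name,
                 matrix = matrix, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$motif_id, sprintf("(%s), L=%d\n", x$tf_name, nrow(x$matrix)))
  invisible(x)
}

#' Write PWMs in minimal MEME format
#' @param pwms List of pwm objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwms, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (pw in pwms) {
    lines <- c(lines,
               paste("MOTIF", pw$motif_id, pw$tf_name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(pw$matrix)),
               apply(pw$matrix, 1L, function(r) {
                 paste(sprintf("%.10f", r), collapse = " ")
               }),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read PWMs from a minimal MEME file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix:` sections (A, C,
#' G, T column order). Each row must sum to 1 within 0.01; the stored matrix
#' keeps the file's probabilities and records the requested pseudocount,
#' which is applied (then renormalised) at calibration time.
#'
#' @param path Path to a MEME-format text file.
#' @param pseudocount Per-cell pseudocount recorded on each motif.
#' @return A named list of pwm objects, in file order.
#' @export
read_meme <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  motif_idx <- grep("^MOTIF ", lines)
  if (length(motif_idx) == 0) abort("no MOTIF blocks found")
  pwms <- list()
  for (mi in motif_idx) {
    hdr <- strsplit(trimws(lines[mi]), "\\s+")[[1]]
    motif_id <- hdr[2]
    tf_name <- if (length(hdr) >= 3) hdr[3] else motif_id
    li <- mi + 1L
    while (li <= length(lines) && !grepl("^letter-probability matrix:", lines[li])) {
      if (grepl("^MOTIF ", lines[li])) {
        abort(paste0("malformed block: no probability matrix for ", motif_id))
      }
      li <- li + 1L
    }
    if (li > length(lines)) {
      abort(paste0("malformed block: no probability matrix for ", motif_id))
    }
    w <- suppressWarnings(as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[li])))
    if (is.na(w) || w < 4) abort(paste0("bad or missing motif width for ", motif_id))
    rows <- lines[(li + 1L):(li + w)]
    vals <- suppressWarnings(lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    if (any(vapply(vals, function(v) length(v) != 4 || anyNA(v), TRUE))) {
      abort(paste0("malformed probability row in motif ", motif_id))
    }
    m <- do.call(rbind, vals)
    if (any(abs(rowSums(m) - 1) > 0.01)) {
      abort(paste0("probability rows do not sum to 1 in motif ", motif_id))
    }
    colnames(m) <- c("A", "C", "G", "T")
    pwms[[motif_id]] <- new_pwm(motif_id, tf_name, m, pseudocount)
  }
  pwms
}
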