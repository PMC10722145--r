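# Motif stage: exact calibration, scanning, enrichment, TF gating.

random_pwm <- function(L, seed, id = "m") {
  withr::with_seed(seed, {
    m <- matrix(rexp(L * 4), ncol = 4)
    m <- m / rowSums(m)
    colnames(m) <- c("A", "C", "G", "T")
    chromcord:::new_pwm(id, paste0(id, "_tf"), m, pseudocount = 0)
  })
}

consensus_pwm <- function(consensus, p = 0.94, id = "cons") {
  L <- length(consensus)
  m <- matrix((1 - p) / 3, nrow = L, ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(L), match(consensus, c("A", "C", "G", "T")))] <- p
  chromcord:::new_pwm(id, paste0(id, "_tf"), m, pseudocount = 0)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("dynamic-programming null tails equal exhaustive enumeration", {
  for (L in c(5, 6)) {
    pwm <- random_pwm(L, seed = L, id = paste0("r", L))
    cal <- calibrate_threshold(pwm, p_target = 1e-3, pseudocount = 0)
    enum <- oracle_pwm_tails(cal$int_matrix)
    attained <- cal$null_probs > 0
    dp <- tibble::tibble(score_int = cal$null_scores_int[attained],
                         tail = rev(cumsum(rev(cal$null_probs)))[attained])
    merged <- dplyr::inner_join(dp, enum, by = "score_int",
                                suffix = c("_dp", "_enum"))
    expect_setequal(dp$score_int, enum$score_int)  # grid-identical scores
    expect_equal(merged$tail_dp, merged$tail_enum, tolerance = 1e-12)
  }
})

test_that("the threshold is the smallest grid score meeting the target", {
  pwm <- random_pwm(6, seed = 3, id = "thr")
  cal <- calibrate_threshold(pwm, p_target = 1e-3, pseudocount = 0)
  expect_lte(cal$attained_pvalue, 1e-3)
  attained <- cal$null_scores_int[cal$null_probs > 0]
  below <- attained[attained < cal$threshold_int]
  if (length(below) > 0) {
    tail_below <- sum(cal$null_probs[cal$null_scores_int >= max(below)])
    expect_gt(tail_below, 1e-3)  # one grid step lower overshoots the target
  }
  # p_target = 1: everything hits, threshold at the minimum attainable score
  cal1 <- calibrate_threshold(pwm, p_target = 1, pseudocount = 0)
  expect_equal(cal1$threshold_int, min(attained))
  expect_equal(cal1$attained_pvalue, 1)
})

test_that("degenerate calibrations behave: uniform motif, zero probabilities", {
  uni <- chromcord:::new_pwm("uni", "uniTF",
                             matrix(0.25, 4, 4,
                                    dimnames = list(NULL, c("A","C","G","T"))))
  cal <- calibrate_threshold(uni, p_target = 1e-4, pseudocount = 0)
  expect_true(all(cal$int_matrix == 0))  # log-odds identically zero
  seqs <- c(pk = paste(rep("ACGT", 30), collapse = ""))
  scan <- scan_peaks(seqs, list(uni), list(cal))
  expect_equal(sum(scan$occupancy), 0)   # no window can beat the target

  zero <- chromcord:::new_pwm("z", "zTF",
                              matrix(c(1, 0, 0, 0), 4, 4, byrow = TRUE,
                                     dimnames = list(NULL, c("A","C","G","T"))))
  expect_error(calibrate_threshold(zero, pseudocount = 0), "zero probabilities")
  expect_s3_class(calibrate_threshold(zero, pseudocount = 0.1),
                  "scan_calibration")
})

test_that("planted consensus sites are found at the right offset and strand", {
  withr::with_seed(13, {
    cons <- "ACGTACGG"
    pwm <- consensus_pwm(strsplit(cons, "")[[1]])
    cal <- calibrate_threshold(pwm, pseudocount = 0.1)
    backbone <- paste(sample(c("A","C","G","T"), 60, replace = TRUE),
                      collapse = "")
    seq <- paste0(substr(backbone, 1, 20), cons, substr(backbone, 29, 60))
    scan <- scan_peaks(c(pk1 = seq), list(pwm), list(cal))
    fwd <- scan$hits[scan$hits$strand == "+", ]
    expect_true(any(fwd$offset == 20))
    # the reverse complement sequence carries the hit on the minus strand at
    # the mirrored offset
    rc <- revcomp(seq)
    scan_rc <- scan_peaks(c(pk1 = rc), list(pwm), list(cal))
    expect_setequal(
      nchar(seq) - nchar(cons) - scan$hits$offset,
      scan_rc$hits$offset
    )
    expect_setequal(scan_rc$hits$strand,
                    ifelse(scan$hits$strand == "+", "-", "+"))
    expect_equal(sort(scan_rc$hits$score), sort(scan$hits$score))
  })
})

test_that("N windows are skipped and short sequences scan to nothing", {
  pwm <- consensus_pwm(c("A", "C", "G", "T", "A", "C", "G", "T"))
  cal <- calibrate_threshold(pwm, pseudocount = 0.1)
  seqs <- c(alln = paste(rep("N", 50), collapse = ""),
            short = "ACG",
            planted = paste0("NNNN", "ACGTACGT", "NNNN"))
  expect_message(scan <- scan_peaks(seqs, list(pwm), list(cal)), "shorter")
  expect_equal(unname(scan$occupancy["alln", ]), 0L)
  expect_equal(unname(scan$occupancy["short", ]), 0L)
  expect_equal(unname(scan$occupancy["planted", ]), 1L)
  # ACGTACGT is palindromic: both strands report the same planted offset
  expect_true(all(scan$hits$offset == 4L))
})

test_that("the null hit rate respects the calibrated p-value", {
  withr::with_seed(14, {
    pwm <- consensus_pwm(sample(c("A","C","G","T"), 10, replace = TRUE),
                         p = 0.97)
    cal <- calibrate_threshold(pwm, p_target = 1e-4, pseudocount = 0.1)
    seqs <- setNames(
      vapply(1:40, function(i) paste(sample(c("A","C","G","T"), 5000,
                                            replace = TRUE), collapse = ""),
             character(1)),
      paste0("pk", 1:40))
    scan <- scan_peaks(seqs, list(pwm), list(cal))
    rate <- nrow(scan$hits) / scan$n_windows
    expect_lte(rate, 1.5e-4)
  })
})

test_that("motif enrichment reproduces hypergeometric closed forms", {
  occ <- matrix(0L, nrow = 40, ncol = 3,
                dimnames = list(paste0("pk", 1:40),
                                c("all_fg", "even", "nowhere")))
  fg <- paste0("pk", 1:20); bg <- paste0("pk", 21:40)
  occ[fg, "all_fg"] <- 1L
  occ[c(fg[1:10], bg[1:10]), "even"] <- 1L
  res <- motif_enrichment(occ, fg, bg)
  expect_equal(res$p_value[res$motif_id == "all_fg"], 1 / choose(40, 20),
               tolerance = 1e-12)
  expect_lt(res$enrichment_score[res$motif_id == "even"], 0.7)
  expect_equal(res$p_value[res$motif_id == "nowhere"], 1)
  expect_equal(res$motif_id[1], "all_fg")
  expect_error(motif_enrichment(occ, fg, c(bg, fg[1])), "disjoint")
  expect_error(motif_enrichment(occ, character(0), bg), "non-empty")
})

test_that("potential TFs are gated by expression and enrichment", {
  man <- flat_manifest(n_per_subset = 3)
  tpm <- matrix(10, nrow = 3, ncol = nrow(man),
                dimnames = list(c("tfA", "tfB", "tfC"), man$sample_id))
  ilc_cols <- man$sample_id[man$lineage == "ILC"]
  tpm["tfA", ilc_cols] <- 200
  tpm["tfC", ilc_cols] <- 400
  attr(tpm, "layer") <- "tpm"
  records <- tibble::tibble(
    motif_id = c("m1", "m2", "m3"),
    p_value = c(1e-6, 1e-6, 0.5),
    enrichment_score = -log10(p_value)
  )
  tf_map <- tibble::tibble(motif_id = c("m1", "m2", "m3"),
                           tf_gene = c("tfA", "tfB", "tfC"))
  got <- potential_tfs(records, tpm, man, tf_map,
                       subsets = c("ILC1", "ILC2", "ILC3"))
  expect_equal(got$motif_id, "m1")        # m2 fails TPM, m3 fails p
  expect_gt(got$mean_tpm, 50)
  # fewer survivors than top_n: all returned, no padding
  expect_equal(nrow(potential_tfs(records, tpm, man, tf_map,
                                  subsets = c("ILC1", "ILC2", "ILC3"),
                                  top_n = 10)), 1L)
  # all_subsets mode needs the gate in every subset
  tpm2 <- tpm
  tpm2["tfA", man$sample_id[man$cell_type == "ILC3"]] <- 1
  attr(tpm2, "layer") <- "tpm"
  expect_equal(nrow(potential_tfs(records, tpm2, man, tf_map,
                                  subsets = c("ILC1", "ILC2", "ILC3"),
                                  tpm_mode = "all_subsets")), 0L)
  expect_equal(nrow(potential_tfs(records, tpm2, man, tf_map,
                                  subsets = c("ILC1", "ILC2", "ILC3"),
                                  tpm_mode = "any_subset")), 1L)
  expect_error(potential_tfs(records, tpm, man, tf_map[1:2, ],
                             subsets = c("ILC1", "ILC2", "ILC3")), "m3")
})

test_that("occupancy fraction comparison runs the paired signed-rank test", {
  # construct occupancy with exact fractions .9/.8/.7/.9/.8 vs .2/.1/.3/.2/.1
  fa <- c(9, 8, 7, 9, 8); fb <- c(2, 1, 3, 2, 1)
  occ <- matrix(0L, nrow = 20, ncol = 5,
                dimnames = list(paste0("pk", 1:20), paste0("m", 1:5)))
  for (j in 1:5) {
    occ[seq_len(fa[j]), j] <- 1L
    occ[10 + seq_len(fb[j]), j] <- 1L
  }
  a <- paste0("pk", 1:10); b <- paste0("pk", 11:20)
  cmp <- occupancy_fraction_comparison(occ, paste0("m", 1:5), a, b)
  expect_equal(cmp$test$p_value, 0.0625, tolerance = 1e-12)
  expect_equal(cmp$fractions$frac_a, fa / 10)
  expect_equal(cmp$fractions$frac_b, fb / 10)

  # identical occupancy patterns: degenerate pairing flagged with p = 1
  occ_same <- occ
  occ_same[11:20, ] <- occ[1:10, ]
  cmp_deg <- occupancy_fraction_comparison(occ_same, paste0("m", 1:5), a, b)
  expect_equal(cmp_deg$test$p_value, 1)
  expect_true(cmp_deg$test$degenerate)

  # a single motif cannot be sign-rank tested: rank-sum fallback with warning
  expect_warning(
    cmp1 <- occupancy_fraction_comparison(occ, "m1", a, b),
    "rank-sum"
  )
  expect_equal(cmp1$test$method, "mann_whitney_u")
  expect_error(occupancy_fraction_comparison(occ, character(0), a, b), "empty")
  expect_error(occupancy_fraction_comparison(occ, "m1", a, a), "disjoint")
})
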