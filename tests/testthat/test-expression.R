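# Expression stage: TPM arithmetic, filtering boundaries, batch removal,
# differential expression and the geneset rules.

test_that("TPM follows the length-normalised formula", {
  counts <- matrix(c(10, 20), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  attr(counts, "layer") <- "counts"
  tpm <- compute_tpm(counts, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))

  eq <- matrix(c(7, 7, 7, 7), nrow = 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tpm_eq <- compute_tpm(eq, c(g1 = 1500, g2 = 1500))
  expect_true(all(tpm_eq == 5e5))

  z <- matrix(c(0, 10), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(compute_tpm(z, c(g1 = 1000, g2 = 1000))["g1", 1], 0)

  withr::with_seed(1, {
    big <- matrix(rpois(600, 40), nrow = 60,
                  dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:10)))
    lens <- setNames(round(runif(60, 500, 5000)), rownames(big))
    expect_equal(unname(colSums(compute_tpm(big, lens))), rep(1e6, 10),
                 tolerance = 1e-6)
  })
  expect_error(compute_tpm(matrix(-1, 1, 1, dimnames = list("g", "s")),
                           c(g = 100)), "non-negative")
  zc <- matrix(c(0, 0, 3, 4), nrow = 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(out <- compute_tpm(zc, c(a = 1000, b = 1000)), "all-zero")
  expect_equal(unname(out[, "s1"]), c(0, 0))
})

test_that("the prevalence filter applies strict thresholds per subset", {
  man <- flat_manifest(n_per_subset = 5)
  means <- matrix(0, nrow = 3, ncol = 6,
                  dimnames = list(c("boundary", "ilc2_only", "low"), subsets6))
  means["boundary", ] <- 10        # exactly at min_tpm: must drop
  means["ilc2_only", "ILC2"] <- 11 # above threshold in 100% of one subset
  mat <- subset_matrix(man, means)
  kept <- filter_low_expression(mat, man, min_tpm = 10, min_frac = 0.8)
  expect_false("boundary" %in% kept)
  expect_true("ilc2_only" %in% kept)
  expect_false("low" %in% kept)

  # 4 of 5 samples = 0.8 exactly: fails the strict > 0.8 rule
  mat2 <- mat
  cols <- man$sample_id[man$cell_type == "ILC1"]
  mat2["low", cols[1:4]] <- 50
  expect_false("low" %in% filter_low_expression(mat2, man))
  mat2["low", cols[5]] <- 50
  expect_true("low" %in% filter_low_expression(mat2, man))
})

test_that("batch removal is exact on noiseless balanced designs", {
  man <- flat_manifest(n_per_subset = 4, n_batches = 2)
  withr::with_seed(9, {
    n_g <- 30
    ct_means <- matrix(rnorm(n_g * 6, 6, 1), nrow = n_g,
                       dimnames = list(sprintf("g%02d", 1:n_g), subsets6))
    offsets <- matrix(rnorm(n_g * 2, 0, 1), nrow = n_g,
                      dimnames = list(rownames(ct_means), c("b1", "b2")))
    mat <- subset_matrix(man, ct_means, layer = "log2_tpm1")
    mat <- mat + offsets[, man$batch]
    attr(mat, "layer") <- "log2_tpm1"
    corrected <- remove_batch_effect(mat, man)
    # between-batch variance vanishes
    for (g in rownames(mat)) {
      b_means <- tapply(corrected[g, man$sample_id], man$batch, mean)
      expect_lt(var(b_means), 1e-8)
    }
    # cell-type means are preserved (input vs corrected)
    for (ct in subsets6) {
      cols <- man$sample_id[man$cell_type == ct]
      expect_equal(unname(rowMeans(corrected[, cols])),
                   unname(rowMeans(mat[, cols])), tolerance = 1e-8)
    }
    # idempotence
    twice <- remove_batch_effect(corrected, man)
    expect_equal(twice, corrected, tolerance = 1e-10)
  })
})

test_that("single-batch input passes through and confounding is an error", {
  man1 <- flat_manifest(n_per_subset = 3, n_batches = 1)
  mat <- subset_matrix(man1, matrix(rnorm(6 * 5), nrow = 5,
                                    dimnames = list(paste0("g", 1:5), subsets6)),
                       layer = "log2_tpm1")
  out <- remove_batch_effect(mat, man1)
  expect_equal(out, mat, ignore_attr = TRUE)

  man_conf <- flat_manifest(n_per_subset = 3, n_batches = 1)
  man_conf$batch <- man_conf$cell_type  # batch == cell type
  expect_error(remove_batch_effect(mat, man_conf), "confounded")
})

test_that("differential expression reports rank-sum p and pseudocount fold change", {
  man <- flat_manifest(n_per_subset = 8)
  a <- man$sample_id[man$cell_type == "ILC1"]
  b <- man$sample_id[man$cell_type == "Th1"]
  means <- matrix(1, nrow = 3, ncol = 6,
                  dimnames = list(c("up", "flat", "const"), subsets6))
  means["up", "ILC1"] <- 3
  mat <- subset_matrix(man, means)
  de <- differential_expression(mat, a, b)
  expect_equal(de$log2fc[de$gene == "up"], 1)        # log2(4) - log2(2)
  expect_equal(de$log2fc[de$gene == "flat"], 0)
  expect_equal(de$p_value[de$gene == "const"], 1)    # no signal
  expect_lt(de$p_value[de$gene == "up"], 0.01)

  de_same <- differential_expression(mat, a, a[c(3:8, 1:2)])
  expect_true(all(de_same$log2fc == 0))
  expect_error(differential_expression(mat, a[1], b), "at least 2")
  expect_error(differential_expression(mat, c(a, "ghost"), b), "absent")
})

test_that("lineage genesets enforce the min-fold-change / max-p rule", {
  man <- flat_manifest(n_per_subset = 8)
  genes <- c("in_ilc", "boundary", "conflict", "null")
  means <- matrix(3, nrow = length(genes), ncol = 6,
                  dimnames = list(genes, subsets6))
  means["in_ilc", c("ILC1", "ILC2", "ILC3")] <-
    mean_for_lfc(c(0.3, 0.4, 0.26))
  # one pairing sits at the threshold (a hair below, so floating-point noise
  # cannot tip the strict comparison): the min-fold-change rule must exclude
  means["boundary", c("ILC1", "ILC2", "ILC3")] <-
    mean_for_lfc(c(0.3, 0.4, 0.25 - 1e-9))
  means["conflict", c("ILC1", "ILC2")] <- mean_for_lfc(c(2, 2))
  means["conflict", "ILC3"] <- mean_for_lfc(-2)
  mat <- subset_matrix(man, means)
  gs <- lineage_genesets(mat, man)
  expect_true("in_ilc" %in% gs$sets$ILC)
  expect_false("boundary" %in% gs$sets$ILC)
  expect_false("conflict" %in% gs$sets$ILC)
  expect_false("conflict" %in% gs$sets$Th)
  expect_false("null" %in% c(gs$sets$ILC, gs$sets$Th))

  # swapping the lineage labels swaps the genesets exactly
  swap <- c(ILC1 = "Th1", ILC2 = "Th2", ILC3 = "Th17",
            Th1 = "ILC1", Th2 = "ILC2", Th17 = "ILC3")
  man_sw <- man
  man_sw$cell_type <- unname(swap[man$cell_type])
  gs_sw <- lineage_genesets(mat, complete_manifest(man_sw[, c("sample_id",
                                                              "cell_type",
                                                              "batch")]))
  expect_setequal(gs_sw$sets$ILC, gs$sets$Th)
  expect_setequal(gs_sw$sets$Th, gs$sets$ILC)

  expect_error(lineage_genesets(mat, man[man$cell_type != "Th2", ]), "missing")
})

test_that("response genesets require conservation across both arms", {
  man <- flat_manifest(n_per_subset = 8)
  genes <- c("both2", "ilc2_only", "zero")
  means <- matrix(2, nrow = length(genes), ncol = 6,
                  dimnames = list(genes, subsets6))
  means["both2", c("ILC2", "Th2")] <- 12
  means["ilc2_only", "ILC2"] <- 12
  means["zero", ] <- 0
  mat <- subset_matrix(man, means)
  rs <- response_genesets(mat, man)
  expect_true("both2" %in% rs$sets$type2)
  expect_false("ilc2_only" %in% rs$sets$type2)
  expect_false("zero" %in% unlist(rs$sets))
  expect_false("both2" %in% c(rs$sets$type1, rs$sets$type3))
})

test_that("over-representation matches hypergeometric closed forms", {
  universe <- sprintf("g%02d", 1:20)
  geneset <- universe[1:5]
  terms <- dplyr::bind_rows(
    tibble::tibble(term_id = "hit", gene_id = universe[1:5],
                   description = "exactly the geneset"),
    tibble::tibble(term_id = "miss", gene_id = universe[11:15],
                   description = "disjoint"),
    tibble::tibble(term_id = "half", gene_id = universe[c(1:3, 11:12)],
                   description = "partial")
  )
  res <- go_overrepresentation(geneset, universe, terms)
  expect_equal(res$p_value[res$term_id == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$term_id[1], "hit")  # minimal p sorts first
  expect_gte(res$p_value[res$term_id == "miss"], 0.5)
  expect_false(res$significant[res$term_id == "miss"])

  # terms with no universe genes are skipped with a message
  terms2 <- dplyr::bind_rows(terms,
                             tibble::tibble(term_id = "ghost",
                                            gene_id = "not_in_universe",
                                            description = NA))
  expect_message(res2 <- go_overrepresentation(geneset, universe, terms2),
                 "ghost")
  expect_false("ghost" %in% res2$term_id)
  expect_error(go_overrepresentation(c(geneset, "alien"), universe, terms),
               "subset")
})

test_that("embedding QC needs enough samples and scores label agreement", {
  man <- flat_manifest(n_per_subset = 6)
  withr::with_seed(2, {
    means <- matrix(rnorm(40 * 6, 6, 2), nrow = 40,
                    dimnames = list(sprintf("g%02d", 1:40), subsets6))
    mat <- subset_matrix(man, means, layer = "corrected")
    mat <- mat + matrix(rnorm(length(mat), 0, 0.05), nrow = nrow(mat))
    attr(mat, "layer") <- "corrected"
    qc <- embed_and_score(mat, man, n_pcs = 10)
    expect_gte(qc$ari, 0.9)  # well-separated subsets cluster cleanly
    expect_equal(nrow(qc$embedding), nrow(man))
    expect_error(embed_and_score(mat, man, n_pcs = 40), "at least")
  })
})
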