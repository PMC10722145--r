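# Independent brute-force oracles. These re-derive expected values by
# enumeration or by a literal reading of the published rules, and stay
# independent of the implementation paths they check.

subsets6 <- c("ILC1", "ILC2", "ILC3", "Th1", "Th2", "Th17")

# exact two-sided Mann-Whitney by enumeration of all group assignments
oracle_mwu <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  comb <- utils::combn(length(vals), n1)
  us <- apply(comb, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  list(U = u_obs, p = p)
}

# exact two-sided signed-rank by enumeration of all 2^n sign patterns
oracle_signed_rank <- function(d) {
  nz <- d[d != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  w_obs <- sum(r[nz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
  list(W = w_obs, p = p)
}

# hypergeometric tails from binomial coefficients
oracle_hypergeom <- function(k, K, n, N) {
  supp <- max(0, n + K - N):min(K, n)
  pmf <- choose(K, supp) * choose(N - K, n - supp) / choose(N, n)
  list(one = sum(pmf[supp >= k]),
       two = sum(pmf[pmf <= pmf[supp == k] * (1 + 1e-7)]))
}

# adjusted Rand index straight from the contingency-table formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(length(a), 2)
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# literal three-part concordance rule, scalar loops only
oracle_classify <- function(bpm, acc, links, geneset, up_lineage,
                            fc_min = 1.5, floor = 0.5) {
  is_ilc <- grepl("^ILC", acc$cell_type)
  up <- acc$acc_sample[if (up_lineage == "ILC") is_ilc else !is_ilc]
  down <- setdiff(acc$acc_sample, up)
  pks <- unique(links$peak_id[links$gene_id %in% geneset])
  cls <- character(length(pks))
  for (i in seq_along(pks)) {
    uv <- as.numeric(bpm[pks[i], up])
    dv <- as.numeric(bpm[pks[i], down])
    fc_ok <- if (mean(dv) == 0) mean(uv) > 0 else mean(uv) / mean(dv) > fc_min
    sep_ok <- min(uv) > max(dv)
    floor_ok <- min(uv) > floor
    cls[i] <- if (fc_ok && sep_ok && floor_ok) "concordant" else "non_concordant"
  }
  tibble::tibble(peak_id = pks, class = cls)
}

# literal subset-specific rule for one direction (up cell type vs its pair)
oracle_subset_specific <- function(bpm, acc, links, geneset, up_ct, down_ct,
                                   fc_min = 1.5, floor = 0.5) {
  up <- acc$acc_sample[acc$cell_type == up_ct]
  down <- acc$acc_sample[acc$cell_type == down_ct]
  pks <- unique(links$peak_id[links$gene_id %in% geneset])
  cls <- character(length(pks))
  for (i in seq_along(pks)) {
    uv <- as.numeric(bpm[pks[i], up])
    dv <- as.numeric(bpm[pks[i], down])
    fc_ok <- if (mean(dv) == 0) mean(uv) > 0 else mean(uv) / mean(dv) > fc_min
    sep_ok <- min(uv) > max(dv)
    floor_ok <- min(uv) > floor
    cls[i] <- if (fc_ok && sep_ok && floor_ok) {
      paste0(up_ct, "_specific")
    } else "non_specific"
  }
  tibble::tibble(peak_id = pks, class = cls)
}

# exhaustive null tail probabilities of an integer-scored PWM over all 4^L
# windows under a 0-order background
oracle_pwm_tails <- function(int_matrix, background = rep(0.25, 4)) {
  L <- nrow(int_matrix)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- integer(nrow(grid))
  w <- rep(1, nrow(grid))
  for (j in seq_len(L)) {
    sc <- sc + int_matrix[j, grid[, j]]
    w <- w * background[grid[, j]]
  }
  scores <- sort(unique(sc))
  tails <- vapply(scores, function(s) sum(w[sc >= s]), numeric(1))
  tibble::tibble(score_int = scores, tail = tails)
}

# random accessibility fixture shared by the chromatin rule tests
random_rule_fixture <- function(n_peaks, seed) {
  withr::with_seed(seed, {
    acc <- chromcord:::make_acc_manifest()
    bpm <- matrix(round(runif(n_peaks * nrow(acc), 0, 3), 3),
                  nrow = n_peaks,
                  dimnames = list(sprintf("pk%04d", seq_len(n_peaks)),
                                  acc$acc_sample))
    links <- tibble::tibble(peak_id = rownames(bpm), gene_id = "g1",
                            tss_distance = 0L, abs_distance = 0L)
    list(bpm = bpm, acc = acc, links = links, geneset = "g1")
  })
}
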