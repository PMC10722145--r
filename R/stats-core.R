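# Statistical primitives used throughout the pipeline. Each test returns a
# one-row tibble so results bind cleanly into larger tables.

test_result <- function(statistic, p_value, method, n1, n2, ...) {
  tibble(statistic = unname(statistic), p_value = unname(p_value),
         method = method, n1 = as.integer(n1), n2 = as.integer(n2), ...)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The exact null
#' distribution is used when the larger sample has at most `exact_max_n`
#' observations and there are no ties; otherwise a normal approximation with
#' tie correction and continuity correction is applied.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_max_n Largest group size for which the exact null is used.
#' @return One-row tibble with `statistic` (U for `x`), `p_value`, `method`,
#'   group sizes `n1`, `n2` and a logical `exact` flag.
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))
#' @export
mwu_test <- function(x, y, exact_max_n = 50) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) abort("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && max(length(x), length(y)) <= exact_max_n
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  test_result(ht$statistic, min(p, 1), "mann_whitney_u",
              length(x), length(y), exact = exact)
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Exact differences of zero are dropped before ranking (Wilcoxon's original
#' rule). The exact null is used when at most `exact_max_n` non-zero
#' differences remain and their absolute values are tie-free; otherwise a
#' tie-corrected normal approximation with continuity correction.
#'
#' @param paired_diffs Numeric vector of paired differences.
#' @param exact_max_n Largest n for which the exact null is enumerated.
#' @return One-row tibble; `n1` is the number of non-zero differences used,
#'   `n2` the number of zeros dropped.
#' @examples
#' signed_rank_test(c(1, 2, 3, 4, 5))
#' @export
signed_rank_test <- function(paired_diffs, exact_max_n = 25) {
  d <- paired_diffs[!is.na(paired_diffs)]
  if (length(d) < 1) abort("empty sample")
  nz <- d[d != 0]
  if (length(nz) == 0) abort("degenerate pairing: all differences are zero")
  ties <- anyDuplicated(abs(nz)) > 0
  n <- length(nz)
  r <- rank(abs(nz))
  w_obs <- sum(r[nz > 0])
  if (ties && n <= 15) {
    # exact null with tied ranks by enumeration of all sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
    return(test_result(w_obs, p, "wilcoxon_signed_rank",
                       n, length(d) - n, exact = TRUE))
  }
  exact <- !ties && n <= exact_max_n
  ht <- suppressWarnings(wilcox.test(nz, exact = exact, correct = TRUE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  test_result(ht$statistic, min(p, 1), "wilcoxon_signed_rank",
              n, length(d) - n, exact = exact)
}

#' Exact hypergeometric test (two-sided and enrichment tail)
#'
#' Draws `n` without replacement from a universe of `N` containing `K`
#' category members and observes `k` in the category. The two-sided p-value
#' follows the minimum-likelihood definition (sum of all point masses not
#' exceeding the observed one); the one-sided enrichment tail
#' \eqn{P(X \ge k)} is returned as the `statistic` and is the quantity used
#' for enrichment ranking elsewhere in the package.
#'
#' @param k Observed category count in the draw.
#' @param K Category size in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return One-row tibble with `statistic` (one-sided tail), `p_value`
#'   (two-sided), the counts, and both tails as `one_sided`/`two_sided`.
#' @examples
#' hypergeom_test(k = 5, K = 5, n = 5, N = 10)
#' @export
hypergeom_test <- function(k, K, n, N) {
  v <- c(k = k, K = K, n = n, N = N)
  if (any(v < 0) || any(v != round(v))) abort("counts must be non-negative integers")
  if (K > N || n > N) abort("inconsistent counts: K and n must not exceed N")
  if (k > min(K, n) || k < max(0, n + K - N)) {
    abort("inconsistent counts: k outside the hypergeometric support")
  }
  support <- max(0, n + K - N):min(K, n)
  pmf <- dhyper(support, K, N - K, n)
  p_obs <- dhyper(k, K, N - K, n)
  two_sided <- min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
  one_sided <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  test_result(one_sided, two_sided, "hypergeom_two_sided", n, N,
              k = as.integer(k), K = as.integer(K),
              one_sided = one_sided, two_sided = two_sided)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment; the returned q-values are monotone when ordered by p
#' and never smaller than the input p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 iff identical up to relabeling, near 0 for independent labelings.
#'
#' @param labels_a,labels_b Equal-length label vectors (length >= 2).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("label vectors differ in length")
  if (length(labels_a) < 2) abort("need at least two items")
  unname(mclust::adjustedRandIndex(labels_a, labels_b))
}

# Vectorised row-wise rank-sum test (normal approximation with tie and
# continuity corrections). Used for gene x sample matrices where thousands
# of tests run per call; the scalar mwu_test() is the reference behaviour.
row_mwu <- function(mat, idx_a, idx_b) {
  n1 <- length(idx_a); n2 <- length(idx_b)
  stopifnot(n1 >= 1, n2 >= 1)
  sub <- mat[, c(idx_a, idx_b), drop = FALSE]
  N <- n1 + n2
  mu <- n1 * n2 / 2
  res <- apply(sub, 1L, function(v) {
    r <- rank(v)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - rle_tie_term(v) / (N * (N - 1)))
    if (sig2 <= 0) return(c(U, 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    c(U, min(1, 2 * pnorm(-abs(z))))
  })
  tibble(statistic = res[1L, ], p_value = res[2L, ])
}
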