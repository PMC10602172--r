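# Shared fixtures and independent brute-force oracles used across tests.

# Small expression matrix from named cell vectors: make_em(c1 = c(KLRD1 = 3, ...))
make_em <- function(..., normalization = "ln_cpm1") {
  cells <- list(...)
  m <- do.call(rbind, cells)
  rownames(m) <- names(cells)
  expression_matrix(m, normalization)
}

# Brute-force hypergeometric tails by enumerating all size-n draws from a
# universe with K marked elements.
brute_hyper <- function(k, K, n, N) {
  if (n == 0) {
    overlaps <- 0L
  } else {
    draws <- utils::combn(N, n)
    overlaps <- colSums(draws <= K)  # elements 1..K are the marked set
  }
  list(p_over = mean(overlaps >= k), p_under = mean(overlaps <= k))
}

# Independent exact two-sided Mann-Whitney p by enumerating value
# assignments and counting pairs directly (no ranks).
perm_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  mu <- na * length(b) / 2
  obs <- abs(u_of(a, b) - mu)
  idx <- utils::combn(length(pooled), na)
  devs <- apply(idx, 2, function(i) abs(u_of(pooled[i], pooled[-i]) - mu))
  mean(devs >= obs - 1e-9)
}

# AUROC by explicit positive/negative pair counting.
pair_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Spot classes of a generated spatial dataset, as a named list of id vectors.
spot_groups <- function(spatial) {
  cls <- identify_spatial_cd8(spatial)
  split(cls$spot_id, cls$class)
}
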