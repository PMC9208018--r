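# Independent brute-force oracles: explicit window enumeration, string-keyed
# dictionary counting, and a permutation list generated by filtering the full
# n^n grid.  Deliberately shares no code with the package internals.

oracle_perm_list <- function(n) {
  g <- expand.grid(rep(list(seq_len(n)), n))[, n:1, drop = FALSE]
  keep <- apply(g, 1L, function(r) length(unique(r)) == n)
  P <- as.matrix(g[keep, , drop = FALSE])
  keys <- apply(P, 1L, paste, collapse = "-")
  P[order(keys), , drop = FALSE]  # lexicographic for single-digit ranks
}

oracle_ranks <- function(w) rank(-w, ties.method = "first")

oracle_symbolize <- function(x, n, tau) {
  m <- length(x) - (n - 1) * tau
  P <- oracle_perm_list(n)
  keys <- apply(P, 1L, paste, collapse = "-")
  vapply(seq_len(m), function(t) {
    w <- x[t + (0:(n - 1)) * tau]
    match(paste(oracle_ranks(w), collapse = "-"), keys) - 1L
  }, integer(1))
}

oracle_pe <- function(x, n, tau) {
  s <- oracle_symbolize(x, n, tau)
  p <- as.numeric(table(s)) / length(s)
  -sum(p * log(p)) / log(factorial(n))
}

oracle_jpe_inv <- function(x, y, n, tau, renormalize = TRUE) {
  sx <- oracle_symbolize(x, n, tau)
  sy <- oracle_symbolize(y, n, tau)
  P <- oracle_perm_list(n)
  mirror_of <- vapply(seq_len(nrow(P)), function(i) {
    key <- paste(n + 1 - P[i, ], collapse = "-")
    match(key, apply(P, 1L, paste, collapse = "-")) - 1L
  }, integer(1))
  keep <- !(sy == sx | sy == mirror_of[sx + 1L])
  nf <- factorial(n)
  n_bins <- nf * nf - 2 * nf
  if (!any(keep)) return(0)
  tab <- table(paste(sx[keep], sy[keep]))
  cnt <- as.numeric(tab)
  denom <- if (renormalize) sum(cnt) else length(sx)
  p <- cnt / denom
  H <- -sum(p * log(p))
  min(max(1 - H / log(n_bins), 0), 1)
}

# independent BH step-up: q_(i) = min over j >= i of p_(j) * m / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exhaustive permutation p-value for small two-group vectors (one ROI)
oracle_exact_perm_p <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  parts <- utils::combn(length(x), na)
  Ts <- apply(parts, 2L, function(idx) {
    abs(mean(x[idx]) - mean(x[-idx]))
  })
  mean(Ts >= obs - 1e-12)
}

# midrank Mann-Whitney AUC
oracle_auc_mw <- function(score, is_pos) {
  r <- rank(score, ties.method = "average")
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small helper used across test files
quiet_jpe <- function(...) suppressWarnings(jpe_inv(...))
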