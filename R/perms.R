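# Codec between rank vectors (permutations of 1..n) and their lexicographic
# index in 0 .. n!-1, plus the amplitude-mirror map.  All heavier callers go
# through the cached tables in .perm_cache.

.perm_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as rows, in lexicographic order.
perm_table <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n == as.integer(n), n >= 1L)
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  gen <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], gen(v[-i]))
    }))
  }
  tbl <- gen(seq_len(as.integer(n)))
  storage.mode(tbl) <- "integer"
  .perm_cache[[key]] <- tbl
  tbl
}

# Lehmer encoding: rank-vector rows -> lexicographic index.
# R is an m x n matrix whose rows are permutations of 1..n.
lehmer_encode <- function(R) {
  n <- ncol(R)
  m <- nrow(R)
  if (n == 1L) return(integer(m))
  fact <- as.integer(rev(cumprod(c(1, seq_len(n - 1L)))))  # (n-1)!, ..., 0!
  s <- integer(m)
  for (i in seq_len(n - 1L)) {
    ci <- integer(m)
    for (j in (i + 1L):n) ci <- ci + (R[, j] < R[, i])
    s <- s + ci * fact[i]
  }
  s
}

#' Mirror an ordinal symbol (amplitude reversal)
#'
#' Maps an ordinal-pattern symbol to the symbol of the amplitude-inverted
#' signal: every rank `r` in the underlying rank vector is replaced by
#' `n + 1 - r`.  Mirroring is an involution: `mirror_symbol(mirror_symbol(s,
#' n), n)` equals `s`.  Pairs of identical or mirrored symbols across two
#' channels are the signature of zero-lag signal mixing (volume
#' conduction/field spread) and are excluded from the joint permutation
#' entropy (see [jpe_inv()]).
#'
#' @param symbol Integer vector of symbols in `0 .. n!-1` (lexicographic
#'   index of the rank vector, see [symbolize()]).
#' @param n Embedding dimension.
#' @return Integer vector of mirrored symbols.
#' @examples
#' mirror_symbol(0L, 3L)  # ranks (1,2,3) -> (3,2,1) -> symbol 5
#' @export
mirror_symbol <- function(symbol, n) {
  nf <- factorial(n)
  symbol <- as.integer(symbol)
  if (any(!is.finite(symbol)) || any(symbol < 0L) || any(symbol >= nf)) {
    stop("`symbol` must lie in 0 .. n!-1 (n = ", n, ")", call. = FALSE)
  }
  tbl <- perm_table(n)
  key <- paste0("mirror", n)
  if (is.null(.perm_cache[[key]])) {
    .perm_cache[[key]] <- lehmer_encode(as.integer(n) + 1L - tbl)
  }
  .perm_cache[[key]][symbol + 1L]
}

# Linear indices (1-based) into an n! x n! joint matrix, column-major with
# cell (sx, sy) at sx*n! + sy + 1, of the identical and mirrored symbol
# pairs.  Computed from the actual identical-union-mirrored set rather than
# assuming 2*n! distinct cells.
masked_cells <- function(n) {
  nf <- factorial(n)
  a <- 0:(nf - 1L)
  unique(c(a * nf + a, a * nf + mirror_symbol(a, n)) + 1L)
}
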