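#' Convert a time series to a sequence of ordinal-pattern symbols
#'
#' Slides a window of `n` samples, each separated by `tau` samples, along the
#' series and encodes the ordinal pattern of every window as an integer
#' symbol.  Within a window the sample with the highest amplitude receives
#' rank 1, the second highest rank 2, and so on down to rank `n` for the
#' lowest sample; equal amplitudes are ranked by temporal order (the earlier
#' sample gets the lower rank number).  The symbol is the lexicographic index
#' (0-based) of the resulting rank vector among all `n!` permutations.
#'
#' Note the rank convention: rank 1 marks the *highest* amplitude.  This is
#' the reverse of argsort-based conventions used by some permutation-entropy
#' libraries; entropy values are unaffected but individual symbol codes
#' differ.
#'
#' @param x Numeric vector, a single-channel time series (finite values).
#' @param n Embedding dimension (samples per pattern), `n >= 2`.
#' @param tau Time delay in samples between pattern elements, `tau >= 1`.
#' @return Integer vector of `length(x) - (n-1)*tau` symbols in `0 .. n!-1`.
#' @examples
#' symbolize(c(1, 2, 3, 4, 5), n = 3)   # monotone ramp: all symbols 5
#' symbolize(c(3, 1, 2), n = 3)         # ranks (1,3,2) -> symbol 1
#' @seealso [permutation_entropy()], [jpe_inv()]
#' @export
symbolize <- function(x, n = 4L, tau = 1L) {
  check_ordinal_params(n, tau)
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  out <- symbolize_matrix(matrix(x, ncol = 1L), n, tau)
  out[, 1L]
}

# Symbolize every column of a samples x k matrix at once; returns an
# m x k integer matrix, m = nrow(X) - (n-1)*tau.  This is the vectorized
# kernel all higher-level entry points share.
symbolize_matrix <- function(X, n = 4L, tau = 1L) {
  n <- as.integer(n); tau <- as.integer(tau)
  T_len <- nrow(X)
  m <- T_len - (n - 1L) * tau
  if (m < 1L) {
    stop("series of length ", T_len, " too short for n = ", n,
         ", tau = ", tau, " (needs at least ", (n - 1L) * tau + 1L,
         " samples)", call. = FALSE)
  }
  k <- ncol(X)
  rows <- seq_len(m)
  # rank of each window position: 1 + (# larger) + (# earlier equal)
  R <- vector("list", n)
  W <- lapply(seq_len(n), function(i) X[rows + (i - 1L) * tau, , drop = FALSE])
  for (i in seq_len(n)) {
    ri <- matrix(1L, m, k)
    for (j in seq_len(n)) {
      if (j == i) next
      if (j < i) ri <- ri + (W[[j]] >= W[[i]])
      else       ri <- ri + (W[[j]] >  W[[i]])
    }
    R[[i]] <- ri
  }
  # Lehmer code of the rank vector -> lexicographic symbol
  fact <- as.integer(rev(cumprod(c(1, seq_len(n - 1L)))))
  S <- matrix(0L, m, k)
  for (i in seq_len(n - 1L)) {
    ci <- matrix(0L, m, k)
    for (j in (i + 1L):n) ci <- ci + (R[[j]] < R[[i]])
    S <- S + ci * fact[i]
  }
  S
}

check_ordinal_params <- function(n, tau) {
  if (length(n) != 1L || !is.numeric(n) || n != round(n) || n < 2L) {
    stop("embedding dimension `n` must be a single integer >= 2",
         call. = FALSE)
  }
  if (length(tau) != 1L || !is.numeric(tau) || tau != round(tau) || tau < 1L) {
    stop("time delay `tau` must be a single integer >= 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Ordinal-pattern probability distribution
#'
#' Relative frequency of each of the `n!` ordinal patterns in a symbol
#' sequence.
#'
#' @param symbols Integer vector of symbols as produced by [symbolize()].
#' @param n Embedding dimension the symbols were generated with.
#' @return Numeric vector of length `n!` summing to 1; element `i` is the
#'   probability of symbol `i - 1`.
#' @export
pattern_distribution <- function(symbols, n = 4L) {
  nf <- factorial(as.integer(n))
  if (length(symbols) == 0L) stop("empty symbol sequence", call. = FALSE)
  if (any(symbols < 0L | symbols >= nf)) {
    stop("symbols out of range 0 .. n!-1", call. = FALSE)
  }
  tabulate(as.integer(symbols) + 1L, nbins = nf) / length(symbols)
}

#' Shannon entropy of a discrete distribution
#'
#' Natural-log Shannon entropy with the convention `0 * log(0) = 0`.
#'
#' @param p Numeric vector of probabilities (non-negative, summing to 1).
#' @return Entropy in nats, in `[0, log(length(p))]`.
#' @export
shannon_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("probabilities must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  p <- p[p > 0]
  -sum(p * log(p)) + 0  # + 0 avoids returning negative zero for point masses
}

#' Permutation entropy of a single time series
#'
#' Shannon entropy of the ordinal-pattern distribution, normalized by its
#' maximum `log(n!)` so that values lie in `[0, 1]`.  A strictly monotone
#' series yields 0 (one pattern); white noise approaches 1.
#'
#' @inheritParams symbolize
#' @return Normalized permutation entropy in `[0, 1]`.
#' @examples
#' permutation_entropy(sin(seq(0, 10 * pi, length.out = 1000)), n = 4)
#' @export
permutation_entropy <- function(x, n = 4L, tau = 1L) {
  s <- symbolize(x, n, tau)
  shannon_entropy(pattern_distribution(s, n)) / log(factorial(as.integer(n)))
}

#' Joint ordinal-pattern distribution of two channels
#'
#' Joint relative frequency of simultaneous symbol pairs from two
#' time-aligned symbol sequences, together with the exclusion mask marking
#' identical and mirrored pattern pairs (the cells attributed to volume
#' conduction/field spread).
#'
#' @param sx,sy Integer symbol sequences of equal length from [symbolize()]
#'   with the same `n`.
#' @param n Embedding dimension.
#' @return An object of class `joint_pattern_matrix`: a list with `probs`
#'   (`n! x n!` matrix, cell `(a+1, b+1)` the probability of symbol `a` in x
#'   and `b` in y), logical `mask` of excluded cells, and `retained_mass`,
#'   the probability mass outside the mask.
#' @export
joint_distribution <- function(sx, sy, n = 4L) {
  if (length(sx) != length(sy)) {
    stop("symbol sequences must have equal length", call. = FALSE)
  }
  if (length(sx) == 0L) stop("empty symbol sequences", call. = FALSE)
  nf <- factorial(as.integer(n))
  if (any(sx < 0L | sx >= nf) || any(sy < 0L | sy >= nf)) {
    stop("symbols out of range 0 .. n!-1; wrong `n`?", call. = FALSE)
  }
  counts <- joint_counts(as.integer(sx), as.integer(sy), nf)
  probs <- matrix(counts / length(sx), nf, nf)
  mask <- matrix(FALSE, nf, nf)
  mask[masked_cells(n)] <- TRUE
  structure(
    list(probs = probs, mask = mask,
         retained_mass = sum(probs[!mask]), n = as.integer(n)),
    class = "joint_pattern_matrix"
  )
}

# counts in column-major layout: cell (x-symbol a, y-symbol b) at
# index b*nf + a + 1, so matrix(counts, nf, nf)[a+1, b+1] = #(x=a, y=b)
joint_counts <- function(sx, sy, nf) {
  tabulate(sy * nf + sx + 1L, nbins = nf * nf)
}

#' @export
print.joint_pattern_matrix <- function(x, ...) {
  cat("Joint ordinal-pattern matrix (n = ", x$n, ", ", nrow(x$probs), " x ",
      ncol(x$probs), " bins)\n", sep = "")
  cat("  excluded cells (identical/mirrored): ", sum(x$mask), "\n", sep = "")
  cat("  retained probability mass: ", format(x$retained_mass), "\n", sep = "")
  invisible(x)
}

# JPE_inv from a joint count vector (column-major, length nf^2).
# Returns the scalar value; attribute "degenerate" marks all-mass-masked.
jpe_inv_from_counts <- function(counts, n, corrected = TRUE,
                                renormalize = TRUE) {
  nf <- factorial(as.integer(n))
  total <- sum(counts)
  if (corrected) {
    cells <- masked_cells(n)
    counts[cells] <- 0L
    n_bins <- nf * nf - length(cells)
  } else {
    n_bins <- nf * nf
  }
  retained <- sum(counts)
  if (retained / total < 1e-9) {
    # all probability mass sits on identical/mirrored pairs: the signature
    # of pure zero-lag mixing, scored as absence of genuine coupling
    warning("all joint probability mass on identical/mirrored symbol pairs; ",
            "returning JPE_inv = 0 (degenerate, leakage-like input)",
            call. = FALSE)
    return(structure(0, degenerate = TRUE))
  }
  denom <- if (renormalize) retained else total
  # sorting the positive counts makes the floating-point sum independent of
  # channel order, so jpe_inv(x, y) == jpe_inv(y, x) bit-exactly
  p <- sort(counts[counts > 0L]) / denom
  H <- -sum(p * log(p))
  jpe <- H / log(n_bins)
  min(max(1 - jpe, 0), 1)
}

#' Inverted joint permutation entropy of two channels
#'
#' Network-level measure of nonlinear coupling between two simultaneous time
#' series.  Both channels are symbolized ([symbolize()]); the joint
#' symbol-pair distribution is formed; cells holding identical or mirrored
#' pattern pairs are excluded (volume-conduction correction) and the retained
#' cells renormalized; the joint Shannon entropy is normalized by the log of
#' the number of retained bins, `log(n!*n! - 2*n!)`, giving the joint
#' permutation entropy JPE in `[0, 1]`; the returned value is `1 - JPE`, so
#' that stronger coupling gives larger values.
#'
#' If essentially all joint mass falls on identical/mirrored pairs (e.g.
#' `y = x` or `y = -x`), the input is indistinguishable from pure zero-lag
#' mixing and the function returns 0 with a warning.
#'
#' @param x,y Numeric vectors of equal length, the two channels.
#' @inheritParams symbolize
#' @param corrected Exclude identical and mirrored symbol pairs (the
#'   volume-conduction correction).  `FALSE` gives the uncorrected variant
#'   normalized by `log(n!*n!)`, for sensitivity analyses.
#' @param renormalize Renormalize the retained cells to sum 1 before the
#'   entropy sum (default).  `FALSE` keeps the raw retained probabilities,
#'   mirroring implementations that only zero the excluded cells.
#' @return JPE_inv in `[0, 1]`.  Symmetric in `x` and `y`.
#' @examples
#' set.seed(1)
#' x <- rnorm(2000); y <- rnorm(2000)
#' jpe_inv(x, y, n = 3)            # independent channels: near 0
#' @export
jpe_inv <- function(x, y, n = 4L, tau = 1L, corrected = TRUE,
                    renormalize = TRUE) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  sx <- symbolize(x, n, tau)
  sy <- symbolize(y, n, tau)
  nf <- factorial(as.integer(n))
  val <- jpe_inv_from_counts(joint_counts(sx, sy, nf), n,
                             corrected = corrected, renormalize = renormalize)
  as.numeric(val)
}

#' Pairwise JPE_inv connectivity matrix over channels
#'
#' Computes [jpe_inv()] for every unordered pair of channels, symbolizing
#' each channel once and reusing the symbol sequences across pairs.
#'
#' @param x Numeric matrix, channels x samples (one row per ROI/channel).
#' @inheritParams jpe_inv
#' @param labels Optional channel labels; defaults to rownames or
#'   `ROI_001, ...`.
#' @param band Optional band label stored with the result.
#' @return An object of class `connectivity_result`: list with the symmetric
#'   `matrix` (diagonal 0), `roi_profile` (per-channel mean over the other
#'   channels), `n`, `tau`, `band`, `labels`.  `tidy()` returns one row per
#'   unordered pair; `autoplot()` draws the matrix.
#' @export
connectivity_matrix <- function(x, n = 4L, tau = 1L, labels = NULL,
                                corrected = TRUE, renormalize = TRUE,
                                band = "raw") {
  if (!is.matrix(x) || nrow(x) < 2L) {
    stop("`x` must be a channels x samples matrix with >= 2 channels",
         call. = FALSE)
  }
  k <- nrow(x)
  if (is.null(labels)) {
    labels <- rownames(x)
    if (is.null(labels)) labels <- sprintf("ROI_%03d", seq_len(k))
  }
  S <- symbolize_matrix(t(x), n, tau)
  M <- jpe_matrix_from_symbols(S, n, corrected = corrected,
                               renormalize = renormalize)
  dimnames(M) <- list(labels, labels)
  new_connectivity_result(M, n, tau, band, labels)
}

# pairwise JPE_inv from an m x k symbol matrix (columns = channels).
# Inlines jpe_inv_from_counts with the mask hoisted out of the O(k^2) loop.
jpe_matrix_from_symbols <- function(S, n, corrected = TRUE,
                                    renormalize = TRUE) {
  k <- ncol(S)
  nf <- factorial(as.integer(n))
  cells <- if (corrected) masked_cells(n) else integer(0)
  n_bins <- nf * nf - length(cells)
  log_bins <- log(n_bins)
  m_rows <- nrow(S)
  Sy <- S * nf  # precomputed y-part of the pair code (see joint_counts)
  M <- matrix(0, k, k)
  degenerate <- FALSE
  for (i in seq_len(k - 1L)) {
    si <- S[, i] + 1L
    for (j in (i + 1L):k) {
      cnt <- tabulate(Sy[, j] + si, nbins = nf * nf)
      cnt[cells] <- 0L
      retained <- sum(cnt)
      if (retained / m_rows < 1e-9) {
        degenerate <- TRUE
        next  # value stays 0
      }
      p <- sort.int(cnt[cnt > 0L]) / (if (renormalize) retained else m_rows)
      jpe <- -sum(p * log(p)) / log_bins
      M[i, j] <- M[j, i] <- min(max(1 - jpe, 0), 1)
    }
  }
  if (degenerate) {
    warning("channel pair(s) with all joint mass on identical/mirrored ",
            "patterns; their JPE_inv was set to 0", call. = FALSE)
  }
  M
}

new_connectivity_result <- function(M, n, tau, band, labels) {
  k <- nrow(M)
  profile <- (rowSums(M)) / (k - 1)  # diagonal is 0 and excluded
  structure(
    list(matrix = M, roi_profile = setNames(profile, labels),
         n = as.integer(n), tau = as.integer(tau), band = band,
         labels = labels),
    class = "connectivity_result"
  )
}

#' @export
print.connectivity_result <- function(x, ...) {
  k <- nrow(x$matrix)
  off <- x$matrix[upper.tri(x$matrix)]
  cat("JPE_inv connectivity (n = ", x$n, ", tau = ", x$tau, ", band = ",
      x$band, ")\n", sep = "")
  cat("  ", k, " channels, ", length(off), " pairs; mean JPE_inv = ",
      format(mean(off), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname connectivity_matrix
#' @param x A `connectivity_result`.
#' @param ... Unused.
#' @method tidy connectivity_result
#' @export
tidy.connectivity_result <- function(x, ...) {
  k <- nrow(x$matrix)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(
    roi_a = x$labels[idx[, 1L]],
    roi_b = x$labels[idx[, 2L]],
    jpe_inv = x$matrix[idx],
    band = x$band
  )
}

#' @rdname connectivity_matrix
#' @param object A `connectivity_result`.
#' @method autoplot connectivity_result
#' @export
autoplot.connectivity_result <- function(object, ...) {
  df <- expand.grid(roi_a = object$labels, roi_b = object$labels,
                    stringsAsFactors = FALSE)
  df$jpe_inv <- as.vector(object$matrix)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_a, y = .data$roi_b,
                                   fill = .data$jpe_inv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "JPE_inv") +
    ggplot2::labs(
      title = paste0("JPE_inv connectivity (", object$band, " band)"),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
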