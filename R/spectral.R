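#' Canonical frequency bands
#'
#' The four analysis bands used throughout the pipeline: theta (4-8 Hz),
#' alpha (8-13 Hz), beta (13-30 Hz), broadband (0.5-45 Hz).  Band edges are
#' half-open `[f_low, f_high)`, so a shared edge belongs to the higher band
#' (8 Hz is alpha, not theta).
#'
#' @return A tibble with columns `band`, `f_low`, `f_high`.
#' @export
canonical_bands <- function() {
  tibble::tibble(
    band = c("theta", "alpha", "beta", "broadband"),
    f_low = c(4, 8, 13, 0.5),
    f_high = c(8, 13, 30, 45)
  )
}

check_band <- function(f_low, f_high, fs) {
  if (!(is.numeric(f_low) && is.numeric(f_high) && f_low > 0 &&
        f_low < f_high)) {
    stop("band must satisfy 0 < f_low < f_high", call. = FALSE)
  }
  if (f_high > fs / 2) {
    stop("band upper edge ", f_high, " Hz exceeds the Nyquist frequency ",
         fs / 2, " Hz", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cut a continuous recording into consecutive epochs
#'
#' Takes `n_epochs` consecutive non-overlapping windows of `epoch_len`
#' samples starting at the first sample.  Defaults follow the analysis
#' protocol of 20 epochs of 4,096 samples (3.2768 s at 1,250 Hz).
#'
#' @param raw Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param n_epochs Number of epochs to extract.
#' @param epoch_len Epoch length in samples.
#' @param labels Optional channel labels (default: rownames or `ROI_001...`).
#' @return An `epoched_recording`: list with `data` (channels x epochs x
#'   samples array), `fs`, `channel_labels`, `band` (initially `"raw"`).
#' @export
extract_epochs <- function(raw, fs, n_epochs = 20L, epoch_len = 4096L,
                           labels = NULL) {
  if (!is.matrix(raw)) stop("`raw` must be a channels x samples matrix",
                            call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  needed <- n_epochs * epoch_len
  if (ncol(raw) < needed) {
    stop("recording has ", ncol(raw), " samples but ", needed,
         " are required (", n_epochs, " epochs x ", epoch_len,
         " samples); short by ", needed - ncol(raw), call. = FALSE)
  }
  k <- nrow(raw)
  if (is.null(labels)) {
    labels <- rownames(raw)
    if (is.null(labels)) labels <- sprintf("ROI_%03d", seq_len(k))
  }
  data <- array(NA_real_, dim = c(k, n_epochs, epoch_len))
  for (e in seq_len(n_epochs)) {
    data[, e, ] <- raw[, ((e - 1L) * epoch_len + 1L):(e * epoch_len)]
  }
  structure(
    list(data = data, fs = fs, channel_labels = labels, band = "raw"),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoched recording: ", d[1], " channels x ", d[2], " epochs x ", d[3],
      " samples @ ", x$fs, " Hz (", format(d[3] / x$fs), " s/epoch, band: ",
      x$band, ")\n", sep = "")
  invisible(x)
}

#' Epoch duration in seconds
#'
#' @param epoch_len Epoch length in samples.
#' @param fs Sampling rate in Hz.
#' @return Duration in seconds (`epoch_len / fs`).
#' @examples
#' epoch_duration(4096, 1250)  # 3.2768 s
#' @export
epoch_duration <- function(epoch_len, fs) {
  if (fs <= 0 || epoch_len <= 0) stop("arguments must be positive",
                                      call. = FALSE)
  epoch_len / fs
}

# |f| of every DFT bin of a length-N transform at sampling rate fs
bin_freqs <- function(N, fs) {
  k <- 0:(N - 1)
  k2 <- pmin(k, N - k)
  k2 * fs / N
}

#' Brick-wall FFT band-pass filter
#'
#' Forward FFT, zeroing of all bins whose absolute frequency lies outside
#' `[f_low, f_high)` (the DC bin is always zeroed), inverse FFT.  No taper,
#' no padding: spectral ringing is accepted as part of the epoch-wise
#' filtering workflow.  Filtering is idempotent, and the output spectrum is
#' exactly zero in the suppressed bins.
#'
#' @param x Numeric vector (one epoch of one channel) or samples x channels
#'   matrix; columns are filtered independently.
#' @param fs Sampling rate in Hz.
#' @param f_low,f_high Band edges in Hz, half-open `[f_low, f_high)`.
#' @return Filtered series, same shape as `x`.
#' @export
bandpass <- function(x, fs, f_low, f_high) {
  check_band(f_low, f_high, fs)
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, ncol = 1L) else x
  N <- nrow(X)
  fr <- bin_freqs(N, fs)
  keep <- fr >= f_low & fr < f_high
  keep[1] <- FALSE  # DC
  Xf <- mvfft(X)
  Xf[!keep, ] <- 0+0i
  out <- Re(mvfft(Xf, inverse = TRUE)) / N
  if (vec) out[, 1L] else out
}

#' Relative band power
#'
#' Fraction of spectral power (squared FFT magnitude over the positive
#' frequencies in `[f_low, f_high)`) relative to the power in a reference
#' band, by default the broadband range 0.5-45 Hz.
#'
#' @inheritParams bandpass
#' @param total Reference band as `c(f_low, f_high)` (default broadband
#'   0.5-45 Hz).
#' @return Relative power in `[0, 1]` (scalar for a vector input, one value
#'   per column for a matrix).
#' @export
relative_power <- function(x, fs, f_low, f_high, total = c(0.5, 45)) {
  check_band(f_low, f_high, fs)
  check_band(total[1], total[2], fs)
  if (f_low < total[1] - 1e-12 || f_high > total[2] + 1e-12) {
    stop("band must lie within the reference band", call. = FALSE)
  }
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, ncol = 1L) else x
  N <- nrow(X)
  fr <- bin_freqs(N, fs)
  pos <- seq_len(floor(N / 2)) + 1L  # positive-frequency bins
  P <- abs(mvfft(X)[pos, , drop = FALSE])^2
  fp <- fr[pos]
  in_band <- fp >= f_low & fp < f_high
  in_total <- fp >= total[1] & fp < total[2]
  denom <- colSums(P[in_total, , drop = FALSE])
  if (any(denom <= 0)) {
    stop("zero power in the reference band", call. = FALSE)
  }
  out <- colSums(P[in_band, , drop = FALSE]) / denom
  if (vec) out[[1L]] else out
}

#' Time delay from band upper edge
#'
#' Rule of thumb mapping a band's upper frequency edge to the ordinal time
#' delay: `tau = round(fs / (3 * f_high))`, floored at 1.  The delay is small
#' enough that patterns still resolve the fastest oscillations present after
#' filtering.
#'
#' @param fs Sampling rate in Hz.
#' @param f_high Upper band edge in Hz.
#' @return Integer delay in samples, `>= 1`.
#' @examples
#' tau_from_band(1250, 45)  # 9
#' tau_from_band(1250, 8)   # 52
#' @export
tau_from_band <- function(fs, f_high) {
  if (fs <= 0 || f_high <= 0) stop("arguments must be positive",
                                   call. = FALSE)
  max(1L, as.integer(round(fs / (3 * f_high))))
}

#' Average per-epoch values per subject
#'
#' Metrics are estimated for each epoch separately and averaged per subject
#' before any group statistics.
#'
#' @param values Numeric epochs x channels matrix of per-epoch estimates.
#' @return Numeric vector of per-channel means over epochs.
#' @export
per_subject_aggregate <- function(values) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (nrow(values) < 1L) stop("no epochs to aggregate", call. = FALSE)
  colMeans(values)
}
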