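#' Specification of one synthetic multichannel subject
#'
#' Describes a simulated resting-state recording: per-ROI stochastic AR(2)
#' oscillators (a dominant-rhythm component at `osc_freq` and an irregular
#' theta component at 6 Hz mixed by `theta_fraction`), a 1/f background, a
#' lagged common drive shared by all ROIs implementing genuine
#' (non-zero-lag) coupling of strength `coupling`, and instantaneous mixing
#' between neighboring channels of strength `leakage` emulating volume
#' conduction/field spread.
#'
#' ROI `i` receives the common drive delayed by `(i - 1) * coupling_lag`
#' samples, so every channel pair shares the drive at a non-zero relative
#' lag and genuine coupling survives the identical/mirrored-pattern
#' exclusion.
#'
#' @param n_rois Number of channels/ROIs.
#' @param fs Sampling rate (Hz).
#' @param n_epochs,epoch_len Epoch grid (defaults 20 x 4096 samples).
#' @param osc_freq Peak frequency (Hz) of the dominant oscillator
#'   (10 Hz = alpha-peaked, control-like).
#' @param osc_bandwidth Bandwidth (Hz) of the dominant oscillator.
#' @param theta_fraction Mixing weight in `[0, 1]` of the irregular 6 Hz
#'   theta component (higher = more theta power, MCI-like slowing).
#' @param theta_bandwidth Bandwidth (Hz) of the theta component; wide by
#'   default so added theta is arrhythmic rather than a pure rhythm.
#' @param coupling Strength `kappa` in `[0, 1]` of the lagged common drive.
#' @param coupling_lag Per-ROI drive delay increment in samples (`>= 1`).
#' @param leakage Zero-lag mixing weight `lambda` in `[0, 1)`:
#'   `x_i <- (1 - lambda) x_i + lambda * mean(ring neighbors)`.
#' @param noise_sd Amplitude of the 1/f background relative to the
#'   unit-variance oscillatory components.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return Object of class `subject_spec`.
#' @export
subject_spec <- function(n_rois = 80L, fs = 1250, n_epochs = 20L,
                         epoch_len = 4096L, osc_freq = 10,
                         osc_bandwidth = 2, theta_fraction = 0.15,
                         theta_bandwidth = 3, coupling = 0.6,
                         coupling_lag = 10L, leakage = 0, noise_sd = 1,
                         seed = 1L) {
  spec <- list(
    n_rois = as.integer(n_rois), fs = fs, n_epochs = as.integer(n_epochs),
    epoch_len = as.integer(epoch_len), osc_freq = osc_freq,
    osc_bandwidth = osc_bandwidth, theta_fraction = theta_fraction,
    theta_bandwidth = theta_bandwidth, coupling = coupling,
    coupling_lag = as.integer(coupling_lag), leakage = leakage,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_subject_spec(spec)
  structure(spec, class = "subject_spec")
}

validate_subject_spec <- function(s) {
  stopifnot(s$n_rois >= 1L, s$fs > 0, s$n_epochs >= 1L, s$epoch_len >= 2L)
  if (s$osc_freq <= 0 || s$osc_freq >= s$fs / 2) {
    stop("`osc_freq` must lie in (0, Nyquist)", call. = FALSE)
  }
  for (f in c("theta_fraction", "coupling")) {
    if (s[[f]] < 0 || s[[f]] > 1) {
      stop("`", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (s$leakage < 0 || s$leakage >= 1) {
    stop("`leakage` must lie in [0, 1)", call. = FALSE)
  }
  if (s$coupling_lag < 1L) {
    stop("`coupling_lag` must be >= 1 sample so genuine coupling is not ",
         "removed by the zero-lag exclusion", call. = FALSE)
  }
  if (s$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  invisible(s)
}

# Unit-variance stochastic AR(2) resonator; pole radius from bandwidth,
# pole angle from the peak frequency (standard pole-placement mapping).
ar2_oscillator <- function(n, fs, freq, bandwidth, innov = rnorm(n)) {
  r <- exp(-pi * bandwidth / fs)
  phi <- 2 * pi * freq / fs
  x <- as.numeric(stats::filter(innov, c(2 * r * cos(phi), -r^2),
                                method = "recursive"))
  x / sd(x)
}

# Unit-variance 1/f (pink-like) noise via spectral shaping of white noise;
# amplitude ~ f^(-1/2) above a 0.5 Hz floor, DC removed.
pink_noise <- function(n, fs) {
  # shape on an FFT-friendly length and truncate; the trimmed tail only
  # perturbs the spectrum at the 1/n level
  m <- stats::nextn(n, c(2L, 3L, 5L))
  w <- rnorm(m)
  fr <- bin_freqs(m, fs)
  amp <- 1 / sqrt(pmax(fr, 0.5))
  amp[1] <- 0
  x <- Re(fft(fft(w) * amp, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

#' Generate one synthetic subject
#'
#' Simulates the multichannel recording described by a [subject_spec()] and
#' epochs it.  Each ROI is
#' `(1 - theta_fraction) * alpha-osc + theta_fraction * theta-osc +
#' coupling * drive(t - (i-1) * coupling_lag) + noise_sd * pink`,
#' followed by optional zero-lag neighbor mixing (leakage).  All component
#' signals have unit variance before weighting, so the weights are directly
#' interpretable as amplitude ratios.
#'
#' @param spec A [subject_spec()].
#' @return An `epoched_recording` (see [extract_epochs()]).
#' @export
generate_subject <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  validate_subject_spec(spec)
  total <- spec$n_epochs * spec$epoch_len
  burn <- 2000L
  max_lag <- (spec$n_rois - 1L) * spec$coupling_lag
  n_all <- total + burn + max_lag
  raw <- withr::with_seed(spec$seed, {
    drive <- ar2_oscillator(n_all, spec$fs, 6, 0.5)
    X <- matrix(0, spec$n_rois, total)
    for (i in seq_len(spec$n_rois)) {
      osc <- ar2_oscillator(n_all, spec$fs, spec$osc_freq,
                            spec$osc_bandwidth)
      th <- ar2_oscillator(n_all, spec$fs, 6, spec$theta_bandwidth)
      pk <- pink_noise(n_all, spec$fs)
      lag_i <- (i - 1L) * spec$coupling_lag
      sel <- (burn + max_lag + 1L):(burn + max_lag + total)
      xi <- (1 - spec$theta_fraction) * osc[sel] +
        spec$theta_fraction * th[sel] +
        spec$coupling * drive[sel - lag_i] +
        spec$noise_sd * pk[sel]
      X[i, ] <- xi
    }
    if (spec$leakage > 0 && spec$n_rois >= 2L) {
      up <- X[c(2:spec$n_rois, 1L), , drop = FALSE]
      dn <- X[c(spec$n_rois, 1:(spec$n_rois - 1L)), , drop = FALSE]
      X <- (1 - spec$leakage) * X + spec$leakage * (up + dn) / 2
    }
    X
  })
  labels <- if (spec$n_rois == 80L) aal80_labels() else NULL
  extract_epochs(raw, spec$fs, spec$n_epochs, spec$epoch_len,
                 labels = labels)
}

#' Specification of a two-group synthetic cohort
#'
#' Default templates contrast a control-like group A (alpha-peaked spectrum,
#' modest theta, stronger coupling) with a patient-like group B (more
#' irregular theta activity, weaker coupling), emulating the oscillatory
#' slowing and loss of network coupling reported in early Alzheimer's
#' disease cohorts.
#'
#' @param group_a,group_b [subject_spec()] templates for the two groups.
#' @param n_a,n_b Subjects per group (default 18 and 18).
#' @param labels Group labels, length 2.
#' @param jitter Relative between-subject jitter (uniform, +/- this
#'   fraction) applied to `coupling` and `theta_fraction`.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_a = subject_spec(osc_freq = 10,
                                               theta_fraction = 0.15,
                                               coupling = 0.6),
                        group_b = subject_spec(osc_freq = 8,
                                               theta_fraction = 0.45,
                                               coupling = 0.3),
                        n_a = 18L, n_b = 18L,
                        labels = c("SCD", "MCI"),
                        jitter = 0.1, seed = 42L) {
  stopifnot(inherits(group_a, "subject_spec"),
            inherits(group_b, "subject_spec"),
            length(labels) == 2L, !anyDuplicated(labels),
            jitter >= 0, jitter < 1)
  if (n_a < 2L || n_b < 2L) stop("need at least 2 subjects per group",
                                 call. = FALSE)
  structure(
    list(group_a = group_a, group_b = group_b, n_a = as.integer(n_a),
         n_b = as.integer(n_b), labels = labels, jitter = jitter,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a two-group synthetic cohort
#'
#' Draws per-subject seeds from the master seed and jitters `coupling` and
#' `theta_fraction` by the cohort's relative `jitter` to create
#' between-subject variance.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `recordings` (list of
#'   `epoched_recording`), `manifest` (tibble with `subject_id`, `group`,
#'   `seed`, and the jittered parameters), and the `spec`.
#' @export
generate_cohort <- function(spec) {
  subs <- cohort_subject_specs(spec)
  recs <- lapply(subs$specs, generate_subject)
  structure(
    list(recordings = setNames(recs, subs$manifest$subject_id),
         manifest = subs$manifest, spec = spec),
    class = "synthetic_cohort"
  )
}

# Derive per-subject specs (jittered, reseeded) and the manifest without
# generating any data; lets the pipeline stream subjects one at a time.
cohort_subject_specs <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ntot <- spec$n_a + spec$n_b
  groups <- rep(spec$labels, c(spec$n_a, spec$n_b))
  draw <- withr::with_seed(spec$seed, {
    list(
      seeds = sample.int(.Machine$integer.max - 1L, ntot),
      jit_k = runif(ntot, -spec$jitter, spec$jitter),
      jit_t = runif(ntot, -spec$jitter, spec$jitter)
    )
  })
  specs <- vector("list", ntot)
  man <- vector("list", ntot)
  for (s in seq_len(ntot)) {
    tmpl <- if (s <= spec$n_a) spec$group_a else spec$group_b
    sub <- tmpl
    sub$coupling <- min(1, max(0, tmpl$coupling * (1 + draw$jit_k[s])))
    sub$theta_fraction <- min(1, max(0, tmpl$theta_fraction *
                                       (1 + draw$jit_t[s])))
    sub$seed <- draw$seeds[s]
    class(sub) <- "subject_spec"
    specs[[s]] <- sub
    man[[s]] <- tibble::tibble(
      subject_id = sprintf("S%03d", s), group = groups[s],
      seed = sub$seed, coupling = sub$coupling,
      theta_fraction = sub$theta_fraction,
      osc_freq = sub$osc_freq, noise_sd = sub$noise_sd,
      leakage = sub$leakage
    )
  }
  list(specs = specs, manifest = dplyr::bind_rows(man))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", x$spec$n_a, " '", x$spec$labels[1], "' + ",
      x$spec$n_b, " '", x$spec$labels[2], "' subjects, ",
      x$spec$group_a$n_rois, " ROIs each\n", sep = "")
  invisible(x)
}
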