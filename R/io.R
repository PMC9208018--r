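#' Read a multichannel ASCII recording
#'
#' Reads a delimited text matrix (samples x channels) with an optional
#' header line of channel labels.  The delimiter (comma or whitespace) and
#' the presence of a header are auto-detected.  Headerless files are labeled
#' `ROI_001, ...`.  The sampling rate is supplied by the caller/config, not
#' the file.
#'
#' @param path Path to the file.
#' @param expected_channels Optional channel count to validate against.
#' @return List with `data` (channels x samples numeric matrix) and
#'   `labels`.
#' @export
read_recording <- function(path, expected_channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!nzchar(trimws(first))) stop("empty recording file: ", path,
                                   call. = FALSE)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else " "
  toks <- strsplit(trimws(gsub(",", " ", first)), "\\s+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks)))
  df <- tryCatch(
    data.table::fread(path, sep = sep, header = has_header,
                      data.table = FALSE, showProgress = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric values in column(s) ",
         paste(names(df)[bad], collapse = ", "), " of ", path,
         call. = FALSE)
  }
  labels <- if (has_header) names(df) else sprintf("ROI_%03d",
                                                   seq_along(df))
  if (!is.null(expected_channels) && ncol(df) != expected_channels) {
    stop("channel-count mismatch in ", path, ": found ", ncol(df),
         ", expected ", expected_channels, call. = FALSE)
  }
  data <- t(as.matrix(df))
  dimnames(data) <- NULL
  rownames(data) <- labels
  list(data = data, labels = labels)
}

#' Write a multichannel recording as delimited ASCII
#'
#' Writes samples x channels with a header of channel labels,
#' space-delimited, at full double precision (round-trips through
#' [read_recording()] to better than 1e-10).
#'
#' @param data Channels x samples numeric matrix.
#' @param path Output path.
#' @param labels Channel labels (default: rownames or `ROI_001...`).
#' @export
write_recording <- function(data, path, labels = NULL) {
  stopifnot(is.matrix(data))
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- sprintf("ROI_%03d", seq_len(nrow(data)))
  }
  df <- as.data.frame(t(data))
  names(df) <- labels
  data.table::fwrite(df, path, sep = " ", col.names = TRUE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One ASCII recording per subject (samples x channels with a header of
#' channel labels, the concatenated epochs in order) plus a YAML manifest
#' listing subject IDs, group labels, seeds, and generation parameters.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  files <- character(nrow(man))
  for (s in seq_len(nrow(man))) {
    rec <- cohort$recordings[[man$subject_id[s]]]
    d <- dim(rec$data)
    flat <- matrix(aperm(rec$data, c(1, 3, 2)), d[1], d[2] * d[3])
    rownames(flat) <- rec$channel_labels
    files[s] <- file.path(dir, paste0(man$subject_id[s], ".txt"))
    write_recording(flat, files[s])
  }
  manifest <- list(
    fs = cohort$spec$group_a$fs,
    n_epochs = cohort$spec$group_a$n_epochs,
    epoch_len = cohort$spec$group_a$epoch_len,
    subjects = lapply(seq_len(nrow(man)), function(s) {
      c(list(file = basename(files[s])),
        as.list(man[s, , drop = FALSE]))
    })
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.yaml` and the per-subject
#'   recordings.
#' @return List with `recordings` (named list of `epoched_recording`) and
#'   `manifest` (tibble).
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.yaml")
  if (!file.exists(mp)) stop("no manifest.yaml in ", dir, call. = FALSE)
  manifest <- yaml::read_yaml(mp)
  man <- dplyr::bind_rows(lapply(manifest$subjects, function(s) {
    tibble::as_tibble(s[setdiff(names(s), "file")])
  }))
  recs <- lapply(manifest$subjects, function(s) {
    rr <- read_recording(file.path(dir, s$file))
    extract_epochs(rr$data, manifest$fs, manifest$n_epochs,
                   manifest$epoch_len, labels = rr$labels)
  })
  names(recs) <- man$subject_id
  list(recordings = recs, manifest = man)
}

#' AAL-style labels for an 80-ROI parcellation
#'
#' Region labels (78 cortical areas plus both hippocampi, left/right
#' interleaved) shipped as a fixture for realistic channel naming of
#' 80-channel recordings.
#'
#' @return Character vector of 80 unique labels.
#' @export
aal80_labels <- function() {
  readLines(system.file("extdata", "aal80_labels.txt", package = "ordinet"))
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Unknown fields are rejected.  The reliability rule `n! <= epoch_len / 10`
#' (patterns need enough windows for stable statistics) is enforced here.
#'
#' @param bands Tibble of bands (`band`, `f_low`, `f_high`); default
#'   [canonical_bands()].
#' @param n Embedding dimension (default 4).
#' @param tau Time delay in samples (default 1); used when
#'   `tau_rule = "fixed"`.
#' @param tau_rule `"fixed"` or `"band"` ([tau_from_band()] per band).
#' @param fs Sampling rate (Hz).
#' @param n_epochs,epoch_len Epoch grid.
#' @param n_perm Permutation-test repartitions (default 10,000).
#' @param alpha_q FDR significance threshold (default 0.05).
#' @param seed Integer seed for all stochastic stages.
#' @param cohort Optional [cohort_spec()] to simulate input from.
#' @param input_dir Optional directory with a written cohort (alternative
#'   to `cohort`).
#' @param output_dir Optional directory for result files.
#' @param classification_band Band whose global means feed the classifiers
#'   (default `"theta"`).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(bands = canonical_bands(), n = 4L, tau = 1L,
                            tau_rule = c("fixed", "band"), fs = 1250,
                            n_epochs = 20L, epoch_len = 4096L,
                            n_perm = 10000L, alpha_q = 0.05, seed = 1L,
                            cohort = NULL, input_dir = NULL,
                            output_dir = NULL,
                            classification_band = "theta") {
  tau_rule <- match.arg(tau_rule)
  check_ordinal_params(n, tau)
  stopifnot(is.data.frame(bands),
            all(c("band", "f_low", "f_high") %in% names(bands)))
  for (b in seq_len(nrow(bands))) {
    check_band(bands$f_low[b], bands$f_high[b], fs)
  }
  if (factorial(n) > epoch_len / 10) {
    stop("n! = ", factorial(n), " exceeds epoch_len/10 = ", epoch_len / 10,
         "; ordinal statistics would be unreliable (choose smaller n or ",
         "longer epochs)", call. = FALSE)
  }
  if (!classification_band %in% bands$band) {
    stop("`classification_band` must be one of the configured bands",
         call. = FALSE)
  }
  cfg <- list(bands = tibble::as_tibble(bands), n = as.integer(n),
              tau = as.integer(tau), tau_rule = tau_rule, fs = fs,
              n_epochs = as.integer(n_epochs),
              epoch_len = as.integer(epoch_len),
              n_perm = as.integer(n_perm), alpha_q = alpha_q,
              seed = as.integer(seed), cohort = cohort,
              input_dir = input_dir, output_dir = output_dir,
              classification_band = classification_band)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; recognized keys are passed to
#' [pipeline_config()].
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads the bare key `n` as the boolean FALSE; map it back
  names(raw)[names(raw) == "FALSE"] <- "n"
  allowed <- setdiff(names(formals(pipeline_config)), "cohort")
  unknown <- setdiff(names(raw), c(allowed, "cohort"))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$bands)) raw$bands <- dplyr::bind_rows(raw$bands)
  if (!is.null(raw$cohort)) {
    ck <- raw$cohort
    mk <- function(g) do.call(subject_spec, g)
    raw$cohort <- cohort_spec(
      group_a = mk(ck$group_a), group_b = mk(ck$group_b),
      n_a = ck$n_a %||% 18L, n_b = ck$n_b %||% 18L,
      labels = unlist(ck$labels %||% c("SCD", "MCI")),
      jitter = ck$jitter %||% 0.1, seed = ck$seed %||% 42L
    )
  }
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
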