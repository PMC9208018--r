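#' Per-subject band-wise entropy and power metrics
#'
#' For each configured band and epoch: FFT band-pass filter, permutation
#' entropy per ROI, pairwise JPE_inv over all ROI pairs, and relative band
#' power per ROI (numerator the band, denominator the broadband reference).
#' Per-epoch estimates are averaged per subject.  Symbolization is performed
#' once per channel per epoch and reused across all pairs.
#'
#' @param rec An `epoched_recording`.
#' @param bands Tibble of bands (`band`, `f_low`, `f_high`).
#' @param n Embedding dimension.
#' @param tau Fixed time delay (used when `tau_rule = "fixed"`).
#' @param tau_rule `"fixed"` or `"band"` (per-band [tau_from_band()]).
#' @param total_band Reference band for relative power.
#' @return Tibble with columns `band`, `tau`, `roi`, `pe`, `jpe_inv`
#'   (per-ROI mean over the other ROIs), `rel_power`.
#' @export
compute_subject_metrics <- function(rec, bands = canonical_bands(),
                                    n = 4L, tau = 1L,
                                    tau_rule = c("fixed", "band"),
                                    total_band = c(0.5, 45)) {
  stopifnot(inherits(rec, "epoched_recording"))
  tau_rule <- match.arg(tau_rule)
  d <- dim(rec$data)
  k <- d[1]; n_ep <- d[2]; len <- d[3]
  nf <- factorial(as.integer(n))
  out <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    lo <- bands$f_low[b]; hi <- bands$f_high[b]
    tau_b <- if (tau_rule == "band") tau_from_band(rec$fs, hi) else
      as.integer(tau)
    pe_ep <- matrix(NA_real_, n_ep, k)
    rp_ep <- matrix(NA_real_, n_ep, k)
    prof_ep <- matrix(NA_real_, n_ep, k)
    for (e in seq_len(n_ep)) {
      ep <- t(matrix(rec$data[, e, ], nrow = k))   # samples x channels
      rp_ep[e, ] <- relative_power(ep, rec$fs, lo, hi, total = total_band)
      filt <- bandpass(ep, rec$fs, lo, hi)
      S <- symbolize_matrix(filt, n, tau_b)
      cnts <- apply(S + 1L, 2L, tabulate, nbins = nf) / nrow(S)
      pe_ep[e, ] <- apply(cnts, 2L, shannon_entropy) / log(nf)
      M <- jpe_matrix_from_symbols(S, n)
      prof_ep[e, ] <- rowSums(M) / (k - 1)
    }
    out[[b]] <- tibble::tibble(
      band = bands$band[b], tau = tau_b, roi = rec$channel_labels,
      pe = per_subject_aggregate(pe_ep),
      jpe_inv = per_subject_aggregate(prof_ep),
      rel_power = per_subject_aggregate(rp_ep)
    )
  }
  dplyr::bind_rows(out)
}

#' Run the full analysis pipeline
#'
#' End-to-end run: obtain subjects (simulated from `config$cohort` or read
#' from `config$input_dir`), compute per-subject band-wise PE, JPE_inv and
#' relative power ([compute_subject_metrics()]), compare groups per ROI and
#' band by permutation testing with BH-FDR ([permutation_test()]), fit
#' single-feature logistic classifiers on the global (ROI-averaged)
#' classification-band features ([logistic_auc()]), and run a one-way ANCOVA
#' of global JPE_inv on group controlling for relative power
#' ([ancova_oneway()]).  When `config$output_dir` is set, all result tables
#' are written with the resolved configuration embedded as provenance.
#'
#' Simulated subjects are generated one at a time and discarded after
#' feature extraction, so memory stays flat in cohort size.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: list with `features` (tibble:
#'   subject, group, band, roi, metrics), `global_features` (tibble of
#'   ROI-averaged classification-band features per subject), `roi_tests`
#'   (tibble: band, metric, roi, stat, p, q, significant), `classification`
#'   (tibble of AUC rows per metric), `reports` (the underlying
#'   `classification_report` objects), `ancova`, `config`, `log` (stage
#'   timings and seeds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  mark <- function(stage, t0, seed = NA_integer_) {
    tibble::tibble(stage = stage,
                   seconds = as.numeric(Sys.time()) - t0,
                   seed = seed)
  }

  # --- input stage -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$cohort)) {
    subs <- cohort_subject_specs(config$cohort)
    manifest <- subs$manifest
    get_rec <- function(s) generate_subject(subs$specs[[s]])
    n_sub <- nrow(manifest)
  } else if (!is.null(config$input_dir)) {
    cohort <- read_cohort(config$input_dir)
    manifest <- cohort$manifest
    get_rec <- function(s) cohort$recordings[[manifest$subject_id[s]]]
    n_sub <- nrow(manifest)
  } else {
    stop("pipeline stage 'input': config needs either `cohort` or ",
         "`input_dir`", call. = FALSE)
  }
  log <- c(log, list(mark("input", t0, config$seed)))

  # --- per-subject features ---------------------------------------------
  t0 <- as.numeric(Sys.time())
  feats <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    rec <- get_rec(s)
    fs_tbl <- tryCatch(
      compute_subject_metrics(rec, bands = config$bands, n = config$n,
                              tau = config$tau, tau_rule = config$tau_rule),
      error = function(e) stop("pipeline stage 'features' failed for ",
                               manifest$subject_id[s], ": ",
                               conditionMessage(e), call. = FALSE)
    )
    fs_tbl$subject_id <- manifest$subject_id[s]
    fs_tbl$group <- manifest$group[s]
    feats[[s]] <- fs_tbl
    rm(rec)
  }
  features <- dplyr::bind_rows(feats)
  log <- c(log, list(mark("features", t0)))

  # --- group comparison per band and metric ------------------------------
  t0 <- as.numeric(Sys.time())
  groups <- unique(manifest$group)
  if (length(groups) != 2L) {
    stop("pipeline stage 'compare': need exactly two groups, found ",
         length(groups), call. = FALSE)
  }
  metrics <- c("pe", "jpe_inv", "rel_power")
  tests <- list()
  seed_i <- config$seed
  for (b in unique(features$band)) {
    for (m in metrics) {
      wide <- features |>
        dplyr::filter(.data$band == b) |>
        tidyr::pivot_wider(id_cols = c("subject_id", "group"),
                           names_from = "roi", values_from = dplyr::all_of(m))
      A <- as.matrix(wide[wide$group == groups[1],
                          -(1:2)])
      B <- as.matrix(wide[wide$group == groups[2], -(1:2)])
      seed_i <- seed_i + 1L
      gc_res <- permutation_test(A, B, n_perm = config$n_perm,
                                 seed = seed_i, alpha_q = config$alpha_q)
      gc_res$band <- b
      gc_res$metric <- m
      tests <- c(tests, list(tibble::as_tibble(gc_res)))
    }
  }
  roi_tests <- dplyr::bind_rows(tests) |>
    dplyr::select("band", "metric", "roi", "stat", "p", "q", "significant")
  log <- c(log, list(mark("compare", t0, config$seed + 1L)))

  # --- classification and ANCOVA on global means -------------------------
  t0 <- as.numeric(Sys.time())
  glob <- features |>
    dplyr::filter(.data$band == config$classification_band) |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metrics), mean),
                     .groups = "drop")
  reports <- lapply(metrics, function(m) {
    logistic_auc(glob, feature = !!rlang::sym(m), label = group,
                 positive = groups[2])
  })
  names(reports) <- metrics
  classification <- dplyr::bind_rows(lapply(metrics, function(m) {
    dplyr::bind_cols(tibble::tibble(metric = m, band =
                                      config$classification_band),
                     glance(reports[[m]]))
  }))
  anc <- ancova_oneway(glob, outcome = jpe_inv, group = group,
                       covariate = rel_power)
  log <- c(log, list(mark("classify", t0)))

  result <- structure(
    list(features = features, global_features = glob,
         roi_tests = roi_tests, classification = classification,
         reports = reports, ancova = anc, manifest = manifest,
         config = config, log = dplyr::bind_rows(log)),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_results(result, config$output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("ordinet pipeline result\n")
  cat("  subjects: ", nrow(x$manifest), " (",
      paste(unique(x$manifest$group), collapse = " vs "), ")\n", sep = "")
  sig <- x$roi_tests |>
    dplyr::group_by(.data$band, .data$metric) |>
    dplyr::summarise(n_sig = sum(.data$significant), .groups = "drop")
  cat("  significant ROIs (q < ", x$config$alpha_q, "):\n", sep = "")
  for (i in seq_len(nrow(sig))) {
    cat(sprintf("    %-10s %-10s %d\n", sig$band[i], sig$metric[i],
                sig$n_sig[i]))
  }
  cat("  classification (", x$config$classification_band, " band):\n",
      sep = "")
  for (i in seq_len(nrow(x$classification))) {
    cat(sprintf("    %-10s AUC = %.1f%% [%.1f-%.1f%%]\n",
                x$classification$metric[i], 100 * x$classification$auc[i],
                100 * x$classification$ci_low[i],
                100 * x$classification$ci_high[i]))
  }
  print(x$ancova)
  invisible(x)
}

provenance_header <- function(config) {
  cfg <- unclass(config)
  cfg$bands <- as.data.frame(cfg$bands)
  cfg$cohort <- if (is.null(cfg$cohort)) NULL else
    lapply(unclass(cfg$cohort), function(x)
      if (inherits(x, "subject_spec")) unclass(x) else x)
  c(paste0("# ordinet ", as.character(utils::packageVersion("ordinet"))),
    paste0("# generated: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("# ", strsplit(yaml::as.yaml(cfg), "\n")[[1]]))
}

write_table_with_provenance <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

# Write all result tables of a pipeline run, each carrying the resolved
# config as comment-line provenance.
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(result$config)
  write_table_with_provenance(result$features,
                              file.path(dir, "features.tsv"), hdr)
  write_table_with_provenance(result$roi_tests,
                              file.path(dir, "roi_tests.tsv"), hdr)
  write_table_with_provenance(result$classification,
                              file.path(dir, "classification.tsv"), hdr)
  write_table_with_provenance(result$reports$jpe_inv$roc_points,
                              file.path(dir, "roc_points.tsv"), hdr)
  write_table_with_provenance(glance(result$ancova),
                              file.path(dir, "ancova.tsv"), hdr)
  write_table_with_provenance(result$log, file.path(dir, "log.tsv"), hdr)
  summary_path <- file.path(dir, "summary.txt")
  con <- file(summary_path, "w")
  writeLines(hdr, con)
  sink(con)
  print(result)
  sink()
  close(con)
  invisible(dir)
}

#' Write a connectivity matrix as square delimited text
#'
#' @param conn A `connectivity_result`.
#' @param path Output path.
#' @export
write_connectivity <- function(conn, path) {
  stopifnot(inherits(conn, "connectivity_result"))
  df <- as.data.frame(conn$matrix)
  names(df) <- conn$labels
  data.table::fwrite(df, path, sep = "\t", col.names = TRUE)
  invisible(path)
}
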