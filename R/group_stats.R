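#' Nonparametric permutation test for group differences per ROI
#'
#' Two-sided permutation test of the group difference in means for every
#' column (ROI) of two subject x ROI matrices.  The observed statistic is the
#' absolute difference of group means; subject labels are randomly
#' repartitioned preserving group sizes, and the p-value is the proportion of
#' repartitions with a statistic at least as large as the observed one.  By
#' default the add-one Monte-Carlo correction
#' `p = (1 + #\{T_perm >= T_obs\}) / (n_perm + 1)` is used so that p > 0; the
#' literal proportion is available with `plus_one = FALSE`.  Benjamini-
#' Hochberg FDR-adjusted q-values and significance flags at `alpha_q` are
#' attached.
#'
#' @param group_a,group_b Numeric subjects x ROI matrices (or data frames)
#'   with matching columns.
#' @param n_perm Number of random repartitions (default 10,000).
#' @param seed Integer seed making the repartitions reproducible.
#' @param plus_one Use the add-one corrected Monte-Carlo p-value (default).
#' @param alpha_q Significance threshold on the q-value (default 0.05).
#' @return A tibble of class `group_comparison` with columns `roi`, `stat`
#'   (observed |mean difference|), `p`, `q`, `significant`, and attributes
#'   `n_perm` and `seed`.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 10000L, seed = 1L,
                             plus_one = TRUE, alpha_q = 0.05) {
  A <- as.matrix(group_a)
  B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) stop("groups must have the same ROIs",
                               call. = FALSE)
  na <- nrow(A); nb <- nrow(B)
  if (na < 2L || nb < 2L) stop("need at least 2 subjects per group",
                               call. = FALSE)
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  X <- rbind(A, B)
  ntot <- na + nb
  obs <- abs(colMeans(A) - colMeans(B))
  tot <- colSums(X)
  exceed <- integer(ncol(X))
  # the statistic depends only on the unordered partition, so repartitions
  # are drawn as subsets of the smaller group size, over subjects in a
  # canonical (data-derived) order; together these make the p-values exactly
  # invariant to which group is called "a".  Comparisons use a small
  # relative tolerance so partitions tying the observed statistic count as
  # exceedances despite floating-point noise.
  ns <- min(na, nb)
  X <- X[order(rowMeans(X), X[, 1L]), , drop = FALSE]
  withr::with_seed(as.integer(seed), {
    P <- matrix(0L, n_perm, ntot)
    for (r in seq_len(n_perm)) P[r, sample.int(ntot, ns)] <- 1L
    SA <- P %*% X                                   # n_perm x ROI sums
    Tperm <- abs(SA / ns - sweep(-SA, 2L, tot, `+`) / (ntot - ns))
    thresh <- obs - 1e-9 * pmax(obs, .Machine$double.eps)
    exceed <- colSums(Tperm >= matrix(thresh, n_perm, ncol(X), byrow = TRUE))
  })
  p <- if (plus_one) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  q <- fdr_bh(pmax(p, .Machine$double.xmin))
  rois <- colnames(A)
  if (is.null(rois)) rois <- sprintf("ROI_%03d", seq_len(ncol(A)))
  out <- tibble::tibble(
    roi = rois, stat = unname(obs), p = unname(p), q = unname(q),
    significant = unname(q < alpha_q)
  )
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "alpha_q") <- alpha_q
  class(out) <- c("group_comparison", class(out))
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Permutation group comparison (", attr(x, "n_perm"),
      " repartitions, seed ", attr(x, "seed"), "): ", sum(x$significant),
      "/", nrow(x), " ROIs significant at q < ", attr(x, "alpha_q"),
      "\n", sep = "")
  NextMethod()
}

#' @rdname permutation_test
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$stat,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = paste0("q < ",
                                               attr(object, "alpha_q"))) +
    ggplot2::labs(x = "ROI", y = "|group mean difference|",
                  title = "Per-ROI permutation test") +
    ggplot2::theme_minimal()
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR-adjusted q-values under the independence (1995) variant.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Single-feature logistic classification with ROC analysis
#'
#' Fits an unregularized maximum-likelihood logistic regression of a binary
#' label on one feature, computes the in-sample ROC curve over the fitted
#' probabilities, the trapezoidal AUC (midrank tie handling), and a 95%
#' DeLong confidence interval.
#'
#' @param data A data frame with one row per subject.
#' @param feature Column (tidy-eval) holding the numeric feature.
#' @param label Column (tidy-eval) holding the binary group label.
#' @param positive Level treated as the positive class; defaults to the last
#'   level (factor) or the larger value.
#' @return An object of class `classification_report`: list with `auc`,
#'   `ci_low`, `ci_high`, `roc_points` (tibble of FPR/TPR), `coefficients`,
#'   `separation` (TRUE if the fit was flagged for perfect separation), and
#'   the underlying `glm` fit.  `tidy()` returns the coefficient table,
#'   `glance()` the AUC row, `autoplot()` the ROC curve.
#' @export
logistic_auc <- function(data, feature, label, positive = NULL) {
  x <- dplyr::pull(data, {{ feature }})
  g <- dplyr::pull(data, {{ label }})
  if (any(!is.finite(x))) stop("feature must be finite", call. = FALSE)
  g <- as.factor(g)
  if (nlevels(droplevels(g)) != 2L) {
    stop("label must have exactly two classes present", call. = FALSE)
  }
  g <- droplevels(g)
  if (!is.null(positive)) {
    if (!positive %in% levels(g)) stop("`positive` is not a label level",
                                       call. = FALSE)
    g <- stats::relevel(g, ref = setdiff(levels(g), positive))
  }
  y <- as.integer(g) - 1L  # second level = positive class
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  prob <- fitted(fit)
  roc <- pROC::roc(response = y, predictor = as.numeric(prob),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong"))),
    error = function(e) c(auc, auc, auc))
  pts <- tibble::tibble(
    fpr = rev(1 - roc$specificities),
    tpr = rev(roc$sensitivities),
    threshold = rev(roc$thresholds)
  )
  structure(
    list(auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
         roc_points = pts, coefficients = coef(fit),
         separation = separation, positive = levels(g)[2L], fit = fit),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "Logistic classification (positive class: %s)\n  AUC = %.3f [%.3f-%.3f] (DeLong 95%% CI)%s\n",
    x$positive, x$auc, x$ci_low, x$ci_high,
    if (x$separation) "  [perfect separation flagged]" else ""))
  invisible(x)
}

#' @rdname logistic_auc
#' @param x A `classification_report`.
#' @param ... Unused.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @rdname logistic_auc
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 separation = x$separation)
}

#' @rdname logistic_auc
#' @param object A `classification_report`.
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr,
                                                  y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.1f%%)",
                                  100 * object$auc)) +
    ggplot2::theme_minimal()
}

#' One-way ANCOVA with a single covariate
#'
#' Tests the effect of a two-level group on an outcome after adjusting for a
#' continuous covariate, via the linear model
#' `outcome ~ covariate + group`.  The F statistic for the group term has
#' `(1, N - 3)` degrees of freedom; the partial eta-squared is
#' `SS_group / (SS_group + SS_residual)`.
#'
#' @param data A data frame, one row per subject.
#' @param outcome,group,covariate Columns (tidy-eval).
#' @return Object of class `ancova_report`: list with `F`, `df` (between,
#'   residual), `p`, `eta_sq`, and the `lm` fit.  `glance()` returns a
#'   one-row tibble.
#' @export
ancova_oneway <- function(data, outcome, group, covariate) {
  y <- dplyr::pull(data, {{ outcome }})
  g <- droplevels(as.factor(dplyr::pull(data, {{ group }})))
  z <- dplyr::pull(data, {{ covariate }})
  if (nlevels(g) != 2L) stop("`group` must have two levels", call. = FALSE)
  if (min(table(g)) < 3L) stop("need at least 3 subjects per group",
                               call. = FALSE)
  fit <- lm(y ~ z + g)
  if (any(is.na(coef(fit)))) {
    stop("covariate is collinear with group; model not estimable",
         call. = FALSE)
  }
  an <- anova(fit)
  ss_g <- an["g", "Sum Sq"]
  ss_r <- an["Residuals", "Sum Sq"]
  Fval <- an["g", "F value"]
  pval <- an["g", "Pr(>F)"]
  structure(
    list(F = Fval, df = c(between = an["g", "Df"],
                          residual = an["Residuals", "Df"]),
         p = pval, eta_sq = ss_g / (ss_g + ss_r), fit = fit),
    class = "ancova_report"
  )
}

#' @export
print.ancova_report <- function(x, ...) {
  cat(sprintf("One-way ANCOVA: F(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.2f\n",
              x$df[["between"]], x$df[["residual"]], x$F, x$p, x$eta_sq))
  invisible(x)
}

#' @rdname ancova_oneway
#' @param x An `ancova_report`.
#' @param ... Unused.
#' @method glance ancova_report
#' @export
glance.ancova_report <- function(x, ...) {
  tibble::tibble(F = x$F, df_between = x$df[["between"]],
                 df_residual = x$df[["residual"]], p = x$p,
                 eta_sq = x$eta_sq)
}
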