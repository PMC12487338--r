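#' Lin's concordance correlation coefficient
#'
#' `2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. Penalizes location and scale shifts as well as
#' loss of correlation, so |CCC| <= |Pearson r| always.
#'
#' @param est,truth Equal-length numeric vectors (matrices are flattened).
#' @return Scalar in \[-1, 1\].
#' @examples
#' lins_ccc(1:10, 1:10)        # 1
#' lins_ccc(1:10, 1:10 + 2)    # < 1: location shift penalized
#' @export
lins_ccc <- function(est, truth) {
  est <- as.numeric(est); truth <- as.numeric(truth)
  stopifnot(length(est) == length(truth), length(est) >= 2,
            all(is.finite(est)), all(is.finite(truth)))
  n <- length(est)
  mx <- mean(est); my <- mean(truth)
  vx <- mean((est - mx)^2); vy <- mean((truth - my)^2)
  if (vx == 0 && vy == 0) {
    if (mx == my) return(1)
    warning("both inputs are constant with different means; CCC = 0", call. = FALSE)
    return(0)
  }
  if (vx == 0 || vy == 0) {
    warning("one input has zero variance; CCC = 0", call. = FALSE)
    return(0)
  }
  sxy <- mean((est - mx) * (truth - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Mean absolute error
#' @inheritParams lins_ccc
#' @return Scalar >= 0; zero iff the inputs are equal.
#' @export
mae <- function(est, truth) {
  est <- as.numeric(est); truth <- as.numeric(truth)
  stopifnot(length(est) == length(truth))
  mean(abs(est - truth))
}

#' Pearson correlation
#' @inheritParams lins_ccc
#' @return Scalar in \[-1, 1\].
#' @export
pearson_r <- function(est, truth) {
  stats::cor(as.numeric(est), as.numeric(truth))
}

#' Cohort-level deconvolution accuracy report
#'
#' Computes CCC, MAE and Pearson r on the flattened (sample x cell type)
#' proportion pairs, plus a per-cell-type breakdown.
#'
#' @param est,truth n x k proportion matrices with matching layout.
#' @return A `metric_report`: list with scalars `ccc`, `mae`, `pearson_r` and
#'   a `per_cell_type` data.frame.
#' @export
proportion_metrics <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  stopifnot(all(dim(est) == dim(truth)))
  per <- data.frame(
    cell_type = if (!is.null(colnames(truth))) colnames(truth)
                else paste0("type", seq_len(ncol(truth))),
    ccc = vapply(seq_len(ncol(est)), function(c) lins_ccc(est[, c], truth[, c]), 0),
    mae = vapply(seq_len(ncol(est)), function(c) mae(est[, c], truth[, c]), 0),
    pearson_r = vapply(seq_len(ncol(est)), function(c) pearson_r(est[, c], truth[, c]), 0)
  )
  structure(list(ccc = lins_ccc(est, truth), mae = mae(est, truth),
                 pearson_r = pearson_r(est, truth), per_cell_type = per),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> CCC %.4f | MAE %.4f | r %.4f\n",
              x$ccc, x$mae, x$pearson_r))
  invisible(x)
}

#' Wilcoxon rank-sum differential test on purified profiles
#'
#' Two-sided rank-sum test per feature between two groups of purified
#' cell-type-specific profiles, exact for small combined samples (n <= 25)
#' and normal-approximated with continuity correction otherwise (midranks for
#' ties), followed by Benjamini-Hochberg adjustment across the retained
#' features. Features with zero variance across all samples are considered
#' invalid and excluded before testing.
#'
#' @param groupA,groupB samples x features matrices with matching columns.
#' @param alpha FDR threshold for calls (default 0.05).
#' @param truth Optional logical vector of true DE flags (full feature set);
#'   adds sensitivity/specificity/F1 to the report.
#' @return A `de_report`: data.frame `table` (feature, tested, raw_p, adj_p,
#'   call) plus `alpha`, `n_tested` and, with `truth`, detection metrics.
#' @export
ctsde_test <- function(groupA, groupB, alpha = 0.05, truth = NULL) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  stopifnot(ncol(groupA) == ncol(groupB))
  if (nrow(groupA) < 3 || nrow(groupB) < 3) {
    stop("at least 3 samples per group are required", call. = FALSE)
  }
  m <- ncol(groupA)
  feat <- colnames(groupA)
  if (is.null(feat)) feat <- paste0("f", seq_len(m))
  all_vals <- rbind(groupA, groupB)
  valid <- apply(all_vals, 2, function(x) stats::var(x) > 0)
  if (!any(valid)) stop("all features have zero variance; nothing to test", call. = FALSE)
  exact <- (nrow(groupA) + nrow(groupB)) <= 25
  raw_p <- rep(NA_real_, m)
  for (jj in which(valid)) {
    raw_p[jj] <- suppressWarnings(
      stats::wilcox.test(groupA[, jj], groupB[, jj], exact = exact,
                         correct = TRUE)$p.value
    )
  }
  adj_p <- rep(NA_real_, m)
  adj_p[valid] <- stats::p.adjust(raw_p[valid], method = "BH")
  calls <- !is.na(adj_p) & adj_p < alpha
  out <- structure(
    list(table = data.frame(feature = feat, tested = valid,
                            raw_p = raw_p, adj_p = adj_p, call = calls),
         alpha = alpha, n_tested = sum(valid)),
    class = "de_report"
  )
  if (!is.null(truth)) {
    stopifnot(length(truth) == m)
    dm <- de_detection_metrics(calls, truth)
    out$sensitivity <- dm[["sensitivity"]]
    out$specificity <- dm[["specificity"]]
    out$f1 <- dm[["f1"]]
    out$truth <- truth
  }
  out
}

#' @export
print.de_report <- function(x, ...) {
  cat(sprintf("<de_report> %d features tested, %d called at FDR < %g\n",
              x$n_tested, sum(x$table$call), x$alpha))
  if (!is.null(x$f1)) {
    cat(sprintf("  sensitivity %.3f | specificity %.3f | F1 %.3f\n",
                x$sensitivity, x$specificity, x$f1))
  }
  invisible(x)
}

#' Detection metrics for DE calls against ground truth
#'
#' Standard confusion-matrix definitions; F1 is 0 when nothing is called but
#' true positives exist.
#'
#' @param calls,truth Equal-length logical vectors.
#' @return Named vector `c(sensitivity, specificity, f1)`.
#' @export
de_detection_metrics <- function(calls, truth) {
  calls <- as.logical(calls); truth <- as.logical(truth)
  stopifnot(length(calls) == length(truth))
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0 && !is.na(sens)) 2 * prec * sens / (prec + sens) else 0
  c(sensitivity = sens, specificity = spec, f1 = f1)
}

#' Minimum-valid-features filter for purified profiles
#'
#' A purified result enters downstream differential analysis only if it
#' carries at least `threshold` valid (nonzero-variance) features.
#'
#' @param purified samples x features matrix of purified profiles.
#' @param threshold Minimum number of valid features (default 300).
#' @return List with `pass` (logical), `n_valid` and the logical `valid`
#'   feature mask.
#' @export
min_valid_features_filter <- function(purified, threshold = 300L) {
  stopifnot(threshold >= 1)
  purified <- as.matrix(purified)
  valid <- apply(purified, 2, function(x) stats::var(x) > 0)
  list(pass = sum(valid) >= threshold, n_valid = sum(valid), valid = valid)
}

#' Match estimated signature/proportion columns to the truth
#'
#' Deconvolution recovers cell types up to a column permutation. This finds
#' the permutation of estimated columns maximizing the summed Pearson
#' correlation with the true columns (optimal assignment; exhaustive over
#' permutations, exact for the small k used here).
#'
#' @param est,truth Matrices with the same number of columns (k <= 8).
#' @return List with `perm` (est column for each truth column), `correlations`
#'   (matched per-column r) and `mean_r`.
#' @export
match_columns <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  k <- ncol(truth)
  stopifnot(ncol(est) == k, k <= 8)
  cmat <- suppressWarnings(stats::cor(est, truth))  # est cols x truth cols
  cmat[!is.finite(cmat)] <- -1
  perms <- permutations_of(k)
  best <- NULL; best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    val <- sum(cmat[cbind(p, seq_len(k))])
    if (val > best_val) {
      best_val <- val
      best <- p
    }
  }
  list(perm = best, correlations = cmat[cbind(best, seq_len(k))],
       mean_r = best_val / k)
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    left <- sub[, seq_len(pos - 1L), drop = FALSE]
    right <- if (pos <= k - 1L) sub[, pos:(k - 1L), drop = FALSE]
             else sub[, 0, drop = FALSE]
    cbind(left, k, right)
  }))
}
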