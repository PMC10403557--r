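#' ROC AUC by the Mann-Whitney formulation
#'
#' The fraction of (positive, negative) score pairs in which the positive
#' scores higher, with ties counted 0.5 — identical to the trapezoidal area
#' under the ROC curve. Computed from ranks in O(n log n). Invariant under
#' any strictly increasing transform of the scores, and
#' `auc(scores, labels) + auc(scores, 1 - labels) = 1` exactly.
#'
#' @param scores Numeric vector of scores (higher = more positive).
#' @param labels 0/1 vector, same length; both classes must be present.
#' @return The AUC in \[0, 1\].
#' @examples
#' compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
compute_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 and scores non-missing", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC is undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores) # average ranks handle ties as 0.5 per tied pair
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' AUC with a stratified percentile bootstrap confidence interval
#'
#' Positives and negatives are resampled independently with replacement
#' (preserving the class counts, so no replicate ever loses a class) and the
#' percentile interval at the `(1 - level)/2` and `1 - (1 - level)/2`
#' quantiles of the replicate AUCs is reported. Deterministic given `seed`.
#'
#' @inheritParams compute_auc
#' @param replicates Number of bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return An object of class `auc_result` with fields `auc`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`, `replicates`, `level`, `seed`, and
#'   `ci_flag` (TRUE in the pathological tie cases where the point AUC falls
#'   outside the percentile interval).
#' @export
bootstrap_auc_ci <- function(scores, labels, replicates = 2000, level = 0.95,
                             seed = 1) {
  assert_scalar_num(replicates, "replicates", min = 1)
  assert_scalar_num(level, "level", min = 0, strict_min = TRUE)
  if (level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  auc <- compute_auc(scores, labels)
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  n_pos <- length(pos)
  n_neg <- length(neg)
  replicates <- as.integer(replicates)
  reps <- with_seed(seed, {
    vapply(seq_len(replicates), function(b) {
      sp <- pos[sample.int(n_pos, n_pos, replace = TRUE)]
      sn <- neg[sample.int(n_neg, n_neg, replace = TRUE)]
      r <- rank(c(sp, sn))
      (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  structure(
    list(auc = auc, ci_low = ci[1], ci_high = ci[2],
         n_pos = n_pos, n_neg = n_neg, replicates = replicates,
         level = level, seed = as.integer(seed),
         ci_flag = (auc < ci[1] || auc > ci[2])),
    class = "auc_result"
  )
}

#' @export
format.auc_result <- function(x, digits = 2, ...) {
  sprintf("%s [%s, %s]", fmt_num(x$auc, digits),
          fmt_num(x$ci_low, digits), fmt_num(x$ci_high, digits))
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %s  (n_pos = %d, n_neg = %d, %d bootstrap replicates, %g%% CI)\n",
              format(x), x$n_pos, x$n_neg, x$replicates, 100 * x$level))
  if (isTRUE(x$ci_flag)) {
    cat("  note: point AUC falls outside the percentile interval (heavy ties)\n")
  }
  invisible(x)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs at every distinct score threshold, for export or quick
#' plotting.
#'
#' @inheritParams compute_auc
#' @return A data.frame with columns `fpr` and `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  keep <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / n_neg), tpr = c(0, tp[keep] / n_pos))
}
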