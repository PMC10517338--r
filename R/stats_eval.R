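# Statistical evaluation layer: two-sided rank-sum testing, ROC/AUC with
# rank-based pair counting, Youden-J threshold selection, and the
# stratified benchmark report.

#' Two-sided Mann-Whitney rank-sum test
#'
#' The U statistic is computed from midranks. When the two samples are
#' tie-free and `n1 + n2` does not exceed `exact_cap`, the two-sided
#' p-value is exact: twice the smaller tail of the exact null distribution
#' of U, capped at 1. Otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param groupA,groupB Non-empty numeric vectors.
#' @param exact_cap Largest `n1 + n2` for which the exact distribution is
#'   enumerated (default 25, covering the curated group sizes).
#' @return Object of class `comparison_result`: list with `u_statistic`
#'   (U of `groupA`), `p_value`, `method` (`"exact"`/`"normal_approx"`),
#'   `n1`, `n2`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
rank_sum_test <- function(groupA, groupB, exact_cap = 25L) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  if (length(groupA) == 0L || length(groupB) == 0L)
    utr_input_error("both groups must be non-empty")
  if (anyNA(groupA) || anyNA(groupB))
    utr_input_error("NA values in rank-sum input")
  n1 <- length(groupA); n2 <- length(groupB)
  pooled <- c(groupA, groupB)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))

  if (!ties && n1 + n2 <= exact_cap) {
    lower <- pwilcox(u, n1, n2)
    upper <- 1 - pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      d <- u - mu
      cc <- sign(d) * 0.5  # continuity correction toward the mean
      z <- (d - cc) / sqrt(sigma2)
      p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    }
    method <- "normal_approx"
  }
  structure(list(u_statistic = u, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<rank-sum U=%.1f p=%.4g (%s, n=%d/%d)>\n", x$u_statistic,
              x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' ROC curve, AUC and best-separating threshold
#'
#' The AUC is the rank-based pair statistic
#' `(#{pos > neg} + 0.5 * #{pos = neg}) / (n_pos * n_neg)`. The curve is
#' evaluated on the pooled score grid with the classification rule
#' `score >= threshold => positive`; the best threshold maximises Youden's
#' J (TPR - FPR), ties resolved to the lowest threshold.
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors for the
#'   positive and negative class.
#' @return Object of class `roc_result`: `auc`, `curve` (data.frame
#'   `threshold`, `tpr`, `fpr`), `best_threshold`, `criterion`
#'   (`"youden"`).
#' @examples
#' roc_auc(c(0.9, 0.4), c(0.5, 0.1))$auc  # 0.75
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    utr_input_error("both score classes must be non-empty")
  n1 <- length(pos_scores); n2 <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)

  grid <- sort(unique(c(pos_scores, neg_scores)))
  tpr <- vapply(grid, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(grid, function(t) mean(neg_scores >= t), numeric(1))
  j <- tpr - fpr
  best <- grid[which(j == max(j))[1]]  # grid ascending: first = lowest
  structure(list(
    auc = auc,
    curve = data.frame(threshold = grid, tpr = tpr, fpr = fpr),
    best_threshold = best, criterion = "youden"
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<ROC auc=%.4f best_threshold=%.4g (%s)>\n", x$auc,
              x$best_threshold, x$criterion))
  invisible(x)
}

#' Best-separating threshold between two score sets
#'
#' @param pos,neg Non-empty numeric vectors.
#' @return The threshold on the pooled grid maximising Youden's J for the
#'   rule `score >= threshold => positive` (ties -> lowest threshold).
#' @export
threshold_separation <- function(pos, neg) {
  roc_auc(pos, neg)$best_threshold
}

#' Evaluate a benchmark dataset against effect scores
#'
#' Runs the stratified comparison: three two-sided rank-sum tests
#' (model-matched P/LP vs putative benign, matched vs mismatched P/LP,
#' and all P/LP vs benign) plus the ROC/AUC for matched vs benign, on
#' absolute or raw scores.
#'
#' @param dataset A [assign_groups()] `benchmark_dataset`.
#' @param scores data.frame (`variant_key`, `raw`, `abs`) as from
#'   [effect_score_table()], covering every dataset item.
#' @param use_abs Score scale: `TRUE` (default) uses `abs`, matching the
#'   rationale that pathogenicity is conferred through both expression
#'   increase and decrease.
#' @return Object of class `benchmark_report`: list with `comparisons`
#'   (named `comparison_result`s: `matched_vs_benign`,
#'   `matched_vs_mismatched`, `plp_vs_benign`), `roc` (matched vs benign),
#'   `group_sizes` and `use_abs`.
#' @export
evaluate_benchmark <- function(dataset, scores, use_abs = TRUE) {
  idx <- match(dataset$key, scores$variant_key)
  if (anyNA(idx))
    utr_input_error(paste0("missing score for item(s): ",
                           paste(dataset$key[is.na(idx)], collapse = ", ")))
  val <- if (use_abs) scores$abs[idx] else scores$raw[idx]
  g <- dataset$group
  matched <- val[g == "plp_matched"]
  mismatched <- val[g == "plp_mismatched"]
  benign <- val[g == "benign"]
  structure(list(
    comparisons = list(
      matched_vs_benign = rank_sum_test(matched, benign),
      matched_vs_mismatched = rank_sum_test(matched, mismatched),
      plp_vs_benign = rank_sum_test(c(matched, mismatched), benign)
    ),
    roc = roc_auc(matched, benign),
    group_sizes = c(plp_matched = length(matched),
                    plp_mismatched = length(mismatched),
                    benign = length(benign)),
    use_abs = use_abs
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark report (%s scores)\n",
              if (x$use_abs) "absolute" else "raw"))
  cat(sprintf("  groups: matched=%d mismatched=%d benign=%d\n",
              x$group_sizes[["plp_matched"]],
              x$group_sizes[["plp_mismatched"]],
              x$group_sizes[["benign"]]))
  for (nm in names(x$comparisons)) {
    cr <- x$comparisons[[nm]]
    cat(sprintf("  %-22s U=%.1f p=%.3g (%s)\n", nm, cr$u_statistic,
                cr$p_value, cr$method))
  }
  cat(sprintf("  matched-vs-benign AUC=%.3f best_threshold=%.3g\n",
              x$roc$auc, x$roc$best_threshold))
  invisible(x)
}

#' Flatten a benchmark report for TSV/JSON export
#' @param report A `benchmark_report`.
#' @return One-row data.frame of the headline numbers.
#' @export
report_summary <- function(report) {
  cmp <- report$comparisons
  data.frame(
    use_abs = report$use_abs,
    n_matched = report$group_sizes[["plp_matched"]],
    n_mismatched = report$group_sizes[["plp_mismatched"]],
    n_benign = report$group_sizes[["benign"]],
    p_matched_vs_benign = cmp$matched_vs_benign$p_value,
    p_matched_vs_mismatched = cmp$matched_vs_mismatched$p_value,
    p_plp_vs_benign = cmp$plp_vs_benign$p_value,
    auc_matched_vs_benign = report$roc$auc,
    best_threshold = report$roc$best_threshold
  )
}
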