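#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the given class
#' order.
#'
#' @param truth,predicted equal-length label vectors; every label must be
#'   one of `classes`.
#' @param classes ordered class identifiers; defaults to the union of
#'   levels/values of `truth` and `predicted`.
#' @return A `k x k` integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stopf("truth and predicted must have the same length")
  }
  if (length(truth) == 0) stopf("cannot build a confusion matrix from no instances")
  if (is.null(classes)) {
    classes <- unique(c(levels(factor(truth)), levels(factor(predicted))))
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!all(truth %in% classes) || !all(predicted %in% classes)) {
    stopf("labels outside the declared class set")
  }
  cm <- table(factor(truth, levels = classes), factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Balanced accuracy (macro-averaged recall)
#'
#' Balanced accuracy is the mean of the per-class recalls
#' `S_i = cm[i, i] / rowSums(cm)[i]` over the `k` classes that have at
#' least one true instance.  With equal class supports it coincides with
#' plain accuracy; under imbalance it weights every class equally.
#'
#' @param cm a [confusion_matrix()] (any square numeric matrix with rows =
#'   true classes works).
#' @return A list: `per_class_recall` (named, `NA` for unsupported
#'   classes), `k_effective`, and `value` in \[0, 1\].
#' @examples
#' cm <- matrix(c(8, 3, 2, 7), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' balanced_accuracy(cm)$value  # 0.75
#' @export
balanced_accuracy <- function(cm) {
  rs <- rowSums(cm)
  if (all(rs == 0)) stopf("confusion matrix has no true instances")
  recall <- ifelse(rs > 0, diag(as.matrix(cm)) / rs, NA_real_)
  names(recall) <- rownames(cm)
  eff <- which(rs > 0)
  list(per_class_recall = recall,
       k_effective = length(eff),
       value = mean(recall[eff]))
}

#' 1-nearest-neighbour HEOM baseline
#'
#' Reference classifier: the label of the training instance nearest to `x`
#' under HEOM, ties resolved toward the first instance in dataset order.
#' Used as an independent oracle for the degenerate configuration of the
#' immune classifier.
#'
#' @param train a non-empty [mixed_dataset()].
#' @param x a single instance (one-row data.frame or named list).
#' @param ranges a [heom_ranges()] from `train`; computed if missing.
#' @return The predicted class label (character).
#' @export
nn_baseline <- function(train, x, ranges = heom_ranges(train)) {
  if (n_instances(train) == 0) stopf("empty training set")
  kinds <- attribute_kinds(train)
  best_d <- Inf
  best_i <- NA_integer_
  for (i in seq_len(n_instances(train))) {
    d <- heom(x, train$x[i, , drop = FALSE], kinds, ranges)
    if (d < best_d) { best_d <- d; best_i <- i }
  }
  as.character(train$y[best_i])
}

#' Wilcoxon signed-rank comparison of two classifiers
#'
#' Paired two-sided test over per-dataset scores, with the conventions
#' standard for small classifier-benchmark collections: absolute
#' differences (zeros included) are ranked with average ranks for ties;
#' the ranks of zero differences are split evenly between the positive and
#' negative rank sums (one zero is dropped, and `n` reduced by one, when
#' their count is odd); the p-value uses the normal approximation with
#' continuity correction applied to the smaller rank sum,
#' `z = (min(R+, R-) - 0.5 - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)`,
#' `p = 2 * pnorm(z)`.  The null hypothesis of equal performance is
#' rejected when `p < alpha`.
#'
#' @param a,b equal-length (`n >= 5`) paired score vectors; differences are
#'   `a - b`.
#' @param alpha significance level (default 0.05).
#' @return A `wilcoxon_result` list: `n`, `r_plus`, `r_minus`, `p_value`,
#'   `reject_h0`.  `r_plus + r_minus = n(n+1)/2` always.
#' @examples
#' a <- c(.784, .969, 1, .965, .767, .688, .797, .731, .765, .845)
#' b <- c(.729, .953, .984, .960, .707, .531, .752, .682, .660, .760)
#' wilcoxon_signed_rank(a, b)  # R+ = 55, R- = 0, p ~ 0.0043
#' @export
wilcoxon_signed_rank <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stopf("paired samples must have equal length")
  d <- a - b
  if (length(d) < 5) stopf("need at least 5 pairs for the normal approximation")
  nz <- sum(d == 0)
  if (nz == length(d)) {
    n <- length(d)
    res <- list(n = n, r_plus = n * (n + 1) / 4, r_minus = n * (n + 1) / 4,
                p_value = 1, reject_h0 = FALSE, alpha = alpha)
    return(structure(res, class = "wilcoxon_result"))
  }
  if (nz %% 2 == 1) d <- d[-which(d == 0)[1]]  # odd zero count: drop one, n -> n-1
  n <- length(d)
  r <- rank(abs(d))
  r_plus <- sum(r[d > 0]) + sum(r[d == 0]) / 2
  r_minus <- sum(r[d < 0]) + sum(r[d == 0]) / 2
  w <- min(r_plus, r_minus)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (w - 0.5 - n * (n + 1) / 4) / sigma
  p <- min(1, 2 * stats::pnorm(z))
  structure(list(n = n, r_plus = r_plus, r_minus = r_minus,
                 p_value = p, reject_h0 = p < alpha, alpha = alpha),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: n=%d  R+=%g  R-=%g  p=%.6f  %s\n",
              x$n, x$r_plus, x$r_minus, x$p_value,
              if (x$reject_h0) "Reject H0" else "Accept H0"))
  invisible(x)
}

#' Count datasets where a focal classifier ties-or-beats all others
#'
#' A row counts as "best" for the focal column when its score is greater
#' than or equal to every other column's score (ties count as best, the
#' convention used when benchmark tables bold tied winners).
#'
#' @param table matrix or data.frame of scores, rows = datasets, columns =
#'   classifiers.
#' @param focal focal column name or index.
#' @return Integer count of rows where the focal classifier is best.
#' @export
best_count <- function(table, focal) {
  m <- as.matrix(table)
  if (nrow(m) < 1) stopf("score table needs at least one row")
  fi <- if (is.character(focal)) match(focal, colnames(m)) else as.integer(focal)
  if (is.na(fi)) stopf("focal column not found")
  sum(apply(m, 1, function(row) row[fi] >= max(row)))
}

#' Pairwise Wilcoxon comparison report
#'
#' Compares a focal classifier against every other column of a score table
#' (rows = datasets), producing one Wilcoxon signed-rank row per
#' competitor: `R+`, `R-`, p-value and decision at `alpha`.
#'
#' @param scores matrix or data.frame of scores.
#' @param focal focal column name.
#' @param alpha significance level.
#' @return A data.frame with columns `versus`, `r_plus`, `r_minus`,
#'   `p_value`, `decision`.
#' @export
comparison_report <- function(scores, focal, alpha = 0.05) {
  m <- as.matrix(scores)
  if (!(focal %in% colnames(m))) stopf("focal column '%s' not found", focal)
  others <- setdiff(colnames(m), focal)
  rows <- lapply(others, function(col) {
    w <- wilcoxon_signed_rank(m[, focal], m[, col], alpha = alpha)
    data.frame(versus = col, r_plus = w$r_plus, r_minus = w$r_minus,
               p_value = w$p_value,
               decision = if (w$reject_h0) "Reject H0" else "Accept H0",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render a comparison report as an aligned text table
#'
#' @param report a data.frame from [comparison_report()].
#' @return A character vector of lines.
#' @export
format_comparison <- function(report) {
  hdr <- sprintf("%-14s %6s %6s %10s  %s", "versus", "R+", "R-", "p-value", "decision")
  body <- sprintf("%-14s %6g %6g %10.6f  %s", report$versus, report$r_plus,
                  report$r_minus, report$p_value, report$decision)
  c(hdr, body)
}
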