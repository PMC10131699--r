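# Metrics: precision/recall/F1, grade MAE, multilabel scores, fold
# dispersion, and closed-form expected metrics for the trivial baselines.

#' Per-class and macro precision, recall, F1
#'
#' Standard one-vs-rest precision/recall/F1 per class, macroaveraged with
#' equal weight. A class with zero predicted and zero true positives scores
#' 0 on all three (the zero-division convention, matching how never-predicted
#' rare criteria are reported).
#'
#' @param truth,pred Aligned vectors of class labels.
#' @param classes Class universe (defaults to the union of observed values,
#'   sorted). Classes absent from both vectors still get a row.
#' @return A tibble (`class`, `precision`, `recall`, `f1`, `support`) with
#'   attributes `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
prf <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  rows <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    tibble::tibble(class = as.character(cl), precision = p, recall = r,
                   f1 = f, support = tp + fn)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "macro_precision") <- mean(out$precision)
  attr(out, "macro_recall") <- mean(out$recall)
  attr(out, "macro_f1") <- mean(out$f1)
  out
}

macro_f1 <- function(truth, pred, classes = NULL) {
  attr(prf(truth, pred, classes), "macro_f1")
}

positive_f1 <- function(truth, pred) {
  tab <- prf(truth, pred, classes = c(0L, 1L))
  tab$f1[tab$class == "1"]
}

#' Mean absolute error on the grade scale
#'
#' @param pred,truth Integer grades (0--3).
#' @return Scalar MAE in \[0, 3\].
#' @export
mae_grade <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  mean(abs(as.numeric(pred) - as.numeric(truth)))
}

#' Multilabel scores over the five criteria
#'
#' Exact-match accuracy (a row counts only if all five criteria are
#' predicted correctly), micro-F1 from the pooled contingency counts, and
#' macro-F1 (unweighted mean of the per-criterion positive-class F1s).
#'
#' @param pred,truth 0/1 matrices or data frames, columns = [criteria()].
#' @return A one-row tibble (`exact_match`, `micro_f1`, `macro_f1`).
#' @export
multilabel_scores <- function(pred, truth) {
  pred <- as.matrix(pred)[, criteria(), drop = FALSE]
  truth <- as.matrix(truth)[, criteria(), drop = FALSE]
  stopifnot(nrow(pred) == nrow(truth))
  exact <- mean(rowSums(pred == truth) == ncol(truth))
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  micro <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  per <- vapply(criteria(), function(cr) {
    positive_f1(truth[, cr], pred[, cr])
  }, numeric(1))
  tibble::tibble(exact_match = exact, micro_f1 = micro,
                 macro_f1 = mean(per))
}

#' Median absolute deviation across folds
#'
#' The dispersion measure reported alongside cross-validated scores:
#' `median(|s_i - median(s)|)`, unscaled (no consistency constant).
#'
#' @param scores Numeric vector of per-fold scores.
#' @return Scalar MAD.
#' @export
mad_across_folds <- function(scores) {
  stats::median(abs(scores - stats::median(scores)))
}

#' Closed-form expected metrics of the trivial baselines
#'
#' For a label distribution, computes the exact expected per-class precision,
#' recall and F1 (and MAE on the 4-tier grade task) of the trivial
#' predictors, for use as analytic oracles:
#' * `majority` predicts one fixed class `m`: `F1_m = 2 p_m / (1 + p_m)`,
#'   0 elsewhere; `MAE = sum_c p_c |c - m|`.
#' * `random_uniform` predicts each of the `L` classes with probability
#'   `1/L`, independently of the truth: `F1_c = 2 p_c (1/L) / (p_c + 1/L)`.
#' * `random_empirical` predicts class `c` with probability `p_c`:
#'   `F1_c = p_c`.
#'
#' @param dist Named probability vector over the classes (sums to 1). For the
#'   4-tier grade task use names `grade_levels()`; for a binary criterion
#'   task use `c(negative = 1 - p, positive = p)`.
#' @param baseline `"majority"`, `"random_uniform"` or `"random_empirical"`.
#' @param task `"grade4"`, `"grade2"` or `"criterion"` (controls the MAE
#'   computation and default class ordering).
#' @param predicted_class For `majority`: the class predicted (default the
#'   mode of `dist`; ties resolve to the earlier class).
#' @return A tibble (`class`, `precision`, `recall`, `f1`) with attributes
#'   `macro_precision`, `macro_recall`, `macro_f1`, and `mae` for
#'   `task = "grade4"`.
#' @export
expected_baseline_metrics <- function(dist,
                                      baseline = c("majority",
                                                   "random_uniform",
                                                   "random_empirical"),
                                      task = c("grade4", "grade2",
                                               "criterion"),
                                      predicted_class = NULL) {
  baseline <- match.arg(baseline)
  task <- match.arg(task)
  if (is.null(names(dist)) || any(dist < 0) || abs(sum(dist) - 1) > 1e-9) {
    stop("dist must be a named probability vector summing to 1",
         call. = FALSE)
  }
  p <- unname(dist)
  L <- length(p)
  cls <- names(dist)
  if (baseline == "majority") {
    m <- if (!is.null(predicted_class)) match(predicted_class, cls) else
      which.max(p)
    if (is.na(m)) stop("predicted_class not in dist", call. = FALSE)
    precision <- ifelse(seq_len(L) == m, p[m], 0)
    recall <- as.numeric(seq_len(L) == m)
    q <- as.numeric(seq_len(L) == m)
  } else if (baseline == "random_uniform") {
    q <- rep(1 / L, L)
    precision <- p
    recall <- q
  } else {
    q <- p
    precision <- p
    recall <- p
  }
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  out <- tibble::tibble(class = cls, precision = precision, recall = recall,
                        f1 = f1)
  attr(out, "macro_precision") <- mean(precision)
  attr(out, "macro_recall") <- mean(recall)
  attr(out, "macro_f1") <- mean(f1)
  if (task == "grade4") {
    vals <- grade_value(cls)
    attr(out, "mae") <- sum(vapply(seq_len(L), function(ci) {
      sum(p[ci] * q * abs(vals - vals[ci]))
    }, numeric(1)))
  }
  out
}
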