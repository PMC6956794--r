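## Evaluation: pair-level splitting, training downsampling, class-prior
## adjusted precision-recall analysis, cross-validation over alpha, and
## bootstrap model comparison.

#' Split entity pairs into train and test sets
#'
#' The split is performed at the pair level so that all co-mentions of a
#' pair land entirely on one side, keeping training and test data
#' independent. Deterministic given `seed`.
#'
#' @param pairs character vector of unique pair keys (see [pair_key()]).
#' @param test_fraction fraction of pairs reserved for the test side,
#'   strictly between 0 and 1 (default 0.2).
#' @param seed integer seed.
#' @return list with character components `train` and `test`, a disjoint
#'   exhaustive partition of `pairs`.
#' @export
split_pairs <- function(pairs, test_fraction = 0.2, seed = 1L) {
  stopifnot(length(pairs) >= 2, !anyDuplicated(pairs))
  if (!is.numeric(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  n <- length(pairs)
  n_test <- min(n - 1L, max(1L, round(test_fraction * n)))
  test_idx <- withr::with_seed(as.integer(seed), sample.int(n, n_test))
  list(train = pairs[-test_idx], test = pairs[test_idx])
}

#' Cap the number of training co-mentions per pair
#'
#' Pairs with at most `max_per_pair` co-mentions are kept intact; larger
#' pairs are uniformly subsampled without replacement to exactly
#' `max_per_pair`, so very frequently co-mentioned pairs cannot dominate
#' classifier training. Apply to the training side only; test data is
#' never downsampled. Deterministic given `seed`; input row order is
#' preserved.
#'
#' @param comentions training co-mention data frame.
#' @param max_per_pair maximal retained co-mentions per pair (default
#'   100).
#' @param seed integer seed.
#' @return subset of `comentions`.
#' @export
downsample_train <- function(comentions, max_per_pair = 100L, seed = 1L) {
  max_per_pair <- as.integer(max_per_pair)
  if (is.na(max_per_pair) || max_per_pair < 1) {
    stop("max_per_pair must be at least 1")
  }
  key <- comention_pair_keys(comentions)
  keep <- withr::with_seed(as.integer(seed), {
    k <- rep(TRUE, nrow(comentions))
    for (rows in split(seq_len(nrow(comentions)), key)) {
      if (length(rows) > max_per_pair) {
        k[rows] <- FALSE
        k[sample(rows, max_per_pair)] <- TRUE
      }
    }
    k
  })
  out <- comentions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Class-prior-adjusted precision
#'
#' Rescales precision to a fixed target positive fraction `a` given the
#' observed positive fraction `b`:
#' \deqn{\mathrm{precision}_{adj} = \frac{(a/b)\,TP}
#'   {(a/b)\,TP + \frac{1-a}{1-b}\,FP}.}
#' With `a = b` the factors cancel and ordinary precision is recovered;
#' with `FP = 0` the value is 1 regardless of the priors. Adjustment
#' makes precision-recall areas comparable between datasets with
#' different class balance.
#'
#' @param tp,fp true/false positive counts (vectorized; `tp + fp > 0`).
#' @param a target positive fraction, strictly in (0, 1).
#' @param b observed positive fraction, strictly in (0, 1).
#' @return numeric vector of adjusted precisions.
#' @export
adjusted_precision <- function(tp, fp, a, b) {
  if (!is.numeric(a) || length(a) != 1 || a <= 0 || a >= 1) {
    stop("a must lie strictly in (0, 1)")
  }
  if (!is.numeric(b) || length(b) != 1 || b <= 0 || b >= 1) {
    stop("b must lie strictly in (0, 1)")
  }
  if (any(tp + fp <= 0)) stop("tp + fp must be positive")
  num <- (a / b) * tp
  num / (num + ((1 - a) / (1 - b)) * fp)
}

#' Precision-recall curve over pair scores
#'
#' Pairs are sorted by decreasing score; each distinct score value forms
#' one threshold (tied scores are grouped at a single curve point, so no
#' within-tie ordering luck enters the curve). At each threshold the
#' counts `TP`, `FP`, `FN`, precision, recall and [adjusted_precision()]
#' (to target prior `a`, with `b` the observed positive fraction) are
#' reported.
#'
#' @param scores numeric vector of pair scores.
#' @param labels logical (or 0/1) vector; `TRUE` for gold-positive pairs.
#'   Both classes must be present.
#' @param a target positive fraction for the adjustment (default 0.1).
#' @return data frame of class `pr_curve` with columns `threshold`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `adjusted_precision`, and
#'   attributes `P`, `N`, `a`, `b`.
#' @export
pr_curve <- function(scores, labels, a = 0.1) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)),
            !any(is.na(labels)))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) {
    stop("pr_curve requires at least one positive and one negative pair")
  }
  b <- P / (P + N)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  n <- length(s)
  last_of_group <- c(s[-n] != s[-1], TRUE)
  tp <- cumsum(l)[last_of_group]
  fp <- cumsum(!l)[last_of_group]
  curve <- data.frame(threshold = s[last_of_group], tp = tp, fp = fp,
                      fn = P - tp, precision = tp / (tp + fp),
                      recall = tp / P,
                      adjusted_precision = adjusted_precision(tp, fp, a, b))
  structure(curve, class = c("pr_curve", "data.frame"),
            P = P, N = N, a = a, b = b)
}

#' Area under the (adjusted) precision-recall curve
#'
#' Integrates the step curve by average-precision summation: the sum
#' over thresholds of (recall increment) times (precision at that
#' threshold). Rectangular summation is used rather than trapezoidal
#' interpolation, since linear interpolation in PR space is known to be
#' optimistic. A perfect ranking yields 1; a random ranking yields the
#' positive fraction (the target prior `a` after adjustment).
#'
#' @param curve a [pr_curve()].
#' @param adjusted use the class-prior-adjusted precision column
#'   (default `TRUE`).
#' @return scalar area in \[0, 1\].
#' @export
auprc <- function(curve, adjusted = TRUE) {
  stopifnot(inherits(curve, "pr_curve"))
  prec <- if (adjusted) curve$adjusted_precision else curve$precision
  sum(diff(c(0, curve$recall)) * prec)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive pair
#' outscores a random negative pair, counting ties as one half.
#'
#' @inheritParams pr_curve
#' @return scalar AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) {
    stop("auroc requires at least one positive and one negative pair")
  }
  r <- rank(scores)
  (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
}

#' Evaluate a set of scored pairs
#'
#' Convenience wrapper computing unadjusted and adjusted AUPRC plus
#' AUROC for one scorer.
#'
#' @inheritParams pr_curve
#' @return list with `auprc`, `adjusted_auprc`, `auroc`, `n_pairs`,
#'   `n_positives`.
#' @export
evaluate_scores <- function(scores, labels, a = 0.1) {
  curve <- pr_curve(scores, labels, a = a)
  list(auprc = auprc(curve, adjusted = FALSE),
       adjusted_auprc = auprc(curve, adjusted = TRUE),
       auroc = auroc(scores, labels),
       n_pairs = length(scores), n_positives = sum(as.logical(labels)))
}

# Aggregate scored co-mentions, combine at alpha, and return adjusted
# AUPRC against gold pair labels; NA when fewer than two classes survive.
alpha_performance <- function(scored, gold, alpha_grid, a) {
  tab <- co_occurrence_counts(document_scores(scored))
  vapply(alpha_grid, function(alpha) {
    st <- combine(tab, alpha)
    lab <- label_pairs(st$pairs, gold)
    keep <- lab %in% c("positive", "negative")
    y <- lab[keep] == "positive"
    if (sum(y) == 0 || sum(!y) == 0) return(NA_real_)
    auprc(pr_curve(st$pairs$score[keep], y, a = a))
  }, 0.0)
}

#' Cross-validate the aggregation exponent alpha
#'
#' Pairs of the training set are partitioned into `folds` folds. For
#' each fold, the sentence classifier is trained on the remaining folds'
#' co-mentions (no leakage), the held-out fold is scored, aggregated and
#' combined at every alpha on the grid, and adjusted AUPRC against the
#' gold labels is recorded. The alpha with the best mean performance
#' across folds is returned, ties broken toward the smaller alpha. With
#' `model = "baseline"` all sentence scores are constant 1 and no
#' classifier is trained.
#'
#' @param comentions labeled training co-mentions.
#' @param gold a [gold_standard()] object.
#' @param folds number of folds (default 3).
#' @param alpha_grid alphas to evaluate (default 0 to 1 in steps of
#'   0.05).
#' @param seed integer seed for fold assignment and classifier training.
#' @param hp [hyperparams()] for the per-fold classifiers.
#' @param model `"context"` (classifier sentence scores) or `"baseline"`
#'   (constant scores).
#' @param a target positive fraction for adjustment.
#' @return list with `best_alpha`, `results` (data frame of `alpha` and
#'   `mean_adjusted_auprc`) and `fold_matrix` (folds x alphas).
#' @export
cv_alpha <- function(comentions, gold, folds = 3L,
                     alpha_grid = seq(0, 1, by = 0.05), seed = 1L,
                     hp = hyperparams(), model = c("context", "baseline"),
                     a = 0.1) {
  model <- match.arg(model)
  folds <- as.integer(folds)
  stopifnot(length(alpha_grid) >= 1, folds >= 2)
  alpha_grid <- sort(alpha_grid)
  keys <- unique(comention_pair_keys(comentions))
  if (length(keys) < folds) stop("too few pairs for the requested folds")
  assignment <- withr::with_seed(as.integer(seed), {
    sample(rep_len(seq_len(folds), length(keys)))
  })
  fold_of <- stats::setNames(assignment, keys)
  row_fold <- fold_of[comention_pair_keys(comentions)]
  perf <- matrix(NA_real_, nrow = folds, ncol = length(alpha_grid))
  for (f in seq_len(folds)) {
    va <- comentions[row_fold == f, , drop = FALSE]
    if (model == "context") {
      tr <- comentions[row_fold != f, , drop = FALSE]
      hp_f <- hp
      hp_f$seed <- as.integer(seed) + f
      clf <- train_sentence_classifier(tr, hp_f)
      va <- score_sentences(clf, va)
    } else {
      va$sentence_score <- rep(1.0, nrow(va))
    }
    perf[f, ] <- alpha_performance(va, gold, alpha_grid, a)
  }
  mean_perf <- colMeans(perf, na.rm = TRUE)
  best <- alpha_grid[which.max(mean_perf)]
  list(best_alpha = best,
       results = data.frame(alpha = alpha_grid,
                            mean_adjusted_auprc = mean_perf),
       fold_matrix = perf)
}

#' Bootstrap comparison of two scorers on the same test pairs
#'
#' Resamples the test pairs with replacement `n_boot` times; for each
#' replicate the adjusted AUPRC of both scorers is computed on the
#' resampled pair set. Reports the standard deviation of each scorer's
#' replicate distribution, the mean difference, and a paired t-test
#' p-value on the per-replicate differences. Replicates that happen to
#' contain a single class are redrawn (at most `max_redraw` attempts per
#' replicate).
#'
#' @param scores_a,scores_b numeric score vectors of the two models over
#'   the same pairs.
#' @param labels logical vector of gold labels for those pairs.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param a target positive fraction for adjustment.
#' @param max_redraw cap on redraws of degenerate replicates.
#' @return list with `sd_a`, `sd_b`, `mean_diff` (A minus B), `p_value`,
#'   `n_boot`.
#' @export
bootstrap_compare <- function(scores_a, scores_b, labels, n_boot = 1000L,
                              seed = 1L, a = 0.1, max_redraw = 100L) {
  labels <- as.logical(labels)
  n <- length(labels)
  stopifnot(length(scores_a) == n, length(scores_b) == n, n_boot >= 2)
  boot <- withr::with_seed(as.integer(seed), {
    aup_a <- aup_b <- numeric(n_boot)
    for (r in seq_len(n_boot)) {
      attempts <- 0L
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(labels[idx]) && any(!labels[idx])) break
        attempts <- attempts + 1L
        if (attempts > max_redraw) {
          stop("could not draw a two-class bootstrap replicate")
        }
      }
      aup_a[r] <- auprc(pr_curve(scores_a[idx], labels[idx], a = a))
      aup_b[r] <- auprc(pr_curve(scores_b[idx], labels[idx], a = a))
    }
    list(a = aup_a, b = aup_b)
  })
  d <- boot$a - boot$b
  p_value <- if (sd(d) == 0) {
    if (mean(d) == 0) 1.0 else 0.0
  } else {
    t.test(d)$p.value
  }
  list(sd_a = sd(boot$a), sd_b = sd(boot$b), mean_diff = mean(d),
       p_value = p_value, n_boot = as.integer(n_boot))
}
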