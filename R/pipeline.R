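## End-to-end pipeline: label -> pair split -> downsample -> train ->
## score -> aggregate -> combine -> evaluate, for both the context-aware
## model and the constant-score baseline.

#' Run the full co-occurrence scoring pipeline
#'
#' Labels the co-mentions against the gold standard, splits pairs into
#' train/test, caps training co-mentions per pair, trains the sentence
#' classifier on the training side, scores the test co-mentions,
#' aggregates them into context-aware pair scores at `alpha` and into
#' baseline (constant sentence score) pair scores at `baseline_alpha`,
#' and evaluates both with class-prior-adjusted precision-recall
#' analysis on the test pairs. Evaluation covers test pairs that are
#' co-mentioned at least once and label as positive or negative;
#' grey-listed and unknown-entity pairs are excluded, as are gold pairs
#' never co-mentioned. Marginals are computed within the evaluated set.
#' All randomness derives from `seed`.
#'
#' @param comentions co-mention data frame.
#' @param gold a [gold_standard()] object.
#' @param hp [hyperparams()] for the sentence classifier; its seed is
#'   overridden from `seed`.
#' @param alpha aggregation exponent of the context-aware model
#'   (default 0.65).
#' @param baseline_alpha aggregation exponent of the baseline (default
#'   0.55).
#' @param test_fraction fraction of pairs reserved for testing.
#' @param max_per_pair training co-mention cap per pair.
#' @param a target positive fraction for the precision adjustment.
#' @param seed integer master seed.
#' @param pretrained optional [embedding_table()] of pretrained vectors.
#' @return list of class `comention_run` with components `classifier`,
#'   `context_scores` and `baseline_scores` (combined `score_table`s
#'   over the test pairs), `context_eval` and `baseline_eval` (see
#'   [evaluate_scores()]), `test_pair_scores` (data frame with both
#'   models' scores and the pair label), `label_summary`, `split`, and
#'   the settings used.
#' @export
run_pipeline <- function(comentions, gold, hp = hyperparams(),
                         alpha = 0.65, baseline_alpha = 0.55,
                         test_fraction = 0.2, max_per_pair = 100L,
                         a = 0.1, seed = 1L, pretrained = NULL) {
  seed <- as.integer(seed)
  lab <- label_comentions(comentions, gold)
  com <- lab$comentions
  keys <- unique(comention_pair_keys(com))
  sp <- split_pairs(keys, test_fraction, seed = seed)
  row_key <- comention_pair_keys(com)
  train_com <- com[row_key %in% sp$train, , drop = FALSE]
  test_com <- com[row_key %in% sp$test, , drop = FALSE]
  train_com <- downsample_train(train_com, max_per_pair, seed = seed + 1L)
  hp$seed <- seed + 2L
  clf <- train_sentence_classifier(train_com, hp, pretrained = pretrained)
  test_scored <- score_sentences(clf, test_com)
  ctx <- combine(co_occurrence_counts(document_scores(test_scored)), alpha)
  base <- combine(baseline_counts(test_com), baseline_alpha)
  # both tables cover exactly the co-mentioned test pairs
  ctx_key <- pair_key(ctx$pairs$ns1, ctx$pairs$id1, ctx$pairs$ns2,
                      ctx$pairs$id2)
  base_key <- pair_key(base$pairs$ns1, base$pairs$id1, base$pairs$ns2,
                       base$pairs$id2)
  m <- match(ctx_key, base_key)
  pair_lab <- label_pairs(ctx$pairs, gold)
  scores <- data.frame(ns1 = ctx$pairs$ns1, id1 = ctx$pairs$id1,
                       ns2 = ctx$pairs$ns2, id2 = ctx$pairs$id2,
                       context_score = ctx$pairs$score,
                       baseline_score = base$pairs$score[m],
                       label = pair_lab, stringsAsFactors = FALSE)
  keep <- scores$label %in% c("positive", "negative")
  y <- scores$label[keep] == "positive"
  ctx_eval <- evaluate_scores(scores$context_score[keep], y, a = a)
  base_eval <- evaluate_scores(scores$baseline_score[keep], y, a = a)
  structure(list(classifier = clf, context_scores = ctx,
                 baseline_scores = base, context_eval = ctx_eval,
                 baseline_eval = base_eval, test_pair_scores = scores,
                 label_summary = lab$summary, split = sp,
                 settings = list(alpha = alpha,
                                 baseline_alpha = baseline_alpha,
                                 test_fraction = test_fraction,
                                 max_per_pair = as.integer(max_per_pair),
                                 a = a, seed = seed,
                                 hyperparams = unclass(hp))),
            class = "comention_run")
}

#' @export
print.comention_run <- function(x, ...) {
  cat("comention_run\n")
  cat(sprintf("  test pairs evaluated: %d (%d positive)\n",
              x$context_eval$n_pairs, x$context_eval$n_positives))
  cat(sprintf("  context model  (alpha = %.2f): adjusted AUPRC %.4f, AUROC %.4f\n",
              x$settings$alpha, x$context_eval$adjusted_auprc,
              x$context_eval$auroc))
  cat(sprintf("  baseline model (alpha = %.2f): adjusted AUPRC %.4f, AUROC %.4f\n",
              x$settings$baseline_alpha, x$baseline_eval$adjusted_auprc,
              x$baseline_eval$auroc))
  invisible(x)
}
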