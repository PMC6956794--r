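## Corpus-level aggregation: per-document maxima of sentence scores are
## summed into soft co-occurrence counts C(i,j), then combined with the
## observed-over-expected ratio into the final pair score
##   S(i,j) = C(i,j)^alpha * (C(i,j) C(.,.) / (C(i,.) C(.,j)))^(1-alpha).

#' Per-document pair scores
#'
#' For every (document, pair) combination present in the input, the
#' document score `s_k` is the maximum sentence score the pair attains in
#' that document. Pairs not co-mentioned in a document contribute no
#' record (equivalently, zero).
#'
#' @param comentions co-mention data frame with `sentence_score` set on
#'   every row.
#' @return data frame with columns `document_id`, `ns1`, `id1`, `ns2`,
#'   `id2`, `score`.
#' @export
document_scores <- function(comentions) {
  if (any(is.na(comentions$sentence_score))) {
    i <- which(is.na(comentions$sentence_score))[1]
    stop(sprintf(
      "missing sentence_score for document %s, sentence %d, pair %s",
      comentions$document_id[i], comentions$sentence_index[i],
      comention_pair_keys(comentions)[i]))
  }
  if (nrow(comentions) == 0) {
    return(data.frame(document_id = character(), ns1 = character(),
                      id1 = character(), ns2 = character(),
                      id2 = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(comentions$document_id, comention_pair_keys(comentions),
               sep = "\t")
  first <- !duplicated(key)
  mx <- vapply(split(comentions$sentence_score, key), max, 0.0)
  out <- comentions[first, c("document_id", "ns1", "id1", "ns2", "id2"),
                    drop = FALSE]
  out$score <- unname(mx[key[first]])
  rownames(out) <- NULL
  out
}

score_table_from_counts <- function(pairs) {
  if (nrow(pairs) > 0) {
    e1 <- entity_key(pairs$ns1, pairs$id1)
    e2 <- entity_key(pairs$ns2, pairs$id2)
    marginals <- vapply(split(c(pairs$count, pairs$count), c(e1, e2)),
                        sum, 0.0)
  } else {
    marginals <- numeric(0)
  }
  pairs$score <- rep(NA_real_, nrow(pairs))
  structure(list(pairs = pairs, marginals = marginals,
                 total = sum(pairs$count), alpha = NA_real_),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d pair(s), total count %.4g, alpha %s\n",
              nrow(x$pairs), x$total,
              if (is.na(x$alpha)) "unset" else format(x$alpha)))
  invisible(x)
}

#' Soft co-occurrence counts from document scores
#'
#' Sums each pair's per-document maxima into the corpus-wide count
#' `C(i,j)`, and computes the per-entity marginals `C(i,.)` (sum of
#' counts of all pairs involving entity `i`) and the grand total
#' `C(.,.)`. Marginals are computed over all pairs present in the input,
#' so the sum of all entity marginals is exactly twice the grand total.
#'
#' @param doc_scores data frame from [document_scores()].
#' @return an object of class `score_table` with components `pairs`
#'   (columns `ns1`, `id1`, `ns2`, `id2`, `count`, `score` = `NA` until
#'   [combine()] is applied), `marginals` (named by entity key), `total`
#'   and `alpha`.
#' @export
co_occurrence_counts <- function(doc_scores) {
  if (nrow(doc_scores) == 0) {
    return(score_table_from_counts(
      data.frame(ns1 = character(), id1 = character(), ns2 = character(),
                 id2 = character(), count = numeric(),
                 stringsAsFactors = FALSE)))
  }
  key <- pair_key(doc_scores$ns1, doc_scores$id1, doc_scores$ns2,
                  doc_scores$id2)
  first <- !duplicated(key)
  cnt <- vapply(split(doc_scores$score, key), sum, 0.0)
  pairs <- doc_scores[first, c("ns1", "id1", "ns2", "id2"), drop = FALSE]
  pairs$count <- unname(cnt[key[first]])
  rownames(pairs) <- NULL
  score_table_from_counts(pairs)
}

#' Context-blind baseline counts
#'
#' The baseline scores every co-mention equally: each document
#' co-mentioning a pair contributes exactly 1, so the baseline count is
#' the number of distinct documents co-mentioning the pair. This equals
#' [co_occurrence_counts()] applied with every sentence score set to 1,
#' and reproduces the classical counting co-occurrence schemes used by
#' literature-mining association databases.
#'
#' @param comentions co-mention data frame (sentence scores and labels
#'   are ignored).
#' @return a `score_table` of counts.
#' @export
baseline_counts <- function(comentions) {
  com <- comentions
  com$sentence_score <- rep(1.0, nrow(com))
  co_occurrence_counts(document_scores(com))
}

#' Combine counts and enrichment into final pair scores
#'
#' Fills the score column of a `score_table` with
#' \deqn{S(i,j) = C(i,j)^{\alpha} \left(\frac{C(i,j)\,C(\cdot,\cdot)}
#'   {C(i,\cdot)\,C(\cdot,j)}\right)^{1-\alpha},}
#' where `alpha` in \[0, 1\] trades off the raw count against the
#' observed-over-expected ratio. `alpha = 1` reduces to the plain count;
#' `alpha = 0` keeps only the enrichment ratio. Pairs with zero count are
#' omitted. Pairs are returned ordered by decreasing score, ties broken
#' by canonical pair key, so written outputs are diffable.
#'
#' @param table a `score_table` from [co_occurrence_counts()] or
#'   [baseline_counts()].
#' @param alpha weighting exponent in \[0, 1\]. The recommended defaults
#'   are 0.65 for context-aware scores and 0.55 for the baseline, the
#'   cross-validated optima on large literature corpora (see
#'   [cv_alpha()] to tune on your own data).
#' @return the `score_table` with `score` filled and `alpha` recorded.
#' @export
combine <- function(table, alpha = 0.65) {
  stopifnot(inherits(table, "score_table"))
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single number in [0, 1]")
  }
  pairs <- table$pairs[table$pairs$count > 0, , drop = FALSE]
  if (nrow(pairs) > 0) {
    ci <- unname(table$marginals[entity_key(pairs$ns1, pairs$id1)])
    cj <- unname(table$marginals[entity_key(pairs$ns2, pairs$id2)])
    ratio <- pairs$count * table$total / (ci * cj)
    pairs$score <- pairs$count^alpha * ratio^(1 - alpha)
    o <- order(-pairs$score,
               pair_key(pairs$ns1, pairs$id1, pairs$ns2, pairs$id2))
    pairs <- pairs[o, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, marginals = table$marginals,
                 total = table$total, alpha = alpha),
            class = "score_table")
}

#' Filter co-mentions by sentence score
#'
#' Optional variant mode: retains co-mentions whose sentence score is at
#' least `threshold`; downstream aggregation (context-aware or baseline)
#' can then be re-run on the survivors.
#'
#' @param comentions scored co-mention data frame.
#' @param threshold numeric in \[0, 1\].
#' @return the surviving subset of `comentions`.
#' @export
apply_score_filter <- function(comentions, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  if (any(is.na(comentions$sentence_score))) {
    stop("all co-mentions must carry a sentence_score")
  }
  out <- comentions[comentions$sentence_score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a combined score table to TSV
#'
#' Columns `ns1`, `id1`, `ns2`, `id2`, `count`, `score`, ordered by
#' decreasing score then canonical pair key.
#'
#' @param table a combined `score_table`.
#' @param path file path.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  p <- table$pairs
  rows <- if (nrow(p) == 0) character(0) else {
    paste(p$ns1, p$id1, p$ns2, p$id2,
          sprintf("%.17g", p$count), sprintf("%.17g", p$score), sep = "\t")
  }
  writeLines(c("ns1\tid1\tns2\tid2\tcount\tscore", rows), path,
             useBytes = TRUE)
  invisible(path)
}
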