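## Sentence-level classifier: averaged unigram + hashed-bigram embeddings
## feeding a logistic output, trained by SGD on distantly supervised labels.

#' Hyperparameters for the sentence classifier
#'
#' Defaults follow the reference configuration for full-scale corpora:
#' 300-dimensional embeddings, 50 epochs of SGD with initial learning
#' rate 0.005 (linearly decayed to zero), unigram plus hashed-bigram
#' features with a 2,000,000-bucket hash space. Tests and small corpora
#' typically use a smaller `dim` and `n_buckets`.
#'
#' @param dim embedding dimensionality (positive integer).
#' @param epochs number of SGD passes over the training sentences.
#' @param learning_rate initial SGD learning rate; decays linearly.
#' @param use_bigrams include hashed bigram features to partially capture
#'   local word order.
#' @param n_buckets size of the bigram hash space (FNV-1a 64-bit modulo
#'   `n_buckets`).
#' @param seed integer seed controlling initialisation and epoch
#'   shuffling; training is bit-reproducible given the seed.
#' @return a validated list of class `comention_hyperparams`.
#' @export
hyperparams <- function(dim = 300L, epochs = 50L, learning_rate = 0.005,
                        use_bigrams = TRUE, n_buckets = 2000000L,
                        seed = 1L) {
  dim <- as.integer(dim); epochs <- as.integer(epochs)
  n_buckets <- as.integer(n_buckets); seed <- as.integer(seed)
  stopifnot(dim > 0, epochs > 0, learning_rate > 0, n_buckets > 0,
            is.logical(use_bigrams), length(use_bigrams) == 1)
  structure(list(dim = dim, epochs = epochs, learning_rate = learning_rate,
                 use_bigrams = use_bigrams, n_buckets = n_buckets,
                 seed = seed),
            class = "comention_hyperparams")
}

#' Tokenize a blanked sentence
#'
#' Whitespace-splits, lowercases, and isolates punctuation characters as
#' separate tokens. Placeholder tokens (upper-case class name followed by
#' an underscore, e.g. `"GENE_"`) are preserved verbatim so they survive
#' as distinct vocabulary items. Idempotent on its own re-joined output.
#'
#' @param text a single character string.
#' @param placeholder_pattern regular expression recognising placeholder
#'   tokens to be kept verbatim (also when glued to punctuation, as in
#'   `"GENE_."`).
#' @return character vector of tokens (empty for an empty sentence).
#' @export
tokenize <- function(text, placeholder_pattern = "[A-Z][A-Z0-9]*_") {
  stopifnot(is.character(text), length(text) == 1)
  raw <- strsplit(trimws(text), "\\s+")[[1]]
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) return(character(0))
  lower_split <- function(seg) {
    seg <- tolower(seg)
    parts <- strsplit(gsub("([[:punct:]])", " \\1 ", seg), "\\s+")[[1]]
    parts[nzchar(parts)]
  }
  out <- lapply(raw, function(tok) {
    m <- gregexpr(placeholder_pattern, tok)[[1]]
    if (m[1] == -1) return(lower_split(tok))
    len <- attr(m, "match.length")
    pieces <- character(0)
    pos <- 1L
    for (k in seq_along(m)) {
      if (m[k] > pos) {
        pieces <- c(pieces, lower_split(substr(tok, pos, m[k] - 1L)))
      }
      pieces <- c(pieces, substr(tok, m[k], m[k] + len[k] - 1L))
      pos <- m[k] + len[k]
    }
    if (pos <= nchar(tok)) {
      pieces <- c(pieces, lower_split(substr(tok, pos, nchar(tok))))
    }
    pieces
  })
  unlist(out, use.names = FALSE)
}

tokenize_all <- function(texts, ...) lapply(texts, tokenize, ...)

#' Hash token bigrams into buckets
#'
#' Adjacent token pairs are joined with a single space and hashed with
#' 64-bit FNV-1a modulo `n_buckets`. The hash is fixed and
#' platform-independent, so a given bigram always lands in the same
#' bucket.
#'
#' @param tokens character vector of tokens.
#' @param n_buckets hash space size.
#' @return integer vector of 0-based bucket ids, length
#'   `max(0, length(tokens) - 1)`.
#' @export
bigram_buckets <- function(tokens, n_buckets) {
  n <- length(tokens)
  if (n < 2) return(integer(0))
  keys <- paste(tokens[-n], tokens[-1])
  cpp_fnv1a_bucket(keys, as.integer(n_buckets))
}

#' Extract classifier features from a token sequence
#'
#' Features are unigram vocabulary indices (out-of-vocabulary tokens are
#' skipped) plus, when bigrams are enabled, one hashed bucket id per
#' adjacent token pair. `n` tokens yield at most `n` unigram features and
#' exactly `n - 1` bigram features.
#'
#' @param tokens character vector of tokens.
#' @param hp a [hyperparams()] object.
#' @param vocab named integer vector mapping token to vocabulary index.
#' @return list with integer components `unigrams` (1-based vocabulary
#'   indices) and `bigrams` (0-based bucket ids; empty when disabled).
#' @export
featurize <- function(tokens, hp, vocab) {
  uni <- unname(vocab[tokens])
  uni <- uni[!is.na(uni)]
  big <- if (hp$use_bigrams) bigram_buckets(tokens, hp$n_buckets)
         else integer(0)
  list(unigrams = as.integer(uni), bigrams = as.integer(big))
}

#' Average embedding vectors of a feature set
#'
#' The sentence representation is the arithmetic mean of all selected
#' embedding rows; an empty feature set yields the zero vector.
#'
#' @param rows integer vector of 1-based row indices into `embeddings`.
#' @param embeddings numeric matrix, one row per feature.
#' @return numeric vector of length `ncol(embeddings)`.
#' @export
sentence_vector <- function(rows, embeddings) {
  if (length(rows) == 0) return(numeric(ncol(embeddings)))
  colMeans(embeddings[rows, , drop = FALSE])
}

#' An embedding table of word vectors
#'
#' @param words character vector of vocabulary words (unique).
#' @param vectors numeric matrix with one row per word.
#' @return object of class `embedding_table` with components `words`,
#'   `vectors` and a named index `vocab`.
#' @export
embedding_table <- function(words, vectors) {
  vectors <- as.matrix(vectors)
  stopifnot(length(words) == nrow(vectors), !anyDuplicated(words),
            all(is.finite(vectors)))
  structure(list(words = as.character(words), vectors = vectors,
                 vocab = stats::setNames(seq_along(words),
                                         as.character(words))),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d words x %d dimensions\n",
              length(x$words), ncol(x$vectors)))
  invisible(x)
}

# CSR feature layout for a list of token vectors: 0-based combined row
# indices (unigram rows first, then bigram bucket rows offset by n_unigrams)
# plus offsets. bucket_index maps bucket id (as character) to a dense row.
build_feature_csr <- function(token_lists, hp, vocab, bucket_index,
                              n_unigrams) {
  feats <- lapply(token_lists, function(toks) {
    f <- featurize(toks, hp, vocab)
    rows <- f$unigrams - 1L
    if (length(f$bigrams) > 0) {
      br <- bucket_index[as.character(f$bigrams)]
      br <- br[!is.na(br)]
      rows <- c(rows, n_unigrams + br - 1L)
    }
    as.integer(rows)
  })
  lens <- vapply(feats, length, 1L)
  list(feat = unlist(feats, use.names = FALSE),
       offsets = c(0L, cumsum(lens)))
}

#' Train the sentence classifier
#'
#' Keeps only co-mentions labeled `positive` or `negative`, tokenizes
#' their blanked text, and fits a logistic classifier on the mean of the
#' sentence's unigram and hashed-bigram embedding vectors. Embedding rows
#' and logistic weights are updated jointly by per-sentence SGD for
#' `hp$epochs` passes with an initial learning rate of
#' `hp$learning_rate`, decayed linearly to zero; sentence order is
#' reshuffled every epoch from `hp$seed`, making training fully
#' deterministic. When `pretrained` vectors are supplied, unigram rows
#' for covered words start from them (transfer learning); uncovered
#' unigrams and all bigram buckets start from small seeded uniform noise.
#' Only hash buckets observed in the training data are materialised, so
#' memory scales with the number of distinct bigrams, not `hp$n_buckets`.
#'
#' @param comentions labeled co-mention data frame with at least one
#'   positive and one negative sentence.
#' @param hp a [hyperparams()] object.
#' @param pretrained optional [embedding_table()] of pretrained word
#'   vectors; its dimensionality must equal `hp$dim`.
#' @return an object of class `sentence_classifier`.
#' @export
train_sentence_classifier <- function(comentions, hp = hyperparams(),
                                      pretrained = NULL) {
  stopifnot(inherits(hp, "comention_hyperparams"))
  keep <- comentions$label %in% c("positive", "negative")
  com <- comentions[keep, , drop = FALSE]
  y <- as.integer(com$label == "positive")
  if (length(y) == 0 || all(y == 1) || all(y == 0)) {
    stop("training requires at least one positive and one negative sentence")
  }
  if (!is.null(pretrained)) {
    stopifnot(inherits(pretrained, "embedding_table"))
    if (ncol(pretrained$vectors) != hp$dim) {
      stop(sprintf("pretrained vectors have dim %d but hyperparams dim %d",
                   ncol(pretrained$vectors), hp$dim))
    }
  }
  toks <- tokenize_all(com$text)
  words <- sort(unique(unlist(toks, use.names = FALSE)))
  vocab <- stats::setNames(seq_along(words), words)
  n_uni <- length(words)
  buckets <- if (hp$use_bigrams) {
    sort(unique(unlist(lapply(toks, bigram_buckets, hp$n_buckets),
                       use.names = FALSE)))
  } else integer(0)
  bucket_index <- stats::setNames(seq_along(buckets), as.character(buckets))
  csr <- build_feature_csr(toks, hp, vocab, bucket_index, n_uni)
  n_rows <- n_uni + length(buckets)
  n_sent <- length(y)
  init <- withr::with_seed(hp$seed, {
    E <- matrix(runif(n_rows * hp$dim, -1 / hp$dim, 1 / hp$dim),
                nrow = n_rows, ncol = hp$dim)
    orders <- vapply(seq_len(hp$epochs),
                     function(e) sample.int(n_sent), integer(n_sent))
    list(E = E, orders = orders)
  })
  E <- init$E
  if (!is.null(pretrained)) {
    hit <- match(words, pretrained$words)
    found <- which(!is.na(hit))
    if (length(found) > 0) {
      E[found, ] <- pretrained$vectors[hit[found], , drop = FALSE]
    }
  }
  fit <- cpp_sgd_train(E, csr$feat, csr$offsets, y,
                       matrix(init$orders - 1L, nrow = n_sent),
                       hp$learning_rate)
  structure(list(vocab = vocab, words = words, bucket_index = bucket_index,
                 n_unigrams = n_uni, embeddings = fit$embeddings,
                 weights = as.numeric(fit$weights), bias = fit$bias,
                 hyperparams = hp),
            class = "sentence_classifier")
}

#' @export
print.sentence_classifier <- function(x, ...) {
  cat(sprintf(
    "sentence_classifier: %d unigrams, %d bigram buckets, dim %d\n",
    x$n_unigrams, length(x$bucket_index), x$hyperparams$dim))
  invisible(x)
}

classifier_csr <- function(object, texts) {
  toks <- tokenize_all(texts)
  build_feature_csr(toks, object$hyperparams, object$vocab,
                    object$bucket_index, object$n_unigrams)
}

#' Score sentences with a trained classifier
#'
#' Returns `sigmoid(w . v + b)` where `v` is the mean embedding vector of
#' the sentence's features; tokens and bigram buckets unseen during
#' training are skipped, and an empty feature set scores `sigmoid(bias)`.
#' Outputs are clamped to lie strictly inside (0, 1).
#'
#' @param object a trained `sentence_classifier`.
#' @param newdata character vector of blanked sentences, or a co-mention
#'   data frame (its `text` column is used).
#' @param ... unused.
#' @return numeric vector of scores in (0, 1).
#' @export
predict.sentence_classifier <- function(object, newdata, ...) {
  texts <- if (is.data.frame(newdata)) newdata$text else newdata
  if (length(texts) == 0) return(numeric(0))
  csr <- classifier_csr(object, texts)
  V <- cpp_sentence_vectors(object$embeddings, csr$feat, csr$offsets)
  z <- drop(V %*% object$weights) + object$bias
  p <- plogis(z)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Attach sentence scores to a co-mention table
#' @param classifier a trained `sentence_classifier`.
#' @param comentions co-mention data frame.
#' @return the co-mention data frame with `sentence_score` filled.
#' @export
score_sentences <- function(classifier, comentions) {
  comentions$sentence_score <- predict(classifier, comentions)
  comentions
}

#' Pretrain word embeddings with skipgram and negative sampling
#'
#' Learns unigram vectors on a corpus of (blanked) sentences so that
#' words appearing in similar contexts receive similar vectors; the
#' resulting table can seed [train_sentence_classifier()] (transfer
#' learning). Training is a standard skipgram objective with negative
#' sampling from the unigram distribution raised to 3/4, a per-position
#' window sampled uniformly in `1..window`, and a linearly decaying
#' learning rate. All randomness is derived from `seed`, so the same
#' seed reproduces the identical table.
#'
#' @param sentences character vector of sentences, or a list of token
#'   vectors.
#' @param dim embedding dimensionality.
#' @param seed integer seed.
#' @param window maximal context window half-width.
#' @param epochs training passes over the corpus.
#' @param negative number of negative samples per context pair.
#' @param learning_rate initial learning rate.
#' @param min_count drop words rarer than this.
#' @return an [embedding_table()].
#' @export
pretrain_embeddings <- function(sentences, dim = 300L, seed = 1L,
                                window = 5L, epochs = 5L, negative = 5L,
                                learning_rate = 0.05, min_count = 1L) {
  toks <- if (is.list(sentences)) sentences else tokenize_all(sentences)
  toks <- toks[vapply(toks, length, 1L) > 0]
  if (length(toks) == 0) stop("empty corpus")
  counts <- table(unlist(toks, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) stop("empty vocabulary after min_count filtering")
  # deterministic vocabulary order: frequency desc, then lexicographic
  o <- order(-as.integer(counts), names(counts))
  words <- names(counts)[o]
  freq <- as.numeric(counts)[o]
  vocab <- stats::setNames(seq_along(words), words)
  ids <- lapply(toks, function(t) {
    v <- unname(vocab[t]); as.integer(v[!is.na(v)]) - 1L
  })
  ids <- ids[vapply(ids, length, 1L) > 0]
  offsets <- c(0L, cumsum(vapply(ids, length, 1L)))
  tokens <- unlist(ids, use.names = FALSE)
  p <- freq^0.75
  tab_size <- 100000L
  neg_table <- rep.int(seq_along(words) - 1L,
                       pmax(1L, as.integer(round(p / sum(p) * tab_size))))
  Uin <- withr::with_seed(as.integer(seed), {
    matrix(runif(length(words) * dim, -0.5 / dim, 0.5 / dim),
           nrow = length(words))
  })
  U <- cpp_skipgram(tokens, offsets, Uin, neg_table, as.integer(window),
                    as.integer(negative), as.integer(epochs),
                    learning_rate, as.double(seed))
  embedding_table(words, U)
}
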