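## Flat-file persistence: word2vec text format for embedding tables and a
## word2vec-derived format for trained classifiers.

fmt_vec <- function(v) paste(sprintf("%.17g", v), collapse = " ")

#' Read and write word vectors in word2vec text format
#'
#' The format is a header line `"<vocab_size> <dim>"` followed by one
#' line per word: the word then `dim` space-separated values. Values are
#' written with 17 significant digits so round trips are bit-exact.
#'
#' @param path file path.
#' @return `read_word2vec`: an [embedding_table()].
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) stop(path, ": empty word2vec file")
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  if (length(hdr) != 2 || any(is.na(hdr))) {
    stop(path, ": malformed word2vec header")
  }
  n <- hdr[1]; dim <- hdr[2]
  if (length(lines) - 1 != n) {
    stop(sprintf("%s: header promises %d rows, found %d", path, n,
                 length(lines) - 1))
  }
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != dim + 1L)
  if (length(bad) > 0) {
    stop(sprintf("%s: malformed row at line %d", path, bad[1] + 1L))
  }
  words <- vapply(parts, `[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim)))
  embedding_table(words, vecs)
}

#' @param table an [embedding_table()] to write.
#' @rdname read_word2vec
#' @export
write_word2vec <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  rows <- vapply(seq_along(table$words), function(i) {
    paste(table$words[i], fmt_vec(table$vectors[i, ]))
  }, "")
  writeLines(c(sprintf("%d %d", length(table$words), ncol(table$vectors)),
               rows), path, useBytes = TRUE)
  invisible(path)
}

#' Save and load a trained sentence classifier
#'
#' The file is plain text: a JSON header line carrying the
#' hyperparameters and layout, a word2vec-format section with the unigram
#' rows (named by word) followed by the materialised bigram-bucket rows
#' (named `__bucket_<id>`), then the logistic weights and bias.
#'
#' @param classifier a trained `sentence_classifier`.
#' @param path file path.
#' @return `load_classifier`: the reconstructed `sentence_classifier`.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "sentence_classifier"))
  hp <- classifier$hyperparams
  header <- jsonlite::toJSON(
    list(format = "comention_classifier", version = 1L,
         n_unigrams = classifier$n_unigrams,
         n_bucket_rows = length(classifier$bucket_index),
         hyperparams = unclass(hp)),
    auto_unbox = TRUE, digits = NA)
  names <- c(classifier$words,
             paste0("__bucket_", names(classifier$bucket_index)))
  E <- classifier$embeddings
  rows <- vapply(seq_len(nrow(E)), function(i) {
    paste(names[i], fmt_vec(E[i, ]))
  }, "")
  writeLines(c(as.character(header),
               sprintf("%d %d", nrow(E), ncol(E)), rows,
               paste("__WEIGHTS__", fmt_vec(classifier$weights)),
               paste("__BIAS__", sprintf("%.17g", classifier$bias))),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- jsonlite::fromJSON(lines[1])
  if (!identical(meta$format, "comention_classifier")) {
    stop(path, ": not a comention classifier file")
  }
  hdr <- as.integer(strsplit(lines[2], " ", fixed = TRUE)[[1]])
  n_rows <- hdr[1]; dim <- hdr[2]
  parts <- strsplit(lines[3:(2 + n_rows)], " ", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1L)
  E <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim)))
  w_line <- strsplit(lines[3 + n_rows], " ", fixed = TRUE)[[1]]
  b_line <- strsplit(lines[4 + n_rows], " ", fixed = TRUE)[[1]]
  stopifnot(w_line[1] == "__WEIGHTS__", b_line[1] == "__BIAS__")
  n_uni <- meta$n_unigrams
  words <- nm[seq_len(n_uni)]
  bucket_ids <- sub("^__bucket_", "", nm[-seq_len(n_uni)])
  hp <- do.call(hyperparams, meta$hyperparams)
  structure(list(vocab = stats::setNames(seq_len(n_uni), words),
                 words = words,
                 bucket_index = stats::setNames(seq_along(bucket_ids),
                                                bucket_ids),
                 n_unigrams = n_uni, embeddings = E,
                 weights = as.numeric(w_line[-1]),
                 bias = as.numeric(b_line[2]), hyperparams = hp),
            class = "sentence_classifier")
}
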