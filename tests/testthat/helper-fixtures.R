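# Programmatic fixtures shared across test files.

# Minimal valid co-mention rows; text defaults to placeholder-bearing
# sentences for the given classes.
make_comentions <- function(n = 4, ns1 = "disease", ns2 = "gene",
                            doc = sprintf("doc%02d", seq_len(n)),
                            sentence = rep(0L, n),
                            id1 = sprintf("D%02d", seq_len(n)),
                            id2 = sprintf("G%02d", seq_len(n)),
                            text = NULL, label = "unlabeled",
                            score = NA_real_) {
  if (is.null(text)) {
    text <- sprintf("%s_ linked to %s_", toupper(rep_len(ns1, n)),
                    toupper(rep_len(ns2, n)))
  }
  as_comentions(data.frame(
    document_id = doc, sentence_index = sentence,
    ns1 = rep_len(ns1, n), id1 = id1, ns2 = rep_len(ns2, n), id2 = id2,
    text = text, label = rep_len(label, n),
    sentence_score = rep_len(score, n), stringsAsFactors = FALSE))
}

# Separable toy training set: positives contain the token "complex",
# negatives the token "unrelated", over a small random background.
make_separable_fixture <- function(n = 200, seed = 1, n_docs = n) {
  withr::with_seed(seed, {
    mk <- function(m, word) {
      vapply(seq_len(m), function(i) {
        bg <- sample(sprintf("b%02d", 1:40), 7, replace = TRUE)
        bg[sample(7, 1)] <- word
        paste(c("GENE_", bg, "GENE_"), collapse = " ")
      }, "")
    }
    half <- n %/% 2
    as_comentions(data.frame(
      document_id = sprintf("d%04d", seq_len(n)),
      sentence_index = 0L,
      ns1 = "gene", id1 = sprintf("A%04d", seq_len(n)),
      ns2 = "gene", id2 = sprintf("B%04d", seq_len(n)),
      text = c(mk(half, "complex"), mk(n - half, "unrelated")),
      label = rep(c("positive", "negative"), c(half, n - half)),
      stringsAsFactors = FALSE))
  })
}

test_hp <- function(seed = 1, ...) {
  hyperparams(dim = 50, epochs = 20, learning_rate = 0.1,
              n_buckets = 10000, seed = seed, ...)
}

# Small synthetic benchmark (shrunk world for module tests; the
# acceptance suite runs the full default conditions).
small_world <- function(seed = 1, ...) {
  cfg <- generator_config(n_entities = c(gene = 12L, disease = 12L),
                          n_gold_positive = 60L, n_grey = 5L,
                          n_documents = 800L, seed = seed, ...)
  world <- generate_world(cfg)
  list(config = cfg, world = world, corpus = generate_corpus(world))
}

trigger_regex <- function(cfg = generator_config()) {
  paste0("\\b(", paste(cfg$trigger_tokens, collapse = "|"), ")\\b")
}
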