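test_that("tokenizer lowercases, splits punctuation, keeps placeholders", {
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("   "), character(0))
  expect_identical(tokenize("GENE_ binds GENE_."),
                   c("GENE_", "binds", "GENE_", "."))
  expect_identical(tokenize("The Gene-X, truly!"),
                   c("the", "gene", "-", "x", ",", "truly", "!"))
  # idempotent on its own re-joined output
  toks <- tokenize("DISEASE_ is Caused-by GENE_, often.")
  expect_identical(tokenize(paste(toks, collapse = " ")), toks)
})

test_that("bigram hashing is fixed and matches precomputed FNV-1a values", {
  # frozen values from an independent FNV-1a implementation
  expect_identical(bigram_buckets(c("GENE_", "binds", "GENE_"), 10000),
                   c(8185L, 5325L))
  expect_identical(bigram_buckets(c("w0001", "w0002"), 10000), 7898L)
  expect_identical(bigram_buckets(c("complex", "."), 2000000), 792001L)
  expect_identical(bigram_buckets(c("a", "b"), 2000000), 1137298L)
  expect_identical(bigram_buckets("lonely", 10), integer(0))
})

test_that("featurize yields unigram indices plus n-1 hashed bigrams", {
  hp <- test_hp()
  vocab <- stats::setNames(1:3, c("GENE_", "binds", "to"))
  f <- featurize("binds", hp, vocab)
  expect_identical(f$unigrams, 2L)
  expect_identical(f$bigrams, integer(0))
  toks <- c("GENE_", "binds", "to", "GENE_", "oov")
  f <- featurize(toks, hp, vocab)
  expect_identical(length(f$unigrams), 4L)   # oov unigram skipped
  expect_identical(length(f$bigrams), 4L)    # exactly n - 1
  hp0 <- test_hp(); hp0$use_bigrams <- FALSE
  expect_identical(featurize(toks, hp0, vocab)$bigrams, integer(0))
})

test_that("sentence vectors are plain feature averages", {
  E <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_identical(sentence_vector(integer(0), E), c(0, 0))
  expect_identical(unname(sentence_vector(2L, E)), c(3, 4))
  expect_identical(unname(sentence_vector(c(1L, 3L), E)), c(3, 4))
})

test_that("training separates a planted keyword rule and is deterministic", {
  com <- make_separable_fixture(200, seed = 5)
  clf <- train_sentence_classifier(com, test_hp(seed = 9))
  clf2 <- train_sentence_classifier(com, test_hp(seed = 9))
  expect_identical(clf$weights, clf2$weights)
  expect_identical(clf$embeddings, clf2$embeddings)
  holdout <- make_separable_fixture(200, seed = 6)
  p <- predict(clf, holdout)
  truth <- holdout$label == "positive"
  expect_gte(mean((p > 0.5) == truth), 0.95)
  expect_gt(mean(p[truth]), mean(p[!truth]))
  expect_true(all(p > 0 & p < 1))
})

test_that("flipping the labels mirrors the scores", {
  com <- make_separable_fixture(200, seed = 2)
  flipped <- com
  flipped$label <- ifelse(com$label == "positive", "negative", "positive")
  clf <- train_sentence_classifier(com, test_hp(seed = 3))
  clf_f <- train_sentence_classifier(flipped, test_hp(seed = 3))
  p <- predict(clf, com)
  pf <- predict(clf_f, com)
  expect_lt(max(abs(pf - (1 - p))), 0.05)
})

test_that("training requires two classes and matching dimensions", {
  com <- make_separable_fixture(20, seed = 1)
  pos_only <- com[com$label == "positive", ]
  expect_error(train_sentence_classifier(pos_only, test_hp()),
               "positive and.*negative")
  pre <- embedding_table(c("complex", "unrelated"),
                         matrix(0.1, 2, 7))
  expect_error(train_sentence_classifier(com, test_hp(), pre),
               "dim 7.*dim 50")
})

test_that("without bigrams prediction is permutation-invariant, with it not", {
  com <- make_separable_fixture(100, seed = 8)
  hp_uni <- test_hp(seed = 4); hp_uni$use_bigrams <- FALSE
  clf <- train_sentence_classifier(com, hp_uni)
  toks <- c("GENE_", "b01", "complex", "b07", "GENE_")
  perm <- c("complex", "GENE_", "b07", "GENE_", "b01")
  expect_identical(predict(clf, paste(toks, collapse = " ")),
                   predict(clf, paste(perm, collapse = " ")))
  clf_bi <- train_sentence_classifier(com, test_hp(seed = 4))
  expect_false(isTRUE(all.equal(
    predict(clf_bi, paste(toks, collapse = " ")),
    predict(clf_bi, paste(perm, collapse = " ")))))
})

test_that("an untrained-zero classifier scores sigmoid of the bias", {
  com <- make_separable_fixture(40, seed = 3)
  clf <- train_sentence_classifier(com, test_hp(seed = 1))
  clf$weights <- rep(0, clf$hyperparams$dim)
  clf$bias <- 0
  expect_equal(unname(predict(clf, "GENE_ b01 complex GENE_")), 0.5)
  clf$bias <- 1.2
  # empty / fully out-of-vocabulary sentences fall back to the bias
  expect_equal(unname(predict(clf, "")), plogis(1.2))
  expect_equal(unname(predict(clf, "zz qq")), plogis(1.2))
})

test_that("skipgram pretraining learns planted topics deterministically", {
  # two-topic corpus: topic words co-occur within sentences
  mk_corpus <- function(seed) {
    withr::with_seed(seed, {
      topics <- list(sprintf("cell%02d", 1:10), sprintf("star%02d", 1:10))
      lapply(seq_len(400), function(i) {
        t <- topics[[1 + (i %% 2)]]
        sample(t, 6, replace = TRUE)
      })
    })
  }
  corpus <- mk_corpus(1)
  emb <- pretrain_embeddings(corpus, dim = 16, seed = 3, epochs = 10)
  emb2 <- pretrain_embeddings(corpus, dim = 16, seed = 3, epochs = 10)
  expect_identical(emb$vectors, emb2$vectors)
  expect_setequal(emb$words, unique(unlist(corpus)))
  cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  V <- emb$vectors; rownames(V) <- emb$words
  within <- cross <- c()
  for (i in 1:8) {
    a <- sprintf("cell%02d", i); b <- sprintf("cell%02d", i + 1)
    s <- sprintf("star%02d", i)
    within <- c(within, cos(V[a, ], V[b, ]))
    cross <- c(cross, cos(V[a, ], V[s, ]))
  }
  expect_gt(mean(within), mean(cross))
  expect_error(pretrain_embeddings(list()), "empty corpus")
  one <- pretrain_embeddings(list(c("a", "b")), dim = 4, seed = 1)
  expect_setequal(one$words, c("a", "b"))
})

test_that("pretrained vectors transfer to small supervised sets", {
  # with few labeled sentences, initializing unigram vectors from a large
  # unlabeled corpus should not hurt and typically helps (sign test)
  wins <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    big <- make_separable_fixture(600, seed = 100 + seed)
    emb <- pretrain_embeddings(big$text, dim = 24, seed = seed,
                               epochs = 5)
    small <- make_separable_fixture(60, seed = 200 + seed)
    hold <- make_separable_fixture(200, seed = 300 + seed)
    truth <- hold$label == "positive"
    hp <- hyperparams(dim = 24, epochs = 10, learning_rate = 0.1,
                      n_buckets = 10000, seed = seed)
    auc_pre <- auroc(predict(train_sentence_classifier(small, hp, emb),
                             hold), truth)
    auc_raw <- auroc(predict(train_sentence_classifier(small, hp), hold),
                     truth)
    wins <- wins + (auc_pre >= auc_raw)
  }
  expect_gte(wins, ceiling(n_seeds / 2))
})

test_that("classifier and embedding tables survive file round trips", {
  com <- make_separable_fixture(60, seed = 12)
  clf <- train_sentence_classifier(com, test_hp(seed = 2))
  path <- withr::local_tempfile()
  save_classifier(clf, path)
  clf2 <- load_classifier(path)
  expect_identical(clf2$weights, clf$weights)
  expect_identical(clf2$bias, clf$bias)
  expect_identical(clf2$embeddings, unname(clf$embeddings))
  texts <- make_separable_fixture(20, seed = 13)$text
  expect_identical(predict(clf2, texts), predict(clf, texts))
  emb <- embedding_table(c("alpha", "beta"),
                         matrix(c(0.25, -1 / 3, 1e-9, 2), 2, 2))
  w2v <- withr::local_tempfile()
  write_word2vec(emb, w2v)
  emb2 <- read_word2vec(w2v)
  expect_identical(emb2$words, emb$words)
  expect_identical(emb2$vectors, unname(emb$vectors))
})
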