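## Synthetic benchmark generator: gold standards, small ontologies and
## co-mention corpora with a planted, tunable context signal. Sentences
## about truly associated pairs contain an association-trigger token with
## probability pi1, sentences about other pairs with probability pi0
## (pi0 <= pi1), over a Zipf-distributed background vocabulary; this is
## the minimal textual structure the distant-supervision setup assumes.

#' Configuration of the synthetic corpus generator
#'
#' The defaults define the package's standard benchmark world: two
#' entity classes of 25 entities each (gene and disease, so pairs are
#' cross-class), 300 gold-positive pairs, 20 grey-listed pairs, 5000
#' documents with a zero-truncated Poisson(1.5) number of co-mention
#' sentences each, a 2000-word Zipf(1.1) background vocabulary, a strong
#' context signal (`pi1 = 0.8`, `pi0 = 0.1`), and 70% of sentences drawn
#' from truly associated pairs so that associated pairs are also
#' co-mentioned more often (giving the context-blind baseline a count
#' signal to work with).
#'
#' @param entity_classes one or two entity class names; with two
#'   classes, pairs are cross-class, with one class, within-class.
#' @param n_entities named integer vector of entity counts per class.
#' @param n_gold_positive number of gold-positive pairs.
#' @param n_grey number of grey-listed pairs.
#' @param n_documents number of documents.
#' @param sentences_per_document Poisson mean of the per-document
#'   sentence count (zero-truncated).
#' @param vocabulary_size background vocabulary size.
#' @param zipf_exponent Zipf exponent of the background word
#'   distribution.
#' @param trigger_tokens association-trigger vocabulary.
#' @param pi1 probability that a sentence about a truly associated pair
#'   contains a trigger token.
#' @param pi0 same for non-associated pairs; must satisfy
#'   `pi0 <= pi1`.
#' @param assoc_fraction probability that a sentence is about a truly
#'   associated pair.
#' @param gold_incompleteness fraction of truly associated pairs
#'   withheld from the gold standard (they then label as negatives,
#'   emulating an incomplete knowledge base).
#' @param background_length_mean Poisson mean of the number of
#'   background tokens per sentence.
#' @param n_ontology_children extra ontology child terms per entity of
#'   the second class (0 disables ontology generation).
#' @param seed integer master seed for the generator.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(entity_classes = c("gene", "disease"),
                             n_entities = c(gene = 25L, disease = 25L),
                             n_gold_positive = 300L, n_grey = 20L,
                             n_documents = 5000L,
                             sentences_per_document = 1.5,
                             vocabulary_size = 2000L, zipf_exponent = 1.1,
                             trigger_tokens = c("associated", "linked",
                                                "causes", "implicated",
                                                "predisposes"),
                             pi1 = 0.8, pi0 = 0.1, assoc_fraction = 0.7,
                             gold_incompleteness = 0,
                             background_length_mean = 8,
                             n_ontology_children = 0L, seed = 1L) {
  stopifnot(length(entity_classes) %in% c(1L, 2L),
            all(entity_classes %in% names(n_entities)),
            all(n_entities[entity_classes] > 0),
            n_gold_positive >= 0, n_grey >= 0, n_documents > 0,
            sentences_per_document > 0, vocabulary_size > 0,
            zipf_exponent > 0, length(trigger_tokens) > 0,
            pi0 >= 0, pi1 <= 1, pi0 <= pi1,
            assoc_fraction >= 0, assoc_fraction <= 1,
            gold_incompleteness >= 0, gold_incompleteness < 1,
            background_length_mean > 0, n_ontology_children >= 0)
  structure(list(entity_classes = entity_classes,
                 n_entities = n_entities,
                 n_gold_positive = as.integer(n_gold_positive),
                 n_grey = as.integer(n_grey),
                 n_documents = as.integer(n_documents),
                 sentences_per_document = sentences_per_document,
                 vocabulary_size = as.integer(vocabulary_size),
                 zipf_exponent = zipf_exponent,
                 trigger_tokens = trigger_tokens, pi1 = pi1, pi0 = pi0,
                 assoc_fraction = assoc_fraction,
                 gold_incompleteness = gold_incompleteness,
                 background_length_mean = background_length_mean,
                 n_ontology_children = as.integer(n_ontology_children),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# zero-truncated Poisson draws
rztpois <- function(n, lambda) {
  x <- rpois(n, lambda)
  while (any(x == 0)) {
    z <- x == 0
    x[z] <- rpois(sum(z), lambda)
  }
  x
}

#' Generate a synthetic world: entities, truth, gold standard, ontology
#'
#' Samples entity identifiers, a set of truly associated pairs, and a
#' gold standard equal to the truth minus a withheld fraction
#' (`gold_incompleteness`); grey pairs are sampled from the
#' non-associated pairs. All generated entities are in the gold
#' standard's entity universe, so non-gold pairs label as negatives.
#' When `n_ontology_children > 0`, each entity of the (last) class gains
#' that many child terms in a two-level ontology; child terms are absent
#' from the gold standard until [propagate_gold()] is applied.
#' Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_world` with components `gold`
#'   ([gold_standard()]), `ontology` ([ontology()]), `true_pairs` (data
#'   frame of truly associated pairs), `all_pairs`, `entities` (data
#'   frame with `ns`, `id`) and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    classes <- config$entity_classes
    entities <- do.call(rbind, lapply(classes, function(cl) {
      n <- config$n_entities[[cl]]
      data.frame(ns = cl,
                 id = sprintf("%s%04d", toupper(substr(cl, 1, 1)),
                              seq_len(n)),
                 stringsAsFactors = FALSE)
    }))
    if (length(classes) == 2) {
      a <- entities[entities$ns == classes[1], ]
      b <- entities[entities$ns == classes[2], ]
      grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
      pairs <- data.frame(ns1 = a$ns[grid$i], id1 = a$id[grid$i],
                          ns2 = b$ns[grid$j], id2 = b$id[grid$j],
                          stringsAsFactors = FALSE)
    } else {
      idx <- t(utils::combn(nrow(entities), 2))
      pairs <- data.frame(ns1 = entities$ns[idx[, 1]],
                          id1 = entities$id[idx[, 1]],
                          ns2 = entities$ns[idx[, 2]],
                          id2 = entities$id[idx[, 2]],
                          stringsAsFactors = FALSE)
    }
    cp <- canonicalize_pair(pairs$ns1, pairs$id1, pairs$ns2, pairs$id2)
    pairs <- data.frame(ns1 = cp$ns1, id1 = cp$id1, ns2 = cp$ns2,
                        id2 = cp$id2, stringsAsFactors = FALSE)
    w <- config$gold_incompleteness
    n_true <- round(config$n_gold_positive / (1 - w))
    if (n_true + config$n_grey > nrow(pairs)) {
      stop("requested more gold and grey pairs than possible pairs")
    }
    true_idx <- sample.int(nrow(pairs), n_true)
    rest <- setdiff(seq_len(nrow(pairs)), true_idx)
    grey_idx <- if (config$n_grey > 0) sample(rest, config$n_grey)
                else integer(0)
    withheld <- if (w > 0 && n_true > 0) {
      sample(true_idx, round(w * n_true))
    } else integer(0)
    gold_idx <- setdiff(true_idx, withheld)
    ont <- if (config$n_ontology_children > 0) {
      cl <- classes[length(classes)]
      parents <- entities[entities$ns == cl, ]
      edges <- do.call(rbind, lapply(seq_len(nrow(parents)), function(i) {
        data.frame(child_ns = cl,
                   child_id = sprintf("%s.c%d", parents$id[i],
                                      seq_len(config$n_ontology_children)),
                   parent_ns = cl, parent_id = parents$id[i],
                   stringsAsFactors = FALSE)
      }))
      ontology(edges)
    } else {
      ontology(data.frame())
    }
    structure(list(
      gold = gold_standard(pairs[gold_idx, , drop = FALSE],
                           pairs[grey_idx, , drop = FALSE],
                           entities = entity_key(entities$ns, entities$id)),
      ontology = ont,
      true_pairs = pairs[true_idx, , drop = FALSE],
      all_pairs = pairs,
      entities = entities,
      config = config), class = "synthetic_world")
  })
}

#' Generate a synthetic co-mention corpus from a world
#'
#' Each document holds a zero-truncated Poisson number of co-mention
#' sentences. Each sentence is about a truly associated pair with
#' probability `assoc_fraction` (drawn uniformly from the true pairs)
#' and otherwise about a uniformly drawn non-associated pair. Sentence
#' text consists of the two class placeholder tokens around a Zipf
#' sample of background words, with one trigger token inserted at a
#' random position with probability `pi1` (associated pair) or `pi0`
#' (other pair). Deterministic given `config$seed` (a sub-seed distinct
#' from the world's is used, so world and corpus draws do not interact).
#'
#' @param world a `synthetic_world` from [generate_world()].
#' @param config a [generator_config()]; defaults to the world's own.
#' @return an unlabeled co-mention data frame (see [as_comentions()]).
#' @export
generate_corpus <- function(world, config = world$config) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(config, "generator_config"))
  withr::with_seed(config$seed + 1L, {
    true_keys <- pair_key(world$true_pairs$ns1, world$true_pairs$id1,
                          world$true_pairs$ns2, world$true_pairs$id2)
    all_keys <- pair_key(world$all_pairs$ns1, world$all_pairs$id1,
                         world$all_pairs$ns2, world$all_pairs$id2)
    neg_rows <- which(!all_keys %in% true_keys)
    true_rows <- which(all_keys %in% true_keys)
    if (length(true_rows) == 0 && config$assoc_fraction > 0) {
      stop("world has no true pairs but assoc_fraction > 0")
    }
    vocab <- sprintf("w%04d", seq_len(config$vocabulary_size))
    zipf_p <- 1 / seq_len(config$vocabulary_size)^config$zipf_exponent
    zipf_p <- zipf_p / sum(zipf_p)
    n_sent_per_doc <- rztpois(config$n_documents,
                              config$sentences_per_document)
    n_total <- sum(n_sent_per_doc)
    is_assoc <- runif(n_total) < config$assoc_fraction &
      length(true_rows) > 0
    pick <- integer(n_total)
    if (any(is_assoc)) {
      pick[is_assoc] <- true_rows[sample.int(length(true_rows),
                                             sum(is_assoc), replace = TRUE)]
    }
    if (any(!is_assoc)) {
      if (length(neg_rows) == 0) stop("no non-associated pairs available")
      pick[!is_assoc] <- neg_rows[sample.int(length(neg_rows),
                                             sum(!is_assoc),
                                             replace = TRUE)]
    }
    has_trigger <- runif(n_total) < ifelse(is_assoc, config$pi1,
                                           config$pi0)
    trig <- sample(config$trigger_tokens, n_total, replace = TRUE)
    bg_len <- rpois(n_total, config$background_length_mean)
    bg_tokens <- sample(vocab, sum(bg_len), replace = TRUE, prob = zipf_p)
    bg_split <- split(bg_tokens,
                      rep.int(seq_len(n_total), bg_len))
    ph <- default_placeholders(config$entity_classes)
    p1 <- ph[world$all_pairs$ns1[pick]]
    p2 <- ph[world$all_pairs$ns2[pick]]
    text <- vapply(seq_len(n_total), function(i) {
      mid <- if (bg_len[i] > 0) bg_split[[as.character(i)]] else character(0)
      if (has_trigger[i]) {
        at <- sample.int(length(mid) + 1L, 1L)
        mid <- append(mid, trig[i], after = at - 1L)
      }
      paste(c(p1[i], mid, p2[i]), collapse = " ")
    }, "")
    doc_id <- sprintf("doc%05d", rep.int(seq_len(config$n_documents),
                                         n_sent_per_doc))
    sent_idx <- unlist(lapply(n_sent_per_doc, seq_len),
                       use.names = FALSE) - 1L
    df <- data.frame(document_id = doc_id, sentence_index = sent_idx,
                     ns1 = world$all_pairs$ns1[pick],
                     id1 = world$all_pairs$id1[pick],
                     ns2 = world$all_pairs$ns2[pick],
                     id2 = world$all_pairs$id2[pick],
                     text = text, stringsAsFactors = FALSE)
    # a document may draw the same pair twice; such sentences are distinct
    # co-mentions and keep their own sentence_index, so no duplicates arise
    as_comentions(df)
  })
}
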