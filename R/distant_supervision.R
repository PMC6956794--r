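## Distant supervision: weak labeling of co-mentions from a gold standard,
## with grey-listing and ontology propagation.

#' Propagate a gold standard down an ontology
#'
#' For every positive pair whose ontology-typed entity is `d`, every
#' descendant `d'` of `d` (a term from which `d` is reachable via
#' child-to-parent edges) yields an additional positive pair `(d', g)`:
#' a sentence linking a more specific term to `g` supports the more
#' general association, so co-mentions of descendant terms should count
#' as positives. The grey list is propagated the same way; a propagated
#' grey pair never overrides a positive.
#'
#' @param gold a [gold_standard()] object.
#' @param ont an [ontology()] object (child-to-parent edges; acyclic).
#' @param namespace entity class to propagate on (e.g. `"disease"`);
#'   defaults to the ontology's namespace. Pairs without an entity in this
#'   namespace are left untouched.
#' @return an augmented [gold_standard()]; idempotent, so applying it
#'   twice changes nothing.
#' @export
propagate_gold <- function(gold, ont, namespace = NULL) {
  stopifnot(inherits(gold, "gold_standard"), inherits(ont, "ontology"))
  edges <- ont$edges
  if (nrow(edges) == 0) return(gold)
  ont_ns <- unique(edges$child_ns)
  if (is.null(namespace)) namespace <- ont_ns
  if (length(namespace) != 1 || !namespace %in% ont_ns) {
    stop("propagation namespace does not match the ontology's namespace")
  }
  gold_ns <- unique(c(gold$positives$ns1, gold$positives$ns2,
                      gold$grey$ns1, gold$grey$ns2))
  if (length(gold_ns) > 0 && !namespace %in% gold_ns) {
    stop(sprintf(
      "namespace mismatch: ontology namespace '%s' absent from gold entities",
      namespace))
  }
  # children adjacency: parent key -> child keys
  pk <- entity_key(edges$parent_ns, edges$parent_id)
  ck <- entity_key(edges$child_ns, edges$child_id)
  children <- split(seq_len(nrow(edges)), pk)
  descendants <- function(key) {
    seen <- character(0)
    frontier <- key
    while (length(frontier) > 0) {
      idx <- unlist(children[frontier], use.names = FALSE)
      nxt <- setdiff(unique(ck[idx]), c(seen, key))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  expand <- function(df) {
    if (nrow(df) == 0) return(df)
    extra <- list()
    for (i in seq_len(nrow(df))) {
      for (side in 1:2) {
        ns <- df[[sprintf("ns%d", side)]][i]
        if (ns != namespace) next
        id <- df[[sprintf("id%d", side)]][i]
        desc_keys <- descendants(entity_key(ns, id))
        if (length(desc_keys) == 0) next
        desc_id <- sub(paste0("^", namespace, ":"), "", desc_keys)
        other_ns <- df[[sprintf("ns%d", 3 - side)]][i]
        other_id <- df[[sprintf("id%d", 3 - side)]][i]
        extra[[length(extra) + 1L]] <- data.frame(
          ns1 = namespace, id1 = desc_id,
          ns2 = other_ns, id2 = other_id, stringsAsFactors = FALSE)
      }
    }
    if (length(extra) > 0) df <- rbind(df, do.call(rbind, extra))
    df
  }
  pos <- expand(gold$positives)
  gry <- expand(gold$grey)
  # grey never overrides positive
  if (nrow(gry) > 0) {
    pos_keys <- {
      cp <- canonicalize_pair(pos$ns1, pos$id1, pos$ns2, pos$id2)
      pair_key(cp$ns1, cp$id1, cp$ns2, cp$id2)
    }
    cp <- canonicalize_pair(gry$ns1, gry$id1, gry$ns2, gry$id2)
    gry <- gry[!pair_key(cp$ns1, cp$id1, cp$ns2, cp$id2) %in% pos_keys, ,
               drop = FALSE]
  }
  gold_standard(pos, gry, entities = gold$entities)
}

#' Weakly label co-mentions against a gold standard
#'
#' Implements the distant-supervision rule: a co-mention is `positive` if
#' its pair is a gold positive, `excluded_grey` if the pair is
#' grey-listed, `negative` if both entities are known to the gold standard
#' but the pair is neither positive nor grey, and `excluded_unknown` if
#' either entity is absent from the gold standard (the pair is
#' unlabelable). Labeling is deterministic and independent of row order;
#' any pre-existing labels are overwritten.
#'
#' @param comentions a co-mention data frame.
#' @param gold a [gold_standard()] object.
#' @return a list with components `comentions` (the labeled data frame)
#'   and `summary`, a one-row data frame with counts `n_positive`,
#'   `n_negative`, `n_excluded_grey`, `n_excluded_unknown` summing to the
#'   number of input co-mentions.
#' @export
label_comentions <- function(comentions, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  key <- comention_pair_keys(comentions)
  e1 <- entity_key(comentions$ns1, comentions$id1)
  e2 <- entity_key(comentions$ns2, comentions$id2)
  label <- ifelse(key %in% gold$positive_keys, "positive",
           ifelse(key %in% gold$grey_keys, "excluded_grey",
           ifelse(e1 %in% gold$entities & e2 %in% gold$entities,
                  "negative", "excluded_unknown")))
  comentions$label <- label
  list(comentions = comentions, summary = label_summary(comentions))
}

#' Tabulate label counts of a labeled co-mention table
#' @param comentions a labeled co-mention data frame.
#' @return one-row data frame with columns `n_positive`, `n_negative`,
#'   `n_excluded_grey`, `n_excluded_unknown`, `n_unlabeled`, `n_total`.
#' @export
label_summary <- function(comentions) {
  n <- function(l) sum(comentions$label == l)
  data.frame(n_positive = n("positive"), n_negative = n("negative"),
             n_excluded_grey = n("excluded_grey"),
             n_excluded_unknown = n("excluded_unknown"),
             n_unlabeled = n("unlabeled"), n_total = nrow(comentions))
}

#' Label entity pairs (rather than sentences) against a gold standard
#'
#' Pair-level analogue of [label_comentions()], used when evaluating
#' aggregated pair scores: a pair is `positive` iff in the gold positives,
#' `excluded_grey` iff grey-listed, `negative` iff both entities are in
#' the gold universe, else `excluded_unknown`.
#'
#' @param pairs data frame with columns `ns1`, `id1`, `ns2`, `id2`
#'   (canonical order).
#' @param gold a [gold_standard()] object.
#' @return character vector of labels, one per row of `pairs`.
#' @export
label_pairs <- function(pairs, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  key <- pair_key(pairs$ns1, pairs$id1, pairs$ns2, pairs$id2)
  e1 <- entity_key(pairs$ns1, pairs$id1)
  e2 <- entity_key(pairs$ns2, pairs$id2)
  ifelse(key %in% gold$positive_keys, "positive",
  ifelse(key %in% gold$grey_keys, "excluded_grey",
  ifelse(e1 %in% gold$entities & e2 %in% gold$entities,
         "negative", "excluded_unknown")))
}
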