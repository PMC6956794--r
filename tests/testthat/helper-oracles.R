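# Independent brute-force oracles, deliberately written as direct
# transcriptions of the definitions and kept free of package internals.

# Pair score S = C^alpha * (C * total / (Ci * Cj))^(1-alpha), computed
# pair by pair with explicit marginal sums.
oracle_combine <- function(pairs, alpha) {
  key_of <- function(i) paste(pairs$ns1[i], pairs$id1[i], pairs$ns2[i],
                              pairs$id2[i])
  ent <- function(ns, id) paste(ns, id)
  total <- sum(pairs$count)
  s <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ci <- 0; cj <- 0
    for (j in seq_len(nrow(pairs))) {
      ents_j <- c(ent(pairs$ns1[j], pairs$id1[j]),
                  ent(pairs$ns2[j], pairs$id2[j]))
      if (ent(pairs$ns1[i], pairs$id1[i]) %in% ents_j) {
        ci <- ci + pairs$count[j]
      }
      if (ent(pairs$ns2[i], pairs$id2[i]) %in% ents_j) {
        cj <- cj + pairs$count[j]
      }
    }
    s[i] <- pairs$count[i]^alpha *
      (pairs$count[i] * total / (ci * cj))^(1 - alpha)
  }
  s
}

# Precision/recall at every distinct threshold, recomputing TP and FP
# from scratch by comparing all scores against the threshold.
oracle_pr_points <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  do.call(rbind, lapply(thr, function(t) {
    called <- scores >= t
    tp <- sum(called & labels)
    fp <- sum(called & !labels)
    data.frame(threshold = t, tp = tp, fp = fp,
               precision = tp / (tp + fp), recall = tp / P)
  }))
}

# Average-precision area: sum over threshold steps of
# delta-recall * precision, from the brute-force points.
oracle_auprc <- function(scores, labels, a = NULL) {
  pts <- oracle_pr_points(scores, labels)
  prec <- pts$precision
  if (!is.null(a)) {
    b <- mean(labels)
    prec <- (a / b * pts$tp) /
      (a / b * pts$tp + (1 - a) / (1 - b) * pts$fp)
  }
  sum(diff(c(0, pts$recall)) * prec)
}

# AUROC by exhaustive pair counting: P(pos > neg) + 0.5 P(tie).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Transitive reachability closure of a child->parent edge list via
# repeated boolean matrix multiplication.
oracle_descendants <- function(edges, node) {
  nodes <- unique(c(edges$child, edges$parent))
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) A[edges$child[i], edges$parent[i]] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  if (!node %in% nodes) return(character(0))
  nodes[R[, node]]
}
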