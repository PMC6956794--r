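## Domain types and file formats: co-mentions, gold standards, ontologies.
##
## Entities are (namespace, identifier) pairs, e.g. ("gene", "ENSG...") or
## ("disease", "DOID:14330"). Pairs are stored canonically so (i, j) and
## (j, i) are the same pair. All files are strict TSV: no quoting, tabs
## forbidden inside fields.

COMENTION_COLUMNS <- c("document_id", "sentence_index", "ns1", "id1",
                       "ns2", "id2", "text", "label", "sentence_score")

LABEL_LEVELS <- c("positive", "negative", "excluded_grey",
                  "excluded_unknown", "unlabeled")

#' Entity and pair keys
#'
#' An entity key is `"namespace:identifier"`; a pair key joins the two
#' canonically ordered entity keys with `"|"`. Keys are used internally to
#' index marginals and gold-standard sets; namespaces and identifiers must
#' therefore not contain tabs or `"|"`.
#'
#' @param ns,id character vectors of namespaces and identifiers.
#' @return character vector of keys.
#' @export
entity_key <- function(ns, id) paste(ns, id, sep = ":")

#' @param ns1,id1,ns2,id2 character vectors describing the two entities of
#'   each pair (already canonically ordered for `pair_key`).
#' @rdname entity_key
#' @export
pair_key <- function(ns1, id1, ns2, id2) {
  paste(entity_key(ns1, id1), entity_key(ns2, id2), sep = "|")
}

#' Canonical ordering of entity pairs
#'
#' Orders the two entities of each pair lexicographically by namespace,
#' then identifier, so that a pair and its swap map to the same
#' representation. Self-pairs (identical entities) are invalid.
#'
#' @inheritParams pair_key
#' @return a list with components `ns1`, `id1`, `ns2`, `id2`, `swapped`.
#' @export
canonicalize_pair <- function(ns1, id1, ns2, id2) {
  stopifnot(length(ns1) == length(id1), length(ns1) == length(ns2),
            length(ns1) == length(id2))
  if (any(ns1 == ns2 & id1 == id2)) {
    stop("self-pairs (identical entities) are not allowed")
  }
  swap <- ns1 > ns2 | (ns1 == ns2 & id1 > id2)
  list(ns1 = ifelse(swap, ns2, ns1), id1 = ifelse(swap, id2, id1),
       ns2 = ifelse(swap, ns1, ns2), id2 = ifelse(swap, id1, id2),
       swapped = swap)
}

#' Default placeholder token for an entity class
#'
#' Blanked sentences replace entity names by one placeholder token per
#' entity class; by default the upper-cased class name followed by an
#' underscore (`"GENE_"`, `"DISEASE_"`, ...). A named character vector can
#' be supplied wherever placeholders are configurable.
#'
#' @param classes character vector of entity class (namespace) names.
#' @return named character vector mapping class to placeholder token.
#' @export
default_placeholders <- function(classes) {
  stats::setNames(paste0(toupper(classes), "_"), classes)
}

check_no_tabs <- function(x, what) {
  if (any(grepl("[\t\n]", x))) {
    stop(sprintf("tabs and newlines are forbidden in %s", what))
  }
}

#' Construct and validate a co-mention table
#'
#' A co-mention table is a data frame with one row per sentence-level
#' co-mention and columns `document_id`, `sentence_index` (non-negative
#' integer), `ns1`, `id1`, `ns2`, `id2` (entity pair, canonicalized here),
#' `text` (the blanked sentence), `label` (one of `positive`, `negative`,
#' `excluded_grey`, `excluded_unknown`, `unlabeled`) and `sentence_score`
#' (numeric in (0,1) or `NA`). Validation enforces the invariants:
#' canonically ordered non-self pairs, unique (document, sentence, pair)
#' triples, no tabs in fields, and at least one placeholder token per
#' entity class of the pair in `text`.
#'
#' @param df data frame with at least the first seven columns above.
#' @param placeholders named character vector mapping entity classes to
#'   placeholder tokens; defaults to [default_placeholders()] of the
#'   namespaces present.
#' @param check_placeholders logical; verify the placeholder invariant.
#' @return validated co-mention data frame.
#' @export
as_comentions <- function(df, placeholders = NULL, check_placeholders = TRUE) {
  required <- COMENTION_COLUMNS[1:7]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing co-mention columns: ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) df$label <- rep("unlabeled", nrow(df))
  if (!"sentence_score" %in% names(df)) {
    df$sentence_score <- rep(NA_real_, nrow(df))
  }
  df <- df[, COMENTION_COLUMNS]
  df$document_id <- as.character(df$document_id)
  df$sentence_index <- as.integer(df$sentence_index)
  df$text <- as.character(df$text)
  df$sentence_score <- as.numeric(df$sentence_score)
  for (col in c("ns1", "id1", "ns2", "id2")) df[[col]] <- as.character(df[[col]])
  if (any(is.na(df$sentence_index)) || any(df$sentence_index < 0)) {
    stop("sentence_index must be a non-negative integer")
  }
  bad <- !df$label %in% LABEL_LEVELS
  if (any(bad)) {
    stop("unknown label value(s): ", paste(unique(df$label[bad]), collapse = ", "))
  }
  ok_score <- is.na(df$sentence_score) |
    (df$sentence_score > 0 & df$sentence_score < 1)
  if (!all(ok_score)) stop("sentence_score must lie strictly in (0, 1)")
  check_no_tabs(df$text, "sentence text")
  check_no_tabs(c(df$ns1, df$id1, df$ns2, df$id2, df$document_id),
                "identifier fields")
  if (any(grepl("[|]", c(df$ns1, df$id1, df$ns2, df$id2)))) {
    stop("'|' is reserved and forbidden in namespaces and identifiers")
  }
  if (nrow(df) > 0) {
    cp <- canonicalize_pair(df$ns1, df$id1, df$ns2, df$id2)
    df$ns1 <- cp$ns1; df$id1 <- cp$id1; df$ns2 <- cp$ns2; df$id2 <- cp$id2
    key <- paste(df$document_id, df$sentence_index,
                 pair_key(df$ns1, df$id1, df$ns2, df$id2), sep = "\t")
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key))[1]
      stop(sprintf(
        "duplicate (document_id, sentence_index, pair) at row %d", dup))
    }
    if (check_placeholders) {
      classes <- unique(c(df$ns1, df$ns2))
      ph <- default_placeholders(classes)
      if (!is.null(placeholders)) ph[names(placeholders)] <- placeholders
      has1 <- mapply(grepl, ph[df$ns1], df$text,
                     MoreArgs = list(fixed = TRUE), USE.NAMES = FALSE)
      has2 <- mapply(grepl, ph[df$ns2], df$text,
                     MoreArgs = list(fixed = TRUE), USE.NAMES = FALSE)
      if (!all(has1 & has2)) {
        stop(sprintf(
          "row %d: text lacks a placeholder token for one of its entity classes",
          which(!(has1 & has2))[1]))
      }
    }
  }
  rownames(df) <- NULL
  df
}

#' Pair keys of a co-mention table
#' @param comentions a co-mention data frame (see [as_comentions()]).
#' @return character vector, one canonical pair key per row.
#' @export
comention_pair_keys <- function(comentions) {
  pair_key(comentions$ns1, comentions$id1, comentions$ns2, comentions$id2)
}

empty_comentions <- function() {
  as_comentions(data.frame(document_id = character(), sentence_index = integer(),
                           ns1 = character(), id1 = character(),
                           ns2 = character(), id2 = character(),
                           text = character(), stringsAsFactors = FALSE))
}

split_tsv_lines <- function(lines, n_fields, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; pad rows that are one short and
  # end in a tab
  fields <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) == n_fields - 1 && endsWith(lines[i], "\t")) f <- c(f, "")
    f
  })
  bad <- which(vapply(fields, length, 1L) != n_fields)
  if (length(bad) > 0) {
    stop(sprintf("%s: malformed row at line %d (expected %d fields, got %d)",
                 path, bad[1] + 1L, n_fields, length(fields[[bad[1]]])))
  }
  do.call(rbind, fields)
}

#' Read and write co-mention TSV files
#'
#' The file format is header-first TSV with columns `document_id`,
#' `sentence_index`, `ns1`, `id1`, `ns2`, `id2`, `text` and optionally
#' `label` and `sentence_score` (empty field for a missing score). No
#' quoting is used and tabs are forbidden inside fields, so round trips
#' are exact: `read_comentions(write_comentions(x, path))` reproduces `x`.
#'
#' @param path file path.
#' @inheritParams as_comentions
#' @return `read_comentions`: a validated co-mention data frame.
#' @export
read_comentions <- function(path, placeholders = NULL,
                            check_placeholders = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) return(empty_comentions())
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- COMENTION_COLUMNS[1:7]
  if (length(header) < 7 || !identical(header[1:7], required) ||
      !all(header[-(1:7)] %in% c("label", "sentence_score"))) {
    stop(path, ": unexpected co-mention header: ",
         paste(header, collapse = ", "))
  }
  body <- lines[-1]
  if (length(body) == 0) return(empty_comentions())
  m <- split_tsv_lines(body, length(header), path)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  si <- suppressWarnings(as.integer(df$sentence_index))
  if (any(is.na(si))) {
    stop(sprintf("%s: malformed sentence_index at line %d", path,
                 which(is.na(si))[1] + 1L))
  }
  df$sentence_index <- si
  if ("sentence_score" %in% names(df)) {
    df$sentence_score <- suppressWarnings(
      as.numeric(replace(df$sentence_score, df$sentence_score == "", NA)))
  }
  tryCatch(
    as_comentions(df, placeholders = placeholders,
                  check_placeholders = check_placeholders),
    error = function(e) {
      msg <- conditionMessage(e)
      row <- regmatches(msg, regexpr("row [0-9]+", msg))
      if (length(row) == 1) {
        line <- as.integer(sub("row ", "", row)) + 1L
        stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
      }
      stop(sprintf("%s: %s", path, msg), call. = FALSE)
    })
}

#' @param comentions co-mention data frame to write.
#' @rdname read_comentions
#' @return `write_comentions`: `path`, invisibly.
#' @export
write_comentions <- function(comentions, path) {
  comentions <- as_comentions(comentions, check_placeholders = FALSE)
  score <- ifelse(is.na(comentions$sentence_score), "",
                  sprintf("%.17g", comentions$sentence_score))
  rows <- paste(comentions$document_id, comentions$sentence_index,
                comentions$ns1, comentions$id1, comentions$ns2,
                comentions$id2, comentions$text, comentions$label,
                score, sep = "\t")
  writeLines(c(paste(COMENTION_COLUMNS, collapse = "\t"), rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Construct a gold standard of known entity pairs
#'
#' A gold standard holds a set of positive pairs, a grey list of pairs with
#' ambiguous evidence (excluded from both classes during distant
#' supervision), and the universe of entities known to the gold standard.
#' The entity universe is the union of the entities of all listed pairs
#' plus any explicitly supplied entity keys; during labeling a pair whose
#' entities are both in the universe but which is neither positive nor
#' grey counts as negative.
#'
#' @param positives,grey data frames with columns `ns1`, `id1`, `ns2`,
#'   `id2` (canonicalized here); `grey` may be empty.
#' @param entities optional character vector of extra entity keys
#'   (`"ns:id"`) to include in the universe.
#' @return an object of class `gold_standard` with components `positives`,
#'   `grey` (canonical pair data frames), `positive_keys`, `grey_keys`, and
#'   `entities`.
#' @export
gold_standard <- function(positives, grey = NULL, entities = NULL) {
  canon_df <- function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (nrow(df) == 0) {
      return(data.frame(ns1 = character(), id1 = character(),
                        ns2 = character(), id2 = character(),
                        stringsAsFactors = FALSE))
    }
    cp <- canonicalize_pair(as.character(df$ns1), as.character(df$id1),
                            as.character(df$ns2), as.character(df$id2))
    out <- data.frame(ns1 = cp$ns1, id1 = cp$id1, ns2 = cp$ns2, id2 = cp$id2,
                      stringsAsFactors = FALSE)
    out[!duplicated(pair_key(out$ns1, out$id1, out$ns2, out$id2)), ,
        drop = FALSE]
  }
  if (is.null(grey)) grey <- data.frame()
  pos <- canon_df(positives)
  gry <- canon_df(grey)
  pos_keys <- pair_key(pos$ns1, pos$id1, pos$ns2, pos$id2)
  grey_keys <- pair_key(gry$ns1, gry$id1, gry$ns2, gry$id2)
  overlap <- intersect(pos_keys, grey_keys)
  if (length(overlap) > 0) {
    stop("pair(s) listed as both positive and grey: ",
         paste(head(overlap, 3), collapse = ", "))
  }
  ents <- unique(c(entity_key(pos$ns1, pos$id1), entity_key(pos$ns2, pos$id2),
                   entity_key(gry$ns1, gry$id1), entity_key(gry$ns2, gry$id2),
                   entities))
  structure(list(positives = pos, grey = gry, positive_keys = pos_keys,
                 grey_keys = grey_keys, entities = ents),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf(
    "gold_standard: %d positive pair(s), %d grey pair(s), %d entit(ies)\n",
    nrow(x$positives), nrow(x$grey), length(x$entities)))
  invisible(x)
}

#' Read a gold-standard TSV file
#'
#' Expects header-first TSV with columns `ns1`, `id1`, `ns2`, `id2`,
#' `class` where `class` is `positive` or `grey`.
#'
#' @param path file path.
#' @return a [gold_standard()] object.
#' @export
read_gold <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- c("ns1", "id1", "ns2", "id2", "class")
  if (length(lines) == 0 || !identical(strsplit(lines[1], "\t")[[1]], hdr)) {
    stop(path, ": expected header ", paste(hdr, collapse = "\t"))
  }
  body <- lines[-1]
  if (length(body) == 0) return(gold_standard(data.frame()))
  m <- split_tsv_lines(body, 5L, path)
  cls <- m[, 5]
  bad <- which(!cls %in% c("positive", "grey"))
  if (length(bad) > 0) {
    stop(sprintf("%s: unknown class token '%s' at line %d", path,
                 cls[bad[1]], bad[1] + 1L))
  }
  df <- data.frame(ns1 = m[, 1], id1 = m[, 2], ns2 = m[, 3], id2 = m[, 4],
                   stringsAsFactors = FALSE)
  gold_standard(df[cls == "positive", ], df[cls == "grey", ])
}

#' Write a gold standard to TSV
#' @param gold a [gold_standard()] object.
#' @param path file path.
#' @export
write_gold <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  fmt <- function(df, cls) {
    if (nrow(df) == 0) return(character(0))
    paste(df$ns1, df$id1, df$ns2, df$id2, cls, sep = "\t")
  }
  writeLines(c("ns1\tid1\tns2\tid2\tclass",
               fmt(gold$positives, "positive"), fmt(gold$grey, "grey")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Construct a child-to-parent ontology edge list
#'
#' Edges run from a child term to its parent; both ends of an edge must
#' share a namespace and the edge relation must be acyclic.
#'
#' @param edges data frame with columns `child_ns`, `child_id`,
#'   `parent_ns`, `parent_id`.
#' @return an object of class `ontology`.
#' @export
ontology <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    edges <- data.frame(child_ns = character(), child_id = character(),
                        parent_ns = character(), parent_id = character(),
                        stringsAsFactors = FALSE)
  } else {
    for (col in c("child_ns", "child_id", "parent_ns", "parent_id")) {
      edges[[col]] <- as.character(edges[[col]])
    }
    if (any(edges$child_ns != edges$parent_ns)) {
      stop("ontology edges must connect terms of the same namespace")
    }
    cyc <- find_cycle(entity_key(edges$child_ns, edges$child_id),
                      entity_key(edges$parent_ns, edges$parent_id))
    if (!is.null(cyc)) {
      stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
    }
  }
  structure(list(edges = edges), class = "ontology")
}

# Detect a directed cycle in an edge list; returns one cycle as a vector of
# node keys, or NULL. Iterative colored DFS.
find_cycle <- function(from, to) {
  nodes <- unique(c(from, to))
  adj <- split(match(to, nodes), factor(match(from, nodes),
                                        levels = seq_along(nodes)))
  color <- integer(length(nodes))  # 0 white, 1 grey, 2 black
  parent <- integer(length(nodes))
  for (start in seq_along(nodes)) {
    if (color[start] != 0) next
    stack <- list(c(start, 0L))
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      v <- top[1]; i <- top[2]
      if (i == 0L) color[v] <- 1L
      nbrs <- adj[[v]]
      if (i < length(nbrs)) {
        stack[[length(stack)]][2] <- i + 1L
        u <- nbrs[i + 1L]
        if (color[u] == 1L) {
          path <- v
          w <- v
          while (w != u) { w <- parent[w]; path <- c(w, path) }
          return(nodes[c(path, u)])
        } else if (color[u] == 0L) {
          parent[u] <- v
          stack[[length(stack) + 1L]] <- c(u, 0L)
        }
      } else {
        color[v] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

#' Read an ontology TSV file
#'
#' Expects header-first TSV with columns `child_ns`, `child_id`,
#' `parent_ns`, `parent_id`. Acyclicity is verified; a cycle raises an
#' error listing one offending cycle.
#'
#' @param path file path.
#' @return an [ontology()] object.
#' @export
read_ontology <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- c("child_ns", "child_id", "parent_ns", "parent_id")
  if (length(lines) == 0 || !identical(strsplit(lines[1], "\t")[[1]], hdr)) {
    stop(path, ": expected header ", paste(hdr, collapse = "\t"))
  }
  body <- lines[-1]
  if (length(body) == 0) return(ontology(data.frame()))
  m <- split_tsv_lines(body, 4L, path)
  ontology(data.frame(child_ns = m[, 1], child_id = m[, 2],
                      parent_ns = m[, 3], parent_id = m[, 4],
                      stringsAsFactors = FALSE))
}

#' Write an ontology to TSV
#' @param ont an [ontology()] object.
#' @param path file path.
#' @export
write_ontology <- function(ont, path) {
  stopifnot(inherits(ont, "ontology"))
  e <- ont$edges
  rows <- if (nrow(e) == 0) character(0) else
    paste(e$child_ns, e$child_id, e$parent_ns, e$parent_id, sep = "\t")
  writeLines(c("child_ns\tchild_id\tparent_ns\tparent_id", rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Blank entity names in a raw sentence
#'
#' Replaces each entity span by the placeholder token configured for its
#' entity class, leaving all other text unchanged. Spans are 0-based,
#' half-open character offsets into `text` and must be non-overlapping and
#' in range.
#'
#' @param text a single raw sentence.
#' @param spans data frame with columns `start`, `end`, `class` (0-based,
#'   half-open offsets).
#' @param placeholders named character vector mapping entity classes to
#'   placeholder tokens; defaults to [default_placeholders()].
#' @return the blanked sentence.
#' @export
blank_sentence <- function(text, spans, placeholders = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  spans <- as.data.frame(spans, stringsAsFactors = FALSE)
  if (nrow(spans) == 0) return(text)
  if (any(spans$start < 0 | spans$end > nchar(text) |
          spans$start >= spans$end)) {
    stop("span out of range")
  }
  o <- order(spans$start)
  spans <- spans[o, , drop = FALSE]
  if (nrow(spans) > 1 &&
      any(spans$end[-nrow(spans)] > spans$start[-1])) {
    stop("overlapping entity spans")
  }
  ph <- default_placeholders(unique(spans$class))
  if (!is.null(placeholders)) ph[names(placeholders)] <- placeholders
  out <- text
  for (i in rev(seq_len(nrow(spans)))) {
    out <- paste0(substr(out, 1, spans$start[i]),
                  ph[[spans$class[i]]],
                  substr(out, spans$end[i] + 1, nchar(out)))
  }
  out
}
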