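# Implicit multihop relation derivation for deep ontologies.
#
# In nonshallow ontologies (e.g. computational-chemistry calculation chains)
# the property of a species can sit several hops from the species entity.
# Deriving the composite relations ahead of training, and materializing one
# triple per realizing entity path, lets the embedding model answer such
# multihop questions as if they were 1-hop.
#
# Paths are simple (no repeated entities), which keeps the derived triple
# set finite on cyclic graphs; composite labels join the step relations with
# the reserved separator "|", inverse steps carrying a "^" prefix.

composite_label <- function(relations, inverse) {
  paste(ifelse(inverse, paste0("^", relations), relations), collapse = "|")
}

# adjacency list: for each entity, a matrix of (relation id, neighbor id,
# inverse flag)
kg_adjacency <- function(kg, allow_inverse) {
  tri <- kg$triples
  # composite relations (containing '|') are excluded from the path alphabet
  plain <- !grepl("|", kg$relations[tri[, 2L]], fixed = TRUE)
  tri <- tri[plain, , drop = FALSE]
  n <- length(kg$entities)
  edges <- cbind(from = tri[, 1L], rel = tri[, 2L], to = tri[, 3L], inv = 0L)
  if (allow_inverse)
    edges <- rbind(edges,
                   cbind(from = tri[, 3L], rel = tri[, 2L], to = tri[, 1L], inv = 1L))
  split.data.frame(edges[, c("rel", "to", "inv"), drop = FALSE],
                   factor(edges[, "from"], levels = seq_len(n)))
}

# depth-first enumeration of simple paths up to max_hops; `visit` is called
# with (start, end, rel_ids, inv_flags) for every path of length >= 2
walk_paths <- function(adj, n_entities, max_hops, visit) {
  rel_path <- integer(max_hops); inv_path <- integer(max_hops)
  recurse <- function(start, node, depth, visited) {
    nbrs <- adj[[node]]
    if (nrow(nbrs) == 0L) return()
    for (k in seq_len(nrow(nbrs))) {
      to <- nbrs[k, "to"]
      if (visited[to]) next
      rel_path[depth] <<- nbrs[k, "rel"]; inv_path[depth] <<- nbrs[k, "inv"]
      if (depth >= 2L)
        visit(start, to, rel_path[seq_len(depth)], inv_path[seq_len(depth)])
      if (depth < max_hops) {
        visited[to] <- TRUE
        recurse(start, to, depth + 1L, visited)
        visited[to] <- FALSE
      }
    }
  }
  for (s in seq_len(n_entities)) {
    visited <- logical(n_entities); visited[s] <- TRUE
    recurse(s, s, 1L, visited)
  }
}

#' Enumerate composite relation paths realized in a graph
#'
#' Finds every relation-type path of length 2..`max_hops` realized by at
#' least `min_support` distinct simple entity paths, traversing edges
#' forward (and optionally inverse, with marked steps).
#'
#' @param kg a knowledge_graph.
#' @param max_hops maximum path length (>= 2).
#' @param min_support minimum number of distinct realizing simple entity
#'   paths.
#' @param allow_inverse permit traversing edges against their direction;
#'   inverse steps are prefixed `"^"` in the composite label. Off by default
#'   (calculation-chain ontologies point forward).
#' @return data.frame with columns `label` (composite label), `length`,
#'   `support`, sorted by label; attribute `"paths"` holds the per-path
#'   relation id / inverse flag lists.
#' @export
enumerate_relation_paths <- function(kg, max_hops = 2L, min_support = 1L,
                                     allow_inverse = FALSE) {
  if (max_hops < 2L) stop("max_hops must be >= 2", call. = FALSE)
  adj <- kg_adjacency(kg, allow_inverse)
  counts <- new.env(parent = emptyenv())
  paths <- new.env(parent = emptyenv())
  visit <- function(start, end, rels, invs) {
    lab <- composite_label(kg$relations[rels], invs == 1L)
    counts[[lab]] <- (counts[[lab]] %||% 0L) + 1L
    if (is.null(paths[[lab]]))
      paths[[lab]] <- list(relations = rels, inverse = invs == 1L)
  }
  walk_paths(adj, length(kg$entities), max_hops, visit)
  labs <- sort(ls(counts))
  support <- vapply(labs, function(l) counts[[l]], integer(1))
  keep <- support >= min_support
  labs <- labs[keep]; support <- support[keep]
  out <- data.frame(label = labs,
                    length = vapply(labs, function(l) length(paths[[l]]$relations),
                                    integer(1)),
                    support = unname(support),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "paths") <- lapply(labs, function(l) paths[[l]])
  out
}

#' Materialize implicit multihop triples
#'
#' For each derived composite relation and each simple entity path realizing
#' it, emits one triple (path start, composite label, path end),
#' deduplicated. The original graph is untouched; use [kg_add_triples()] to
#' augment it for training.
#'
#' @param kg the knowledge_graph the relations were enumerated on.
#' @param derived output of [enumerate_relation_paths()], or a character
#'   vector of composite labels built from `kg`'s relation IRIs.
#' @param max_hops used only when `derived` is a character vector.
#' @return data.frame of triples (head, relation, tail) in IRI space.
#' @export
derive_implicit_triples <- function(kg, derived, max_hops = NULL) {
  empty <- data.frame(head = character(), relation = character(),
                      tail = character(), stringsAsFactors = FALSE)
  if (NROW(derived) == 0L && length(derived) == 0L) return(empty)
  if (is.data.frame(derived) && nrow(derived) == 0L) return(empty)
  if (is.character(derived)) {
    labels <- derived
    steps <- strsplit(derived, "|", fixed = TRUE)
    max_hops <- max_hops %||% max(lengths(steps))
    for (s in unlist(steps)) {
      s0 <- sub("^\\^", "", s)
      if (!s0 %in% kg$relations)
        stop_kgqa(sprintf("unknown relation in composite label: %s", s0),
                  "kgqa_relation_not_found")
    }
    allow_inverse <- any(startsWith(unlist(steps), "^"))
  } else {
    labels <- derived$label
    pl <- attr(derived, "paths")
    for (p in pl)
      if (any(p$relations < 1L | p$relations > length(kg$relations)))
        stop_kgqa("derived relation references an unknown relation id",
                  "kgqa_relation_not_found")
    max_hops <- max_hops %||% max(derived$length)
    allow_inverse <- any(vapply(pl, function(p) any(p$inverse), logical(1)))
  }
  if (length(labels) == 0L)
    return(data.frame(head = character(), relation = character(),
                      tail = character(), stringsAsFactors = FALSE))
  wanted <- new.env(parent = emptyenv())
  for (l in labels) wanted[[l]] <- TRUE
  acc <- new.env(parent = emptyenv())
  adj <- kg_adjacency(kg, allow_inverse)
  visit <- function(start, end, rels, invs) {
    lab <- composite_label(kg$relations[rels], invs == 1L)
    if (!isTRUE(wanted[[lab]])) return()
    key <- paste(start, lab, end, sep = "\r")
    acc[[key]] <- c(start, end, match(lab, labels))
  }
  walk_paths(adj, length(kg$entities), max_hops, visit)
  keys <- ls(acc)
  if (length(keys) == 0L)
    return(data.frame(head = character(), relation = character(),
                      tail = character(), stringsAsFactors = FALSE))
  m <- do.call(rbind, lapply(keys, function(k) acc[[k]]))
  out <- data.frame(head = kg$entities[m[, 1L]],
                    relation = labels[m[, 3L]],
                    tail = kg$entities[m[, 2L]], stringsAsFactors = FALSE)
  out <- out[order(out$head, out$relation, out$tail), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive and attach composite multihop triples in one step
#'
#' @param kg a knowledge_graph.
#' @inheritParams enumerate_relation_paths
#' @return the augmented knowledge_graph; derived relations are appended to
#'   the relation vocabulary.
#' @export
augment_with_multihop <- function(kg, max_hops = 2L, min_support = 1L,
                                  allow_inverse = FALSE) {
  derived <- enumerate_relation_paths(kg, max_hops, min_support, allow_inverse)
  kg_add_triples(kg, derive_implicit_triples(kg, derived))
}
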