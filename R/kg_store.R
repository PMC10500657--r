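# Knowledge-graph container and I/O.
#
# A knowledge_graph holds relation triples (head, relation, tail), numeric
# attribute triples (entity, attribute, value, unit) and an entity label table.
# Entities, relations and attributes are indexed by contiguous 1-based integer
# ids assigned in first-seen order; all triple storage is in id space.

#' Construct a knowledge graph
#'
#' Builds an indexed knowledge graph from character-level triple tables.
#' Entity, relation and attribute vocabularies are assigned contiguous integer
#' ids in first-seen order (heads before tails, relation triples before
#' attribute triples). Duplicate relation triples are collapsed.
#'
#' @param triples data.frame with character columns `head`, `relation`, `tail`
#'   (IRIs or any identifier strings). May have zero rows.
#' @param attr_triples optional data.frame with columns `entity`, `attribute`,
#'   `value` (numeric, finite) and optionally `unit`.
#' @param labels optional data.frame with columns `iri`, `label`, `type`,
#'   `aliases` (aliases pipe-separated in one string).
#' @param ontology label naming the ontology this graph represents.
#' @param check_reserved reject relation/attribute IRIs containing `"|"`
#'   (the composite-relation separator). Disabled internally when re-building
#'   a graph augmented with derived composite relations.
#' @return An object of class `knowledge_graph` with components `entities`,
#'   `relations`, `attributes` (character vectors; position = id), `triples`
#'   (integer matrix, columns head/relation/tail), `attr_triples` (data.frame
#'   in id space with `value`, `unit`), `labels`, `ontology`.
#' @details Relation and attribute IRIs must not contain the reserved
#'   character `"|"`, which separates steps in composite multihop relation
#'   labels (see [enumerate_relation_paths()]).
#' @export
knowledge_graph <- function(triples = NULL, attr_triples = NULL, labels = NULL,
                            ontology = "kg", check_reserved = TRUE) {
  if (is.null(triples))
    triples <- data.frame(head = character(), relation = character(),
                          tail = character(), stringsAsFactors = FALSE)
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  stopifnot(all(c("head", "relation", "tail") %in% names(triples)))
  if (!is.null(attr_triples)) {
    attr_triples <- as.data.frame(attr_triples, stringsAsFactors = FALSE)
    stopifnot(all(c("entity", "attribute", "value") %in% names(attr_triples)))
    if (is.null(attr_triples$unit)) attr_triples$unit <- ""
    if (nrow(attr_triples) && !is.numeric(attr_triples$value))
      stop("attribute values must be numeric", call. = FALSE)
    if (nrow(attr_triples) && any(!is.finite(attr_triples$value)))
      stop("attribute values must be finite", call. = FALSE)
  } else {
    attr_triples <- data.frame(entity = character(), attribute = character(),
                               value = numeric(), unit = character(),
                               stringsAsFactors = FALSE)
  }

  rels <- unique(as.character(triples$relation))
  attrs <- unique(as.character(attr_triples$attribute))
  if (check_reserved && any(grepl("|", c(rels, attrs), fixed = TRUE)))
    stop("relation/attribute IRIs must not contain the reserved character '|'",
         call. = FALSE)

  # first-seen entity order: row-wise head then tail, then attribute entities
  ent_seen <- as.character(t(cbind(as.character(triples$head),
                                   as.character(triples$tail))))
  entities <- unique(c(ent_seen, as.character(attr_triples$entity)))

  tri <- cbind(head = match(as.character(triples$head), entities),
               relation = match(as.character(triples$relation), rels),
               tail = match(as.character(triples$tail), entities))
  storage.mode(tri) <- "integer"
  tri <- unique(tri)

  at <- data.frame(entity = match(as.character(attr_triples$entity), entities),
                   attribute = match(as.character(attr_triples$attribute), attrs),
                   value = as.numeric(attr_triples$value),
                   unit = as.character(attr_triples$unit),
                   stringsAsFactors = FALSE)
  at <- at[!duplicated(at[, c("entity", "attribute", "value")]), , drop = FALSE]
  rownames(at) <- NULL

  if (is.null(labels)) {
    labels <- data.frame(iri = character(), label = character(),
                         type = character(), aliases = character(),
                         stringsAsFactors = FALSE)
  } else {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    stopifnot(all(c("iri", "label") %in% names(labels)))
    if (is.null(labels$type)) labels$type <- ""
    if (is.null(labels$aliases)) labels$aliases <- ""
    labels <- labels[, c("iri", "label", "type", "aliases")]
  }

  structure(list(ontology = ontology, entities = entities, relations = rels,
                 attributes = attrs, triples = tri, attr_triples = at,
                 labels = labels),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf(
    "<knowledge_graph '%s': %d entities, %d relations, %d triples, %d attribute triples>\n",
    x$ontology, length(x$entities), length(x$relations), nrow(x$triples),
    nrow(x$attr_triples)))
  invisible(x)
}

#' Resolve an entity IRI or id to an integer id
#'
#' @param kg a knowledge_graph.
#' @param entity entity IRI (character) or 1-based integer id.
#' @return integer id; errors with class `kgqa_entity_not_found` if unknown.
#' @export
entity_id <- function(kg, entity) {
  if (is.character(entity)) {
    id <- match(entity, kg$entities)
  } else {
    id <- as.integer(entity)
    id[id < 1L | id > length(kg$entities)] <- NA_integer_
  }
  if (anyNA(id))
    stop_kgqa(sprintf("entity not found: %s",
                      paste(entity[is.na(id)], collapse = ", ")),
              "kgqa_entity_not_found")
  id
}

relation_id <- function(kg, relation) {
  if (is.character(relation)) id <- match(relation, kg$relations)
  else id <- as.integer(relation)
  if (anyNA(id) || any(id < 1L | id > length(kg$relations)))
    stop_kgqa(sprintf("relation not found: %s", paste(relation, collapse = ", ")),
              "kgqa_relation_not_found")
  id
}

attribute_id <- function(kg, attribute) {
  if (is.character(attribute)) id <- match(attribute, kg$attributes)
  else id <- as.integer(attribute)
  if (anyNA(id) || any(id < 1L | id > length(kg$attributes)))
    stop_kgqa(sprintf("attribute not found: %s", paste(attribute, collapse = ", ")),
              "kgqa_attribute_not_found")
  id
}

triple_keys <- function(tri) {
  paste(tri[, 1L], tri[, 2L], tri[, 3L], sep = "\r")
}

#' Parse triples into a knowledge graph
#'
#' Reads the TSV dialects or the N-Triples subset. In the TSV dialect,
#' relation triples, attribute triples and labels live in separate sections
#' passed as separate character vectors; in the N-Triples subset a single
#' stream mixes relation statements `<iri> <iri> <iri> .` and attribute
#' statements `<iri> <iri> "number"^^xsd:double .`.
#'
#' @param text character vector of lines: the relation TSV (with header
#'   `head\\trelation\\ttail`) for `format = "tsv"`, or the full N-Triples
#'   stream for `format = "ntriples"`.
#' @param format `"tsv"` or `"ntriples"`.
#' @param attr_text optional attribute TSV lines (header
#'   `entity\\tattribute\\tvalue\\tunit`); TSV format only.
#' @param labels_text optional labels TSV lines (header
#'   `iri\\tlabel\\ttype\\taliases`, aliases pipe-separated).
#' @param ontology ontology label for the resulting graph.
#' @return a [knowledge_graph()].
#' @export
parse_kg <- function(text, format = c("tsv", "ntriples"), attr_text = NULL,
                     labels_text = NULL, ontology = "kg") {
  format <- match.arg(format)
  if (format == "tsv")
    parse_kg_tsv(text, attr_text, labels_text, ontology)
  else
    parse_kg_ntriples(text, ontology)
}

parse_tsv_section <- function(lines, expected_header, what) {
  if (length(lines) == 0L)
    stop(sprintf("%s section is empty (missing header)", what), call. = FALSE)
  if (!identical(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]], expected_header))
    stop(sprintf("%s line 1: expected header '%s'", what,
                 paste(expected_header, collapse = "\\t")), call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    out <- as.data.frame(matrix(character(), 0, length(expected_header)),
                         stringsAsFactors = FALSE)
    names(out) <- expected_header
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  # a trailing empty field (e.g. empty unit) is dropped by strsplit; restore it
  short_ok <- nf == length(expected_header) - 1L &
    endsWith(body, "\t")
  parts[short_ok] <- lapply(parts[short_ok], function(p) c(p, ""))
  nf <- lengths(parts)
  bad <- which(nf != length(expected_header))
  if (length(bad))
    stop(sprintf("%s line %d: expected %d tab-separated fields, found %d",
                 what, bad[1L] + 1L, length(expected_header), nf[bad[1L]]),
         call. = FALSE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- expected_header
  out
}

parse_kg_tsv <- function(text, attr_text, labels_text, ontology) {
  tri <- parse_tsv_section(text, c("head", "relation", "tail"), "relation TSV")
  at <- NULL
  if (!is.null(attr_text)) {
    at <- parse_tsv_section(attr_text, c("entity", "attribute", "value", "unit"),
                            "attribute TSV")
    if (nrow(at)) {
      v <- suppressWarnings(as.numeric(at$value))
      bad <- which(!is.finite(v))
      if (length(bad))
        stop(sprintf("attribute TSV line %d: non-numeric attribute value '%s'",
                     bad[1L] + 1L, at$value[bad[1L]]), call. = FALSE)
      at$value <- v
    } else at$value <- numeric(0)
  }
  lab <- NULL
  if (!is.null(labels_text))
    lab <- parse_tsv_section(labels_text, c("iri", "label", "type", "aliases"),
                             "labels TSV")
  knowledge_graph(tri, at, lab, ontology)
}

parse_kg_ntriples <- function(text, ontology) {
  lines <- text[nzchar(trimws(text))]
  re_rel <- "^<([^<>\"]*)> <([^<>\"]*)> <([^<>\"]*)> \\.$"
  re_attr <- "^<([^<>\"]*)> <([^<>\"]*)> \"([^\"]*)\"\\^\\^xsd:double \\.$"
  is_rel <- grepl(re_rel, lines)
  is_attr <- !is_rel & grepl(re_attr, lines)
  bad <- which(!is_rel & !is_attr)
  if (length(bad)) {
    orig <- match(lines[bad[1L]], text)
    stop(sprintf("N-Triples line %d: not a relation or xsd:double attribute statement: '%s'",
                 orig, lines[bad[1L]]), call. = FALSE)
  }
  rel_m <- regmatches(lines[is_rel], regexec(re_rel, lines[is_rel]))
  at_m <- regmatches(lines[is_attr], regexec(re_attr, lines[is_attr]))
  tri <- data.frame(
    head = vapply(rel_m, `[`, "", 2L),
    relation = vapply(rel_m, `[`, "", 3L),
    tail = vapply(rel_m, `[`, "", 4L), stringsAsFactors = FALSE)
  vals <- suppressWarnings(as.numeric(vapply(at_m, `[`, "", 4L)))
  if (length(vals) && any(!is.finite(vals))) {
    first <- which(!is.finite(vals))[1L]
    stop(sprintf("N-Triples: non-numeric attribute value '%s'",
                 vapply(at_m, `[`, "", 4L)[first]), call. = FALSE)
  }
  at <- data.frame(
    entity = vapply(at_m, `[`, "", 2L),
    attribute = vapply(at_m, `[`, "", 3L),
    value = vals, unit = rep("", length(vals)), stringsAsFactors = FALSE)
  knowledge_graph(tri, at, NULL, ontology)
}

#' Serialize a knowledge graph
#'
#' Deterministic, canonical serialization: rows are sorted lexicographically
#' by their IRI strings (head, relation, tail; entity, attribute, value), so
#' the output is independent of the order in which ids were assigned and
#' `write(parse(write(kg)))` is byte-stable.
#'
#' @param kg a knowledge_graph.
#' @param format `"tsv"` or `"ntriples"`.
#' @return for `"tsv"`, a list of character vectors `relations`, `attributes`,
#'   `labels` (each with header line); for `"ntriples"`, one character vector.
#'   N-Triples drops units (the dialect has no unit slot).
#' @export
write_kg <- function(kg, format = c("tsv", "ntriples")) {
  format <- match.arg(format)
  tri <- kg$triples
  h <- kg$entities[tri[, 1L]]; r <- kg$relations[tri[, 2L]]
  t <- kg$entities[tri[, 3L]]
  ord <- order(h, r, t, method = "radix")
  h <- h[ord]; r <- r[ord]; t <- t[ord]
  at <- kg$attr_triples
  at <- at[order(kg$entities[at$entity], kg$attributes[at$attribute],
                 at$value, method = "radix"), , drop = FALSE]
  if (format == "tsv") {
    lab <- kg$labels
    if (nrow(lab)) lab <- lab[order(lab$iri, method = "radix"), , drop = FALSE]
    list(
      relations = c("head\trelation\ttail",
                    if (nrow(tri)) paste(h, r, t, sep = "\t")),
      attributes = c("entity\tattribute\tvalue\tunit",
                     if (nrow(at)) paste(kg$entities[at$entity],
                                         kg$attributes[at$attribute],
                                         format(at$value, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         at$unit, sep = "\t")),
      labels = c("iri\tlabel\ttype\taliases",
                 if (nrow(lab)) paste(lab$iri, lab$label, lab$type, lab$aliases,
                                      sep = "\t")))
  } else {
    c(if (nrow(tri)) sprintf("<%s> <%s> <%s> .", h, r, t),
      if (nrow(at)) sprintf("<%s> <%s> \"%s\"^^xsd:double .",
                            kg$entities[at$entity], kg$attributes[at$attribute],
                            format(at$value, digits = 17, trim = TRUE,
                                   scientific = FALSE)))
  }
}

#' Save / load a knowledge graph as TSV files in a directory
#'
#' Writes `relations.tsv`, `attributes.tsv`, `labels.tsv`.
#' @param kg a knowledge_graph.
#' @param dir directory path (created if missing).
#' @return `save_kg` the directory, invisibly; `load_kg` a knowledge_graph.
#' @export
save_kg <- function(kg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- write_kg(kg, "tsv")
  writeLines(out$relations, file.path(dir, "relations.tsv"))
  writeLines(out$attributes, file.path(dir, "attributes.tsv"))
  writeLines(out$labels, file.path(dir, "labels.tsv"))
  writeLines(kg$ontology, file.path(dir, "ontology.txt"))
  invisible(dir)
}

#' @rdname save_kg
#' @export
load_kg <- function(dir) {
  ont_file <- file.path(dir, "ontology.txt")
  ontology <- if (file.exists(ont_file)) readLines(ont_file)[1L] else basename(dir)
  lab_file <- file.path(dir, "labels.tsv")
  at_file <- file.path(dir, "attributes.tsv")
  parse_kg(readLines(file.path(dir, "relations.tsv")), "tsv",
           attr_text = if (file.exists(at_file)) readLines(at_file),
           labels_text = if (file.exists(lab_file)) readLines(lab_file),
           ontology = ontology)
}

kg_igraph <- function(kg) {
  edges <- as.vector(t(kg$triples[, c(1L, 3L), drop = FALSE]))
  igraph::make_graph(edges, n = length(kg$entities), directed = TRUE)
}

#' Entities within n hops of a head entity (the subgraph agent)
#'
#' Returns all entities reachable from `head` by 1..n edges, traversing edges
#' forward only or in both directions. The head itself is excluded.
#'
#' @param kg a knowledge_graph.
#' @param head entity IRI or id.
#' @param n maximum number of hops (>= 1).
#' @param direction `"both"` (default; answers in deep ontologies may sit on
#'   inverse paths) or `"forward"`.
#' @return sorted integer vector of entity ids, named by IRI.
#' @export
n_hop_neighbors <- function(kg, head, n = 1L, direction = c("both", "forward")) {
  direction <- match.arg(direction)
  id <- entity_id(kg, head)
  stopifnot(length(id) == 1L, n >= 1L)
  g <- kg_igraph(kg)
  mode <- if (direction == "forward") "out" else "all"
  nb <- igraph::ego(g, order = n, nodes = id, mode = mode)[[1L]]
  ids <- sort(setdiff(as.integer(nb), id))
  stats::setNames(ids, kg$entities[ids])
}

#' Numeric attribute values of one entity (the lateral lookup agent)
#'
#' @param kg a knowledge_graph.
#' @param entity entity IRI or id.
#' @return data.frame with columns `attribute` (IRI), `value`, `unit`;
#'   zero rows when the entity carries no attributes.
#' @export
lateral_lookup <- function(kg, entity) {
  id <- entity_id(kg, entity)
  rows <- kg$attr_triples[kg$attr_triples$entity == id, , drop = FALSE]
  data.frame(attribute = kg$attributes[rows$attribute],
             value = rows$value, unit = rows$unit,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Validate knowledge-graph invariants
#'
#' Checks index bijectivity/contiguity, that every triple references indexed
#' items, absence of duplicate triples and finiteness of attribute values.
#' @param kg a knowledge_graph.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_kg <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"),
            !anyDuplicated(kg$entities), !anyDuplicated(kg$relations),
            !anyDuplicated(kg$attributes))
  tri <- kg$triples
  stopifnot(is.integer(tri),
            all(tri[, c(1L, 3L)] >= 1L), all(tri[, c(1L, 3L)] <= length(kg$entities)),
            all(tri[, 2L] >= 1L | nrow(tri) == 0L),
            all(tri[, 2L] <= length(kg$relations) | nrow(tri) == 0L),
            !anyDuplicated(triple_keys(tri)))
  at <- kg$attr_triples
  stopifnot(all(at$entity >= 1L & at$entity <= length(kg$entities)),
            all(at$attribute >= 1L & at$attribute <= length(kg$attributes)),
            all(is.finite(at$value)))
  invisible(TRUE)
}

#' Merge additional relation triples into a knowledge graph
#'
#' Used to augment a graph with derived composite-relation triples; the
#' original triples are untouched and new relations are appended to the
#' relation vocabulary.
#'
#' @param kg a knowledge_graph.
#' @param triples data.frame with character columns head, relation, tail.
#'   Head and tail must already be indexed entities.
#' @return a new knowledge_graph.
#' @export
kg_add_triples <- function(kg, triples) {
  if (nrow(triples) == 0L) return(kg)
  entity_id(kg, unique(c(triples$head, triples$tail)))  # must exist
  old <- triples_chr(kg)
  knowledge_graph(rbind(old, triples[, c("head", "relation", "tail")]),
                  attr_df_chr(kg), kg$labels, kg$ontology,
                  check_reserved = FALSE)
}

attr_df_chr <- function(kg) {
  at <- kg$attr_triples
  if (nrow(at) == 0L) return(NULL)
  data.frame(entity = kg$entities[at$entity],
             attribute = kg$attributes[at$attribute],
             value = at$value, unit = at$unit, stringsAsFactors = FALSE)
}

triples_chr <- function(kg) {
  data.frame(head = kg$entities[kg$triples[, 1L]],
             relation = kg$relations[kg$triples[, 2L]],
             tail = kg$entities[kg$triples[, 3L]],
             stringsAsFactors = FALSE)
}
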