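# Per-ontology QA workflow: fuzzy entity linking over the label table,
# template-based relation prediction, n-hop candidate extraction,
# hypothetical-triple scoring, and the two-round numerical filter.

#' Structured question specification
#'
#' @param question_text optional natural-language question.
#' @param head_entity entity IRI or unresolved textual mention.
#' @param relation relation IRI or unresolved relation text.
#' @param numeric_filter optional list(operator, value, unit, tolerance)
#'   with operator in `"larger"`, `"smaller"`, `"close"`; `tolerance` is
#'   required (> 0) for `"close"` and defaults to 5% of |value|.
#' @param hops candidate-extraction hop limit n.
#' @param top_k answers to return (k >= 1).
#' @return object of class `question_spec`.
#' @export
question_spec <- function(question_text = NULL, head_entity = NULL,
                          relation = NULL, numeric_filter = NULL,
                          hops = 3L, top_k = 10L) {
  if (is.null(question_text) && is.null(head_entity))
    stop("at least one of question_text / head_entity is required",
         call. = FALSE)
  stopifnot(top_k >= 1L, hops >= 1L)
  if (!is.null(numeric_filter)) {
    stopifnot(numeric_filter$operator %in% c("larger", "smaller", "close"))
    assert_scalar_number(numeric_filter$value, "numeric_filter$value")
    if (numeric_filter$operator == "close") {
      numeric_filter$tolerance <- numeric_filter$tolerance %||%
        (0.05 * abs(numeric_filter$value))
      stopifnot(numeric_filter$tolerance > 0)
    }
  }
  structure(list(question_text = question_text, head_entity = head_entity,
                 relation = relation, numeric_filter = numeric_filter,
                 hops = as.integer(hops), top_k = as.integer(top_k)),
            class = "question_spec")
}

# one row per candidate string (label, alias), mapping back to entity id
label_index <- function(kg) {
  lab <- kg$labels
  if (nrow(lab) == 0L)
    return(data.frame(entity = integer(), text = character(),
                      type = character(), stringsAsFactors = FALSE))
  ids <- match(lab$iri, kg$entities)
  keep <- !is.na(ids)
  lab <- lab[keep, , drop = FALSE]; ids <- ids[keep]
  alias_lists <- strsplit(lab$aliases, "|", fixed = TRUE)
  n_alias <- lengths(alias_lists)
  idx <- data.frame(
    entity = c(ids, rep(ids, n_alias)),
    text = c(lab$label, unlist(alias_lists)),
    type = c(lab$type, rep(lab$type, n_alias)),
    stringsAsFactors = FALSE)
  idx[nzchar(idx$text), , drop = FALSE]
}

#' Fuzzy entity linking over labels, formulas and aliases
#'
#' Ranks entities by normalized edit similarity between the mention and any
#' of the entity's label strings (primary label and pipe-separated aliases,
#' which may include formulas). An exact label match scores 1.0.
#'
#' @param mention mention text (or a short question containing little more
#'   than the mention).
#' @param kg knowledge_graph with a label table.
#' @param threshold minimum similarity in `[0, 1]`.
#' @return data.frame (possibly zero rows = explicit no-match) with columns
#'   `entity` (id), `iri`, `similarity`, `matched_label`, `type`, sorted by
#'   decreasing similarity with deterministic tie-break by entity id.
#' @export
link_entity_fuzzy <- function(mention, kg, threshold = 0.6) {
  idx <- label_index(kg)
  if (nrow(idx) == 0L)
    return(data.frame(entity = integer(), iri = character(),
                      similarity = numeric(), matched_label = character(),
                      type = character(), stringsAsFactors = FALSE))
  sim <- string_similarity(mention, idx$text)
  # best string per entity
  ord <- order(idx$entity, -sim)
  first <- !duplicated(idx$entity[ord])
  best <- ord[first]
  out <- data.frame(entity = idx$entity[best], iri = kg$entities[idx$entity[best]],
                    similarity = sim[best], matched_label = idx$text[best],
                    type = idx$type[best], stringsAsFactors = FALSE)
  out <- out[out$similarity >= threshold, , drop = FALSE]
  out <- out[order(-out$similarity, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default question templates for a knowledge graph
#'
#' One template per relation, phrased from the relation IRI's final segment
#' (e.g. `ont:boiling_point` -> "what is the boiling point of {entity}?").
#'
#' @param kg a knowledge_graph.
#' @return data.frame with columns `relation`, `template` (containing the
#'   `{entity}` placeholder).
#' @export
default_templates <- function(kg) {
  words <- gsub("[_-]", " ", sub(".*[:/#]", "", kg$relations))
  data.frame(relation = kg$relations,
             template = sprintf("what is the %s of {entity}?", words),
             stringsAsFactors = FALSE)
}

#' Predict the relation embedding for a question
#'
#' The default predictor matches the question against per-relation question
#' templates by token overlap (entity placeholders removed); the matched
#' relation's embedding row is returned exactly. This defines the contract a
#' learned relation predictor plugs into.
#'
#' @param question_text the question.
#' @param kg knowledge_graph.
#' @param space embedding_space for `kg`.
#' @param templates data.frame (relation, template); defaults to
#'   [default_templates()].
#' @param threshold minimum token-overlap score to accept a match.
#' @return list with `relation` (IRI), `relation_id`, `embedding` (the
#'   relation's embedding row; for ComplEx a list of real/imaginary parts),
#'   `score`; or `NULL` when no template matches (unresolved relation).
#' @export
predict_relation_embedding <- function(question_text, kg, space,
                                       templates = default_templates(kg),
                                       threshold = 0.5) {
  qt <- tokenize(question_text)
  stopwords <- c("what", "is", "the", "of", "a", "an", "for", "which", "does",
                 "it", "do", "how")
  scores <- vapply(templates$template, function(tpl) {
    tt <- setdiff(tokenize(gsub("\\{entity\\}", " ", tpl)), stopwords)
    if (length(tt) == 0L) return(0)
    length(intersect(tt, qt)) / length(tt)
  }, numeric(1))
  best <- which(scores == max(scores))[1L]
  if (scores[best] < threshold) return(NULL)
  rel <- templates$relation[best]
  rid <- match(rel, space$relations)
  if (is.na(rid)) return(NULL)
  emb <- if (space$method == "ComplEx")
    list(re = space$rel[rid, ], im = space$rel_im[rid, ]) else space$rel[rid, ]
  list(relation = rel, relation_id = rid, embedding = emb,
       score = unname(scores[best]))
}

#' Parse a numerical qualifier from a question
#'
#' Recognizes the filtering qualifiers "larger", "smaller" and "close to"
#' (and common synonyms; a bare "at <value> <unit>" qualifier counts as
#' "close") with a numeric value and an optional trailing unit token. Units
#' are kept as literal text; no unit conversion is attempted.
#'
#' @param question_text the question.
#' @return list(operator, value, unit); `NULL` when no number is present;
#'   operator `"unresolved"` when a number is present but no qualifier is
#'   recognized.
#' @export
parse_numeric_operator <- function(question_text) {
  q <- normalize_text(question_text)
  num_re <- "[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?"
  m <- regexpr(num_re, q)
  if (m < 0) return(NULL)
  value <- as.numeric(regmatches(q, m))
  after <- substring(q, m + attr(m, "match.length"))
  unit <- regmatches(after, regexpr("^ ?([a-zA-Z%][a-zA-Z0-9/^%.-]*)", after))
  unit <- if (length(unit)) trimws(unit) else ""
  if (unit %in% c("and", "or", "of", "in", "to", "than")) unit <- ""
  before <- substring(q, 1L, m - 1L)
  op <-
    if (grepl("(larger|greater|bigger|higher|more|above|over)( than)? ?$", before))
      "larger"
    else if (grepl("(smaller|less|lower|fewer|below|under)( than)? ?$", before))
      "smaller"
    else if (grepl("(close to|about|around|approximately|near|at) ?$", before))
      "close"
    else "unresolved"
  list(operator = op, value = value, unit = unit)
}

resolve_head <- function(spec, kg, link_threshold = 0.6) {
  head <- spec$head_entity
  if (!is.null(head) && head %in% kg$entities) return(match(head, kg$entities))
  mention <- head %||% spec$question_text
  linked <- link_entity_fuzzy(mention, kg, threshold = link_threshold)
  if (nrow(linked) == 0L)
    stop_kgqa(sprintf("could not link head entity for: %s", mention),
              "kgqa_entity_not_found")
  linked$entity[1L]
}

#' Answer a structured question against one embedding space
#'
#' The QA workflow for one ontology: resolve the head entity (directly or by
#' fuzzy linking), resolve the relation (IRI lookup or template prediction),
#' extract candidate answers within n hops of the head, score each
#' hypothetical triple (h, r, a') under the space's score function, and
#' return the top-k candidates with their numeric attribute values attached.
#'
#' @param spec a [question_spec()].
#' @param kg knowledge_graph.
#' @param space embedding_space trained on `kg`.
#' @param templates relation templates for the default relation predictor.
#' @param direction candidate-extraction traversal policy (see
#'   [n_hop_neighbors()]).
#' @param link_threshold fuzzy-linking similarity threshold.
#' @return data.frame of class `scored_candidates` with columns `entity`
#'   (IRI), `score` (raw, in the space's polarity), `norm_score` (higher =
#'   better, distances mapped to `1/(1+d)`), `ontology`; attribute
#'   `"numeric_values"` holds each candidate's [lateral_lookup()] table.
#'   Empty candidate set yields a zero-row result (not an error).
#' @export
answer <- function(spec, kg, space, templates = default_templates(kg),
                   direction = "both", link_threshold = 0.6) {
  stopifnot(inherits(spec, "question_spec"))
  h <- resolve_head(spec, kg, link_threshold)
  rid <- NULL
  if (!is.null(spec$relation) && spec$relation %in% kg$relations) {
    rid <- relation_id(kg, spec$relation)
  } else {
    qtext <- spec$relation %||% spec$question_text
    if (is.null(qtext))
      stop_kgqa("no relation given and no question text to predict from",
                "kgqa_unresolved_relation")
    pred <- predict_relation_embedding(qtext, kg, space, templates)
    if (is.null(pred))
      stop_kgqa(sprintf("could not resolve relation for: %s", qtext),
                "kgqa_unresolved_relation")
    rid <- pred$relation_id
  }
  cand <- n_hop_neighbors(kg, h, n = spec$hops, direction = direction)
  out <- score_candidates(kg, space, h, rid, cand, spec$top_k)
  attr(out, "head") <- kg$entities[h]
  attr(out, "relation") <- kg$relations[rid]
  out
}

# map graph ids into the space's id assignment by IRI; the two may have been
# indexed in different first-seen orders (e.g. space trained on a split)
space_entity_ids <- function(kg, space, ids) {
  sid <- match(kg$entities[ids], space$entities)
  if (anyNA(sid))
    stop(sprintf("space does not cover entities: %s",
                 paste(utils::head(kg$entities[ids][is.na(sid)], 5L),
                       collapse = ", ")), call. = FALSE)
  sid
}

score_candidates <- function(kg, space, h, rid, cand, top_k) {
  if (length(cand) == 0L) {
    out <- data.frame(entity = character(), score = numeric(),
                      norm_score = numeric(), ontology = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("scored_candidates", "data.frame")
    attr(out, "numeric_values") <- list()
    return(out)
  }
  srid <- match(kg$relations[rid], space$relations)
  if (is.na(srid))
    stop(sprintf("space does not cover relation %s", kg$relations[rid]),
         call. = FALSE)
  s <- score_triples(space, rep.int(space_entity_ids(kg, space, h), length(cand)),
                     rep.int(srid, length(cand)),
                     space_entity_ids(kg, space, as.integer(cand)))
  norm <- polarity_normalize(s, space$polarity)
  ord <- order(-norm, cand)  # deterministic tie-break by entity id
  keep <- ord[seq_len(min(top_k, length(cand)))]
  out <- data.frame(entity = kg$entities[cand[keep]], score = s[keep],
                    norm_score = norm[keep], ontology = kg$ontology,
                    stringsAsFactors = FALSE)
  class(out) <- c("scored_candidates", "data.frame")
  attr(out, "numeric_values") <-
    stats::setNames(lapply(cand[keep], function(e) lateral_lookup(kg, e)),
                    kg$entities[cand[keep]])
  out
}

# single higher-is-better scale: distances map to 1/(1+d) in (0, 1],
# similarities pass through
polarity_normalize <- function(scores, polarity) {
  if (polarity == "distance") 1 / (1 + scores) else scores
}

#' Two-round numerical filtering
#'
#' Round 1 keeps entities whose predicted attribute value (linear head
#' `e . l + b`) satisfies the operator with slack `delta`; round 2 keeps the
#' survivors whose actual stored value satisfies the operator exactly.
#' Candidates lacking a stored value are dropped in round 2 but reported
#' separately rather than silently discarded. With `delta = Inf` round 1 is
#' disabled and the result equals a brute-force filter over stored values.
#'
#' @param attribute attribute IRI.
#' @param operator `"larger"`, `"smaller"` or `"close"`.
#' @param value filter value.
#' @param kg knowledge_graph.
#' @param space TransEA/TransRA embedding_space with that attribute.
#' @param tau closeness tolerance (required for `"close"`; default 5% of
#'   |value|).
#' @param delta round-1 slack; default 2 sample standard deviations of the
#'   prediction residual on the graph's stored values for this attribute
#'   (targets high round-1 recall).
#' @return list with `answers` (IRIs passing both rounds), `round1` (IRIs
#'   passing round 1), `no_data` (round-1 survivors lacking a stored value)
#'   and the `delta` used.
#' @export
numeric_filter_answer <- function(attribute, operator, value, kg, space,
                                  tau = NULL, delta = NULL) {
  stopifnot(operator %in% c("larger", "smaller", "close"))
  aid_kg <- attribute_id(kg, attribute)
  if (operator == "close") {
    tau <- tau %||% (0.05 * abs(value))
    stopifnot(tau > 0)
  }
  # predictions aligned to this graph's entity ids via IRIs
  pred <- predict_attribute_values(space, attribute)[kg$entities]
  if (anyNA(pred))
    stop(sprintf("space does not cover entities: %s",
                 paste(utils::head(kg$entities[is.na(pred)], 5L),
                       collapse = ", ")), call. = FALSE)
  stored <- kg$attr_triples[kg$attr_triples$attribute == aid_kg, , drop = FALSE]
  if (is.null(delta)) {
    eid <- stored$entity
    res <- pred[eid] - stored$value
    delta <- if (length(res) > 1L) 2 * stats::sd(res) else 0
  }
  satisfies <- function(v, slack) {
    switch(operator,
           larger = v > value - slack,
           smaller = v < value + slack,
           close = abs(v - value) <= tau + slack)
  }
  round1 <- which(if (is.infinite(delta)) rep(TRUE, length(pred))
                  else satisfies(pred, delta))
  stored_map <- split(stored$value, stored$entity)
  has_value <- as.character(round1) %in% names(stored_map)
  no_data <- round1[!has_value]
  with_value <- round1[has_value]
  keep <- vapply(as.character(with_value), function(e)
    any(satisfies(stored_map[[e]], 0)), logical(1))
  list(answers = kg$entities[with_value[keep]],
       round1 = kg$entities[round1],
       no_data = kg$entities[no_data],
       delta = delta)
}

#' Evaluate the QA pipeline over a question set
#'
#' Runs [answer()] for each question and ranks the gold answer among the
#' extracted candidates. Under the `"gold-head"` protocol the true head
#' entity is supplied directly; under `"linked"` the head is resolved by
#' fuzzy entity linking from the (possibly perturbed) mention, so linking
#' errors can push the gold answer out of the candidate set (rank `Inf`).
#'
#' @param questions list of entries with `question` (text), `head` (gold
#'   IRI), `mention` (text for linking), `relation` (gold IRI), `gold`
#'   (character vector of acceptable answer IRIs).
#' @param kg knowledge_graph.
#' @param space embedding_space.
#' @param templates relation templates.
#' @param protocol `"gold-head"` or `"linked"`.
#' @param hops,ks,direction see [answer()] / [eval_report()].
#' @return an [eval_report()]. The rank of a question is the best position
#'   of an acceptable gold answer in the engine's returned answer list
#'   (which orders ties deterministically by entity id), `Inf` when no gold
#'   is retrieved.
#' @export
evaluate_qa <- function(questions, kg, space, templates = default_templates(kg),
                        protocol = c("gold-head", "linked"), hops = 3L,
                        ks = c(1, 5, 10), direction = "both") {
  protocol <- match.arg(protocol)
  ranks <- vapply(questions, function(qq) {
    spec <- question_spec(
      question_text = qq$question,
      head_entity = if (protocol == "gold-head") qq$head else qq$mention,
      relation = qq$relation, hops = hops,
      top_k = length(kg$entities))
    res <- tryCatch(answer(spec, kg, space, templates, direction = direction),
                    kgqa_error = function(e) NULL)
    if (is.null(res) || nrow(res) == 0L) return(Inf)
    pos <- match(qq$gold, res$entity)
    pos <- pos[!is.na(pos)]
    if (length(pos) == 0L) return(Inf)
    min(pos)
  }, numeric(1))
  eval_report(ranks, ks, protocol = protocol)
}
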