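test_that("fuzzy linking finds exact labels, misspellings and no-matches", {
  kg <- chem_kg_fixture()
  hit <- link_entity_fuzzy("benzene", kg)
  expect_equal(hit$iri[1], "sp:benzene")
  expect_equal(hit$similarity[1], 1)
  expect_equal(hit$type[1], "species")
  # misspelling, checked against a DP edit-distance oracle over all strings
  hit2 <- link_entity_fuzzy("benzen", kg, threshold = 0.3)
  expect_equal(hit2$iri[1], "sp:benzene")
  idx_strings <- c(kg$labels$label, unlist(strsplit(kg$labels$aliases, "|",
                                                    fixed = TRUE)))
  dists <- vapply(tolower(idx_strings), oracle_edit_distance,
                  integer(1), a = "benzen")
  expect_equal(min(dists), oracle_edit_distance("benzen", "benzene"))
  # aliases and formulas are matchable
  expect_equal(link_entity_fuzzy("C2H5OH", kg)$iri[1], "sp:ethanol")
  # explicit no-match, not an error
  none <- link_entity_fuzzy("xqzzy", kg, threshold = 0.6)
  expect_equal(nrow(none), 0L)
})

test_that("misspelled mentions still link top-1 against the oracle table", {
  p <- planted_fixture()
  kg <- p$kgs[[1]]
  set.seed(30)
  labs <- kg$labels$label[sample.int(nrow(kg$labels), 25L)]
  for (lab in labs) {
    pos <- sample(nchar(lab), 1)
    bad <- paste0(substr(lab, 1, pos - 1), "x", substring(lab, pos + 1))
    got <- link_entity_fuzzy(bad, kg, threshold = 0.3)
    want <- kg$labels$iri[match(lab, kg$labels$label)]
    expect_equal(got$iri[1], want)
  }
})

test_that("template matching returns the exact relation embedding row", {
  tri <- data.frame(
    head = c("sp:benzene", "sp:ethanol", "sp:benzene"),
    relation = c("rel:weight", "rel:weight", "rel:has_use"),
    tail = c("val:w78", "val:w46", "use:solvent"), stringsAsFactors = FALSE)
  kg <- knowledge_graph(tri, NULL, NULL, "toy")
  space <- train_embeddings(kg, "TransE",
                            training_config(epochs = 5, seed = 1L, dim = 4))
  templates <- data.frame(
    relation = c("rel:has_use", "rel:weight"),
    template = c("what is the use of {entity}?", "how much does it weigh?"),
    stringsAsFactors = FALSE)
  # question generated from a known template -> that relation's row exactly
  got <- predict_relation_embedding("what is the use of benzene?", kg, space,
                                    templates)
  expect_equal(got$relation, "rel:has_use")
  expect_identical(got$embedding, space$rel[got$relation_id, ])
  # the weight-question template maps to the planted weight relation
  got2 <- predict_relation_embedding("how much does it weigh?", kg, space,
                                     templates)
  expect_equal(got2$relation, "rel:weight")
  expect_identical(got2$embedding, space$rel[got2$relation_id, ])
  # unmatched gibberish gives the unresolved-relation signal
  expect_null(predict_relation_embedding("zzz qqq xxx", kg, space, templates))
})

test_that("numerical qualifiers parse with operator, value and unit", {
  q1 <- parse_numeric_operator(
    "which species have a molecular weight less than 50 g/mol?")
  expect_equal(q1, list(operator = "smaller", value = 50, unit = "g/mol"))
  q2 <- parse_numeric_operator("what is the heat capacity of benzene at 100 K?")
  expect_equal(q2, list(operator = "close", value = 100, unit = "k"))
  q3 <- parse_numeric_operator("larger than 2.5")
  expect_equal(q3, list(operator = "larger", value = 2.5, unit = ""))
  expect_null(parse_numeric_operator("no numbers here"))
  q4 <- parse_numeric_operator("the speed is exactly 12 maybe")
  expect_equal(q4$operator, "unresolved")
})

test_that("answers are the top-k of a full-sort oracle with ties by id", {
  p <- planted_fixture()
  kg <- p$kgs[[1]]
  set.seed(32)
  n <- length(kg$entities)
  space <- train_embeddings(kg, "TransE",
                            training_config(epochs = 0, seed = 9L, dim = 8))
  h <- kg$triples[1, 1]; rid <- kg$triples[1, 2]
  spec <- question_spec(head_entity = kg$entities[h],
                        relation = kg$relations[rid], hops = 2, top_k = 7)
  res <- answer(spec, kg, space)
  cand <- n_hop_neighbors(kg, h, 2, "both")
  s <- score_triples(space, rep(h, length(cand)), rep(rid, length(cand)),
                     as.integer(cand))
  ord <- order(-(1 / (1 + s)), cand)
  expect_equal(res$entity,
               kg$entities[cand[ord][seq_len(min(7L, length(cand)))]])
  # k larger than the candidate count returns everything, ordered
  spec2 <- question_spec(head_entity = kg$entities[h],
                         relation = kg$relations[rid], hops = 1,
                         top_k = 10 * n)
  res2 <- answer(spec2, kg, space)
  expect_equal(nrow(res2), length(n_hop_neighbors(kg, h, 1, "both")))
  expect_true(all(diff(res2$norm_score) <= 0))
})

test_that("answer attaches numeric values and signals unresolved inputs", {
  kg <- chem_kg_fixture()
  space <- train_embeddings(kg, "TransE",
                            training_config(epochs = 5, seed = 2L, dim = 4))
  spec <- question_spec(head_entity = "sp:benzene", relation = "rel:has_use",
                        hops = 1, top_k = 3)
  res <- answer(spec, kg, space)
  expect_true(nrow(res) >= 1)
  expect_true(is.data.frame(attr(res, "numeric_values")[[res$entity[1]]]))
  expect_error(
    answer(question_spec(head_entity = "qqqq zzz", relation = "rel:has_use"),
           kg, space),
    class = "kgqa_entity_not_found")
  expect_error(
    answer(question_spec(head_entity = "sp:benzene",
                         question_text = "gibberish prompt"), kg, space),
    class = "kgqa_unresolved_relation")
})

test_that("two-round filtering matches planted values and the brute force", {
  # planted: three species with values 10, 45, 60 and perfect predictions
  tri <- data.frame(head = c("a", "b", "c"), relation = "r",
                    tail = c("b", "c", "a"), stringsAsFactors = FALSE)
  at <- data.frame(entity = c("a", "b", "c"), attribute = "w",
                   value = c(10, 45, 60), unit = "g/mol",
                   stringsAsFactors = FALSE)
  kg <- knowledge_graph(tri, at, NULL, "toy")
  space <- structure(list(
    method = "TransEA", dim = 2, ontology = "toy",
    entities = kg$entities, relations = kg$relations, attributes = "w",
    polarity = "distance",
    ent = cbind(c(10, 45, 60), 0), rel = matrix(0, 1, 2),
    attr_vec = matrix(c(1, 0), 1), attr_bias = 0,
    config = training_config(dim = 2), loss_trace = numeric(0)),
    class = "embedding_space")
  res <- numeric_filter_answer("w", "smaller", 50, kg, space, delta = 0)
  expect_setequal(res$answers, c("a", "b"))
  res2 <- numeric_filter_answer("w", "close", 45, kg, space, tau = 1, delta = 0)
  expect_equal(res2$answers, "b")
  expect_error(numeric_filter_answer("zz", "smaller", 1, kg, space),
               class = "kgqa_attribute_not_found")

  # round 2 is always a subset of round 1
  expect_true(all(res$answers %in% res$round1))

  # delta = Inf reduces to the brute-force actual-value filter
  p <- planted_fixture()
  pkg_ <- p$kgs[[1]]
  sp <- trained_fixture("TransRA")
  rows <- pkg_$attr_triples[pkg_$attr_triples$attribute == 1L, ]
  for (op in c("larger", "smaller", "close")) {
    for (v in stats::quantile(rows$value, c(0.25, 0.5, 0.75))) {
      got <- numeric_filter_answer(pkg_$attributes[1], op, v, pkg_, sp,
                                   tau = 0.1, delta = Inf)
      keep <- switch(op, larger = rows$value > v, smaller = rows$value < v,
                     close = abs(rows$value - v) <= 0.1)
      oracle <- unique(pkg_$entities[rows$entity[keep]])
      expect_setequal(got$answers, oracle)
    }
  }
})

test_that("gold-head evaluation dominates fuzzy-linked evaluation", {
  p <- planted_fixture()
  kg <- p$kgs[[1]]
  sp <- trained_fixture("TransRA")
  qs <- generate_questions(p, synthetic_config(seed = 20260926L),
                           perturb_rate = 0.7, seed = 881L)[[1]]
  single <- Filter(function(q) q$type == "single-hop", qs$questions)[1:60]
  gold <- evaluate_qa(single, kg, sp, templates = qs$templates,
                      protocol = "gold-head")
  linked <- evaluate_qa(single, kg, sp, templates = qs$templates,
                        protocol = "linked")
  expect_true(all(gold$hits_at >= linked$hits_at))
  expect_gte(gold$mrr, linked$mrr)
})

test_that("round-1 recall never decreases as the slack grows", {
  p <- planted_fixture()
  kg <- p$kgs[[1]]
  sp <- trained_fixture("TransRA")
  rows <- kg$attr_triples[kg$attr_triples$attribute == 2L, ]
  v <- stats::median(rows$value)
  oracle <- unique(kg$entities[rows$entity[rows$value < v]])
  recalls <- vapply(c(0, 0.05, 0.2, 1, Inf), function(d) {
    got <- numeric_filter_answer(kg$attributes[2], "smaller", v, kg, sp,
                                 delta = d)
    length(intersect(got$answers, oracle)) / length(oracle)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  expect_equal(recalls[length(recalls)], 1)
})
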