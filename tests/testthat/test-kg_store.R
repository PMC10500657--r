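test_that("TSV parsing builds the vocabulary and collapses duplicates", {
  kg <- parse_kg(c("head\trelation\ttail", "a\tr1\tb", "b\tr2\tc", "a\tr1\tb"))
  expect_equal(length(kg$entities), 3L)
  expect_equal(length(kg$relations), 2L)
  expect_equal(nrow(kg$triples), 2L)
  # first-seen id order: heads before tails, row by row
  expect_equal(kg$entities, c("a", "b", "c"))
})

test_that("malformed input is rejected with a line number and reason", {
  expect_error(parse_kg(c("head\trelation\ttail", "a\tr1")), "line 2")
  expect_error(parse_kg(c("bad\theader\there", "a\tr1\tb")), "header")
  expect_error(
    parse_kg(c("head\trelation\ttail", "a\tr1\tb"),
             attr_text = c("entity\tattribute\tvalue\tunit",
                           "a\tweight\tabc\tg/mol")),
    "non-numeric")
  expect_error(
    parse_kg("<a> <r> \"foo\" .", format = "ntriples"),
    "line 1")
  expect_error(knowledge_graph(
    data.frame(head = "a", relation = "r|s", tail = "b")), "reserved")
})

test_that("empty and single-triple graphs serialize to header-only / one line", {
  empty <- knowledge_graph()
  out <- write_kg(empty, "tsv")
  expect_equal(out$relations, "head\trelation\ttail")
  one <- knowledge_graph(data.frame(head = "a", relation = "r", tail = "b"))
  expect_equal(length(write_kg(one, "tsv")$relations), 2L)
  expect_equal(length(write_kg(one, "ntriples")), 1L)
})

test_that("write/parse roundtrips preserve random graphs in both dialects", {
  for (seed in 1:5) {
    kg <- random_kg(seed, n_nodes = 25L, n_edges = 100L, n_attr = 15L,
                    with_labels = TRUE)
    out <- write_kg(kg, "tsv")
    back <- parse_kg(out$relations, "tsv", attr_text = out$attributes,
                     labels_text = out$labels, ontology = kg$ontology)
    # independent line-by-line comparison on the canonical serialization
    expect_identical(write_kg(back, "tsv"), out)
    # and set equality of the string-form triples
    orig_lines <- sort(with(as.data.frame(kg$triples),
                            paste(kg$entities[head], kg$relations[relation],
                                  kg$entities[tail])))
    back_lines <- sort(with(as.data.frame(back$triples),
                            paste(back$entities[head], back$relations[relation],
                                  back$entities[tail])))
    expect_identical(back_lines, orig_lines)

    nt <- write_kg(kg, "ntriples")
    back2 <- parse_kg(nt, "ntriples")
    expect_identical(write_kg(back2, "ntriples"), nt)
    validate_kg(back)
  }
})

test_that("save_kg/load_kg roundtrip through a directory", {
  kg <- random_kg(42, n_attr = 10L, with_labels = TRUE)
  d <- withr::local_tempdir()
  save_kg(kg, d)
  back <- load_kg(d)
  expect_identical(write_kg(back, "tsv"), write_kg(kg, "tsv"))
  expect_identical(back$ontology, kg$ontology)
})

test_that("n-hop neighborhoods match chains and the BFS oracle", {
  chain <- parse_kg(c("head\trelation\ttail", "a\tr\tb", "b\tr\tc"))
  expect_equal(names(n_hop_neighbors(chain, "a", 1, "forward")), "b")
  expect_equal(names(n_hop_neighbors(chain, "a", 2, "forward")), c("b", "c"))
  expect_error(n_hop_neighbors(chain, "zz", 1), class = "kgqa_entity_not_found")

  for (seed in 1:8) {
    kg <- random_kg(seed, n_nodes = sample(5:50, 1L), n_edges = 80L)
    head <- sample(seq_along(kg$entities), 1L)
    n <- sample(1:4, 1L)
    for (dir in c("forward", "both")) {
      got <- unname(n_hop_neighbors(kg, head, n, dir))
      expect_equal(got, oracle_bfs(kg, head, n, dir))
    }
    # monotone in n, and forward subset of both
    r1 <- n_hop_neighbors(kg, head, n, "forward")
    r2 <- n_hop_neighbors(kg, head, n + 1L, "forward")
    expect_true(all(r1 %in% r2))
    expect_true(all(r1 %in% n_hop_neighbors(kg, head, n, "both")))
  }
})

test_that("lateral lookup returns exactly the entity's attribute triples", {
  kg <- chem_kg_fixture()
  expect_equal(nrow(lateral_lookup(kg, "use:fuel")), 0L)
  got <- lateral_lookup(kg, "sp:benzene")
  expect_equal(got$value, 78.11)
  expect_equal(got$unit, "g/mol")
  expect_error(lateral_lookup(kg, "nope"), class = "kgqa_entity_not_found")

  rkg <- random_kg(9, n_attr = 40L)
  for (e in seq_along(rkg$entities)) {
    got <- lateral_lookup(rkg, e)
    scan <- rkg$attr_triples[rkg$attr_triples$entity == e, , drop = FALSE]
    expect_equal(nrow(got), nrow(scan))
    expect_setequal(paste(got$attribute, got$value),
                    paste(rkg$attributes[scan$attribute], scan$value))
  }
})
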