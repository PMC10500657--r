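test_that("rank_of handles polarity and all three tie policies", {
  expect_equal(rank_of(c(0.9, 0.5, 0.1), 1), 1)
  expect_equal(rank_of(c(0.9, 0.5, 0.1), 3), 3)
  expect_equal(rank_of(c(1, 1, 0), 2, tie_policy = "average"), 1.5)
  expect_equal(rank_of(c(1, 1, 0), 2, tie_policy = "optimistic"), 1)
  expect_equal(rank_of(c(1, 1, 0), 2, tie_policy = "pessimistic"), 2)
  expect_equal(rank_of(c(0.2, 0.5), 1, polarity = "distance"), 1)
  expect_error(rank_of(numeric(0), 1), "empty")
  set.seed(10)
  for (i in 1:50) {
    s <- sample(round(runif(20), 2), 20, TRUE)  # duplicates force ties
    ti <- sample.int(20, 1)
    for (tp in c("average", "optimistic", "pessimistic"))
      expect_equal(rank_of(s, ti, tie_policy = tp), oracle_rank(s, ti, tp))
  }
})

test_that("hits@k and MRR match counting and arithmetic oracles", {
  expect_equal(hits_at_k(c(1, 3, 11), 5), 2 / 3)
  expect_equal(hits_at_k(c(1, 3, 11), 1), 1 / 3)
  expect_equal(mrr(c(1, 1, 1)), 1)
  expect_equal(mrr(c(1, 2, 4)), (1 + 0.5 + 0.25) / 3)
  expect_error(hits_at_k(numeric(0), 1), "empty")
  set.seed(11)
  for (i in 1:20) {
    ranks <- sample.int(50, 30, TRUE)
    k <- sample.int(20, 1)
    expect_equal(hits_at_k(ranks, k), sum(ranks <= k) / length(ranks))
    inv <- 0
    for (rk in ranks) inv <- inv + 1 / rk
    expect_equal(mrr(ranks), inv / length(ranks), tolerance = 1e-12)
  }
  # hits@k monotone in k; hits at the candidate count is 1
  ranks <- sample.int(40, 25, TRUE)
  hs <- vapply(1:40, function(k) hits_at_k(ranks, k), numeric(1))
  expect_true(all(diff(hs) >= 0))
  expect_equal(hs[40], 1)
})

test_that("a planted exact space achieves perfect tail inference", {
  # entities on a line, relation = +1 step: t = h + r exactly
  kg <- parse_kg(c("head\trelation\ttail", "a\tr\tb", "b\tr\tc", "c\tr\td"))
  space <- structure(list(
    method = "TransE", dim = 2, ontology = "toy",
    entities = kg$entities, relations = kg$relations, attributes = character(0),
    polarity = "distance",
    ent = cbind(seq_along(kg$entities), 0), rel = matrix(c(1, 0), 1),
    config = training_config(dim = 2, squared = FALSE),
    loss_trace = numeric(0)), class = "embedding_space")
  rep <- evaluate_link_prediction(kg, data.frame(
    head = "a", relation = "r", tail = "b"), space, protocol = "raw")
  expect_equal(rep$mrr, 1)
  expect_equal(unname(rep$hits_at["hits@1"]), 1)
})

test_that("random embeddings rank near the uniform expectation", {
  kg <- random_kg(12, n_nodes = 40L, n_edges = 120L)
  set.seed(13)
  n <- length(kg$entities)
  space <- structure(list(
    method = "TransE", dim = 8, ontology = "rand",
    entities = kg$entities, relations = kg$relations, attributes = character(0),
    polarity = "distance",
    ent = matrix(rnorm(n * 8), n), rel = matrix(rnorm(length(kg$relations) * 8),
                                                length(kg$relations)),
    config = training_config(dim = 8), loss_trace = numeric(0)),
    class = "embedding_space")
  test <- triples_df(kg)[seq_len(30), ]
  rep <- evaluate_link_prediction(kg, test, space, protocol = "raw")
  # permutation oracle: for i.i.d. scores the gold rank is uniform on 1..C,
  # so E[1/rank] = mean(1/(1:C)); compare within 3 standard errors
  recip <- 1 / seq_len(n)
  expect_lt(abs(rep$mrr - mean(recip)),
            3 * stats::sd(recip) / sqrt(rep$Q))
})

test_that("filtered metrics dominate raw metrics on 1-to-N graphs", {
  p <- planted_fixture()
  sp <- trained_fixture("TransRA")
  tkg <- training_kg(p)
  tt <- p$truth[[1]]$test_triples
  raw <- evaluate_link_prediction(tkg, tt, sp, protocol = "raw")
  fil <- evaluate_link_prediction(tkg, tt, sp, protocol = "filtered")
  expect_true(all(fil$ranks <= raw$ranks))
  expect_gte(fil$mrr, raw$mrr)
  expect_true(all(fil$hits_at >= raw$hits_at))
})

test_that("attribute error metrics recover planted offsets", {
  kg <- chem_kg_fixture()
  space <- structure(list(
    method = "TransEA", dim = 2, ontology = "chem",
    entities = kg$entities, relations = kg$relations, attributes = kg$attributes,
    polarity = "distance",
    ent = cbind(kg$attr_triples$value[match(seq_along(kg$entities),
                                            kg$attr_triples$entity)], 1),
    rel = matrix(0, length(kg$relations), 2),
    attr_vec = matrix(c(1, 0), 1), attr_bias = 0,
    config = training_config(dim = 2), loss_trace = numeric(0)),
    class = "embedding_space")
  space$ent[is.na(space$ent[, 1]), 1] <- 0
  m <- attribute_error_metrics(space, kg)
  expect_equal(m$mean_absolute_error, 0)
  # constant offset in the bias shifts the error by exactly that constant
  space$attr_bias <- 2.5
  m2 <- attribute_error_metrics(space, kg)
  expect_equal(m2$mean_absolute_error, 2.5)
})

test_that("reports serialize to JSON and table-style CSV", {
  rep <- eval_report(c(1, 2, 4), ks = c(1, 5, 10), protocol = "gold-head")
  d <- withr::local_tempdir()
  write_eval_report(rep, file.path(d, "r.json"), "json")
  back <- jsonlite::read_json(file.path(d, "r.json"), simplifyVector = TRUE)
  expect_equal(back$mrr, rep$mrr)
  write_eval_report(rep, file.path(d, "r.csv"), "csv")
  csv <- utils::read.csv(file.path(d, "r.csv"), check.names = FALSE)
  expect_true(all(c("hit 1 rate", "hit 5 rate", "hit 10 rate", "mrr")
                  %in% names(csv)))
})
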