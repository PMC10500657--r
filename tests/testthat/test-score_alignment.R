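test_that("max-normalization baseline scales and merges as defined", {
  one <- list(o1 = data.frame(entity = c("x", "y"), norm_score = c(2, 4),
                              ontology = "o1"))
  m <- normalize_scores_baseline(one)
  expect_equal(sort(m$merged_score), c(0.5, 1))
  expect_equal(m$entity, c("y", "x"))  # order preserved within the ontology
  single <- list(o1 = data.frame(entity = "x", norm_score = 3, ontology = "o1"))
  expect_equal(normalize_scores_baseline(single)$merged_score, 1)
  # scale invariance: multiplying one ontology by a positive constant
  # leaves the merged ranking unchanged
  two <- list(o1 = data.frame(entity = paste0("a", 1:3),
                              norm_score = c(3, 2, 1), ontology = "o1"),
              o2 = data.frame(entity = paste0("b", 1:3),
                              norm_score = c(0.9, 0.5, 0.1), ontology = "o2"))
  m1 <- normalize_scores_baseline(two)
  two$o2$norm_score <- two$o2$norm_score * 57
  m2 <- normalize_scores_baseline(two)
  expect_equal(m1$entity, m2$entity)
  # non-positive maximum: scores become 0 with a warning
  neg <- list(o1 = data.frame(entity = "x", norm_score = -1, ontology = "o1"),
              o2 = data.frame(entity = "y", norm_score = 1, ontology = "o2"))
  expect_warning(m3 <- normalize_scores_baseline(neg), "non-positive")
  expect_equal(m3$merged_score[m3$entity == "x"], 0)
})

test_that("affiliation separates disjoint vocabularies and is deterministic", {
  bm <- mismatch_benchmark(seed = 21L)
  model <- train_alignment(bm$train, seed = 5L, epochs = 20)
  acc <- mean(vapply(bm$test, function(ex) {
    aff <- compute_affiliation(ex$question, model)
    names(which.max(aff)) == ex$gold_ontology
  }, logical(1)))
  expect_gte(acc, 0.95)
  # empty question: each label at its base rate
  aff0 <- compute_affiliation("", model)
  expect_equal(unname(aff0), c(0.5, 0.5), tolerance = 1e-12)
  # identical inputs, identical outputs
  expect_identical(compute_affiliation("what is the boiling point", model),
                   compute_affiliation("what is the boiling point", model))
})

test_that("alignment training is seeded-reproducible and needs 2 ontologies", {
  bm <- mismatch_benchmark(seed = 22L)
  m1 <- train_alignment(bm$train, seed = 9L, epochs = 30)
  m2 <- train_alignment(bm$train, seed = 9L, epochs = 30)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$u, m2$u)
  solo <- lapply(bm$train, function(ex) {
    ex$answers <- ex$answers["ontoA"]
    ex$gold_ontology <- "ontoA"; ex$gold_entity <- ex$answers$ontoA$entity[1]
    ex
  })
  expect_error(train_alignment(solo), "2 ontologies")
})

test_that("an identity model reproduces the baseline merge order", {
  bm <- mismatch_benchmark(seed = 23L)
  model <- train_alignment(bm$train, seed = 1L, epochs = 1)
  model$w[] <- 1
  model$u[] <- 0
  for (ex in bm$test[1:5]) {
    base <- normalize_scores_baseline(ex$answers)
    re <- rerank_cross_ontology(ex$question, ex$answers, model)
    expect_equal(re$entity, base$entity)
  }
  expect_error(
    rerank_cross_ontology("q", list(ontoZ = bm$test[[1]]$answers$ontoA), model),
    "does not cover")
})

test_that("adjustment never reorders candidates within one ontology", {
  bm <- mismatch_benchmark(seed = 24L)
  model <- train_alignment(bm$train, seed = 2L, epochs = 50)
  expect_true(all(model$w > 0))
  for (ex in bm$test[1:10]) {
    re <- rerank_cross_ontology(ex$question, ex$answers, model)
    for (ont in names(ex$answers)) {
      within <- re$entity[re$ontology == ont]
      expect_equal(within, ex$answers[[ont]]$entity)
    }
  }
})

test_that("alignment beats the max-normalization baseline under mismatch", {
  bm <- mismatch_benchmark(seed = 25L)
  model <- train_alignment(bm$train, seed = 4L)
  base <- merged_hit1(bm$test, function(ex)
    normalize_scores_baseline(ex$answers))
  aligned <- merged_hit1(bm$test, function(ex)
    rerank_cross_ontology(ex$question, ex$answers, model))
  expect_gt(aligned, base)
  expect_gte(aligned, 0.9)
})

test_that("alignment models roundtrip through JSON", {
  bm <- mismatch_benchmark(seed = 26L)
  model <- train_alignment(bm$train, seed = 3L, epochs = 20)
  path <- withr::local_tempfile(fileext = ".json")
  save_alignment_model(model, path)
  back <- load_alignment_model(path)
  ex <- bm$test[[1]]
  expect_equal(rerank_cross_ontology(ex$question, ex$answers, back),
               rerank_cross_ontology(ex$question, ex$answers, model))
})
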