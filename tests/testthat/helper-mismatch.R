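# Constructed score-mismatch benchmark for the alignment model: two
# ontologies with disjoint question vocabularies; ontology B reports scores
# on a 10x scale; the gold answer alternates between A and B (always the
# top answer within its own engine). Max-normalization forces both engines'
# tops to 1.0, so the baseline must break the resulting cross-ontology tie
# blindly, while the alignment model can use the question affiliation.
mismatch_benchmark <- function(n_train = 40L, n_test = 40L, scale = 10,
                               seed = 3L) {
  words_a <- c("boiling", "melting", "density", "viscosity")
  words_b <- c("orbital", "frequency", "charge", "spin")
  mk_example <- function(i) {
    gold_in_a <- i %% 2L == 0L
    words <- if (gold_in_a) words_a else words_b
    q <- paste("what is the", paste(sample(words, 2L), collapse = " "),
               "of species", i)
    sa <- sort(stats::runif(5, 0.1, 0.9), decreasing = TRUE)
    sb <- sort(stats::runif(5, 0.1, 0.9), decreasing = TRUE) * scale
    A <- data.frame(entity = paste0("A", seq_len(5)), norm_score = sa,
                    ontology = "ontoA", stringsAsFactors = FALSE)
    B <- data.frame(entity = paste0("B", seq_len(5)), norm_score = sb,
                    ontology = "ontoB", stringsAsFactors = FALSE)
    if (gold_in_a) A$entity[1L] <- "A_gold" else B$entity[1L] <- "B_gold"
    list(question = q,
         gold_entity = if (gold_in_a) "A_gold" else "B_gold",
         gold_ontology = if (gold_in_a) "ontoA" else "ontoB",
         answers = list(ontoA = A, ontoB = B))
  }
  set.seed(seed)
  list(train = lapply(seq_len(n_train), mk_example),
       test = lapply(n_train + seq_len(n_test), mk_example))
}

merged_hit1 <- function(examples, merge_fun) {
  mean(vapply(examples, function(ex) {
    m <- merge_fun(ex)
    m$entity[1L] == ex$gold_entity && m$ontology[1L] == ex$gold_ontology
  }, logical(1)))
}
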