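# Ranking metrics and the link-prediction evaluation protocols.
#
# All ranking is done on a single higher-is-better convention: distance
# scores are negated internally. "Filtered" link prediction removes known
# true tails (other than the one being ranked) from the candidate list, the
# standard convention whose metrics dominate their raw counterparts.

#' Rank of the true answer among scored candidates
#'
#' `1 + (number of strictly better candidates) + tie adjustment`: ties
#' contribute half their count under `"average"` (default, so constant-score
#' degenerate models cannot look perfect), nothing under `"optimistic"`, all
#' under `"pessimistic"`.
#'
#' @param scores numeric vector of candidate scores.
#' @param true_index index of the true answer within `scores`.
#' @param polarity `"distance"` (lower = better) or `"similarity"`.
#' @param tie_policy `"average"`, `"optimistic"` or `"pessimistic"`.
#' @return rank (>= 1, possibly fractional under `"average"`).
#' @export
rank_of <- function(scores, true_index,
                    polarity = c("similarity", "distance"),
                    tie_policy = c("average", "optimistic", "pessimistic")) {
  polarity <- match.arg(polarity)
  tie_policy <- match.arg(tie_policy)
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  stopifnot(true_index >= 1L, true_index <= length(scores))
  s <- if (polarity == "distance") -scores else scores
  st <- s[true_index]
  better <- sum(s > st)
  ties <- sum(s == st) - 1L
  better + 1 + switch(tie_policy, average = ties / 2, optimistic = 0,
                      pessimistic = ties)
}

#' Fraction of ranks within the top k
#'
#' @param ranks numeric vector of ranks (>= 1; `Inf` allowed for misses).
#' @param k cutoff (>= 1).
#' @return fraction in `[0, 1]`.
#' @export
hits_at_k <- function(ranks, k) {
  if (length(ranks) == 0L) stop("empty rank vector", call. = FALSE)
  stopifnot(k >= 1)
  mean(ranks <= k)
}

#' Mean reciprocal rank
#'
#' `mean(1 / rank_i)` over all evaluation questions.
#'
#' @param ranks numeric vector of ranks (>= 1; `Inf` contributes 0).
#' @return MRR in `(0, 1]` (0 only if every rank is infinite).
#' @export
mrr <- function(ranks) {
  if (length(ranks) == 0L) stop("empty rank vector", call. = FALSE)
  stopifnot(all(ranks >= 1))
  mean(1 / ranks)
}

#' Build an evaluation report from ranks
#'
#' @param ranks numeric ranks, one per question.
#' @param ks cutoffs for hits@k.
#' @param protocol name of the protocol that produced the ranks.
#' @return object of class `eval_report` with `protocol`, `Q`, `ranks`,
#'   `hits_at` (named vector), `mrr`.
#' @export
eval_report <- function(ranks, ks = c(1, 5, 10), protocol = "raw") {
  structure(list(protocol = protocol, Q = length(ranks), ranks = ranks,
                 hits_at = stats::setNames(vapply(ks, function(k)
                   hits_at_k(ranks, k), numeric(1)), paste0("hits@", ks)),
                 mrr = mrr(ranks)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report protocol=%s Q=%d mrr=%.4f %s>\n", x$protocol, x$Q,
              x$mrr, paste(sprintf("%s=%.4f", names(x$hits_at), x$hits_at),
                           collapse = " ")))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' JSON, or a one-row CSV with the column naming of the QA evaluation tables
#' (`hit 1 rate`, `hit 5 rate`, `hit 10 rate`, `mrr`).
#'
#' @param report an eval_report.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @export
write_eval_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(protocol = report$protocol, Q = report$Q,
                              mrr = report$mrr,
                              hits_at = as.list(report$hits_at),
                              ranks = report$ranks),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(protocol = report$protocol,
                     as.list(stats::setNames(report$hits_at,
                       sub("hits@", "hit ", names(report$hits_at), fixed = TRUE))),
                     mrr = report$mrr, check.names = FALSE)
    names(df) <- sub("^(hit [0-9]+)$", "\\1 rate", names(df))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# score all entities as tail candidates for (h, r, .); returns numeric vector
# over entity ids, same polarity as the space
score_all_tails <- function(space, h, r) {
  n <- length(space$entities)
  score_triples(space, rep.int(h, n), rep.int(r, n), seq_len(n))
}

#' Tail-inference link-prediction evaluation
#'
#' For each test triple (h, r, t), scores every entity as a candidate tail
#' and ranks the true tail. Under the `"filtered"` protocol, other tails t'
#' known true for (h, r) in train or test are removed from the candidate
#' list before ranking; `"raw"` keeps them.
#'
#' @param train_kg knowledge_graph used for training (supplies the known
#'   triples for filtering).
#' @param test_triples data.frame (head, relation, tail in IRIs) or integer
#'   id matrix of held-out triples.
#' @param space trained embedding_space covering the vocabulary.
#' @param protocol `"filtered"` or `"raw"`.
#' @param ks hits@k cutoffs.
#' @param tie_policy see [rank_of()].
#' @return an [eval_report()].
#' @export
evaluate_link_prediction <- function(train_kg, test_triples, space,
                                     protocol = c("filtered", "raw"),
                                     ks = c(1, 5, 10),
                                     tie_policy = "average") {
  protocol <- match.arg(protocol)
  tt <- as_id_triples(test_triples, space)
  missing_ent <- setdiff(c(train_kg$entities), space$entities)
  if (length(missing_ent))
    stop(sprintf("space does not cover entities: %s",
                 paste(utils::head(missing_ent, 5L), collapse = ", ")),
         call. = FALSE)
  # known true tails per (h, r) over train + test
  train_ids <- cbind(match(train_kg$entities[train_kg$triples[, 1L]], space$entities),
                     match(train_kg$relations[train_kg$triples[, 2L]], space$relations),
                     match(train_kg$entities[train_kg$triples[, 3L]], space$entities))
  all_known <- rbind(train_ids, tt)
  known_key <- paste(all_known[, 1L], all_known[, 2L], sep = "\r")
  known_tails <- split(all_known[, 3L], known_key)

  pol <- space$polarity
  ranks <- numeric(nrow(tt))
  for (i in seq_len(nrow(tt))) {
    h <- tt[i, 1L]; r <- tt[i, 2L]; t <- tt[i, 3L]
    s <- score_all_tails(space, h, r)
    keep <- seq_along(s)
    if (protocol == "filtered") {
      kt <- known_tails[[paste(h, r, sep = "\r")]]
      keep <- setdiff(keep, setdiff(kt, t))
    }
    ranks[i] <- rank_of(s[keep], match(t, keep), polarity = pol,
                        tie_policy = tie_policy)
  }
  eval_report(ranks, ks, protocol = if (protocol == "filtered")
    "filtered-link-prediction" else "raw")
}

as_id_triples <- function(test_triples, space) {
  if (is.matrix(test_triples) && is.numeric(test_triples)) {
    tt <- test_triples
    storage.mode(tt) <- "integer"
    return(tt)
  }
  tt <- as.data.frame(test_triples, stringsAsFactors = FALSE)
  h <- match(tt$head, space$entities); r <- match(tt$relation, space$relations)
  t <- match(tt$tail, space$entities)
  miss <- c(tt$head[is.na(h)], tt$relation[is.na(r)], tt$tail[is.na(t)])
  if (length(miss))
    stop(sprintf("space does not cover: %s",
                 paste(unique(utils::head(miss, 5L)), collapse = ", ")),
         call. = FALSE)
  cbind(h, r, t)
}

#' Attribute prediction error metrics
#'
#' Mean absolute error of the linear attribute head against stored attribute
#' values, overall and per attribute.
#'
#' @param space a TransEA/TransRA embedding_space.
#' @param attr_triples data.frame (entity, attribute IRIs, value) or a
#'   knowledge_graph (its attribute triples are used).
#' @return list with `mean_absolute_error` and named vector
#'   `per_attribute` of mean absolute errors.
#' @export
attribute_error_metrics <- function(space, attr_triples) {
  if (inherits(attr_triples, "knowledge_graph"))
    attr_triples <- attr_df_chr(attr_triples)
  if (is.null(space$attr_vec))
    stop("space has no attribute head (train with TransEA or TransRA)",
         call. = FALSE)
  e <- match(attr_triples$entity, space$entities)
  a <- match(attr_triples$attribute, space$attributes)
  if (anyNA(e) || anyNA(a))
    stop_kgqa("attribute triples reference items absent from the space",
              "kgqa_attribute_not_found")
  pred <- rowSums(space$ent[e, , drop = FALSE] *
                  space$attr_vec[a, , drop = FALSE]) + space$attr_bias[a]
  err <- abs(pred - attr_triples$value)
  per <- tapply(err, space$attributes[a], mean)
  list(mean_absolute_error = mean(err),
       per_attribute = stats::setNames(as.vector(per), names(per)))
}
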