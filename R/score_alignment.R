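# Cross-ontology score alignment.
#
# Each per-ontology QA engine scores its answers on its own scale, so
# answers from different embedding spaces are not directly comparable. The
# alignment model applies a per-ontology affine adjustment
#     s' = w_o * s_norm + u_o . x(q)
# where s_norm is the max-normalized polarity-normalized score, x(q) a
# bag-of-words indicator vector of the question and (w_o, u_o) learned by
# pairwise margin ranking of gold answers above non-gold answers. The
# ablation baseline divides each ontology's scores by its maximum and merges.
# Within an ontology the adjustment is monotone (w_o is kept positive), so
# only the cross-ontology interleaving can change.

#' Max-normalization merge baseline
#'
#' Within each ontology list, divides the polarity-normalized scores by that
#' ontology's maximum, then merges all lists and sorts by descending score
#' with deterministic tie-break (ontology label, entity).
#'
#' @param answers named list (by ontology label) of `scored_candidates`
#'   data.frames (or any data.frame with `entity`, `norm_score`, `ontology`).
#' @return merged data.frame with an added `merged_score` column.
#' @export
normalize_scores_baseline <- function(answers) {
  stopifnot(length(answers) >= 1L)
  parts <- lapply(answers, function(df) {
    df <- as.data.frame(df)
    m <- max(df$norm_score)
    if (m <= 0) {
      warning("non-positive maximum score in an ontology list; mapped to 0")
      df$merged_score <- 0
    } else df$merged_score <- df$norm_score / m
    df
  })
  merged <- do.call(rbind, c(parts, make.row.names = FALSE))
  merged <- merged[order(-merged$merged_score, merged$ontology, merged$entity), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

bow_vector <- function(text, vocab) {
  as.numeric(vocab %in% tokenize(text))
}

# Bernoulli naive Bayes, one-vs-rest per ontology label; an empty question
# yields each label's training base rate
train_affiliation_nb <- function(questions, labels) {
  vocab <- sort(unique(unlist(lapply(questions, tokenize))))
  labs <- sort(unique(labels))
  X <- t(vapply(questions, bow_vector, numeric(length(vocab)), vocab = vocab))
  fit <- lapply(labs, function(l) {
    pos <- labels == l
    list(prior = mean(pos),
         p1 = (colSums(X[pos, , drop = FALSE]) + 1) / (sum(pos) + 2),
         p0 = (colSums(X[!pos, , drop = FALSE]) + 1) / (sum(!pos) + 2))
  })
  list(vocab = vocab, labels = labs, fit = stats::setNames(fit, labs))
}

#' Question-ontology affiliation probabilities
#'
#' Independent per-label Bernoulli naive-Bayes classifier over bag-of-words
#' features. An empty question returns each label's training base rate.
#'
#' @param question_text the question.
#' @param model a trained [train_alignment()] model (or the affiliation
#'   component of one).
#' @return named numeric vector of probabilities in `[0, 1]`, one per
#'   ontology label.
#' @export
compute_affiliation <- function(question_text, model) {
  aff <- if (!is.null(model$affiliation)) model$affiliation else model
  if (is.null(aff$vocab)) stop("untrained affiliation model", call. = FALSE)
  x <- bow_vector(question_text, aff$vocab)
  present <- x == 1
  vapply(aff$fit, function(f) {
    # only tokens present in the question discriminate; absent tokens are
    # ignored so short questions degrade gracefully toward the prior
    log_pos <- log(f$prior) + sum(log(f$p1[present]))
    log_neg <- log(1 - f$prior) + sum(log(f$p0[present]))
    1 / (1 + exp(log_neg - log_pos))
  }, numeric(1))
}

#' Train the cross-ontology score alignment model
#'
#' Learns a per-ontology scale `w_o` (kept positive, so within-ontology
#' order is preserved) and a question-dependent bias `u_o . x(q)` by
#' stochastic gradient descent on a pairwise margin objective that ranks
#' each gold answer above every non-gold answer after adjustment.
#'
#' @param training_set list of examples, each a list with `question` (text),
#'   `gold_entity` (IRI), `gold_ontology` (label) and `answers` (named list
#'   by ontology of data.frames with `entity`, `norm_score`, `ontology`).
#' @param seed integer seed (example shuffling).
#' @param margin pairwise margin.
#' @param learning_rate SGD step size.
#' @param epochs training epochs.
#' @return object of class `alignment_model` with `w` (named vector), `u`
#'   (label x vocab matrix), `affiliation` (naive-Bayes affiliation model),
#'   `vocab`, `ontologies`, and the final-objective `training_trace`.
#' @export
train_alignment <- function(training_set, seed = 42L, margin = 0.1,
                            learning_rate = 0.05, epochs = 200L) {
  onts <- sort(unique(unlist(lapply(training_set, function(ex)
    names(ex$answers)))))
  if (length(onts) < 2L)
    stop("score alignment needs answers from at least 2 ontologies",
         call. = FALSE)
  questions <- vapply(training_set, `[[`, "", "question")
  affiliation <- train_affiliation_nb(
    questions, vapply(training_set, `[[`, "", "gold_ontology"))
  vocab <- affiliation$vocab

  # precompute per-example normalized candidate tables and features
  prep <- lapply(training_set, function(ex) {
    merged <- normalize_scores_baseline(ex$answers)
    gold <- merged$entity == ex$gold_entity &
      merged$ontology == ex$gold_ontology
    if (!any(gold)) stop("gold answer missing from candidate lists",
                         call. = FALSE)
    list(s = merged$merged_score, ont = match(merged$ontology, onts),
         gold = which(gold)[1L], x = bow_vector(ex$question, vocab))
  })

  w <- stats::setNames(rep(1, length(onts)), onts)
  U <- matrix(0, length(onts), length(vocab),
              dimnames = list(onts, NULL))
  set.seed(as.integer(seed))
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    total <- 0
    for (i in sample.int(length(prep))) {
      ex <- prep[[i]]
      bias <- as.vector(U %*% ex$x)
      adj <- w[ex$ont] * ex$s + bias[ex$ont]
      g <- ex$gold
      viol <- which(adj[g] - adj < margin)
      viol <- setdiff(viol, g)
      total <- total + sum(pmax(0, margin - (adj[g] - adj[viol])))
      if (length(viol) == 0L) next
      og <- ex$ont[g]
      # gradient: push gold up, violators down
      w[og] <- w[og] + learning_rate * length(viol) * ex$s[g]
      U[og, ] <- U[og, ] + learning_rate * length(viol) * ex$x
      for (v in viol) {
        ov <- ex$ont[v]
        w[ov] <- w[ov] - learning_rate * ex$s[v]
        U[ov, ] <- U[ov, ] - learning_rate * ex$x
      }
      w <- pmax(w, 1e-6)  # keep within-ontology order intact
    }
    trace[ep] <- total
  }
  structure(list(w = w, u = U, affiliation = affiliation, vocab = vocab,
                 ontologies = onts, training_trace = trace),
            class = "alignment_model")
}

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf("<alignment_model: %d ontologies (%s), vocab %d>\n",
              length(x$ontologies), paste(x$ontologies, collapse = ", "),
              length(x$vocab)))
  invisible(x)
}

#' Rerank answers from multiple QA engines on one scale
#'
#' Max-normalizes each ontology's scores, applies the learned affine
#' adjustment `w_o * s + u_o . x(q)` and merges all lists sorted by the
#' adjusted score (deterministic tie-break: ontology label, entity).
#'
#' @param question_text the question (source of the bias features).
#' @param answers named list by ontology label of data.frames with
#'   `entity`, `norm_score`, `ontology`.
#' @param model a trained [train_alignment()] model.
#' @return merged data.frame with an `aligned_score` column.
#' @export
rerank_cross_ontology <- function(question_text, answers, model) {
  unknown <- setdiff(names(answers), model$ontologies)
  if (length(unknown))
    stop(sprintf("alignment model does not cover ontologies: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  merged <- normalize_scores_baseline(answers)
  x <- bow_vector(question_text, model$vocab)
  bias <- as.vector(model$u %*% x)
  oi <- match(merged$ontology, model$ontologies)
  merged$aligned_score <- model$w[oi] * merged$merged_score + bias[oi]
  merged <- merged[order(-merged$aligned_score, merged$ontology, merged$entity), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Save / load an alignment model as JSON
#'
#' @param model an alignment_model.
#' @param path file path.
#' @return `save_alignment_model` the path invisibly; `load_alignment_model`
#'   an alignment_model.
#' @export
save_alignment_model <- function(model, path) {
  jsonlite::write_json(
    list(w = as.list(model$w), u = model$u, vocab = model$vocab,
         ontologies = model$ontologies,
         affiliation = list(vocab = model$affiliation$vocab,
                            labels = model$affiliation$labels,
                            fit = model$affiliation$fit),
         training_trace = model$training_trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_alignment_model
#' @export
load_alignment_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- lapply(m$affiliation$fit, function(f)
    list(prior = f$prior, p1 = as.numeric(f$p1), p0 = as.numeric(f$p0)))
  structure(list(
    w = stats::setNames(as.numeric(m$w), names(m$w)),
    u = matrix(as.numeric(m$u), nrow = length(m$ontologies),
               dimnames = list(m$ontologies, NULL)),
    affiliation = list(vocab = m$affiliation$vocab,
                       labels = m$affiliation$labels, fit = fit),
    vocab = m$vocab, ontologies = m$ontologies,
    training_trace = as.numeric(m$training_trace)),
    class = "alignment_model")
}
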