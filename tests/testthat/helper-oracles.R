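# Independent brute-force oracles. These deliberately use plain loops and
# direct definitions, not the package's vectorized code paths.

oracle_transe <- function(h, r, t, norm_order) {
  acc <- 0
  for (i in seq_along(h)) {
    u <- h[i] + r[i] - t[i]
    acc <- acc + if (norm_order == 1) abs(u) else u * u
  }
  if (norm_order == 1) acc else sqrt(acc)
}

oracle_complex <- function(h, r, t) {
  acc <- 0 + 0i
  for (i in seq_along(h)) acc <- acc + h[i] * r[i] * Conj(t[i])
  Re(acc)
}

oracle_matvec <- function(M, v) {
  out <- numeric(nrow(M))
  for (i in seq_len(nrow(M))) {
    s <- 0
    for (j in seq_len(ncol(M))) s <- s + M[i, j] * v[j]
    out[i] <- s
  }
  out
}

oracle_dot <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + a[i] * b[i]
  s
}

# breadth-first search over an explicit adjacency list
oracle_bfs <- function(kg, head, n, direction) {
  tri <- kg$triples
  frontier <- head
  seen <- head
  for (hop in seq_len(n)) {
    nxt <- integer(0)
    for (f in frontier) {
      nxt <- c(nxt, tri[tri[, 1L] == f, 3L])
      if (direction == "both") nxt <- c(nxt, tri[tri[, 3L] == f, 1L])
    }
    frontier <- setdiff(unique(nxt), seen)
    seen <- c(seen, frontier)
  }
  sort(setdiff(seen, head))
}

# exhaustive recursive enumeration of simple paths of length 2..max_hops;
# returns list(triples = data.frame(head, label, tail), support = named counts)
oracle_enumerate <- function(kg, max_hops, allow_inverse = FALSE) {
  tri <- kg$triples
  plain <- !grepl("|", kg$relations[tri[, 2L]], fixed = TRUE)
  tri <- tri[plain, , drop = FALSE]
  results <- list()
  support <- new.env(parent = emptyenv())
  step <- function(node) {
    out <- tri[tri[, 1L] == node, , drop = FALSE]
    steps <- lapply(seq_len(nrow(out)), function(i)
      list(rel = kg$relations[out[i, 2L]], to = out[i, 3L], inv = FALSE))
    if (allow_inverse) {
      inn <- tri[tri[, 3L] == node, , drop = FALSE]
      steps <- c(steps, lapply(seq_len(nrow(inn)), function(i)
        list(rel = kg$relations[inn[i, 2L]], to = inn[i, 1L], inv = TRUE)))
    }
    steps
  }
  recurse <- function(start, node, labels, visited) {
    if (length(labels) >= 2L) {
      lab <- paste(labels, collapse = "|")
      results[[length(results) + 1L]] <<- c(start, lab, node)
      support[[lab]] <<- (if (is.null(support[[lab]])) 0L else support[[lab]]) + 1L
    }
    if (length(labels) >= max_hops) return()
    for (s in step(node)) {
      if (s$to %in% visited) next
      recurse(start, s$to, c(labels, if (s$inv) paste0("^", s$rel) else s$rel),
              c(visited, s$to))
    }
  }
  for (start in seq_along(kg$entities)) recurse(start, start, character(0), start)
  if (length(results) == 0L)
    return(list(triples = data.frame(head = character(), label = character(),
                                     tail = character(), stringsAsFactors = FALSE),
                support = integer(0)))
  m <- do.call(rbind, results)
  df <- unique(data.frame(head = kg$entities[as.integer(m[, 1L])],
                          label = m[, 2L],
                          tail = kg$entities[as.integer(m[, 3L])],
                          stringsAsFactors = FALSE))
  df <- df[order(df$head, df$label, df$tail), , drop = FALSE]
  rownames(df) <- NULL
  supp <- vapply(ls(support), function(l) support[[l]], integer(1))
  list(triples = df, support = supp)
}

# classic dynamic-programming edit distance
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  D <- matrix(0L, la + 1L, lb + 1L)
  D[, 1L] <- 0:la; D[1L, ] <- 0:lb
  for (i in seq_len(la)) for (j in seq_len(lb))
    D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L,
                             D[i, j] + (a[i] != b[j]))
  D[la + 1L, lb + 1L]
}

# sort-based rank oracle (higher-is-better scores)
oracle_rank <- function(scores, true_index, tie_policy) {
  ord <- order(-scores)
  pos <- which(ord == true_index)
  ties <- which(scores == scores[true_index])
  first <- 1 + sum(scores > scores[true_index])
  switch(tie_policy,
         optimistic = first,
         pessimistic = first + length(ties) - 1,
         average = first + (length(ties) - 1) / 2)
}

triples_df <- function(kg) {
  data.frame(head = kg$entities[kg$triples[, 1L]],
             relation = kg$relations[kg$triples[, 2L]],
             tail = kg$entities[kg$triples[, 3L]], stringsAsFactors = FALSE)
}

# small random KG (plain edge sampling, no planted structure)
random_kg <- function(seed, n_nodes = 20L, n_rel = 3L, n_edges = 30L,
                      n_attr = 0L, with_labels = FALSE) {
  set.seed(seed)
  ent <- sprintf("e%02d", seq_len(n_nodes))
  rel <- sprintf("r%d", seq_len(n_rel))
  tri <- unique(data.frame(
    head = sample(ent, n_edges, TRUE), relation = sample(rel, n_edges, TRUE),
    tail = sample(ent, n_edges, TRUE), stringsAsFactors = FALSE))
  tri <- tri[tri$head != tri$tail, , drop = FALSE]
  at <- NULL
  if (n_attr > 0L)
    at <- data.frame(entity = sample(ent, n_attr, TRUE),
                     attribute = sample(c("weight", "bp"), n_attr, TRUE),
                     value = round(stats::runif(n_attr, 0, 100), 3),
                     unit = sample(c("g/mol", "K", ""), n_attr, TRUE),
                     stringsAsFactors = FALSE)
  labels <- NULL
  if (with_labels)
    labels <- data.frame(iri = ent, label = paste0("name ", ent),
                         type = "species", aliases = paste0("al", seq_len(n_nodes)),
                         stringsAsFactors = FALSE)
  knowledge_graph(tri, at, labels, "rand")
}
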