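# Synthetic knowledge graphs with planted geometric structure.
#
# The generator emulates the structures the embedding methods assume:
# entities carry latent vectors, each relation a latent translation, and
# every generated triple (h, r, t) satisfies t* ~= h* + r* up to a small
# placement noise. It plants (i) 1-to-N relations with geometric fan-out,
# (ii) numeric attributes that are noisy linear functions of the latents
# (v = e* . l* + b* + noise), (iii) deep calculation chains whose leaf
# values sit `chain_depth` hops from their species entity, and (iv) a label
# table with pseudo-word names and aliases for entity-linking experiments.
# Everything is reproducible from the seed.

#' Synthetic knowledge-graph configuration
#'
#' @param n_entities total entities per ontology.
#' @param n_relations total relations; when deep chains are enabled the last
#'   `chain_depth` relations are reserved as the chain-hop relations.
#' @param dim latent dimension (defaults to the trainer's default dimension
#'   so exact recovery is possible).
#' @param one_to_n_fraction fraction of the general relations that are
#'   1-to-N.
#' @param fanout_p success probability of the truncated geometric fan-out
#'   draw for 1-to-N relations.
#' @param max_fanout fan-out truncation.
#' @param geom_noise sd of the placement noise around `h* + r*`.
#' @param n_attributes number of numeric attributes.
#' @param attr_fraction fraction of entities carrying each attribute.
#' @param sigma observation noise sd of attribute values.
#' @param n_deep_chains number of species -> ... -> leaf chains.
#' @param chain_depth hops from species to leaf (>= 2).
#' @param n_ontologies number of independent ontologies to generate.
#' @param test_fraction fraction of general triples held out for evaluation.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_entities = 200L, n_relations = 8L, dim = 16L,
                             one_to_n_fraction = 0.25, fanout_p = 0.5,
                             max_fanout = 5L, geom_noise = 0.02,
                             n_attributes = 3L, attr_fraction = 0.7,
                             sigma = 0.05, n_deep_chains = 12L,
                             chain_depth = 3L, n_ontologies = 1L,
                             test_fraction = 0.2, seed = 1L) {
  stopifnot(n_entities >= 10L, n_relations >= 1L, dim >= 2L,
            one_to_n_fraction >= 0, one_to_n_fraction <= 1,
            fanout_p > 0, fanout_p <= 1, max_fanout >= 1L, geom_noise >= 0,
            n_attributes >= 0L, attr_fraction > 0, attr_fraction <= 1,
            sigma >= 0, n_deep_chains >= 0L,
            n_deep_chains == 0L || chain_depth >= 2L,
            n_ontologies >= 1L, test_fraction >= 0, test_fraction < 1)
  if (n_deep_chains > 0L && n_relations <= chain_depth)
    stop("n_relations must exceed chain_depth when deep chains are enabled",
         call. = FALSE)
  chain_budget <- n_deep_chains * (chain_depth + 1L)
  if (chain_budget + 10L > n_entities)
    stop("infeasible config: deep chains exceed the entity budget",
         call. = FALSE)
  structure(as.list(environment())[names(formals(synthetic_config))],
            class = "synthetic_config")
}

consonants <- strsplit("bcdfghklmnprstvz", "")[[1]]
vowels <- strsplit("aeiou", "")[[1]]

make_words <- function(n, n_syllables = 3L) {
  out <- character(0)
  while (length(out) < n) {
    w <- vapply(seq_len(n - length(out)), function(i)
      paste0(sample(consonants, n_syllables, TRUE),
             sample(vowels, n_syllables, TRUE), collapse = ""),
      character(1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate planted knowledge graphs
#'
#' @param config a [synthetic_config()].
#' @return list with `kgs` (named list of knowledge_graph, one per
#'   ontology) and `truth` (named list of ground-truth records: latent
#'   entity/relation/attribute parameters, chains, train/test triple split,
#'   question templates).
#' @export
generate_planted_kg <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  kgs <- list(); truth <- list()
  for (o in seq_len(config$n_ontologies)) {
    one <- generate_one_ontology(config, o)
    kgs[[one$ontology]] <- one$kg
    truth[[one$ontology]] <- one$truth
  }
  list(kgs = kgs, truth = truth)
}

generate_one_ontology <- function(config, o) {
  set.seed((config$seed + 7919L * o) %% 2147483647L)
  d <- config$dim
  n <- config$n_entities
  ontology <- sprintf("onto%d", o)
  has_chains <- config$n_deep_chains > 0L
  n_chain_rel <- if (has_chains) config$chain_depth else 0L
  n_general <- config$n_relations - n_chain_rel
  rel_words <- make_words(config$n_relations + config$n_attributes)
  attr_words <- utils::tail(rel_words, config$n_attributes)
  rel_words <- utils::head(rel_words, config$n_relations)
  rel_iris <- paste0(ontology, ":", rel_words)
  general_rel <- seq_len(n_general)
  chain_rel <- if (has_chains) n_general + seq_len(n_chain_rel) else integer(0)
  n_1n <- round(config$one_to_n_fraction * n_general)
  one_to_n <- utils::head(general_rel, n_1n)

  # latent translations, norm 0.5
  R <- matrix(stats::rnorm(config$n_relations * d), config$n_relations, d)
  R <- R / sqrt(rowSums(R * R)) * 0.5

  E <- matrix(0, n, d)
  used <- 0L
  new_entity <- function(pos) {
    used <<- used + 1L
    E[used, ] <<- pos
    used
  }
  jitter <- function() stats::rnorm(d, 0, config$geom_noise)
  tri_h <- integer(0); tri_r <- integer(0); tri_t <- integer(0)
  tri_keys <- new.env(parent = emptyenv())
  add_triple <- function(h, r, t) {
    key <- paste(h, r, t)
    if (h == t || !is.null(tri_keys[[key]])) return(FALSE)
    tri_keys[[key]] <- TRUE
    tri_h <<- c(tri_h, h); tri_r <<- c(tri_r, r); tri_t <<- c(tri_t, t)
    TRUE
  }

  # deep chains: species -> ... -> leaf, one fresh entity per node
  chains <- NULL
  for (ci in seq_len(config$n_deep_chains)) {
    node <- new_entity(stats::runif(d, -0.5, 0.5))
    species <- node
    for (step in seq_len(config$chain_depth)) {
      nxt <- new_entity(E[node, ] + R[chain_rel[step], ] + jitter())
      add_triple(node, chain_rel[step], nxt)
      node <- nxt
    }
    chains <- rbind(chains, c(species = species, leaf = node))
  }

  # general entities live on the integer lattice spanned by the general
  # relation translations: an entity with coordinate c sits at
  # base + sum_i c_i R_i (+ placement jitter). Relation paths commute there,
  # so distinct paths meet at shared points; materializing the lattice
  # closure (every pair one +r step apart) yields a dense, geometrically
  # consistent triple set. Multiple entities in one cell are near-duplicate
  # points and give the 1-to-N fan-out clusters.
  coord_max <- 2L
  coords <- matrix(0L, n, max(n_general, 1L))
  lattice <- integer(0)
  base <- stats::runif(d, -0.3, 0.3)
  pos_of <- function(cd)
    base + as.vector(cd %*% R[general_rel, , drop = FALSE]) + jitter()
  origin <- new_entity(pos_of(coords[1L, ]))
  lattice <- c(lattice, origin)
  attempts <- 0L
  while (used < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n) {  # degenerate walk: fill cells uniformly
      cd <- sample.int(coord_max + 1L, n_general, replace = TRUE) - 1L
    } else {
      h <- lattice[sample.int(length(lattice), 1L)]
      r <- if (n_general > 1L) sample.int(n_general, 1L) else 1L
      cd <- coords[h, ]; cd[r] <- cd[r] + 1L
      if (cd[r] > coord_max) next
    }
    k <- if (general_rel[r] %in% one_to_n)
      min(1L + stats::rgeom(1L, config$fanout_p), config$max_fanout, n - used)
    else 1L
    for (j in seq_len(max(k, 1L))) {
      if (used >= n) break
      t <- new_entity(pos_of(cd))
      coords[t, ] <- cd
      lattice <- c(lattice, t)
    }
  }
  cell <- split(lattice,
                apply(coords[lattice, , drop = FALSE], 1L, paste, collapse = ","))
  for (h in lattice) {
    for (r in seq_len(n_general)) {
      cd <- coords[h, ]; cd[r] <- cd[r] + 1L
      for (t in cell[[paste(cd, collapse = ",")]] %||% integer(0))
        add_triple(h, general_rel[r], t)
    }
  }
  # guarantee every general relation appears at least once: connect the
  # entity pair whose latent geometry best matches the translation
  missing_rel <- setdiff(general_rel, unique(tri_r))
  for (r in missing_rel) {
    t_cand <- sample.int(used, 1L)
    translated <- sweep(E[seq_len(used), , drop = FALSE], 2L, R[r, ], "+")
    d2 <- rowSums(sweep(translated, 2L, E[t_cand, ], "-")^2)
    d2[t_cand] <- Inf
    add_triple(which.min(d2), r, t_cand)
  }

  # scale everything into the unit ball; translation structure is preserved
  mx <- max(sqrt(rowSums(E * E)))
  sc <- if (mx > 0.95) 0.95 / mx else 1
  E <- E * sc; R <- R * sc

  # attributes: noisy linear readouts of the latents
  attr_iris <- if (config$n_attributes > 0L)
    paste0(ontology, ":", attr_words) else character(0)
  units <- c("g/mol", "K", "eV", "pa", "nm")
  AL <- matrix(stats::rnorm(config$n_attributes * d), config$n_attributes, d)
  if (config$n_attributes > 0L)
    AL <- AL / sqrt(rowSums(AL * AL))
  AB <- stats::runif(config$n_attributes, -0.25, 0.25)
  at <- NULL
  n_per_attr <- round(config$attr_fraction * n)
  for (a in seq_len(config$n_attributes)) {
    who <- sort(sample.int(n, n_per_attr))
    v <- as.vector(E[who, , drop = FALSE] %*% AL[a, ]) + AB[a] +
      stats::rnorm(n_per_attr, 0, config$sigma)
    at <- rbind(at, data.frame(entity = who, attribute = a, value = v,
                               unit = units[(a - 1L) %% length(units) + 1L],
                               stringsAsFactors = FALSE))
  }

  # labels: pseudo-word names, an abbreviation alias and a formula alias
  ent_iris <- paste0(ontology, sprintf(":E%04d", seq_len(n)))
  ent_words <- make_words(n)
  formulas <- sprintf("C%dH%d", sample.int(30L, n, TRUE), sample.int(60L, n, TRUE))
  abbrev <- toupper(substr(ent_words, 1L, 3L))
  types <- rep("species", n)
  if (has_chains) types[chains[, "leaf"]] <- "value"
  labels <- data.frame(iri = ent_iris, label = ent_words, type = types,
                       aliases = paste(abbrev, formulas, sep = "|"),
                       stringsAsFactors = FALSE)

  tri_df <- data.frame(head = ent_iris[tri_h], relation = rel_iris[tri_r],
                       tail = ent_iris[tri_t], stringsAsFactors = FALSE)
  at_df <- if (is.null(at)) NULL else
    data.frame(entity = ent_iris[at$entity], attribute = attr_iris[at$attribute],
               value = at$value, unit = at$unit, stringsAsFactors = FALSE)
  kg <- knowledge_graph(tri_df, at_df, labels, ontology)

  # train/test split over the general (non-chain) triples, keeping every
  # entity and relation covered in train
  is_chain <- tri_r %in% chain_rel
  cand <- which(!is_chain)
  n_test <- floor(config$test_fraction * length(cand))
  test_idx <- sort(sample(cand, n_test))
  repeat {
    train_idx <- setdiff(seq_along(tri_h), test_idx)
    ent_cov <- unique(c(tri_h[train_idx], tri_t[train_idx]))
    rel_cov <- unique(tri_r[train_idx])
    uncovered <- !(tri_h[test_idx] %in% ent_cov & tri_t[test_idx] %in% ent_cov &
                     tri_r[test_idx] %in% rel_cov)
    if (!any(uncovered)) break
    test_idx <- test_idx[!uncovered]
  }
  train_idx <- setdiff(seq_along(tri_h), test_idx)

  # two template phrasings per relation: one for the relation predictor,
  # a held-out phrasing for generated test questions
  templates <- data.frame(
    relation = rep(rel_iris, 2L),
    template = c(sprintf("what is the %s of {entity}?", rel_words),
                 sprintf("tell me the %s of {entity}", rel_words)),
    split = rep(c("train", "test"), each = config$n_relations),
    stringsAsFactors = FALSE)

  truth <- list(
    ontology = ontology, dim = d,
    ent_latent = `rownames<-`(E, ent_iris),
    rel_latent = `rownames<-`(R, rel_iris),
    attr_l = if (config$n_attributes > 0L) `rownames<-`(AL, attr_iris),
    attr_b = stats::setNames(AB, attr_iris),
    sigma = config$sigma,
    chain_relations = rel_iris[chain_rel],
    chains = if (has_chains)
      data.frame(species = ent_iris[chains[, "species"]],
                 leaf = ent_iris[chains[, "leaf"]], stringsAsFactors = FALSE),
    one_to_n = rel_iris[one_to_n],
    train_triples = tri_df[train_idx, , drop = FALSE],
    test_triples = tri_df[test_idx, , drop = FALSE],
    templates = templates,
    attr_words = stats::setNames(attr_words, attr_iris))
  rownames(truth$train_triples) <- rownames(truth$test_triples) <- NULL
  list(ontology = ontology, kg = kg, truth = truth)
}

#' Knowledge graph restricted to the training split
#'
#' @param planted output of [generate_planted_kg()].
#' @param ontology ontology label (default the first).
#' @return knowledge_graph containing only the training triples (attribute
#'   triples and labels unchanged).
#' @export
training_kg <- function(planted, ontology = names(planted$kgs)[1L]) {
  kg <- planted$kgs[[ontology]]
  tr <- planted$truth[[ontology]]$train_triples
  knowledge_graph(tr, attr_df_chr(kg), kg$labels, kg$ontology)
}

#' Exact embedding space from the generator's ground truth
#'
#' Builds an embedding space directly from the planted latents: entity rows
#' are the latent vectors, each relation row its latent translation, and a
#' composite relation `"a|b|c"` the sum of its step translations. With zero
#' placement noise every planted triple scores exactly 0. The attribute
#' head, when present, is the planted linear map.
#'
#' @param kg the (possibly augmented) knowledge_graph.
#' @param truth the matching ground-truth record.
#' @return an `embedding_space` (method `"TransEA"` when attributes exist,
#'   else `"TransE"`).
#' @export
exact_space_from_truth <- function(kg, truth) {
  d <- truth$dim
  ent <- truth$ent_latent[kg$entities, , drop = FALSE]
  rel <- t(vapply(kg$relations, function(r) {
    steps <- strsplit(r, "|", fixed = TRUE)[[1L]]
    colSums(truth$rel_latent[steps, , drop = FALSE])
  }, numeric(d)))
  has_attr <- length(kg$attributes) > 0L && !is.null(truth$attr_l)
  space <- list(method = if (has_attr) "TransEA" else "TransE", dim = d,
                ontology = kg$ontology, entities = kg$entities,
                relations = kg$relations, attributes = kg$attributes,
                polarity = "distance",
                ent = unname(ent), rel = unname(rel),
                config = training_config(dim = d, squared = FALSE),
                loss_trace = numeric(0))
  if (has_attr) {
    space$attr_vec <- unname(truth$attr_l[kg$attributes, , drop = FALSE])
    space$attr_bias <- unname(truth$attr_b[kg$attributes])
  }
  class(space) <- "embedding_space"
  space
}

perturb_mention <- function(word, rng_chars = letters) {
  n <- nchar(word)
  if (n < 2L) return(word)
  pos <- sample.int(n, 1L)
  if (stats::runif(1) < 0.5) {
    # substitute one character
    repl <- sample(setdiff(rng_chars, substr(word, pos, pos)), 1L)
    paste0(substr(word, 1L, pos - 1L), repl, substr(word, pos + 1L, n))
  } else {
    # delete one character
    paste0(substr(word, 1L, pos - 1L), substr(word, pos + 1L, n))
  }
}

#' Generate question sets with gold answers
#'
#' Builds natural-language questions from the held-out template phrasings:
#' one single-hop question per held-out test triple, one multihop question
#' per deep chain (relation = the composite chain label, answerable after
#' [augment_with_multihop()]), and numerical filter questions per attribute.
#' Mentions are the head entity's label, optionally perturbed by a
#' single-character edit at `perturb_rate` for entity-linking experiments.
#'
#' @param planted output of [generate_planted_kg()].
#' @param config the generating [synthetic_config()].
#' @param perturb_rate fraction of mentions receiving a single-character
#'   edit.
#' @param n_numeric numerical questions per attribute.
#' @param seed seed for perturbation/sampling randomness.
#' @return named list by ontology; each element has `questions` (list of
#'   entries with `question`, `head`, `mention`, `relation`, `gold`, `type`,
#'   plus operator/value/unit for numeric questions) and `templates` (the
#'   predictor-facing training phrasings).
#' @export
generate_questions <- function(planted, config, perturb_rate = 0,
                               n_numeric = 5L,
                               seed = (config$seed + 104729L) %% 2147483647L) {
  set.seed(as.integer(seed))
  out <- list()
  for (ontology in names(planted$kgs)) {
    kg <- planted$kgs[[ontology]]
    tr <- planted$truth[[ontology]]
    lab_of <- stats::setNames(kg$labels$label, kg$labels$iri)
    word_of <- stats::setNames(
      gsub("[_-]", " ", sub(".*[:/#]", "", kg$relations)), kg$relations)
    test_tpl <- tr$templates[tr$templates$split == "test", , drop = FALSE]
    tpl_of <- stats::setNames(test_tpl$template, test_tpl$relation)
    all_keys <- paste(kg$triples[, 1L], kg$triples[, 2L])
    gold_tails <- split(kg$entities[kg$triples[, 3L]], all_keys)

    qs <- list()
    mk_mention <- function(label) {
      if (perturb_rate > 0 && stats::runif(1) < perturb_rate)
        perturb_mention(label) else label
    }
    tt <- tr$test_triples
    for (i in seq_len(nrow(tt))) {
      h <- tt$head[i]; r <- tt$relation[i]
      label <- unname(lab_of[h])
      key <- paste(match(h, kg$entities), match(r, kg$relations))
      qs[[length(qs) + 1L]] <- list(
        question = sub("{entity}", label, tpl_of[[r]], fixed = TRUE),
        head = h, mention = mk_mention(label), relation = r,
        gold = unname(gold_tails[[key]]), type = "single-hop")
    }
    if (!is.null(tr$chains)) {
      comp <- paste(tr$chain_relations, collapse = "|")
      comp_words <- paste(word_of[tr$chain_relations], collapse = " ")
      for (i in seq_len(nrow(tr$chains))) {
        h <- tr$chains$species[i]
        label <- unname(lab_of[h])
        qs[[length(qs) + 1L]] <- list(
          question = sprintf("tell me the %s of %s", comp_words, label),
          head = h, mention = mk_mention(label), relation = comp,
          gold = tr$chains$leaf[i], type = "multihop")
      }
    }
    for (a in kg$attributes) {
      aid <- match(a, kg$attributes)
      rows <- kg$attr_triples[kg$attr_triples$attribute == aid, , drop = FALSE]
      word <- gsub("[_-]", " ", sub(".*[:/#]", "", a))
      for (j in seq_len(n_numeric)) {
        op <- sample(c("larger", "smaller", "close"), 1L)
        value <- round(stats::quantile(rows$value, stats::runif(1), names = FALSE), 3)
        unit <- rows$unit[1L]
        tau <- 0.05 * max(abs(value), 1e-6)
        keep <- switch(op, larger = rows$value > value,
                       smaller = rows$value < value,
                       close = abs(rows$value - value) <= tau)
        phrase <- switch(op, larger = "larger than", smaller = "smaller than",
                         close = "close to")
        qs[[length(qs) + 1L]] <- list(
          question = sprintf("which species have a %s %s %s %s?",
                             word, phrase, format(value), unit),
          attribute = a, operator = op, value = value, unit = unit, tau = tau,
          gold = unique(kg$entities[rows$entity[keep]]), type = "numeric")
      }
    }
    train_tpl <- tr$templates[tr$templates$split == "train", , drop = FALSE]
    out[[ontology]] <- list(questions = qs,
                            templates = train_tpl[, c("relation", "template")])
  }
  out
}
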