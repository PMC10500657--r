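# Training for the five embedding methods. Plain stochastic gradient descent
# on a margin ranking loss over corrupted triples, with an optional joint
# linear attribute head (TransEA / TransRA) weighted by alpha, entity-norm
# projection after each batch, and a per-epoch mean-loss trace.
#
# Reduction identities honoured by construction:
#  - TransRA(alpha = 0) performs exactly the updates of TransR, and
#    TransEA(alpha = 0) those of TransE, with identical seeded RNG streams:
#    initialization draws happen in a fixed order (entities, relations,
#    projections [no RNG], attributes), the RNG is re-seeded before the epoch
#    loop, and the attribute step draws nothing when alpha == 0.

KGQA_METHODS <- c("TransE", "TransEA", "TransR", "TransRA", "ComplEx")

method_uses_attributes <- function(method) method %in% c("TransEA", "TransRA")
method_uses_projection <- function(method) method %in% c("TransR", "TransRA")

#' Training configuration
#'
#' Defaults are chosen for desk-scale reproducibility on graphs of a few
#' hundred entities; all are overridable.
#'
#' @param margin hinge margin gamma (>= 0).
#' @param alpha attribute weight in `[0, 1]`; used only by TransEA/TransRA.
#' @param dim embedding dimension d.
#' @param norm_order 1 or 2, norm for translation distances.
#' @param squared use squared L2 distance; `NULL` means the per-method
#'   default (unsquared for TransE/TransEA, squared for TransR/TransRA).
#' @param penalty attribute penalty, `"squared"` or `"absolute"`.
#' @param learning_rate SGD step size.
#' @param epochs number of passes over the relation triples.
#' @param batch_size triples per SGD batch.
#' @param negatives corrupted triples per positive.
#' @param norm_constraint project entity embeddings to the unit ball after
#'   each batch; `NULL` means on for translation methods, off for ComplEx.
#' @param filtered_negatives avoid sampling corruptions that are known true
#'   triples (best effort inside training batches).
#' @param loss `"margin"` (default) or `"logistic"` (ComplEx only; trains the
#'   similarity with a logistic objective instead of negated-distance margin
#'   ranking).
#' @param seed integer seed controlling initialization and sampling.
#' @return an object of class `training_config`.
#' @export
training_config <- function(margin = 1, alpha = 0.3, dim = 16, norm_order = 2,
                            squared = NULL, penalty = c("squared", "absolute"),
                            learning_rate = 0.01, epochs = 500, batch_size = 128,
                            negatives = 1, norm_constraint = NULL,
                            filtered_negatives = TRUE,
                            loss = c("margin", "logistic"), seed = 42L) {
  penalty <- match.arg(penalty)
  loss <- match.arg(loss)
  stopifnot(margin >= 0, alpha >= 0, alpha <= 1, dim >= 1,
            norm_order %in% c(1, 2), learning_rate > 0, epochs >= 0,
            batch_size >= 1, negatives >= 1)
  structure(list(margin = margin, alpha = alpha, dim = as.integer(dim),
                 norm_order = norm_order, squared = squared, penalty = penalty,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 negatives = as.integer(negatives),
                 norm_constraint = norm_constraint,
                 filtered_negatives = isTRUE(filtered_negatives), loss = loss,
                 seed = as.integer(seed)),
            class = "training_config")
}

resolve_config <- function(config, method) {
  if (is.null(config$squared))
    config$squared <- method_uses_projection(method)
  if (is.null(config$norm_constraint))
    config$norm_constraint <- method != "ComplEx"
  if (config$loss == "logistic" && method != "ComplEx")
    stop("logistic loss is available for ComplEx only", call. = FALSE)
  config
}

#' Corrupt one side of a triple (negative sampling)
#'
#' Replaces the head or tail of a triple with a uniformly drawn entity.
#' With `filtered = TRUE` the corrupted triple is guaranteed not to be a
#' known true triple of the graph. Uses the current RNG state.
#'
#' @param triple character vector `c(head, relation, tail)` of IRIs, or
#'   integer ids of length 3.
#' @param kg a knowledge_graph with at least 2 entities.
#' @param side `"uniform"` (pick head or tail at random), `"head"` or `"tail"`.
#' @param filtered exclude corruptions that are known true triples.
#' @return a triple in the same form as the input, differing from it on
#'   exactly one side; errors with class `kgqa_negative_exhausted` when
#'   `filtered` and no valid corruption exists.
#' @export
negative_sample <- function(triple, kg, side = c("uniform", "head", "tail"),
                            filtered = TRUE) {
  side <- match.arg(side)
  n_ent <- length(kg$entities)
  if (n_ent < 2L) stop("need at least 2 entities", call. = FALSE)
  chr <- is.character(triple)
  h <- entity_id(kg, triple[[1L]]); r <- relation_id(kg, triple[[2L]])
  t <- entity_id(kg, triple[[3L]])
  pick <- if (side == "uniform") sample(c("head", "tail"), 1L) else side
  orig <- if (pick == "head") h else t
  cand <- setdiff(seq_len(n_ent), orig)
  if (filtered) {
    keys <- triple_keys(kg$triples)
    cand_keys <- if (pick == "head") paste(cand, r, t, sep = "\r")
                 else paste(h, r, cand, sep = "\r")
    cand <- cand[!(cand_keys %in% keys)]
  }
  if (length(cand) == 0L) {
    if (side == "uniform") {
      # try the other side before giving up
      other <- if (pick == "head") "tail" else "head"
      return(negative_sample(triple, kg, other, filtered))
    }
    stop_kgqa("no valid corruption exists for this triple/side",
              "kgqa_negative_exhausted")
  }
  repl <- cand[sample.int(length(cand), 1L)]
  out <- c(h, r, t)
  out[if (pick == "head") 1L else 3L] <- repl
  if (chr) c(kg$entities[out[1L]], kg$relations[out[2L]], kg$entities[out[3L]])
  else out
}

init_embedding_space <- function(kg, method, config) {
  d <- config$dim
  n <- length(kg$entities); m <- length(kg$relations)
  a <- length(kg$attributes)
  bound <- 6 / sqrt(d)
  runif_mat <- function(nr) matrix(stats::runif(nr * d, -bound, bound), nr, d)
  ball_project <- function(x) {
    nrm <- sqrt(rowSums(x * x))
    sc <- pmin(1, 1 / pmax(nrm, 1e-12))
    x * sc
  }
  space <- list(method = method, dim = d, ontology = kg$ontology,
                entities = kg$entities, relations = kg$relations,
                attributes = kg$attributes,
                polarity = if (method == "ComplEx") "similarity" else "distance",
                config = config)
  if (method == "ComplEx") {
    space$ent <- runif_mat(n); space$ent_im <- runif_mat(n)
    space$rel <- runif_mat(m); space$rel_im <- runif_mat(m)
    if (isTRUE(config$norm_constraint)) {
      nrm <- sqrt(rowSums(space$ent^2 + space$ent_im^2))
      sc <- pmin(1, 1 / pmax(nrm, 1e-12))
      space$ent <- space$ent * sc; space$ent_im <- space$ent_im * sc
    }
  } else {
    space$ent <- ball_project(runif_mat(n))
    space$rel <- runif_mat(m)
    if (method_uses_projection(method))
      space$proj <- lapply(seq_len(m), function(i) diag(d))
    if (method_uses_attributes(method)) {
      space$attr_vec <- runif_mat(max(a, 0L))
      space$attr_bias <- numeric(a)
    }
  }
  space$init_entity_norms <- if (method == "ComplEx")
    sqrt(rowSums(space$ent^2 + space$ent_im^2)) else sqrt(rowSums(space$ent^2))
  space$loss_trace <- numeric(0)
  class(space) <- "embedding_space"
  space
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space %s d=%d: %d entities, %d relations%s, polarity=%s>\n",
              x$method, x$dim, length(x$entities), length(x$relations),
              if (length(x$attributes)) sprintf(", %d attributes", length(x$attributes)) else "",
              x$polarity))
  invisible(x)
}

# raw plausibility scores for id-vectors h, r, t (equal length).
# polarity follows the space: distances for translation methods,
# similarities for ComplEx.
#' Score triples under a trained embedding space
#'
#' @param space an embedding_space.
#' @param h,r,t equal-length integer id vectors (entity, relation, entity).
#' @return numeric score vector; distances (lower = better) for the
#'   translation methods, similarities (higher = better) for ComplEx.
#' @export
score_triples <- function(space, h, r, t) {
  cfg <- resolve_config(space$config, space$method)
  method <- space$method
  if (method == "ComplEx") {
    hr <- space$ent[h, , drop = FALSE]; hi <- space$ent_im[h, , drop = FALSE]
    rr <- space$rel[r, , drop = FALSE]; ri <- space$rel_im[r, , drop = FALSE]
    tr <- space$ent[t, , drop = FALSE]; ti <- space$ent_im[t, , drop = FALSE]
    return(rowSums((hr * rr - hi * ri) * tr + (hr * ri + hi * rr) * ti))
  }
  if (method_uses_projection(method)) {
    out <- numeric(length(h))
    for (rid in unique(r)) {
      ii <- which(r == rid)
      M <- space$proj[[rid]]
      U <- space$ent[h[ii], , drop = FALSE] %*% t(M) -
        space$ent[t[ii], , drop = FALSE] %*% t(M)
      U <- sweep(U, 2L, space$rel[rid, ], "+")
      out[ii] <- lp_norm(U, cfg$norm_order, cfg$squared)
    }
    return(out)
  }
  U <- space$ent[h, , drop = FALSE] + space$rel[r, , drop = FALSE] -
    space$ent[t, , drop = FALSE]
  lp_norm(U, cfg$norm_order, cfg$squared)
}

lp_norm <- function(U, norm_order, squared) {
  if (norm_order == 1) rowSums(abs(U))
  else if (squared) rowSums(U * U)
  else sqrt(rowSums(U * U))
}

# gradient of the distance wrt U (the translation residual rows)
lp_grad <- function(U, norm_order, squared) {
  if (norm_order == 1) sign(U)
  else if (squared) 2 * U
  else U / pmax(sqrt(rowSums(U * U)), 1e-12)
}

#' Train knowledge-graph embeddings
#'
#' Stochastic gradient descent with margin ranking loss over corrupted
#' triples; TransEA/TransRA additionally fit the linear attribute head
#' `e . l + b ~ v` on the graph's numeric attribute triples, with the two
#' objectives combined as `(1 - alpha) L_relation + alpha L_attribute`.
#' Training is reproducible given `config$seed`; per-epoch mean combined
#' loss is recorded in `loss_trace`.
#'
#' @param kg a knowledge_graph with at least one relation triple.
#' @param method one of `"TransE"`, `"TransEA"`, `"TransR"`, `"TransRA"`,
#'   `"ComplEx"`.
#' @param config a [training_config()].
#' @return a trained `embedding_space`.
#' @export
train_embeddings <- function(kg, method = KGQA_METHODS,
                             config = training_config()) {
  method <- match.arg(method)
  config <- resolve_config(config, method)
  if (nrow(kg$triples) == 0L) stop("kg has no relation triples", call. = FALSE)
  if (method_uses_attributes(method) && nrow(kg$attr_triples) == 0L)
    stop(sprintf("%s requires attribute triples", method), call. = FALSE)

  set.seed(config$seed)
  space <- init_embedding_space(kg, method, config)
  if (config$epochs == 0L) return(space)
  # decouple the epoch-loop RNG stream from initialization so methods with
  # different parameter sets draw identical training randomness
  set.seed((config$seed + 1L) %% 2147483647L)

  tri <- kg$triples
  nT <- nrow(tri)
  n_ent <- length(kg$entities)
  keys <- triple_keys(tri)
  at <- kg$attr_triples
  alpha_w <- if (method_uses_attributes(method)) config$alpha else 0
  lr <- config$learning_rate
  use_attr <- method_uses_attributes(method) && config$alpha > 0
  trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(nT)
    rel_loss <- 0; rel_n <- 0L; attr_loss_sum <- 0; attr_n <- 0L
    for (start in seq(1L, nT, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, nT)]
      if (config$negatives > 1L) idx <- rep(idx, config$negatives)
      nb <- length(idx)
      hp <- tri[idx, 1L]; rp <- tri[idx, 2L]; tp <- tri[idx, 3L]

      side <- sample.int(2L, nb, replace = TRUE)  # 1 = head, 2 = tail
      repl <- sample.int(n_ent, nb, replace = TRUE)
      for (round in 1:10) {
        nh <- ifelse(side == 1L, repl, hp)
        nt <- ifelse(side == 2L, repl, tp)
        bad <- repl == ifelse(side == 1L, hp, tp)
        if (config$filtered_negatives)
          bad <- bad | (paste(nh, rp, nt, sep = "\r") %in% keys)
        if (!any(bad)) break
        repl[bad] <- sample.int(n_ent, sum(bad), replace = TRUE)
      }
      nh <- ifelse(side == 1L, repl, hp)
      nt <- ifelse(side == 2L, repl, tp)

      step <- sgd_relation_step(space, config, method, hp, rp, tp, nh, nt,
                                lr * (1 - alpha_w))
      space <- step$space
      rel_loss <- rel_loss + step$loss_sum; rel_n <- rel_n + nb

      if (use_attr) {
        ii <- sample.int(nrow(at), min(config$batch_size, nrow(at)),
                         replace = nrow(at) < config$batch_size)
        step <- sgd_attribute_step(space, config, at[ii, , drop = FALSE],
                                   lr * alpha_w)
        space <- step$space
        attr_loss_sum <- attr_loss_sum + step$loss_sum
        attr_n <- attr_n + length(ii)
      }

      if (isTRUE(config$norm_constraint)) space <- project_entity_norms(space)
    }
    attr_mean <- if (attr_n > 0L) attr_loss_sum / attr_n else 0
    trace[epoch] <- (1 - alpha_w) * rel_loss / rel_n + alpha_w * attr_mean
  }
  space$loss_trace <- trace
  space
}

sgd_relation_step <- function(space, config, method, hp, rp, tp, nh, nt, lr) {
  if (method == "ComplEx")
    return(sgd_complex_step(space, config, hp, rp, tp, nh, nt, lr))
  sp <- score_triples(space, hp, rp, tp)
  sn <- score_triples(space, nh, rp, nt)
  hinge <- config$margin + sp - sn
  act <- which(hinge > 0)
  loss_sum <- sum(pmax(0, hinge))
  if (length(act) == 0L) return(list(space = space, loss_sum = loss_sum))
  hp <- hp[act]; rp <- rp[act]; tp <- tp[act]; nh <- nh[act]; nt <- nt[act]

  if (!method_uses_projection(method)) {
    Up <- space$ent[hp, , drop = FALSE] + space$rel[rp, , drop = FALSE] -
      space$ent[tp, , drop = FALSE]
    Un <- space$ent[nh, , drop = FALSE] + space$rel[rp, , drop = FALSE] -
      space$ent[nt, , drop = FALSE]
    Gp <- lp_grad(Up, config$norm_order, config$squared)
    Gn <- lp_grad(Un, config$norm_order, config$squared)
    G <- rowsum(rbind(Gp, -Gp, -Gn, Gn), c(hp, tp, nh, nt))
    uid <- as.integer(rownames(G))
    space$ent[uid, ] <- space$ent[uid, , drop = FALSE] - lr * G
    GR <- rowsum(rbind(Gp, -Gn), c(rp, rp))
    rid <- as.integer(rownames(GR))
    space$rel[rid, ] <- space$rel[rid, , drop = FALSE] - lr * GR
    return(list(space = space, loss_sum = loss_sum))
  }

  # relation-space methods: per-relation projected residuals and
  # projection-matrix gradients
  ids <- integer(0); grads <- NULL; rids <- integer(0); rgrads <- NULL
  for (rid in unique(rp)) {
    ii <- which(rp == rid)
    M <- space$proj[[rid]]; tM <- t(M)
    Hp <- space$ent[hp[ii], , drop = FALSE]; Tp <- space$ent[tp[ii], , drop = FALSE]
    Hn <- space$ent[nh[ii], , drop = FALSE]; Tn <- space$ent[nt[ii], , drop = FALSE]
    Up <- sweep((Hp - Tp) %*% tM, 2L, space$rel[rid, ], "+")
    Un <- sweep((Hn - Tn) %*% tM, 2L, space$rel[rid, ], "+")
    Gp <- lp_grad(Up, config$norm_order, config$squared)
    Gn <- lp_grad(Un, config$norm_order, config$squared)
    GpM <- Gp %*% M; GnM <- Gn %*% M   # chain rule through the projection
    ids <- c(ids, hp[ii], tp[ii], nh[ii], nt[ii])
    grads <- rbind(grads, GpM, -GpM, -GnM, GnM)
    rids <- c(rids, rid)
    rgrads <- rbind(rgrads, colSums(Gp) - colSums(Gn))
    dM <- crossprod(Gp, Hp - Tp) - crossprod(Gn, Hn - Tn)
    space$proj[[rid]] <- M - lr * dM
  }
  G <- rowsum(grads, ids)
  uid <- as.integer(rownames(G))
  space$ent[uid, ] <- space$ent[uid, , drop = FALSE] - lr * G
  space$rel[rids, ] <- space$rel[rids, , drop = FALSE] - lr * rgrads
  list(space = space, loss_sum = loss_sum)
}

# gradients of Re(<h, r, conj(t)>) wrt the six component matrices
complex_score_grads <- function(space, h, r, t) {
  hr <- space$ent[h, , drop = FALSE]; hi <- space$ent_im[h, , drop = FALSE]
  rr <- space$rel[r, , drop = FALSE]; ri <- space$rel_im[r, , drop = FALSE]
  tr <- space$ent[t, , drop = FALSE]; ti <- space$ent_im[t, , drop = FALSE]
  list(score = rowSums((hr * rr - hi * ri) * tr + (hr * ri + hi * rr) * ti),
       dhr = rr * tr + ri * ti, dhi = -ri * tr + rr * ti,
       drr = hr * tr + hi * ti, dri = -hi * tr + hr * ti,
       dtr = hr * rr - hi * ri, dti = hr * ri + hi * rr)
}

sgd_complex_step <- function(space, config, hp, rp, tp, nh, nt, lr) {
  gp <- complex_score_grads(space, hp, rp, tp)
  gn <- complex_score_grads(space, nh, rp, nt)
  if (config$loss == "margin") {
    # distances are negated similarities
    hinge <- config$margin - gp$score + gn$score
    act <- hinge > 0
    loss_sum <- sum(pmax(0, hinge))
    wp <- -as.numeric(act)   # d loss / d score_pos
    wn <- as.numeric(act)
  } else {
    # logistic: softplus(-s_pos) + softplus(s_neg)
    loss_sum <- sum(log1p(exp(-gp$score))) + sum(log1p(exp(gn$score)))
    wp <- -stats::plogis(-gp$score)
    wn <- stats::plogis(gn$score)
    act <- rep(TRUE, length(hp))
  }
  if (!any(wp != 0 | wn != 0)) return(list(space = space, loss_sum = loss_sum))

  Gr <- rowsum(rbind(wp * gp$dhr, wp * gp$dtr, wn * gn$dhr, wn * gn$dtr),
               c(hp, tp, nh, nt))
  Gi <- rowsum(rbind(wp * gp$dhi, wp * gp$dti, wn * gn$dhi, wn * gn$dti),
               c(hp, tp, nh, nt))
  uid <- as.integer(rownames(Gr))
  space$ent[uid, ] <- space$ent[uid, , drop = FALSE] - lr * Gr
  space$ent_im[uid, ] <- space$ent_im[uid, , drop = FALSE] - lr * Gi
  RR <- rowsum(rbind(wp * gp$drr, wn * gn$drr), c(rp, rp))
  RI <- rowsum(rbind(wp * gp$dri, wn * gn$dri), c(rp, rp))
  rid <- as.integer(rownames(RR))
  space$rel[rid, ] <- space$rel[rid, , drop = FALSE] - lr * RR
  space$rel_im[rid, ] <- space$rel_im[rid, , drop = FALSE] - lr * RI
  list(space = space, loss_sum = loss_sum)
}

sgd_attribute_step <- function(space, config, at, lr) {
  e <- at$entity; a <- at$attribute; v <- at$value
  pred <- rowSums(space$ent[e, , drop = FALSE] * space$attr_vec[a, , drop = FALSE]) +
    space$attr_bias[a]
  res <- pred - v
  if (config$penalty == "squared") {
    loss_sum <- sum(res * res); g <- 2 * res
  } else {
    loss_sum <- sum(abs(res)); g <- sign(res)
  }
  GE <- rowsum(g * space$attr_vec[a, , drop = FALSE], e)
  uid <- as.integer(rownames(GE))
  space$ent[uid, ] <- space$ent[uid, , drop = FALSE] - lr * GE
  GL <- rowsum(g * space$ent[e, , drop = FALSE], a)
  aid <- as.integer(rownames(GL))
  space$attr_vec[aid, ] <- space$attr_vec[aid, , drop = FALSE] - lr * GL
  gb <- rowsum(matrix(g, ncol = 1L), a)
  space$attr_bias[aid] <- space$attr_bias[aid] - lr * as.vector(gb)
  list(space = space, loss_sum = loss_sum)
}

project_entity_norms <- function(space) {
  if (space$method == "ComplEx") {
    nrm <- sqrt(rowSums(space$ent^2 + space$ent_im^2))
    sc <- pmin(1, 1 / pmax(nrm, 1e-12))
    space$ent <- space$ent * sc
    space$ent_im <- space$ent_im * sc
  } else {
    nrm <- sqrt(rowSums(space$ent^2))
    sc <- pmin(1, 1 / pmax(nrm, 1e-12))
    space$ent <- space$ent * sc
  }
  space
}

#' Predict attribute values for many entities at once
#'
#' Vectorized linear attribute head `v_hat = e . l + b` over all (or a
#' subset of) entities for one attribute.
#'
#' @param space a TransEA/TransRA embedding_space.
#' @param attribute attribute IRI or id.
#' @param entities integer entity ids (default all).
#' @return numeric vector of predicted values, named by entity IRI.
#' @export
predict_attribute_values <- function(space, attribute,
                                     entities = seq_along(space$entities)) {
  if (is.null(space$attr_vec))
    stop("space has no attribute head (train with TransEA or TransRA)",
         call. = FALSE)
  aid <- if (is.character(attribute)) match(attribute, space$attributes)
         else as.integer(attribute)
  if (is.na(aid) || aid < 1L || aid > length(space$attributes))
    stop_kgqa(sprintf("attribute not found in space: %s", attribute),
              "kgqa_attribute_not_found")
  v <- as.vector(space$ent[entities, , drop = FALSE] %*% space$attr_vec[aid, ]) +
    space$attr_bias[aid]
  stats::setNames(v, space$entities[entities])
}

#' Persist / load an embedding space as text files
#'
#' Writes a JSON manifest (method, dimension, alpha, polarity and the full
#' vocabularies) plus one TSV matrix file per parameter block. The loader
#' validates the vocabularies against a knowledge graph when one is given.
#'
#' @param space an embedding_space.
#' @param dir directory (created if missing).
#' @param kg optional knowledge_graph to validate vocabularies against.
#' @return `save_embedding_space` the directory invisibly;
#'   `load_embedding_space` an embedding_space.
#' @export
save_embedding_space <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- space$config
  manifest <- list(method = space$method, dim = space$dim,
                   ontology = space$ontology, polarity = space$polarity,
                   alpha = cfg$alpha, norm_order = cfg$norm_order,
                   squared = resolve_config(cfg, space$method)$squared,
                   seed = cfg$seed,
                   entities = space$entities, relations = space$relations,
                   attributes = space$attributes,
                   loss_trace = space$loss_trace)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  wm <- function(x, f) utils::write.table(
    format(x, digits = 17, trim = TRUE, scientific = TRUE),
    file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  wm(space$ent, "ent.tsv")
  wm(space$rel, "rel.tsv")
  if (!is.null(space$ent_im)) { wm(space$ent_im, "ent_im.tsv"); wm(space$rel_im, "rel_im.tsv") }
  if (!is.null(space$proj)) wm(do.call(rbind, space$proj), "proj.tsv")
  if (!is.null(space$attr_vec) && length(space$attributes)) {
    wm(space$attr_vec, "attr_vec.tsv")
    wm(matrix(space$attr_bias, ncol = 1L), "attr_bias.tsv")
  }
  invisible(dir)
}

#' @rdname save_embedding_space
#' @export
load_embedding_space <- function(dir, kg = NULL) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rm_ <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    as.matrix(utils::read.table(p, sep = "\t", header = FALSE,
                                colClasses = "numeric"))
  }
  d <- as.integer(man$dim)
  space <- list(method = man$method, dim = d, ontology = man$ontology,
                entities = man$entities, relations = man$relations,
                attributes = man$attributes %||% character(0),
                polarity = man$polarity,
                config = training_config(alpha = man$alpha,
                                         norm_order = man$norm_order,
                                         squared = man$squared,
                                         seed = man$seed),
                loss_trace = man$loss_trace %||% numeric(0))
  space$ent <- unname(rm_("ent.tsv")); space$rel <- unname(rm_("rel.tsv"))
  space$ent_im <- unname(rm_("ent_im.tsv")); space$rel_im <- unname(rm_("rel_im.tsv"))
  proj <- rm_("proj.tsv")
  if (!is.null(proj))
    space$proj <- lapply(seq_along(space$relations),
                         function(i) unname(proj[((i - 1L) * d + 1L):(i * d), , drop = FALSE]))
  space$attr_vec <- unname(rm_("attr_vec.tsv"))
  ab <- rm_("attr_bias.tsv")
  if (!is.null(ab)) space$attr_bias <- as.vector(ab)
  class(space) <- "embedding_space"
  if (!is.null(kg)) {
    if (!identical(space$entities, kg$entities) ||
        !identical(space$relations, kg$relations) ||
        !identical(space$attributes, kg$attributes))
      stop("embedding space vocabularies do not match the knowledge graph",
           call. = FALSE)
  }
  space
}
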