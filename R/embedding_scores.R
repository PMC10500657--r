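# Score functions and losses for the translation-family and bilinear
# embedding methods. Scores for TransE/TransEA/TransR/TransRA are distances
# (lower = more plausible); ComplEx scores are similarities (higher = better).

#' TransE translation distance
#'
#' Distance between the translated head `h + r` and the tail `t`,
#' `||h + r - t||` under the L1 or L2 norm. Zero exactly when `t = h + r`.
#'
#' @param h_vec,r_vec,t_vec numeric vectors of equal length.
#' @param norm_order 1 or 2.
#' @param squared if TRUE return the squared L2 distance (the inner form used
#'   by the relation-space methods); ignored for L1.
#' @return nonnegative scalar distance.
#' @export
transe_score <- function(h_vec, r_vec, t_vec, norm_order = 2, squared = FALSE) {
  if (length(h_vec) != length(r_vec) || length(h_vec) != length(t_vec))
    stop("dimension mismatch between h, r, t", call. = FALSE)
  u <- h_vec + r_vec - t_vec
  if (norm_order == 1) sum(abs(u))
  else if (squared) sum(u * u)
  else sqrt(sum(u * u))
}

#' ComplEx trilinear similarity
#'
#' Real part of the trilinear product with the tail conjugated,
#' `Re(<h, r, conj(t)>)`. Positive for plausible triples under a trained
#' model; with all imaginary parts zero this reduces to the real trilinear
#' sum `sum(h * r * t)`.
#'
#' @param h,r,t complex (or numeric) vectors of equal length.
#' @return real scalar similarity.
#' @export
complex_score <- function(h, r, t) {
  if (length(h) != length(r) || length(h) != length(t))
    stop("dimension mismatch between h, r, t", call. = FALSE)
  Re(sum(as.complex(h) * as.complex(r) * Conj(as.complex(t))))
}

#' Relation-space projection (TransR / TransRA)
#'
#' Projects an entity vector into a relation-specific semantic space via the
#' relation's learned d x d projection matrix.
#'
#' @param e_vec numeric d-vector.
#' @param M_r numeric d x d matrix.
#' @return numeric d-vector `M_r %*% e_vec`.
#' @export
transr_project <- function(e_vec, M_r) {
  if (!is.matrix(M_r) || ncol(M_r) != length(e_vec) || nrow(M_r) != length(e_vec))
    stop("shape mismatch: M_r must be d x d with d = length(e_vec)", call. = FALSE)
  as.vector(M_r %*% e_vec)
}

#' Margin ranking (hinge) loss
#'
#' `max(0, gamma + pos_score - neg_score)` for distance scores: zero whenever
#' the corrupted triple is worse than the true one by at least the margin.
#'
#' @param pos_score,neg_score distances of the true and corrupted triple.
#' @param gamma nonnegative margin.
#' @return nonnegative loss (vectorized over inputs).
#' @export
margin_ranking_loss <- function(pos_score, neg_score, gamma) {
  pmax(0, gamma + pos_score - neg_score)
}

#' Numerical attribute loss
#'
#' Penalty on the residual of the linear attribute head, `e . l + b - v`,
#' where `l` is the attribute embedding, `b` its scalar bias and `v` the
#' entity's observed numeric attribute value.
#'
#' @param e_vec entity embedding.
#' @param l_vec attribute embedding (same length).
#' @param b attribute bias.
#' @param v observed value (finite).
#' @param penalty `"squared"` (default; smooth gradients) or `"absolute"`.
#' @return nonnegative loss.
#' @export
attribute_loss <- function(e_vec, l_vec, b, v,
                           penalty = c("squared", "absolute")) {
  penalty <- match.arg(penalty)
  if (length(e_vec) != length(l_vec))
    stop("dimension mismatch between e and l", call. = FALSE)
  assert_scalar_number(v, "v")
  res <- sum(e_vec * l_vec) + b - v
  if (penalty == "squared") res * res else abs(res)
}

#' Combined relation + attribute loss
#'
#' Convex combination `(1 - alpha) * relation_loss + alpha * attr_loss`
#' with the adjustable attribute weight alpha in `[0, 1]`. At `alpha = 0`
#' the joint methods reduce to their relation-only counterparts.
#'
#' @param relation_loss,attr_loss component losses.
#' @param alpha attribute weight in `[0, 1]`.
#' @return combined loss.
#' @export
combined_loss <- function(relation_loss, attr_loss, alpha) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]", call. = FALSE)
  (1 - alpha) * relation_loss + alpha * attr_loss
}

#' Predict an entity's numeric attribute value from embeddings
#'
#' The linear attribute head `v_hat = e . l + b` used by the joint numerical
#' embedding methods for round-one numerical filtering.
#'
#' @param e_vec entity embedding.
#' @param l_vec attribute embedding.
#' @param b attribute bias.
#' @return predicted value.
#' @export
predict_attribute_value <- function(e_vec, l_vec, b) {
  if (length(e_vec) != length(l_vec))
    stop("dimension mismatch between e and l", call. = FALSE)
  sum(e_vec * l_vec) + b
}
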