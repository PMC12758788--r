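# The five training losses. Each loss has a tape builder (ad_*_loss,
# differentiable, used by the training step) and a thin exported numeric
# wrapper that evaluates the same builder on a fresh tape, so there is a
# single source of truth for every formula.

pr_eps_default <- 1e-8

## ---- tape builders ----

# projection regularizer: reciprocal total absolute deviation of the query
# batch about its per-dimension means, plus mean |off-diagonal Pearson
# correlation| and mean |per-dimension mean| of both batches. The deviation
# term is averaged over cells only (summed over dimensions), as printed.
ad_pr_loss <- function(tape, Dq, Dr, eps = pr_eps_default) {
  m <- ncol(Dq$value)
  mean_abs_corr <- function(D) {
    n <- nrow(D$value)
    mu <- ad_colmeans(tape, D)
    Dc <- ad_sub_rowvec(tape, D, mu)
    ss <- ad_scale(tape, ad_colmeans(tape, ad_square(tape, Dc)), n)  # 1 x m colSums
    denom <- ad_sqrt(tape, ad_addc(tape, ss, eps))                   # 1 x m
    C <- ad_matmul(tape, ad_t(tape, Dc), Dc)                         # m x m
    C <- ad_div_rowvec(tape, C, denom)
    C <- ad_div_colvec(tape, C, ad_t(tape, denom))
    offdiag <- matrix(1, m, m) - diag(m)
    ad_scale(tape, ad_sum(tape, ad_mulc(tape, ad_abs(tape, C), offdiag)), 1 / m^2)
  }
  mean_abs_mean <- function(D) {
    ad_scale(tape, ad_sum(tape, ad_abs(tape, ad_colmeans(tape, D))), 1 / m)
  }
  muq <- ad_colmeans(tape, Dq)
  dev <- ad_scale(tape, ad_sum(tape, ad_abs(tape, ad_sub_rowvec(tape, Dq, muq))),
                  1 / nrow(Dq$value))
  t1 <- ad_div(tape, ad_leaf(tape, 1), ad_addc(tape, dev, eps))
  out <- ad_add(tape, t1, mean_abs_corr(Dq))
  out <- ad_add(tape, out, mean_abs_mean(Dq))
  out <- ad_add(tape, out, mean_abs_corr(Dr))
  ad_add(tape, out, mean_abs_mean(Dr))
}

# supervised cross-entropy from logits (stable log-softmax form)
ad_ce_loss_logits <- function(tape, logits, y) {
  lse <- ad_logsumexp_rows(tape, logits)
  ad_mean(tape, ad_sub(tape, lse, ad_pick(tape, logits, y)))
}

# contrastive loss: anchors vs one sampled graph-neighbor positive each;
# negatives are the other anchors of the query batch (cosine similarity,
# temperature tau)
ad_cl_loss <- function(tape, Danchor, Dpos, tau) {
  nb <- nrow(Danchor$value)
  if (nb < 2L) stop_data("contrastive loss needs a batch of at least 2 query cells")
  if (tau <= 0) stop_data("temperature tau must be positive")
  Qn <- ad_l2_normalize_rows(tape, Danchor)
  Pn <- ad_l2_normalize_rows(tape, Dpos)
  s_pos <- ad_scale(tape, ad_rowsums(tape, ad_mul(tape, Qn, Pn)), 1 / tau)
  S <- ad_scale(tape, ad_matmul(tape, Qn, ad_t(tape, Qn)), 1 / tau)
  S <- ad_addc(tape, S, diag(-1e9, nb))      # self never serves as negative
  lse <- ad_logsumexp_rows(tape, ad_cbind(tape, s_pos, S))
  ad_mean(tape, ad_sub(tape, lse, s_pos))
}

# feature alignment: best-match cosine similarity per query cell over the
# reference batch; the top p_frac fraction of query cells (ties broken by
# ascending index) contribute their negated mean
ad_fa_loss <- function(tape, Dq, Dr, p_frac = 0.2) {
  if (p_frac <= 0 || p_frac > 1) stop_data("p_frac must lie in (0, 1]")
  Qn <- ad_l2_normalize_rows(tape, Dq)
  Rn <- ad_l2_normalize_rows(tape, Dr)
  S <- ad_matmul(tape, Qn, ad_t(tape, Rn))
  sv <- S$value
  best_idx <- apply(sv, 1L, which.max)
  best_val <- sv[cbind(seq_len(nrow(sv)), best_idx)]
  n_top <- ceiling(p_frac * nrow(sv))
  sel <- order(-best_val, seq_along(best_val))[seq_len(n_top)]
  best <- ad_pick(tape, S, best_idx)
  ad_scale(tape, ad_mean(tape, ad_gather_rows(tape, best, sel)), -1)
}

# sparse center loss: attention-weighted squared distance to the class
# center, averaged over cells (summed over dimensions); centers are
# non-learnable buffers
ad_sc_loss <- function(tape, D, a, centers, labels) {
  n <- nrow(D$value)
  if (length(labels) != n) stop_data("one label per embedded cell required")
  if (any(labels < 1L) || any(labels > nrow(centers))) {
    stop_data("labels out of range of the class centers")
  }
  Cmat <- centers[labels, , drop = FALSE]
  diff2 <- ad_square(tape, ad_addc(tape, D, -Cmat))
  ad_scale(tape, ad_sum(tape, ad_mul(tape, a, diff2)), 1 / n)
}

## ---- exported numeric wrappers ----

#' Supervised cross-entropy loss
#'
#' Mean over the reference batch of the negative log-probability assigned to
#' each cell's true type.
#'
#' @param p n x K matrix of class probabilities (rows on the simplex).
#' @param y integer labels in `1..K`.
#' @return scalar loss.
#' @export
ce_loss <- function(p, y) {
  p <- as.matrix(p)
  if (nrow(p) == 0L) stop_data("empty batch")
  y <- as.integer(y)
  if (length(y) != nrow(p)) stop_data("one label per row required")
  if (any(y < 1L) || any(y > ncol(p))) stop_data("label out of range")
  -mean(log(p[cbind(seq_along(y), y)]))
}

#' Projection regularization loss
#'
#' Encourages informative, decorrelated, centered embeddings: the
#' reciprocal of the query batch's total absolute deviation about its
#' per-dimension means (averaged over cells), plus the mean absolute
#' off-diagonal Pearson feature correlation and the mean absolute
#' per-dimension mean of both the query and the reference batch. `eps`
#' guards the reciprocal and zero-variance dimensions (whose correlations
#' count as 0).
#'
#' @param d_q,d_r query / reference embedding matrices (same width).
#' @param eps numerical guard (default 1e-8).
#' @return scalar loss.
#' @export
pr_loss <- function(d_q, d_r, eps = pr_eps_default) {
  d_q <- as.matrix(d_q); d_r <- as.matrix(d_r)
  if (nrow(d_q) < 2L || nrow(d_r) < 2L) {
    stop_data("pr_loss needs at least 2 cells per batch (correlation undefined)")
  }
  if (ncol(d_q) != ncol(d_r)) stop_data("embedding widths differ")
  tape <- ad_tape()
  ad_pr_loss(tape, ad_leaf(tape, d_q), ad_leaf(tape, d_r), eps)$value[1L]
}

#' Neighborhood-preserving contrastive loss
#'
#' For each query cell in the batch, one positive is sampled uniformly from
#' its raw-space k-nearest-neighbor list (via the current RNG, or supplied
#' explicitly); negatives are the other batch members. The per-anchor loss
#' is the InfoNCE negative log-softmax of cosine similarities at temperature
#' `tau`, averaged over the batch.
#'
#' @param d_q embedding matrix covering all query cells referenced by
#'   `graph` (row i = query cell i).
#' @param graph a `neighbor_graph` from [build_knn_graph].
#' @param batch_indices integer indices of the anchor cells.
#' @param tau positive temperature.
#' @param positives optional integer vector of positive indices (one per
#'   anchor); sampled from the neighbor lists when `NULL`.
#' @return scalar loss.
#' @export
cl_loss <- function(d_q, graph, batch_indices, tau, positives = NULL) {
  d_q <- as.matrix(d_q)
  if (is.null(positives)) {
    positives <- sample_positives(graph, batch_indices)
  }
  tape <- ad_tape()
  ad_cl_loss(tape,
             ad_leaf(tape, d_q[batch_indices, , drop = FALSE]),
             ad_leaf(tape, d_q[positives, , drop = FALSE]),
             tau)$value[1L]
}

# one uniformly sampled neighbor per anchor (consumes the current RNG)
sample_positives <- function(graph, batch_indices) {
  nbr <- graph$neighbor_indices
  vapply(batch_indices, function(i) {
    row <- nbr[i, ]
    row[sample.int(length(row), 1L)]
  }, integer(1))
}

#' Cross-domain feature alignment loss
#'
#' Each query cell is matched to its most cosine-similar reference cell;
#' the top `p_frac` fraction of query cells by match similarity contribute,
#' and the loss is the negated mean of their best-match similarities
#' (range `[-1, 1]`; more negative = better aligned).
#'
#' @param d_q,d_r query / reference embedding matrices.
#' @param p_frac fraction of query cells kept, in (0, 1] (default 0.2).
#' @return scalar loss.
#' @export
fa_loss <- function(d_q, d_r, p_frac = 0.2) {
  d_q <- as.matrix(d_q); d_r <- as.matrix(d_r)
  if (nrow(d_q) == 0L || nrow(d_r) == 0L) stop_data("empty batch")
  tape <- ad_tape()
  ad_fa_loss(tape, ad_leaf(tape, d_q), ad_leaf(tape, d_r), p_frac)$value[1L]
}

#' Sparse center loss
#'
#' Attention-weighted squared distance of each embedding to its class
#' center, averaged over cells and summed over embedding dimensions:
#' `(1/|B|) sum_i sum_j a_ij (d_ij - c_{y_i,j})^2`. Dimensions the attention
#' network down-weights contribute less, letting the model concentrate
#' class-compactness pressure on discriminative dimensions.
#'
#' @param d n x m embedding matrix (reference and pseudo-labeled query).
#' @param labels integer class labels in `1..K` (true for reference cells,
#'   pseudo-labels for query cells).
#' @param a n x m attention weight matrix.
#' @param centers K x m matrix of class centers.
#' @return scalar loss (nonnegative).
#' @export
sc_loss <- function(d, labels, a, centers) {
  d <- as.matrix(d); a <- as.matrix(a); centers <- as.matrix(centers)
  if (!all(dim(d) == dim(a))) stop_data("attention weights must match embeddings")
  tape <- ad_tape()
  ad_sc_loss(tape, ad_leaf(tape, d), ad_leaf(tape, a), centers,
             as.integer(labels))$value[1L]
}

#' Initialize / update dynamic class centers
#'
#' Centers start at zero and take a partial step toward the batch mean of
#' each class present in the batch:
#' `c_k <- c_k - update_rate * (c_k - mean_k)`. Absent classes are
#' untouched.
#'
#' @param centers K x m matrix (see [init_centers]).
#' @param d n x m embedding matrix.
#' @param labels integer labels in `1..K`.
#' @param update_rate step size in (0, 1] (default 0.5).
#' @return updated K x m matrix.
#' @export
update_centers <- function(centers, d, labels, update_rate = 0.5) {
  stopifnot(update_rate > 0, update_rate <= 1)
  d <- as.matrix(d)
  labels <- as.integer(labels)
  for (k in unique(labels)) {
    mk <- colMeans(d[labels == k, , drop = FALSE])
    centers[k, ] <- centers[k, ] - update_rate * (centers[k, ] - mk)
  }
  centers
}

#' @rdname update_centers
#' @param K number of classes.
#' @param m embedding dimensionality.
#' @export
init_centers <- function(K, m) matrix(0, K, m)

#' Combine the loss terms
#'
#' The joint objective is
#' `L = L_CE + 0.1 * L_PR + alpha * L_CL + beta * L_FA + gamma * L_SC`,
#' with the projection-regularizer coefficient fixed at 0.1.
#'
#' @param l_ce,l_pr,l_cl,l_fa,l_sc the five loss values.
#' @param alpha,beta,gamma nonnegative weights of the contrastive, feature
#'   alignment and sparse center terms.
#' @return a `loss_breakdown` list with the five parts and `total`.
#' @export
total_loss <- function(l_ce, l_pr, l_cl, l_fa, l_sc, alpha, beta, gamma) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma),
            alpha >= 0, beta >= 0, gamma >= 0)
  structure(list(l_ce = l_ce, l_pr = l_pr, l_cl = l_cl, l_fa = l_fa,
                 l_sc = l_sc,
                 total = l_ce + 0.1 * l_pr + alpha * l_cl + beta * l_fa +
                   gamma * l_sc),
            class = "loss_breakdown")
}
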