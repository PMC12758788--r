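#' Specification for a synthetic paired-domain dataset
#'
#' Describes two single-cell datasets (a labeled reference and an unlabeled
#' query) drawn from shared cell-type structure. Each cell type has a mean
#' profile in log-expression space; query means are pushed through a fixed
#' random affine map whose deviation from the identity scales with
#' `shift_strength`, emulating a modality / protocol batch effect that is
#' nonlinear in count space yet invertible, so the transfer task stays
#' solvable. Optional novel types appear only in the query.
#'
#' @param n_ref,n_query cell counts.
#' @param n_features feature count.
#' @param K number of cell types shared by both domains.
#' @param n_novel number of query-only (novel) cell types.
#' @param ref_proportions,query_proportions type proportions (simplex
#'   vectors of length `K` and `K + n_novel`); default uniform.
#' @param separation expected Euclidean distance between two type means in
#'   log-expression space, in units of the within-type noise sd (1).
#' @param shift_strength nonnegative scale of the query affine distortion;
#'   0 means the two domains are exchangeable.
#' @param dropout_rate probability in `[0, 1)` that an observed value is
#'   zeroed (multiplicative Bernoulli dropout).
#' @param seed integer seed; all generator randomness flows through it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_ref = 2000, n_query = 2000, n_features = 150,
                           K = 5, n_novel = 0,
                           ref_proportions = NULL, query_proportions = NULL,
                           separation = 6, shift_strength = 0,
                           dropout_rate = 0.3, seed = 1) {
  if (is.null(ref_proportions)) ref_proportions <- rep(1 / K, K)
  if (is.null(query_proportions)) {
    query_proportions <- rep(1 / (K + n_novel), K + n_novel)
  }
  spec <- structure(list(n_ref = as.integer(n_ref), n_query = as.integer(n_query),
                         n_features = as.integer(n_features), K = as.integer(K),
                         n_novel = as.integer(n_novel),
                         ref_proportions = ref_proportions,
                         query_proportions = query_proportions,
                         separation = separation,
                         shift_strength = shift_strength,
                         dropout_rate = dropout_rate, seed = as.integer(seed)),
                    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_ref < 1L || n_query < 1L || n_features < 1L || K < 1L || n_novel < 0L)
      stop_data("all synthetic counts must be positive (n_novel >= 0)")
    if (abs(sum(ref_proportions) - 1) > 1e-9 ||
        abs(sum(query_proportions) - 1) > 1e-9)
      stop_data("type proportions must sum to 1")
    if (length(ref_proportions) != K)
      stop_data("ref_proportions must have length K")
    if (length(query_proportions) != K + n_novel)
      stop_data("query_proportions must have length K + n_novel")
    if (any(ref_proportions < 0) || any(query_proportions < 0))
      stop_data("type proportions must be nonnegative")
    if (dropout_rate < 0 || dropout_rate >= 1)
      stop_data("dropout_rate must lie in [0, 1)")
    if (shift_strength < 0) stop_data("shift_strength must be nonnegative")
  })
  invisible(spec)
}

# Deterministic latent structure shared by generate_paired_domains and
# generate_marker_lists: type means (shared + novel) and the query affine map.
# Means are scaled so the expected distance between two type means equals
# `separation`.
synthetic_latents <- function(spec) {
  with_seed(spec$seed, {
    p <- spec$n_features
    Kall <- spec$K + spec$n_novel
    mu <- matrix(stats::rnorm(Kall * p), Kall, p) * spec$separation / sqrt(2 * p)
    # The affine distortion acts inside the span of the type means: a random
    # displacement in the full feature space is almost orthogonal to every
    # discriminative direction in high dimension and would leave a
    # reference-trained classifier untouched, whereas real batch effects mix
    # the directions that separate cell types. I + s*B G B' stays invertible
    # for moderate s and reduces to the identity at s = 0.
    s <- spec$shift_strength
    B <- qr.Q(qr(t(mu)))[, seq_len(min(Kall, p)), drop = FALSE]
    G <- matrix(stats::rnorm(ncol(B)^2), ncol(B)) / sqrt(ncol(B))
    A <- diag(p) + s * B %*% G %*% t(B)
    b <- as.vector(s * B %*% stats::rnorm(ncol(B)))
    list(mu = mu, A = A, b = b,
         type_names = paste0("type", seq_len(Kall)))
  })
}

#' Generate a reference/query dataset pair
#'
#' Reference cells are Gaussian (sd 1) around their type mean in log space
#' and exponentiated to nonnegative pseudo-counts; query cells use the
#' affinely shifted type means. Dropout is applied to both domains. The true
#' query labels are returned only for evaluation — the query matrix itself
#' carries no labels.
#'
#' @param spec a [synthetic_spec].
#' @return list with `ref` (labeled [expression_matrix]), `query` (unlabeled
#'   [expression_matrix]) and `query_labels` (character vector of held-out
#'   true types, `"type<K+1>"` ... for novel cells).
#' @export
generate_paired_domains <- function(spec) {
  validate_synthetic_spec(spec)
  lat <- synthetic_latents(spec)
  with_seed(spec$seed + 1L, {
    p <- spec$n_features
    ref_t <- sample.int(spec$K, spec$n_ref, replace = TRUE,
                        prob = spec$ref_proportions)
    qry_t <- sample.int(spec$K + spec$n_novel, spec$n_query, replace = TRUE,
                        prob = spec$query_proportions)
    g_ref <- lat$mu[ref_t, , drop = FALSE] +
      matrix(stats::rnorm(spec$n_ref * p), spec$n_ref, p)
    mu_q <- sweep(lat$mu %*% t(lat$A), 2L, lat$b, "+")
    g_qry <- mu_q[qry_t, , drop = FALSE] +
      matrix(stats::rnorm(spec$n_query * p), spec$n_query, p)
    x_ref <- exp(g_ref)
    x_qry <- exp(g_qry)
    if (spec$dropout_rate > 0) {
      x_ref <- x_ref * matrix(stats::rbinom(length(x_ref), 1L,
                                            1 - spec$dropout_rate),
                              nrow(x_ref), ncol(x_ref))
      x_qry <- x_qry * matrix(stats::rbinom(length(x_qry), 1L,
                                            1 - spec$dropout_rate),
                              nrow(x_qry), ncol(x_qry))
    }
    feat <- paste0("feat", seq_len(p))
    ref <- expression_matrix(x_ref,
                             cell_ids = paste0("ref", seq_len(spec$n_ref)),
                             feature_names = feat,
                             labels = lat$type_names[ref_t])
    qry <- expression_matrix(x_qry,
                             cell_ids = paste0("qry", seq_len(spec$n_query)),
                             feature_names = feat)
    list(ref = ref, query = qry, query_labels = lat$type_names[qry_t])
  })
}

#' Planted ground-truth marker features per cell type
#'
#' For each type (shared and novel), returns the `n_markers` features with
#' the largest absolute gap between that type's latent mean and the average
#' latent mean of the other types — the features the generator itself made
#' discriminative. Ties are broken by ascending feature index.
#'
#' @param spec the same [synthetic_spec] passed to [generate_paired_domains].
#' @param n_markers markers per type.
#' @return named list of character vectors of feature names.
#' @export
generate_marker_lists <- function(spec, n_markers = 20) {
  validate_synthetic_spec(spec)
  if (n_markers > spec$n_features) {
    stop_data("n_markers exceeds the number of features")
  }
  lat <- synthetic_latents(spec)
  Kall <- nrow(lat$mu)
  out <- vector("list", Kall)
  names(out) <- lat$type_names
  feat <- paste0("feat", seq_len(spec$n_features))
  for (t in seq_len(Kall)) {
    gap <- abs(lat$mu[t, ] - colMeans(lat$mu[-t, , drop = FALSE]))
    ord <- order(-gap, seq_along(gap))
    out[[t]] <- feat[ord[seq_len(n_markers)]]
  }
  out
}
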