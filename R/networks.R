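#' Model architecture configuration
#'
#' The annotator has three parts sharing one embedding space of width `m`:
#' a feature extractor `f` (fully connected, batch-normalized ReLU hidden
#' layers), a linear softmax classifier `c` over the `K` reference cell
#' types, and an auxiliary attention network `A`. The attention network
#' consists of a context-encoder unit (linear to `e_dim`, batch norm, tanh)
#' followed by `m` two-logit heads that score each embedding dimension for
#' inclusion vs exclusion; the two-way softmax of those scores is the
#' attention weight used by the sparse center loss.
#'
#' @param input_dim number of input features.
#' @param K number of reference cell types (>= 2).
#' @param hidden_dims integer vector of hidden widths for `f` (default 1024).
#' @param m embedding dimensionality (default 64).
#' @param e_dim context-encoder latent width (default 32).
#' @return an object of class `model_config`.
#' @export
model_config <- function(input_dim, K, hidden_dims = 1024L, m = 64L, e_dim = 32L) {
  stopifnot(input_dim >= 1, K >= 2, m >= 1, e_dim >= 1, all(hidden_dims >= 1))
  structure(list(input_dim = as.integer(input_dim), K = as.integer(K),
                 hidden_dims = as.integer(hidden_dims), m = as.integer(m),
                 e_dim = as.integer(e_dim)),
            class = "model_config")
}

#' Initialize model parameters
#'
#' Deterministic given `seed`. Hidden layers use He-scaled Gaussian weights;
#' linear output layers use 1/sqrt(fan-in) scaling; biases start at zero,
#' batch-norm gains at one. The two attention head banks start identical so
#' the initial attention weight is exactly 0.5 everywhere (no dimension is
#' preferred before training).
#'
#' @param config a [model_config].
#' @param seed integer seed.
#' @return an object of class `lb_model`: list with `config`, `params`
#'   (named matrices), `buffers` (batch-norm running statistics), and slots
#'   `classes` / `feature_names` filled in by [fit_annotator].
#' @export
init_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    p <- list()
    dims <- c(config$input_dim, config$hidden_dims)
    for (l in seq_along(config$hidden_dims)) {
      fan <- dims[l]
      p[[paste0("W", l)]] <- matrix(stats::rnorm(fan * dims[l + 1L]) * sqrt(2 / fan),
                                    fan, dims[l + 1L])
      p[[paste0("b", l)]] <- matrix(0, 1L, dims[l + 1L])
      p[[paste0("bn_g", l)]] <- matrix(1, 1L, dims[l + 1L])
      p[[paste0("bn_b", l)]] <- matrix(0, 1L, dims[l + 1L])
    }
    h_last <- dims[length(dims)]
    p$W_emb <- matrix(stats::rnorm(h_last * config$m) * sqrt(1 / h_last),
                      h_last, config$m)
    p$b_emb <- matrix(0, 1L, config$m)
    # zero-init linear head: the untrained classifier is exactly uniform
    # (confidence 1/K), so early pseudo-labels carry no spurious signal
    p$W_cls <- matrix(0, config$m, config$K)
    p$b_cls <- matrix(0, 1L, config$K)
    # attention: CE-Unit then inclusion/exclusion head banks
    p$W_att <- matrix(stats::rnorm(config$m * config$e_dim) * sqrt(1 / config$m),
                      config$m, config$e_dim)
    p$b_att <- matrix(0, 1L, config$e_dim)
    p$bn_g_att <- matrix(1, 1L, config$e_dim)
    p$bn_b_att <- matrix(0, 1L, config$e_dim)
    A0 <- matrix(stats::rnorm(config$e_dim * config$m) * sqrt(1 / config$e_dim),
                 config$e_dim, config$m)
    p$A_in <- A0
    p$A_ex <- A0       # identical start -> attention 0.5 everywhere
    p$b_in <- matrix(0, 1L, config$m)
    p$b_ex <- matrix(0, 1L, config$m)
    buffers <- list()
    for (l in seq_along(config$hidden_dims)) {
      buffers[[paste0("rm", l)]] <- rep(0, dims[l + 1L])
      buffers[[paste0("rv", l)]] <- rep(1, dims[l + 1L])
    }
    buffers$rm_att <- rep(0, config$e_dim)
    buffers$rv_att <- rep(1, config$e_dim)
    structure(list(config = config, params = p, buffers = buffers,
                   classes = NULL, feature_names = NULL),
              class = "lb_model")
  })
}

#' @export
print.lb_model <- function(x, ...) {
  cat(sprintf("label-transfer model: %d features -> [%s] -> m=%d, K=%d, e_dim=%d%s\n",
              x$config$input_dim, paste(x$config$hidden_dims, collapse = ","),
              x$config$m, x$config$K, x$config$e_dim,
              if (is.null(x$classes)) " (untrained)" else " (trained)"))
  invisible(x)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# numeric batch-norm, eval mode
bn_eval_num <- function(X, g, b, rm, rv) {
  Xh <- sweep(sweep(X, 2L, rm, "-"), 2L, sqrt(rv + bn_eps), "/")
  sweep(sweep(Xh, 2L, as.vector(g), "*"), 2L, as.vector(b), "+")
}

#' Embed cells into the shared space
#'
#' Runs the feature extractor in evaluation mode (batch-norm layers use
#' running statistics), so the output is a deterministic function of the
#' parameters and the input.
#'
#' @param model an `lb_model`.
#' @param x numeric matrix (cells x input features).
#' @return n x m matrix of embeddings.
#' @export
embed_cells <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$config$input_dim) {
    stop_data("input has ", ncol(x), " features but the model expects ",
              model$config$input_dim)
  }
  p <- model$params; bf <- model$buffers
  H <- x
  for (l in seq_along(model$config$hidden_dims)) {
    H <- H %*% p[[paste0("W", l)]]
    H <- sweep(H, 2L, as.vector(p[[paste0("b", l)]]), "+")
    H <- bn_eval_num(H, p[[paste0("bn_g", l)]], p[[paste0("bn_b", l)]],
                     bf[[paste0("rm", l)]], bf[[paste0("rv", l)]])
    H <- pmax(H, 0)
  }
  sweep(H %*% p$W_emb, 2L, as.vector(p$b_emb), "+")
}

softmax_rows <- function(L) {
  if (nrow(L) == 0L) return(L)
  mx <- apply(L, 1L, max)
  E <- exp(L - mx)
  E / rowSums(E)
}

#' Classify embedded cells
#'
#' Applies the linear classifier head and a row-wise softmax.
#'
#' @param model an `lb_model`.
#' @param d n x m embedding matrix.
#' @return list: `p` (n x K probabilities), `predicted_class` (integer,
#'   1-based), `confidence` (row maxima of `p`).
#' @export
classify_cells <- function(model, d) {
  d <- as.matrix(d)
  if (ncol(d) != model$config$m) stop_data("embedding width mismatch")
  L <- sweep(d %*% model$params$W_cls, 2L, as.vector(model$params$b_cls), "+")
  p <- softmax_rows(L)
  list(p = p,
       predicted_class = if (nrow(p)) max.col(p, ties.method = "first") else integer(0),
       confidence = if (nrow(p)) apply(p, 1L, max) else numeric(0))
}

#' Attention weights over embedding dimensions
#'
#' The context-encoder unit maps the embedding to an `e_dim` latent
#' (linear + batch norm + tanh); each embedding dimension's head scores it
#' for inclusion and exclusion, and the attention weight is the two-way
#' softmax `exp(p_in) / (exp(p_in) + exp(p_ex))`, computed stably as the
#' logistic of `p_in - p_ex`. Evaluation mode.
#'
#' @param model an `lb_model`.
#' @param d n x m embedding matrix.
#' @return list: `a` (n x m weights, strictly in (0,1)), `latent` (n x
#'   e_dim), `p_in`, `p_ex` (n x m score matrices).
#' @export
attention_weights <- function(model, d) {
  d <- as.matrix(d)
  if (ncol(d) != model$config$m) stop_data("embedding width mismatch")
  p <- model$params; bf <- model$buffers
  E <- sweep(d %*% p$W_att, 2L, as.vector(p$b_att), "+")
  E <- tanh(bn_eval_num(E, p$bn_g_att, p$bn_b_att, bf$rm_att, bf$rv_att))
  p_in <- sweep(E %*% p$A_in, 2L, as.vector(p$b_in), "+")
  p_ex <- sweep(E %*% p$A_ex, 2L, as.vector(p$b_ex), "+")
  z <- p_in - p_ex
  a <- ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z)))
  a <- matrix(a, nrow(d), model$config$m)
  list(a = a, latent = E, p_in = p_in, p_ex = p_ex)
}

## ---- tape-based training-mode forward ----

# lift all parameters onto the tape; returns named list of leaf nodes
ad_param_leaves <- function(tape, params) {
  lapply(params, function(v) ad_leaf(tape, v))
}

# extractor forward in training mode (batch statistics); returns the
# embedding node and the batch bn stats for running-buffer updates
nn_embed_train <- function(tape, leaves, config, Xnode) {
  H <- Xnode
  stats <- list()
  for (l in seq_along(config$hidden_dims)) {
    H <- ad_add_rowvec(tape, ad_matmul(tape, H, leaves[[paste0("W", l)]]),
                       leaves[[paste0("b", l)]])
    bn <- ad_batchnorm_train(tape, H, leaves[[paste0("bn_g", l)]],
                             leaves[[paste0("bn_b", l)]], eps = bn_eps)
    stats[[paste0("l", l)]] <- bn[c("batch_mean", "batch_var")]
    H <- ad_relu(tape, bn$out)
  }
  D <- ad_add_rowvec(tape, ad_matmul(tape, H, leaves$W_emb), leaves$b_emb)
  list(d = D, bn_stats = stats)
}

nn_logits <- function(tape, leaves, Dnode) {
  ad_add_rowvec(tape, ad_matmul(tape, Dnode, leaves$W_cls), leaves$b_cls)
}

# attention forward in training mode; returns attention node + bn stats
nn_attention_train <- function(tape, leaves, Dnode) {
  E <- ad_add_rowvec(tape, ad_matmul(tape, Dnode, leaves$W_att), leaves$b_att)
  bn <- ad_batchnorm_train(tape, E, leaves$bn_g_att, leaves$bn_b_att, eps = bn_eps)
  E <- ad_tanh(tape, bn$out)
  p_in <- ad_add_rowvec(tape, ad_matmul(tape, E, leaves$A_in), leaves$b_in)
  p_ex <- ad_add_rowvec(tape, ad_matmul(tape, E, leaves$A_ex), leaves$b_ex)
  a <- ad_sigmoid(tape, ad_sub(tape, p_in, p_ex))
  list(a = a, bn_stats = bn[c("batch_mean", "batch_var")])
}

# extractor + classifier forward in EVAL mode on the tape (for integrated
# gradients: batch-norm is a fixed affine map, rows independent)
nn_logits_eval_tape <- function(tape, model, Xnode) {
  p <- model$params; bf <- model$buffers
  leaves <- ad_param_leaves(tape, p)
  H <- Xnode
  for (l in seq_along(model$config$hidden_dims)) {
    H <- ad_add_rowvec(tape, ad_matmul(tape, H, leaves[[paste0("W", l)]]),
                       leaves[[paste0("b", l)]])
    H <- ad_batchnorm_eval(tape, H, leaves[[paste0("bn_g", l)]],
                           leaves[[paste0("bn_b", l)]],
                           bf[[paste0("rm", l)]], bf[[paste0("rv", l)]],
                           eps = bn_eps)
    H <- ad_relu(tape, H)
  }
  D <- ad_add_rowvec(tape, ad_matmul(tape, H, leaves$W_emb), leaves$b_emb)
  ad_add_rowvec(tape, ad_matmul(tape, D, leaves$W_cls), leaves$b_cls)
}

update_running_stats <- function(model, bn_stats_f, bn_stats_a = NULL) {
  for (l in seq_along(model$config$hidden_dims)) {
    s <- bn_stats_f[[paste0("l", l)]]
    model$buffers[[paste0("rm", l)]] <-
      (1 - bn_momentum) * model$buffers[[paste0("rm", l)]] + bn_momentum * s$batch_mean
    model$buffers[[paste0("rv", l)]] <-
      (1 - bn_momentum) * model$buffers[[paste0("rv", l)]] + bn_momentum * s$batch_var
  }
  if (!is.null(bn_stats_a)) {
    model$buffers$rm_att <-
      (1 - bn_momentum) * model$buffers$rm_att + bn_momentum * bn_stats_a$batch_mean
    model$buffers$rv_att <-
      (1 - bn_momentum) * model$buffers$rv_att + bn_momentum * bn_stats_a$batch_var
  }
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the architecture config, all parameters, the
#' batch-norm running statistics, the class names and the training feature
#' order, so loading restores bit-identical evaluation-mode behavior.
#'
#' @param model an `lb_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `lb_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lb_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_data("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "lb_model")) stop_data("not a model checkpoint: ", path)
  model
}
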