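# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Internal infrastructure for training and attribution. Every value on the
# tape is a base-R double matrix (scalars are 1x1). Nodes are created eagerly
# in topological order, so the backward pass is a single reverse sweep with
# gradient accumulation at shared nodes. Not exported.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  stopifnot(is.matrix(value))
  node <- new.env(parent = emptyenv())
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node$id <- tape$n
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  tape$nodes[[tape$n]] <- node
  node
}

as_ad_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.double(x), nrow = 1L)
}

# leaf: a constant or a parameter (parameters are just leaves whose grads
# the caller reads after ad_backward)
ad_leaf <- function(tape, x) ad_node(tape, as_ad_matrix(x))

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse sweep from `root` (must be 1x1). Afterwards every leaf on a path to
# root carries $grad; untouched nodes keep grad NULL.
ad_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  root$grad <- matrix(1.0, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    pgrads <- node$backward(node$grad)
    for (k in seq_along(node$parents)) {
      if (!is.null(pgrads[[k]])) ad_accum(node$parents[[k]], pgrads[[k]])
    }
  }
  invisible(NULL)
}

ad_grad <- function(node) {
  if (is.null(node$grad)) matrix(0, nrow(node$value), ncol(node$value)) else node$grad
}

## ---- arithmetic ----

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

# multiply by an R scalar constant
ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(g) list(g * k))
}

# add an R constant (scalar or matrix)
ad_addc <- function(tape, a, k) {
  ad_node(tape, a$value + k, list(a), function(g) list(g))
}

# elementwise multiply by a constant matrix (masking)
ad_mulc <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(g) list(g * k))
}

ad_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

ad_t <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(g) list(t(g)))
}

## ---- broadcasting: v is 1 x m (row vector), u is n x 1 (column vector) ----

ad_add_rowvec <- function(tape, X, v) {
  n <- nrow(X$value)
  ad_node(tape, sweep(X$value, 2L, as.vector(v$value), "+"), list(X, v),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_sub_rowvec <- function(tape, X, v) {
  ad_node(tape, sweep(X$value, 2L, as.vector(v$value), "-"), list(X, v),
          function(g) list(g, matrix(-colSums(g), 1L)))
}

ad_mul_rowvec <- function(tape, X, v) {
  Xv <- X$value; vv <- as.vector(v$value)
  ad_node(tape, sweep(Xv, 2L, vv, "*"), list(X, v),
          function(g) list(sweep(g, 2L, vv, "*"), matrix(colSums(g * Xv), 1L)))
}

ad_div_rowvec <- function(tape, X, v) {
  Xv <- X$value; vv <- as.vector(v$value)
  Y <- sweep(Xv, 2L, vv, "/")
  ad_node(tape, Y, list(X, v), function(g) {
    list(sweep(g, 2L, vv, "/"),
         matrix(-colSums(g * Y) / vv, 1L))
  })
}

ad_mul_colvec <- function(tape, X, u) {
  Xv <- X$value; uv <- as.vector(u$value)
  ad_node(tape, Xv * uv, list(X, u),
          function(g) list(g * uv, matrix(rowSums(g * Xv), ncol = 1L)))
}

ad_div_colvec <- function(tape, X, u) {
  Xv <- X$value; uv <- as.vector(u$value)
  Y <- Xv / uv
  ad_node(tape, Y, list(X, u), function(g) {
    list(g / uv, matrix(-rowSums(g * Y) / uv, ncol = 1L))
  })
}

## ---- elementwise nonlinearities ----

ad_relu <- function(tape, a) {
  av <- a$value
  ad_node(tape, pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

ad_tanh <- function(tape, a) {
  y <- tanh(a$value)
  ad_node(tape, y, list(a), function(g) list(g * (1 - y * y)))
}

ad_exp <- function(tape, a) {
  y <- exp(a$value)
  ad_node(tape, y, list(a), function(g) list(g * y))
}

ad_log <- function(tape, a) {
  av <- a$value
  ad_node(tape, log(av), list(a), function(g) list(g / av))
}

ad_abs <- function(tape, a) {
  av <- a$value
  ad_node(tape, abs(av), list(a), function(g) list(g * sign(av)))
}

ad_square <- function(tape, a) {
  av <- a$value
  ad_node(tape, av * av, list(a), function(g) list(2 * g * av))
}

ad_sqrt <- function(tape, a) {
  y <- sqrt(a$value)
  ad_node(tape, y, list(a), function(g) list(g / (2 * y)))
}

# numerically stable logistic
ad_sigmoid <- function(tape, a) {
  av <- a$value
  y <- ifelse(av >= 0, 1 / (1 + exp(-av)), exp(av) / (1 + exp(av)))
  y <- matrix(y, nrow(av), ncol(av))
  ad_node(tape, y, list(a), function(g) list(g * y * (1 - y)))
}

## ---- reductions ----

ad_sum <- function(tape, a) {
  d <- dim(a$value)
  ad_node(tape, matrix(sum(a$value), 1L, 1L), list(a),
          function(g) list(matrix(g[1L], d[1L], d[2L])))
}

ad_mean <- function(tape, a) {
  d <- dim(a$value)
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value), 1L, 1L), list(a),
          function(g) list(matrix(g[1L] / n, d[1L], d[2L])))
}

ad_colmeans <- function(tape, a) {
  n <- nrow(a$value)
  ad_node(tape, matrix(colMeans(a$value), 1L), list(a),
          function(g) list(matrix(rep(as.vector(g) / n, each = n),
                                  n, ncol(a$value))))
}

ad_rowsums <- function(tape, a) {
  m <- ncol(a$value)
  ad_node(tape, matrix(rowSums(a$value), ncol = 1L), list(a),
          function(g) list(matrix(rep(as.vector(g), m), nrow(a$value), m)))
}

## ---- indexing ----

# rows of a by integer index (duplicates allowed); backward scatter-adds
ad_gather_rows <- function(tape, a, idx) {
  d <- dim(a$value)
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    G <- matrix(0, d[1L], d[2L])
    for (r in seq_along(idx)) G[idx[r], ] <- G[idx[r], ] + g[r, ]
    list(G)
  })
}

# picks entry (i, cols[i]) of each row -> n x 1
ad_pick <- function(tape, a, cols) {
  d <- dim(a$value)
  sel <- cbind(seq_len(d[1L]), cols)
  ad_node(tape, matrix(a$value[sel], ncol = 1L), list(a), function(g) {
    G <- matrix(0, d[1L], d[2L])
    G[sel] <- as.vector(g)
    list(G)
  })
}

ad_cbind <- function(tape, a, b) {
  na <- ncol(a$value)
  ad_node(tape, cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

# row-wise log(sum(exp(x))), stable -> n x 1
ad_logsumexp_rows <- function(tape, a) {
  av <- a$value
  mx <- apply(av, 1L, max)
  lse <- mx + log(rowSums(exp(av - mx)))
  soft <- exp(av - lse)
  ad_node(tape, matrix(lse, ncol = 1L), list(a),
          function(g) list(soft * as.vector(g)))
}

## ---- composites used by the networks ----

# Batch normalization, training mode (batch statistics). Returns the output
# node; the batch mean/var are also returned so the caller can update running
# statistics.
ad_batchnorm_train <- function(tape, X, gamma, beta, eps = 1e-5) {
  mu <- ad_colmeans(tape, X)
  Xc <- ad_sub_rowvec(tape, X, mu)
  v <- ad_colmeans(tape, ad_square(tape, Xc))
  sd <- ad_sqrt(tape, ad_addc(tape, v, eps))
  Xh <- ad_div_rowvec(tape, Xc, sd)
  out <- ad_add_rowvec(tape, ad_mul_rowvec(tape, Xh, gamma), beta)
  list(out = out, batch_mean = as.vector(mu$value), batch_var = as.vector(v$value))
}

# Batch normalization, evaluation mode (running statistics; pure affine map)
ad_batchnorm_eval <- function(tape, X, gamma, beta, run_mean, run_var, eps = 1e-5) {
  sd <- sqrt(run_var + eps)
  Xc <- ad_addc(tape, X, matrix(rep(-run_mean, each = nrow(X$value)),
                                nrow(X$value), ncol(X$value)))
  Xh <- ad_mulc(tape, Xc, matrix(rep(1 / sd, each = nrow(X$value)),
                                 nrow(X$value), ncol(X$value)))
  ad_add_rowvec(tape, ad_mul_rowvec(tape, Xh, gamma), beta)
}

# L2-normalize rows (cosine preprocessing); eps guards zero rows
ad_l2_normalize_rows <- function(tape, X, eps = 1e-12) {
  nrm <- ad_sqrt(tape, ad_addc(tape, ad_rowsums(tape, ad_square(tape, X)), eps))
  ad_div_colvec(tape, X, nrm)
}
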