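# Independent brute-force oracles: plain double loops, no vectorization,
# written against the formulas directly and never sharing code with the
# implementation.

oracle_ce <- function(p, y) {
  s <- 0
  for (b in seq_along(y)) s <- s - log(p[b, y[b]])
  s / length(y)
}

oracle_pr <- function(dq, dr, eps = 1e-8) {
  m <- ncol(dq)
  col_mean <- function(x, j) {
    s <- 0
    for (b in seq_len(nrow(x))) s <- s + x[b, j]
    s / nrow(x)
  }
  abs_corr_sum <- function(x) {
    mu <- sapply(seq_len(m), function(j) col_mean(x, j))
    total <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      num <- 0; ssi <- 0; ssj <- 0
      for (b in seq_len(nrow(x))) {
        num <- num + (x[b, i] - mu[i]) * (x[b, j] - mu[j])
        ssi <- ssi + (x[b, i] - mu[i])^2
        ssj <- ssj + (x[b, j] - mu[j])^2
      }
      total <- total + abs(num / sqrt((ssi + eps) * (ssj + eps)))
    }
    total / m^2
  }
  abs_mean_sum <- function(x) {
    total <- 0
    for (j in seq_len(m)) total <- total + abs(col_mean(x, j))
    total / m
  }
  dev <- 0
  muq <- sapply(seq_len(m), function(j) col_mean(dq, j))
  for (b in seq_len(nrow(dq))) for (j in seq_len(m)) {
    dev <- dev + abs(dq[b, j] - muq[j])
  }
  dev <- dev / nrow(dq)
  1 / (dev + eps) + abs_corr_sum(dq) + abs_mean_sum(dq) +
    abs_corr_sum(dr) + abs_mean_sum(dr)
}

oracle_cosine <- function(u, v) {
  num <- 0; nu <- 0; nv <- 0
  for (j in seq_along(u)) {
    num <- num + u[j] * v[j]
    nu <- nu + u[j]^2
    nv <- nv + v[j]^2
  }
  num / sqrt((nu + 1e-12) * (nv + 1e-12))
}

oracle_cl <- function(anchors, positives, tau) {
  nb <- nrow(anchors)
  total <- 0
  for (b in seq_len(nb)) {
    sp <- exp(oracle_cosine(anchors[b, ], positives[b, ]) / tau)
    den <- sp
    for (i in seq_len(nb)) {
      if (i == b) next
      den <- den + exp(oracle_cosine(anchors[b, ], anchors[i, ]) / tau)
    }
    total <- total - log(sp / den)
  }
  total / nb
}

oracle_fa <- function(dq, dr, p_frac) {
  nq <- nrow(dq)
  best <- numeric(nq)
  for (b in seq_len(nq)) {
    mx <- -Inf
    for (i in seq_len(nrow(dr))) {
      s <- oracle_cosine(dq[b, ], dr[i, ])
      if (s > mx) mx <- s
    }
    best[b] <- mx
  }
  n_top <- ceiling(p_frac * nq)
  keep <- order(-best, seq_len(nq))[seq_len(n_top)]
  s <- 0
  for (b in keep) s <- s + best[b]
  -s / n_top
}

oracle_sc <- function(d, labels, a, centers) {
  total <- 0
  for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d))) {
    total <- total + a[i, j] * (d[i, j] - centers[labels[i], j])^2
  }
  total / nrow(d)
}

# midrank AUROC oracle by pair enumeration
oracle_auroc <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores) for (n in neg_scores) {
    if (p > n) wins <- wins + 1 else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos_scores) * length(neg_scores))
}

# confusion-matrix-based accuracy / macro-F1 oracle
oracle_metrics <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- numeric(length(classes))
  correct <- 0
  for (i in seq_along(truth)) if (truth[i] == pred[i]) correct <- correct + 1
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- sum(truth == cl & pred == cl)
    prec_den <- sum(pred == cl)
    rec_den <- sum(truth == cl)
    prec <- if (prec_den == 0) 0 else tp / prec_den
    rec <- if (rec_den == 0) 0 else tp / rec_den
    f1[k] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  list(accuracy = correct / length(truth), macro_f1 = mean(f1))
}

numeric_gradient <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
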