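test_that("cross-entropy matches hand-computed cases", {
  expect_equal(ce_loss(matrix(1 / 3, 4, 3), rep(2, 4)), log(3))
  p <- diag(3)[c(1, 2, 3), ]
  expect_equal(ce_loss(p, 1:3), 0)
  p2 <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(ce_loss(p2, c(1, 1)), (log(2) + log(4)) / 2)
  expect_error(ce_loss(p2[0, , drop = FALSE], integer(0)), "empty")
  expect_error(ce_loss(p2, c(1, 3)), "out of range")
})

test_that("projection regularizer matches the double-loop oracle and guards", {
  set.seed(1)
  for (s in 1:5) {
    dq <- matrix(rnorm(15 * 4), 15, 4)
    dr <- matrix(rnorm(12 * 4), 12, 4)
    expect_equal(pr_loss(dq, dr), oracle_pr(dq, dr), tolerance = 1e-9)
  }
  # constant query embeddings: deviation term saturates at ~1/eps
  dq_const <- matrix(1, 10, 4)
  dr <- matrix(rnorm(40), 10, 4)
  expect_gt(pr_loss(dq_const, dr), 0.5e8)
  # scaling embeddings by 10 scales the reciprocal-deviation term by 0.1
  # and leaves correlations unchanged
  dq <- matrix(rnorm(40), 10, 4)
  t1 <- function(d) 1 / (sum(abs(sweep(d, 2, colMeans(d)))) / nrow(d) + 1e-8)
  delta <- pr_loss(10 * dq, 10 * dr) - pr_loss(dq, dr)
  expect_equal(delta, (t1(10 * dq) - t1(dq)) +
                 (mean(abs(colMeans(10 * dq))) - mean(abs(colMeans(dq)))) +
                 (mean(abs(colMeans(10 * dr))) - mean(abs(colMeans(dr)))),
               tolerance = 1e-7)
  expect_error(pr_loss(dq[1, , drop = FALSE], dr), "at least 2")
})

test_that("contrastive loss matches closed forms and is scale invariant", {
  # identical embeddings: all similarities equal -> -log(1/(1+N)) with N=4
  v <- matrix(rep(c(1, 2, 3), 5), 5, 3, byrow = TRUE)
  g <- structure(list(neighbor_indices = matrix(rep(1:5, 2), 5, 2),
                      k = 2, n_components = 1), class = "neighbor_graph")
  expect_equal(cl_loss(v, g, 1:5, tau = 0.5, positives = c(2, 3, 4, 5, 1)),
               log(5), tolerance = 1e-9)
  # perfectly separated positive/negative at low temperature
  d <- rbind(c(1, 0), c(-1, 0))
  expect_lt(cl_loss(d, g, 1:2, tau = 0.1, positives = c(1, 2)), 1e-8)
  # cosine similarity: positive rescaling leaves the loss unchanged
  set.seed(2)
  dq <- matrix(rnorm(18), 6, 3)
  pos <- c(2, 3, 4, 5, 6, 1)
  l1 <- cl_loss(dq, g, 1:6, tau = 0.7, positives = pos)
  l2 <- cl_loss(37.5 * dq, g, 1:6, tau = 0.7, positives = pos)
  expect_equal(l1, l2, tolerance = 1e-9)
  expect_equal(l1, oracle_cl(dq, dq[pos, ], 0.7), tolerance = 1e-9)
  expect_error(cl_loss(dq, g, 1:6, tau = 0, positives = pos), "tau")
})

test_that("feature alignment selects the top fraction of best matches", {
  dr <- matrix(c(1, 0), 1, 2)
  dq <- rbind(c(0.8, 0.6), c(0.6, 0.8))
  expect_equal(fa_loss(dq, dq, p_frac = 1), -1)
  expect_equal(fa_loss(dq, dq, p_frac = 1), oracle_fa(dq, dq, 1))
  expect_equal(fa_loss(rbind(c(1, 0)), rbind(c(0, 1)), p_frac = 1), 0,
               tolerance = 1e-9)
  expect_equal(fa_loss(dq, dr, p_frac = 0.5), -0.8, tolerance = 1e-9)
  set.seed(3)
  a <- matrix(rnorm(24), 8, 3); b <- matrix(rnorm(15), 5, 3)
  expect_equal(fa_loss(a, b, 0.4), oracle_fa(a, b, 0.4), tolerance = 1e-9)
  expect_equal(fa_loss(3 * a, 0.5 * b, 0.4), fa_loss(a, b, 0.4),
               tolerance = 1e-9)
  expect_error(fa_loss(a, b, 0), "p_frac")
})

test_that("sparse center loss weights squared center distances", {
  centers <- rbind(c(0, 0), c(5, 5))
  expect_equal(sc_loss(centers, c(1, 2), matrix(1, 2, 2), centers), 0)
  d <- rbind(c(2, 0))
  expect_equal(sc_loss(d, 1, matrix(c(0.5, 1), 1), centers), 0.5 * 4)
  expect_equal(sc_loss(d, 1, matrix(0, 1, 2), centers), 0)
  set.seed(4)
  dmat <- matrix(rnorm(12), 6, 2)
  amat <- matrix(runif(12), 6, 2)
  lab <- sample(1:2, 6, replace = TRUE)
  expect_equal(sc_loss(dmat, lab, amat, centers),
               oracle_sc(dmat, lab, amat, centers), tolerance = 1e-9)
  # monotone nondecreasing in every attention weight
  base <- sc_loss(dmat, lab, amat, centers)
  for (k in sample(12, 4)) {
    bumped <- amat; bumped[k] <- bumped[k] + 0.1
    expect_gte(sc_loss(dmat, lab, bumped, centers), base)
  }
})

test_that("center updates take convex steps toward batch means", {
  c0 <- init_centers(2, 2)
  d <- rbind(c(1, 1), c(1, 1))
  expect_equal(update_centers(c0, d, c(1, 1), update_rate = 1)[1, ], c(1, 1))
  expect_equal(update_centers(c0, d, c(1, 1), update_rate = 1)[2, ], c(0, 0))
  expect_equal(update_centers(c0, rbind(c(2, 2)), 1, update_rate = 0.5)[1, ],
               c(1, 1))
})

test_that("loss composition follows the documented weighting", {
  bd <- total_loss(1, 2, 3, -1, 4, alpha = 0.1, beta = 0, gamma = 0.1)
  expect_equal(bd$total, 1 + 0.2 + 0.3 + 0 + 0.4, tolerance = 1e-12)
  bd0 <- total_loss(1.3, 0.7, 9, 9, 9, 0, 0, 0)
  expect_equal(bd0$total, 1.3 + 0.07, tolerance = 1e-12)
  set.seed(5)
  v <- rnorm(5); w <- runif(3)
  bd2 <- total_loss(v[1], v[2], v[3], v[4], v[5], w[1], w[2], w[3])
  expect_equal(bd2$total,
               v[1] + 0.1 * v[2] + w[1] * v[3] + w[2] * v[4] + w[3] * v[5],
               tolerance = 1e-9)
})
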