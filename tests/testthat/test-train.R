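test_that("built-in scenario presets load exactly", {
  m <- scenario_preset("matched_rna_atac")
  expect_equal(c(m$alpha, m$beta, m$gamma, m$tau), c(0.06, 0.05, 0.01, 0.04))
  expect_equal(m$max_iterations, 3000L)
  u <- scenario_preset("unmatched_rna_atac")
  expect_equal(c(u$alpha, u$beta, u$gamma, u$tau), c(1.2, 0.05, 0.01, 0.8))
  expect_equal(u$max_iterations, 3000L)
  r <- scenario_preset("rna_to_rna")
  expect_equal(c(r$alpha, r$beta, r$gamma, r$tau), c(0.1, 0, 0.1, 0.8))
  expect_equal(r$max_iterations, 200L)
  a <- scenario_preset("atac_to_atac")
  expect_equal(c(a$alpha, a$beta, a$gamma, a$tau), c(0.1, 0, 0.001, 0.8))
  expect_equal(a$max_iterations, 200L)
  expect_error(scenario_preset("bulk_to_bulk"), "unknown scenario")
  # shared defaults
  expect_equal(m$batch_size, 512L)
  expect_equal(m$learning_rate, 0.001)
  expect_equal(m$confidence_threshold, 0.95)
  expect_equal(m$patience, 20L)
})

test_that("mini-batch sampling recycles the smaller side with full coverage", {
  withr::with_seed(8, {
    sr <- labelbridge:::make_sampler(10)
    sq <- labelbridge:::make_sampler(100)
    seen <- integer(0)
    for (i in 1:5) {
      b <- labelbridge:::sample_minibatches(sr, sq, 20)
      expect_length(b$batch_r, 20)
      expect_length(b$batch_q, 20)
      expect_lte(max(table(b$batch_q)), 1)  # no replacement within an epoch
      seen <- c(seen, b$batch_r)
    }
    # over one epoch of the larger side, every small-side cell recycled in
    expect_setequal(unique(seen), 1:10)
  })
  withr::with_seed(9, {
    s1 <- labelbridge:::make_sampler(50)
    d1 <- labelbridge:::draw_batch(s1, 30)
  })
  withr::with_seed(9, {
    s2 <- labelbridge:::make_sampler(50)
    d2 <- labelbridge:::draw_batch(s2, 30)
  })
  expect_identical(d1, d2)
})

test_that("training runs, logs every loss term, and obeys the iteration cap", {
  dat <- prepared_domains(small_spec(seed = 31, n_ref = 120, n_query = 120,
                                     n_features = 30, K = 3))
  cfg <- small_config(max_iterations = 5L, batch_size = 40L,
                      hidden_dims = 16L, warmup = 2L)
  fit <- fit_annotator(dat$ref, dat$query, cfg)
  expect_s3_class(fit, "lb_fit")
  expect_equal(nrow(fit$log), 5L)
  expect_named(fit$log, c("iteration", "l_ce", "l_pr", "l_cl", "l_fa",
                          "l_sc", "total"))
  expect_equal(fit$log$total,
               fit$log$l_ce + 0.1 * fit$log$l_pr + cfg$alpha * fit$log$l_cl +
                 cfg$beta * fit$log$l_fa + cfg$gamma * fit$log$l_sc,
               tolerance = 1e-9)
  expect_identical(fit$model$classes, sort(unique(dat$ref$labels)))
  # single-iteration cap honored
  fit1 <- fit_annotator(dat$ref, dat$query,
                        small_config(max_iterations = 1L, batch_size = 40L,
                                     hidden_dims = 16L))
  expect_equal(nrow(fit1$log), 1L)
})

test_that("with alpha=beta=gamma=0 the objective reduces to CE + 0.1 PR", {
  dat <- prepared_domains(small_spec(seed = 32, n_ref = 100, n_query = 100,
                                     n_features = 25, K = 3))
  cfg <- small_config(alpha = 0, beta = 0, gamma = 0, max_iterations = 3L,
                      batch_size = 30L, hidden_dims = 16L)
  fit <- fit_annotator(dat$ref, dat$query, cfg)
  expect_equal(fit$log$total, fit$log$l_ce + 0.1 * fit$log$l_pr,
               tolerance = 1e-12)
})

test_that("pseudo-labels start near-chance confidence and cover scored cells", {
  dat <- prepared_domains(small_spec(seed = 33, n_ref = 90, n_query = 90,
                                     n_features = 25, K = 3))
  cfg <- small_config(max_iterations = 1L, batch_size = 30L,
                      hidden_dims = 16L)
  fit <- fit_annotator(dat$ref, dat$query, cfg)
  pl <- pseudo_labels(fit)
  scored <- !is.na(pl$confidence)
  expect_equal(sum(scored), 30L)       # one batch scored after one step
  # an untrained symmetric classifier is near-uniform
  expect_lt(max(pl$confidence[scored]), 1 / 3 + 0.1)
})

test_that("sparse-loss plateau stops training early; gamma=0 disables the rule", {
  # identical cells force embeddings (and so the SC loss) to a constant once
  # the centers converge; learning rate 0 keeps parameters fixed
  vals <- matrix(rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), each = 40), 40, 10)
  ref <- expression_matrix(vals, labels = rep(c("a", "b"), 20))
  qry <- expression_matrix(vals)
  cfg <- small_config(gamma = 0.1, alpha = 0.1, beta = 0.1,
                      learning_rate = 0, warmup = 1000L,
                      max_iterations = 100L, patience = 5L,
                      sc_tolerance = 1e-4, batch_size = 20L,
                      hidden_dims = 8L, knn_k = 3L)
  fit <- fit_annotator(ref, qry, cfg)
  expect_lt(nrow(fit$log), 100L)
  expect_gte(nrow(fit$log), 5L)
  cfg0 <- cfg; cfg0$gamma <- 0; cfg0$max_iterations <- 30L
  fit0 <- fit_annotator(ref, qry, cfg0)
  expect_equal(nrow(fit0$log), 30L)    # plateau rule off, cap governs
})

test_that("training is bitwise reproducible for a fixed seed", {
  dat <- prepared_domains(small_spec(seed = 34, n_ref = 100, n_query = 100,
                                     n_features = 25, K = 3))
  cfg <- small_config(max_iterations = 8L, batch_size = 30L,
                      hidden_dims = 16L, seed = 77)
  f1 <- fit_annotator(dat$ref, dat$query, cfg)
  f2 <- fit_annotator(dat$ref, dat$query, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("reference CE decreases over training on separable data", {
  dat <- prepared_domains(small_spec(seed = 35, n_ref = 200, n_query = 200,
                                     n_features = 40, K = 3,
                                     shift_strength = 0))
  cfg <- small_config(max_iterations = 120L, batch_size = 64L,
                      hidden_dims = 32L)
  fit <- fit_annotator(dat$ref, dat$query, cfg)
  ma <- function(x, w = 30) stats::filter(x, rep(1 / w, w), sides = 1)
  sm <- ma(fit$log$l_ce)
  expect_lt(sm[120], sm[40])
})
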