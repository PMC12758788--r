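test_that("integrated gradients are exact on a linear model", {
  # no hidden layer: logit_k(x) = x %*% (W_emb W_cls) + const, so the
  # attribution must equal weight * displacement exactly at any n_steps
  cfg <- model_config(4, 2, hidden_dims = integer(0), m = 3, e_dim = 2)
  model <- init_model(cfg, seed = 2)
  model$params$W_cls <- matrix(rnorm(6), 3, 2)
  W <- model$params$W_emb %*% model$params$W_cls
  x <- matrix(c(1, 2, -1, 0.5, 0, 1, 3, -2), 2, 4)
  for (steps in c(1, 7)) {
    ig <- integrated_gradients(model, x, target = c(1, 2), n_steps = steps)
    expect_equal(ig$attributions[1, ], x[1, ] * W[, 1], tolerance = 1e-12)
    expect_equal(ig$attributions[2, ], x[2, ] * W[, 2], tolerance = 1e-12)
  }
  # nonzero baseline: displacement replaces x
  base <- c(1, 1, 1, 1)
  igb <- integrated_gradients(model, x, c(1, 1), baseline = base, n_steps = 3)
  expect_equal(igb$attributions[1, ], (x[1, ] - base) * W[, 1],
               tolerance = 1e-12)
})

test_that("attributions vanish for constant outputs and constant features", {
  cfg <- model_config(3, 2, hidden_dims = integer(0), m = 2, e_dim = 2)
  model <- init_model(cfg, seed = 3)
  model$params$W_emb[] <- 0    # constant logits
  ig <- integrated_gradients(model, matrix(rnorm(6), 2, 3), 1, n_steps = 5)
  expect_equal(max(abs(ig$attributions)), 0)
  # a feature equal to its baseline along the whole path gets 0 attribution
  # and does not perturb the ranking of the others
  fx <- trained_fixture()
  x <- fx$dat$query$values[1:5, ]
  x[, 3] <- 0
  ig2 <- integrated_gradients(fx$fit$model, x, 1, n_steps = 20)
  expect_equal(unname(ig2$attributions[, 3]), rep(0, 5))
})

test_that("completeness holds on the trained model", {
  fx <- trained_fixture()
  model <- fx$fit$model
  x <- fx$dat$query$values[1:40, ]
  cls <- classify_cells(model, embed_cells(model, x))
  ig <- integrated_gradients(model, x, cls$predicted_class, n_steps = 200)
  fx_val <- labelbridge:::logit_scores(model, x, cls$predicted_class)
  f0 <- labelbridge:::logit_scores(model, matrix(0, nrow(x), ncol(x)),
                                   cls$predicted_class)
  gap <- abs(rowSums(ig$attributions) - (fx_val - f0))
  expect_lt(max(gap), 1e-3)
  # coarser grids are still covered by the kink-refined partition
  ig2 <- integrated_gradients(model, x, cls$predicted_class, n_steps = 10)
  gap2 <- abs(rowSums(ig2$attributions) - (fx_val - f0))
  expect_lt(max(gap2), 1e-3)
})

test_that("determinant feature lists rank by attribution then frequency", {
  attr <- structure(list(attributions = rbind(c(0.1, 0.9, 0.5)),
                         target_class = 1L, baseline = rep(0, 3),
                         n_steps = 5L), class = "attribution_result")
  pred <- structure(list(cell_ids = "c1", assigned_type = "T",
                         confidence = 0.99,
                         full_probabilities = matrix(0.99)),
                    class = "prediction_result")
  det <- determinant_features(attr, pred, c("f1", "f2", "f3"))
  expect_identical(det$per_cell_top[["c1"]], c("f2", "f3", "f1"))
  expect_equal(nrow(det$per_type_top[["T"]]), 3L)   # clipped to n_features

  # shared feature outranks a private one across two cells of one type
  attr2 <- structure(list(attributions = rbind(c(0.9, 0.8, 0.1, 0),
                                               c(0, 0.7, 0.6, 0.1)),
                          target_class = c(1L, 1L), baseline = rep(0, 4),
                          n_steps = 5L), class = "attribution_result")
  pred2 <- structure(list(cell_ids = c("c1", "c2"),
                          assigned_type = c("T", "T"),
                          confidence = c(0.99, 0.99),
                          full_probabilities = matrix(0.99, 2)),
                     class = "prediction_result")
  det2 <- determinant_features(attr2, pred2, paste0("f", 1:4),
                               n_per_cell = 2, n_per_type = 4)
  expect_identical(det2$per_type_top[["T"]]$feature[1], "f2")
  expect_equal(det2$per_type_top[["T"]]$frequency[1], 1)

  # Unknown cells are excluded from per-type aggregation
  pred3 <- pred2
  pred3$assigned_type <- c("T", "Unknown")
  det3 <- determinant_features(attr2, pred3, paste0("f", 1:4),
                               n_per_cell = 2, n_per_type = 2)
  expect_named(det3$per_type_top, "T")
  expect_identical(det3$per_type_top[["T"]]$feature, c("f1", "f2"))
})

test_that("hit rate is the overlap fraction of determinant lists", {
  det <- list(A = c("g1", "g2"), B = c("g3", "g4"))
  expect_equal(unname(kghr(det, list(A = c("g1", "g2", "g9"),
                                     B = c("g7", "g8")))),
               c(1, 0))
  det50 <- list(A = paste0("g", 1:50))
  mark <- list(A = paste0("g", seq(2, 100, by = 2)))  # 25 of 50 overlap
  expect_equal(unname(kghr(det50, mark)), 0.5)
  expect_error(kghr(list(A = "g1"), list(B = "g2")), "no cell types shared")
})

test_that("interpretation tables round-trip through TSV", {
  markers <- list(A = c("g1", "g2"), B = "g3")
  path <- tempfile(fileext = ".tsv")
  write_marker_lists(markers, path)
  expect_equal(read_marker_lists(path), markers)
})
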