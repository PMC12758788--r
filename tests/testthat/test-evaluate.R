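test_that("accuracy counts exact matches and open-set novel hits", {
  expect_equal(annotation_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(annotation_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(annotation_accuracy(c("a", "a", "b", "b"),
                                   c("a", "a", "b", "a")), 0.75)
  # novel type counts as correct iff rejected
  expect_equal(annotation_accuracy(c("a", "nov"), c("a", "Unknown"),
                                   novel_types = "nov"), 1)
  expect_equal(annotation_accuracy(c("a", "nov"), c("a", "a"),
                                   novel_types = "nov"), 0.5)
  expect_error(annotation_accuracy(character(0), character(0)), "empty")
})

test_that("macro-F1 matches hand computation and the confusion oracle", {
  # confusion [[2,0],[1,1]] -> F1 = 0.8 and 2/3
  truth <- c("a", "a", "b", "b")
  pred <- c("a", "a", "a", "b")
  mf <- macro_f1(truth, pred, details = TRUE)
  expect_equal(unname(mf$per_class_f1), c(0.8, 2 / 3), tolerance = 1e-12)
  expect_equal(mf$macro_f1, mean(c(0.8, 2 / 3)), tolerance = 1e-12)
  expect_equal(macro_f1(truth, truth), 1)
  # class never predicted and never correct contributes 0
  mf2 <- macro_f1(c("a", "b", "c"), c("a", "b", "a"), details = TRUE)
  expect_equal(unname(mf2$per_class_f1["c"]), 0)
  # prediction-only classes (e.g. Unknown in closed-set mode) are excluded
  mf3 <- macro_f1(c("a", "a"), c("a", "Unknown"), details = TRUE)
  expect_named(mf3$per_class_f1, "a")
  set.seed(10)
  for (s in 1:100) {
    truth <- sample(letters[1:4], 30, replace = TRUE)
    pred <- sample(letters[1:4], 30, replace = TRUE)
    o <- oracle_metrics(truth, pred)
    expect_equal(macro_f1(truth, pred), o$macro_f1, tolerance = 1e-12)
    expect_equal(annotation_accuracy(truth, pred), o$accuracy,
                 tolerance = 1e-12)
  }
})

test_that("novelty AUROC follows the midrank formulation", {
  expect_equal(novelty_auroc(c(TRUE, TRUE, FALSE, FALSE),
                             c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(novelty_auroc(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4)), 0.5)
  # enumerated 4-pair case: novel confidences {0.2, 0.4}, shared {0.3, 0.9}
  expect_equal(novelty_auroc(c(TRUE, TRUE, FALSE, FALSE),
                             c(0.2, 0.4, 0.3, 0.9)), 0.75)
  set.seed(11)
  for (s in 1:20) {
    conf <- round(runif(30), 1)      # force ties
    novel <- runif(30) < 0.4
    if (!any(novel) || all(novel)) next
    expect_equal(novelty_auroc(novel, conf),
                 oracle_auroc((1 - conf)[novel], (1 - conf)[!novel]),
                 tolerance = 1e-12)
  }
  expect_error(novelty_auroc(rep(TRUE, 3), runif(3)), "both novel")
})

test_that("AUROC is invariant to strictly monotone confidence transforms", {
  set.seed(12)
  conf <- runif(40)
  novel <- runif(40) < 0.3
  a0 <- novelty_auroc(novel, conf)
  expect_equal(novelty_auroc(novel, plogis(5 * conf - 2)), a0)
  expect_equal(novelty_auroc(novel, conf^3), a0)
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  conf <- runif(50)
  novel <- runif(50) < 0.4
  ours <- novelty_auroc(novel, conf)
  ref <- as.numeric(pROC::auc(pROC::roc(response = novel,
                                        predictor = 1 - conf,
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("OSCR spans its closed-form extremes and matches a manual sweep", {
  # perfect classifier, perfectly separated confidences
  expect_equal(oscr(c("a", "a", "n", "n"), c("a", "a", "a", "a"),
                    c(0.9, 0.8, 0.2, 0.1), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # always wrong on shared cells
  expect_equal(oscr(c("a", "a", "n"), c("b", "b", "a"),
                    c(0.9, 0.8, 0.1), c(FALSE, FALSE, TRUE)), 0)
  # 6-cell hand case, brute-force sweep over distinct confidences
  truth <- c("a", "a", "b", "b", "n", "n")
  pred <- c("a", "b", "b", "b", "a", "b")
  conf <- c(0.9, 0.6, 0.8, 0.4, 0.7, 0.3)
  novel <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  correct <- !novel & truth == pred
  thr <- c(sort(unique(conf), decreasing = TRUE), -1)
  ccr <- sapply(thr, function(t) sum(correct & conf > t) / 4)
  fpr <- sapply(thr, function(t) sum(novel & conf > t) / 2)
  manual <- sum(diff(c(0, fpr)) * (c(0, head(ccr, -1)) + ccr) / 2)
  expect_equal(oscr(truth, pred, conf, novel), manual, tolerance = 1e-12)
  expect_error(oscr(truth, pred, conf, rep(FALSE, 6)), "no novel")
})

test_that("evaluation report is internally consistent", {
  fx <- trained_fixture()
  pred <- annotate_cells(fx$fit$model, fx$dat$query, 0.95)
  rep <- evaluation_report(fx$dat$query_labels, pred)
  expect_equal(rep$accuracy,
               mean(fx$dat$query_labels == pred$assigned_type),
               tolerance = 1e-12)
  expect_equal(sum(rep$confusion), n_cells(fx$dat$query))
  expect_true(all(rep$per_class_f1 >= 0 & rep$per_class_f1 <= 1))
  expect_null(rep$auroc)   # closed-set: no novel types declared
})
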