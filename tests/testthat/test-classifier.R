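small_spec <- function(epochs = 30L, ...) {
  model_spec(hidden = c(32L, 16L, 8L), epochs = epochs, patience = 6L, ...)
}

test_that("metrics match the textbook confusion-matrix values", {
  # TP=40, TN=45, FP=5, FN=10
  labels <- c(rep(1, 50), rep(0, 50))
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 5), rep(0.1, 45))
  m <- compute_metrics(labels, scores)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$precision, 0.888888888888889, tolerance = 1e-10)
  expect_equal(m$f1, 0.842105263157895, tolerance = 1e-10)
  expect_equal(m$mcc, 0.703526470027794, tolerance = 1e-6)

  perfect <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unname(unlist(perfect)), rep(1, 7), tolerance = 1e-12)
  ranked <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.6))
  expect_equal(ranked$auc, 1)
  expect_warning(one <- compute_metrics(c(1, 1), c(0.9, 0.8)))
  expect_true(is.na(one$auc) && is.na(one$mcc))
})

test_that("metrics agree with brute-force recount and pairwise AUC on random draws", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2) # ties included
    m <- compute_metrics(y, s)
    o <- oracle_metrics(y, s)
    expect_equal(m$auc, o$auc, tolerance = 1e-12)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
    if (is.finite(o$mcc)) expect_equal(m$mcc, o$mcc, tolerance = 1e-12)
  }
})

test_that("training separates separable data and is deterministic", {
  tb <- make_feature_table(500, class_sep = 6, noise = 0, seed = 7)
  X <- tb[, feature_cols()]
  m1 <- train(X, tb$label, small_spec(), seed = 3)
  p1 <- predict_proba(m1, X)
  acc <- mean((p1 >= 0.5) == tb$label)
  expect_gte(acc, 0.99)
  m2 <- train(X, tb$label, small_spec(), seed = 3)
  p2 <- predict_proba(m2, X)
  expect_identical(p1, p2)

  expect_error(train(X, rep(1, nrow(X))),
               class = "plantmir_argument_error")
  expect_error(predict_proba(m1, X[, 1:10]),
               class = "plantmir_argument_error")
  expect_length(predict_proba(m1, X[0, ]), 0)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # deep inside the positive cluster
  centre <- colMeans(X[tb$label == 1, ])
  expect_gt(predict_proba(m1, t(as.matrix(centre))), 0.9)
})

test_that("model reporting helpers describe the network", {
  tb <- make_feature_table(100, class_sep = 6, seed = 8)
  m <- train(tb[, feature_cols()], tb$label, small_spec(), seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 3L)
  expect_equal(td$units, c(32L, 16L, 8L))
  g <- glance(m)
  expect_equal(g$n_features, 170L)
})

test_that("stratified k-fold cross-validation partitions both classes evenly", {
  tb <- make_feature_table(60, class_sep = 6, seed = 9)
  X <- tb[, feature_cols()]
  set.seed(1)
  rep1 <- kfold_cv(X, tb$label, k = 5, small_spec(epochs = 15L), seed = 2)
  fold <- rep1$fold_assignment
  expect_equal(sort(unique(fold)), 1:5)
  # folds are disjoint, cover everything, and are class-balanced
  expect_equal(length(fold), nrow(X))
  for (f in 1:5) {
    expect_equal(sum(fold == f & tb$label == 1), 12L)
    expect_equal(sum(fold == f & tb$label == 0), 12L)
  }
  rep2 <- kfold_cv(X, tb$label, k = 5, small_spec(epochs = 15L), seed = 2)
  expect_identical(rep1$fold_assignment, rep2$fold_assignment)
  expect_equal(tidy(rep1)$accuracy, tidy(rep2)$accuracy)
  expect_gte(glance(rep1)$accuracy, 0.95)
  expect_error(kfold_cv(X, tb$label, k = 100),
               class = "plantmir_argument_error")
  s <- rep1$summary
  expect_setequal(s$metric, c("accuracy", "sensitivity", "specificity",
                              "precision", "f1", "mcc", "auc"))
})

test_that("leave-one-group-out never leaks the held-out group", {
  tb <- make_feature_table(90, class_sep = 6, seed = 10)
  X <- tb[, feature_cols()]
  groups <- rep(c("sp1", "sp2", "sp3"), length.out = nrow(X))
  out <- leave_one_group_out(X, tb$label, groups, small_spec(epochs = 15L),
                             seed = 4)
  expect_equal(sort(out$group), c("sp1", "sp2", "sp3"))
  splits <- attr(out, "splits")
  for (g in names(splits)) {
    expect_length(intersect(splits[[g]]$train, splits[[g]]$test), 0)
    expect_setequal(c(splits[[g]]$train, splits[[g]]$test), seq_len(nrow(X)))
    expect_true(all(groups[splits[[g]]$test] == g))
    expect_true(all(groups[splits[[g]]$train] != g))
  }
  expect_gte(mean(out$accuracy), 0.9)
  expect_error(leave_one_group_out(X, tb$label, rep("one", nrow(X))),
               class = "plantmir_argument_error")
})

test_that("test accuracy tracks 1 - label-noise as n grows", {
  accs <- vapply(c(0, 0.1, 0.2), function(eps) {
    tb <- make_feature_table(400, class_sep = 6, noise = eps,
                             seed = 100 + round(eps * 10))
    X <- tb[, feature_cols()]
    idx <- sample(nrow(X))
    tr <- idx[1:600]; te <- idx[601:800]
    m <- train(X[tr, ], tb$label[tr], small_spec(epochs = 20L), seed = 5)
    mean((predict_proba(m, X[te, ]) >= 0.5) == tb$label[te])
  }, 1.0)
  expect_gte(accs[1], 0.97)
  expect_lt(abs(accs[2] - 0.9), 0.08)
  expect_lt(abs(accs[3] - 0.8), 0.1)
})
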