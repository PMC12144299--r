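test_that("decode selects the masked columns and round-trips", {
  ds <- small_ds()
  all_on <- binary_learner(rep(1L, 8), 2, 1)
  expect_equal(decode(all_on, ds)$columns, 1:8)
  one <- binary_learner(c(1L, rep(0L, 7)), 3, 0.5)
  d <- decode(one, ds)
  expect_equal(d$columns, 1L)
  expect_equal(d$c_value, 3)
  expect_equal(d$sigma_value, 0.5)
  # decode then re-encode is the identity
  re <- binary_learner(as.integer(seq_len(8) %in% d$columns),
                       d$c_value, d$sigma_value)
  expect_equal(re, one)
  expect_error(decode(binary_learner(c(1L, 0L), 2, 1), ds), "mask length")
})

test_that("wrapper fitness separates well-separated classes", {
  # informative features shifted by 10 SD: margin is enormous
  gen <- make_synthetic(synthetic_spec(120, 4, 4, 0.5, 10, seed = 31))
  bl <- binary_learner(rep(1L, 4), 2, 1)
  r <- evaluate_fitness(bl, gen$dataset, k_folds = 5, seed = 31)
  expect_gte(r$fitness, 0.99)
  # independent nearest-centroid oracle agrees the problem is trivial
  X <- gen$dataset$features; y <- gen$dataset$labels
  mu0 <- colMeans(X[y == 0, ]); mu1 <- colMeans(X[y == 1, ])
  pred <- as.integer(rowSums(sweep(X, 2, mu1)^2) <
                       rowSums(sweep(X, 2, mu0)^2))
  expect_gte(mean(pred == y), 0.99)
})

test_that("wrapper fitness is at chance on label-permuted data", {
  gen <- make_synthetic(synthetic_spec(150, 4, 4, 0.5, 10, seed = 32))
  ds <- gen$dataset
  bl <- binary_learner(rep(1L, 4), 2, 1)
  fits <- vapply(1:10, function(s) {
    set.seed(s)
    null_ds <- bc_dataset(ds$features, sample(ds$labels),
                          provenance = "synthetic")
    evaluate_fitness(bl, null_ds, k_folds = 5, seed = s)$fitness
  }, numeric(1))
  expect_gte(mean(fits), 0.4)
  expect_lte(mean(fits), 0.6)
})

test_that("fitness result satisfies its identities and is deterministic", {
  ds <- small_ds()
  bl <- binary_learner(c(1, 1, 1, 0, 0, 0, 0, 0), 2, 1)
  r1 <- evaluate_fitness(bl, ds, k_folds = 5, seed = 11)
  r2 <- evaluate_fitness(bl, ds, k_folds = 5, seed = 11)
  expect_identical(r1, r2)
  expect_equal(r1$fitness, mean(r1$fold_accuracies), tolerance = 1e-12)
  expect_equal(sum(r1$confusion), nrow(ds$features))
  expect_equal(r1$n_selected, 3L)
  # row permutation leaves the fitness unchanged (canonical folds)
  set.seed(33)
  perm <- sample(nrow(ds$features))
  ds_p <- bc_dataset(ds$features[perm, ], ds$labels[perm],
                     provenance = "synthetic")
  r3 <- evaluate_fitness(bl, ds_p, k_folds = 5, seed = 11)
  expect_equal(r3$fitness, r1$fitness, tolerance = 1e-12)
  expect_equal(r3$confusion, r1$confusion)
  # invalid hyperparameters rejected
  expect_error(evaluate_fitness(bl, ds, k_folds = 1), "k_folds")
})

test_that("adding a pure-noise feature does not raise expected null accuracy", {
  # null world: neither feature carries signal; CV accuracy with the
  # noise feature added should not exceed the single-feature case in
  # expectation (both are chance)
  diffs <- vapply(1:50, function(s) {
    gen <- make_synthetic(synthetic_spec(80, 2, 1, 0.5, 0, seed = 1000 + s))
    f1 <- evaluate_fitness(binary_learner(c(1L, 0L), 2, 1), gen$dataset,
                           k_folds = 4, seed = s)$fitness
    f2 <- evaluate_fitness(binary_learner(c(1L, 1L), 2, 1), gen$dataset,
                           k_folds = 4, seed = s)$fitness
    f2 - f1
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lte(mean(diffs), 3 * se)  # not significantly positive
})

test_that("metric suite matches hand arithmetic and its identities", {
  m <- compute_metrics(c(TP = 50, FN = 10, TN = 30, FP = 10))
  expect_equal(m$sensitivity, 50 / 60, tolerance = 1e-9)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$auc_balanced, (50 / 60 + 0.75) / 2, tolerance = 1e-9)
  expect_equal(m$precision, 50 / 60, tolerance = 1e-9)
  expect_equal(m$fpr, 10 / 40)
  # perfect classifier
  mp <- compute_metrics(c(TP = 40, FN = 0, TN = 60, FP = 0))
  for (k in c("accuracy", "sensitivity", "specificity", "precision",
              "f_score", "auc_balanced"))
    expect_equal(mp[[k]], 1.0)
  # identities over random confusions
  set.seed(34)
  for (i in 1:25) {
    cf <- c(TP = rpois(1, 20) + 1, FP = rpois(1, 5), TN = rpois(1, 20) + 1,
            FN = rpois(1, 5))
    mm <- compute_metrics(cf)
    expect_equal(mm$sensitivity + mm$fnr, 1, tolerance = 1e-12)
    expect_equal(mm$specificity + mm$fpr, 1, tolerance = 1e-12)
  }
  # zero denominators flagged as undefined, not zero
  mz <- compute_metrics(c(TP = 0, FN = 0, TN = 5, FP = 5))
  expect_true(is.na(mz$sensitivity))
  expect_true("sensitivity" %in% attr(mz, "undefined"))
})

test_that("the SMO SVM solves a hand-checkable separable problem", {
  # 1-D separable points: maximum-margin line is x = 0
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- svm_fit(X, y, C = 10, kernel = "linear")
  expect_equal(svm_predict(m, X), y)
  # decision value at the midpoint is 0 (margin symmetry)
  expect_equal(svm_predict(m, matrix(0), decision = TRUE), 0,
               tolerance = 1e-6)
  # w = sum alpha_i y_i x_i must have |w| = 2 / margin = 1
  w <- sum(m$alpha * m$y * X)
  expect_equal(w, 1, tolerance = 1e-3)
  expect_error(svm_fit(X, y, C = -1), "positive")
})
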