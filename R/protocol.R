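#' Outer holdout protocol: optimize on a train split, report test accuracy
#'
#' The reporting protocol for benchmark tables: an 80/20 stratified outer
#' split (seeded); the optimizer runs on the 80% partition with its
#' internal K-fold fitness; the final best learner is then refit once on
#' the whole training partition and scored on the untouched 20% test
#' partition. The test accuracy is an honest estimate, unlike the in-run
#' fitness, which is maximized over masks and therefore optimistic.
#'
#' @param dataset a [bc_dataset()].
#' @param config an [optimizer_config()].
#' @param train_fraction fraction of samples in the training partition
#'   (default 0.8).
#' @return list with `record` (the training-partition `run_record`),
#'   `train_accuracy` (its in-run best fitness), `test_accuracy`,
#'   `test_metrics` (a `metric_set`), and `test_indices`.
#' @export
holdout_protocol <- function(dataset, config = optimizer_config(),
                             train_fraction = 0.8) {
  stopifnot(inherits(dataset, "bc_dataset"),
            train_fraction > 0, train_fraction < 1)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  y <- dataset$labels
  test_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(length(idx) * (1 - train_fraction)))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  tr <- setdiff(seq_along(y), test_idx)
  train_ds <- bc_dataset(dataset$features[tr, , drop = FALSE], y[tr],
                         dataset$feature_names, dataset$provenance)
  rec <- run_baseline(train_ds, config)
  dec <- decode(rec$best_learner, train_ds)
  Xtr <- train_ds$features[, dec$columns, drop = FALSE]
  Xte <- dataset$features[test_idx, dec$columns, drop = FALSE]
  mu <- colMeans(Xtr)
  sd_ <- apply(Xtr, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  scale2 <- function(M) sweep(sweep(M, 2, mu), 2, sd_, "/")
  model <- svm_fit(scale2(Xtr), train_ds$labels, dec$c_value,
                   dec$sigma_value, config$kernel)
  pred <- svm_predict(model, scale2(Xte))
  truth <- y[test_idx]
  conf <- c(TP = sum(pred == 1L & truth == 1L),
            FP = sum(pred == 1L & truth == 0L),
            TN = sum(pred == 0L & truth == 0L),
            FN = sum(pred == 0L & truth == 1L))
  list(record = rec, train_accuracy = rec$best_fitness,
       test_accuracy = mean(pred == truth),
       test_metrics = compute_metrics(conf), test_indices = test_idx)
}

# published reference accuracies (percent) on the real UCI files; used
# only to flag deviation when a user supplies those files
.reference_accuracy <- c(wbcd = 96.11, wdbc = 97.43)

#' Flag deviation from the published reference accuracy
#'
#' When a run used one of the real Wisconsin files, compare the achieved
#' accuracy (percent) with the published reference for that collection
#' and warn — never fail — if the deviation exceeds 3 percentage points.
#' Synthetic or generic data is ignored. The references require the
#' external UCI files, so no automated test asserts them.
#'
#' @param accuracy achieved accuracy in percent (e.g. 95.2).
#' @param provenance dataset provenance string (`"wbcd"`, `"wdbc"`,
#'   anything else is ignored).
#' @return invisibly, the signed deviation in points (or `NA` when no
#'   reference applies).
#' @export
flag_accuracy_deviation <- function(accuracy, provenance) {
  if (!provenance %in% names(.reference_accuracy))
    return(invisible(NA_real_))
  ref <- .reference_accuracy[[provenance]]
  dev <- accuracy - ref
  if (abs(dev) > 3)
    warning(sprintf(
      "accuracy %.2f%% deviates %.2f points from the published %.2f%% on %s",
      accuracy, dev, ref, provenance))
  invisible(dev)
}
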