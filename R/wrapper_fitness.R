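#' Fit a soft-margin kernel SVM (internal SMO solver)
#'
#' Solves the C-SVM dual by sequential minimal optimization with
#' maximal-violating-pair working-set selection (compiled, deterministic).
#' `sigma` parameterizes the RBF kernel as
#' `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`; the polynomial kernel is
#' `(x.y + 1)^3` and the linear kernel the plain inner product.
#'
#' @param X numeric training matrix (rows = samples).
#' @param y 0/1 labels.
#' @param C positive penalty.
#' @param sigma positive RBF width (ignored by linear/poly).
#' @param kernel `"rbf"`, `"poly"` or `"linear"`.
#' @return an `svm_model` list (support data, dual coefficients, bias).
#' @export
svm_fit <- function(X, y, C, sigma = 1, kernel = c("rbf", "poly", "linear")) {
  kernel <- match.arg(kernel)
  if (!is.finite(C) || C <= 0) stop("C must be positive")
  if (kernel == "rbf" && (!is.finite(sigma) || sigma <= 0))
    stop("sigma must be positive")
  X <- as.matrix(X); storage.mode(X) <- "double"
  ys <- ifelse(y == 1L, 1, -1)
  kid <- match(kernel, c("rbf", "linear", "poly")) - 1L
  gamma <- if (kernel == "rbf") 1 / (2 * sigma^2) else 0
  K <- kernel_matrix(X, X, kid, gamma)
  # 5000 pair updates bound the solve on unseparable data at large C;
  # well past convergence for the wrapper's fold sizes
  fit <- smo_solve(K, ys, C, max_iter = 5000L)
  structure(list(X = X, y = ys, alpha = fit$alpha, b = fit$b,
                 kernel = kernel, kid = kid, gamma = gamma, C = C,
                 sigma = sigma),
            class = "svm_model")
}

#' Predict 0/1 labels from a fitted SVM
#'
#' @param model an [svm_fit()] result.
#' @param newdata numeric matrix with the training feature count.
#' @param decision if `TRUE`, return raw decision values instead of labels.
#' @return integer 0/1 labels (or numeric decision values).
#' @export
svm_predict <- function(model, newdata, decision = FALSE) {
  stopifnot(inherits(model, "svm_model"))
  newdata <- as.matrix(newdata); storage.mode(newdata) <- "double"
  Kt <- kernel_matrix(model$X, newdata, model$kid, model$gamma)
  f <- svm_decision(Kt, model$alpha, model$y, model$b)
  if (decision) return(f)
  as.integer(f > 0)
}

#' Decode a binary learner against a dataset
#'
#' @param binary a [binary_learner()].
#' @param dataset a [bc_dataset()] whose feature count matches the mask.
#' @return list with `columns` (selected indices), `c_value`,
#'   `sigma_value`.
#' @export
decode <- function(binary, dataset) {
  stopifnot(inherits(binary, "binary_learner"),
            inherits(dataset, "bc_dataset"))
  if (length(binary$mask) != ncol(dataset$features))
    stop("mask length must equal the dataset feature count")
  list(columns = which(binary$mask == 1L),
       c_value = binary$c_value, sigma_value = binary$sigma_value)
}

# Canonical stratified fold assignment. Rows are first put in a canonical
# order (label, then lexicographic feature order) so the folds -- and hence
# the fitness -- are invariant to row permutation of the input; the
# canonical order is then shuffled with the run seed and folds are dealt
# round-robin within each class.
stratified_folds <- function(dataset, k_folds, seed) {
  n <- nrow(dataset$features)
  key <- do.call(order, c(list(dataset$labels),
                          lapply(seq_len(ncol(dataset$features)),
                                 function(j) dataset$features[, j])))
  fold <- integer(n)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (cl in c(0L, 1L)) {
    idx <- key[dataset$labels[key] == cl]
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Wrapper fitness: stratified K-fold CV accuracy of the decoded SVM
#'
#' Decodes the learner into (feature subset, C, sigma), then for each of
#' K seeded stratified folds: standardizes on the training part only,
#' fits the kernel SVM, predicts the held-out part. The fitness is the
#' mean of the per-fold accuracies; the confusion counts are summed over
#' folds. Deterministic given `(learner, dataset, k_folds, kernel, seed)`.
#' Folds whose training part degenerates to a single class are skipped
#' with a warning and K is reduced accordingly.
#'
#' @param learner a [binary_learner()].
#' @param dataset a [bc_dataset()].
#' @param k_folds number of folds (>= 2; each class needs >= k_folds
#'   members). Default 10.
#' @param kernel `"rbf"`, `"poly"` or `"linear"`.
#' @param seed integer seed controlling the fold shuffle.
#' @return a `fitness_result` list: `fitness`, `fold_accuracies`,
#'   `confusion` (TP, FP, TN, FN summed over folds), `n_selected`.
#' @export
evaluate_fitness <- function(learner, dataset, k_folds = 10,
                             kernel = c("rbf", "poly", "linear"),
                             seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(learner, "binary_learner"),
            inherits(dataset, "bc_dataset"), k_folds >= 2)
  if (length(unique(dataset$labels)) < 2L)
    stop("both classes must be present to evaluate fitness")
  if (min(table(dataset$labels)) < k_folds)
    stop("each class needs at least k_folds members")
  dec <- decode(learner, dataset)
  if (dec$c_value <= 0 || dec$sigma_value <= 0)
    stop("C and sigma must be positive")
  Xs <- dataset$features[, dec$columns, drop = FALSE]
  y <- dataset$labels
  fold <- stratified_folds(dataset, k_folds, seed)
  acc <- numeric(0)
  conf <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (k in seq_len(k_folds)) {
    tr <- fold != k; te <- !tr
    if (length(unique(y[tr])) < 2L) {
      warning("fold ", k, " has a single-class training part; skipped")
      next
    }
    mu <- colMeans(Xs[tr, , drop = FALSE])
    sd_ <- apply(Xs[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    Ztr <- sweep(sweep(Xs[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
    Zte <- sweep(sweep(Xs[te, , drop = FALSE], 2, mu), 2, sd_, "/")
    model <- svm_fit(Ztr, y[tr], dec$c_value, dec$sigma_value, kernel)
    pred <- svm_predict(model, Zte)
    truth <- y[te]
    acc <- c(acc, mean(pred == truth))
    conf["TP"] <- conf["TP"] + sum(pred == 1L & truth == 1L)
    conf["FP"] <- conf["FP"] + sum(pred == 1L & truth == 0L)
    conf["TN"] <- conf["TN"] + sum(pred == 0L & truth == 0L)
    conf["FN"] <- conf["FN"] + sum(pred == 0L & truth == 1L)
  }
  structure(list(fitness = mean(acc), fold_accuracies = acc,
                 confusion = conf, n_selected = length(dec$columns)),
            class = "fitness_result")
}

#' Confusion-derived metric suite
#'
#' Standard formulas: accuracy `(TP+TN)/total`, sensitivity (= recall =
#' TPR) `TP/(TP+FN)`, specificity (= TNR) `TN/(FP+TN)`, precision
#' `TP/(TP+FP)`, F-score `2PR/(P+R)`, balanced AUC
#' `(sensitivity+specificity)/2` (the source defines its AUC this way, so
#' it is named `auc_balanced` here), FNR `FN/(TP+FN)` and FPR
#' `FP/(FP+TN)`. The source prints FPR as `FP/(FP+FN)`, which breaks the
#' identity `specificity + FPR = 1`; the standard form is used and the
#' discrepancy noted here. Metrics with a zero denominator are reported
#' as `NA` and listed in the `undefined` attribute.
#'
#' @param confusion named numeric vector with `TP`, `FP`, `TN`, `FN`
#'   (all >= 0, total > 0).
#' @return a named list of metrics (class `metric_set`) with an
#'   `undefined` attribute naming any NA metrics.
#' @export
compute_metrics <- function(confusion) {
  tp <- confusion[["TP"]]; fp <- confusion[["FP"]]
  tn <- confusion[["TN"]]; fn <- confusion[["FN"]]
  stopifnot(all(c(tp, fp, tn, fn) >= 0), tp + fp + tn + fn > 0)
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  total <- tp + fp + tn + fn
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, fp + tn)
  prec <- sdiv(tp, tp + fp)
  f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  m <- list(accuracy = (tp + tn) / total,
            sensitivity = sens, specificity = spec, precision = prec,
            f_score = f,
            auc_balanced = if (!is.na(sens) && !is.na(spec))
              (sens + spec) / 2 else NA_real_,
            tpr = sens, tnr = spec,
            fpr = sdiv(fp, fp + tn), fnr = sdiv(fn, tp + fn))
  undef <- names(m)[vapply(m, is.na, logical(1))]
  structure(m, undefined = undef, class = "metric_set")
}
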