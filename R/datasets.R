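#' Construct a dataset container
#'
#' @param features numeric matrix (samples x features), no missing values.
#' @param labels 0/1 integer vector (1 = malignant/positive).
#' @param feature_names optional character vector.
#' @param provenance one of `"wbcd"`, `"wdbc"`, `"synthetic"`, `"generic"`.
#' @return a `bc_dataset` list.
#' @export
bc_dataset <- function(features, labels,
                       feature_names = colnames(features),
                       provenance = "generic") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  if (anyNA(features)) stop("dataset must not contain missing values")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(features)))
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names, provenance = provenance),
            class = "bc_dataset")
}

#' @export
print.bc_dataset <- function(x, ...) {
  cat(sprintf("<bc_dataset:%s> %d samples x %d features, %d positive (%.1f%%)\n",
              x$provenance, nrow(x$features), ncol(x$features),
              sum(x$labels), 100 * mean(x$labels)))
  invisible(x)
}

#' Load a WBCD-style CSV (original Wisconsin dialect)
#'
#' Headerless, 11 comma-separated fields per row: id, nine integer
#' cytology features in 1-10, class label 2 (benign) or 4 (malignant).
#' '?' marks missing values; rows containing any are dropped (the
#' canonical 699-row file keeps 683 complete cases). Class 2 maps to
#' label 0, class 4 to label 1.
#'
#' @param path path to a local CSV file.
#' @return a [bc_dataset()] with provenance `"wbcd"`.
#' @export
load_wbcd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) != 11L)
    stop("WBCD dialect expects 11 fields per row, got ", ncol(raw))
  keep <- !apply(raw == "?", 1L, any)
  raw <- raw[keep, , drop = FALSE]
  cls <- raw[[11]]
  bad <- which(!cls %in% c("2", "4"))
  if (length(bad))
    stop("unknown class label at line ", bad[1], ": ", cls[bad[1]])
  feats <- vapply(raw[2:10], as.numeric, numeric(nrow(raw)))
  feats <- matrix(feats, nrow = nrow(raw))
  nm <- c("clump_thickness", "uniformity_cell_size", "uniformity_cell_shape",
          "marginal_adhesion", "single_epithelial_cell_size", "bare_nuclei",
          "bland_chromatin", "normal_nucleoli", "mitoses")
  bc_dataset(feats, as.integer(cls == "4"), nm, provenance = "wbcd")
}

#' Load a WDBC-style CSV (diagnostic Wisconsin dialect)
#'
#' Headerless, 32 fields per row: id, diagnosis M/B, then 30 real-valued
#' features (mean, standard-error and worst groups of ten cell-nucleus
#' measurements). M maps to label 1, B to 0.
#'
#' @param path path to a local CSV file.
#' @return a [bc_dataset()] with provenance `"wdbc"`.
#' @export
load_wdbc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) != 32L)
    stop("WDBC dialect expects 32 fields per row, got ", ncol(raw))
  diag <- raw[[2]]
  bad <- which(!diag %in% c("M", "B"))
  if (length(bad))
    stop("unknown diagnosis at line ", bad[1], ": ", diag[bad[1]])
  feats <- vapply(raw[3:32], as.numeric, numeric(nrow(raw)))
  feats <- matrix(feats, nrow = nrow(raw))
  base <- c("radius", "texture", "perimeter", "area", "smoothness",
            "compactness", "concavity", "concave_points", "symmetry",
            "fractal_dimension")
  nm <- paste0(rep(base, 3), "_", rep(c("mean", "se", "worst"), each = 10))
  bc_dataset(feats, as.integer(diag == "M"), nm, provenance = "wdbc")
}

#' Synthetic-data specification
#'
#' Describes a two-class Gaussian mixture: `n_informative` features whose
#' class means differ by `mean_shift` noise-standard-deviations (with
#' optional equicorrelation `correlation` inside the informative block),
#' the remaining features pure standard noise identical across classes.
#' Emulates the shapes of the two Wisconsin dialects, e.g.
#' `(699, 9, 4, 0.345, 2.0)` and `(569, 30, 8, 0.372, 2.0)`.
#'
#' @param n_samples,n_features,n_informative sizes;
#'   `1 <= n_informative <= n_features`.
#' @param class_fraction_positive expected positive-class share in (0, 1).
#' @param mean_shift class separation per informative feature, in
#'   noise-SD units.
#' @param correlation equicorrelation within the informative block,
#'   in `[0, 1)`.
#' @param seed integer seed; the generated dataset is deterministic
#'   given the spec.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 400, n_features = 20,
                           n_informative = 5, class_fraction_positive = 0.5,
                           mean_shift = 2.0, correlation = 0.0, seed = 1L) {
  stopifnot(n_samples >= 4, n_features >= 1,
            n_informative >= 1, n_informative <= n_features,
            class_fraction_positive > 0, class_fraction_positive < 1,
            mean_shift >= 0, correlation >= 0, correlation < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 class_fraction_positive = class_fraction_positive,
                 mean_shift = mean_shift, correlation = correlation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-class Gaussian dataset
#'
#' Labels are drawn Bernoulli(`class_fraction_positive`) with both classes
#' forced present. Informative features are unit-variance Gaussians whose
#' means sit at `+/- mean_shift / 2` by class (total separation
#' `mean_shift` SD) with equicorrelated noise inside the block; the
#' remaining features are N(0, 1) regardless of class. The informative
#' columns are the first `n_informative` indices, returned explicitly as
#' ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [bc_dataset()]) and `informative`
#'   (integer index vector of the informative columns).
#' @export
make_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_samples; d <- spec$n_features; k <- spec$n_informative
  y <- stats::rbinom(n, 1L, spec$class_fraction_positive)
  if (sum(y) == 0L) y[1L] <- 1L
  if (sum(y) == n) y[1L] <- 0L
  X <- matrix(stats::rnorm(n * d), n, d)
  if (spec$correlation > 0 && k > 1) {
    # equicorrelated block via a shared factor
    rho <- spec$correlation
    z <- stats::rnorm(n)
    X[, 1:k] <- sqrt(rho) * z + sqrt(1 - rho) * X[, 1:k]
  }
  shift <- spec$mean_shift * (y - 0.5)  # +/- mean_shift/2 by class
  X[, seq_len(k)] <- X[, seq_len(k)] + shift
  ds <- bc_dataset(X, y, paste0("f", seq_len(d)), provenance = "synthetic")
  list(dataset = ds, informative = seq_len(k))
}

#' Write a dataset in the WDBC-style dialect
#'
#' Emits a headerless CSV: synthetic id, M/B diagnosis, feature columns.
#' Round-trips through [load_wdbc()] only for 30-feature data; otherwise
#' use [read_dataset_csv()].
#'
#' @param dataset a [bc_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_wdbc_style <- function(dataset, path) {
  stopifnot(inherits(dataset, "bc_dataset"))
  feat_chr <- apply(dataset$features, 2, function(x) sprintf("%.17g", x))
  feat_chr <- matrix(feat_chr, nrow = nrow(dataset$features))
  df <- data.frame(id = seq_len(nrow(dataset$features)) + 1e6,
                   diagnosis = ifelse(dataset$labels == 1L, "M", "B"))
  df <- cbind(df, as.data.frame(feat_chr))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a generic WDBC-style CSV with any feature count
#'
#' Same layout as [load_wdbc()] (id, M/B, features) without the 30-column
#' restriction; used for synthetic fixtures written by
#' [write_dataset_wdbc_style()].
#'
#' @param path CSV path.
#' @return a [bc_dataset()] with provenance `"generic"`.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 3L) stop("expected id, diagnosis and >= 1 feature column")
  diag <- raw[[2]]
  bad <- which(!diag %in% c("M", "B"))
  if (length(bad))
    stop("unknown diagnosis at line ", bad[1], ": ", diag[bad[1]])
  feats <- vapply(raw[3:ncol(raw)], as.numeric, numeric(nrow(raw)))
  feats <- matrix(feats, nrow = nrow(raw))
  bc_dataset(feats, as.integer(diag == "M"), provenance = "generic")
}
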