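#' Average ranks of algorithms across blocks
#'
#' Ranks each block (row) of a score matrix in descending order — rank 1
#' is the best score — with midranks for ties, then averages per column.
#'
#' @param scores numeric matrix, `N` blocks x `k` algorithms, higher =
#'   better; finite.
#' @return a `rank_table` list: `scores`, `ranks` (N x k), `avg_ranks`
#'   (length k, named when `scores` has column names).
#' @export
average_ranks <- function(scores) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (nrow(scores) < 2 || ncol(scores) < 2)
    stop("need at least 2 blocks and 2 algorithms")
  ranks <- t(apply(-scores, 1, rank))  # midranks by default
  avg <- colMeans(ranks)
  names(avg) <- colnames(scores)
  structure(list(scores = scores, ranks = ranks, avg_ranks = avg),
            class = "rank_table")
}

#' Friedman chi-square statistic from average ranks
#'
#' `chi^2 = [12 N / (k (k + 1))] * sum_j (Rbar_j - (k + 1)/2)^2` on
#' `k - 1` degrees of freedom, with the upper-tail chi-square p-value.
#'
#' @param avg_ranks length-`k` vector of average ranks.
#' @param N number of blocks.
#' @param k number of algorithms (default `length(avg_ranks)`).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
friedman_statistic <- function(avg_ranks, N, k = length(avg_ranks)) {
  stopifnot(length(avg_ranks) == k, N >= 2, k >= 2)
  stat <- 12 * N / (k * (k + 1)) * sum((avg_ranks - (k + 1) / 2)^2)
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Post-hoc z comparisons against the control algorithm
#'
#' For each competitor `i`, `z_i = (Rbar_i - Rbar_0) / SE` with
#' `SE = sqrt(k (k + 1) / (6 N))` and the control `0` the algorithm with
#' the minimal average rank. Two-sided normal p-values; rejection
#' thresholds at level `alpha` for the Holm (`alpha / (m - i + 1)` over
#' p-sorted comparisons), Hochberg (same thresholds, largest-p first) and
#' Li (`alpha (1 - p_max) / (1 - alpha)`, and `alpha` for the largest p)
#' step procedures. Comparisons are labelled by competitor identity and
#' sorted by decreasing z.
#'
#' @param avg_ranks named average-rank vector.
#' @param N number of blocks.
#' @param k number of algorithms (default `length(avg_ranks)`).
#' @param control_index index of the control; defaults to the minimal
#'   average rank and must point at it.
#' @param alpha significance level (default 0.05).
#' @return a `posthoc_result` data frame: `algorithm`, `z`, `p`,
#'   thresholds `holm`, `hochberg`, `li`, and logical rejections
#'   `reject_holm`, `reject_hochberg`, `reject_li`; `SE` as attribute.
#' @export
posthoc_z <- function(avg_ranks, N, k = length(avg_ranks),
                      control_index = which.min(avg_ranks), alpha = 0.05) {
  stopifnot(length(avg_ranks) == k, N >= 2, k >= 2)
  if (avg_ranks[control_index] != min(avg_ranks))
    stop("control must have the minimal average rank")
  se <- sqrt(k * (k + 1) / (6 * N))
  comp <- setdiff(seq_len(k), control_index)
  z <- (avg_ranks[comp] - avg_ranks[control_index]) / se
  p <- 2 * stats::pnorm(-abs(z))
  nm <- if (!is.null(names(avg_ranks))) names(avg_ranks)[comp]
        else paste0("alg", comp)
  ord <- order(-z)  # most significant first (largest rank distance)
  z <- z[ord]; p <- p[ord]; nm <- nm[ord]
  m_cmp <- length(z)
  holm <- alpha / (m_cmp - seq_len(m_cmp) + 1)
  hochberg <- holm
  li <- c(rep(alpha * (1 - p[m_cmp]) / (1 - alpha), m_cmp - 1), alpha)
  reject_holm <- logical(m_cmp)
  for (i in seq_len(m_cmp)) {  # step-down: stop at first failure
    if (p[i] <= holm[i]) reject_holm[i] <- TRUE else break
  }
  reject_hochberg <- logical(m_cmp)
  for (i in rev(seq_len(m_cmp))) {  # step-up: largest p first
    if (p[i] <= hochberg[i]) { reject_hochberg[seq_len(i)] <- TRUE; break }
  }
  reject_li <- p <= li
  out <- data.frame(algorithm = nm, z = unname(z), p = unname(p),
                    holm = holm, hochberg = hochberg, li = li,
                    reject_holm = reject_holm,
                    reject_hochberg = reject_hochberg,
                    reject_li = reject_li,
                    stringsAsFactors = FALSE)
  attr(out, "SE") <- se
  attr(out, "control") <- if (!is.null(names(avg_ranks)))
    names(avg_ranks)[control_index] else paste0("alg", control_index)
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Repeated-run benchmark of several optimizers on one dataset
#'
#' Runs each algorithm `n_runs` times with per-run seeds derived from the
#' master seed (`seed + run - 1`), collects the final best fitness as the
#' score matrix (runs x algorithms), aggregates metrics and emits FP/FN
#' rate histogram data.
#'
#' @param dataset a [bc_dataset()].
#' @param algorithms character vector of algorithm names.
#' @param n_runs runs per algorithm (>= 1).
#' @param config base [optimizer_config()]; `algorithm` and `seed` are
#'   overridden per run.
#' @param breaks histogram break count for the FP/FN rates.
#' @return a `benchmark_report` list: `scores`, `records`, `summary`
#'   (mean/sd of fitness per algorithm), `fp_hist`, `fn_hist` (per
#'   algorithm lists of (bin_edge, count)), and `ranks` (a `rank_table`
#'   when `n_runs >= 2` and at least two algorithms).
#' @export
run_benchmark <- function(dataset, algorithms = c("seqtlboga", "ga"),
                          n_runs = 1L, config = optimizer_config(),
                          breaks = 10L) {
  stopifnot(n_runs >= 1, length(algorithms) >= 1)
  records <- list()
  scores <- matrix(NA_real_, n_runs, length(algorithms),
                   dimnames = list(NULL, algorithms))
  fp <- fn <- matrix(NA_real_, n_runs, length(algorithms),
                     dimnames = list(NULL, algorithms))
  for (a in seq_along(algorithms)) {
    records[[algorithms[a]]] <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      cfg <- config
      cfg$algorithm <- algorithms[a]
      cfg$seed <- config$seed + r - 1L
      rec <- run_baseline(dataset, cfg)
      records[[algorithms[a]]][[r]] <- rec
      scores[r, a] <- rec$best_fitness
      fp[r, a] <- rec$final_metrics$fpr
      fn[r, a] <- rec$final_metrics$fnr
    }
  }
  edges <- seq(0, 1, length.out = breaks + 1L)
  hist_of <- function(x) {
    cnt <- as.integer(table(cut(x, edges, include.lowest = TRUE)))
    data.frame(bin_edge = edges[-length(edges)], count = cnt)
  }
  summary <- data.frame(
    algorithm = algorithms,
    mean_fitness = colMeans(scores),
    sd_fitness = apply(scores, 2, stats::sd),
    mean_fpr = colMeans(fp, na.rm = TRUE),
    mean_fnr = colMeans(fn, na.rm = TRUE),
    row.names = NULL)
  ranks <- if (n_runs >= 2 && length(algorithms) >= 2)
    average_ranks(scores) else NULL
  structure(list(scores = scores, records = records, summary = summary,
                 fp_hist = lapply(as.data.frame(fp), hist_of),
                 fn_hist = lapply(as.data.frame(fn), hist_of),
                 ranks = ranks),
            class = "benchmark_report")
}
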