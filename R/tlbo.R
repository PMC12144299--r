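#' TLBO parameters
#'
#' @param omega_min,omega_max rank-based inertia-weight bounds,
#'   `0 < omega_min <= omega_max <= 1`.
#' @param i_omega cosine rate of the adaptive teaching factor, in
#'   `[0, pi/2]` radians. Default 0.9 (the rate is otherwise unspecified;
#'   an upper PSO-style inertia constant).
#' @param tf_mode teaching-factor mode: `"classic"` (random integer in
#'   \{1, 2\}), `"adaptive"` (cosine decay, the default used by the
#'   engine), or `"rp_threshold"` (2 when the ranking probability is
#'   below `rp_epsilon`, else 1).
#' @param rp_epsilon threshold for the `rp_threshold` mode (default 0.5).
#' @param best_gets_max_omega if `TRUE` (default) the best-ranked learner
#'   receives `omega_max` (elite retention); flip to give the best learner
#'   the smallest inertia instead.
#' @return a `tlbo_params` list.
#' @export
tlbo_params <- function(omega_min = 0.4, omega_max = 0.9, i_omega = 0.9,
                        tf_mode = c("adaptive", "classic", "rp_threshold"),
                        rp_epsilon = 0.5, best_gets_max_omega = TRUE) {
  tf_mode <- match.arg(tf_mode)
  stopifnot(omega_min > 0, omega_min <= omega_max, omega_max <= 1,
            i_omega >= 0, i_omega <= pi / 2 + 1e-12)
  structure(list(omega_min = omega_min, omega_max = omega_max,
                 i_omega = i_omega, tf_mode = tf_mode,
                 rp_epsilon = rp_epsilon,
                 best_gets_max_omega = best_gets_max_omega),
            class = "tlbo_params")
}

#' Rank-based inertia weight
#'
#' `omega = (rank / total_pop) * (omega_max - omega_min) + omega_min`.
#' With the default orientation the best learner holds the top rank
#' (`total_pop`) and so receives `omega_max`.
#'
#' @param rank 1-based rank of the learner.
#' @param total_pop population size.
#' @param params a [tlbo_params()].
#' @return inertia weight in `(omega_min, omega_max]`.
#' @export
inertia_weight <- function(rank, total_pop, params = tlbo_params()) {
  if (any(rank < 1 | rank > total_pop)) stop("rank out of range")
  (rank / total_pop) * (params$omega_max - params$omega_min) + params$omega_min
}

#' Teaching factor
#'
#' Three modes: `classic` draws `round(1 + u)`, `u ~ U(0,1)`, so 1 or 2
#' with equal probability; `adaptive` is the cosine decay
#' `cos(i_omega * it / max_it)`, monotone non-increasing over iterations;
#' `rp_threshold` returns 2 when the ranking probability `rp` is below
#' `rp_epsilon`, else 1.
#'
#' @param mode one of `"classic"`, `"adaptive"`, `"rp_threshold"`.
#' @param i_omega cosine rate (radians), used by `adaptive`.
#' @param it,max_it current and maximum iteration, `0 <= it <= max_it`.
#' @param rp ranking probability in `[0, 1]`, used by `rp_threshold`.
#' @param rp_epsilon threshold, default 0.5.
#' @return the teaching factor (numeric scalar).
#' @export
teaching_factor <- function(mode = c("adaptive", "classic", "rp_threshold"),
                            i_omega = 0.9, it = 0, max_it = 1,
                            rp = NULL, rp_epsilon = 0.5) {
  mode <- match.arg(mode)
  stopifnot(it >= 0, it <= max_it)
  switch(mode,
    classic = round(1 + stats::runif(1)),
    adaptive = cos(i_omega * it / max_it),
    rp_threshold = {
      if (is.null(rp)) stop("rp_threshold mode needs a ranking probability")
      if (rp < rp_epsilon) 2 else 1
    })
}

#' Rank a population by fitness
#'
#' Best fitness receives rank `total_pop` (so that [inertia_weight()]
#' assigns `omega_max` to the best learner). Ties are broken toward fewer
#' selected features, then lower index, deterministically.
#'
#' @param fitness numeric fitness vector (maximization).
#' @param n_selected optional per-learner count of selected features used
#'   as the first tie-break; defaults to zero for all.
#' @return integer vector of 1-based ranks.
#' @export
rank_population <- function(fitness, n_selected = NULL) {
  n <- length(fitness)
  if (is.null(n_selected)) n_selected <- rep(0L, n)
  stopifnot(length(n_selected) == n)
  # best first: highest fitness, then fewer features, then lower index
  ord <- order(-fitness, n_selected, seq_len(n))
  ranks <- integer(n)
  ranks[ord] <- n:1L
  ranks
}

#' Teacher phase on the real-coded dimensions
#'
#' `X_new = omega_i * X_old + r * (X_teacher - T_f * M)` per learner, with
#' `M` the per-dimension population mean, r a single U(0,1) draw per
#' learner, and the result clipped to `bounds` (a 2 x d matrix of
#' lower/upper rows). If an `evaluate` function is supplied (mapping a row
#' to a fitness), each learner's move is accepted greedily: the new
#' position replaces the old only if its fitness is not worse.
#'
#' @param X numeric matrix (learners x real dimensions).
#' @param fitness fitness vector (used to locate the teacher and for
#'   greedy acceptance when `evaluate` is given).
#' @param params a [tlbo_params()].
#' @param it,max_it iteration counters for the adaptive teaching factor.
#' @param bounds 2 x d matrix: row 1 lower, row 2 upper bounds.
#' @param omega optional per-learner inertia weights; computed from ranks
#'   when `NULL`.
#' @param evaluate optional function(row) -> fitness for greedy acceptance.
#' @return list with updated `X` and `fitness`.
#' @export
teacher_phase <- function(X, fitness, params = tlbo_params(), it = 0,
                          max_it = 1, bounds = NULL, omega = NULL,
                          evaluate = NULL) {
  n <- nrow(X)
  teacher <- which.max(fitness)
  M <- colMeans(X)
  ranks <- rank_population(fitness)
  if (is.null(omega)) {
    oriented <- if (params$best_gets_max_omega) ranks else n + 1L - ranks
    omega <- inertia_weight(oriented, n, params)
  }
  rp <- ranks / n  # ranking probability (undefined in the source; rank share)
  Xn <- X
  fn <- fitness
  for (i in seq_len(n)) {
    tf <- teaching_factor(params$tf_mode, params$i_omega, it, max_it,
                          rp = rp[i], rp_epsilon = params$rp_epsilon)
    r <- stats::runif(1)
    xi <- omega[i] * X[i, ] + r * (X[teacher, ] - tf * M)
    if (!is.null(bounds)) xi <- pmin(pmax(xi, bounds[1, ]), bounds[2, ])
    if (is.null(evaluate)) {
      Xn[i, ] <- xi
    } else {
      f_new <- evaluate(xi)
      if (f_new >= fitness[i]) { Xn[i, ] <- xi; fn[i] <- f_new }
    }
  }
  list(X = Xn, fitness = fn)
}

#' Learner phase on the real-coded dimensions
#'
#' For each learner i, two distinct peers p != q are drawn; the learner
#' moves along the difference vector toward the fitter of the two:
#' `X_i + r (X_p - X_q)` if `f(X_p) > f(X_q)`, else `X_i + r (X_q - X_p)`.
#' Clipped to bounds; greedy acceptance when `evaluate` is supplied.
#'
#' @inheritParams teacher_phase
#' @return list with updated `X` and `fitness`.
#' @export
learner_phase <- function(X, fitness, bounds = NULL, evaluate = NULL) {
  n <- nrow(X)
  if (n < 2) stop("learner phase needs a population of at least 2")
  Xn <- X
  fn <- fitness
  for (i in seq_len(n)) {
    pq <- sample.int(n, 2)
    p <- pq[1]; q <- pq[2]
    r <- stats::runif(1)
    d <- if (fitness[p] > fitness[q]) X[p, ] - X[q, ] else X[q, ] - X[p, ]
    xi <- X[i, ] + r * d
    if (!is.null(bounds)) xi <- pmin(pmax(xi, bounds[1, ]), bounds[2, ])
    if (is.null(evaluate)) {
      Xn[i, ] <- xi
    } else {
      f_new <- evaluate(xi)
      if (f_new >= fitness[i]) { Xn[i, ] <- xi; fn[i] <- f_new }
    }
  }
  list(X = Xn, fitness = fn)
}
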