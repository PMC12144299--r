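#' Self-adaptive GA parameters
#'
#' The constants `c1..c6` drive the fitness-dependent crossover and
#' mutation probabilities; all lie in `[0, 1]`. The defaults anchor the
#' lower branches to the configured base rates (base crossover 0.7, base
#' mutation 0.4): `c3 = base_pc`, `c6 = base_pm`, `c1 = c4 = 0.5`,
#' `c2 = c5 = 0`.
#'
#' @param c1,c2,c3,c4,c5,c6 constants in `[0, 1]`.
#' @param base_pc,base_pm default crossover / mutation probabilities.
#' @param tournament_size tournament size for selection (default 3).
#' @param crossover_kind one of `"uniform"`, `"one_point"`, `"two_point"`.
#' @param mutation_kind one of `"bit_flip"`, `"gaussian_real"` (both are
#'   always applied to their respective chromosome parts; the flag records
#'   the configured operator set).
#' @return a `saga_params` list.
#' @export
saga_params <- function(c1 = 0.5, c2 = 0.0, c3 = 0.7, c4 = 0.5, c5 = 0.0,
                        c6 = 0.4, base_pc = 0.7, base_pm = 0.4,
                        tournament_size = 3L,
                        crossover_kind = c("uniform", "one_point", "two_point"),
                        mutation_kind = c("bit_flip", "gaussian_real")) {
  crossover_kind <- match.arg(crossover_kind)
  mutation_kind <- match.arg(mutation_kind)
  cs <- c(c1, c2, c3, c4, c5, c6, base_pc, base_pm)
  stopifnot(all(cs >= 0 & cs <= 1), tournament_size >= 2)
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
                 base_pc = base_pc, base_pm = base_pm,
                 tournament_size = as.integer(tournament_size),
                 crossover_kind = crossover_kind,
                 mutation_kind = mutation_kind),
            class = "saga_params")
}

#' Population fitness summary feeding the adaptive probabilities
#'
#' @param f_max,f_min,f_avg population maximum, minimum and average
#'   fitness (maximization; `f_min <= f_avg <= f_max`).
#' @param f_b best fitness after crossover and mutation among selected
#'   learners (population-level, per generation).
#' @return a `fitness_summary` list.
#' @export
fitness_summary <- function(f_max, f_min, f_avg, f_b) {
  if (!(f_min <= f_avg && f_avg <= f_max))
    stop("need f_min <= f_avg <= f_max")
  structure(list(f_max = f_max, f_min = f_min, f_avg = f_avg, f_b = f_b),
            class = "fitness_summary")
}

#' Adaptive crossover probability
#'
#' Upper branch (`f_b >= f_avg`):
#' `Pc = [1 - c1 (f_max - f_b)/(f_max - f_avg)] - c2`, clamped to
#' `[0.01, 1]`; lower branch returns `c3` exactly. A degenerate population
#' (`f_max = f_avg`) also returns `c3`. The floor 0.01 prevents operator
#' extinction (the bracketed expression is unbounded below in the source
#' formulation).
#'
#' @param s a [fitness_summary()].
#' @param p a [saga_params()].
#' @return probability in `[0.01, 1]` (or exactly `c3`).
#' @export
adaptive_pc <- function(s, p = saga_params()) {
  if (s$f_b < s$f_avg) return(p$c3)
  if (s$f_max == s$f_avg) return(p$c3)
  pc <- (1 - p$c1 * (s$f_max - s$f_b) / (s$f_max - s$f_avg)) - p$c2
  min(max(pc, 0.01), 1)
}

#' Adaptive mutation probability
#'
#' Upper branch (`f_b >= f_avg`):
#' `Pm = [1 - c4 f_b / (f_max - f_min + f_avg)] - c5`, clamped to
#' `[0.001, 1]`; lower branch returns `c6` exactly; a zero denominator
#' returns `c6`.
#'
#' @inheritParams adaptive_pc
#' @return probability in `[0.001, 1]` (or exactly `c6`).
#' @export
adaptive_pm <- function(s, p = saga_params()) {
  if (s$f_b < s$f_avg) return(p$c6)
  den <- s$f_max - s$f_min + s$f_avg
  if (den == 0) return(p$c6)
  pm <- (1 - p$c4 * s$f_b / den) - p$c5
  min(max(pm, 0.001), 1)
}

#' Quantum crossover rate from a qubit amplitude
#'
#' The per-position crossover probability derived from the quantum
#' genotype: `beta[position]^2`, the probability of the selected state.
#'
#' @param q a [qubit_learner()].
#' @param position 1-based qubit index.
#' @return probability in `[0, 1]`.
#' @export
quantum_pc <- function(q, position) {
  stopifnot(inherits(q, "qubit_learner"),
            position >= 1, position <= length(q$beta))
  q$beta[position]^2
}

#' Quantum mutation rate from a state overlap
#'
#' `p_m = scale * arccos(overlap) / (pi/2)`, clamped to `[0, 1]`:
#' identical states (overlap 1) mutate at rate 0, orthogonal states
#' (overlap 0) at `scale`. Overlaps outside `[0, 1]` are clipped with a
#' warning.
#'
#' @param overlap_value per-qubit inner-product magnitude, see [overlap()].
#' @param scale maximum rate at orthogonality (default 1).
#' @return probability in `[0, 1]`.
#' @export
quantum_pm <- function(overlap_value, scale = 1) {
  if (overlap_value < 0 || overlap_value > 1) {
    warning("overlap outside [0, 1]; clipping")
    overlap_value <- min(max(overlap_value, 0), 1)
  }
  min(max(scale * acos(overlap_value) / (pi / 2), 0), 1)
}

#' Crossover of two binary learners
#'
#' With probability `pc` the masks are recombined by the chosen operator
#' (`one_point`, `two_point` or `uniform`; cut points / swap draws from
#' the global RNG) and the real `(C, sigma)` tails are blended by
#' arithmetic crossover with the same mixing draw; otherwise the parents
#' are copied. Empty offspring masks are repaired to the single position
#' with the highest parental agreement (lowest index on ties).
#'
#' @param parent_a,parent_b [binary_learner()] objects of equal length.
#' @param pc crossover probability.
#' @param kind `"uniform"`, `"one_point"` or `"two_point"`.
#' @return list of two offspring [binary_learner()]s.
#' @export
crossover <- function(parent_a, parent_b, pc,
                      kind = c("uniform", "one_point", "two_point")) {
  kind <- match.arg(kind)
  stopifnot(inherits(parent_a, "binary_learner"),
            inherits(parent_b, "binary_learner"))
  m <- length(parent_a$mask)
  if (length(parent_b$mask) != m) stop("masks must have equal length")
  a <- parent_a$mask; b <- parent_b$mask
  ca <- parent_a$c_value; cb <- parent_b$c_value
  sa <- parent_a$sigma_value; sb <- parent_b$sigma_value
  if (stats::runif(1) < pc) {
    if (kind == "one_point" && m > 1) {
      cut <- sample.int(m - 1L, 1L)
      idx <- seq_len(m) > cut
    } else if (kind == "two_point" && m > 2) {
      cuts <- sort(sample.int(m - 1L, 2L))
      idx <- seq_len(m) > cuts[1] & seq_len(m) <= cuts[2]
    } else {
      idx <- stats::runif(m) < 0.5
    }
    tmp <- a[idx]; a[idx] <- b[idx]; b[idx] <- tmp
    u <- stats::runif(1)  # arithmetic blend in log space, shared draw
    lg <- function(x, y, w) exp(w * log(x) + (1 - w) * log(y))
    ca2 <- lg(parent_a$c_value, parent_b$c_value, u)
    cb2 <- lg(parent_b$c_value, parent_a$c_value, u)
    sa2 <- lg(parent_a$sigma_value, parent_b$sigma_value, u)
    sb2 <- lg(parent_b$sigma_value, parent_a$sigma_value, u)
    ca <- ca2; cb <- cb2; sa <- sa2; sb <- sb2
  }
  repair <- function(mask) {
    if (sum(mask) == 0L) mask[which.max(parent_a$mask + parent_b$mask)] <- 1L
    mask
  }
  list(binary_learner(repair(a), ca, sa),
       binary_learner(repair(b), cb, sb))
}

#' Mutate a binary learner
#'
#' Each mask bit flips independently with probability `pm`; each real tail
#' value is, with the same probability, multiplied by a log-normal step
#' `exp(N(0, real_sigma))` and clipped to `bounds`. Empty masks are
#' repaired to a single uniformly chosen bit.
#'
#' @param learner a [binary_learner()].
#' @param pm per-position mutation probability in `[0, 1]`.
#' @param real_sigma standard deviation of the log-normal tail step.
#' @param bounds a [hyper_bounds()] for clipping the tail.
#' @return the mutated [binary_learner()].
#' @export
mutate <- function(learner, pm, real_sigma = 0.3, bounds = hyper_bounds()) {
  stopifnot(inherits(learner, "binary_learner"), pm >= 0, pm <= 1)
  mask <- learner$mask
  flip <- stats::runif(length(mask)) < pm
  mask[flip] <- 1L - mask[flip]
  if (sum(mask) == 0L) mask[sample.int(length(mask), 1L)] <- 1L
  cv <- learner$c_value
  sv <- learner$sigma_value
  if (stats::runif(1) < pm)
    cv <- min(max(cv * exp(stats::rnorm(1, 0, real_sigma)), bounds$c_min),
              bounds$c_max)
  if (stats::runif(1) < pm)
    sv <- min(max(sv * exp(stats::rnorm(1, 0, real_sigma)), bounds$sigma_min),
              bounds$sigma_max)
  binary_learner(mask, cv, sv)
}

#' Tournament selection of parent indices
#'
#' Draws `n_parents` independent tournaments whose contestants are
#' sampled without replacement; each returns the index with the best
#' (fitness, fewer-features, lower-index) key, so a tournament of the
#' whole population is deterministic. Elitism is enforced by the caller:
#' the incumbent best learner always survives unmodified.
#'
#' @param fitness numeric fitness vector (maximization).
#' @param n_parents number of indices to return (default
#'   `length(fitness)`).
#' @param tournament_size tournament size (>= 2).
#' @param n_selected optional feature counts for tie-breaking.
#' @return integer vector of parent indices.
#' @export
select_parents <- function(fitness, n_parents = length(fitness),
                           tournament_size = 3L, n_selected = NULL) {
  n <- length(fitness)
  if (n < 1) stop("population must be non-empty")
  tournament_size <- min(tournament_size, n)
  if (is.null(n_selected)) n_selected <- rep(0L, n)
  # goodness order for deterministic tie-breaks
  key <- rank_population(fitness, n_selected)  # higher = better
  # tournaments draw contestants without replacement, so a tournament of
  # the whole population deterministically returns the best learner
  vapply(seq_len(n_parents), function(i) {
    cand <- sample.int(n, tournament_size)
    cand[which.max(key[cand])]
  }, integer(1))
}
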