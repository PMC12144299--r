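#' Qubit learner: the quantum genotype
#'
#' A qubit learner encodes one candidate solution as `n_features` amplitude
#' pairs `(alpha_j, beta_j)` with `alpha_j^2 + beta_j^2 = 1`, plus a
#' real-coded tail holding the SVM penalty `C` and RBF width `sigma`
#' (the n + 2 encoding). `beta_j^2` is the probability that feature `j`
#' is selected when the learner is observed.
#'
#' @param alpha,beta numeric vectors of equal length; per-position
#'   amplitudes, normalized so `alpha^2 + beta^2 = 1` within `1e-9`.
#' @param c_value positive SVM penalty.
#' @param sigma_value positive RBF width.
#' @return an object of class `qubit_learner`.
#' @export
qubit_learner <- function(alpha, beta, c_value, sigma_value) {
  stopifnot(length(alpha) == length(beta), length(alpha) >= 1L)
  if (any(abs(alpha^2 + beta^2 - 1) > 1e-9))
    stop("amplitudes must satisfy alpha^2 + beta^2 = 1 within 1e-9")
  if (!is.finite(c_value) || c_value <= 0)
    stop("c_value must be a positive real")
  if (!is.finite(sigma_value) || sigma_value <= 0)
    stop("sigma_value must be a positive real")
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         c_value = as.numeric(c_value), sigma_value = as.numeric(sigma_value)),
    class = "qubit_learner")
}

#' Binary learner: the observed phenotype
#'
#' The classical solution evaluated by the wrapper: a feature mask (1 =
#' selected) plus the decoded `(C, sigma)` pair. At least one bit must be
#' set; [observe()] repairs empty masks deterministically.
#'
#' @param mask integer/logical vector of 0/1.
#' @param c_value,sigma_value positive reals.
#' @return an object of class `binary_learner`.
#' @export
binary_learner <- function(mask, c_value, sigma_value) {
  mask <- as.integer(mask)
  stopifnot(length(mask) >= 1L, all(mask %in% c(0L, 1L)))
  if (sum(mask) < 1L) stop("mask must have at least one bit set")
  if (!is.finite(c_value) || c_value <= 0) stop("c_value must be positive")
  if (!is.finite(sigma_value) || sigma_value <= 0)
    stop("sigma_value must be positive")
  structure(list(mask = mask, c_value = as.numeric(c_value),
                 sigma_value = as.numeric(sigma_value)),
            class = "binary_learner")
}

#' Hyperparameter bounds for the real-coded tail
#'
#' @param c_min,c_max bounds for the SVM penalty C.
#' @param sigma_min,sigma_max bounds for the RBF width sigma.
#' @return a `hyper_bounds` list.
#' @export
hyper_bounds <- function(c_min = 0.01, c_max = 100,
                         sigma_min = 0.01, sigma_max = 10) {
  # equal bounds pin a hyperparameter (pure feature-subset search)
  stopifnot(c_min > 0, c_max >= c_min, sigma_min > 0, sigma_max >= sigma_min)
  structure(list(c_min = c_min, c_max = c_max,
                 sigma_min = sigma_min, sigma_max = sigma_max),
            class = "hyper_bounds")
}

#' Rotation policy for the quantum movement
#'
#' The paper's rotation-direction table is not printed; the policy here is
#' the classical lookup for qubit-encoded EAs: no rotation where the
#' current and guiding bits agree or where the current learner is fitter;
#' otherwise a step of magnitude `theta_step` signed so that `beta^2`
#' moves toward the guiding learner's bit.
#'
#' @param theta_step rotation magnitude in radians (default `0.01 * pi`).
#' @param rotate_when_current_better if `TRUE`, also rotate (toward the
#'   current learner's own bit) when the current learner is fitter;
#'   default `FALSE`, the classical table.
#' @return a `rotation_policy` list.
#' @export
rotation_policy <- function(theta_step = 0.01 * pi,
                            rotate_when_current_better = FALSE) {
  stopifnot(is.finite(theta_step), theta_step >= 0)
  structure(list(theta_step = theta_step,
                 rotate_when_current_better = rotate_when_current_better),
            class = "rotation_policy")
}

#' Initialize a quantum population
#'
#' Every amplitude pair starts in the equal superposition
#' `(1/sqrt(2), 1/sqrt(2))`, so each feature is selected with probability
#' 1/2 on first observation. The `(C, sigma)` tail is drawn log-uniformly
#' inside `bounds` (C and sigma span orders of magnitude). Uses R's global
#' RNG; seed with [set.seed()] for reproducibility.
#'
#' @param n_learners population size (>= 2).
#' @param n_features number of features (>= 1).
#' @param bounds a [hyper_bounds()] object.
#' @return list of [qubit_learner()] objects.
#' @export
init_population <- function(n_learners, n_features, bounds = hyper_bounds()) {
  if (!is.numeric(n_learners) || n_learners < 2)
    stop("n_learners must be >= 2")
  if (!is.numeric(n_features) || n_features < 1)
    stop("n_features must be >= 1")
  amp <- rep(1 / sqrt(2), n_features)
  lapply(seq_len(n_learners), function(i) {
    cv <- exp(stats::runif(1, log(bounds$c_min), log(bounds$c_max)))
    sv <- exp(stats::runif(1, log(bounds$sigma_min), log(bounds$sigma_max)))
    qubit_learner(amp, amp, cv, sv)
  })
}

#' Observe (collapse) a qubit learner into a binary learner
#'
#' Each bit is 1 independently with probability `beta_j^2` (a uniform draw
#' `u_j < beta_j^2`). An all-zero mask is repaired deterministically by
#' setting the single bit with maximal `beta^2` (ties broken toward the
#' lowest index), since the wrapper needs at least one feature.
#'
#' @param q a [qubit_learner()].
#' @return a [binary_learner()] with the qubit's `(C, sigma)` copied through.
#' @export
observe <- function(q) {
  stopifnot(inherits(q, "qubit_learner"))
  p1 <- q$beta^2
  mask <- as.integer(stats::runif(length(p1)) < p1)
  if (sum(mask) == 0L) mask[which.max(p1)] <- 1L
  binary_learner(mask, q$c_value, q$sigma_value)
}

#' Apply the rotation gate to a qubit learner
#'
#' Per position, `(alpha', beta') = (alpha cos(dt) - beta sin(dt),
#' alpha sin(dt) + beta cos(dt))`; the gate is orthogonal so normalization
#' is preserved exactly.
#'
#' @param q a [qubit_learner()].
#' @param delta_theta signed rotation angles in radians, one per position.
#' @return the rotated [qubit_learner()].
#' @export
rotate <- function(q, delta_theta) {
  stopifnot(inherits(q, "qubit_learner"))
  if (length(delta_theta) != length(q$alpha))
    stop("delta_theta length must match the number of qubits")
  if (any(!is.finite(delta_theta))) stop("delta_theta must be finite")
  ct <- cos(delta_theta); st <- sin(delta_theta)
  a <- q$alpha * ct - q$beta * st
  b <- q$alpha * st + q$beta * ct
  qubit_learner(a, b, q$c_value, q$sigma_value)
}

#' Rotation angles steering a qubit toward a guiding binary learner
#'
#' Positions where the two masks agree get zero rotation (XOR guidance:
#' only disagreement positions move). Where they disagree and the current
#' learner is not fitter, the angle has magnitude `policy$theta_step`,
#' signed so `beta^2` moves toward the guiding bit's state; the sign
#' accounts for the quadrant via `sign(alpha * beta)` (since
#' `d(beta^2)/d(theta) = 2 alpha beta`).
#'
#' @param current,best [binary_learner()] masks of equal length.
#' @param current_fitness,best_fitness fitness values (maximization).
#' @param policy a [rotation_policy()].
#' @param q the current [qubit_learner()] (for quadrant-aware signs);
#'   if `NULL`, amplitudes are assumed non-negative.
#' @return numeric vector of signed angles in radians.
#' @export
rotation_angles <- function(current, best, current_fitness, best_fitness,
                            policy = rotation_policy(), q = NULL) {
  stopifnot(inherits(current, "binary_learner"),
            inherits(best, "binary_learner"))
  m <- length(current$mask)
  if (length(best$mask) != m) stop("masks must have equal length")
  dt <- numeric(m)
  disagree <- entangle_xor(current, best) == 1L
  current_worse <- !isTRUE(current_fitness > best_fitness)
  if (!current_worse && !policy$rotate_when_current_better) return(dt)
  target <- if (current_worse) best$mask else current$mask
  # +1 steers beta^2 up (toward bit 1), -1 down, in the first quadrant
  dir <- ifelse(target == 1L, 1, -1)
  if (!is.null(q)) {
    s <- sign(q$alpha * q$beta)
    s[s == 0] <- 1
    dir <- dir * s
  }
  dt[disagree] <- policy$theta_step * dir[disagree]
  dt
}

#' Normalized Hamming-distance ratio between two binary learners
#'
#' `d = delta / (2m - sum(B1) - sum(B2))` where `delta` counts differing
#' bits and `m` is the mask length: the Hamming distance relative to the
#' number of unselected slots in the two solutions. Identical masks give 0;
#' identical all-ones masks give 0 by convention (the 0/0 form).
#'
#' @param b1,b2 [binary_learner()] objects (or plain 0/1 vectors) with
#'   equal-length masks.
#' @return non-negative real; symmetric in its arguments.
#' @export
distance_ratio <- function(b1, b2) {
  m1 <- if (inherits(b1, "binary_learner")) b1$mask else as.integer(b1)
  m2 <- if (inherits(b2, "binary_learner")) b2$mask else as.integer(b2)
  m <- length(m1)
  if (length(m2) != m) stop("masks must have equal length")
  stopifnot(all(m1 %in% 0:1), all(m2 %in% 0:1))
  delta <- sum(m1 != m2)
  if (delta == 0L) return(0)
  delta / (2 * m - sum(m1) - sum(m2))
}

#' Mean per-qubit overlap of two quantum states
#'
#' Mean over positions of `|alpha_p alpha_q + beta_p beta_q|`, the
#' magnitude of the per-qubit inner product; 1 for identical states,
#' 0 for orthogonal ones. Drives the quantum mutation rate
#' ([quantum_pm()]).
#'
#' @param p,q [qubit_learner()] objects with equal length.
#' @return real in `[0, 1]`.
#' @export
overlap <- function(p, q) {
  stopifnot(inherits(p, "qubit_learner"), inherits(q, "qubit_learner"))
  if (length(p$alpha) != length(q$alpha)) stop("lengths must match")
  # per-qubit |<psi_p|psi_q>| is <= 1 for unit states; clamp rounding error
  min(mean(pmin(abs(p$alpha * q$alpha + p$beta * q$beta), 1)), 1)
}

#' Position-wise XOR of two binary learners' masks
#'
#' The disagreement indicator used to gate guided rotation: a 1 marks a
#' position where teacher and learner differ.
#'
#' @param teacher_bits,learner_bits [binary_learner()] objects (or plain
#'   0/1 vectors) of equal length.
#' @return integer 0/1 vector.
#' @export
entangle_xor <- function(teacher_bits, learner_bits) {
  a <- if (inherits(teacher_bits, "binary_learner")) teacher_bits$mask
       else as.integer(teacher_bits)
  b <- if (inherits(learner_bits, "binary_learner")) learner_bits$mask
       else as.integer(learner_bits)
  if (length(a) != length(b)) stop("lengths must match")
  as.integer(xor(a == 1L, b == 1L))
}

#' @export
print.qubit_learner <- function(x, ...) {
  cat(sprintf("<qubit_learner> %d qubits, C = %.4g, sigma = %.4g\n",
              length(x$alpha), x$c_value, x$sigma_value))
  invisible(x)
}

#' @export
print.binary_learner <- function(x, ...) {
  cat(sprintf("<binary_learner> %d/%d features, C = %.4g, sigma = %.4g\n",
              sum(x$mask), length(x$mask), x$c_value, x$sigma_value))
  invisible(x)
}
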