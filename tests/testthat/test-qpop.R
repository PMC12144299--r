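test_that("init_population starts in equal superposition with in-bounds tails", {
  set.seed(1)
  b <- hyper_bounds(0.1, 50, 0.05, 5)
  pop <- init_population(30, 9, b)
  expect_length(pop, 30)
  for (q in pop) {
    expect_equal(q$beta^2, rep(0.5, 9), tolerance = 1e-12)
    expect_true(q$c_value >= b$c_min && q$c_value <= b$c_max)
    expect_true(q$sigma_value >= b$sigma_min && q$sigma_value <= b$sigma_max)
  }
  tiny <- init_population(2, 1, b)
  expect_equal(tiny[[1]]$alpha, 1 / sqrt(2), tolerance = 1e-15)
  expect_equal(tiny[[1]]$beta, 1 / sqrt(2), tolerance = 1e-15)
  pop5 <- init_population(5, 4, b)
  for (q in pop5) expect_equal(q$alpha^2 + q$beta^2, rep(1, 4),
                               tolerance = 1e-12)
  expect_error(init_population(1, 4), "n_learners")
  expect_error(init_population(5, 0), "n_features")
})

test_that("observation follows beta^2 with deterministic empty-mask repair", {
  set.seed(2)
  all1 <- observe(q_beta(rep(1, 5)))
  expect_equal(all1$mask, rep(1L, 5))
  # beta = 0 everywhere: forced repair to exactly one bit (lowest index)
  none <- observe(q_beta(rep(0, 5)))
  expect_equal(sum(none$mask), 1L)
  expect_equal(none$mask[1], 1L)
  # tails copied through
  q <- q_equal(3, cv = 7.5, sv = 0.2)
  ob <- observe(q)
  expect_equal(ob$c_value, 7.5)
  expect_equal(ob$sigma_value, 0.2)
  # empirical collapse frequency of a fair qubit; a beta = 1 companion
  # qubit keeps the mask non-empty so repair never biases the draw
  set.seed(3)
  q1 <- q_beta(c(sqrt(0.5), 1))
  freq <- mean(replicate(20000, observe(q1)$mask[1]))
  expect_gt(freq, 0.48)
  expect_lt(freq, 0.52)
})

test_that("rotation gate matches the hand-worked matrix and preserves norm", {
  q <- q_equal(3)
  expect_equal(rotate(q, rep(0, 3)), q)
  r <- rotate(q_equal(1), pi / 4)
  expect_equal(r$alpha, 0, tolerance = 1e-12)
  expect_equal(r$beta, 1, tolerance = 1e-12)
  # inverse rotation restores the state
  set.seed(4)
  dt <- runif(3, -pi, pi)
  q2 <- rotate(rotate(q, dt), -dt)
  expect_equal(q2$alpha, q$alpha, tolerance = 1e-12)
  expect_equal(q2$beta, q$beta, tolerance = 1e-12)
  # norm conservation under long random rotation chains
  set.seed(5)
  qq <- q_equal(4)
  worst <- 0
  for (i in 1:500) {
    qq <- rotate(qq, runif(4, -0.1, 0.1))
    worst <- max(worst, max(abs(qq$alpha^2 + qq$beta^2 - 1)))
  }
  expect_lt(worst, 1e-9)
  expect_error(rotate(q, c(0, 0)), "length")
})

test_that("rotation angles move beta^2 toward the guiding bit", {
  pol <- rotation_policy(0.01 * pi)
  b1 <- binary_learner(c(1, 0, 1, 1), 2, 1)
  expect_equal(rotation_angles(b1, b1, 0.5, 0.9, pol), rep(0, 4))
  # current bit 0, best bit 1, current worse: +step, beta^2 grows
  cur <- binary_learner(c(0, 1), 2, 1)
  best <- binary_learner(c(1, 1), 2, 1)
  q <- q_equal(2)
  dt <- rotation_angles(cur, best, 0.4, 0.9, pol, q)
  expect_equal(dt, c(0.01 * pi, 0))
  q2 <- rotate(q, dt)
  expect_gt(q2$beta[1]^2, 0.5)
  # current fitter than the guide: no movement under the default policy
  expect_equal(rotation_angles(cur, best, 0.95, 0.9, pol, q), rep(0, 2))
  # guiding toward bit 0 shrinks beta^2
  dt0 <- rotation_angles(best, cur, 0.4, 0.9, pol, q)
  expect_equal(dt0, c(-0.01 * pi, 0))
  expect_lt(rotate(q, dt0)$beta[1]^2, 0.5)
  # magnitudes never exceed the step
  expect_true(all(abs(dt) <= pol$theta_step + 1e-15))
})

test_that("distance_ratio matches the printed formula and its properties", {
  expect_identical(distance_ratio(c(1, 0, 1, 1), c(1, 0, 1, 1)), 0)
  expect_equal(distance_ratio(c(1, 0, 1), c(0, 1, 1)), 1.0)
  expect_equal(distance_ratio(c(1, 0, 0), c(0, 0, 0)), 0.2)
  # all-ones pair: 0/0 form defined as 0
  expect_identical(distance_ratio(c(1, 1, 1), c(1, 1, 1)), 0)
  # symmetry, non-negativity, XOR popcount = numerator
  set.seed(6)
  for (i in 1:50) {
    a <- rbinom(6, 1, 0.5); b <- rbinom(6, 1, 0.5)
    expect_equal(distance_ratio(a, b), distance_ratio(b, a))
    expect_gte(distance_ratio(a, b), 0)
    expect_identical(distance_ratio(a, b) == 0, all(a == b))
    denom <- 2 * 6 - sum(a) - sum(b)
    if (denom > 0)
      expect_equal(distance_ratio(a, b) * denom, sum(entangle_xor(a, b)))
  }
})

test_that("overlap is the mean per-qubit inner-product magnitude", {
  p <- q_equal(3)
  expect_equal(overlap(p, p), 1.0)
  zero <- qubit_learner(rep(1, 3), rep(0, 3), 2, 1)
  one <- qubit_learner(rep(0, 3), rep(1, 3), 2, 1)
  expect_equal(overlap(zero, one), 0.0)
  expect_equal(overlap(q_equal(3), zero), 1 / sqrt(2), tolerance = 1e-9)
})

test_that("entangle_xor is position-wise XOR", {
  x <- binary_learner(c(1, 1, 0, 0), 2, 1)
  expect_equal(entangle_xor(x, x), rep(0L, 4))
  expect_equal(entangle_xor(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               c(0L, 1L, 1L, 0L))
})

test_that("constructors validate their invariants", {
  expect_error(qubit_learner(c(1, 1), c(1, 0), 2, 1), "alpha")
  expect_error(qubit_learner(0.6, 0.8, -1, 1), "c_value")
  expect_error(binary_learner(c(0, 0, 0), 2, 1), "at least one")
  expect_error(binary_learner(c(1, 2), 2, 1))
  expect_silent(binary_learner(c(0, 1), 2, 1))
})
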