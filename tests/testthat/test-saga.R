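test_that("adaptive crossover probability follows the two-branch rule", {
  p <- saga_params(c1 = 0.5, c2 = 0, c3 = 0.7)
  # lower branch: f_b < f_avg returns c3 exactly
  s_low <- fitness_summary(1, 0.2, 0.6, 0.5)
  expect_identical(adaptive_pc(s_low, p), 0.7)
  # f_b = f_max: bracket becomes 1, Pc = 1 - c2
  s_top <- fitness_summary(1, 0.2, 0.6, 1)
  expect_equal(adaptive_pc(s_top, p), 1.0)
  # degenerate population guard
  s_deg <- fitness_summary(0.6, 0.6, 0.6, 0.6)
  expect_identical(adaptive_pc(s_deg, p), 0.7)
})

test_that("adaptive mutation probability follows the two-branch rule", {
  p <- saga_params(c4 = 0.5, c5 = 0, c6 = 0.4)
  s_low <- fitness_summary(1, 0.2, 0.6, 0.5)
  expect_identical(adaptive_pm(s_low, p), 0.4)
  # hand-worked upper branch: 1 - 0.5 * 0.9 / (1 - 0.5 + 0.8)
  s <- fitness_summary(1, 0.5, 0.8, 0.9)
  expect_equal(adaptive_pm(s, p), 1 - 0.5 * 0.9 / 1.3, tolerance = 1e-12)
  expect_equal(adaptive_pm(s, p), 0.65385, tolerance = 1e-5)
  # degenerate guard (zero denominator)
  s_deg <- fitness_summary(0, 0, 0, 0)
  expect_identical(adaptive_pm(s_deg, p), 0.4)
})

test_that("adaptive probabilities stay in [0, 1] over random ordered summaries", {
  set.seed(21)
  for (i in 1:200) {
    v <- sort(runif(3))
    s <- fitness_summary(v[3], v[1], v[2], runif(1))
    cs <- runif(6)
    p <- saga_params(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    expect_true(adaptive_pc(s, p) >= 0 && adaptive_pc(s, p) <= 1)
    expect_true(adaptive_pm(s, p) >= 0 && adaptive_pm(s, p) <= 1)
  }
  # with c1 = c2 = c4 = c5 = 0 the upper branches are the constant 1
  p0 <- saga_params(0, 0, 0.7, 0, 0, 0.4)
  s_up <- fitness_summary(1, 0.1, 0.5, 0.8)
  expect_identical(adaptive_pc(s_up, p0), 1)
  expect_identical(adaptive_pm(s_up, p0), 1)
})

test_that("quantum operator rates derive from amplitudes and overlaps", {
  expect_equal(quantum_pc(q_beta(c(1, 0.6)), 1), 1.0)
  expect_equal(quantum_pc(q_equal(2), 1), 0.5, tolerance = 1e-12)
  expect_equal(quantum_pc(q_beta(c(1, 0.6)), 2), 0.36, tolerance = 1e-12)
  expect_equal(quantum_pm(1), 0)
  expect_equal(quantum_pm(0, scale = 1), 1.0)
  expect_equal(quantum_pm(1 / sqrt(2), scale = 1), 0.5, tolerance = 1e-9)
  expect_warning(quantum_pm(1.5), "clipping")
  # identical states never mutate via the quantum rate (up to the
  # floating-point noise that acos amplifies near overlap 1)
  set.seed(22)
  for (i in 1:20) {
    q <- rotate(q_equal(3), runif(3, -1, 1))
    expect_lt(quantum_pm(overlap(q, q)), 1e-6)
  }
})

test_that("crossover recombines masks and blends tails", {
  a <- binary_learner(c(1, 1, 0, 0), 4, 0.5)
  b <- binary_learner(c(0, 0, 1, 1), 1, 2)
  # pc = 0: exact copies
  set.seed(23)
  off0 <- crossover(a, b, pc = 0)
  expect_equal(off0[[1]]$mask, a$mask)
  expect_equal(off0[[2]]$mask, b$mask)
  expect_equal(off0[[1]]$c_value, 4)
  # one-point at cut 2 on 1100 x 0011: 1111 and repaired 0000
  set.seed(3)  # this seed draws cut = 2 after the pc gate
  off <- crossover(a, b, pc = 1, kind = "one_point")
  expect_equal(off[[1]]$mask, c(1L, 1L, 1L, 1L))
  expect_equal(sum(off[[2]]$mask), 1L)  # repaired from empty
  # per-position allele multiset conserved by splicing operators
  set.seed(24)
  for (kind in c("one_point", "two_point")) {
    for (i in 1:25) {
      pa <- binary_learner(pmax(rbinom(6, 1, 0.5), 0) | c(1, rep(0, 5)), 2, 1)
      pb <- binary_learner(pmax(rbinom(6, 1, 0.5), 0) | c(1, rep(0, 5)), 2, 1)
      off <- crossover(pa, pb, pc = 1, kind = kind)
      # repair can only add a bit to an empty mask; skip those cases
      if (sum(off[[1]]$mask) + sum(off[[2]]$mask) ==
          sum(pa$mask) + sum(pb$mask))
        expect_equal(off[[1]]$mask + off[[2]]$mask, pa$mask + pb$mask)
    }
  }
})

test_that("mutation flips bits at the stated rate and clips tails", {
  l <- binary_learner(c(1, 0, 1, 0), 2, 1)
  set.seed(25)
  expect_equal(mutate(l, pm = 0), l)
  m1 <- mutate(l, pm = 1)
  expect_equal(m1$mask, c(0L, 1L, 0L, 1L))
  # expected flips per learner: 10 bits at pm = 0.1 -> 1.0 +/- 0.03
  set.seed(26)
  base <- binary_learner(rep(1L, 10), 2, 1)
  flips <- replicate(2e4, sum(mutate(base, pm = 0.1)$mask != base$mask))
  expect_equal(mean(flips), 1.0, tolerance = 0.03)
  # tails stay inside bounds under heavy mutation
  set.seed(27)
  b <- hyper_bounds(0.5, 4, 0.2, 2)
  l2 <- binary_learner(c(1, 1), 1, 1)
  for (i in 1:50) {
    l2 <- mutate(l2, pm = 1, real_sigma = 2, bounds = b)
    expect_true(l2$c_value >= 0.5 && l2$c_value <= 4)
    expect_true(l2$sigma_value >= 0.2 && l2$sigma_value <= 2)
  }
})

test_that("tournament selection prefers the fit with exact tie-breaking", {
  f <- c(0.2, 0.9, 0.4, 0.6)
  set.seed(28)
  # tournament of population size always returns the best index
  idx <- select_parents(f, n_parents = 50, tournament_size = 4)
  expect_true(all(idx == 2L))
  # uniform fitness: index i wins iff it is the minimum of its
  # tournament (tie-break order); without-replacement draws give
  # P(i) = choose(n - i, t - 1) / choose(n, t)
  set.seed(29)
  n <- 5; t_size <- 3
  draws <- select_parents(rep(0.5, n), n_parents = 4e4,
                          tournament_size = t_size)
  emp <- tabulate(draws, n) / 4e4
  theo <- choose(n - 1:n, t_size - 1) / choose(n, t_size)
  expect_equal(emp, theo, tolerance = 0.02)
  expect_error(select_parents(numeric(0)), "non-empty")
})
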