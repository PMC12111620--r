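test_that("feature vectors expose the reference transition probabilities", {
  m3 <- fixture_machine_3state()
  expect_equal(state_feature_vector(m3, "troll"), c(0.24, 0.76))
  expect_equal(state_feature_vector(fair_coin_machine(), "s"), c(0.5, 0.5))
  t2 <- fixture_transducer_2state()
  expect_equal(state_feature_vector(t2, "troll"), c(0.71, 0.29, 0.28, 0.72))
  expect_equal(state_feature_vector(t2, "non-troll"),
               c(0.72, 0.28, 0.52, 0.48))
})

test_that("unobserved emission cells are imputed at 0.5 and flagged", {
  em <- data.frame(state = "s", input = 0L, output = c(0L, 1L),
                   prob = c(0.4, 0.6))
  tr <- data.frame(state = "s", input = 0L, output = c(0L, 1L), to = "s")
  partial <- epsilon_transducer(em, tr)
  v <- state_feature_vector(partial, "s")
  expect_equal(as.numeric(v), c(0.4, 0.6, 0.5, 0.5))
  expect_true(attr(v, "imputed"))
})

test_that("the assignment solver is exact against exhaustive search", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:4, 1)
    cm <- matrix(stats::runif(n * n), n)
    sol <- hungarian_solve(cm)
    expect_equal(sol$cost, exhaustive_assignment_cost(cm),
                 tolerance = 1e-12)
    expect_true(all(sort(sol$assignment) == seq_len(n)))
  }
})

test_that("alignment finds identity, swaps, and role matches under jitter", {
  m3 <- fixture_machine_3state()
  self <- align_states(m3, m3)
  expect_equal(unname(self$permutation), m3$states)
  expect_equal(self$cost, 0)

  # reference with states relabeled in reverse: the swap is recovered
  relab <- c("non-troll" = "c", "transition" = "b", "troll" = "a")
  tr <- m3$transitions
  tr$from <- unname(relab[tr$from])
  tr$to <- unname(relab[tr$to])
  rev3 <- epsilon_machine(tr, states = c("a", "b", "c"))
  al <- align_states(m3, rev3)
  expect_equal(al$cost, 0)
  expect_equal(al$permutation[["troll"]], "a")
  expect_equal(al$permutation[["non-troll"]], "c")

  set.seed(1)
  j1 <- epsimech:::jitter_machine(m3, 0.02)
  set.seed(2)
  j2 <- epsimech:::jitter_machine(m3, 0.02)
  alj <- align_states(j1, j2)
  expect_equal(unname(alj$permutation), j1$states)  # roles preserved
  expect_lt(alj$cost, 0.2)
  # oracle: no permutation beats the solver
  expect_equal(alj$cost, exhaustive_assignment_cost(alj$cost_matrix),
               tolerance = 1e-12)
  expect_error(align_states(m3, fixture_machine_2state()),
               "state counts differ")
})

test_that("averaging one model or identical copies is the identity", {
  m3 <- fixture_machine_3state()
  a1 <- average_models(list(m3))
  expect_equal(a1$transitions[order(a1$transitions$from,
                                    a1$transitions$symbol), ]$prob,
               m3$transitions[order(m3$transitions$from,
                                    m3$transitions$symbol), ]$prob)
  a2 <- average_models(list(m3, m3, m3))
  for (s in m3$states) {
    expect_equal(transition_prob(a2, s, 1), transition_prob(m3, s, 1))
  }
  expect_false(a2$meta$structural_summary)
  expect_error(average_models(list()), "empty")
})

test_that("the average of jittered models matches the direct mean", {
  set.seed(7)
  models <- lapply(1:20, function(i) {
    epsimech:::jitter_machine(fixture_machine_3state(), 0.02)
  })
  avg <- average_models(models)
  direct <- mean(vapply(models, function(m) {
    transition_prob(m, "troll", 1)
  }, 1))
  expect_equal(transition_prob(avg, "troll", 1), direct, tolerance = 1e-9)
  expect_lt(abs(transition_prob(avg, "troll", 1) - 0.76), 0.02)
  # averaged rows are stochastic
  for (s in avg$states) {
    expect_equal(sum(avg$transitions$prob[avg$transitions$from == s]), 1,
                 tolerance = 1e-9)
  }
})

test_that("averaging is invariant to the order of the input list", {
  set.seed(11)
  models <- lapply(1:10, function(i) {
    epsimech:::jitter_machine(fixture_machine_3state(), 0.05)
  })
  avg1 <- average_models(models, reference_index = 1)
  shuffled <- c(models[1], models[c(6:10, 2:5)])
  avg2 <- average_models(shuffled, reference_index = 1)
  for (s in avg1$states) {
    for (a in 0:1) {
      expect_lt(abs(transition_prob(avg1, s, a) -
                      transition_prob(avg2, s, a)), 1e-12)
    }
  }
})

test_that("transducer averaging aligns input-conditional roles", {
  set.seed(13)
  models <- lapply(1:15, function(i) {
    epsimech:::jitter_transducer(fixture_transducer_2state(), 0.02)
  })
  avg <- average_models(models)
  expect_identical(validate_transducer(avg), character(0))
  direct <- mean(vapply(models, function(t) {
    emission_prob(t, "troll", 1, 1)
  }, 1))
  expect_equal(emission_prob(avg, "troll", 1, 1), direct, tolerance = 1e-9)
  expect_lt(abs(emission_prob(avg, "troll", 1, 1) - 0.72), 0.02)
})
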