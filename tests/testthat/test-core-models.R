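test_that("sequence constructors enforce the binary alphabet and alignment", {
  expect_error(binary_sequence(integer(0)), "at least one")
  expect_error(binary_sequence(c(0, 2, 1)), "position 2")
  expect_error(io_pair(c(0, 1), c(0, 1, 1)), "equal length")
  s <- binary_sequence(c(0, 1, 1))
  expect_equal(length(s), 3L)
})

test_that("validate_machine flags each invariant violation by name", {
  expect_identical(validate_machine(fair_coin_machine()), character(0))
  bad_rows <- epsilon_machine(data.frame(from = "s", symbol = c(0L, 1L),
                                         prob = c(0.6, 0.6), to = "s"))
  v <- validate_machine(bad_rows)
  expect_length(v, 1)
  expect_match(v, "row sum")
  dup <- epsilon_machine(data.frame(from = c("A", "A", "A"),
                                    symbol = c(1L, 1L, 0L),
                                    prob = c(0.25, 0.25, 0.5),
                                    to = c("A", "A", "A")))
  expect_true(any(grepl("unifilarity", validate_machine(dup))))
})

test_that("stationary distribution solves pi P = pi and zeroes transients", {
  expect_equal(stationary_distribution(fair_coin_machine()),
               c(s = 1))
  expect_equal(stationary_distribution(period2_machine()),
               c(A = 0.5, B = 0.5))
  m3 <- fixture_machine_3state()
  pi_hat <- stationary_distribution(m3)
  pi_oracle <- stationary_by_power_iteration(m3)
  expect_equal(unname(pi_hat[m3$states]), unname(pi_oracle[m3$states]),
               tolerance = 1e-10)
  expect_equal(unname(pi_hat[c("non-troll", "transition", "troll")]),
               c(0.5435, 0.1739, 0.2826), tolerance = 1e-4)
  # fixed-point property
  P <- matrix(0, 3, 3, dimnames = list(m3$states, m3$states))
  for (i in seq_len(nrow(m3$transitions))) {
    tr <- m3$transitions[i, ]
    P[tr$from, tr$to] <- P[tr$from, tr$to] + tr$prob
  }
  expect_lt(max(abs(as.numeric(pi_hat %*% P) - pi_hat)), 1e-9)
})

test_that("stationary distribution reports reducible recurrent parts", {
  split_m <- epsilon_machine(data.frame(
    from = c("A", "B"), symbol = c(0L, 1L), prob = c(1, 1),
    to = c("A", "B")),
    recurrent = c(A = TRUE, B = TRUE))
  expect_error(stationary_distribution(split_m), "reducible")
})

test_that("state filtering synchronizes and labels the walked states", {
  f <- filter_states(fair_coin_machine(), c(0, 1, 1, 0))
  expect_equal(f$sync, 1L)
  expect_false(any(f$desync))
  # the first symbol of the alternating process reveals the state
  f2 <- filter_states(period2_machine(), c(0, 1, 0, 1))
  expect_equal(f2$sync, 2L)
  expect_equal(f2$pre_state[2:4], c("A", "B", "A"))
  # walking 0,1,1 through the three-state model visits the three roles
  f3 <- filter_states(fixture_machine_3state(), c(0, 1, 1))
  expect_equal(f3$post_state, c("non-troll", "transition", "troll"))
})

test_that("filtering flags impossible observations and restarts", {
  f <- filter_states(period2_machine(), c(0, 0, 1, 0))
  expect_true(f$desync[2])
  expect_equal(f$pre_state[4], "B")
})

test_that("log loss matches closed forms on known processes", {
  set.seed(41)
  x <- binary_sequence(rbinom(1000, 1, 0.5))
  expect_equal(sequence_log_loss(fair_coin_machine(), x)$bits_per_symbol, 1)
  alt <- binary_sequence(rep(c(0, 1), 500))
  expect_equal(sequence_log_loss(period2_machine(), alt)$bits_per_symbol, 0)
  # biased coin scored by its own model converges to the binary entropy
  xb <- simulate_machine(biased_coin_machine(0.7), 1e5, seed = 7)
  ll <- sequence_log_loss(biased_coin_machine(0.7), xb)
  expect_equal(ll$bits_per_symbol, binary_entropy(0.7), tolerance = 0.01)
  expect_equal(ll$n_scored, 1e5)
})

test_that("the generating machine beats the memoryless fit on its own data", {
  m3 <- fixture_machine_3state()
  wins <- 0L
  for (seed in 1:20) {
    x <- simulate_machine(m3, 1e5, seed = 1000 + seed)
    iid <- biased_coin_machine(mean(x$symbols))
    l_true <- sequence_log_loss(m3, x)$bits_per_symbol
    l_iid <- sequence_log_loss(iid, x)$bits_per_symbol
    if (l_true <= l_iid) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("simulation reproduces the generator's conditional frequencies", {
  # alternating process is reproduced exactly
  alt <- simulate_machine(period2_machine(), 1000, seed = 5)
  expect_true(all(abs(diff(alt$symbols)) == 1))
  x <- simulate_machine(fair_coin_machine(), 1e5, seed = 9)
  expect_lt(abs(mean(x$symbols) - (0.5)), 0.01)
  # troll-state persistence: P(1 | two preceding 1s) in a long stream
  x3 <- simulate_machine(fixture_machine_3state(), 2e5, seed = 11)$symbols
  n <- length(x3)
  idx <- which(x3[1:(n - 2)] == 1 & x3[2:(n - 1)] == 1) + 2L
  expect_lt(abs(mean(x3[idx]) - (0.76)), 0.01)
})

test_that("simulated conditional frequencies tighten as n grows", {
  m <- fixture_machine_2state()
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    x <- simulate_machine(m, n, seed = round(n))$symbols
    idx <- which(x[-length(x)] == 1) + 1L
    abs(mean(x[idx]) - 0.67)
  }, 1)
  expect_lt(err[3], 0.02)
  expect_lt(err[3], err[1])
})
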