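test_that("joint counts match hand counts and the window-scan oracle", {
  pair <- io_pair(c(0, 1, 0, 1), c(1, 0, 0, 1))
  # joint codes: 2*y + x = 1, 2, 0, 3
  counts <- count_joint_histories(pair, 1)
  expect_equal(sum(counts$tab[[1]]), 4)
  expect_equal(unname(counts$tab[[1]][["1"]]), 1)
  expect_equal(unname(counts$tab[[2]][["12"]]), 1)
  nc <- epsimech:::joint_next_counts(counts, "1")
  expect_equal(unname(nc["1", "0"]), 1)  # after (0,1): next (1,0)
  expect_equal(sum(nc), 1)

  set.seed(3)
  pr <- io_pair(rbinom(1e4, 1, 0.5), rbinom(1e4, 1, 0.4))
  cr <- count_joint_histories(pr, 2)
  expect_equal(sum(cr$tab[[1]]), 1e4)
  codes <- paste0(2 * pr$inputs + pr$outputs$symbols)
  w <- "30"
  expect_equal(unname(cr$tab[[2]][w]), brute_force_word_count(codes, w),
               ignore_attr = TRUE)
  expect_error(count_joint_histories(io_pair(c(0, 1), c(1, 0)), 2),
               "too short")
})

test_that("input-independent i.i.d. outputs give a one-state transducer", {
  set.seed(5)
  pair <- io_pair(rbinom(4e4, 1, 0.5), rbinom(4e4, 1, 0.35))
  t1 <- estimate_transducer(pair, cssr_config(lmax = 2))
  expect_equal(length(t1$states), 1)
  p_in0 <- emission_prob(t1, t1$states[1], 0, 1)
  p_in1 <- emission_prob(t1, t1$states[1], 1, 1)
  expect_lt(abs(p_in0 - 0.35), 0.02)
  expect_lt(abs(p_in1 - 0.35), 0.02)
})

test_that("the reference two-state transducer is recovered from its data", {
  set.seed(7)
  ins <- simulate_input_process(2e5, 0.5)
  pair <- simulate_transducer(fixture_transducer_2state(), ins)
  that <- estimate_transducer(pair, cssr_config(lmax = 2))
  expect_identical(validate_transducer(that), character(0))
  expect_equal(length(that$states), 2)
  s0 <- state_after_output(that, 0)
  s1 <- state_after_output(that, 1)
  expect_lt(abs(emission_prob(that, s0, 1, 1) - 0.48), 0.02)
  expect_lt(abs(emission_prob(that, s1, 1, 1) - 0.72), 0.02)
  expect_lt(abs(emission_prob(that, s1, 0, 0) - 0.71), 0.02)
})

test_that("an output that copies the previous input is a 2-state machine", {
  set.seed(11)
  y <- rbinom(2e4, 1, 0.5)
  x <- c(0L, y[-length(y)])  # reply echoes the previous parent
  pair <- io_pair(y, x)
  tc <- estimate_transducer(pair, cssr_config(lmax = 1))
  expect_equal(length(tc$states), 2)
  # emissions are deterministic given the state, whatever the input
  for (s in tc$states) {
    for (yin in 0:1) {
      p <- emission_prob(tc, s, yin, 1)
      if (!is.na(p)) expect_true(p %in% c(0, 1))
    }
  }
})

test_that("constant inputs make machine and transducer estimates agree", {
  x <- simulate_machine(fixture_machine_2state(), 1e5, seed = 13)
  pair <- io_pair(rep(0L, 1e5), x)
  m <- estimate_machine(x, cssr_config(lmax = 2))
  t <- estimate_transducer(pair, cssr_config(lmax = 2))
  expect_equal(length(t$states), n_states(m))
  # the input-0 emission of each transducer state matches a machine row
  m_p1 <- sort(vapply(m$states, function(s) transition_prob(m, s, 1), 1))
  t_p1 <- sort(vapply(t$states, function(s) emission_prob(t, s, 0, 1), 1))
  expect_equal(unname(t_p1), unname(m_p1), tolerance = 1e-9)
})

test_that("transducers see structure that output-only machines need too", {
  # input-coupled data: the transducer must have at least as many states
  # as the machine fit to the outputs alone
  wins <- 0L
  for (seed in 1:6) {
    set.seed(2000 + seed)
    ins <- simulate_input_process(1e5, 0.5)
    pair <- simulate_transducer(fixture_transducer_2state(), ins)
    t <- estimate_transducer(pair, cssr_config(lmax = 2))
    m <- estimate_machine(pair$outputs, cssr_config(lmax = 2))
    if (length(t$states) >= n_states(m)) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("transducer log loss matches closed forms", {
  # emissions all 0.5: one bit per symbol regardless of the data
  em <- expand.grid(state = "s", input = 0:1, output = 0:1,
                    stringsAsFactors = FALSE)
  em$prob <- 0.5
  tr <- em[, c("state", "input", "output")]
  tr$to <- "s"
  flat <- epsilon_transducer(em, tr)
  set.seed(17)
  pair <- io_pair(rbinom(1000, 1, 0.5), rbinom(1000, 1, 0.5))
  expect_equal(transducer_log_loss(flat, pair)$bits_per_symbol, 1)

  # deterministic copy transducer on consistent data scores zero
  y <- rbinom(1000, 1, 0.5)
  x <- c(0L, y[-1000])
  cp <- estimate_transducer(io_pair(y, x), cssr_config(lmax = 1))
  ll <- transducer_log_loss(cp, io_pair(y, x))
  expect_equal(ll$bits_per_symbol, 0)
})

test_that("fixture transducer loss equals its weighted emission entropy", {
  t2 <- fixture_transducer_2state()
  set.seed(19)
  ins <- simulate_input_process(1e5, 0.5)
  pair <- simulate_transducer(t2, ins)
  ll <- transducer_log_loss(t2, pair)$bits_per_symbol
  # oracle: entropy of each (state, input) emission, weighted by the
  # empirical visitation frequencies of the simulated stream
  y <- pair$inputs
  x <- pair$outputs$symbols
  n <- length(x)
  st <- ifelse(x[-n] == 1, "troll", "non-troll")  # state = last output
  w <- table(st, y[-1])
  w <- w / sum(w)
  href <- 0
  for (s in rownames(w)) {
    for (yy in colnames(w)) {
      href <- href + w[s, yy] *
        binary_entropy(emission_prob(t2, s, as.integer(yy), 1))
    }
  }
  expect_lt(abs(ll - href), 0.01)
})

test_that("transducer lmax selection prefers the smallest adequate window", {
  set.seed(23)
  ins <- simulate_input_process(6e4, 0.5)
  pair <- simulate_transducer(fixture_transducer_2state(), ins)
  sel <- select_lmax_transducer(pair, 1:3)
  expect_equal(sel$lmax, 1L)  # state = last output: one step suffices
  expect_true(all(is.finite(sel$table$loss)))
})
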