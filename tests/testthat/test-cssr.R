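test_that("sliding-window counts match hand counts and a brute-force scan", {
  counts <- count_histories(binary_sequence(c(0, 1, 0, 1)), 1)
  expect_equal(unname(counts$tab[[2]][["01"]]), 2)
  expect_equal(unname(counts$tab[[2]][["10"]]), 1)
  expect_equal(unname(counts$tab[[1]][["0"]]), 2)
  expect_equal(unname(counts$tab[[1]][["1"]]), 2)

  const <- binary_sequence(rep(0, 50))
  cc <- count_histories(const, 3)
  for (k in 1:4) {
    expect_equal(unname(cc$tab[[k]][[strrep("0", k)]]), 50 - k + 1)
  }

  set.seed(17)
  x <- rbinom(1e4, 1, 0.4)
  cr <- count_histories(binary_sequence(x), 2)
  expect_equal(sum(cr$tab[[2]]), 9999)
  for (w in c("01", "110", "00")) {
    expect_equal(unname(cr$tab[[nchar(w)]][w]),
                 brute_force_word_count(x, w), ignore_attr = TRUE)
  }
  expect_error(count_histories(binary_sequence(c(0, 1, 0)), 3), "smaller lmax")
})

test_that("next-symbol distributions are ML estimates with support counts", {
  set.seed(23)
  x <- rbinom(2000, 1, 0.6)
  counts <- count_histories(binary_sequence(x), 2)
  # empty history gives the marginal next-symbol frequency
  d <- next_distribution(counts, "")
  expect_equal(unname(d$dist[["1"]]), mean(x))
  expect_equal(d$n, 2000)
  # conditional frequency oracle for a length-1 history
  d1 <- next_distribution(counts, "1")
  idx <- which(x[-length(x)] == 1) + 1L
  expect_equal(unname(d1$dist[["1"]]), mean(x[idx]))
  # an unobserved history is flagged
  const <- count_histories(binary_sequence(rep(0, 100)), 2)
  expect_false(next_distribution(const, "11")$observed)
  expect_error(next_distribution(counts, "101"), "longer than lmax")
})

test_that("the splitting test agrees with an independent chi-square", {
  r <- split_test(c(0.9, 0.1), 1000, c(0.1, 0.9), 1000)
  expect_equal(r$decision, "different")
  oracle <- stats::chisq.test(rbind(c(900, 100), c(100, 900)),
                              correct = FALSE)
  expect_equal(r$statistic, unname(oracle$statistic))
  expect_gt(r$statistic, 1000)

  r2 <- split_test(c(0.52, 0.48), 100, c(0.48, 0.52), 100)
  expect_equal(r2$decision, "same")
  oracle2 <- stats::chisq.test(rbind(c(52, 48), c(48, 52)),
                               correct = FALSE)
  expect_equal(r2$p, oracle2$p.value)
  expect_lt(abs(r2$p - 0.57), 0.02)

  expect_equal(split_test(c(1, 0), 50, c(1, 0), 80)$decision, "same")
  # identical counts can never split
  expect_equal(split_test(c(0.3, 0.7), 10, c(0.3, 0.7), 10)$decision, "same")
})

test_that("random 2x2 splitting decisions track stats::chisq.test", {
  set.seed(31)
  for (i in 1:50) {
    ca <- rmultinom(1, sample(20:200, 1), c(0.5, 0.5))[, 1]
    cb <- rmultinom(1, sample(20:200, 1), c(0.3, 0.7))[, 1]
    mine <- split_test(ca / sum(ca), sum(ca), cb / sum(cb), sum(cb))
    ref <- suppressWarnings(
      stats::chisq.test(rbind(ca, cb), correct = FALSE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_identical(mine$decision == "different", ref$p.value < 0.001)
  }
})

test_that("phase one recovers the canonical state partitions", {
  set.seed(43)
  iid <- binary_sequence(rbinom(5e4, 1, 0.5))
  counts <- count_histories(iid, 3)
  st <- cssr_phase1(counts, cssr_config(lmax = 3))
  expect_length(st, 1)

  alt <- binary_sequence(rep(c(0, 1), 600))
  st2 <- cssr_phase1(count_histories(alt, 2), cssr_config(lmax = 2))
  expect_length(st2, 2)

  # three-state data: length-3 histories group by suffix ...0 / ...01 / ...11
  x3 <- simulate_machine(fixture_machine_3state(), 2e5, seed = 3)
  m <- estimate_machine(x3, cssr_config(lmax = 3))
  hm <- m$meta$history_map
  hm <- hm[!is.na(hm)]
  suffix_class <- function(h) {
    if (endsWith(h, "0")) "A" else if (endsWith(h, "01")) "B" else "C"
  }
  expected <- vapply(names(hm), suffix_class, "")
  expect_equal(length(unique(hm)), 3)
  expect_true(all(tapply(hm, expected, function(v) length(unique(v)) == 1)))
})

test_that("phase-one grouping matches a brute-force pairwise partition", {
  # oracle: group all length-3 histories of the same data by pairwise
  # chi-square agreement of their empirical next-symbol counts
  x3 <- simulate_machine(fixture_machine_3state(), 2e5, seed = 3)
  counts <- count_histories(x3, 3)
  hists <- names(counts$tab[[3]])
  nc <- lapply(hists, function(h) {
    c(unname(counts$tab[[4]][paste0(h, "0")]),
      unname(counts$tab[[4]][paste0(h, "1")]))
  })
  nc <- lapply(nc, function(v) ifelse(is.na(v), 0, v))
  groups <- integer(length(hists))
  g <- 0L
  for (i in seq_along(hists)) {
    assigned <- FALSE
    if (i > 1) {
      for (j in 1:(i - 1)) {
        ref <- suppressWarnings(stats::chisq.test(rbind(nc[[i]], nc[[j]]),
                                                  correct = FALSE))
        if (ref$p.value >= 0.001) {
          groups[i] <- groups[j]
          assigned <- TRUE
          break
        }
      }
    }
    if (!assigned) {
      g <- g + 1L
      groups[i] <- g
    }
  }
  m <- estimate_machine(x3, cssr_config(lmax = 3))
  hm <- m$meta$history_map[hists]
  expect_equal(length(unique(groups)), 3)
  # same partition: the two labelings agree up to renaming
  expect_equal(length(unique(paste(groups, hm))), 3)
})

test_that("phase two yields unifilar machines and exact deterministic fits", {
  alt <- binary_sequence(rep(c(0, 1), 600))
  m <- estimate_machine(alt, cssr_config(lmax = 2))
  expect_identical(validate_machine(m), character(0))
  expect_equal(n_states(m), 2)
  expect_true(all(m$transitions$prob == 1))

  const <- binary_sequence(rep(1, 500))
  mc <- estimate_machine(const, cssr_config(lmax = 1))
  expect_equal(n_states(mc), 1)
  expect_equal(mc$transitions$prob, 1)
  expect_equal(mc$transitions$symbol, 1L)
})

test_that("three-state recovery hits the generator probabilities", {
  x3 <- simulate_machine(fixture_machine_3state(), 2e5, seed = 19)
  m <- estimate_machine(x3, cssr_config(lmax = 3))
  expect_identical(validate_machine(m), character(0))
  expect_equal(n_states(m), 3)
  troll <- state_after(m, "11")
  trans <- state_after(m, "01")
  nont <- state_after(m, "00")
  expect_lt(abs(transition_prob(m, troll, 1) - 0.76), 0.02)
  expect_lt(abs(transition_prob(m, trans, 1) - 0.39), 0.02)
  expect_lt(abs(transition_prob(m, nont, 0) - 0.68), 0.02)
})

test_that("two-state recovery and the memoryless cases behave", {
  x2 <- simulate_machine(fixture_machine_2state(), 2e5, seed = 29)
  m <- estimate_machine(x2, cssr_config(lmax = 2))
  expect_equal(n_states(m), 2)
  expect_lt(abs(transition_prob(m, state_after(m, "1"), 1) - 0.67), 0.01)

  set.seed(37)
  coin <- binary_sequence(rbinom(5e4, 1, 0.5))
  mi <- estimate_machine(coin, cssr_config(lmax = 3))
  expect_equal(n_states(mi), 1)
  expect_lt(abs(transition_prob(mi, mi$states[1], 1) - 0.5), 0.02)
})

test_that("estimated machines are always valid with a complete history map", {
  for (seed in 1:5) {
    cohort <- generate_cohort(cohort_config(
      n_users = 1, length_range = c(5000, 5000), seed = seed,
      mix = c(coin = 0.25, two_state = 0.25, three_state = 0.25,
              transducer_coupled = 0.25)))
    m <- estimate_machine(cohort[[1]]$pair$outputs, cssr_config(lmax = 2))
    expect_identical(validate_machine(m), character(0))
    hm <- m$meta$history_map
    # every observed length-2 history maps to at most one state
    expect_true(all(nchar(names(hm)) == 2))
    expect_false(any(duplicated(names(hm))))
  }
})

test_that("lmax selection minimizes held-out loss with smallest-tie rule", {
  set.seed(53)
  iid <- binary_sequence(rbinom(3e4, 1, 0.5))
  sel <- select_lmax(iid, 1:3)
  expect_equal(sel$lmax, 1L)
  expect_lt(max(sel$table$loss) - min(sel$table$loss), 0.02)

  alt <- binary_sequence(rep(c(0, 1), 2000))
  sel_alt <- select_lmax(alt, 1:3)
  expect_equal(sel_alt$lmax, 1L)
  expect_equal(min(sel_alt$table$loss), 0)

  x3 <- simulate_machine(fixture_machine_3state(), 2e5, seed = 61)
  sel3 <- select_lmax(x3, 1:4)
  expect_gte(sel3$lmax, 2L)
})

test_that("more data never hurts the selected model's held-out loss much", {
  m <- fixture_machine_2state()
  for (seed in 1:10) {
    x_small <- simulate_machine(m, 2e4, seed = 500 + seed)
    x_big <- simulate_machine(m, 4e4, seed = 700 + seed)
    holdout <- simulate_machine(m, 2e4, seed = 900 + seed)
    fit <- function(x) {
      sel <- select_lmax(x, 1:3)
      estimate_machine(x, cssr_config(lmax = sel$lmax))
    }
    l_small <- sequence_log_loss(fit(x_small), holdout)$bits_per_symbol
    l_big <- sequence_log_loss(fit(x_big), holdout)$bits_per_symbol
    expect_lt(l_big - l_small, 0.01)
  }
})
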