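# Small reference models and oracles shared across tests.

fair_coin_machine <- function() {
  epsilon_machine(data.frame(from = "s", symbol = c(0L, 1L),
                             prob = c(0.5, 0.5), to = "s"))
}

biased_coin_machine <- function(p_one) {
  epsilon_machine(data.frame(from = "s", symbol = c(0L, 1L),
                             prob = c(1 - p_one, p_one), to = "s"))
}

# A -1-> B, B -0-> A: deterministic alternating process.
period2_machine <- function() {
  epsilon_machine(data.frame(from = c("A", "B"), symbol = c(1L, 0L),
                             prob = c(1, 1), to = c("B", "A")))
}

binary_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

# Independent stationary-distribution oracle: power-iterate the state
# chain until successive iterates differ by < 1e-12.
stationary_by_power_iteration <- function(m) {
  st <- m$states
  P <- matrix(0, length(st), length(st), dimnames = list(st, st))
  tr <- m$transitions
  for (i in seq_len(nrow(tr))) {
    P[tr$from[i], tr$to[i]] <- P[tr$from[i], tr$to[i]] + tr$prob[i]
  }
  pi_s <- rep(1 / length(st), length(st))
  for (k in 1:100000) {
    nxt <- as.numeric(pi_s %*% P)
    if (max(abs(nxt - pi_s)) < 1e-12) break
    pi_s <- nxt
  }
  stats::setNames(pi_s, st)
}

# Brute-force overlapping-window word counter (oracle for the sliding
# window tables).
brute_force_word_count <- function(symbols, word) {
  k <- nchar(word)
  n <- length(symbols)
  if (k > n) return(0L)
  s <- paste(symbols, collapse = "")
  sum(vapply(1:(n - k + 1L), function(i) {
    substr(s, i, i + k - 1L) == word
  }, TRUE))
}

# Exhaustive assignment oracle for small cost matrices.
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

exhaustive_assignment_cost <- function(cost) {
  n <- nrow(cost)
  min(vapply(all_permutations(seq_len(n)), function(p) {
    sum(cost[cbind(seq_len(n), p)])
  }, 1))
}
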