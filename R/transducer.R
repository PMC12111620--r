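#' Input-output epsilon-transducer
#'
#' A unifilar hidden-state model for a socially-driven process: at each
#' step the model observes the current input symbol (e.g. whether the
#' parent comment is trolling), emits an output symbol from a distribution
#' conditional on (state, input), and moves to a unique next state
#' determined by (state, input, output).
#'
#' @param emissions Data frame with columns `state`, `input` (0/1),
#'   `output` (0/1), `prob`.
#' @param transitions Data frame with columns `state`, `input`, `output`,
#'   `to`.
#' @param states Optional canonical state ordering.
#' @param meta Optional estimation metadata.
#' @return An object of class `epsilon_transducer`.
#' @export
epsilon_transducer <- function(emissions, transitions, states = NULL,
                               meta = list()) {
  stopifnot(is.data.frame(emissions),
            all(c("state", "input", "output", "prob") %in% names(emissions)),
            is.data.frame(transitions),
            all(c("state", "input", "output", "to") %in% names(transitions)))
  emissions$state <- as.character(emissions$state)
  emissions$input <- as.integer(emissions$input)
  emissions$output <- as.integer(emissions$output)
  emissions$prob <- as.numeric(emissions$prob)
  transitions$state <- as.character(transitions$state)
  transitions$to <- as.character(transitions$to)
  transitions$input <- as.integer(transitions$input)
  transitions$output <- as.integer(transitions$output)
  if (is.null(states)) {
    states <- sort(unique(c(emissions$state, transitions$state,
                            transitions$to)))
  }
  structure(list(states = as.character(states), emissions = emissions,
                 transitions = transitions, meta = meta),
            class = "epsilon_transducer")
}

#' @export
print.epsilon_transducer <- function(x, ...) {
  cat("<epsilon_transducer>", length(x$states), "states:",
      paste(x$states, collapse = ", "), "\n")
  em <- x$emissions[order(x$emissions$state, x$emissions$input,
                          x$emissions$output), ]
  for (i in seq_len(nrow(em))) {
    to <- transducer_dest(x, em$state[i], em$input[i], em$output[i])
    cat(sprintf("  %s  %d|%d: %.4f --> %s\n", em$state[i], em$output[i],
                em$input[i], em$prob[i], if (is.na(to)) "?" else to))
  }
  invisible(x)
}

# 3-d lookup arrays [state, input, output] for probabilities/destinations.
transducer_arrays <- function(t) {
  st <- t$states
  dn <- list(st, c("0", "1"), c("0", "1"))
  p <- array(NA_real_, c(length(st), 2, 2), dimnames = dn)
  d <- array(NA_character_, c(length(st), 2, 2), dimnames = dn)
  em <- t$emissions
  for (i in seq_len(nrow(em))) {
    p[em$state[i], em$input[i] + 1L, em$output[i] + 1L] <- em$prob[i]
  }
  tr <- t$transitions
  for (i in seq_len(nrow(tr))) {
    d[tr$state[i], tr$input[i] + 1L, tr$output[i] + 1L] <- tr$to[i]
  }
  list(prob = p, dest = d)
}

#' Emission probability of a transducer
#'
#' @param t An `epsilon_transducer`.
#' @param state State id.
#' @param input,output Symbols in 0/1.
#' @return `P(output | state, input)`, or `NA` when the (state, input)
#'   combination was never observed during estimation.
#' @export
emission_prob <- function(t, state, input, output) {
  em <- t$emissions
  hit <- em$state == state & em$input == as.integer(input) &
    em$output == as.integer(output)
  if (!any(hit)) {
    # observed (state, input) but missing output row => probability 0
    row <- em$state == state & em$input == as.integer(input)
    if (any(row)) return(0)
    return(NA_real_)
  }
  sum(em$prob[hit])
}

transducer_dest <- function(t, state, input, output) {
  tr <- t$transitions
  hit <- tr$state == state & tr$input == as.integer(input) &
    tr$output == as.integer(output)
  if (!any(hit)) return(NA_character_)
  tr$to[hit][1L]
}

#' Validate an epsilon-transducer
#'
#' Checks that every observed (state, input) emission distribution sums to
#' one, probabilities lie in `[0, 1]`, and transitions are deterministic
#' given (state, input, output).
#'
#' @param t An `epsilon_transducer`.
#' @return Character vector of violations; empty when valid.
#' @export
validate_transducer <- function(t) {
  out <- character(0)
  em <- t$emissions
  if (any(em$prob < 0 | em$prob > 1)) {
    i <- which(em$prob < 0 | em$prob > 1)[1L]
    out <- c(out, paste0("probability out of [0,1] at (", em$state[i], ", ",
                         em$input[i], ", ", em$output[i], ")"))
  }
  key <- paste(em$state, em$input)
  for (k in unique(key)) {
    rs <- sum(em$prob[key == k])
    if (abs(rs - 1) > 1e-9) {
      out <- c(out, paste0("emission distribution for (state, input) = (",
                           sub(" ", ", ", k), ") sums to ", format(rs)))
    }
  }
  tr <- t$transitions
  tkey <- paste(tr$state, tr$input, tr$output)
  dup <- unique(tkey[duplicated(tkey)])
  for (k in dup) {
    out <- c(out, paste0("unifilarity violated: multiple destinations for (",
                         gsub(" ", ", ", k), ")"))
  }
  bad <- setdiff(unique(c(em$state, tr$state, tr$to)), t$states)
  if (length(bad) > 0) {
    out <- c(out, paste0("undeclared state(s): ", paste(bad, collapse = ", ")))
  }
  out
}

#' Simulate an input-output pair from a transducer
#'
#' Feeds the given input sequence through the transducer: at step i the
#' output is drawn from the emission distribution of (current state,
#' `inputs[i]`) and the state advances along the unifilar transition.
#'
#' @param t A valid `epsilon_transducer`.
#' @param inputs Integer 0/1 vector of social inputs.
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @param start Optional start state; default is a uniformly random state.
#' @param user_id Label for the output sequence.
#' @return An [io_pair].
#' @export
simulate_transducer <- function(t, inputs, seed = NULL, start = NULL,
                                user_id = NA_character_) {
  inputs <- as.integer(inputs)
  if (length(inputs) < 1L) stop("inputs must be nonempty")
  if (!all(inputs %in% c(0L, 1L))) {
    stop("input symbol outside the {0,1} alphabet")
  }
  if (!is.null(seed)) set.seed(seed)
  ar <- transducer_arrays(t)
  st <- t$states
  s <- if (is.null(start)) sample.int(length(st), 1L) else match(start, st)
  if (is.na(s)) stop("unknown start state")
  didx <- array(match(ar$dest, st), dim = dim(ar$dest))
  n <- length(inputs)
  u <- stats::runif(n)
  x <- integer(n)
  for (i in seq_len(n)) {
    yi <- inputs[i] + 1L
    p1 <- ar$prob[s, yi, 2L]
    if (is.na(p1)) p1 <- 1 - ar$prob[s, yi, 1L]
    if (is.na(p1)) stop("no emission defined for (state ", st[s],
                        ", input ", inputs[i], ")")
    if (u[i] < p1) {
      x[i] <- 1L
      s <- didx[s, yi, 2L]
    } else {
      s <- didx[s, yi, 1L]
    }
    if (is.na(s)) stop("simulation reached an undefined transition")
  }
  io_pair(inputs, binary_sequence(x, user_id))
}

#' Stationary distribution of a transducer's state chain
#'
#' Under an i.i.d. Bernoulli input process with `P(input = 1) = p_input`,
#' the transducer's states form a Markov chain; this returns its
#' stationary distribution (used to weight states in the transducer's
#' statistical complexity).
#'
#' @param t A valid `epsilon_transducer`.
#' @param p_input Probability that the input symbol is 1.
#' @return Named numeric vector over states.
#' @export
transducer_stationary <- function(t, p_input = 0.5) {
  st <- t$states
  k <- length(st)
  if (k == 1) return(stats::setNames(1, st))
  ar <- transducer_arrays(t)
  P <- matrix(0, k, k, dimnames = list(st, st))
  py <- c(1 - p_input, p_input)
  for (si in seq_len(k)) {
    for (yi in 1:2) {
      for (xi in 1:2) {
        pr <- ar$prob[si, yi, xi]
        to <- ar$dest[si, yi, xi]
        if (!is.na(pr) && !is.na(to) && pr > 0) {
          P[si, to] <- P[si, to] + py[yi] * pr
        }
      }
    }
  }
  # Rows with unobserved (state, input) cells may not sum to 1; renormalize
  # so the chain stays stochastic for the complexity weighting.
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / rs
  A <- rbind(t(P) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_s <- as.numeric(qr.solve(A, b))
  pi_s[pi_s < 0 & pi_s > -1e-12] <- 0
  stats::setNames(pi_s / sum(pi_s), st)
}

#' Per-output-symbol log loss of a transducer on an aligned pair
#'
#' Transducer analogue of [sequence_log_loss()]: the belief set over
#' states is filtered along the joint observations; after synchronization
#' each output is scored with \eqn{-\log_2 P(x_t \mid s_t, y_t)}.
#' Positions whose (state, input) emission is unobserved, and
#' desynchronized positions, are excluded from scoring.
#'
#' @param t A valid `epsilon_transducer`.
#' @param pair An [io_pair].
#' @param floor Probability floor (default `1e-6`).
#' @return List with `bits_per_symbol` and `n_scored`.
#' @export
transducer_log_loss <- function(t, pair, floor = 1e-6) {
  stopifnot(inherits(pair, "io_pair"))
  y <- pair$inputs
  x <- pair$outputs$symbols
  n <- length(y)
  ar <- transducer_arrays(t)
  st <- t$states
  didx <- array(match(ar$dest, st), dim = dim(ar$dest))
  all_states <- seq_along(st)
  S <- all_states
  loss <- 0
  n_scored <- 0L
  for (i in seq_len(n)) {
    yi <- y[i] + 1L
    xi <- x[i] + 1L
    if (length(S) == 1L) {
      p <- ar$prob[S, yi, xi]
      if (!is.na(p)) {
        loss <- loss - log2(max(p, floor))
        n_scored <- n_scored + 1L
      }
    }
    p_all <- ar$prob[S, yi, xi]
    keep <- S[!is.na(p_all) & p_all > 0]
    if (length(keep) == 0L) {
      S <- all_states
      next
    }
    nxt <- didx[cbind(keep, yi, xi)]
    nxt <- unique(nxt[!is.na(nxt)])
    S <- if (length(nxt) == 0L) all_states else nxt
  }
  if (n_scored == 0L) {
    stop("pair never synchronizes with the transducer; ",
         "use more data or a smaller model")
  }
  list(bits_per_symbol = loss / n_scored, n_scored = n_scored)
}

#' Transducer state reached after an observed output
#'
#' Count-weighted majority over the estimated joint histories whose most
#' recent output equals `output` (analogue of [state_after()] for
#' transducers).
#'
#' @param t A CSSR-estimated `epsilon_transducer`.
#' @param output 0 or 1.
#' @return A state id.
#' @export
state_after_output <- function(t, output) {
  hm <- t$meta$history_map
  if (is.null(hm)) {
    stop("transducer carries no history map (not CSSR-estimated)")
  }
  hc <- t$meta$history_count
  hs <- names(hm)
  last <- substr(hs, nchar(hs), nchar(hs))
  hit <- joint_code_output(last) == as.integer(output) & !is.na(hm)
  if (!any(hit)) stop("no observed joint history ends with output ", output)
  w <- hc[hs[hit]]
  tab <- tapply(w, hm[hit], sum)
  names(tab)[which.max(tab)]
}
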