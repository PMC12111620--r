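#' Two-state self-driven reference machine
#'
#' The population-average two-state epsilon-machine of self-driven trolling
#' dynamics: once a user switches to the troll state they tend to remain
#' there (emit 1 and stay with probability 0.67), and symmetrically the
#' non-troll state is sticky (emit 0 and stay with probability 0.69).
#'
#' @return A valid `epsilon_machine` with states `non-troll` and `troll`.
#' @export
fixture_machine_2state <- function() {
  epsilon_machine(data.frame(
    from = c("non-troll", "non-troll", "troll", "troll"),
    symbol = c(0L, 1L, 1L, 0L),
    prob = c(0.69, 0.31, 0.67, 0.33),
    to = c("non-troll", "troll", "troll", "non-troll"),
    stringsAsFactors = FALSE),
    states = c("non-troll", "troll"))
}

#' Three-state self-driven reference machine
#'
#' The population-average three-state machine: a transition state sits
#' between the non-troll and troll states, acting as a threshold. From
#' non-troll, a user stays with probability 0.68 or moves to the
#' transition state (emitting 1) with probability 0.32; from the
#' transition state they advance to troll (emitting 1) with probability
#' 0.39 or fall back to non-troll; once in the troll state they stay with
#' probability 0.76. The troll state cannot be reached directly from
#' non-troll, nor the transition state from troll; every non-staying move
#' returns to non-troll. Edge symbols follow the reading that trolling
#' (1) is what moves a user toward and keeps them in the troll state.
#'
#' @return A valid `epsilon_machine` with states `non-troll`,
#'   `transition`, `troll`.
#' @export
fixture_machine_3state <- function() {
  epsilon_machine(data.frame(
    from = c("non-troll", "non-troll", "transition", "transition",
             "troll", "troll"),
    symbol = c(0L, 1L, 1L, 0L, 1L, 0L),
    prob = c(0.68, 0.32, 0.39, 0.61, 0.76, 0.24),
    to = c("non-troll", "transition", "troll", "non-troll",
           "troll", "non-troll"),
    stringsAsFactors = FALSE),
    states = c("non-troll", "transition", "troll"))
}

#' Two-state social-induced reference transducer
#'
#' The population-average two-state transducer of socially-induced
#' dynamics. The hidden state tracks the user's last reply (troll or not);
#' emissions condition on the parent comment being replied to: from the
#' non-troll state, replying to a troll parent raises the probability of a
#' troll reply to 0.48 (versus 0.28 for a non-troll parent); from the
#' troll state a troll parent reinforces staying (0.72), while a
#' non-troll parent favors a non-troll reply (0.71). The next state is
#' troll iff the emitted reply is 1.
#'
#' @return A valid `epsilon_transducer` with states `non-troll`, `troll`.
#' @export
fixture_transducer_2state <- function() {
  em <- expand.grid(state = c("non-troll", "troll"), input = 0:1,
                    output = 0:1, stringsAsFactors = FALSE)
  p1 <- function(state, input) {
    if (state == "non-troll") {
      if (input == 1) 0.48 else 0.28
    } else {
      if (input == 1) 0.72 else 1 - 0.71
    }
  }
  em$prob <- mapply(function(s, y, x) {
    q <- p1(s, y)
    if (x == 1) q else 1 - q
  }, em$state, em$input, em$output)
  tr <- expand.grid(state = c("non-troll", "troll"), input = 0:1,
                    output = 0:1, stringsAsFactors = FALSE)
  tr$to <- ifelse(tr$output == 1, "troll", "non-troll")
  epsilon_transducer(em, tr, states = c("non-troll", "troll"))
}

#' Balanced input-coupled transducer (synthetic)
#'
#' A synthetic two-state transducer used by the cohort generator's
#' input-coupled archetype. Its input-conditional emissions differ
#' between states, so a transducer is needed to predict the output, but
#' the input-marginal probability of a troll reply is the same 0.38 in
#' both states under i.i.d. Bernoulli(0.5) inputs: viewed through its
#' output sequence alone, such a user is indistinguishable from a coin.
#' This reproduces the headline population structure in which most users
#' look memoryless when modeled self-driven yet show hidden multi-state
#' patterns once the social input is conditioned on. It is a synthetic
#' construction of this package, not an estimated population average.
#'
#' @return A valid `epsilon_transducer` with states `non-troll`, `troll`.
#' @export
fixture_transducer_balanced <- function() {
  em <- expand.grid(state = c("non-troll", "troll"), input = 0:1,
                    output = 0:1, stringsAsFactors = FALSE)
  p1 <- function(state, input) {
    if (state == "non-troll") {
      if (input == 1) 0.48 else 0.28
    } else {
      if (input == 1) 0.56 else 0.20
    }
  }
  em$prob <- mapply(function(s, y, x) {
    q <- p1(s, y)
    if (x == 1) q else 1 - q
  }, em$state, em$input, em$output)
  tr <- expand.grid(state = c("non-troll", "troll"), input = 0:1,
                    output = 0:1, stringsAsFactors = FALSE)
  tr$to <- ifelse(tr$output == 1, "troll", "non-troll")
  epsilon_transducer(em, tr, states = c("non-troll", "troll"))
}
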