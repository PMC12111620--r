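#' Cohort generator configuration
#'
#' Describes a synthetic cohort of users whose structure emulates the kind
#' of population the models are meant for: mostly memoryless users, a
#' minority with two- or three-state hidden self-driven patterns, and a
#' share of input-coupled users whose behavior responds to the social
#' input. Defaults: sequence lengths drawn uniformly from
#' 10,000-30,000 (mean 20,000, on the order of an active user's two-year
#' comment history), archetype mix 60% coin / 20% two-state / 10%
#' three-state / 10% input-coupled, and probability jitter 0.05.
#'
#' @param n_users Number of users to generate.
#' @param length_range Length-2 integer vector, min/max sequence length
#'   (each length drawn uniformly); lengths must be at least 100.
#' @param mix Named numeric vector of archetype proportions over
#'   `coin`, `two_state`, `three_state`, `transducer_coupled`; must sum
#'   to 1.
#' @param jitter Standard deviation of the truncated-Gaussian perturbation
#'   applied to each archetype's emission probabilities, on the
#'   probability scale; in `[0, 0.1]`.
#' @param seed Master random seed for the whole cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_users = 50,
                          length_range = c(10000L, 30000L),
                          mix = c(coin = 0.6, two_state = 0.2,
                                  three_state = 0.1,
                                  transducer_coupled = 0.1),
                          jitter = 0.05,
                          seed = 1L) {
  stopifnot(n_users >= 1, length(length_range) == 2,
            length_range[1] >= 100, length_range[1] <= length_range[2],
            jitter >= 0, jitter <= 0.1)
  need <- c("coin", "two_state", "three_state", "transducer_coupled")
  if (!all(need %in% names(mix))) {
    stop("mix must name the archetypes: ", paste(need, collapse = ", "))
  }
  mix <- mix[need]
  if (abs(sum(mix) - 1) > 1e-9) stop("mix proportions must sum to 1")
  structure(list(n_users = as.integer(n_users),
                 length_range = as.integer(length_range),
                 mix = mix, jitter = jitter, seed = as.integer(seed)),
            class = "cohort_config")
}

#' I.i.d. Bernoulli input process
#'
#' @param n Length.
#' @param p_one Probability of a 1.
#' @param seed Optional seed (`NULL` uses the current RNG stream).
#' @return Integer 0/1 vector of length `n`.
#' @export
simulate_input_process <- function(n, p_one = 0.5, seed = NULL) {
  stopifnot(p_one >= 0, p_one <= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  as.integer(stats::runif(n) < p_one)
}

# Truncated-Gaussian jitter on the probability scale, clipped away from the
# boundary; rows stay normalized because the complement is recomputed.
jitter_prob <- function(p, sd) {
  if (sd == 0) return(p)
  min(max(p + stats::rnorm(1L, 0, sd), 0.01), 0.99)
}

jitter_machine <- function(m, sd) {
  tr <- m$transitions
  for (s in unique(tr$from)) {
    rows <- which(tr$from == s)
    if (length(rows) == 1L) next  # deterministic edge stays deterministic
    i1 <- rows[tr$symbol[rows] == 1L]
    i0 <- rows[tr$symbol[rows] == 0L]
    p1 <- jitter_prob(tr$prob[i1], sd)
    tr$prob[i1] <- p1
    tr$prob[i0] <- 1 - p1
  }
  epsilon_machine(tr, states = m$states)
}

jitter_transducer <- function(t, sd) {
  em <- t$emissions
  key <- paste(em$state, em$input)
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) == 1L) next
    i1 <- rows[em$output[rows] == 1L]
    i0 <- rows[em$output[rows] == 0L]
    p1 <- jitter_prob(em$prob[i1], sd)
    em$prob[i1] <- p1
    em$prob[i0] <- 1 - p1
  }
  epsilon_transducer(em, t$transitions, states = t$states)
}

coin_machine <- function(p_one = 0.5, state = "s") {
  epsilon_machine(data.frame(from = state, symbol = c(0L, 1L),
                             prob = c(1 - p_one, p_one), to = state,
                             stringsAsFactors = FALSE),
                  states = state)
}

#' Generate a synthetic cohort
#'
#' Draws each user's archetype from the configured mix, perturbs the
#' archetype's reference parameters with truncated-Gaussian jitter, and
#' simulates an aligned input-output pair of the drawn length. Inputs are
#' i.i.d. Bernoulli(0.5) for every user; for the non-coupled archetypes
#' they simply do not influence the output. The ground-truth model is
#' returned with each user so recovery can be tested. The whole cohort is
#' a deterministic function of `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return A list of user records, each a list with `user_id`, `pair`
#'   (an [io_pair]), `archetype`, and `truth` (the generating
#'   `epsilon_machine` or `epsilon_transducer`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  archetypes <- sample(names(cfg$mix), cfg$n_users, replace = TRUE,
                       prob = cfg$mix)
  lens <- sample.int(cfg$length_range[2] - cfg$length_range[1] + 1L,
                     cfg$n_users, replace = TRUE) + cfg$length_range[1] - 1L
  users <- vector("list", cfg$n_users)
  for (i in seq_len(cfg$n_users)) {
    uid <- sprintf("user%04d", i)
    n <- lens[i]
    arch <- archetypes[i]
    inputs <- simulate_input_process(n, 0.5)
    if (arch == "transducer_coupled") {
      truth <- jitter_transducer(fixture_transducer_balanced(), cfg$jitter)
      pair <- simulate_transducer(truth, inputs, user_id = uid)
    } else {
      truth <- switch(arch,
        coin = {
          p1 <- jitter_prob(0.5, cfg$jitter)
          coin_machine(p1)
        },
        two_state = jitter_machine(fixture_machine_2state(), cfg$jitter),
        three_state = jitter_machine(fixture_machine_3state(), cfg$jitter))
      out <- simulate_machine(truth, n, user_id = uid)
      pair <- io_pair(inputs, out)
    }
    users[[i]] <- list(user_id = uid, pair = pair, archetype = arch,
                       truth = truth)
  }
  users
}
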