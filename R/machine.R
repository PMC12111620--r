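#' Unifilar edge-emitting hidden Markov model (epsilon-machine)
#'
#' An epsilon-machine is the minimal, unifilar, maximally predictive
#' hidden-state representation of a stationary binary process: each state is
#' an equivalence class of pasts with identical conditional futures, and
#' each transition emits a symbol with a probability and moves to a unique
#' next state.
#'
#' @param transitions Data frame with columns `from` (state id, character),
#'   `symbol` (0 or 1), `prob` (emission probability), `to` (destination
#'   state id).
#' @param states Optional character vector fixing the canonical state
#'   order; defaults to the sorted states appearing in `transitions`.
#' @param recurrent Optional named logical vector flagging recurrent
#'   states; computed from the transition graph when `NULL`.
#' @param meta Optional list of estimation metadata (e.g. the map from
#'   observed histories to states produced by [estimate_machine()]).
#' @return An object of class `epsilon_machine`.
#' @examples
#' coin <- epsilon_machine(data.frame(
#'   from = "s", symbol = c(0, 1), prob = c(0.5, 0.5), to = "s"))
#' validate_machine(coin)
#' @export
epsilon_machine <- function(transitions, states = NULL, recurrent = NULL,
                            meta = list()) {
  stopifnot(is.data.frame(transitions),
            all(c("from", "symbol", "prob", "to") %in% names(transitions)))
  transitions$from <- as.character(transitions$from)
  transitions$to <- as.character(transitions$to)
  transitions$symbol <- as.integer(transitions$symbol)
  transitions$prob <- as.numeric(transitions$prob)
  if (is.null(states)) {
    states <- sort(unique(c(transitions$from, transitions$to)))
  }
  m <- structure(list(states = as.character(states),
                      transitions = transitions,
                      recurrent = recurrent,
                      meta = meta),
                 class = "epsilon_machine")
  if (is.null(recurrent)) {
    m$recurrent <- tryCatch(compute_recurrent_flags(m), error = function(e) {
      stats::setNames(rep(TRUE, length(states)), states)
    })
  }
  m
}

#' @export
print.epsilon_machine <- function(x, ...) {
  cat("<epsilon_machine>", length(x$states), "states:",
      paste(x$states, collapse = ", "), "\n")
  tr <- x$transitions[order(x$transitions$from, x$transitions$symbol), ]
  for (i in seq_len(nrow(tr))) {
    cat(sprintf("  %s --%d: %.4f--> %s\n", tr$from[i], tr$symbol[i],
                tr$prob[i], tr$to[i]))
  }
  invisible(x)
}

#' Number of states of a model
#'
#' @param m An `epsilon_machine` or `epsilon_transducer`.
#' @param recurrent_only Count only recurrent states (default).
#' @return Integer state count.
#' @export
n_states <- function(m, recurrent_only = TRUE) {
  if (inherits(m, "epsilon_transducer")) return(length(m$states))
  if (recurrent_only && !is.null(m$recurrent)) {
    return(sum(m$recurrent[m$states]))
  }
  length(m$states)
}

# Emission-probability and destination lookup matrices: states x symbols
# ("0","1"). Missing edges carry prob 0 / destination NA.
machine_matrices <- function(m) {
  st <- m$states
  p <- matrix(0, length(st), 2, dimnames = list(st, c("0", "1")))
  d <- matrix(NA_character_, length(st), 2, dimnames = list(st, c("0", "1")))
  tr <- m$transitions
  for (i in seq_len(nrow(tr))) {
    p[tr$from[i], as.character(tr$symbol[i])] <- tr$prob[i]
    d[tr$from[i], as.character(tr$symbol[i])] <- tr$to[i]
  }
  list(prob = p, dest = d)
}

#' Emission probability of one machine transition
#'
#' @param m An `epsilon_machine`.
#' @param state State id.
#' @param symbol 0 or 1.
#' @return The probability of emitting `symbol` from `state` (0 if no such
#'   edge).
#' @export
transition_prob <- function(m, state, symbol) {
  tr <- m$transitions
  hit <- tr$from == state & tr$symbol == as.integer(symbol)
  if (!any(hit)) return(0)
  sum(tr$prob[hit])
}

compute_recurrent_flags <- function(m) {
  st <- m$states
  tr <- m$transitions[m$transitions$prob > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$from, to = tr$to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = st, stringsAsFactors = FALSE))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # A component is terminal when no edge leaves it; its states are recurrent.
  terminal <- rep(TRUE, comp$no)
  if (nrow(tr) > 0) {
    cf <- memb[tr$from]
    ct <- memb[tr$to]
    terminal[unique(cf[cf != ct])] <- FALSE
  }
  flags <- terminal[memb[st]]
  stats::setNames(as.logical(flags), st)
}

#' Validate an epsilon-machine
#'
#' Checks the structural invariants of the class: per-state emission
#' probabilities summing to one, unifilarity (at most one edge per state and
#' symbol), probabilities in `[0, 1]`, edges referring to declared states,
#' and mutual reachability of the recurrent states. Validation always
#' returns; it never throws.
#'
#' @param m An `epsilon_machine`.
#' @return A character vector of human-readable violations; empty when all
#'   invariants hold.
#' @export
validate_machine <- function(m) {
  out <- character(0)
  tr <- m$transitions
  st <- m$states
  bad_state <- setdiff(unique(c(tr$from, tr$to)), st)
  if (length(bad_state) > 0) {
    out <- c(out, paste0("transition refers to undeclared state(s): ",
                         paste(bad_state, collapse = ", ")))
  }
  if (any(tr$prob < 0 | tr$prob > 1)) {
    i <- which(tr$prob < 0 | tr$prob > 1)[1L]
    out <- c(out, paste0("probability out of [0,1] on edge (", tr$from[i],
                         ", ", tr$symbol[i], ")"))
  }
  key <- paste(tr$from, tr$symbol)
  dup <- unique(key[duplicated(key)])
  for (k in dup) {
    out <- c(out, paste0("unifilarity violated: multiple edges for (state, symbol) = (",
                         sub(" ", ", ", k), ")"))
  }
  for (s in intersect(st, unique(tr$from))) {
    rs <- sum(tr$prob[tr$from == s])
    if (abs(rs - 1) > 1e-9) {
      out <- c(out, paste0("row sum != 1 for state ", s,
                           " (sum = ", format(rs), ")"))
    }
  }
  no_out <- setdiff(st, unique(tr$from))
  for (s in no_out) {
    out <- c(out, paste0("state ", s, " has no outgoing edges (row sum 0)"))
  }
  # Recurrent states must be mutually reachable.
  rec <- names(m$recurrent)[m$recurrent]
  rec <- intersect(rec, st)
  if (length(rec) > 1 && length(bad_state) == 0) {
    sub <- tr[tr$from %in% rec & tr$to %in% rec & tr$prob > 0, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = sub$from, to = sub$to, stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = rec, stringsAsFactors = FALSE))
    comp <- igraph::components(g, mode = "strong")
    if (comp$no > 1) {
      out <- c(out, paste0("recurrent part not strongly connected (",
                           comp$no, " components)"))
    }
  }
  out
}

#' Stationary distribution over machine states
#'
#' Solves \eqn{\pi P = \pi} for the state chain \eqn{P[s, s'] =
#' \sum_a P(a, s' | s)} restricted to the recurrent states; transient
#' states receive probability 0. This is the occupation distribution that
#' weights states in the statistical complexity.
#'
#' @param m A valid `epsilon_machine` whose recurrent part is irreducible.
#' @return Named numeric vector of probabilities over all states, summing
#'   to 1.
#' @export
stationary_distribution <- function(m) {
  rec <- names(m$recurrent)[m$recurrent]
  tr <- m$transitions[m$transitions$prob > 0, , drop = FALSE]
  sub <- tr[tr$from %in% rec & tr$to %in% rec, , drop = FALSE]
  k <- length(rec)
  if (k == 0) stop("machine has no recurrent states")
  if (k == 1) {
    pi_full <- stats::setNames(rep(0, length(m$states)), m$states)
    pi_full[rec] <- 1
    return(pi_full)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = sub$from, to = sub$to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = rec, stringsAsFactors = FALSE))
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1) {
    groups <- split(rec, comp$membership[rec])
    stop("recurrent part is reducible; disconnected components: ",
         paste(vapply(groups, paste, "", collapse = "+"), collapse = " | "))
  }
  P <- matrix(0, k, k, dimnames = list(rec, rec))
  for (i in seq_len(nrow(sub))) {
    P[sub$from[i], sub$to[i]] <- P[sub$from[i], sub$to[i]] + sub$prob[i]
  }
  # pi (P - I) = 0 with sum(pi) = 1, solved as an augmented linear system.
  A <- rbind(t(P) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_rec <- as.numeric(qr.solve(A, b))
  pi_rec[pi_rec < 0 & pi_rec > -1e-12] <- 0
  pi_rec <- pi_rec / sum(pi_rec)
  pi_full <- stats::setNames(rep(0, length(m$states)), m$states)
  pi_full[rec] <- pi_rec
  pi_full
}

#' Track the hidden state along an observed sequence
#'
#' Walks the sequence maintaining the set of machine states consistent with
#' the observed suffix (starting from all recurrent states). The
#' synchronization index is the first position at which that set has
#' collapsed to a single state; from then on each position carries the
#' unique state occupied *before* its symbol is observed, which is the
#' state used to score that symbol. If an observation has no outgoing edge
#' from any consistent state, the position is flagged desynchronized and
#' filtering restarts from the full state set.
#'
#' @param m A valid `epsilon_machine`.
#' @param seq A [binary_sequence] (or 0/1 vector).
#' @return A list with `pre_state` (state before each observation; NA while
#'   ambiguous), `post_state` (state after each observation; NA while
#'   ambiguous), `sync` (first 1-based position whose pre-observation state
#'   is unique, NA if never), and `desync` (logical flags).
#' @export
filter_states <- function(m, seq) {
  seq <- as_binary_sequence(seq)
  x <- seq$symbols
  n <- length(x)
  mm <- machine_matrices(m)
  st <- m$states
  rec_idx <- which(m$recurrent[st])
  if (length(rec_idx) == 0) rec_idx <- seq_along(st)
  pidx <- mm$prob
  didx <- matrix(match(mm$dest, st), nrow(mm$dest), 2)
  pre <- rep(NA_character_, n)
  post <- rep(NA_character_, n)
  desync <- logical(n)
  sync <- NA_integer_
  S <- rec_idx
  for (i in seq_len(n)) {
    if (length(S) == 1L) {
      pre[i] <- st[S]
      if (is.na(sync)) sync <- i
    }
    col <- x[i] + 1L
    keep <- S[pidx[S, col] > 0]
    if (length(keep) == 0L) {
      desync[i] <- TRUE
      S <- rec_idx
      next
    }
    S <- unique(didx[keep, col])
    if (length(S) == 1L) post[i] <- st[S]
  }
  list(pre_state = pre, post_state = post, sync = sync, desync = desync)
}

#' Per-symbol log loss of a machine on a sequence
#'
#' Mean of \eqn{-\log_2 P(x_t \mid s_t)} over the positions scored after
#' synchronization, where \eqn{s_t} is the unique filtered state before
#' observing \eqn{x_t}. Probabilities below `floor` are floored so that
#' unseen events give finite loss; desynchronized positions are excluded
#' and filtering restarts. Used to compare candidate maximum history
#' lengths on held-out data.
#'
#' @param m A valid `epsilon_machine`.
#' @param seq A [binary_sequence] (or 0/1 vector).
#' @param floor Probability floor for scoring (default `1e-6`).
#' @return List with `bits_per_symbol` and `n_scored`.
#' @export
sequence_log_loss <- function(m, seq, floor = 1e-6) {
  seq <- as_binary_sequence(seq)
  x <- seq$symbols
  f <- filter_states(m, seq)
  mm <- machine_matrices(m)
  scored <- !is.na(f$pre_state) & !f$desync
  if (!any(scored)) {
    stop("sequence never synchronizes with the machine; ",
         "use more data or a smaller model")
  }
  idx <- which(scored)
  p <- mm$prob[cbind(match(f$pre_state[idx], m$states), x[idx] + 1L)]
  p <- pmax(p, floor)
  list(bits_per_symbol = mean(-log2(p)), n_scored = length(idx))
}

#' Simulate a sequence from an epsilon-machine
#'
#' Draws the start state from the stationary distribution, then repeatedly
#' samples an emitted symbol from the current state's edge probabilities
#' and follows the unifilar transition.
#'
#' @param m A valid `epsilon_machine`.
#' @param n Sequence length, at least 1.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so cohort generation stays reproducible from one master seed).
#' @param user_id Label for the returned sequence.
#' @return A [binary_sequence] of length `n`.
#' @export
simulate_machine <- function(m, n, seed = NULL, user_id = NA_character_) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  mm <- machine_matrices(m)
  st <- m$states
  p1 <- mm$prob[, "1"]
  d0 <- match(mm$dest[, "0"], st)
  d1 <- match(mm$dest[, "1"], st)
  pi0 <- stationary_distribution(m)[st]
  s <- sample.int(length(st), 1L, prob = pi0)
  u <- stats::runif(n)
  x <- integer(n)
  for (i in seq_len(n)) {
    if (u[i] < p1[s]) {
      x[i] <- 1L
      s <- d1[s]
    } else {
      s <- d0[s]
    }
    if (is.na(s)) stop("simulation reached a state with no matching edge")
  }
  binary_sequence(x, user_id)
}

#' State reached after an observed suffix
#'
#' For a machine estimated by CSSR (which records the map from observed
#' length-`lmax` histories to states), returns the state that pasts ending
#' in `suffix` lead to, by a count-weighted majority over the matching
#' histories. This is how a named role ("the state reached after two
#' consecutive 1s") is read off an estimated model.
#'
#' @param m An `epsilon_machine` with history metadata.
#' @param suffix Character string of 0/1 symbols, most recent last.
#' @return A state id.
#' @export
state_after <- function(m, suffix) {
  hm <- m$meta$history_map
  if (is.null(hm)) stop("machine carries no history map (not CSSR-estimated)")
  hc <- m$meta$history_count
  hs <- names(hm)
  hit <- endsWith(hs, suffix)
  hit <- hit & !is.na(hm)
  if (!any(hit)) stop("no observed history ends with '", suffix, "'")
  w <- hc[hs[hit]]
  tab <- tapply(w, hm[hit], sum)
  names(tab)[which.max(tab)]
}
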