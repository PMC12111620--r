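#' CSSR configuration
#'
#' Parameters of the Causal State Splitting Reconstruction algorithm.
#'
#' @param alpha Significance level of the state-splitting test; histories
#'   are placed in different states when their next-symbol distributions
#'   differ at p < `alpha`. Default 0.001.
#' @param lmax Maximum history length (sliding-window length minus one);
#'   positive integer.
#' @param min_count Minimum number of observed continuations needed before
#'   a history is tested; histories with fewer inherit their parent's
#'   state. Default 5.
#' @param smoothing_floor Probability floor used when scoring held-out
#'   data. Default `1e-6`.
#' @return A list of class `cssr_config`.
#' @export
cssr_config <- function(alpha = 0.001, lmax = 3L, min_count = 5L,
                        smoothing_floor = 1e-6) {
  stopifnot(alpha > 0, alpha < 1, lmax >= 1, min_count >= 1,
            smoothing_floor > 0)
  structure(list(alpha = alpha, lmax = as.integer(lmax),
                 min_count = as.integer(min_count),
                 smoothing_floor = smoothing_floor),
            class = "cssr_config")
}

#' Sliding-window subsequence counts
#'
#' Counts every subsequence of length 1 to `lmax + 1` in the sequence with
#' an overlapping sliding window. These counts are the sufficient
#' statistics for CSSR: the conditional next-symbol distribution of a
#' history of length k is read off the length-(k+1) table.
#'
#' @param seq A [binary_sequence] (or 0/1 vector).
#' @param lmax Maximum history length; the sequence must be longer than
#'   `lmax + 1`.
#' @return An object of class `history_counts`: a list of named count
#'   vectors `tab[[k]]` (words of length k), plus `n` and `lmax`.
#' @export
count_histories <- function(seq, lmax) {
  seq <- as_binary_sequence(seq)
  n <- length(seq$symbols)
  lmax <- as.integer(lmax)
  if (lmax < 1L) stop("lmax must be >= 1")
  if (n <= lmax + 1L) {
    stop("sequence of length ", n, " is too short for lmax = ", lmax,
         "; use a smaller lmax")
  }
  s <- paste(seq$symbols, collapse = "")
  tab <- vector("list", lmax + 1L)
  for (k in seq_len(lmax + 1L)) {
    words <- substring(s, 1:(n - k + 1L), k:n)
    tab[[k]] <- table(words)
  }
  structure(list(tab = tab, n = n, lmax = lmax), class = "history_counts")
}

word_count <- function(counts, w) {
  k <- nchar(w)
  if (k == 0L || k > length(counts$tab)) return(0L)
  v <- counts$tab[[k]][w]
  if (is.na(v)) 0L else as.integer(v)
}

# Counts of the two one-symbol continuations of a history (the empty
# history's continuations are the single-symbol marginals).
next_counts <- function(counts, history) {
  c(`0` = word_count(counts, paste0(history, "0")),
    `1` = word_count(counts, paste0(history, "1")))
}

#' Next-symbol distribution of a history
#'
#' Maximum-likelihood estimate of `P(next symbol | history)` together with
#' the number of observed continuations it is based on.
#'
#' @param counts A [count_histories()] object.
#' @param history Character string of 0/1 symbols, most recent last; the
#'   empty string gives the marginal next-symbol frequency.
#' @return List with `dist` (named probabilities over "0", "1"), `n`
#'   (support count) and `observed` (`FALSE` for a zero-count history, in
#'   which case `dist` is `NA`).
#' @export
next_distribution <- function(counts, history) {
  if (nchar(history) > counts$lmax) {
    stop("history longer than lmax = ", counts$lmax)
  }
  nc <- next_counts(counts, history)
  n <- sum(nc)
  if (n == 0L) {
    return(list(dist = c(`0` = NA_real_, `1` = NA_real_), n = 0L,
                observed = FALSE))
  }
  list(dist = nc / n, n = n, observed = TRUE)
}

# Two-sample Pearson chi-square on next-symbol count vectors. Columns with
# zero total are dropped; with fewer than two informative columns (both
# samples degenerate on the same symbol) the samples are indistinguishable.
chi2_counts <- function(ca, cb, alpha) {
  M <- rbind(ca, cb)
  M <- M[, colSums(M) > 0, drop = FALSE]
  if (ncol(M) < 2L || any(rowSums(M) == 0)) {
    return(list(same = TRUE, p = 1, statistic = 0))
  }
  E <- outer(rowSums(M), colSums(M)) / sum(M)
  X2 <- sum((M - E)^2 / E)
  p <- stats::pchisq(X2, df = (nrow(M) - 1L) * (ncol(M) - 1L),
                     lower.tail = FALSE)
  list(same = p >= alpha, p = p, statistic = X2)
}

#' Two-sample splitting test
#'
#' Pearson chi-square test of whether two next-symbol distributions could
#' come from the same predictive state; CSSR splits a history off its
#' state when this test rejects at level `alpha`.
#'
#' @param dist_a,dist_b Next-symbol distributions (probabilities over 0/1).
#' @param n_a,n_b Their support counts.
#' @param alpha Significance level.
#' @return List with `decision` ("same" or "different"), `p`, and
#'   `statistic`.
#' @export
split_test <- function(dist_a, n_a, dist_b, n_b, alpha = 0.001) {
  stopifnot(n_a >= 1, n_b >= 1)
  ca <- round(dist_a * n_a)
  cb <- round(dist_b * n_b)
  r <- chi2_counts(ca, cb, alpha)
  list(decision = if (r$same) "same" else "different", p = r$p,
       statistic = r$statistic)
}

# Pooled next-symbol counts of a state's member histories, optionally
# excluding one history (the one being tested against the pool).
state_pool <- function(members, counts, exclude = NULL) {
  members <- setdiff(members, exclude)
  tot <- c(`0` = 0L, `1` = 0L)
  for (h in members) tot <- tot + next_counts(counts, h)
  tot
}

#' CSSR phase one: weakly prescient states
#'
#' Starting from a single state holding the empty history, histories are
#' grown one symbol into the past, level by level, up to length `lmax`.
#' Each sufficiently supported extension is tested against its parent
#' state's pooled next-symbol distribution; on rejection it is tested
#' against every other state and joins the best-matching non-rejecting
#' one (largest p-value), or founds a new state if all reject. Each level
#' is iterated to a fixed point so that assignments settle after pooled
#' distributions change. Extensions with fewer than `min_count`
#' continuations inherit the parent's state untested.
#'
#' @param counts A [count_histories()] object built with `cfg$lmax`.
#' @param cfg A [cssr_config()].
#' @return A list of class `cssr_states`: per state, `histories`,
#'   pooled `counts`, and the predictive distribution `dist`.
#' @export
cssr_phase1 <- function(counts, cfg) {
  stopifnot(inherits(counts, "history_counts"), inherits(cfg, "cssr_config"))
  lmax <- counts$lmax
  # history keys are "."-prefixed so the empty history is indexable
  members <- list(`1` = "")           # state id -> member histories
  assignment <- c(`.` = 1L)
  next_id <- 2L
  for (L in 0:(lmax - 1L)) {
    for (iter in seq_len(100L)) {
      changed <- FALSE
      level <- sort(substring(
        names(assignment)[nchar(names(assignment)) == L + 1L], 2L))
      for (h in level) {
        for (a in c("0", "1")) {
          child <- paste0(a, h)
          nc <- next_counts(counts, child)
          if (sum(nc) == 0L) next
          parent_state <- as.character(assignment[[paste0(".", h)]])
          cur <- if (paste0(".", child) %in% names(assignment)) {
            as.character(assignment[[paste0(".", child)]])
          } else NA_character_
          if (sum(nc) < cfg$min_count) {
            target <- parent_state
          } else {
            pool <- state_pool(members[[parent_state]], counts, child)
            if (sum(pool) == 0L) {
              target <- parent_state
            } else {
              r <- chi2_counts(nc, pool, cfg$alpha)
              if (r$same) {
                target <- parent_state
              } else {
                target <- NA_character_
                best_p <- -1
                for (sid in setdiff(names(members), parent_state)) {
                  pool_s <- state_pool(members[[sid]], counts, child)
                  if (sum(pool_s) == 0L) next
                  rs <- chi2_counts(nc, pool_s, cfg$alpha)
                  if (rs$same && rs$p > best_p) {
                    target <- sid
                    best_p <- rs$p
                  }
                }
                if (is.na(target)) {
                  if (!is.na(cur) && length(members[[cur]]) == 1L &&
                      members[[cur]][1L] == child) {
                    target <- cur   # already alone in its own state
                  } else {
                    target <- as.character(next_id)
                    members[[target]] <- character(0)
                    next_id <- next_id + 1L
                  }
                }
              }
            }
          }
          if (is.na(cur) || cur != target) {
            if (!is.na(cur)) {
              members[[cur]] <- setdiff(members[[cur]], child)
            }
            members[[target]] <- c(members[[target]], child)
            assignment[paste0(".", child)] <- as.integer(target)
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    members <- members[vapply(members, length, 1L) > 0]
  }
  # prune vestigial states: a state survives only if some member is not
  # fully refined into other states (full-length member, a member with an
  # observed child in the same state, or an unextendable member)
  alive <- vapply(names(members), function(sid) {
    any(vapply(members[[sid]], function(h) {
      if (nchar(h) == lmax) return(TRUE)
      kids <- paste0(c("0", "1"), h)
      kids <- kids[vapply(kids, function(k) {
        sum(next_counts(counts, k)) > 0
      }, TRUE)]
      if (length(kids) == 0L) return(TRUE)
      any(kids %in% members[[sid]])
    }, TRUE))
  }, TRUE)
  members <- members[alive]
  states <- lapply(members, function(hs) {
    pool <- state_pool(hs, counts)
    list(histories = sort(hs), counts = pool,
         dist = if (sum(pool) > 0) pool / sum(pool) else pool)
  })
  structure(unname(states), class = "cssr_states")
}

# Greedy compatibility grouping of successor profiles; NA entries act as
# wildcards and are merged into the first compatible group.
group_by_profile <- function(profiles) {
  n <- nrow(profiles)
  group <- integer(n)
  reps <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (g in seq_along(reps)) {
      r <- reps[[g]]
      def <- !is.na(r) & !is.na(profiles[i, ])
      if (!any(def) || all(r[def] == profiles[i, def])) {
        r[is.na(r)] <- profiles[i, is.na(r)]
        reps[[g]] <- r
        group[i] <- g
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- profiles[i, ]
      group[i] <- length(reps)
    }
  }
  group
}

#' CSSR phase two: determinization and transient removal
#'
#' Works on the partition of the observed length-`lmax` histories implied
#' by phase one. States are split until they are unifilar: all member
#' histories must lead, for each emitted symbol, to the same successor
#' state (the successor of history h under symbol a is the state of the
#' length-`lmax` suffix of h+a). Transition probabilities are pooled
#' maximum-likelihood estimates over the member histories; finally the
#' machine is restricted to the terminal strongly connected component of
#' its transition graph.
#'
#' @param states Output of [cssr_phase1()].
#' @param counts The same [count_histories()] object.
#' @param cfg The [cssr_config()] used throughout.
#' @return A valid `epsilon_machine` carrying the history-to-state map in
#'   its `meta`.
#' @export
cssr_phase2 <- function(states, counts, cfg) {
  lmax <- counts$lmax
  assign_l <- integer(0)
  for (i in seq_along(states)) {
    hs <- states[[i]]$histories
    hs <- hs[nchar(hs) == lmax]
    if (length(hs) > 0) {
      assign_l[hs] <- i
    }
  }
  if (length(assign_l) == 0L) {
    stop("no history of length lmax was observed; sequence too short")
  }
  hists <- sort(names(assign_l))
  assign_l <- assign_l[hists]
  succ_of <- function(h, a) {
    if (word_count(counts, paste0(h, a)) == 0L) return(NA_integer_)
    suf <- substr(paste0(h, a), 2L, lmax + 1L)
    v <- assign_l[suf]
    if (is.na(v)) NA_integer_ else as.integer(v)
  }
  next_group <- max(assign_l) + 1L
  repeat {
    changed <- FALSE
    for (sid in unique(assign_l)) {
      mem <- hists[assign_l == sid]
      if (length(mem) <= 1L) next
      prof <- cbind(vapply(mem, succ_of, 1L, a = "0"),
                    vapply(mem, succ_of, 1L, a = "1"))
      grp <- group_by_profile(prof)
      if (max(grp) > 1L) {
        for (g in 2:max(grp)) {
          assign_l[mem[grp == g]] <- next_group
          next_group <- next_group + 1L
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # canonical state names, ordered by lexicographically smallest member
  sids <- unique(assign_l)
  first_member <- vapply(sids, function(s) min(hists[assign_l == s]), "")
  sids <- sids[order(first_member)]
  sname <- stats::setNames(paste0("s", seq_along(sids)), sids)
  edges <- NULL
  for (sid in sids) {
    mem <- hists[assign_l == sid]
    n_a <- c(`0` = 0L, `1` = 0L)
    to_a <- c(`0` = NA_integer_, `1` = NA_integer_)
    for (a in c("0", "1")) {
      n_a[a] <- sum(vapply(mem, function(h) {
        word_count(counts, paste0(h, a))
      }, 1L))
      sv <- unique(stats::na.omit(vapply(mem, succ_of, 1L, a = a)))
      if (length(sv) >= 1L) to_a[a] <- sv[1L]
    }
    # drop continuations whose successor window was never completed
    # (boundary effect of at most one count per history)
    usable <- n_a > 0 & !is.na(to_a)
    tot <- sum(n_a[usable])
    if (tot == 0L) next
    for (a in c("0", "1")[usable]) {
      edges <- rbind(edges, data.frame(
        from = sname[as.character(sid)], symbol = as.integer(a),
        prob = n_a[a] / tot, to = sname[as.character(to_a[a])],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges)) stop("no transitions could be estimated")
  # transient removal: keep the terminal strongly connected component
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = unique(c(edges$from, edges$to)),
                          stringsAsFactors = FALSE))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  terminal <- rep(TRUE, comp$no)
  cf <- memb[edges$from]; ct <- memb[edges$to]
  terminal[unique(cf[cf != ct])] <- FALSE
  term_ids <- which(terminal)
  if (length(term_ids) == 0L) stop("empty recurrent component")
  if (length(term_ids) > 1L) {
    # several absorbing components: keep the most visited one
    weight <- vapply(term_ids, function(ci) {
      sts <- names(memb)[memb == ci]
      sum(vapply(hists[sname[as.character(assign_l)] %in% sts],
                 function(h) sum(next_counts(counts, h)), 1L))
    }, 1)
    term_ids <- term_ids[which.max(weight)]
  }
  keep <- names(memb)[memb %in% term_ids]
  edges <- edges[edges$from %in% keep & edges$to %in% keep, , drop = FALSE]
  # renormalize any row that lost boundary mass
  for (s in unique(edges$from)) {
    rows <- edges$from == s
    edges$prob[rows] <- edges$prob[rows] / sum(edges$prob[rows])
  }
  hmap <- sname[as.character(assign_l)]
  hmap[!(hmap %in% keep)] <- NA_character_
  names(hmap) <- hists
  hcount <- vapply(hists, function(h) sum(next_counts(counts, h)), 1)
  # relabel kept states in canonical order s1..sk
  keep_sorted <- sort(unique(edges$from))
  relabel <- stats::setNames(paste0("s", seq_along(keep_sorted)), keep_sorted)
  edges$from <- relabel[edges$from]
  edges$to <- relabel[edges$to]
  hmap[!is.na(hmap)] <- relabel[hmap[!is.na(hmap)]]
  st <- sort(unique(c(edges$from, edges$to)))
  epsilon_machine(edges, states = st,
                  recurrent = stats::setNames(rep(TRUE, length(st)), st),
                  meta = list(history_map = hmap, history_count = hcount,
                              lmax = lmax, alpha = cfg$alpha))
}

#' Estimate an epsilon-machine from one sequence
#'
#' Full CSSR reconstruction: sliding-window counting, phase-one state
#' splitting, phase-two determinization and transient removal.
#'
#' @param seq A [binary_sequence] (or 0/1 vector).
#' @param cfg A [cssr_config()] fixing `alpha`, `lmax`, `min_count`.
#' @return A valid `epsilon_machine`.
#' @examples
#' \donttest{
#' x <- simulate_machine(fixture_machine_2state(), 5e4, seed = 1)
#' m <- estimate_machine(x, cssr_config(lmax = 2))
#' n_states(m)
#' }
#' @export
estimate_machine <- function(seq, cfg = cssr_config()) {
  counts <- count_histories(seq, cfg$lmax)
  states <- cssr_phase1(counts, cfg)
  cssr_phase2(states, counts, cfg)
}

#' Select the maximum history length by held-out log loss
#'
#' Splits the sequence in half, fits a machine on the first half at each
#' candidate `lmax`, scores it on the second half, and returns the
#' candidate with the smallest held-out log loss (ties going to the
#' smallest candidate). Candidates that cannot be fit are recorded with
#' loss `Inf`.
#'
#' @param seq A [binary_sequence] (or 0/1 vector).
#' @param candidates Integer vector of candidate history lengths
#'   (default 1..6).
#' @param cfg A [cssr_config()]; its `lmax` field is overridden per
#'   candidate.
#' @param tol Parsimony tolerance in bits/symbol: the smallest candidate
#'   whose held-out loss is within `tol` of the minimum is selected, so a
#'   longer memory must buy a real improvement (default 0.005).
#' @return List with `lmax` (the selected value) and `table` (a data
#'   frame of candidate, held-out loss in bits/symbol, and state count).
#' @export
select_lmax <- function(seq, candidates = 1:6, cfg = cssr_config(),
                        tol = 0.005) {
  seq <- as_binary_sequence(seq)
  stopifnot(length(candidates) >= 1)
  candidates <- sort(as.integer(candidates))
  n <- length(seq$symbols)
  half <- n %/% 2L
  train <- binary_sequence(seq$symbols[1:half], seq$user_id)
  test <- binary_sequence(seq$symbols[(half + 1L):n], seq$user_id)
  loss <- rep(Inf, length(candidates))
  nst <- rep(NA_integer_, length(candidates))
  for (i in seq_along(candidates)) {
    res <- tryCatch({
      cfg_i <- cssr_config(alpha = cfg$alpha, lmax = candidates[i],
                           min_count = cfg$min_count,
                           smoothing_floor = cfg$smoothing_floor)
      m <- estimate_machine(train, cfg_i)
      list(loss = sequence_log_loss(m, test,
                                    cfg$smoothing_floor)$bits_per_symbol,
           k = n_states(m))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      loss[i] <- res$loss
      nst[i] <- res$k
    }
  }
  if (all(!is.finite(loss))) stop("no candidate lmax could be fit")
  list(lmax = candidates[which(loss <= min(loss) + tol)[1]],
       table = data.frame(lmax = candidates, loss = loss,
                          n_states = nst))
}
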