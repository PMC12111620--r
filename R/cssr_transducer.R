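#' Sliding-window counts over joint (input, output) words
#'
#' Counts overlapping joint subsequences of the aligned pair, each joint
#' symbol being the (input, output) combination at one step, for word
#' lengths 1 to `lmax + 1`. The conditional distribution
#' `P(next output | joint history, next input)` is read off these tables.
#'
#' @param pair An [io_pair].
#' @param lmax Maximum joint history length.
#' @return An object of class `joint_history_counts`.
#' @export
count_joint_histories <- function(pair, lmax) {
  stopifnot(inherits(pair, "io_pair"))
  lmax <- as.integer(lmax)
  if (lmax < 1L) stop("lmax must be >= 1")
  codes <- joint_codes(pair)
  n <- length(codes)
  if (n <= lmax + 1L) {
    stop("pair of length ", n, " is too short for lmax = ", lmax)
  }
  s <- paste(codes, collapse = "")
  tab <- vector("list", lmax + 1L)
  for (k in seq_len(lmax + 1L)) {
    words <- substring(s, 1:(n - k + 1L), k:n)
    tab[[k]] <- table(words)
  }
  structure(list(tab = tab, n = n, lmax = lmax),
            class = "joint_history_counts")
}

joint_word_count <- function(counts, w) {
  k <- nchar(w)
  if (k == 0L || k > length(counts$tab)) return(0L)
  v <- counts$tab[[k]][w]
  if (is.na(v)) 0L else as.integer(v)
}

# 2x2 matrix of continuation counts for a joint history: rows = next
# input (0/1), columns = next output (0/1).
joint_next_counts <- function(counts, history) {
  m <- matrix(0L, 2, 2, dimnames = list(input = c("0", "1"),
                                        output = c("0", "1")))
  for (y in 0:1) {
    for (x in 0:1) {
      m[y + 1L, x + 1L] <- joint_word_count(
        counts, paste0(history, joint_code_of(y, x)))
    }
  }
  m
}

joint_state_pool <- function(members, counts, exclude = NULL) {
  members <- setdiff(members, exclude)
  tot <- matrix(0L, 2, 2)
  for (h in members) tot <- tot + joint_next_counts(counts, h)
  tot
}

# Equivalence test of a joint history against a state pool: the history
# must agree with the pool's input-conditional output distribution for
# every next-input value with sufficient support, Bonferroni-corrected
# across the two input symbols. Returns the smallest p over the testable
# rows as the match score.
joint_equiv_test <- function(child_counts, pool_counts, alpha, min_count) {
  p_min <- Inf
  tested <- FALSE
  for (y in 1:2) {
    if (sum(child_counts[y, ]) < min_count) next
    if (sum(pool_counts[y, ]) == 0L) next
    r <- chi2_counts(child_counts[y, ], pool_counts[y, ], alpha / 2)
    tested <- TRUE
    p_min <- min(p_min, r$p)
  }
  if (!tested) return(list(same = TRUE, p = 1, tested = FALSE))
  list(same = p_min >= alpha / 2, p = p_min, tested = TRUE)
}

transducer_phase1 <- function(counts, cfg) {
  lmax <- counts$lmax
  # history keys are "."-prefixed so the empty history is indexable
  members <- list(`1` = "")
  assignment <- c(`.` = 1L)
  next_id <- 2L
  code_chars <- c("0", "1", "2", "3")
  for (L in 0:(lmax - 1L)) {
    for (iter in seq_len(100L)) {
      changed <- FALSE
      level <- sort(substring(
        names(assignment)[nchar(names(assignment)) == L + 1L], 2L))
      for (h in level) {
        for (z in code_chars) {
          child <- paste0(z, h)
          nc <- joint_next_counts(counts, child)
          if (sum(nc) == 0L) next
          parent_state <- as.character(assignment[[paste0(".", h)]])
          cur <- if (paste0(".", child) %in% names(assignment)) {
            as.character(assignment[[paste0(".", child)]])
          } else NA_character_
          if (sum(nc) < cfg$min_count) {
            target <- parent_state
          } else {
            pool <- joint_state_pool(members[[parent_state]], counts, child)
            r <- joint_equiv_test(nc, pool, cfg$alpha, cfg$min_count)
            if (r$same) {
              target <- parent_state
            } else {
              target <- NA_character_
              best_p <- -1
              for (sid in setdiff(names(members), parent_state)) {
                pool_s <- joint_state_pool(members[[sid]], counts, child)
                if (sum(pool_s) == 0L) next
                rs <- joint_equiv_test(nc, pool_s, cfg$alpha, cfg$min_count)
                if (rs$same && rs$tested && rs$p > best_p) {
                  target <- sid
                  best_p <- rs$p
                }
              }
              if (is.na(target)) {
                if (!is.na(cur) && length(members[[cur]]) == 1L &&
                    members[[cur]][1L] == child) {
                  target <- cur
                } else {
                  target <- as.character(next_id)
                  members[[target]] <- character(0)
                  next_id <- next_id + 1L
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
  alive <- vapply(names(members), function(sid) {
    any(vapply(members[[sid]], function(h) {
      if (nchar(h) == lmax) return(TRUE)
      kids <- paste0(code_chars, h)
      kids <- kids[vapply(kids, function(k) {
        sum(joint_next_counts(counts, k)) > 0
      }, TRUE)]
      if (length(kids) == 0L) return(TRUE)
      any(kids %in% members[[sid]])
    }, TRUE))
  }, TRUE)
  members[alive]
}

transducer_phase2 <- function(members, counts, cfg) {
  lmax <- counts$lmax
  assign_l <- integer(0)
  ids <- names(members)
  for (i in seq_along(members)) {
    hs <- members[[i]][nchar(members[[i]]) == lmax]
    if (length(hs) > 0) assign_l[hs] <- i
  }
  if (length(assign_l) == 0L) {
    stop("no joint history of length lmax was observed")
  }
  hists <- sort(names(assign_l))
  assign_l <- assign_l[hists]
  code_chars <- c("0", "1", "2", "3")
  succ_of <- function(h, z) {
    if (joint_word_count(counts, paste0(h, z)) == 0L) return(NA_integer_)
    suf <- substr(paste0(h, z), 2L, lmax + 1L)
    v <- assign_l[suf]
    if (is.na(v)) NA_integer_ else as.integer(v)
  }
  next_group <- max(assign_l) + 1L
  repeat {
    changed <- FALSE
    for (sid in unique(assign_l)) {
      mem <- hists[assign_l == sid]
      if (length(mem) <= 1L) next
      prof <- vapply(code_chars, function(z) {
        vapply(mem, succ_of, 1L, z = z)
      }, integer(length(mem)))
      prof <- matrix(prof, nrow = length(mem))
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
  sids <- unique(assign_l)
  first_member <- vapply(sids, function(s) min(hists[assign_l == s]), "")
  sids <- sids[order(first_member)]
  sname <- stats::setNames(paste0("s", seq_along(sids)), sids)
  em <- NULL
  tr <- NULL
  unobserved <- NULL
  for (sid in sids) {
    mem <- hists[assign_l == sid]
    pool <- joint_state_pool(mem, counts)
    for (y in 0:1) {
      tot_y <- sum(pool[y + 1L, ])
      if (tot_y == 0L) {
        unobserved <- rbind(unobserved, data.frame(
          state = sname[as.character(sid)], input = y,
          stringsAsFactors = FALSE))
        next
      }
      for (x in 0:1) {
        n_yx <- pool[y + 1L, x + 1L]
        sv <- unique(stats::na.omit(
          vapply(mem, succ_of, 1L, z = joint_code_of(y, x))))
        em <- rbind(em, data.frame(
          state = sname[as.character(sid)], input = y, output = x,
          prob = n_yx / tot_y, stringsAsFactors = FALSE))
        if (n_yx > 0L && length(sv) >= 1L) {
          tr <- rbind(tr, data.frame(
            state = sname[as.character(sid)], input = y, output = x,
            to = sname[as.character(sv[1L])], stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(tr)) stop("no transitions could be estimated")
  # transient removal over the union of (input, output) edges
  verts <- unique(c(tr$state, tr$to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$state, to = tr$to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  terminal <- rep(TRUE, comp$no)
  cf <- memb[tr$state]; ct <- memb[tr$to]
  terminal[unique(cf[cf != ct])] <- FALSE
  term_ids <- which(terminal)
  if (length(term_ids) == 0L) stop("empty recurrent component")
  if (length(term_ids) > 1L) {
    weight <- vapply(term_ids, function(ci) {
      sts <- names(memb)[memb == ci]
      sum(vapply(hists[sname[as.character(assign_l)] %in% sts], function(h) {
        sum(joint_next_counts(counts, h))
      }, 1L))
    }, 1)
    term_ids <- term_ids[which.max(weight)]
  }
  keep <- names(memb)[memb %in% term_ids]
  em <- em[em$state %in% keep, , drop = FALSE]
  tr <- tr[tr$state %in% keep & tr$to %in% keep, , drop = FALSE]
  # renormalize emission rows that lost boundary mass
  key <- paste(em$state, em$input)
  for (k in unique(key)) {
    rows <- key == k
    s <- sum(em$prob[rows])
    if (s > 0) em$prob[rows] <- em$prob[rows] / s
  }
  hmap <- sname[as.character(assign_l)]
  hmap[!(hmap %in% keep)] <- NA_character_
  names(hmap) <- hists
  hcount <- vapply(hists, function(h) sum(joint_next_counts(counts, h)), 1)
  keep_sorted <- sort(unique(c(em$state, tr$state, tr$to)))
  relabel <- stats::setNames(paste0("s", seq_along(keep_sorted)), keep_sorted)
  em$state <- relabel[em$state]
  tr$state <- relabel[tr$state]
  tr$to <- relabel[tr$to]
  hmap[!is.na(hmap)] <- relabel[hmap[!is.na(hmap)]]
  if (!is.null(unobserved)) {
    unobserved <- unobserved[unobserved$state %in% names(relabel), ,
                             drop = FALSE]
    if (nrow(unobserved) > 0) unobserved$state <- relabel[unobserved$state]
  }
  epsilon_transducer(em, tr, states = sort(unique(relabel)),
                     meta = list(history_map = hmap,
                                 history_count = hcount,
                                 lmax = lmax, alpha = cfg$alpha,
                                 unobserved = unobserved))
}

#' Estimate an epsilon-transducer from an aligned pair
#'
#' CSSR generalized to joint pasts: phase one groups joint (input, output)
#' histories whose conditional next-output distributions agree for every
#' next-input value (Bonferroni across the two input symbols at level
#' `alpha`); phase two determinizes on (input, output) pairs and removes
#' transients. The emission at step t conditions on the input at step t
#' (the parent comment the reply is directed at), which temporally
#' precedes the reply.
#'
#' @param pair An [io_pair].
#' @param cfg A [cssr_config()].
#' @return A valid `epsilon_transducer`.
#' @export
estimate_transducer <- function(pair, cfg = cssr_config()) {
  counts <- count_joint_histories(pair, cfg$lmax)
  members <- transducer_phase1(counts, cfg)
  transducer_phase2(members, counts, cfg)
}

#' Select the transducer's maximum history length by held-out log loss
#'
#' Same train/test protocol as [select_lmax()], scoring with
#' [transducer_log_loss()] on the second half of the pair.
#'
#' @param pair An [io_pair].
#' @param candidates Integer candidate history lengths (default 1..6).
#' @param cfg A [cssr_config()].
#' @param tol Parsimony tolerance in bits/symbol (see [select_lmax()]).
#' @return List with `lmax` and a per-candidate `table`.
#' @export
select_lmax_transducer <- function(pair, candidates = 1:6,
                                   cfg = cssr_config(), tol = 0.005) {
  stopifnot(inherits(pair, "io_pair"), length(candidates) >= 1)
  candidates <- sort(as.integer(candidates))
  n <- length(pair$inputs)
  half <- n %/% 2L
  train <- io_pair(pair$inputs[1:half],
                   binary_sequence(pair$outputs$symbols[1:half],
                                   pair$outputs$user_id))
  test <- io_pair(pair$inputs[(half + 1L):n],
                  binary_sequence(pair$outputs$symbols[(half + 1L):n],
                                  pair$outputs$user_id))
  loss <- rep(Inf, length(candidates))
  nst <- rep(NA_integer_, length(candidates))
  for (i in seq_along(candidates)) {
    res <- tryCatch({
      cfg_i <- cssr_config(alpha = cfg$alpha, lmax = candidates[i],
                           min_count = cfg$min_count,
                           smoothing_floor = cfg$smoothing_floor)
      t <- estimate_transducer(train, cfg_i)
      list(loss = transducer_log_loss(t, test,
                                      cfg$smoothing_floor)$bits_per_symbol,
           k = length(t$states))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      loss[i] <- res$loss
      nst[i] <- res$k
    }
  }
  if (all(!is.finite(loss))) stop("no candidate lmax could be fit")
  list(lmax = candidates[which(loss <= min(loss) + tol)[1]],
       table = data.frame(lmax = candidates, loss = loss, n_states = nst))
}
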