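#' Transition-probability feature vector of a state
#'
#' The vector of next-symbol probabilities that describes a state's
#' predictive role, used as coordinates when aligning states across
#' models: `[P(0|s), P(1|s)]` for machines and
#' `[P(0|s,in=0), P(1|s,in=0), P(0|s,in=1), P(1|s,in=1)]` for
#' transducers. Unobserved (state, input) cells are filled with 0.5 and
#' flagged via the `"imputed"` attribute.
#'
#' @param model An `epsilon_machine` or `epsilon_transducer`.
#' @param state A state id of the model.
#' @return Numeric feature vector.
#' @export
state_feature_vector <- function(model, state) {
  if (inherits(model, "epsilon_transducer")) {
    v <- numeric(4)
    imputed <- FALSE
    i <- 1L
    for (y in 0:1) {
      for (x in 0:1) {
        p <- emission_prob(model, state, y, x)
        if (is.na(p)) {
          p <- 0.5
          imputed <- TRUE
        }
        v[i] <- p
        i <- i + 1L
      }
    }
    if (imputed) attr(v, "imputed") <- TRUE
    return(v)
  }
  c(transition_prob(model, state, 0), transition_prob(model, state, 1))
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the square assignment problem with the Kuhn-Munkres potentials
#' method in O(n^3).
#'
#' @param cost Square numeric cost matrix.
#' @return List with `assignment` (column assigned to each row) and
#'   `cost` (total cost of the optimum).
#' @export
hungarian_solve <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n >= 1)
  m <- n
  # columns shifted by +1 so column 1 is the virtual root of the
  # augmenting path; p[j] = row matched to column j (0 = free)
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2L:(m + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2L:(m + 1L)) assignment[p[j]] <- j - 1L
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

#' Align a model's states to a reference model
#'
#' Builds the cost matrix of Euclidean distances between the
#' transition-probability feature vectors of the model's and the
#' reference's states and finds the minimum-total-cost bijection with the
#' Hungarian algorithm.
#'
#' @param model,reference Two models of the same class with equal state
#'   counts.
#' @return List of class `alignment_result` with `permutation` (named
#'   character: model state -> reference state), `cost` (total distance),
#'   and `cost_matrix`.
#' @export
align_states <- function(model, reference) {
  ms <- model$states
  rs <- reference$states
  if (length(ms) != length(rs)) {
    stop("state counts differ (", length(ms), " vs ", length(rs),
         "); only models with equal state counts can be aligned")
  }
  fm <- t(vapply(ms, function(s) as.numeric(state_feature_vector(model, s)),
                 numeric(length(state_feature_vector(model, ms[1])))))
  fr <- t(vapply(rs, function(s)
    as.numeric(state_feature_vector(reference, s)),
    numeric(ncol(fm))))
  k <- length(ms)
  cost <- matrix(0, k, k, dimnames = list(ms, rs))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cost[i, j] <- sqrt(sum((fm[i, ] - fr[j, ])^2))
    }
  }
  sol <- hungarian_solve(cost)
  structure(list(permutation = stats::setNames(rs[sol$assignment], ms),
                 cost = sol$cost, cost_matrix = cost),
            class = "alignment_result")
}

#' Element-wise average of aligned models
#'
#' Aligns every model to the reference (by default the first of the
#' list), then averages the aligned transition probabilities (machines)
#' or emission probabilities (transducers) element-wise. Destination
#' states are taken by majority among the aligned models; the per-edge
#' destination agreement is reported, and when agreement is below 100%
#' the result is labeled a structural summary rather than a generative
#' model (averaging over differing topologies can lose unifilarity).
#' State names are the reference's, so the roles keep their labels.
#'
#' @param models Nonempty list of models of one class with equal state
#'   counts.
#' @param reference_index Index of the reference model (default 1).
#' @return An averaged model of the same class; its `meta` carries
#'   `destination_agreement` and the logical `structural_summary`.
#' @export
average_models <- function(models, reference_index = 1L) {
  if (length(models) == 0L) stop("empty model list")
  ref <- models[[reference_index]]
  if (inherits(ref, "epsilon_transducer")) {
    return(average_transducers(models, ref))
  }
  rs <- ref$states
  k <- length(rs)
  probs <- array(0, c(length(models), k, 2),
                 dimnames = list(NULL, rs, c("0", "1")))
  dests <- array(NA_character_, c(length(models), k, 2),
                 dimnames = list(NULL, rs, c("0", "1")))
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    al <- align_states(m, ref)$permutation
    mm <- machine_matrices(m)
    for (s in m$states) {
      target <- al[[s]]
      probs[mi, target, ] <- mm$prob[s, ]
      d <- mm$dest[s, ]
      dests[mi, target, ] <- ifelse(is.na(d), NA_character_, al[d])
    }
  }
  avg <- apply(probs, c(2, 3), mean)
  agree <- NULL
  edges <- NULL
  for (s in rs) {
    row <- avg[s, ]
    if (abs(sum(row) - 1) > 1e-9) row <- row / sum(row)
    for (a in c("0", "1")) {
      if (row[a] <= 0) next
      dv <- dests[, s, a]
      dv <- dv[!is.na(dv)]
      if (length(dv) == 0L) next
      tab <- sort(table(dv), decreasing = TRUE)
      modal <- names(tab)[1L]
      agree <- rbind(agree, data.frame(
        from = s, symbol = as.integer(a),
        agreement = as.numeric(tab[1L]) / length(dv),
        stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(
        from = s, symbol = as.integer(a), prob = row[[a]], to = modal,
        stringsAsFactors = FALSE))
    }
  }
  structural <- !is.null(agree) && any(agree$agreement < 1)
  epsilon_machine(edges, states = rs,
                  meta = list(destination_agreement = agree,
                              structural_summary = structural,
                              n_averaged = length(models)))
}

average_transducers <- function(models, ref) {
  rs <- ref$states
  k <- length(rs)
  nmod <- length(models)
  probs <- array(NA_real_, c(nmod, k, 2, 2),
                 dimnames = list(NULL, rs, c("0", "1"), c("0", "1")))
  dests <- array(NA_character_, c(nmod, k, 2, 2),
                 dimnames = list(NULL, rs, c("0", "1"), c("0", "1")))
  for (mi in seq_len(nmod)) {
    t <- models[[mi]]
    al <- align_states(t, ref)$permutation
    ar <- transducer_arrays(t)
    for (s in t$states) {
      target <- al[[s]]
      probs[mi, target, , ] <- ar$prob[s, , ]
      d <- ar$dest[s, , ]
      dests[mi, target, , ] <- ifelse(is.na(d), NA_character_, al[d])
    }
  }
  em <- NULL
  tr <- NULL
  agree <- NULL
  for (s in rs) {
    for (y in c("0", "1")) {
      row <- apply(probs[, s, y, , drop = FALSE], 4, mean, na.rm = TRUE)
      if (all(is.nan(row))) next
      if (abs(sum(row) - 1) > 1e-9) row <- row / sum(row)
      for (x in c("0", "1")) {
        em <- rbind(em, data.frame(
          state = s, input = as.integer(y), output = as.integer(x),
          prob = row[[x]], stringsAsFactors = FALSE))
        dv <- dests[, s, y, x]
        dv <- dv[!is.na(dv)]
        if (length(dv) == 0L) next
        tab <- sort(table(dv), decreasing = TRUE)
        agree <- rbind(agree, data.frame(
          state = s, input = as.integer(y), output = as.integer(x),
          agreement = as.numeric(tab[1L]) / length(dv),
          stringsAsFactors = FALSE))
        tr <- rbind(tr, data.frame(
          state = s, input = as.integer(y), output = as.integer(x),
          to = names(tab)[1L], stringsAsFactors = FALSE))
      }
    }
  }
  structural <- !is.null(agree) && any(agree$agreement < 1)
  epsilon_transducer(em, tr, states = rs,
                     meta = list(destination_agreement = agree,
                                 structural_summary = structural,
                                 n_averaged = nmod))
}
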