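entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Statistical complexity of a model
#'
#' Shannon entropy (bits) of the stationary distribution over the
#' recurrent states: the minimum information a predictor must store about
#' the past to predict optimally. Zero for one-state (memoryless) models.
#'
#' @param m An `epsilon_machine` or `epsilon_transducer`.
#' @param p_input For transducers, the input-symbol probability used to
#'   weight the state chain (default 0.5).
#' @return Complexity in bits.
#' @export
statistical_complexity <- function(m, p_input = 0.5) {
  if (inherits(m, "epsilon_transducer")) {
    return(entropy_bits(transducer_stationary(m, p_input)))
  }
  pi_s <- stationary_distribution(m)
  entropy_bits(pi_s)
}

#' Entropy rate of an epsilon-machine
#'
#' The per-symbol conditional entropy of the process the machine
#' generates: \eqn{h = \sum_s \pi_s H(\text{next symbol} \mid s)}, in
#' bits per symbol. This is the irreducible unpredictability that remains
#' after the past has been fully used.
#'
#' @param m A valid `epsilon_machine`.
#' @return Entropy rate in bits per symbol.
#' @export
machine_entropy_rate <- function(m) {
  pi_s <- stationary_distribution(m)
  tr <- m$transitions
  h <- 0
  for (s in names(pi_s)[pi_s > 0]) {
    p <- tr$prob[tr$from == s]
    h <- h + pi_s[[s]] * entropy_bits(p)
  }
  h
}

#' Transducer output entropy rate
#'
#' \eqn{\sum_s \pi_s \sum_y P(y) H(\text{output} \mid s, y)}: the
#' remaining uncertainty of the output once both the hidden state and the
#' current input are known, under an i.i.d. Bernoulli input process.
#'
#' @param t A valid `epsilon_transducer`.
#' @param p_input Probability that the input is 1.
#' @return Entropy rate in bits per output symbol.
#' @export
transducer_entropy_rate <- function(t, p_input = 0.5) {
  pi_s <- transducer_stationary(t, p_input)
  ar <- transducer_arrays(t)
  py <- c(1 - p_input, p_input)
  h <- 0
  for (si in seq_along(t$states)) {
    for (yi in 1:2) {
      p <- ar$prob[si, yi, ]
      if (all(is.na(p))) next
      p[is.na(p)] <- 0
      h <- h + pi_s[si] * py[yi] * entropy_bits(p)
    }
  }
  h
}

#' Plug-in block entropy
#'
#' Shannon entropy (bits) of the empirical distribution of overlapping
#' length-`L` blocks. Alphabet-generic: accepts a [binary_sequence], an
#' integer vector, or a character vector of symbols.
#'
#' @param seq The symbol sequence.
#' @param L Block length; must not exceed the sequence length.
#' @return Block entropy `H(L)` in bits.
#' @export
block_entropy <- function(seq, L) {
  if (inherits(seq, "binary_sequence")) seq <- seq$symbols
  n <- length(seq)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (L > n) stop("block length L = ", L, " exceeds sequence length ", n)
  s <- paste(as.character(seq), collapse = "")
  step <- max(nchar(as.character(seq[1])), 1L)
  words <- substring(s, seq(1L, (n - L) * step + 1L, by = step),
                     seq(L * step, n * step, by = step))
  tab <- table(words)
  entropy_bits(as.numeric(tab) / sum(tab))
}

#' Empirical predictable information and remaining uncertainty
#'
#' Block-entropy estimators at window length `L`: with `H(L)` the plug-in
#' block entropy, the predictable information (excess entropy) is
#' `E = 2 H(L) - H(2L)` and the remaining uncertainty rate is
#' `h = (H(2L) - H(L)) / L`, i.e. the conditional entropy of the next
#' `L` symbols given the previous `L`, scaled by the window length. Tiny
#' negative plug-in artifacts are clipped to zero. When the sequence is
#' short relative to the block space (length below `10 * 4^L`) a warning
#' string is attached to the result as attribute `"warning"`.
#'
#' @param seq The symbol sequence.
#' @param L Window length, normally the model's selected `lmax`.
#' @return Named numeric vector `c(E =, h =)` in bits (h per symbol).
#' @export
empirical_E_h <- function(seq, L) {
  if (inherits(seq, "binary_sequence")) seq <- seq$symbols
  HL <- block_entropy(seq, L)
  H2L <- block_entropy(seq, 2L * L)
  E <- 2 * HL - H2L
  h <- (H2L - HL) / L
  out <- c(E = max(E, 0), h = max(h, 0))
  if (length(seq) < 10 * 4^L) {
    attr(out, "warning") <- paste0(
      "sequence length ", length(seq), " is small for block length ",
      2 * L, "; entropy estimates may be biased")
  }
  out
}

#' Information-theoretic summary of a fitted model
#'
#' Collects the population-level descriptors of one user's model: the
#' recurrent state count, the selected maximum history length, the
#' statistical complexity C of the model, and the block-entropy estimates
#' of predictable information E and remaining uncertainty h computed from
#' the data at window length `lmax`. For transducers the block entropies
#' are taken over the joint (input, output) symbol stream, so h is in
#' bits per joint symbol; the model-based output entropy rate is also
#' reported as `h_model`.
#'
#' @param model A fitted `epsilon_machine` or `epsilon_transducer`.
#' @param data The [binary_sequence] or [io_pair] the model was fit to.
#' @param lmax The maximum history length used for the fit (defaults to
#'   the model's recorded value).
#' @return An object of class `info_summary`: a list with `n_states`,
#'   `lmax`, `C`, `E`, `h`, `h_model`.
#' @export
summarize_model <- function(model, data, lmax = NULL) {
  if (is.null(lmax)) lmax <- model$meta$lmax
  if (is.null(lmax)) stop("lmax not recorded in the model; pass it")
  if (inherits(model, "epsilon_transducer")) {
    stopifnot(inherits(data, "io_pair"))
    p_in <- mean(data$inputs)
    eh <- empirical_E_h(joint_codes(data), lmax)
    out <- list(n_states = length(model$states), lmax = as.integer(lmax),
                C = statistical_complexity(model, p_in),
                E = eh[["E"]], h = eh[["h"]],
                h_model = transducer_entropy_rate(model, p_in))
  } else {
    data <- as_binary_sequence(data)
    eh <- empirical_E_h(data, lmax)
    out <- list(n_states = n_states(model), lmax = as.integer(lmax),
                C = statistical_complexity(model),
                E = eh[["E"]], h = eh[["h"]],
                h_model = machine_entropy_rate(model))
  }
  structure(out, class = "info_summary")
}

#' @export
print.info_summary <- function(x, ...) {
  cat(sprintf(
    "<info_summary> states: %d  lmax: %d  C: %.4f  E: %.4f  h: %.4f (model h: %.4f)\n",
    x$n_states, x$lmax, x$C, x$E, x$h, x$h_model))
  invisible(x)
}
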