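#' Binary behavior sequence
#'
#' Constructs an ordered sequence of binary behavior labels for one user
#' (1 = the behavior of interest, e.g. a trolling comment; 0 = its absence).
#' This is the elementary data object every model in the package is fit to.
#'
#' @param symbols Integer (or coercible) vector of 0/1 labels, in temporal
#'   order, length at least 1.
#' @param user_id Opaque user label attached to the sequence.
#' @return An object of class `binary_sequence`: a list with elements
#'   `symbols` (integer vector) and `user_id`.
#' @examples
#' s <- binary_sequence(c(0, 1, 1, 0))
#' length(s)
#' @export
binary_sequence <- function(symbols, user_id = NA_character_) {
  symbols <- as.integer(symbols)
  if (length(symbols) < 1L) {
    stop("a binary_sequence needs at least one symbol")
  }
  if (anyNA(symbols) || !all(symbols %in% c(0L, 1L))) {
    bad <- which(is.na(symbols) | !(symbols %in% c(0L, 1L)))[1L]
    stop("symbol at position ", bad, " is not 0 or 1")
  }
  structure(list(symbols = symbols, user_id = user_id),
            class = "binary_sequence")
}

#' @export
length.binary_sequence <- function(x) length(x$symbols)

#' @export
print.binary_sequence <- function(x, ...) {
  n <- length(x$symbols)
  cat("<binary_sequence>", n, "symbols, user:", x$user_id,
      "| fraction of 1s:", round(mean(x$symbols), 4), "\n")
  invisible(x)
}

# Coerce raw vectors to binary_sequence where convenient.
as_binary_sequence <- function(x, user_id = NA_character_) {
  if (inherits(x, "binary_sequence")) return(x)
  binary_sequence(x, user_id)
}

#' Aligned input-output sequence pair
#'
#' Pairs a user's behavior sequence (outputs, `Xt`) with the aligned social
#' input sequence (`Yt`, e.g. whether the parent comment being replied to is
#' itself trolling). The alignment contract is that `inputs[t]` is known
#' before `outputs[t]` is emitted: output t is a reply to input t.
#'
#' @param inputs Integer vector of 0/1 input labels.
#' @param outputs A [binary_sequence] (or 0/1 vector) of the same length.
#' @return An object of class `io_pair` with elements `inputs` and
#'   `outputs`.
#' @examples
#' p <- io_pair(c(0, 1, 0), c(0, 0, 1))
#' @export
io_pair <- function(inputs, outputs) {
  outputs <- as_binary_sequence(outputs)
  inputs <- as.integer(inputs)
  if (anyNA(inputs) || !all(inputs %in% c(0L, 1L))) {
    bad <- which(is.na(inputs) | !(inputs %in% c(0L, 1L)))[1L]
    stop("input symbol at position ", bad, " is not 0 or 1")
  }
  if (length(inputs) != length(outputs$symbols)) {
    stop("inputs (", length(inputs), ") and outputs (",
         length(outputs$symbols), ") must have equal length")
  }
  structure(list(inputs = inputs, outputs = outputs), class = "io_pair")
}

#' @export
length.io_pair <- function(x) length(x$inputs)

#' @export
print.io_pair <- function(x, ...) {
  cat("<io_pair>", length(x$inputs), "aligned steps, user:",
      x$outputs$user_id, "\n")
  invisible(x)
}

# Joint symbol coding for (input, output) pairs: code = 2*y + x, as a
# single character "0".."3". Used by the transducer reconstruction, which
# counts joint words by sliding a window over this coded stream.
joint_codes <- function(pair) {
  as.character(2L * pair$inputs + pair$outputs$symbols)
}

joint_code_of <- function(input, output) as.character(2L * input + output)

joint_code_input <- function(code) as.integer(code) %/% 2L

joint_code_output <- function(code) as.integer(code) %% 2L
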