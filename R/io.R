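#' Read a binary sequence from a text file
#'
#' Accepts two dialects: plain symbols (one character per symbol, on one
#' line or spread over several) and CSV with an `output` column (as
#' written by [write_pair_csv()]). Any character other than 0/1 is
#' rejected with its line number.
#'
#' @param path File to read.
#' @param user_id Label attached to the sequence (defaults to the file
#'   name).
#' @return A [binary_sequence].
#' @export
read_sequence <- function(path, user_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 0 && grepl(",", lines[1])) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"output" %in% names(df)) {
      stop("CSV dialect requires an 'output' column")
    }
    return(binary_sequence(df$output, user_id))
  }
  syms <- integer(0)
  for (i in seq_along(lines)) {
    ln <- gsub("[[:space:]]", "", lines[i])
    if (nchar(ln) == 0) next
    ch <- strsplit(ln, "")[[1]]
    if (!all(ch %in% c("0", "1"))) {
      bad <- which(!(ch %in% c("0", "1")))[1]
      stop("invalid symbol '", ch[bad], "' at line ", i)
    }
    syms <- c(syms, as.integer(ch))
  }
  binary_sequence(syms, user_id)
}

#' @rdname read_sequence
#' @param seq A [binary_sequence] to write as one line of 0/1 characters.
#' @export
write_sequence <- function(seq, path) {
  seq <- as_binary_sequence(seq)
  writeLines(paste(seq$symbols, collapse = ""), path)
  invisible(path)
}

#' Read or write an aligned input-output pair as CSV
#'
#' Columns `t` (strictly increasing time index), `input`, `output`.
#'
#' @param path File path.
#' @param user_id Label for the output sequence.
#' @return `read_pair_csv` returns an [io_pair].
#' @export
read_pair_csv <- function(path, user_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "input", "output")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(diff(df$t) <= 0)) {
    stop("column t must be strictly increasing")
  }
  io_pair(df$input, binary_sequence(df$output, user_id))
}

#' @rdname read_pair_csv
#' @param pair An [io_pair] to write.
#' @export
write_pair_csv <- function(pair, path) {
  stopifnot(inherits(pair, "io_pair"))
  utils::write.csv(data.frame(t = seq_along(pair$inputs),
                              input = pair$inputs,
                              output = pair$outputs$symbols),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a model to JSON
#'
#' Machines use the schema `{"states": [...], "alphabet": [0,1],
#' "transitions": [{"from":, "symbol":, "prob":, "to":}]}`; transducers
#' add an `"input"` field per transition and carry the emission
#' probability in `"prob"`. Probabilities are written with 17 significant
#' digits so a round trip is bit-exact.
#'
#' @param m The model.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
machine_to_json <- function(m, path = NULL) {
  stopifnot(inherits(m, "epsilon_machine"))
  obj <- list(states = m$states, alphabet = c(0L, 1L),
              transitions = m$transitions[, c("from", "symbol", "prob", "to")])
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = FALSE,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname machine_to_json
#' @param json JSON string or file path to parse.
#' @export
machine_from_json <- function(json) {
  txt <- if (file.exists(json[1]) && !grepl("^\\s*\\{", json[1])) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else {
    json
  }
  obj <- jsonlite::fromJSON(txt)
  for (field in c("states", "alphabet", "transitions")) {
    if (is.null(obj[[field]])) stop("machine JSON lacks field '", field, "'")
  }
  for (field in c("from", "symbol", "prob", "to")) {
    if (is.null(obj$transitions[[field]])) {
      stop("machine JSON transitions lack field '", field, "'")
    }
  }
  epsilon_machine(obj$transitions, states = obj$states)
}

#' @rdname machine_to_json
#' @export
transducer_to_json <- function(m, path = NULL) {
  stopifnot(inherits(m, "epsilon_transducer"))
  tr <- merge(m$emissions, m$transitions,
              by = c("state", "input", "output"), all.x = TRUE)
  tr <- data.frame(from = tr$state, input = tr$input, symbol = tr$output,
                   prob = tr$prob, to = tr$to, stringsAsFactors = FALSE)
  obj <- list(states = m$states, alphabet = c(0L, 1L), transitions = tr)
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = FALSE,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname machine_to_json
#' @export
transducer_from_json <- function(json) {
  txt <- if (file.exists(json[1]) && !grepl("^\\s*\\{", json[1])) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else {
    json
  }
  obj <- jsonlite::fromJSON(txt)
  for (field in c("states", "alphabet", "transitions")) {
    if (is.null(obj[[field]])) {
      stop("transducer JSON lacks field '", field, "'")
    }
  }
  tr <- obj$transitions
  for (field in c("from", "input", "symbol", "prob", "to")) {
    if (is.null(tr[[field]])) {
      stop("transducer JSON transitions lack field '", field, "'")
    }
  }
  em <- data.frame(state = tr$from, input = tr$input, output = tr$symbol,
                   prob = tr$prob, stringsAsFactors = FALSE)
  trans <- data.frame(state = tr$from, input = tr$input, output = tr$symbol,
                      to = tr$to, stringsAsFactors = FALSE)
  trans <- trans[!is.na(trans$to), , drop = FALSE]
  epsilon_transducer(em, trans, states = obj$states)
}

#' Export a model as a Graphviz DOT graph
#'
#' One edge per transition, labeled `"symbol: prob"` for machines and
#' `"output|input: prob"` for transducers (the number before the colon is
#' the emitted behavior).
#'
#' @param m The model.
#' @param path Optional output file.
#' @return The DOT source as a character string (invisibly if written).
#' @export
dot_export <- function(m, path = NULL) {
  q <- function(s) paste0("\"", s, "\"")
  if (inherits(m, "epsilon_transducer")) {
    tr <- merge(m$emissions, m$transitions,
                by = c("state", "input", "output"))
    lines <- sprintf("  %s -> %s [label=\"%d|%d: %.2f\"];",
                     q(tr$state), q(tr$to), tr$output, tr$input, tr$prob)
  } else {
    tr <- m$transitions
    lines <- sprintf("  %s -> %s [label=\"%d: %.2f\"];",
                     q(tr$from), q(tr$to), tr$symbol, tr$prob)
  }
  src <- c("digraph model {", "  rankdir=LR;", lines, "}")
  out <- paste(src, collapse = "\n")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
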