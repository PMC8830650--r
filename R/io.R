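# full-precision decimal text for doubles: %.17g round-trips exactly and
# is locale-independent
fmt_num <- function(x) sprintf("%.17g", x)

#' Read sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file, strips line breaks and whitespace
#' from the sequence bodies, uppercases them, and preserves the record
#' identifiers verbatim (everything after `>`). Alphabet membership is not
#' checked here -- that happens when a sequence is bound to a model with
#' [hmm_sequence()].
#'
#' @param source path to a FASTA file, or a character vector of FASTA
#'   lines.
#' @return named character vector: names are identifiers, values are the
#'   uppercased sequences, in file order.
#' @examples
#' fa <- c(">rec1", "acgt", "ACGT")
#' read_fasta(fa)
#' @export
read_fasta <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    path <- source
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(source, path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA input: ", conditionMessage(e),
                         call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA input contains no records", call. = FALSE)
  seqs <- toupper(gsub("[ \t]", "", as.character(set)))
  if (any(nchar(seqs) == 0L))
    stop("FASTA record '", names(set)[which(nchar(seqs) == 0L)[1L]],
         "' has an empty sequence", call. = FALSE)
  names(seqs) <- names(set)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (as returned by [read_fasta()]), or
#'   an [hmm_sequence()].
#' @param path output file path.
#' @param width line width for the sequence body (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is_hmm_seq(seqs)) {
    s <- as.character(seqs)
    names(s) <- "sequence"
    seqs <- s
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---- model document format -------------------------------------------------
#
# A small line-oriented text format holding the full element set of a model:
#
#   alphabet: protein            (or: custom)
#   symbols: A C D ...           (custom alphabets only)
#   states: I M O
#   prior: 0.6 0.1 0.3
#   transitions:                 (K rows, state label first)
#   I 0.98 0.02 0
#   ...
#   emissions:                   (K rows, state label first, alphabet order)
#   I 0.055 ...
#
# Numbers are written as full-precision decimal text (%.17g), so
# write -> read is an exact round trip.

#' Write an HMM to a model file
#'
#' Serializes all six model elements to a line-oriented structured text
#' document at full double precision (see [read_model()] for the format);
#' `read_model(write_model(m, f))` reproduces `m` exactly.
#'
#' @param model an [hmm_model()].
#' @param path output file path; if `NULL`, the lines are returned instead.
#' @return the file path (invisibly), or the character vector of lines if
#'   `path` is `NULL`.
#' @export
write_model <- function(model, path = NULL) {
  stopifnot(is_hmm_model(model))
  lines <- c(
    sprintf("alphabet: %s", model$alphabet$kind),
    if (model$alphabet$kind == "custom")
      sprintf("symbols: %s", paste(model$alphabet$symbols, collapse = " ")),
    sprintf("states: %s", paste(model$states, collapse = " ")),
    sprintf("prior: %s", paste(fmt_num(model$prior), collapse = " ")),
    "transitions:",
    vapply(seq_along(model$states), function(k)
      paste(c(model$states[k], fmt_num(model$transitions[k, ])),
            collapse = " "), character(1)),
    "emissions:",
    vapply(seq_along(model$states), function(k)
      paste(c(model$states[k], fmt_num(model$emissions[k, ])),
            collapse = " "), character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read an HMM from a model file
#'
#' Parses the structured text model document written by [write_model()]
#' and returns a validated model. Every missing field, ragged matrix row
#' or unknown state label is rejected with the offending field named.
#'
#' @param source path to a model file, or a character vector of its lines.
#' @param validate if `FALSE`, parse without enforcing the stochastic
#'   invariants (so the result can be inspected with [validate_hmm()]);
#'   structural parse errors are still rejected.
#' @return a validated [hmm_model()] (or, with `validate = FALSE`, an
#'   `hmm_model`-shaped object that may carry violations).
#' @export
read_model <- function(source, validate = TRUE) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) readLines(source) else source
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0L & !startsWith(lines, "#")]

  field <- function(name) {
    hit <- grep(paste0("^", name, ":"), lines)
    if (length(hit) == 0L)
      stop(sprintf("model file is missing the '%s' field", name),
           call. = FALSE)
    trimws(sub(paste0("^", name, ":"), "", lines[hit[1L]]))
  }
  split_ws <- function(s) strsplit(s, "[ \t]+")[[1]]
  parse_num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      stop(sprintf("non-numeric value in %s", what), call. = FALSE)
    v
  }

  kind <- field("alphabet")
  if (!kind %in% c("DNA", "RNA", "protein", "custom"))
    stop(sprintf("unknown alphabet kind '%s'", kind), call. = FALSE)
  alphabet <- if (kind == "custom")
    hmm_alphabet("custom", split_ws(field("symbols")))
  else hmm_alphabet(kind)

  states <- split_ws(field("states"))
  K <- length(states)
  prior <- parse_num(split_ws(field("prior")), "prior")

  read_matrix <- function(name, ncols) {
    hit <- grep(paste0("^", name, ":"), lines)
    if (length(hit) == 0L)
      stop(sprintf("model file is missing the '%s' section", name),
           call. = FALSE)
    rows <- lines[(hit[1L] + 1L):(hit[1L] + K)]
    if (length(rows) < K || any(is.na(rows)))
      stop(sprintf("'%s' section must have %d rows", name, K), call. = FALSE)
    m <- matrix(NA_real_, K, ncols)
    seen <- character(0)
    for (r in rows) {
      parts <- split_ws(r)
      lab <- parts[1L]
      if (!lab %in% states)
        stop(sprintf("unknown state label '%s' in '%s' section", lab, name),
             call. = FALSE)
      if (length(parts) - 1L != ncols)
        stop(sprintf("'%s' row '%s' has %d values, expected %d",
                     name, lab, length(parts) - 1L, ncols), call. = FALSE)
      m[match(lab, states), ] <- parse_num(parts[-1L],
                                           sprintf("'%s' row '%s'", name, lab))
      seen <- c(seen, lab)
    }
    if (length(unique(seen)) != K)
      stop(sprintf("'%s' section does not cover every state", name),
           call. = FALSE)
    m
  }
  transitions <- read_matrix("transitions", K)
  emissions <- read_matrix("emissions", length(alphabet$symbols))
  if (validate)
    return(hmm_model(alphabet, states, prior, transitions, emissions))
  dimnames(transitions) <- list(states, states)
  dimnames(emissions) <- list(states, alphabet$symbols)
  names(prior) <- states
  structure(list(alphabet = alphabet, states = states, prior = prior,
                 transitions = transitions, emissions = emissions),
            class = "hmm_model")
}

#' Read a probability matrix from a TSV file
#'
#' Classroom-friendly alternate import: a tab-separated table whose first
#' column holds row labels (state labels) and whose header names the
#' columns. Returns a plain numeric matrix for use with [hmm_model()].
#'
#' @param source path to a TSV file, or a character vector of its lines.
#' @return numeric matrix with row and column names.
#' @export
read_prob_matrix_tsv <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    df <- utils::read.delim(source, check.names = FALSE,
                            stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(textConnection(source), check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2L)
    stop("probability-matrix TSV needs a label column plus value columns",
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in probability-matrix TSV",
                           call. = FALSE)
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Export a posterior matrix as tabular text
#'
#' Writes the per-position posterior probabilities -- the data behind a
#' posterior-decoding chart -- as a TSV with one row per 1-based sequence
#' position, one column per hidden state, and a final `argmax` column.
#'
#' @param posterior an object from [hmm_posterior()] or
#'   [posterior_by_enumeration()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_posterior_tsv <- function(posterior, path) {
  stopifnot(inherits(posterior, "hmm_posterior"))
  df <- data.frame(position = seq_len(nrow(posterior$table)),
                   posterior$table, check.names = FALSE)
  df$argmax <- posterior$argmax_path
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
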