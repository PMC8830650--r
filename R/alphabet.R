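#' Observation alphabets
#'
#' An alphabet is the ordered set of symbols a hidden state can emit.
#' Three biological alphabets are built in; any other ordered set of
#' distinct single-character symbols can be supplied as `kind = "custom"`.
#'
#' @param kind one of `"DNA"`, `"RNA"`, `"protein"`, `"custom"`.
#' @param symbols for `kind = "custom"`, a character vector of distinct
#'   single-character symbols. Ignored (must be `NULL`) for the built-in
#'   kinds, whose symbol sets are fixed.
#' @return an object of class `hmm_alphabet` with elements `kind` and
#'   `symbols`.
#' @examples
#' hmm_alphabet("DNA")
#' hmm_alphabet("custom", c("H", "T"))
#' @export
hmm_alphabet <- function(kind = c("DNA", "RNA", "protein", "custom"),
                         symbols = NULL) {
  kind <- match.arg(kind)
  builtin <- list(
    DNA     = c("A", "C", "G", "T"),
    RNA     = c("A", "C", "G", "U"),
    protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  )
  if (kind == "custom") {
    if (is.null(symbols) || length(symbols) == 0L)
      stop("a custom alphabet requires a non-empty `symbols` vector",
           call. = FALSE)
    symbols <- toupper(as.character(symbols))
    if (any(nchar(symbols) != 1L))
      stop("alphabet symbols must be single characters", call. = FALSE)
    if (anyDuplicated(symbols))
      stop("alphabet symbols must be pairwise distinct: duplicated ",
           paste(unique(symbols[duplicated(symbols)]), collapse = ", "),
           call. = FALSE)
  } else {
    if (!is.null(symbols))
      stop("`symbols` can only be given for kind = \"custom\"", call. = FALSE)
    symbols <- builtin[[kind]]
  }
  structure(list(kind = kind, symbols = symbols), class = "hmm_alphabet")
}

#' @export
print.hmm_alphabet <- function(x, ...) {
  cat(sprintf("<hmm_alphabet> %s (%d symbols): %s\n",
              x$kind, length(x$symbols), paste(x$symbols, collapse = " ")))
  invisible(x)
}

is_hmm_alphabet <- function(x) inherits(x, "hmm_alphabet")

#' Observed symbol sequences
#'
#' Binds a raw character string (or vector of symbols) to an alphabet,
#' producing the query sequence for the inference algorithms. Symbols are
#' uppercased on ingestion. By default a symbol not in the alphabet is an
#' error; with `allow_unknown = TRUE` unknown symbols are kept and treated
#' by the algorithms as emitted with a uniform probability `1/|alphabet|`
#' from every hidden state.
#'
#' @param x a single string, or a character vector of single symbols.
#' @param alphabet an [hmm_alphabet()].
#' @param allow_unknown keep symbols absent from the alphabet instead of
#'   rejecting them (default `FALSE`).
#' @return an object of class `hmm_seq`: the symbol vector plus its
#'   alphabet. Positions are 1-based throughout the package.
#' @examples
#' hmm_sequence("ACGT", hmm_alphabet("DNA"))
#' @export
hmm_sequence <- function(x, alphabet, allow_unknown = FALSE) {
  stopifnot(is_hmm_alphabet(alphabet))
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  symbols <- toupper(as.character(x))
  symbols <- symbols[nchar(symbols) > 0L &
                       !symbols %in% c(" ", "\t", "\n", "\r")]
  if (length(symbols) == 0L)
    stop("observed sequence must contain at least one symbol", call. = FALSE)
  unknown <- which(!symbols %in% alphabet$symbols)
  if (length(unknown) > 0L && !allow_unknown)
    stop(sprintf(
      "symbol '%s' at position %d is not in the %s alphabet",
      symbols[unknown[1L]], unknown[1L], alphabet$kind), call. = FALSE)
  structure(
    list(symbols = symbols, alphabet = alphabet,
         allow_unknown = isTRUE(allow_unknown)),
    class = "hmm_seq")
}

#' @export
print.hmm_seq <- function(x, ...) {
  s <- paste(x$symbols, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<hmm_seq> L = %d (%s alphabet): %s\n",
              length(x$symbols), x$alphabet$kind, s))
  invisible(x)
}

#' @export
length.hmm_seq <- function(x) length(x$symbols)

#' @export
as.character.hmm_seq <- function(x, ...) paste(x$symbols, collapse = "")

is_hmm_seq <- function(x) inherits(x, "hmm_seq")
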