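# Probability rows must sum to 1 within this tolerance; there is no silent
# renormalization, so data-entry errors surface immediately.
HMM_TOL <- 1e-9

#' Build a discrete hidden Markov model
#'
#' Assembles the six elements of a discrete first-order HMM -- an
#' observation alphabet, a set of hidden states, the prior (initial)
#' probability vector, the transition matrix and the emission matrix --
#' and validates them jointly. Construction mirrors the natural modeling
#' order: alphabet, states, prior, transitions, emissions.
#'
#' @param alphabet an [hmm_alphabet()].
#' @param states character vector of distinct hidden-state labels
#'   (e.g. `c("I", "M", "O")`). State labels live in a separate namespace
#'   from observed symbols, so the two may collide.
#' @param prior numeric vector of length K: the distribution of the first
#'   hidden state.
#' @param transitions K x K numeric matrix; row k is the distribution of
#'   the next hidden state given current state k. Zero entries are allowed
#'   (they become `-Inf` in log space).
#' @param emissions K x \\|alphabet\\| numeric matrix; row k is the
#'   distribution over emitted symbols in state k.
#' @param renormalize if `TRUE`, rows that sum to a positive value are
#'   rescaled to sum to exactly 1 before validation. Off by default:
#'   surfacing normalization errors is deliberate.
#' @return a validated object of class `hmm_model`.
#' @seealso [validate_hmm()], [random_hmm()]
#' @examples
#' ab <- hmm_alphabet("custom", c("a", "b"))
#' m <- hmm_model(ab, "S", prior = 1, transitions = matrix(1),
#'                emissions = matrix(c(0.5, 0.5), 1))
#' @export
hmm_model <- function(alphabet, states, prior, transitions, emissions,
                      renormalize = FALSE) {
  stopifnot(is_hmm_alphabet(alphabet))
  states <- as.character(states)
  if (length(states) < 1L) stop("at least one hidden state is required",
                                call. = FALSE)
  if (anyDuplicated(states))
    stop("hidden-state labels must be pairwise distinct", call. = FALSE)
  K <- length(states)

  prior <- as.numeric(prior)
  transitions <- as.matrix(transitions)
  emissions <- as.matrix(emissions)
  if (isTRUE(renormalize)) {
    renorm <- function(v) if (sum(v) > 0) v / sum(v) else v
    prior <- renorm(prior)
    transitions <- t(apply(transitions, 1L, renorm))
    emissions <- t(apply(emissions, 1L, renorm))
    # t(apply()) on a 1-row matrix needs its shape restored
    if (K == 1L) {
      transitions <- matrix(transitions, nrow = 1L)
      emissions <- matrix(emissions, nrow = 1L)
    }
  }
  # label dimensions only once they are consistent; validate_hmm reports
  # mismatches either way
  if (length(prior) == K) names(prior) <- states
  if (all(dim(transitions) == c(K, K)))
    dimnames(transitions) <- list(states, states)
  if (all(dim(emissions) == c(K, length(alphabet$symbols))))
    dimnames(emissions) <- list(states, alphabet$symbols)

  model <- structure(
    list(alphabet = alphabet, states = states, prior = prior,
         transitions = transitions, emissions = emissions),
    class = "hmm_model")
  problems <- validate_hmm(model)
  if (length(problems) > 0L)
    stop("invalid HMM:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  model
}

#' Validate an HMM parameter set
#'
#' Checks every structural and stochastic invariant of a model and returns
#' a report of all violations rather than stopping at the first: dimension
#' consistency between the prior, the transition and emission matrices, the
#' state set and the alphabet; entries within \[0, 1\]; and each probability
#' row summing to 1 within tolerance `1e-9`.
#'
#' @param model an `hmm_model`, or a bare list with the same elements.
#' @return character vector of human-readable violations; empty when the
#'   model is valid.
#' @examples
#' ab <- hmm_alphabet("custom", c("a", "b"))
#' m <- hmm_model(ab, "S", 1, matrix(1), matrix(c(0.5, 0.5), 1))
#' validate_hmm(m)  # character(0)
#' @export
validate_hmm <- function(model) {
  problems <- character(0)
  note <- function(fmt, ...) problems[[length(problems) + 1L]] <<-
      sprintf(fmt, ...)

  K <- length(model$states)
  A <- length(model$alphabet$symbols)

  if (length(model$prior) != K)
    note("prior vector has length %d but there are %d hidden states",
         length(model$prior), K)
  if (!all(dim(model$transitions) == c(K, K)))
    note("transition matrix is %dx%d but must be %dx%d",
         nrow(model$transitions), ncol(model$transitions), K, K)
  if (nrow(model$emissions) != K || ncol(model$emissions) != A)
    note("emission matrix is %dx%d but must be %dx%d (states x alphabet)",
         nrow(model$emissions), ncol(model$emissions), K, A)

  check_row <- function(v, what) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      note("%s has entries outside [0, 1]", what)
    } else if (abs(sum(v) - 1) > HMM_TOL) {
      note("%s sums to %.12g (deviation %.3g from 1)", what, sum(v),
           abs(sum(v) - 1))
    }
  }
  check_row(model$prior, "prior vector")
  if (all(dim(model$transitions) == c(K, K)))
    for (k in seq_len(K))
      check_row(model$transitions[k, ],
                sprintf("transition row '%s'", model$states[k]))
  if (nrow(model$emissions) == K && ncol(model$emissions) == A)
    for (k in seq_len(K))
      check_row(model$emissions[k, ],
                sprintf("emission row '%s'", model$states[k]))
  problems
}

#' Generate a random HMM with a seed
#'
#' Draws each probability row (prior, every transition row, every emission
#' row) by normalizing independent uniform(0, 1) variates -- the flat
#' Dirichlet distribution. The generator is R's Mersenne-Twister, isolated
#' from the global RNG state; the same `(n_states, alphabet, seed)` always
#' reproduces the same model bit-for-bit.
#'
#' @param n_states number of hidden states (>= 1). Labels default to
#'   `S1 ... Sn`.
#' @param alphabet an [hmm_alphabet()].
#' @param seed integer seed; required, so that every random model is
#'   reproducible.
#' @param state_labels optional character vector of `n_states` labels.
#' @return a validated `hmm_model`.
#' @examples
#' random_hmm(3, hmm_alphabet("DNA"), seed = 7)
#' @export
random_hmm <- function(n_states, alphabet, seed, state_labels = NULL) {
  if (!is.numeric(n_states) || length(n_states) != 1L || n_states < 1 ||
      n_states != round(n_states))
    stop("`n_states` must be a single integer >= 1", call. = FALSE)
  stopifnot(is_hmm_alphabet(alphabet))
  n_states <- as.integer(n_states)
  if (is.null(state_labels)) state_labels <- paste0("S", seq_len(n_states))
  A <- length(alphabet$symbols)

  rrow <- function(n) { v <- stats::runif(n); v / sum(v) }
  params <- withr::with_seed(seed, {
    list(prior = rrow(n_states),
         transitions = t(vapply(seq_len(n_states), function(k) rrow(n_states),
                                numeric(n_states))),
         emissions = t(vapply(seq_len(n_states), function(k) rrow(A),
                              numeric(A))))
  })
  if (n_states == 1L) {
    params$transitions <- matrix(params$transitions, 1L)
    params$emissions <- matrix(params$emissions, 1L)
  }
  hmm_model(alphabet, state_labels, params$prior, params$transitions,
            params$emissions)
}

#' @export
print.hmm_model <- function(x, digits = 4, ...) {
  cat(sprintf("<hmm_model> %d hidden states over a %s alphabet (%d symbols)\n",
              length(x$states), x$alphabet$kind, length(x$alphabet$symbols)))
  cat("states:", paste(x$states, collapse = " "), "\n")
  cat("prior:\n")
  print(round(x$prior, digits))
  cat("transitions:\n")
  print(round(x$transitions, digits))
  cat("emissions:\n")
  print(round(x$emissions, digits))
  invisible(x)
}

is_hmm_model <- function(x) inherits(x, "hmm_model")

# Emission probabilities for each position of a sequence: an L x K matrix.
# Unknown symbols (allowed only on opt-in) emit uniformly at 1/|alphabet|.
emission_probs <- function(model, seq) {
  stopifnot(is_hmm_model(model), is_hmm_seq(seq))
  idx <- match(seq$symbols, model$alphabet$symbols)
  if (anyNA(idx) && !seq$allow_unknown) {
    j <- which(is.na(idx))[1L]
    stop(sprintf("symbol '%s' at position %d is not in the model alphabet",
                 seq$symbols[j], j), call. = FALSE)
  }
  K <- length(model$states)
  E <- matrix(1 / length(model$alphabet$symbols),
              nrow = length(seq$symbols), ncol = K,
              dimnames = list(NULL, model$states))
  known <- !is.na(idx)
  E[known, ] <- t(model$emissions[, idx[known], drop = FALSE])
  E
}
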