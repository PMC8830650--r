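# log-sum-exp over a vector; max-shifted so that underflow cannot occur and
# an all -Inf input stays -Inf instead of producing NaN.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log() that maps 0 to -Inf without a warning
log0 <- function(x) ifelse(x > 0, log(x), -Inf)

check_mode <- function(mode) match.arg(mode, c("log", "plain"))

result_provenance <- function(model, seq) list(model = model, seq = seq)

same_provenance <- function(res, model, seq) {
  p <- res$provenance
  isTRUE(all.equal(p$model, model)) && isTRUE(all.equal(p$seq, seq))
}

#' Forward algorithm: probability of the observed sequence
#'
#' Fills the dynamic-programming table
#' `alpha[j, k] = P(o_1 .. o_j, q_j = k)` with the recursion
#' `alpha[1, k] = prior(k) e(k, o_1)`;
#' `alpha[j, l] = e(l, o_j) * sum_k alpha[j-1, k] a(k -> l)`,
#' and returns the total sequence probability
#' `P(O) = sum_k alpha[L, k]` -- the answer to "what is the probability of
#' the observed sequence under the model?".
#'
#' The default mode works in log space (log-sum-exp for the sums), which is
#' required for realistic sequence lengths: a 100-residue protein already
#' has `P(O)` far below 1e-100. Plain mode keeps the literal probabilities
#' for readable classroom reports and underflows near L of about 1000.
#'
#' @param model an [hmm_model()].
#' @param seq an [hmm_sequence()]; every symbol must be in the model's
#'   alphabet (or the sequence built with `allow_unknown = TRUE`).
#' @param mode `"log"` (default) or `"plain"`. In log mode all stored
#'   values, including `total`, are log-probabilities.
#' @return object of class `hmm_forward`: `table` (L x K), `total`,
#'   `log_total` (always the log of P(O), whatever the mode), `mode`.
#' @examples
#' ab <- hmm_alphabet("custom", c("a", "b"))
#' m <- hmm_model(ab, "S", 1, matrix(1), matrix(c(0.5, 0.5), 1))
#' hmm_forward(m, hmm_sequence("aa", ab), mode = "plain")$total  # 0.25
#' @export
hmm_forward <- function(model, seq, mode = c("log", "plain")) {
  mode <- check_mode(mode)
  stopifnot(is_hmm_model(model), is_hmm_seq(seq))
  E <- emission_probs(model, seq)
  L <- nrow(E); K <- ncol(E)
  if (mode == "plain") {
    A <- model$transitions
    alpha <- matrix(0, L, K, dimnames = list(NULL, model$states))
    alpha[1L, ] <- model$prior * E[1L, ]
    if (L > 1L) for (j in 2:L)
      alpha[j, ] <- as.numeric(alpha[j - 1L, ] %*% A) * E[j, ]
    total <- sum(alpha[L, ])
    log_total <- log0(total)
  } else {
    lA <- log0(model$transitions)
    lE <- log0(E)
    alpha <- matrix(-Inf, L, K, dimnames = list(NULL, model$states))
    alpha[1L, ] <- log0(model$prior) + lE[1L, ]
    if (L > 1L) for (j in 2:L)
      for (l in seq_len(K))
        alpha[j, l] <- lE[j, l] + logsumexp(alpha[j - 1L, ] + lA[, l])
    total <- logsumexp(alpha[L, ])
    log_total <- total
  }
  structure(list(table = alpha, total = total, log_total = log_total,
                 mode = mode, provenance = result_provenance(model, seq)),
            class = "hmm_forward")
}

#' Backward algorithm: suffix probabilities
#'
#' Fills `beta[j, k] = P(o_{j+1} .. o_L | q_j = k)` with the recursion
#' `beta[L, k] = 1`;
#' `beta[j, k] = sum_l a(k -> l) e(l, o_{j+1}) beta[j+1, l]`,
#' and recomputes the total sequence probability from position 1:
#' `P(O) = sum_k prior(k) e(k, o_1) beta[1, k]`. Together with the forward
#' table it yields per-position state posteriors (see [hmm_posterior()]),
#' answering "what is the probability that hidden state k emitted the
#' observed symbol at position j?".
#'
#' @inheritParams hmm_forward
#' @return object of class `hmm_backward`: `table` (L x K), `total`,
#'   `log_total`, `mode`. In log mode stored values are log-probabilities
#'   (so the last row is 0, not 1).
#' @export
hmm_backward <- function(model, seq, mode = c("log", "plain")) {
  mode <- check_mode(mode)
  stopifnot(is_hmm_model(model), is_hmm_seq(seq))
  E <- emission_probs(model, seq)
  L <- nrow(E); K <- ncol(E)
  if (mode == "plain") {
    A <- model$transitions
    beta <- matrix(1, L, K, dimnames = list(NULL, model$states))
    if (L > 1L) for (j in (L - 1L):1L)
      beta[j, ] <- as.numeric(A %*% (E[j + 1L, ] * beta[j + 1L, ]))
    total <- sum(model$prior * E[1L, ] * beta[1L, ])
    log_total <- log0(total)
  } else {
    lA <- log0(model$transitions)
    lE <- log0(E)
    beta <- matrix(0, L, K, dimnames = list(NULL, model$states))
    if (L > 1L) for (j in (L - 1L):1L)
      for (k in seq_len(K))
        beta[j, k] <- logsumexp(lA[k, ] + lE[j + 1L, ] + beta[j + 1L, ])
    total <- logsumexp(log0(model$prior) + lE[1L, ] + beta[1L, ])
    log_total <- total
  }
  structure(list(table = beta, total = total, log_total = log_total,
                 mode = mode, provenance = result_provenance(model, seq)),
            class = "hmm_backward")
}

#' Viterbi algorithm: most probable hidden path
#'
#' Computes the single most probable sequence of hidden states given the
#' observations, via
#' `delta[1, k] = prior(k) e(k, o_1)`;
#' `delta[j, l] = e(l, o_j) * max_k delta[j-1, k] a(k -> l)`,
#' with traceback from `argmax_k delta[L, k]`. Ties are broken toward the
#' state earliest in the declared state order, both in the maximization and
#' in the traceback, so the output is deterministic.
#'
#' @inheritParams hmm_forward
#' @return object of class `hmm_viterbi`: `path` (character vector of L
#'   state labels), `joint` = P(Q*, O) and `conditional` = P(Q* | O)
#'   (both always on the plain probability scale; `log_joint` carries the
#'   log), `table` (the delta values in the requested mode), `traceback`
#'   (the argmax pointers), `mode`.
#' @examples
#' ab <- hmm_alphabet("custom", c("a", "b"))
#' m <- hmm_model(ab, "S", 1, matrix(1), matrix(c(0.5, 0.5), 1))
#' hmm_viterbi(m, hmm_sequence("ab", ab))$path  # "S" "S"
#' @export
hmm_viterbi <- function(model, seq, mode = c("log", "plain")) {
  mode <- check_mode(mode)
  stopifnot(is_hmm_model(model), is_hmm_seq(seq))
  E <- emission_probs(model, seq)
  L <- nrow(E); K <- ncol(E)

  # the DP itself is run in the requested mode; scores below are that mode's
  scores <- if (mode == "plain") {
    list(A = model$transitions, E = E, pri = model$prior,
         comb = `*`, dead = 0)
  } else {
    list(A = log0(model$transitions), E = log0(E), pri = log0(model$prior),
         comb = `+`, dead = -Inf)
  }
  delta <- matrix(scores$dead, L, K, dimnames = list(NULL, model$states))
  psi <- matrix(NA_integer_, L, K)
  delta[1L, ] <- scores$comb(scores$pri, scores$E[1L, ])
  if (L > 1L) for (j in 2:L) {
    for (l in seq_len(K)) {
      cand <- scores$comb(delta[j - 1L, ], scores$A[, l])
      best <- which.max(cand)  # first maximum = earliest declared state
      psi[j, l] <- best
      delta[j, l] <- scores$comb(cand[best], scores$E[j, l])
    }
  }
  if (all(delta[L, ] == scores$dead))
    stop("the model cannot emit this sequence: every hidden path has ",
         "probability zero", call. = FALSE)
  path_idx <- integer(L)
  path_idx[L] <- which.max(delta[L, ])
  if (L > 1L) for (j in (L - 1L):1L)
    path_idx[j] <- psi[j + 1L, path_idx[j + 1L]]
  path <- model$states[path_idx]

  log_joint <- unname(if (mode == "log") delta[L, path_idx[L]] else
    log0(delta[L, path_idx[L]]))
  log_total <- hmm_forward(model, seq, mode = "log")$log_total
  structure(list(
    path = path, joint = exp(log_joint), log_joint = log_joint,
    conditional = exp(log_joint - log_total),
    table = delta, traceback = psi, mode = mode,
    provenance = result_provenance(model, seq)),
    class = "hmm_viterbi")
}

#' Posterior decoding: per-position state probabilities
#'
#' Combines the forward and backward tables into
#' `gamma[j, k] = P(q_j = k | O) = alpha[j, k] beta[j, k] / P(O)`,
#' the data behind a posterior-decoding chart: one probability curve per
#' hidden state along the sequence positions. Computed in log space, so it
#' is safe for long sequences. The per-position argmax path is reported
#' alongside (ties toward the earliest declared state).
#'
#' @inheritParams hmm_forward
#' @return object of class `hmm_posterior`: `table` (L x K matrix of plain
#'   probabilities, each row summing to 1), `argmax_path` (character
#'   vector of L labels), `log_total`.
#' @export
hmm_posterior <- function(model, seq) {
  fw <- hmm_forward(model, seq, mode = "log")
  if (!is.finite(fw$log_total))
    stop("P(O) = 0 under this model; the posterior is undefined",
         call. = FALSE)
  bw <- hmm_backward(model, seq, mode = "log")
  gamma <- exp(fw$table + bw$table - fw$log_total)
  idx <- apply(gamma, 1L, which.max)
  structure(list(table = gamma, argmax_path = model$states[idx],
                 log_total = fw$log_total,
                 provenance = result_provenance(model, seq)),
            class = "hmm_posterior")
}

#' Joint probability of one hidden path and the observations
#'
#' The probability that the model follows a given hidden path AND emits the
#' observed sequence:
#' `P(Q, O) = prior(q_1) e(q_1, o_1) prod_{j>=2} a(q_{j-1} -> q_j) e(q_j, o_j)`.
#' This is the elementary quantity the enumeration oracle sums; summed over
#' all K^L paths it equals the forward total, and maximized over paths it
#' equals the Viterbi joint.
#'
#' @inheritParams hmm_forward
#' @param path character vector of L hidden-state labels.
#' @param mode `"plain"` (default here: single products do not underflow
#'   until extreme lengths) or `"log"` to return the log probability.
#' @return a single probability (or log probability).
#' @export
joint_probability <- function(model, seq, path, mode = c("plain", "log")) {
  mode <- match.arg(mode)
  stopifnot(is_hmm_model(model), is_hmm_seq(seq))
  L <- length(seq$symbols)
  if (length(path) != L)
    stop(sprintf("path has length %d but the sequence has length %d",
                 length(path), L), call. = FALSE)
  q <- match(as.character(path), model$states)
  if (anyNA(q))
    stop(sprintf("unknown hidden-state label '%s' in path",
                 path[which(is.na(q))[1L]]), call. = FALSE)
  E <- emission_probs(model, seq)
  lp <- log0(model$prior[q[1L]]) + log0(E[1L, q[1L]])
  if (L > 1L) for (j in 2:L)
    lp <- lp + log0(model$transitions[q[j - 1L], q[j]]) + log0(E[j, q[j]])
  lp <- unname(lp)
  if (mode == "log") lp else exp(lp)
}

#' @export
print.hmm_forward <- function(x, ...) {
  cat(sprintf("<hmm_forward> L = %d, K = %d, mode = %s\n",
              nrow(x$table), ncol(x$table), x$mode))
  cat(sprintf("P(O) = %s  (log = %.6f)\n",
              format(exp(x$log_total), digits = 6), x$log_total))
  invisible(x)
}

#' @export
print.hmm_backward <- function(x, ...) {
  cat(sprintf("<hmm_backward> L = %d, K = %d, mode = %s\n",
              nrow(x$table), ncol(x$table), x$mode))
  cat(sprintf("P(O) = %s  (log = %.6f)\n",
              format(exp(x$log_total), digits = 6), x$log_total))
  invisible(x)
}

#' @export
print.hmm_viterbi <- function(x, ...) {
  cat(sprintf("<hmm_viterbi> L = %d, mode = %s\n", length(x$path), x$mode))
  p <- paste(x$path, collapse = "")
  if (nchar(p) > 60) p <- paste0(substr(p, 1, 57), "...")
  cat("Q* =", p, "\n")
  cat(sprintf("P(Q*, O) = %s,  P(Q* | O) = %s\n",
              format(x$joint, digits = 6),
              format(x$conditional, digits = 6)))
  invisible(x)
}

#' @export
print.hmm_posterior <- function(x, ...) {
  cat(sprintf("<hmm_posterior> L = %d, K = %d\n",
              nrow(x$table), ncol(x$table)))
  p <- paste(x$argmax_path, collapse = "")
  if (nchar(p) > 60) p <- paste0(substr(p, 1, 57), "...")
  cat("argmax path =", p, "\n")
  invisible(x)
}
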