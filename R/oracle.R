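#' Brute-force enumeration of all hidden paths
#'
#' Lists every one of the K^L hidden-state paths together with its exact
#' joint probability P(Q, O), computed by [joint_probability()] in plain
#' probability space. This is the independent reference the dynamic
#' programs are verified against: the sum of all joints is P(O) (forward),
#' the best path is the Viterbi path, and per-position sums give the
#' posterior. Deliberately unoptimized; a cap on K^L keeps it honest.
#'
#' Paths are returned sorted by decreasing probability. Ties are ordered by
#' comparing state indices from the LAST position backwards, smallest
#' first -- exactly the order the Viterbi traceback resolves ties in, so
#' the top enumerated path always equals the Viterbi output.
#'
#' @inheritParams hmm_forward
#' @param cap refuse instances with more than this many paths
#'   (default 1e6).
#' @return object of class `hmm_paths`: `paths` (data.frame with one row
#'   per path: the path as a string, its `joint` probability), `total` =
#'   sum of all joints.
#' @examples
#' ab <- hmm_alphabet("custom", c("a", "b"))
#' m <- random_hmm(2, ab, seed = 1)
#' enumerate_paths(m, hmm_sequence("aba", ab))
#' @export
enumerate_paths <- function(model, seq, cap = 1e6) {
  stopifnot(is_hmm_model(model), is_hmm_seq(seq))
  K <- length(model$states)
  L <- length(seq$symbols)
  n_paths <- K^L
  if (n_paths > cap)
    stop(sprintf(
      "K^L = %g exceeds the enumeration cap (%g); use the dynamic-%s",
      n_paths, cap, "programming algorithms instead"), call. = FALSE)

  # all K^L index paths; expand.grid varies the first factor fastest, so
  # build columns position-by-position
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  colnames(grid) <- NULL
  joints <- vapply(seq_len(nrow(grid)), function(i)
    joint_probability(model, seq, model$states[grid[i, ]]), numeric(1))

  # sort: probability descending, then reverse-position lexicographic
  # (position L first), matching the Viterbi traceback tie-break
  ord <- do.call(order, c(list(-joints),
                          lapply(rev(seq_len(L)), function(j) grid[, j])))
  grid <- grid[ord, , drop = FALSE]
  joints <- joints[ord]
  paths <- data.frame(
    path = vapply(seq_len(nrow(grid)), function(i)
      paste(model$states[grid[i, ]], collapse = ""), character(1)),
    joint = joints,
    stringsAsFactors = FALSE)
  structure(list(paths = paths, path_idx = grid, total = sum(joints),
                 provenance = result_provenance(model, seq)),
            class = "hmm_paths")
}

#' @export
print.hmm_paths <- function(x, n = 8, ...) {
  cat(sprintf("<hmm_paths> %d paths enumerated, P(O) = %s\n",
              nrow(x$paths), format(x$total, digits = 6)))
  print(utils::head(x$paths, n))
  if (nrow(x$paths) > n) cat("...\n")
  invisible(x)
}

#' Posterior decoding by exhaustive enumeration
#'
#' Computes `gamma[j, k]` as the sum of P(Q, O) over all paths whose state
#' at position j is k, divided by the sum over all paths -- the definition
#' of the posterior, evaluated without any dynamic programming. Reference
#' implementation for testing [hmm_posterior()].
#'
#' @inheritParams enumerate_paths
#' @return object of class `hmm_posterior` (same shape as
#'   [hmm_posterior()]'s output).
#' @export
posterior_by_enumeration <- function(model, seq, cap = 1e6) {
  en <- enumerate_paths(model, seq, cap = cap)
  if (en$total <= 0)
    stop("P(O) = 0 under this model; the posterior is undefined",
         call. = FALSE)
  K <- length(model$states)
  L <- length(seq$symbols)
  gamma <- matrix(0, L, K, dimnames = list(NULL, model$states))
  for (j in seq_len(L))
    for (k in seq_len(K))
      gamma[j, k] <- sum(en$paths$joint[en$path_idx[, j] == k]) / en$total
  idx <- apply(gamma, 1L, which.max)
  structure(list(table = gamma, argmax_path = model$states[idx],
                 log_total = log0(en$total),
                 provenance = result_provenance(model, seq)),
            class = "hmm_posterior")
}
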