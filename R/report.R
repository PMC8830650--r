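# Display rounding: 4 significant digits, scientific notation below 1e-4.
# These are rounded copies for display only; every computation keeps full
# precision in the result objects.
fmt_disp <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (!is.finite(v)) return(format(v))
    if (v != 0 && abs(v) < 1e-4) formatC(v, format = "e", digits = 3)
    else formatC(v, format = "g", digits = 4)
  }, character(1))
}

# positions whose cell arithmetic is expanded operand-by-operand: all of
# them for short sequences, else the first 3 and last 2 so the 100-residue
# example stays readable
expanded_positions <- function(L, full_limit = 15L) {
  if (L <= full_limit) seq_len(L) else c(1:3, (L - 1L):L)
}

value_table_lines <- function(tab, col0 = "pos") {
  K <- ncol(tab)
  header <- sprintf("%-5s %s", col0,
                    paste(formatC(colnames(tab), width = 11), collapse = " "))
  rows <- vapply(seq_len(nrow(tab)), function(j)
    sprintf("%-5d %s", j,
            paste(formatC(fmt_disp(tab[j, ]), width = 11), collapse = " ")),
    character(1))
  c(header, rows)
}

# one expanded line per state for position j of the forward table
forward_step_lines <- function(model, E, alpha, j, mode) {
  K <- length(model$states)
  out <- character(0)
  for (l in seq_len(K)) {
    s <- model$states[l]
    if (j == 1L) {
      out <- c(out, sprintf(
        "alpha[1,%s] = prior(%s) * e(%s,o1) = %s * %s = %s",
        s, s, s, fmt_disp(model$prior[l]), fmt_disp(E[1L, l]),
        fmt_disp(if (mode == "log") exp(alpha[1L, l]) else alpha[1L, l])))
    } else {
      terms <- vapply(seq_len(K), function(k) sprintf(
        "%s*%s", fmt_disp(if (mode == "log") exp(alpha[j - 1L, k])
                          else alpha[j - 1L, k]),
        fmt_disp(model$transitions[k, l])), character(1))
      out <- c(out, sprintf(
        "alpha[%d,%s] = e(%s,o%d) * (%s) = %s",
        j, s, s, j, paste(terms, collapse = " + "),
        fmt_disp(if (mode == "log") exp(alpha[j, l]) else alpha[j, l])))
    }
  }
  out
}

backward_step_lines <- function(model, E, beta, j, L, mode) {
  K <- length(model$states)
  val <- function(x) fmt_disp(if (mode == "log") exp(x) else x)
  out <- character(0)
  for (k in seq_len(K)) {
    s <- model$states[k]
    if (j == L) {
      out <- c(out, sprintf("beta[%d,%s] = 1 (base case)", L, s))
    } else {
      terms <- vapply(seq_len(K), function(l) sprintf(
        "%s*%s*%s", fmt_disp(model$transitions[k, l]),
        fmt_disp(E[j + 1L, l]), val(beta[j + 1L, l])), character(1))
      out <- c(out, sprintf("beta[%d,%s] = %s = %s",
                            j, s, paste(terms, collapse = " + "),
                            val(beta[j, k])))
    }
  }
  out
}

viterbi_step_lines <- function(model, E, delta, j, mode) {
  K <- length(model$states)
  val <- function(x) fmt_disp(if (mode == "log") exp(x) else x)
  out <- character(0)
  for (l in seq_len(K)) {
    s <- model$states[l]
    if (j == 1L) {
      out <- c(out, sprintf(
        "delta[1,%s] = prior(%s) * e(%s,o1) = %s * %s = %s",
        s, s, s, fmt_disp(model$prior[l]), fmt_disp(E[1L, l]),
        val(delta[1L, l])))
    } else {
      terms <- vapply(seq_len(K), function(k) sprintf(
        "%s*%s", val(delta[j - 1L, k]),
        fmt_disp(model$transitions[k, l])), character(1))
      out <- c(out, sprintf(
        "delta[%d,%s] = e(%s,o%d) * max(%s) = %s",
        j, s, s, j, paste(terms, collapse = ", "), val(delta[j, l])))
    }
  }
  out
}

# Viterbi path printed in fixed-width blocks of 60 under the observations,
# with 1-based position rulers
path_alignment_lines <- function(seq_str, path_str, width = 60L) {
  L <- nchar(seq_str)
  starts <- seq(1L, L, by = width)
  out <- character(0)
  for (s in starts) {
    e <- min(s + width - 1L, L)
    ruler <- if (e - s > 1L)
      sprintf("pos %6d %s%d", s, strrep(" ", e - s - 1L), e)
    else sprintf("pos %6d", s)
    out <- c(out,
             ruler,
             sprintf("obs        %s", substr(seq_str, s, e)),
             sprintf("Q*         %s", substr(path_str, s, e)),
             "")
  }
  out[-length(out)]
}

section_for <- function(res, model, seq) {
  E <- emission_probs(model, seq)
  L <- length(seq$symbols)
  exp_pos <- expanded_positions(L)
  if (inherits(res, "hmm_forward")) {
    steps <- unlist(lapply(exp_pos, function(j)
      forward_step_lines(model, E, res$table, j, res$mode)))
    list(title = "Forward algorithm",
         body = c(
           "Question: what is the probability of the observed sequence,",
           "under the model?",
           "",
           "Recursion: alpha[1,k] = prior(k) e(k,o1);",
           "           alpha[j,l] = e(l,oj) * sum_k alpha[j-1,k] a(k->l);",
           "           P(O) = sum_k alpha[L,k]",
           sprintf("(computed in %s mode)", res$mode),
           "",
           "Step-by-step (expanded positions):",
           steps,
           "",
           sprintf("Full table of alpha values (%s):",
                   if (res$mode == "log") "log scale" else "probabilities"),
           value_table_lines(res$table),
           "",
           sprintf("Result: P(O) = %s  (log P(O) = %s)",
                   formatC(exp(res$log_total), format = "e", digits = 4),
                   fmt_disp(res$log_total))))
  } else if (inherits(res, "hmm_backward")) {
    steps <- unlist(lapply(rev(exp_pos), function(j)
      backward_step_lines(model, E, res$table, j, L, res$mode)))
    list(title = "Backward algorithm",
         body = c(
           "Question: what is the probability that a particular hidden",
           "state emitted the observed symbol at a particular position?",
           "(answered for every position via posterior decoding)",
           "",
           "Recursion: beta[L,k] = 1;",
           "           beta[j,k] = sum_l a(k->l) e(l,o_{j+1}) beta[j+1,l];",
           "           P(O) = sum_k prior(k) e(k,o1) beta[1,k]",
           sprintf("(computed in %s mode)", res$mode),
           "",
           "Step-by-step (expanded positions, from the end):",
           steps,
           "",
           sprintf("Full table of beta values (%s):",
                   if (res$mode == "log") "log scale" else "probabilities"),
           value_table_lines(res$table),
           "",
           sprintf("Result: P(O) = %s  (log P(O) = %s)",
                   formatC(exp(res$log_total), format = "e", digits = 4),
                   fmt_disp(res$log_total))))
  } else if (inherits(res, "hmm_viterbi")) {
    steps <- unlist(lapply(exp_pos, function(j)
      viterbi_step_lines(model, E, res$table, j, res$mode)))
    list(title = "Viterbi algorithm",
         body = c(
           "Question: what is the most probable sequence of hidden states",
           "that emits the observed sequence?",
           "",
           "Recursion: delta[1,k] = prior(k) e(k,o1);",
           "           delta[j,l] = e(l,oj) * max_k delta[j-1,k] a(k->l);",
           "           traceback from argmax_k delta[L,k]",
           sprintf("(computed in %s mode)", res$mode),
           "",
           "Step-by-step (expanded positions):",
           steps,
           "",
           "Most probable path Q* aligned under the observations:",
           path_alignment_lines(as.character(seq),
                                paste(res$path, collapse = "")),
           "",
           sprintf("Result: P(Q*, O) = %s,  P(Q* | O) = %s",
                   formatC(res$joint, format = "e", digits = 4),
                   fmt_disp(res$conditional))))
  } else if (inherits(res, "hmm_posterior")) {
    list(title = "Posterior decoding",
         body = c(
           "Per-position probability of each hidden state given the whole",
           "observed sequence: gamma[j,k] = alpha[j,k] beta[j,k] / P(O).",
           "One curve per hidden state over positions 1..L (chart data):",
           "",
           value_table_lines(res$table),
           "",
           sprintf("Per-position argmax path: %s",
                   paste(res$argmax_path, collapse = ""))))
  } else {
    stop("unsupported result object of class ", paste(class(res),
                                                      collapse = "/"),
         call. = FALSE)
  }
}

header_section <- function(model, seq) {
  list(title = "Model parameters",
       body = c(
         sprintf("Alphabet (%s): %s", model$alphabet$kind,
                 paste(model$alphabet$symbols, collapse = " ")),
         sprintf("Hidden states: %s", paste(model$states, collapse = " ")),
         sprintf("Observed sequence (L = %d):", length(seq$symbols)),
         strwrap(as.character(seq), width = 60),
         "",
         "Prior:",
         sprintf("  %s", paste(sprintf("%s=%s", model$states,
                                       fmt_disp(model$prior)),
                               collapse = "  ")),
         "Transitions (rows: from):",
         value_table_lines(model$transitions, col0 = "row"),
         "Emissions (rows: state):",
         value_table_lines(model$emissions, col0 = "row")))
}

#' Render a step-by-step report
#'
#' Produces the educational results document: an echo of the model
#' parameters followed by one section per supplied algorithm result. Each
#' algorithm section states its recursion, expands the cell-by-cell
#' arithmetic (all positions for L <= 15; the first 3 and last 2 positions,
#' plus the full value table, for longer sequences), and ends with the
#' algorithm's result: P(O) in scientific notation for forward, the path
#' Q* aligned under the observations in 60-column blocks plus P(Q*|O) for
#' Viterbi, the posterior chart data for backward/posterior decoding.
#'
#' All displayed probabilities are rounded copies (4 significant digits,
#' scientific below 1e-4) of the full-precision values stored in the
#' result objects.
#'
#' @param model,seq the model and sequence the results were computed on;
#'   results computed on a different model or sequence are rejected.
#' @param results a list of any subset of objects from [hmm_forward()],
#'   [hmm_backward()], [hmm_viterbi()], [hmm_posterior()]. An empty list
#'   yields a header-only document.
#' @param format `"text"`, `"markdown"` or `"html"`.
#' @return character string: the rendered document.
#' @examples
#' ab <- hmm_alphabet("custom", c("a", "b"))
#' m <- hmm_model(ab, "S", 1, matrix(1), matrix(c(0.5, 0.5), 1))
#' s <- hmm_sequence("aa", ab)
#' cat(render_report(m, s, list(hmm_forward(m, s, "plain"))))
#' @export
render_report <- function(model, seq, results = list(),
                          format = c("text", "markdown", "html")) {
  format <- match.arg(format)
  stopifnot(is_hmm_model(model), is_hmm_seq(seq), is.list(results))
  for (res in results)
    if (!same_provenance(res, model, seq))
      stop("a supplied result was computed on a different model or ",
           "sequence than the ones being reported", call. = FALSE)

  sections <- c(list(header_section(model, seq)),
                lapply(results, section_for, model = model, seq = seq))
  title <- "Hidden Markov model report"

  if (format == "text") {
    out <- c(title, strrep("=", nchar(title)), "")
    for (s in sections)
      out <- c(out, s$title, strrep("-", nchar(s$title)), s$body, "")
    paste(out, collapse = "\n")
  } else if (format == "markdown") {
    out <- c(paste("#", title), "")
    for (s in sections)
      out <- c(out, paste("##", s$title), "", "```", s$body, "```", "")
    paste(out, collapse = "\n")
  } else {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    out <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
             sprintf("<title>%s</title>", esc(title)),
             "<style>body{font-family:sans-serif;margin:2em}",
             "pre{background:#f6f6f6;padding:1em;overflow-x:auto}</style>",
             "</head><body>", sprintf("<h1>%s</h1>", esc(title)))
    for (s in sections)
      out <- c(out, sprintf("<h2>%s</h2>", esc(s$title)),
               "<pre>", esc(s$body), "</pre>")
    out <- c(out, "</body></html>")
    paste(out, collapse = "\n")
  }
}

#' Posterior chart data
#'
#' Extracts the plotting data behind a posterior-decoding chart: one
#' probability series per hidden state over the 1-based sequence
#' positions, plus the per-position argmax state.
#'
#' @param posterior an object from [hmm_posterior()] or
#'   [posterior_by_enumeration()].
#' @return data.frame with a `position` column, one numeric column per
#'   hidden state (each of length L; at every position the state columns
#'   sum to 1), and an `argmax` column.
#' @export
posterior_chart_data <- function(posterior) {
  stopifnot(inherits(posterior, "hmm_posterior"))
  df <- data.frame(position = seq_len(nrow(posterior$table)),
                   posterior$table, check.names = FALSE)
  df$argmax <- posterior$argmax_path
  df
}

#' Plot a posterior-decoding chart
#'
#' One probability curve per hidden state along the sequence positions
#' (base graphics).
#'
#' @param x an `hmm_posterior` object.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.hmm_posterior <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$table)), x$table, type = "l", lty = 1,
                    lwd = 2, xlab = "sequence position (1-based)",
                    ylab = "posterior probability P(state | O)",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = colnames(x$table), lty = 1, lwd = 2,
                   col = seq_len(ncol(x$table)))
  invisible(x)
}
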