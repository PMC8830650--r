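# shared fixtures for the test suite, built in code

ab2 <- hmm_alphabet("custom", c("a", "b"))

# degenerate single-state model: every forward total is a plain product
one_state_model <- function() {
  hmm_model(ab2, "S", prior = 1, transitions = matrix(1),
            emissions = matrix(c(0.5, 0.5), 1))
}

# a fixed, hand-checkable 2-state / 2-symbol model
two_state_model <- function() {
  hmm_model(ab2, c("X", "Y"),
            prior = c(0.6, 0.4),
            transitions = rbind(c(0.7, 0.3), c(0.4, 0.6)),
            emissions = rbind(c(0.9, 0.1), c(0.2, 0.8)))
}

# fully symmetric model: every path of a given length has the same joint,
# so Viterbi ties are exact and exercised deterministically
symmetric_model <- function() {
  hmm_model(ab2, c("X", "Y"),
            prior = c(0.5, 0.5),
            transitions = rbind(c(0.5, 0.5), c(0.5, 0.5)),
            emissions = rbind(c(0.5, 0.5), c(0.5, 0.5)))
}

# one random small instance (model + sequence) per seed, sized so the
# enumeration oracle stays exact: K <= 3, |alphabet| <= 4, L <= 6
random_instance <- function(seed, K_max = 3, A_max = 4, L_max = 6) {
  withr::with_seed(seed + 1000L, {
    K <- sample(K_max, 1)
    A <- sample(2:A_max, 1)
    L <- sample(L_max, 1)
    alphabet <- hmm_alphabet("custom", letters[seq_len(A)])
    obs <- paste(sample(alphabet$symbols, L, replace = TRUE), collapse = "")
    list(model = random_hmm(K, alphabet, seed = seed),
         seq = hmm_sequence(obs, alphabet))
  })
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  denom <- max(abs(expected), .Machine$double.xmin)
  expect_lt(abs(actual - expected) / denom, tol)
}
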