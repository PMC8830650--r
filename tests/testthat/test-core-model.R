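test_that("built-in alphabets carry the standard symbol sets", {
  expect_equal(hmm_alphabet("DNA")$symbols, c("A", "C", "G", "T"))
  expect_equal(hmm_alphabet("RNA")$symbols, c("A", "C", "G", "U"))
  expect_length(hmm_alphabet("protein")$symbols, 20)
  expect_error(hmm_alphabet("custom", c("a", "a")), "distinct")
  expect_error(hmm_alphabet("custom"), "non-empty")
  expect_error(hmm_alphabet("DNA", symbols = c("A")), "custom")
})

test_that("sequences are uppercased and validated against their alphabet", {
  s <- hmm_sequence("acgt", hmm_alphabet("DNA"))
  expect_equal(s$symbols, c("A", "C", "G", "T"))
  expect_equal(length(s), 4L)
  expect_equal(as.character(s), "ACGT")
  # unknown symbols name the position and symbol
  expect_error(hmm_sequence("ACXT", hmm_alphabet("DNA")),
               "'X' at position 3")
  # opt-in unknown handling keeps the symbol
  s2 <- hmm_sequence("ACXT", hmm_alphabet("DNA"), allow_unknown = TRUE)
  expect_equal(s2$symbols[3], "X")
  expect_error(hmm_sequence("", hmm_alphabet("DNA")), "at least one")
})

test_that("model construction validates dimensions and normalization", {
  # degenerate single-state model is valid
  expect_s3_class(one_state_model(), "hmm_model")

  # a prior that sums to 1.1 is rejected, naming the deviation
  expect_error(
    hmm_model(ab2, c("X", "Y"), prior = c(0.5, 0.6),
              transitions = diag(2), emissions = matrix(0.5, 2, 2)),
    "prior vector sums to 1.1")

  # dimension mismatches name the offending component
  expect_error(
    hmm_model(ab2, c("X", "Y"), prior = c(0.5, 0.5),
              transitions = diag(2), emissions = matrix(0.5, 2, 1)),
    "emission matrix")
  expect_error(
    hmm_model(ab2, c("X", "Y"), prior = c(0.5, 0.5),
              transitions = matrix(1), emissions = matrix(0.5, 2, 2)),
    "transition matrix")

  # zero probabilities are allowed anywhere
  m <- hmm_model(ab2, c("X", "Y"), prior = c(1, 0),
                 transitions = rbind(c(1, 0), c(0, 1)),
                 emissions = rbind(c(1, 0), c(0, 1)))
  expect_identical(validate_hmm(m), character(0))
})

test_that("validate_hmm reports every violation instead of stopping", {
  bad <- one_state_model()
  bad$prior <- c(0.9)
  bad$transitions <- matrix(c(0.9, 0.2, 0, 0.8), 2)  # wrong dims AND sums
  problems <- validate_hmm(bad)
  expect_gt(length(problems), 1)
  expect_true(any(grepl("prior", problems)))
  expect_true(any(grepl("transition matrix", problems)))
})

test_that("a transition row violating normalization is named", {
  m <- two_state_model()
  m$transitions["X", ] <- c(0.9, 0.2)
  problems <- validate_hmm(m)
  expect_length(problems, 1)
  expect_match(problems, "transition row 'X'")
})

test_that("renormalize option rescales rows instead of rejecting", {
  m <- hmm_model(ab2, c("X", "Y"), prior = c(2, 2),
                 transitions = rbind(c(7, 3), c(4, 6)),
                 emissions = rbind(c(9, 1), c(2, 8)),
                 renormalize = TRUE)
  expect_equal(unname(m$prior), c(0.5, 0.5))
  expect_equal(unname(m$transitions["X", ]), c(0.7, 0.3))
  expect_identical(validate_hmm(m), character(0))
})

test_that("random models are seeded, reproducible and valid", {
  a <- random_hmm(3, hmm_alphabet("protein"), seed = 7)
  b <- random_hmm(3, hmm_alphabet("protein"), seed = 7)
  expect_identical(a, b)  # bit-for-bit

  # different seeds give different parameters
  c1 <- random_hmm(2, hmm_alphabet("DNA"), seed = 1)
  c2 <- random_hmm(2, hmm_alphabet("DNA"), seed = 2)
  expect_false(isTRUE(all.equal(c1$emissions, c2$emissions)))

  # every generated model passes validation; rows sum to 1
  for (seed in 1:10) {
    m <- random_hmm(1 + seed %% 4, hmm_alphabet("DNA"), seed = seed)
    expect_identical(validate_hmm(m), character(0))
    expect_equal(sum(m$prior), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(m$transitions)),
                 rep(1, length(m$states)), tolerance = 1e-12)
  }
  expect_error(random_hmm(0, hmm_alphabet("DNA"), seed = 1), ">= 1")
})

test_that("random_hmm does not disturb the global RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(random_hmm(2, hmm_alphabet("DNA"), seed = 5))
  expect_identical(runif(1), before)
})

test_that("hidden-state labels may collide with observed symbols", {
  ab <- hmm_alphabet("custom", c("I", "O"))
  m <- hmm_model(ab, c("I", "O"), prior = c(0.5, 0.5),
                 transitions = matrix(0.5, 2, 2),
                 emissions = matrix(0.5, 2, 2))
  s <- hmm_sequence("IO", ab)
  expect_s3_class(hmm_viterbi(m, s), "hmm_viterbi")
})
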