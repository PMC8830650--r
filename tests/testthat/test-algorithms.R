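test_that("forward reduces to closed forms on degenerate models", {
  m <- one_state_model()
  s <- hmm_sequence("aa", ab2)
  # single state, prior 1, self-transition 1, e(a) = 0.5: P(O) = 0.5^2
  expect_equal(hmm_forward(m, s, mode = "plain")$total, 0.25)
  expect_equal(exp(hmm_forward(m, s, mode = "log")$total), 0.25)

  # length-1 sequence: base case only, P(O) = sum_k prior(k) e(k, x)
  m2 <- two_state_model()
  s1 <- hmm_sequence("a", ab2)
  expect_equal(hmm_forward(m2, s1, mode = "plain")$total,
               sum(m2$prior * m2$emissions[, "A"]))
})

test_that("forward equals brute-force path enumeration on small instances", {
  m <- two_state_model()
  s <- hmm_sequence("aba", ab2)
  en <- enumerate_paths(m, s)
  expect_equal(nrow(en$paths), 8)
  fw <- hmm_forward(m, s, mode = "plain")
  expect_rel_equal(fw$total, en$total)
  expect_rel_equal(exp(hmm_forward(m, s, mode = "log")$total), en$total)
})

test_that("backward base case and total match forward", {
  m <- two_state_model()
  s <- hmm_sequence("abba", ab2)
  bw <- hmm_backward(m, s, mode = "plain")
  expect_equal(unname(bw$table[4, ]), c(1, 1))
  bwl <- hmm_backward(m, s, mode = "log")
  expect_equal(unname(bwl$table[4, ]), c(0, 0))  # log(1)
  fw <- hmm_forward(m, s, mode = "plain")
  expect_rel_equal(bw$total, fw$total)

  m1 <- one_state_model()
  s1 <- hmm_sequence("aa", ab2)
  expect_equal(hmm_backward(m1, s1, mode = "plain")$total, 0.25)
})

test_that("backward entries equal brute-force suffix-path sums", {
  m <- two_state_model()
  s <- hmm_sequence("bab", ab2)
  bw <- hmm_backward(m, s, mode = "plain")
  E <- rbind(m$emissions[, "B"], m$emissions[, "A"], m$emissions[, "B"])
  # beta[j,k] = sum over suffix paths q_{j+1..L} of
  #   prod a(q_i -> q_{i+1}) e(q_{i+1}, o_{i+1})
  for (k in 1:2) {
    direct <- 0
    for (l in 1:2) for (r in 1:2)
      direct <- direct +
        m$transitions[k, l] * E[2, l] * m$transitions[l, r] * E[3, r]
    expect_rel_equal(bw$table[1, k], direct)
  }
})

test_that("forward-backward consistency holds at every position", {
  for (seed in 1:5) {
    inst <- random_instance(seed)
    fw <- hmm_forward(inst$model, inst$seq, mode = "plain")
    bw <- hmm_backward(inst$model, inst$seq, mode = "plain")
    expect_rel_equal(bw$total, fw$total)
    for (j in seq_len(length(inst$seq)))
      expect_rel_equal(sum(fw$table[j, ] * bw$table[j, ]), fw$total)
  }
})

test_that("viterbi recovers the argmax path and its probabilities", {
  # single state: the path is that state repeated
  m1 <- one_state_model()
  v1 <- hmm_viterbi(m1, hmm_sequence("abab", ab2))
  expect_equal(v1$path, rep("S", 4))
  expect_equal(v1$conditional, 1)  # only one path exists

  # 2-state length-3: argmax over all 8 paths from the oracle
  m <- two_state_model()
  s <- hmm_sequence("bba", ab2)
  en <- enumerate_paths(m, s)
  v <- hmm_viterbi(m, s, mode = "plain")
  expect_equal(paste(v$path, collapse = ""), en$paths$path[1])
  expect_rel_equal(v$joint, en$paths$joint[1])
  expect_rel_equal(v$conditional, en$paths$joint[1] / en$total)
  # dominance: joint <= P(O)
  expect_lte(v$joint, hmm_forward(m, s, mode = "plain")$total)

  # log and plain agree
  vl <- hmm_viterbi(m, s, mode = "log")
  expect_equal(vl$path, v$path)
  expect_rel_equal(vl$joint, v$joint)
})

test_that("viterbi rejects sequences the model cannot emit", {
  m <- hmm_model(ab2, c("X", "Y"), prior = c(1, 0),
                 transitions = rbind(c(1, 0), c(0, 1)),
                 emissions = rbind(c(1, 0), c(0, 1)))
  # X can never emit 'b' and Y is unreachable
  expect_error(hmm_viterbi(m, hmm_sequence("ab", ab2)), "probability zero")
  expect_error(hmm_viterbi(m, hmm_sequence("ab", ab2), mode = "plain"),
               "probability zero")
})

test_that("viterbi ties break toward the earliest declared state", {
  m <- symmetric_model()
  s <- hmm_sequence("abab", ab2)
  # all 16 paths are tied; the declared-order tie-break selects all-X
  for (mode in c("log", "plain")) {
    v <- hmm_viterbi(m, s, mode = mode)
    expect_equal(v$path, rep("X", 4))
  }
  # and reruns are identical
  expect_identical(hmm_viterbi(m, s)$path, hmm_viterbi(m, s)$path)
})

test_that("posterior rows are normalized and match enumeration", {
  # 1-state model: gamma is identically 1
  p1 <- hmm_posterior(one_state_model(), hmm_sequence("aba", ab2))
  expect_equal(unname(p1$table), matrix(1, 3, 1))

  m <- two_state_model()
  s <- hmm_sequence("bab", ab2)
  po <- hmm_posterior(m, s)
  expect_equal(unname(rowSums(po$table)), rep(1, 3), tolerance = 1e-9)
  ref <- posterior_by_enumeration(m, s)
  expect_equal(po$table, ref$table, tolerance = 1e-9)
  expect_equal(po$argmax_path, ref$argmax_path)

  # P(O) = 0 is rejected
  dead <- hmm_model(ab2, "X", prior = 1, transitions = matrix(1),
                    emissions = matrix(c(1, 0), 1))
  expect_error(hmm_posterior(dead, hmm_sequence("b", ab2)), "undefined")
})

test_that("joint_probability multiplies prior, transitions and emissions", {
  m1 <- one_state_model()
  expect_equal(joint_probability(m1, hmm_sequence("aa", ab2), c("S", "S")),
               0.25)
  m <- two_state_model()
  s <- hmm_sequence("ab", ab2)
  expect_equal(joint_probability(m, s, c("X", "Y")),
               0.6 * 0.9 * 0.3 * 0.8)
  expect_equal(joint_probability(m, s, c("X", "Y"), mode = "log"),
               log(0.6 * 0.9 * 0.3 * 0.8))
  # errors: wrong length, unknown label
  expect_error(joint_probability(m, s, "X"), "length")
  expect_error(joint_probability(m, s, c("X", "Z")), "unknown.*'Z'")
  # a path through a zero transition has probability 0
  mz <- hmm_model(ab2, c("X", "Y"), prior = c(0.5, 0.5),
                  transitions = rbind(c(1, 0), c(0.5, 0.5)),
                  emissions = matrix(0.5, 2, 2))
  expect_equal(joint_probability(mz, s, c("X", "Y")), 0)
})

test_that("log and plain modes agree where plain does not underflow", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    fp <- hmm_forward(inst$model, inst$seq, mode = "plain")
    fl <- hmm_forward(inst$model, inst$seq, mode = "log")
    expect_rel_equal(exp(fl$total), fp$total)
    bp <- hmm_backward(inst$model, inst$seq, mode = "plain")
    bl <- hmm_backward(inst$model, inst$seq, mode = "log")
    expect_rel_equal(exp(bl$total), bp$total)
    expect_equal(exp(bl$table), bp$table, tolerance = 1e-9)
  }
})

test_that("unknown symbols emit uniformly when explicitly allowed", {
  m <- two_state_model()
  s <- hmm_sequence("aZ", ab2, allow_unknown = TRUE)
  fw <- hmm_forward(m, s, mode = "plain")
  # position 2 contributes 1/|alphabet| from every state
  expected <- sum((m$prior * m$emissions[, "A"]) %*% m$transitions * 0.5)
  expect_rel_equal(fw$total, expected)
  # without the opt-in the algorithms reject, naming position and symbol
  s_strict <- hmm_sequence("aa", ab2)
  s_strict$symbols[2] <- "Z"
  expect_error(hmm_forward(m, s_strict), "'Z' at position 2")
})
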