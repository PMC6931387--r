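# Generative-model construction: the temperature transform, the base
# emotion-outcome pattern, structural invariants, and habit biases.

test_that("temperature transform hits its calibration points", {
  one_hot <- matrix(c(1, 0), 2, 1)
  # temp 2 with epsilon 0.1: softmax(2*log(c(1.1, 0.1))) computed by hand
  expect_equal(as.numeric(apply_precision(one_hot, 2)),
               c(1.21, 0.01) / 1.22, tolerance = 1e-10)
  # temp 0 gives uniform columns regardless of the base
  expect_equal(as.numeric(apply_precision(one_hot, 0)), c(0.5, 0.5))
  expect_equal(as.numeric(apply_precision(diag(4), 0)),
               rep(0.25, 16))
  # equal entries are a fixed point at any temperature
  for (temp in c(0, 0.7, 2, 5))
    expect_equal(as.numeric(apply_precision(matrix(0.5, 2, 1), temp)),
                 c(0.5, 0.5))
  # infinite temperature recovers the base support exactly
  expect_equal(apply_precision(diag(4), Inf), diag(4))
  expect_error(apply_precision(one_hot, -1), "non-negative")
  expect_error(apply_precision(matrix(c(0.4, 0.4), 2, 1), 2), "stochastic")
})

test_that("transform sharpness is monotone in temperature", {
  kl_from_uniform <- function(p) sum(ifelse(p > 0, p * log(p * length(p)), 0))
  cols <- list(c(1, 0), c(0.5, 0.5), c(1, 0, 0, 0), c(0.5, 0.5, 0, 0))
  temps <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 5)
  for (col in cols) {
    kl <- vapply(temps, function(tp)
      kl_from_uniform(as.numeric(apply_precision(matrix(col), tp))),
      numeric(1))
    expect_true(all(diff(kl) >= -1e-12))
  }
})

test_that("infinite-precision likelihoods reproduce the emotion definitions", {
  m <- trained_model(Inf, Inf)
  att <- affectinf:::attend_state_of
  # rows are the informative levels, columns SAD, AFRAID, ANGRY, HAPPY
  expect_equal(unname(m$A$valence[2:3, , att("valence")]),
               matrix(c(0, 1, 0, 1, 0, 1, 1, 0), 2))
  expect_equal(unname(m$A$arousal[2:3, , att("arousal")]),
               matrix(c(.5, .5, 1, 0, 1, 0, .5, .5), 2))
  expect_equal(unname(m$A$action[2:3, , att("action")]),
               matrix(c(0, 1, 0, 1, 1, 0, .5, .5), 2))
  expect_equal(unname(m$A$context[2:3, , att("context")]),
               matrix(c(1, 0, .5, .5, 1, 0, 0, 1), 2))
  expect_equal(unname(m$A$blame[2:3, , att("blame")]),
               matrix(c(1, 0, 0, 1, 0, 1, .5, .5), 2))
  expect_equal(m$A$action["approach", "ANGRY", att("action")], 1)
})

test_that("null, feedback, and location structure is exact at any precision", {
  for (m in list(trained_model(2, 2), trained_model(0.5, 1))) {
    # start state emits null in every content modality with certainty
    for (mod in affectinf:::CONTENT_MODALITIES)
      expect_equal(unname(m$A[[mod]][1, , 1]), rep(1, 4))
    # feedback is correct iff the report state matches the emotion
    expect_equal(m$A$feedback["correct", "SAD", "report-SAD"], 1)
    expect_equal(m$A$feedback["incorrect", "SAD", "report-ANGRY"], 1)
    expect_equal(unname(m$A$feedback["null", , "attend-valence"]), rep(1, 4))
    # attended location is an identity on attention states
    for (s in 1:10) expect_equal(unname(m$A$location[s, , s]), rep(1, 4))
  }
})

test_that("categorical normalization and report absorption hold", {
  for (m in list(trained_model(2, 2), trained_model(0, 0.5),
                 blank_model())) {
    for (mod in affectinf:::MODALITIES) {
      cs <- apply(m$A[[mod]], c(2, 3), sum)
      expect_true(all(abs(cs - 1) < 1e-10))
    }
    expect_true(all(abs(colSums(m$B$emotion) - 1) < 1e-10))
    for (u in 1:10) {
      Bu <- m$B$attention[, , u]
      expect_true(all(abs(colSums(Bu) - 1) < 1e-10))
      for (r in 7:10) expect_equal(Bu[r, r], 1)
    }
    expect_equal(sum(m$D$emotion), 1)
    expect_equal(sum(m$E), 1)
  }
})

test_that("emotion transitions are action-independent and identity-based", {
  m <- trained_model(2, 2)
  # a single stability matrix serves every action; at infinite precision
  # it is the exact identity
  expect_true(all(diag(m$B$emotion) > 0.9))
  expect_equal(trained_model(Inf, Inf)$B$emotion, diag(4),
               ignore_attr = TRUE)
  # attention action k targets state k from any non-report state
  for (u in 2:10) for (from in 1:6)
    expect_equal(unname(which(m$B$attention[, from, u] == 1)), u)
})

test_that("blank model is flat over content with learnable counts", {
  b <- blank_model(a0 = 1)
  att <- affectinf:::attend_state_of
  for (mod in affectinf:::CONTENT_MODALITIES)
    expect_equal(unname(b$A[[mod]][2:3, , att(mod)]), matrix(0.5, 2, 4))
  expect_true(all(unlist(b$a) > 0))
  expect_equal(unname(b$D$emotion), rep(0.25, 4))
  # frozen structure is untouched
  expect_equal(unname(b$A$feedback["correct", "SAD", "report-SAD"]), 1)
  expect_error(blank_concept_model(trained_model(), a0 = 0), "a0")
})

test_that("attention bias scales the habit prior and nothing else", {
  m <- trained_model()
  expect_equal(set_attention_bias(m, "external", factor = 1)$E, m$E)
  mb <- set_attention_bias(m, c("attend-context", "attend-blame"), 50)
  expect_equal(sum(mb$E), 1)
  expect_equal(mb$E[["attend-context"]] / mb$E[["attend-valence"]], 50)
  # report actions keep their relative weights
  expect_equal(mb$E[["report-SAD"]] / mb$E[["report-HAPPY"]], 1)
  expect_identical(mb$A, m$A)
  expect_error(set_attention_bias(m, character(0), factor = 50), "empty")
  expect_error(set_attention_bias(m, "report-SAD", 50), "attend")
  # the three named bias sets resolve to attend actions
  for (b in names(attention_bias_sets()))
    expect_silent(set_attention_bias(m, b, 50))
})
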