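test_that("modifier effects follow the invert/reinforce factor rules", {
  lex <- tiny_lex()
  m <- find_matches(c("niet", "goed"), lex)
  expect_identical(nrow(m), 1L)
  expect_identical(m$bigram_score, -1)
  expect_identical(m$trigram_score, -1)

  m <- find_matches(c("heel", "goed"), lex)
  expect_identical(m$bigram_score, 2)

  m <- find_matches(c("niet", "heel", "goed"), lex)
  expect_identical(m$prev1_effect, "reinforce")
  expect_identical(m$prev2_effect, "invert")
  expect_identical(m$trigram_score, -2)

  # double negation cancels; record-initial word takes factor 1
  m <- find_matches(c("niet", "niet", "goed"), lex)
  expect_identical(m$trigram_score, 1)
  m <- find_matches(c("goed"), lex)
  expect_identical(m$prev1_effect, "none")
  expect_identical(m$bigram_score, 1)
})

test_that("record scoring matches hand-enumerated n-gram tables", {
  lex <- tiny_lex()
  r <- score_record(c("patiënt", "at", "vandaag", "erg", "goed"), lex)
  expect_identical(r$bigram_final, 1)
  expect_identical(r$trigram_final, 1)
  expect_identical(r$overall, 1)

  # both matches invert/stay negative; both channels average to -1
  r <- score_record(c("patiënt", "niet", "goed", "wel", "slecht"), lex)
  expect_identical(r$bigram_final, -1)
  expect_identical(r$trigram_final, -1)
  expect_identical(r$overall, -1)

  # irrelevant: fewer than five tokens
  r <- score_record(c("niet", "goed"), lex)
  expect_false(r$relevant_auto)
  expect_true(is.na(r$overall))
})

test_that("flipping every lexicon polarity negates all scores", {
  set.seed(7)
  for (i in 1:100) {
    cs <- random_case()
    r1 <- score_record(cs$tokens, cs$lex)
    r2 <- score_record(cs$tokens, flip_lexicon(cs$lex))
    expect_equal(r2$bigram_final, -r1$bigram_final)
    expect_equal(r2$trigram_final, -r1$trigram_final)
    expect_equal(r2$overall, -r1$overall)
  }
})

test_that("overall score is bounded in [-1, 1] for both strategies", {
  set.seed(11)
  for (i in 1:200) {
    cs <- random_case(max_tokens = 20)
    for (strat in c("ngram_mean", "token_mean")) {
      ov <- score_record(cs$tokens, cs$lex, strategy = strat)$overall
      if (!is.na(ov)) {
        expect_gte(ov, -1)
        expect_lte(ov, 1)
      }
    }
  }
})

test_that("scorer equals the brute-force window-enumeration oracle", {
  set.seed(23)
  for (i in 1:300) {
    cs <- random_case()
    for (strat in c("ngram_mean", "token_mean")) {
      got <- score_record(cs$tokens, cs$lex, strategy = strat)
      want <- oracle_score(cs$tokens, cs$entries, cs$negators,
                           cs$intensifiers, strategy = strat)
      expect_identical(got$relevant_auto, want$relevant)
      expect_equal(got$bigram_final, want$bigram)
      expect_equal(got$trigram_final, want$trigram)
      expect_equal(got$overall, want$overall)
    }
  }
})

test_that("under token_mean an extra unmodified positive match raises the score", {
  lex <- tiny_lex()
  set.seed(5)
  for (i in 1:50) {
    cs <- random_case()
    tokens <- c(sample(c("niet", "heel", "goed", "slecht", "xx", "yy"), 10,
                       replace = TRUE))
    r <- score_record(tokens, lex, strategy = "token_mean")
    # strictly inside the clamp bounds, else the clamp absorbs the change
    if (!r$relevant_auto || is.na(r$overall) ||
        r$overall >= 1 || r$overall <= -1) next
    # two plain fillers ahead of the new match keep it unmodified
    r2 <- score_record(c(tokens, "xx", "yy", "goed"), lex,
                       strategy = "token_mean")
    expect_gt(r2$overall, r$overall)
  }
})

test_that("corpus scoring is per-record, order-independent and filter-aware", {
  lex <- tiny_lex()
  corpus <- data.frame(record_id = c("a", "b", "c"),
                       patient_id = "p1", seq = 1:3)
  corpus$tokens <- list(c("aa", "bb", "cc", "dd", "goed"),
                        c("niet", "goed"),
                        c("heel", "slecht", "dd", "ee", "ff"))
  out <- score_corpus(corpus, lex)
  expect_identical(nrow(out), 3L)
  expect_identical(out$relevant_auto, c(TRUE, FALSE, TRUE))
  shuffled <- corpus[c(3, 1, 2), ]
  out2 <- score_corpus(shuffled, lex)
  expect_equal(out2[match(out$record_id, out2$record_id), "overall"],
               out$overall)
  empty <- score_corpus(corpus[0, ], lex)
  expect_identical(nrow(empty), 0L)
})
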