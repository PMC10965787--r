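test_that("corpus specs validate proportions and probabilities", {
  expect_error(corpus_spec(category_mix = c(positive = 1, negative = 0.5,
                                            neutral = 0, mixed = 0,
                                            irrelevant = 0)),
               "sum to 1")
  expect_error(corpus_spec(p_negation = 1.5), "\\[0, 1\\]")
  expect_error(corpus_spec(p_negation = 0.7, p_intensifier = 0.7),
               "not exceed 1")
})

test_that("generation is deterministic for a fixed seed", {
  sp <- corpus_spec(n_patients = 2, records_per_patient = 10L, seed = 99)
  c1 <- generate_corpus(sp)
  c2 <- generate_corpus(sp)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_corpus(corpus_spec(n_patients = 2, records_per_patient = 10L,
                                    seed = 100))
  expect_false(identical(c1$records$text, c3$records$text))
})

test_that("an all-irrelevant mix produces only filtered records", {
  sp <- corpus_spec(n_patients = 2, records_per_patient = 15L,
                    category_mix = c(positive = 0, negative = 0, neutral = 0,
                                     mixed = 0, irrelevant = 1),
                    seed = 5)
  corp <- generate_corpus(sp)
  lex <- demo_lexicon()
  prepared <- prepare_corpus(corp$records, lex)
  expect_false(any(prepared$relevant_auto))
})

test_that("the scorer reproduces the generator's closed-form ground truth", {
  lex <- demo_lexicon()
  corp <- generate_corpus(corpus_spec(seed = 424242), lex)
  run <- run_score(corp$records, lex)
  m <- merge(run$scores[c("record_id", "overall", "relevant_auto")],
             corp$truth, by = "record_id")
  # relevance agrees with the intended category
  expect_identical(m$relevant_auto, m$category != "irrelevant")
  rel <- m[m$relevant_auto, ]
  agree <- abs(rel$overall - rel$expected_overall) < 1e-12
  expect_gte(mean(agree), 0.99)
  # intended categories carry the right sign
  expect_true(all(rel$expected_overall[rel$category == "positive"] > 0))
  expect_true(all(rel$expected_overall[rel$category == "negative"] < 0))
  expect_true(all(rel$expected_overall[rel$category %in% c("neutral", "mixed")] == 0))
})

test_that("generated category mix matches the spec within sampling error", {
  sp <- corpus_spec(n_patients = 8, records_per_patient = 60L, seed = 77)
  corp <- generate_corpus(sp)
  n <- nrow(corp$truth)
  obs <- table(factor(corp$truth$category, levels = names(sp$category_mix))) / n
  for (cat in names(sp$category_mix)) {
    p <- sp$category_mix[[cat]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs[[cat]] - p), 4 * se + 1e-9)
  }
})

test_that("rater simulation is deterministic and exact in the no-noise limit", {
  latent <- stats::setNames(rnorm(40, 4, 1.2), sprintf("r%02d", 1:40))
  sp <- rater_spec(true_icc = 0.9, seed = 12)
  s1 <- simulate_raters(latent, sp)
  s2 <- simulate_raters(latent, sp)
  expect_identical(s1$continuous, s2$continuous)
  expect_identical(s1$ratings, s2$ratings)

  near1 <- simulate_raters(latent, rater_spec(true_icc = 0.999999,
                                              p_irrelevant_disagree = 0,
                                              seed = 3))
  expect_equal(near1$continuous$r1, near1$continuous$r2, tolerance = 1e-2)
  expect_identical(near1$ratings$score[near1$ratings$rater_id == "rater1"],
                   near1$ratings$score[near1$ratings$rater_id == "rater2"])
})

test_that("rater bias is checked against the requested reliability", {
  latent <- stats::setNames(rnorm(30), sprintf("r%02d", 1:30))
  expect_error(simulate_raters(latent, rater_spec(true_icc = 0.99,
                                                  rater_bias = c(0, 5))),
               "rater_bias too large")
})

test_that("estimated ICC recovers the simulated reliability on average", {
  # light version of the full recovery study (see the acceptance suite)
  est <- vapply(1:60, function(b) {
    latent <- stats::setNames(rnorm(250, 4, 1), sprintf("r%03d", 1:250))
    s <- simulate_raters(latent, rater_spec(true_icc = 0.6,
                                            p_irrelevant_disagree = 0,
                                            seed = 1000 + b))
    icc_a1(s$continuous$r1, s$continuous$r2)$estimate
  }, 0)
  expect_lt(abs(mean(est) - 0.6), 0.03)
})
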