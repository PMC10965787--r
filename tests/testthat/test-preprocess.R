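test_that("pseudonymize replaces names/dates and deletes contact details", {
  expect_identical(pseudonymize("Afspraak met Jan op 03-02-2021"),
                   "Afspraak met (NAME-1) op (DATE-1)")
  expect_identical(pseudonymize("mail: x@y.nl"), "mail:")
  expect_identical(pseudonymize(""), "")
  expect_identical(pseudonymize("Gesprek met Jan en Piet"),
                   "Gesprek met (NAME-1) en (NAME-2)")
  expect_identical(pseudonymize("Zij is 24 jaar en woont in Utrecht"),
                   "Zij is (AGE) en woont in (LOCATION-1)")
  out <- pseudonymize("bel 06-12345678 of kijk op https://x.nl nu")
  expect_false(grepl("06-12345678", out, fixed = TRUE))
  expect_false(grepl("x.nl", out, fixed = TRUE))
  expect_identical(pseudonymize("gewogen op 3 februari 2021"),
                   "gewogen op (DATE-1)")
})

test_that("pseudonymize is idempotent and never adds name-like tokens", {
  texts <- c("Afspraak met Jan op 03-02-2021 in Leiden",
             "Moeder Marie belde. Vader ook.",
             "ROM besproken; Anna is 19 jaar")
  count_names <- function(x)
    lengths(regmatches(x, gregexpr("\\b\\p{Lu}\\p{Ll}+\\b", x, perl = TRUE)))
  for (tx in texts) {
    once <- pseudonymize(tx)
    expect_identical(pseudonymize(once), once)
    expect_lte(count_names(once), count_names(tx))
  }
})

test_that("tokenization lowercases, drops noise tokens and spares modifiers", {
  expect_identical(
    tokenize_clean("De patiënt eet niet goed 2x",
                   stopwords = "de", keep = "niet")[[1]],
    c("patiënt", "eet", "niet", "goed"))
  expect_identical(tokenize_clean("___ 7 a")[[1]], character(0))
  expect_identical(tokenize_clean("Heel Goed")[[1]], c("heel", "goed"))
  # placeholders are dropped as non-words
  expect_identical(tokenize_clean("(NAME-1) was moe vandaag")[[1]],
                   c("was", "moe", "vandaag"))
  # a stopword that is also a negator survives via keep
  expect_identical(tokenize_clean("dat ging niet", stopwords = c("dat", "niet"),
                                  keep = "niet")[[1]],
                   c("ging", "niet"))
})

test_that("tokenization is idempotent on its own re-rendered output", {
  sw <- default_stopwords()
  texts <- c("De patiënt at vandaag niet goed, maar wel iets!",
             "Heel erg moe; 3x gehuild___ en weer opgestaan.")
  for (tx in texts) {
    once <- tokenize_clean(tx, sw, keep = "niet")[[1]]
    again <- tokenize_clean(paste(once, collapse = " "), sw, keep = "niet")[[1]]
    expect_identical(again, once)
  }
})

test_that("relevance filter needs five tokens and one sentiment word", {
  lex <- tiny_lex()
  expect_false(relevance_filter(c("goed", "goed", "goed", "goed"), lex))
  expect_false(relevance_filter(rep("neutraal", 6), lex))
  expect_true(relevance_filter(c("aa", "bb", "cc", "dd", "goed"), lex))
})

test_that("relevance filter is monotone in the lexicon", {
  small <- lexicon(c(goed = 1))
  big <- merge_lexicons(small, lexicon(c(moe = -1)))
  set.seed(41)
  for (i in 1:50) {
    tok <- sample(c("goed", "moe", "xx", "yy", "zz"), sample(1:10, 1),
                  replace = TRUE)
    if (relevance_filter(tok, small)) expect_true(relevance_filter(tok, big))
  }
})

test_that("record IO round-trips CSV and JSONL and validates seq", {
  df <- data.frame(record_id = c("r1", "r2", "r3"),
                   patient_id = c("p1", "p1", "p2"),
                   seq = c(1L, 2L, 1L),
                   text = c("niet goed vandaag", "beter", "rustig"))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  expect_identical(read_records(csv)$record_id, df$record_id)
  jl <- tempfile(fileext = ".jsonl")
  write_jsonl(df, jl)
  expect_identical(read_records(jl)$text, df$text)

  dup <- df; dup$seq <- c(1L, 1L, 1L)
  csv2 <- tempfile(fileext = ".csv")
  utils::write.csv(dup, csv2, row.names = FALSE)
  expect_error(read_records(csv2), "duplicated seq")
  expect_error(read_records(tempfile()), "not found")
})
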