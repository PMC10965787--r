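# Independent brute-force oracles and small fixture builders.
# These re-derive expected values by explicit enumeration, deliberately
# avoiding the package's own code paths.

# enumerate every (prev2, prev1, word) window explicitly
oracle_score <- function(tokens, entries, negators, intensifiers,
                         strategy = "ngram_mean", min_tokens = 5) {
  f <- function(w) {
    if (is.na(w)) return(1)
    if (w %in% negators) return(-1)
    if (w %in% intensifiers) return(2)
    1
  }
  big <- numeric(0); tri <- numeric(0)
  for (i in seq_along(tokens)) {
    w <- tokens[i]
    if (!(w %in% names(entries))) next
    base <- entries[[w]]
    p1 <- if (i >= 2) tokens[i - 1] else NA_character_
    p2 <- if (i >= 3) tokens[i - 2] else NA_character_
    big <- c(big, base * f(p1))
    tri <- c(tri, base * f(p1) * f(p2))
  }
  relevant <- length(tokens) >= min_tokens && length(big) > 0
  if (!length(big))
    return(list(bigram = NA_real_, trigram = NA_real_, overall = NA_real_,
                relevant = relevant))
  bf <- sum(big) / length(big)
  tf <- sum(tri) / length(tri)
  ov <- if (strategy == "ngram_mean") (bf + tf) / 2 else sum(tri) / length(tri)
  list(bigram = bf, trigram = tf,
       overall = if (relevant) max(-1, min(1, ov)) else NA_real_,
       relevant = relevant)
}

# direct double-loop Po/Pe summation
oracle_kappa <- function(m, weights) {
  C <- nrow(m); n <- sum(m)
  w <- matrix(0, C, C)
  for (i in 1:C) for (j in 1:C)
    w[i, j] <- switch(weights,
                      unweighted = as.numeric(i == j),
                      linear = 1 - abs(i - j) / (C - 1),
                      quadratic = 1 - ((i - j) / (C - 1))^2)
  Po <- 0; Pe <- 0
  for (i in 1:C) for (j in 1:C) {
    Po <- Po + w[i, j] * m[i, j] / n
    Pe <- Pe + w[i, j] * (sum(m[i, ]) / n) * (sum(m[, j]) / n)
  }
  (Po - Pe) / (1 - Pe)
}

# explicit residual sums of squares (not the SST decomposition the
# implementation uses)
oracle_icc_a1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  m <- mean(x)
  ri <- rowMeans(x); cj <- colMeans(x)
  SSR <- 0; SSC <- 0; SSE <- 0
  for (i in 1:n) SSR <- SSR + k * (ri[i] - m)^2
  for (j in 1:k) SSC <- SSC + n * (cj[j] - m)^2
  for (i in 1:n) for (j in 1:k)
    SSE <- SSE + (x[i, j] - ri[i] - cj[j] + m)^2
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# random lexicon + token stream for property tests
random_case <- function(max_tokens = 12) {
  vocab <- c("aap", "boom", "ceder", "duin", "egel", "fluit", "gras",
             "hout", "iris", "jurk", "kers", "lamp")
  roles <- sample(rep(c("pos", "neg", "negator", "intens", "plain"),
                      length.out = length(vocab)))
  entries <- integer(0)
  entries[vocab[roles == "pos"]] <- 1L
  entries[vocab[roles == "neg"]] <- -1L
  lex <- lexicon(entries,
                 negators = vocab[roles == "negator"],
                 intensifiers = vocab[roles == "intens"])
  tokens <- sample(vocab, sample(0:max_tokens, 1), replace = TRUE)
  list(lex = lex, tokens = tokens,
       entries = entries, negators = lex$negators,
       intensifiers = lex$intensifiers)
}

flip_lexicon <- function(lex)
  lexicon(-lex$entries, lex$negators, lex$intensifiers)

tiny_lex <- function()
  lexicon(c(goed = 1, slecht = -1), negators = "niet", intensifiers = "heel")

write_tsv_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path, useBytes = TRUE)
  path
}

# counts printed in the human-human contingency table (rows rater 1)
published_xtab <- matrix(c(106, 14, 5,
                           14, 43, 4,
                           7, 13, 57), nrow = 3, byrow = TRUE,
                         dimnames = list(c("negative", "neutral", "positive"),
                                         c("negative", "neutral", "positive")))
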