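#' @name scorer
#' @title Lexicon-based n-gram sentiment scoring
#'
#' @description
#' Each sentiment-bearing token (a token with lexicon polarity +1/-1) is
#' scored in two channels that look at the words immediately preceding it on
#' the cleaned token stream:
#'
#' * **bigram channel** — the base polarity, multiplied by 2 if the
#'   preceding token is an intensifier, negated if it is a negator;
#' * **trigram channel** — the bigram score additionally modified the same
#'   way by the token two positions back.
#'
#' Effect factors compose multiplicatively: `none = 1`, `reinforce = 2`,
#' `invert = -1`, so a double negation cancels and negator+intensifier give
#' -2 in either order. Tokens with no predecessor take factor 1 and still
#' count in the denominator.
#'
#' Channel finals are the channel scores summed over all matches divided by
#' the number of matches. The overall record score combines the channels
#' (see [score_record()]) and is clamped to `[-1, 1]`.
NULL

effect_of <- function(word, lex) {
  if (is.na(word)) return("none")
  if (word %in% lex$negators) return("invert")
  if (word %in% lex$intensifiers) return("reinforce")
  "none"
}

effect_factor <- c(none = 1, reinforce = 2, invert = -1)

#' Find sentiment-bearing tokens and their modifier context
#'
#' @param tokens Cleaned token vector.
#' @param lex A [lexicon()].
#' @return A data.frame with one row per match: `position`, `word`, `base`,
#'   `prev1_effect`, `prev2_effect`, `bigram_score`, `trigram_score`.
#' @examples
#' lex <- lexicon(c(goed = 1), negators = "niet", intensifiers = "heel")
#' find_matches(c("niet", "heel", "goed"), lex)   # trigram score -2
#' @export
find_matches <- function(tokens, lex) {
  pol <- polarity(lex, tokens)
  idx <- which(pol != 0L)
  prev1 <- vapply(idx, function(i)
    effect_of(if (i >= 2) tokens[i - 1] else NA_character_, lex), "")
  prev2 <- vapply(idx, function(i)
    effect_of(if (i >= 3) tokens[i - 2] else NA_character_, lex), "")
  bigram <- pol[idx] * effect_factor[prev1]
  trigram <- bigram * effect_factor[prev2]
  data.frame(position = idx, word = tokens[idx], base = pol[idx],
             prev1_effect = prev1, prev2_effect = prev2,
             bigram_score = unname(bigram), trigram_score = unname(trigram),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score one session record
#'
#' Applies the automated relevance filter, computes both n-gram channels and
#' the overall record score. Two combination strategies are available:
#' `"ngram_mean"` (default) averages the bigram and trigram channel finals;
#' `"token_mean"` averages the per-match trigram scores. Either way the
#' overall score is clamped to `[-1, 1]` (an intensified match can push a
#' channel final to +/-2).
#'
#' @param tokens Cleaned token vector.
#' @param lex A [lexicon()].
#' @param strategy `"ngram_mean"` or `"token_mean"`.
#' @param record_id Optional id carried into the result.
#' @param min_tokens Relevance threshold, see [relevance_filter()].
#' @return An object of class `"sentiment_result"`: list with `record_id`,
#'   `matches` (data.frame), `bigram_final`, `trigram_final`, `overall`
#'   (NA when irrelevant), `relevant_auto`.
#' @export
score_record <- function(tokens, lex, strategy = c("ngram_mean", "token_mean"),
                         record_id = NA_character_, min_tokens = 5L) {
  strategy <- match.arg(strategy)
  relevant <- relevance_filter(tokens, lex, min_tokens)
  matches <- find_matches(tokens, lex)
  nm <- nrow(matches)
  bigram_final <- if (nm) sum(matches$bigram_score) / nm else NA_real_
  trigram_final <- if (nm) sum(matches$trigram_score) / nm else NA_real_
  overall <- if (!relevant) NA_real_ else clamp(switch(
    strategy,
    ngram_mean = (bigram_final + trigram_final) / 2,
    token_mean = mean(matches$trigram_score)))
  structure(list(record_id = record_id, matches = matches,
                 bigram_final = bigram_final, trigram_final = trigram_final,
                 overall = overall, relevant_auto = relevant,
                 strategy = strategy),
            class = "sentiment_result")
}

#' @export
print.sentiment_result <- function(x, ...) {
  cat(sprintf("<sentiment_result> %s: %s\n",
              x$record_id,
              if (!x$relevant_auto) "irrelevant (filtered)"
              else sprintf("overall %.3f (bigram %.3f, trigram %.3f, %d matches)",
                           x$overall, x$bigram_final, x$trigram_final,
                           nrow(x$matches))))
  invisible(x)
}

#' Score every record of a corpus
#'
#' Deterministic, record-independent pass over a prepared corpus.
#'
#' @param corpus Data.frame from [prepare_corpus()] (needs `record_id`,
#'   `patient_id`, `seq`, list-column `tokens`).
#' @param lex A [lexicon()].
#' @inheritParams score_record
#' @param details Keep the per-record match tables as a list-column
#'   `matches` (needed by the audit functions).
#' @return A data.frame: record_id, patient_id, seq, n_tokens, n_matches,
#'   bigram_final, trigram_final, overall, relevant_auto.
#' @export
score_corpus <- function(corpus, lex,
                         strategy = c("ngram_mean", "token_mean"),
                         min_tokens = 5L, details = FALSE) {
  strategy <- match.arg(strategy)
  res <- lapply(seq_len(nrow(corpus)), function(i)
    score_record(corpus$tokens[[i]], lex, strategy,
                 record_id = corpus$record_id[i], min_tokens = min_tokens))
  out <- data.frame(
    record_id = corpus$record_id,
    patient_id = corpus$patient_id,
    seq = corpus$seq,
    n_tokens = lengths(corpus$tokens),
    n_matches = vapply(res, function(r) nrow(r$matches), 0L),
    bigram_final = vapply(res, function(r) r$bigram_final, 0),
    trigram_final = vapply(res, function(r) r$trigram_final, 0),
    overall = vapply(res, function(r) r$overall, 0),
    relevant_auto = vapply(res, function(r) r$relevant_auto, TRUE),
    stringsAsFactors = FALSE)
  if (details) out$matches <- lapply(res, function(r) r$matches)
  out
}
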