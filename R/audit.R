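#' Read a context-specific sentiment word list
#'
#' Expressions of 1-3 lowercase tokens with an intended polarity and a
#' context label (e.g. a diagnosis tag). These capture domain sentiment the
#' general lexicon misses or mis-signs; a small synthetic illustrative list
#' ships in `inst/extdata/context_ed_synthetic.tsv`.
#'
#' @param path TSV path (columns: expression, polarity, context). Default:
#'   the bundled synthetic list.
#' @return Data.frame of class `"context_words"`: expression, polarity,
#'   context, head (last token of the expression).
#' @export
read_context_words <- function(path = system.file(
                                 "extdata", "context_ed_synthetic.tsv",
                                 package = "sentisess")) {
  tl <- read_tsv_lines(path)
  rows <- lapply(tl$idx, function(i) {
    fields <- strsplit(tl$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop_data(sprintf("%s:%d: expected at least 2 tab-separated fields", path, i))
    expr <- tolower(trimws(fields[1]))
    ntok <- length(strsplit(expr, " ", fixed = TRUE)[[1]])
    if (ntok < 1 || ntok > 3)
      stop_data(sprintf("%s:%d: expression must have 1-3 tokens", path, i))
    pol <- parse_polarity(trimws(fields[2]))
    if (is.na(pol)) stop_data(sprintf("%s:%d: unparseable polarity", path, i))
    data.frame(expression = expr, polarity = pol,
               context = if (length(fields) >= 3) trimws(fields[3]) else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$expression), , drop = FALSE]
  out$head <- vapply(strsplit(out$expression, " ", fixed = TRUE),
                     function(t) t[length(t)], "")
  rownames(out) <- NULL
  class(out) <- c("context_words", "data.frame")
  out
}

#' Per-record match report
#'
#' One row per sentiment-bearing token of a scored record, in text order:
#' which word fired, its base polarity, which modifier effects applied, and
#' the resulting bigram/trigram scores. For an irrelevant record an empty
#' table is returned with attribute `note`.
#'
#' @param result A `"sentiment_result"` from [score_record()].
#' @return Data.frame of matches (possibly 0 rows).
#' @export
match_report <- function(result) {
  stopifnot(inherits(result, "sentiment_result"))
  if (!result$relevant_auto) {
    out <- result$matches[0, , drop = FALSE]
    attr(out, "note") <- sprintf("record %s excluded by the relevance filter",
                                 result$record_id)
    return(out)
  }
  result$matches[order(result$matches$position), , drop = FALSE]
}

count_expression <- function(tokens_list, expr_tokens) {
  L <- length(expr_tokens)
  sum(vapply(tokens_list, function(tok) {
    nt <- length(tok)
    if (nt < L) return(0L)
    sum(vapply(seq_len(nt - L + 1), function(s)
      all(tok[s:(s + L - 1)] == expr_tokens), TRUE))
  }, 0L))
}

#' Context expressions the lexicon missed
#'
#' Finds context-list expressions that occur in the cleaned corpus (as a
#' contiguous token run) but whose head (last) token has no lexicon
#' polarity — i.e. domain sentiment invisible to the scorer. Sorted by
#' frequency (desc), then alphabetically.
#'
#' @param corpus Data.frame with list-column `tokens` (see
#'   [prepare_corpus()]).
#' @param lex A [lexicon()].
#' @param context A [read_context_words()] table.
#' @return Data.frame: expression, polarity, context, frequency.
#' @export
missing_context_words <- function(corpus, lex, context) {
  if (!nrow(context)) return(data.frame(expression = character(),
                                        polarity = integer(),
                                        context = character(),
                                        frequency = integer()))
  unmatched <- context[polarity(lex, context$head) == 0L, , drop = FALSE]
  freq <- vapply(strsplit(unmatched$expression, " ", fixed = TRUE),
                 function(et) count_expression(corpus$tokens, et), 0L)
  out <- data.frame(expression = unmatched$expression,
                    polarity = unmatched$polarity,
                    context = unmatched$context,
                    frequency = freq, stringsAsFactors = FALSE)
  out <- out[out$frequency > 0, , drop = FALSE]
  out <- out[order(-out$frequency, out$expression), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lexicon-vs-context polarity conflicts
#'
#' Words the scorer matched whose lexicon polarity has the opposite sign of
#' the context list's intended polarity (e.g. "exercising" positive in a
#' general lexicon, negative in an anorexia context). Counted over the
#' actual matches of a scored corpus.
#'
#' @param scored Data.frame from [score_corpus()] with `details = TRUE`
#'   (needs the `matches` list-column).
#' @param context A [read_context_words()] table.
#' @return Data.frame: word, lexicon_polarity, context_polarity, frequency.
#' @export
polarity_conflicts <- function(scored, context) {
  if (is.null(scored$matches))
    stop_data("polarity_conflicts needs score_corpus(..., details = TRUE)")
  all_matches <- do.call(rbind, scored$matches)
  if (is.null(all_matches) || !nrow(all_matches) || !nrow(context))
    return(data.frame(word = character(), lexicon_polarity = integer(),
                      context_polarity = integer(), frequency = integer()))
  ctx <- context[!duplicated(context$head), , drop = FALSE]
  idx <- match(all_matches$word, ctx$head)
  hit <- !is.na(idx) & sign(all_matches$base) != sign(ctx$polarity[idx])
  if (!any(hit))
    return(data.frame(word = character(), lexicon_polarity = integer(),
                      context_polarity = integer(), frequency = integer()))
  h <- all_matches[hit, , drop = FALSE]
  h$context_polarity <- ctx$polarity[idx[hit]]
  agg <- stats::aggregate(list(frequency = rep(1L, nrow(h))),
                          by = list(word = h$word,
                                    lexicon_polarity = h$base,
                                    context_polarity = h$context_polarity),
                          FUN = sum)
  agg <- agg[order(-agg$frequency, agg$word), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
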