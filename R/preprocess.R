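#' Read session records from CSV or JSONL
#'
#' Expected columns/keys: `record_id`, `patient_id`, `seq` (non-negative
#' integer giving temporal order within a patient) and `text`. Records are
#' returned ordered by patient then sequence; a duplicated or non-increasing
#' `seq` within a patient is an error.
#'
#' @param path File path; format inferred from the extension (`.csv` or
#'   `.jsonl`/`.ndjson`) unless `format` is given.
#' @param format `"csv"`, `"jsonl"` or `NULL` (infer).
#' @return A data.frame with columns record_id, patient_id, seq, text.
#' @export
read_records <- function(path, format = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               csv = "csv", jsonl = "jsonl", ndjson = "jsonl",
                               stop_data("cannot infer format of ", path))
  df <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  } else {
    as.data.frame(jsonlite::stream_in(file(path), verbose = FALSE))
  }
  need <- c("record_id", "patient_id", "seq", "text")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_data("records file lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- df[need]
  df$seq <- as.integer(df$seq)
  if (anyNA(df$seq) || any(df$seq < 0))
    stop_data("seq must be a non-negative integer")
  df <- df[order(df$patient_id, df$seq), , drop = FALSE]
  dup <- stats::ave(df$seq, df$patient_id, FUN = function(s) duplicated(s))
  if (any(dup == 1))
    stop_data("duplicated seq within patient: ",
              paste(unique(df$patient_id[dup == 1]), collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write records or results to JSONL
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' Default Dutch stopword list
#'
#' The bundled compact Dutch list, minus any word configured as a negator or
#' intensifier in `lex` — valence shifters must survive stopword removal or
#' negation handling breaks silently.
#'
#' @param lex Optional [lexicon()] whose modifiers are exempted.
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function(lex = NULL) {
  sw <- read_wordlist(system.file("extdata", "stopwords_nl.tsv",
                                  package = "sentisess"))
  if (!is.null(lex)) sw <- setdiff(sw, c(lex$negators, lex$intensifiers))
  sw
}

months_nl <- c("januari", "februari", "maart", "april", "mei", "juni", "juli",
               "augustus", "september", "oktober", "november", "december")

#' De-identification placeholder pass
#'
#' A best-effort regex/gazetteer pass emulating the *output format* of Dutch
#' clinical de-identification tools: e-mail addresses, URLs, phone numbers
#' and postal codes are deleted; date expressions become `(DATE-k)`, age
#' expressions `(AGE)`, gazetteer place names `(LOCATION-k)` and remaining
#' capitalized name-like tokens (not sentence-initial) `(NAME-k)`.
#' Placeholder numbering restarts at 1 for each record.
#'
#' This is a test-fixture convenience for working with already-pseudonymized
#' corpora — **not** a compliance-grade de-identification tool.
#'
#' @param text Character vector of record texts.
#' @param gazetteer Character vector of lowercase place names; defaults to
#'   the bundled Dutch list.
#' @return Character vector of the same length.
#' @export
pseudonymize <- function(text,
                         gazetteer = read_wordlist(
                           system.file("extdata", "locations_nl.tsv",
                                       package = "sentisess"))) {
  vapply(text, pseudonymize_one, "", gazetteer = gazetteer, USE.NAMES = FALSE)
}

pseudonymize_one <- function(x, gazetteer) {
  if (is.na(x) || !nzchar(x)) return(if (is.na(x)) NA_character_ else x)
  # contact details: deleted outright
  x <- gsub("[[:alnum:]._%+-]+@[[:alnum:].-]+\\.[[:alpha:]]{2,}", "", x)
  x <- gsub("(https?://|www\\.)[^[:space:]]+", "", x)
  x <- gsub("(\\+31|0031|0)([ -]?[0-9]){9}\\b", "", x)                 # phone
  x <- gsub("\\b[1-9][0-9]{3} ?[A-Z]{2}\\b", "", x)                    # postal code
  counters <- new.env(parent = emptyenv())
  place <- function(cat, numbered = TRUE) {
    if (!numbered) return("(AGE)")
    k <- (get0(cat, counters, ifnotfound = 0L)) + 1L
    assign(cat, k, counters)
    sprintf("(%s-%d)", cat, k)
  }
  sub_counted <- function(x, pattern, cat, numbered = TRUE, ...) {
    m <- gregexpr(pattern, x, perl = TRUE, ...)[[1]]
    if (m[1] == -1) return(x)
    regmatches(x, list(m)) <- list(vapply(seq_along(m), function(i)
      place(cat, numbered), ""))
    x
  }
  month_alt <- paste(months_nl, collapse = "|")
  x <- sub_counted(x, "\\b\\d{1,2}[-/]\\d{1,2}[-/]\\d{2,4}\\b", "DATE")
  x <- sub_counted(x, sprintf("(?i)\\b\\d{1,2} (%s)( \\d{4})?\\b", month_alt), "DATE")
  x <- sub_counted(x, "\\b\\d{1,3} jaar( oud)?\\b", "AGE", numbered = FALSE)
  if (length(gazetteer)) {
    gaz <- sprintf("(?i)\\b(%s)\\b", paste(gazetteer, collapse = "|"))
    x <- sub_counted(x, gaz, "LOCATION")
  }
  # capitalized name-like tokens, skipping sentence-initial position
  m <- gregexpr("\\b\\p{Lu}\\p{Ll}+\\b", x, perl = TRUE)[[1]]
  if (m[1] != -1) {
    starts <- as.integer(m)
    keep <- vapply(starts, function(s) {
      before <- substr(x, 1, s - 1)
      !grepl("(^|[.!?])[\"')]*\\s*$", before)  # sentence-initial -> not a name
    }, TRUE)
    if (any(keep)) {
      mm <- m[keep]; attr(mm, "match.length") <- attr(m, "match.length")[keep]
      regmatches(x, list(mm)) <- list(vapply(seq_len(sum(keep)),
                                             function(i) place("NAME"), ""))
    }
  }
  trimws(gsub("[ \t]+", " ", x))
}

#' Tokenize and clean record text
#'
#' Splits on runs of non-letter characters (Unicode letters kept, so
#' diacritics survive; digits, punctuation and underscores act as
#' separators, which also drops placeholders like `(NAME-1)`), lowercases,
#' and removes stopwords, pure-number tokens, single-character tokens and
#' tokens containing underscores. Words listed in `keep` — typically the
#' lexicon's negators and intensifiers — are never removed.
#'
#' @param text Character vector.
#' @param stopwords Character vector (may be empty).
#' @param keep Character vector of words exempt from removal.
#' @return A list of character vectors (one token vector per input element).
#' @export
tokenize_clean <- function(text, stopwords = character(), keep = character()) {
  drop <- setdiff(tolower(stopwords), tolower(keep))
  text <- gsub("\\((NAME|DATE|LOCATION|AGE)(-[0-9]+)?\\)", " ", text)
  lapply(strsplit(tolower(text), "[^\\p{L}]+", perl = TRUE), function(tok) {
    tok <- tok[nzchar(tok)]
    tok <- tok[nchar(tok) > 1]
    tok <- tok[!grepl("^[0-9]+$", tok) & !grepl("_", tok, fixed = TRUE)]
    tok[!tok %in% drop]
  })
}

#' Automated relevance filter
#'
#' A record is relevant for the automated analysis iff its cleaned token
#' stream has at least `min_tokens` tokens **and** contains at least one
#' sentiment-bearing word (a token with lexicon polarity).
#'
#' @param tokens A token vector, or a list of them.
#' @param lex A [lexicon()].
#' @param min_tokens Minimum token count (default 5).
#' @return Logical vector.
#' @export
relevance_filter <- function(tokens, lex, min_tokens = 5L) {
  if (!is.list(tokens)) tokens <- list(tokens)
  vapply(tokens, function(tok)
    length(tok) >= min_tokens && any(polarity(lex, tok) != 0L), TRUE)
}

#' Prepare a corpus for scoring
#'
#' Tokenizes and cleans every record (modifiers exempt from stopword
#' removal) and applies the automated relevance filter.
#'
#' @param records Data.frame from [read_records()] (or with the same columns).
#' @param lex A [lexicon()].
#' @param stopwords Stopword vector; default [default_stopwords()] for `lex`.
#' @return `records` with list-column `tokens` and logical `relevant_auto`.
#' @export
prepare_corpus <- function(records, lex, stopwords = default_stopwords(lex)) {
  records$tokens <- tokenize_clean(records$text, stopwords,
                                   keep = c(lex$negators, lex$intensifiers))
  records$relevant_auto <- relevance_filter(records$tokens, lex)
  records
}
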