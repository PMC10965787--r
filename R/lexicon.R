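#' Construct a sentiment lexicon
#'
#' A lexicon maps lowercase words to a binary polarity (+1 or -1) and carries
#' two modifier word sets that shift the valence of the *following* sentiment
#' word: negators invert it, intensifiers double it. Modifier words and
#' polarity entries are disjoint by default, so a token acts either as a
#' valence shifter or as a sentiment word, never both; set
#' `allow_modifier_overlap = TRUE` to permit the overlap.
#'
#' @param entries Named integer vector, word -> polarity in `{+1, -1}`.
#' @param negators Character vector of negator words.
#' @param intensifiers Character vector of intensifier (reinforcer) words.
#' @param provenance Character vector naming the sources, in merge order.
#' @param allow_modifier_overlap Permit a word to be both an entry and a
#'   modifier (default `FALSE`: the constructor rejects the overlap).
#' @return An object of class `"sentilex"`.
#' @examples
#' lex <- lexicon(c(goed = 1, slecht = -1), negators = "niet",
#'                intensifiers = "heel")
#' polarity(lex, c("goed", "niet", "onbekend"))
#' @export
lexicon <- function(entries = integer(), negators = character(),
                    intensifiers = character(), provenance = "user",
                    allow_modifier_overlap = FALSE) {
  entries <- as.integer(entries) |> stats::setNames(names(entries) %||% character())
  words <- names(entries)
  if (length(entries)) {
    if (is.null(words) || any(!nzchar(words)))
      stop_data("lexicon entries must be a named vector of non-empty words")
    if (any(grepl("\\s", words)))
      stop_data("lexicon words must not contain whitespace: ",
                paste(words[grepl("\\s", words)], collapse = ", "))
    if (any(words != tolower(words)))
      stop_data("lexicon words must be lowercase")
    if (any(duplicated(words)))
      stop_data("duplicate lexicon words: ",
                paste(unique(words[duplicated(words)]), collapse = ", "))
    if (!all(entries %in% c(1L, -1L)))
      stop_data("lexicon polarity must be +1 or -1")
  }
  negators <- unique(tolower(negators))
  intensifiers <- unique(tolower(intensifiers))
  both <- intersect(negators, intensifiers)
  if (length(both))
    stop_data("words cannot be both negator and intensifier: ",
              paste(both, collapse = ", "))
  overlap <- intersect(words, c(negators, intensifiers))
  if (length(overlap) && !allow_modifier_overlap)
    stop_data("words present both as entry and modifier (set ",
              "allow_modifier_overlap = TRUE to permit): ",
              paste(overlap, collapse = ", "))
  structure(list(entries = entries, negators = negators,
                 intensifiers = intensifiers,
                 provenance = as.character(provenance),
                 allow_modifier_overlap = allow_modifier_overlap),
            class = "sentilex")
}

#' @export
print.sentilex <- function(x, ...) {
  cat(sprintf(
    "<sentilex> %d entries (%d positive, %d negative), %d negators, %d intensifiers\n",
    length(x$entries), sum(x$entries > 0), sum(x$entries < 0),
    length(x$negators), length(x$intensifiers)))
  cat("  provenance:", paste(x$provenance, collapse = " < "), "\n")
  invisible(x)
}

#' Look up word polarity
#'
#' @param lex A [lexicon()].
#' @param words Character vector of (lowercase) tokens.
#' @return Integer vector: +1/-1 for lexicon entries, 0 for words with no
#'   polarity (absent or removed words contribute no sentiment).
#' @export
polarity <- function(lex, words) {
  stopifnot(inherits(lex, "sentilex"))
  p <- unname(lex$entries[words])
  p[is.na(p)] <- 0L
  p
}

parse_polarity <- function(tok) {
  switch(tolower(tok), "+1" = 1L, "1" = 1L, "pos" = 1L,
         "-1" = -1L, "neg" = -1L, NA_integer_)
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  list(lines = lines, idx = which(keep))
}

#' Read a polarity lexicon from TSV
#'
#' Expects two tab-separated columns: word and polarity (`+1`, `-1`, `pos` or
#' `neg`). Lines starting with `#` are comments; a single header line is
#' skipped if its second field is not a parseable polarity. Words are
#' lowercased; duplicates with identical polarity are deduplicated, while a
#' duplicate with conflicting polarity is an error.
#'
#' @param path TSV file path.
#' @param negators,intensifiers Optional modifier word vectors (or paths to
#'   one-word-per-line TSV lists, see [read_wordlist()]).
#' @param name Provenance label (defaults to the file name).
#' @inheritParams lexicon
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path, negators = character(),
                         intensifiers = character(),
                         name = basename(path),
                         allow_modifier_overlap = FALSE) {
  tl <- read_tsv_lines(path)
  words <- character(); pols <- integer()
  first_data <- TRUE
  for (i in tl$idx) {
    fields <- strsplit(tl$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop_data(sprintf("%s:%d: expected at least 2 tab-separated fields", path, i))
    pol <- parse_polarity(trimws(fields[2]))
    if (is.na(pol)) {
      if (first_data) { first_data <- FALSE; next }  # header line
      stop_data(sprintf("%s:%d: unparseable polarity '%s'", path, i, fields[2]))
    }
    first_data <- FALSE
    w <- tolower(trimws(fields[1]))
    prev <- match(w, words)
    if (!is.na(prev)) {
      if (pols[prev] != pol)
        stop_data(sprintf("%s:%d: word '%s' already defined with polarity %+d",
                          path, i, w, pols[prev]))
      next  # same-polarity duplicate
    }
    words <- c(words, w); pols <- c(pols, pol)
  }
  if (length(negators) == 1 && file.exists(negators))
    negators <- read_wordlist(negators)
  if (length(intensifiers) == 1 && file.exists(intensifiers))
    intensifiers <- read_wordlist(intensifiers)
  lexicon(stats::setNames(pols, words), negators, intensifiers,
          provenance = name, allow_modifier_overlap = allow_modifier_overlap)
}

#' Read a one-word-per-line word list (TSV/plain text)
#'
#' `#` comment lines are skipped; only the first tab-separated field of each
#' line is used; words are lowercased and deduplicated.
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_wordlist <- function(path) {
  tl <- read_tsv_lines(path)
  w <- vapply(tl$idx, function(i)
    tolower(trimws(strsplit(tl$lines[i], "\t", fixed = TRUE)[[1]][1])), "")
  unique(w[nzchar(w)])
}

#' Construct or read an adjustment dictionary
#'
#' Adjustments resolve words with multiple meanings: a word is either removed
#' from the merged lexicon or its polarity overridden. The two sets are
#' disjoint.
#'
#' @param removals Character vector of words to remove.
#' @param overrides Named integer vector, word -> polarity in `{+1, -1}`.
#' @return An object of class `"sentilex_adjust"`.
#' @export
adjustments <- function(removals = character(), overrides = integer()) {
  removals <- unique(tolower(removals))
  overrides <- stats::setNames(as.integer(overrides),
                               tolower(names(overrides) %||% character()))
  if (length(overrides) && !all(overrides %in% c(1L, -1L)))
    stop_data("override polarity must be +1 or -1")
  both <- intersect(removals, names(overrides))
  if (length(both))
    stop_data("words cannot be both removed and overridden: ",
              paste(both, collapse = ", "))
  structure(list(removals = removals, overrides = overrides),
            class = "sentilex_adjust")
}

#' @describeIn adjustments Read adjustments from a 2-column TSV
#'   (word, action) where action is `remove`, `+1` or `-1`.
#' @param path TSV file path.
#' @export
read_adjustments <- function(path) {
  tl <- read_tsv_lines(path)
  removals <- character(); ow <- character(); op <- integer()
  for (i in tl$idx) {
    fields <- strsplit(tl$lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop_data(sprintf("%s:%d: expected 2 tab-separated fields", path, i))
    w <- tolower(trimws(fields[1])); action <- tolower(trimws(fields[2]))
    if (action == "remove") removals <- c(removals, w)
    else {
      pol <- parse_polarity(action)
      if (is.na(pol))
        stop_data(sprintf("%s:%d: action must be remove, +1 or -1 (got '%s')",
                          path, i, action))
      ow <- c(ow, w); op <- c(op, pol)
    }
  }
  adjustments(removals, stats::setNames(op, ow))
}

#' Merge lexicons with domain precedence and adjustments
#'
#' Mirrors the three-lexicon setup common in domain-tuned sentiment analysis:
#' a broad primary lexicon, a domain-specific lexicon that overrides it on
#' conflicts, and an adjustment dictionary applied last (overrides, then
#' removals). Modifier sets are unioned. Merging with an empty domain lexicon
#' and empty adjustments is the identity.
#'
#' @param primary,domain [lexicon()] objects (`domain` may be `NULL`).
#' @param adj An [adjustments()] object (may be `NULL`).
#' @return A merged [lexicon()]; `provenance` records the merge order.
#' @export
merge_lexicons <- function(primary, domain = NULL, adj = NULL) {
  stopifnot(inherits(primary, "sentilex"))
  entries <- primary$entries
  negators <- primary$negators
  intensifiers <- primary$intensifiers
  prov <- primary$provenance
  allow <- primary$allow_modifier_overlap
  if (!is.null(domain)) {
    stopifnot(inherits(domain, "sentilex"))
    entries[names(domain$entries)] <- domain$entries
    negators <- union(negators, domain$negators)
    intensifiers <- union(intensifiers, domain$intensifiers)
    prov <- c(prov, domain$provenance)
    allow <- allow || domain$allow_modifier_overlap
  }
  if (!is.null(adj)) {
    stopifnot(inherits(adj, "sentilex_adjust"))
    entries[names(adj$overrides)] <- adj$overrides
    entries <- entries[setdiff(names(entries), adj$removals)]
    prov <- c(prov, "adjustments")
  }
  lexicon(entries, negators, intensifiers, provenance = prov,
          allow_modifier_overlap = allow)
}

#' Bundled demonstration lexicon
#'
#' A small Dutch polarity lexicon (40 words) with common negators and
#' intensifiers, shipped for examples, tests and the synthetic-data
#' generator. It is illustrative only — real analyses require user-supplied
#' lexicons.
#'
#' @return A [lexicon()].
#' @export
demo_lexicon <- function() {
  read_lexicon(
    system.file("extdata", "lexicon_demo.tsv", package = "sentisess"),
    negators = system.file("extdata", "negators_nl.tsv", package = "sentisess"),
    intensifiers = system.file("extdata", "intensifiers_nl.tsv",
                               package = "sentisess"),
    name = "demo")
}
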