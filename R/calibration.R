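#' Standardize a set of raw scores
#'
#' Converts raw record scores to z-scores so the automated and human
#' analyses live on a common scale. Standardization pools all supplied
#' records (typically all relevant records across patients).
#'
#' @param values Named numeric vector (names = record ids); NAs dropped.
#' @param population_sd Use the population (divide by n) instead of the
#'   sample (n-1) standard deviation.
#' @return An object of class `"score_set"`: list with `values`, `mean`,
#'   `sd`, `z` (named, same order as `values`).
#' @examples
#' standardize_scores(c(a = 0, b = 1, c = 2))$z   # -1 0 1
#' @export
standardize_scores <- function(values, population_sd = FALSE) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stop_data("standardization needs at least 2 finite values")
  mu <- mean(values)
  sdv <- stats::sd(values)
  if (population_sd) sdv <- sdv * sqrt((length(values) - 1) / length(values))
  if (!is.finite(sdv) || sdv == 0)
    stop_data("standardization undefined: all values identical")
  structure(list(values = values, mean = mu, sd = sdv,
                 z = (values - mu) / sdv),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> n=%d, mean=%.4f, sd=%.4f\n",
              length(x$values), x$mean, x$sd))
  invisible(x)
}

#' Data-driven neutral band for standardized scores
#'
#' Because a continuous scorer rarely produces an exact zero, "neutral" is
#' defined as the interval bounded by the standardized score closest to zero
#' from below and the one closest to zero from above: `lo` = largest
#' strictly-negative z, `hi` = smallest strictly-positive z. Exact zeros lie
#' inside the band.
#'
#' @param z Numeric vector of standardized scores (or a `score_set`).
#' @return An object of class `"neutral_band"`: list with `lo` and `hi`.
#' @examples
#' neutral_band_from_scores(c(-1.2, -0.03, 0.11, 0.9))  # lo -0.03, hi 0.11
#' @export
neutral_band_from_scores <- function(z) {
  if (inherits(z, "score_set")) z <- z$z
  z <- z[is.finite(z)]
  neg <- z[z < 0]; pos <- z[z > 0]
  if (!length(neg) || !length(pos))
    stop_data("scores are one-signed; supply a manual band via neutral_band()")
  neutral_band(max(neg), min(pos))
}

#' @describeIn neutral_band_from_scores Manual band constructor
#'   (`lo <= 0 <= hi`).
#' @param lo,hi Band bounds.
#' @export
neutral_band <- function(lo, hi) {
  if (!(lo <= 0 && 0 <= hi)) stop_data("neutral band must satisfy lo <= 0 <= hi")
  structure(list(lo = lo, hi = hi), class = "neutral_band")
}

#' @export
print.neutral_band <- function(x, ...) {
  cat(sprintf("<neutral_band> [%.4g, %.4g]\n", x$lo, x$hi)); invisible(x)
}

sentiment_levels <- c("negative", "neutral", "positive")

#' Categorize standardized automated scores
#'
#' `negative` for z strictly below the band, `positive` strictly above,
#' `neutral` otherwise (band boundaries inclusive-neutral). NAs propagate.
#'
#' @param z Numeric vector of standardized scores.
#' @param band A [neutral_band()].
#' @return Ordered factor with levels negative < neutral < positive.
#' @export
categorize_auto <- function(z, band) {
  stopifnot(inherits(band, "neutral_band"))
  out <- ifelse(is.na(z), NA_character_,
                ifelse(z < band$lo, "negative",
                       ifelse(z > band$hi, "positive", "neutral")))
  factor(out, levels = sentiment_levels, ordered = TRUE)
}

#' Categorize raw human ratings on the 1-7 scale
#'
#' Ratings below the scale midpoint 4 are negative, 4 is neutral, above 4
#' positive. Applied to raw per-rater scores (their distribution is shared
#' across raters, so raw and standardized categories coincide).
#'
#' @param score Numeric vector of 1-7 ratings (NA = irrelevant).
#' @return Ordered factor with levels negative < neutral < positive.
#' @export
categorize_human <- function(score) {
  out <- ifelse(is.na(score), NA_character_,
                ifelse(score < 4, "negative",
                       ifelse(score > 4, "positive", "neutral")))
  factor(out, levels = sentiment_levels, ordered = TRUE)
}

#' Read human ratings from CSV
#'
#' Expected columns: `record_id`, `rater_id`, `score` (1-7, empty/NA =
#' irrelevant) and optionally `mixed` (0/1). "Mixed" marks records with an
#' equal amount of positive and negative sentiment; they are scored 4 and
#' treated as neutral in all agreement statistics, the flag is descriptive
#' metadata. A mixed flag on a non-neutral score is an error.
#'
#' @param path CSV file path.
#' @return Data.frame: record_id, rater_id, score (numeric), mixed (logical),
#'   category (ordered factor).
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- utils::read.csv(path, encoding = "UTF-8")
  need <- c("record_id", "rater_id", "score")
  if (length(setdiff(need, names(df))))
    stop_data("ratings file lacks columns: ",
              paste(setdiff(need, names(df)), collapse = ", "))
  df$score <- suppressWarnings(as.numeric(df$score))
  bad <- !is.na(df$score) & (df$score < 1 | df$score > 7)
  if (any(bad)) stop_data("ratings outside the 1-7 scale for records: ",
                          paste(df$record_id[bad], collapse = ", "))
  df$mixed <- if ("mixed" %in% names(df)) as.logical(as.integer(df$mixed)) else FALSE
  df$mixed[is.na(df$mixed)] <- FALSE
  df$category <- categorize_human(df$score)
  badmix <- df$mixed & (is.na(df$category) | df$category != "neutral")
  if (any(badmix))
    stop_data("mixed flag on non-neutral rating for records: ",
              paste(df$record_id[badmix], collapse = ", "))
  df[c("record_id", "rater_id", "score", "mixed", "category")]
}

#' Average the two raters' scores per record
#'
#' The overall human sentiment value of a record is the mean of both raters'
#' 1-7 scores, computed only over records rated (non-irrelevant) by *both*
#' raters, then standardized.
#'
#' @param r1,r2 Named numeric vectors of one rater's scores (names = record
#'   ids, NA = irrelevant).
#' @return A `score_set` (see [standardize_scores()]) whose `values` are the
#'   per-record means on the raw 1-7 scale.
#' @export
average_human <- function(r1, r2) {
  ids <- intersect(names(r1)[!is.na(r1)], names(r2)[!is.na(r2)])
  if (!length(ids)) stop_data("no records rated by both raters")
  standardize_scores(stats::setNames((r1[ids] + r2[ids]) / 2, ids))
}

#' Reshape long ratings to one named score vector per rater
#'
#' @param ratings Data.frame from [read_ratings()].
#' @return Named list of named numeric vectors, one element per rater_id.
#' @export
ratings_by_rater <- function(ratings) {
  lapply(split(ratings, ratings$rater_id), function(d)
    stats::setNames(d$score, d$record_id))
}
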