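#' Relevance summary of a scored corpus
#'
#' @param scored Data.frame from [score_corpus()].
#' @return List: `n_total`, `n_relevant`, `pct_relevant` (numeric, half-up
#'   to 1 decimal), `label` (e.g. `"315 (68.5%)"`), and mean/sd of records
#'   per patient.
#' @export
relevance_summary <- function(scored) {
  n <- nrow(scored); nr <- sum(scored$relevant_auto)
  per_patient <- as.vector(table(scored$patient_id))
  list(n_total = n, n_relevant = nr,
       pct_relevant = round_half_up(100 * nr / n, 1),
       label = fmt_count_pct(nr, n),
       mean_records_per_patient = mean(per_patient),
       sd_records_per_patient = stats::sd(per_patient))
}

#' Category frequency table (one rater/analysis)
#'
#' @param cats Factor/character vector of categories (NA = irrelevant,
#'   dropped).
#' @return Data.frame: category, n, pct (of categorized records, half-up to
#'   1 decimal), label.
#' @export
category_frequency <- function(cats) {
  cats <- factor(as.character(cats), levels = sentiment_levels)
  cats <- cats[!is.na(cats)]
  tab <- table(cats); n <- sum(tab)
  data.frame(category = names(tab), n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / n, 1),
             label = vapply(as.integer(tab), fmt_count_pct, "", total = n),
             row.names = NULL)
}

#' Score a record corpus end to end
#'
#' Tokenizes, filters and scores all records, standardizes the relevant
#' scores, derives the data-driven neutral band and the categorical view.
#'
#' @param records Data.frame (record_id, patient_id, seq, text).
#' @param lex A [lexicon()].
#' @param stopwords Stopword vector.
#' @param strategy Scorer strategy, see [score_record()].
#' @param band Optional fixed [neutral_band()]; default: derived from the
#'   standardized scores.
#' @return List of class `"score_run"`: `scores` (per-record data.frame
#'   with added `z` and `category`), `score_set`, `band`, `summary`,
#'   `frequency`.
#' @export
run_score <- function(records, lex, stopwords = default_stopwords(lex),
                      strategy = c("ngram_mean", "token_mean"), band = NULL) {
  corpus <- prepare_corpus(records, lex, stopwords)
  scored <- score_corpus(corpus, lex, strategy, details = TRUE)
  ss <- standardize_scores(stats::setNames(scored$overall, scored$record_id))
  if (is.null(band)) band <- neutral_band_from_scores(ss)
  scored$z <- unname(ss$z[scored$record_id])
  scored$category <- categorize_auto(scored$z, band)
  structure(list(scores = scored, score_set = ss, band = band,
                 summary = relevance_summary(scored),
                 frequency = category_frequency(scored$category)),
            class = "score_run")
}

#' @export
print.score_run <- function(x, ...) {
  cat(sprintf("<score_run> %d records, relevant %s; neutral band [%.3f, %.3f]\n",
              x$summary$n_total, x$summary$label, x$band$lo, x$band$hi))
  print(x$frequency)
  invisible(x)
}

rater_vectors <- function(ratings) {
  rv <- ratings_by_rater(ratings)
  if (length(rv) != 2)
    stop_data("agreement needs exactly 2 raters, got ", length(rv))
  rv
}

#' Full agreement analysis: automated vs raters, rater vs rater
#'
#' Computes, Tables-style: weighted kappa on the categorical views
#' (automated vs each rater, rater vs rater) with the corresponding
#' contingency tables; ICC(A,1) on the continuous views (standardized
#' automated score vs each rater's standardized score; rater 1 vs rater 2
#' raw scores); and per-patient ICCs for each automated-rater pairing.
#'
#' @param run A `"score_run"` from [run_score()].
#' @param ratings Data.frame as from [read_ratings()] with two rater ids.
#' @param alpha Significance level (CIs at `1 - alpha`).
#' @param weights Kappa weight scheme.
#' @param min_pairs Per-patient minimum complete pairs.
#' @return List of class `"agreement_report"`.
#' @export
run_agreement <- function(run, ratings, alpha = 0.05,
                          weights = c("linear", "unweighted", "quadratic"),
                          min_pairs = 3L) {
  weights <- match.arg(weights)
  stopifnot(inherits(run, "score_run"))
  rv <- rater_vectors(ratings)
  rater_ids <- names(rv)
  scored <- run$scores
  auto_cat <- stats::setNames(scored$category, scored$record_id)
  auto_z <- stats::setNames(scored$z, scored$record_id)
  patient_of <- stats::setNames(scored$patient_id, scored$record_id)

  cat_of <- function(v) stats::setNames(as.character(categorize_human(v)), names(v))
  z_of <- function(v) {
    ss <- standardize_scores(v)
    stats::setNames(ss$z, names(ss$values))
  }

  pairs <- list()
  for (r in rater_ids) {
    tab <- build_table(auto_cat, cat_of(rv[[r]]))
    kap <- weighted_kappa(tab, weights, alpha)
    ids <- intersect(names(auto_z)[!is.na(auto_z)],
                     names(rv[[r]])[!is.na(rv[[r]])])
    zr <- z_of(rv[[r]])
    icc <- icc_a1(auto_z[ids], zr[ids], alpha = alpha)
    per_pat <- per_patient_icc(
      data.frame(patient_id = patient_of[ids], x = auto_z[ids], y = zr[ids]),
      alpha = alpha, min_pairs = min_pairs)
    pairs[[paste0("auto_vs_", r)]] <-
      list(table = tab, kappa = kap, icc = icc, per_patient = per_pat)
  }
  tab_hh <- build_table(cat_of(rv[[1]]), cat_of(rv[[2]]))
  kap_hh <- weighted_kappa(tab_hh, weights, alpha)
  ids_hh <- intersect(names(rv[[1]])[!is.na(rv[[1]])],
                      names(rv[[2]])[!is.na(rv[[2]])])
  icc_hh <- icc_a1(rv[[1]][ids_hh], rv[[2]][ids_hh], alpha = alpha)
  pairs[["human_vs_human"]] <-
    list(table = tab_hh, kappa = kap_hh, icc = icc_hh)
  structure(list(pairs = pairs, weights = weights, alpha = alpha,
                 rater_ids = rater_ids),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  for (nm in names(x$pairs)) {
    cat("==", nm, "==\n")
    print(x$pairs[[nm]]$kappa)
    print(x$pairs[[nm]]$icc)
    if (!is.null(x$pairs[[nm]]$per_patient)) {
      cat("per patient:\n")
      print(x$pairs[[nm]]$per_patient, digits = 3)
    }
    cat("\n")
  }
  invisible(x)
}

#' Agreement report as JSON-ready list
#'
#' @param report An `"agreement_report"`.
#' @return A nested list of plain numbers/strings suitable for
#'   `jsonlite::write_json(..., auto_unbox = TRUE)`.
#' @export
report_as_list <- function(report) {
  est_list <- function(e)
    list(kind = e$kind, estimate = e$estimate, ci_lo = e$ci_lo,
         ci_hi = e$ci_hi, alpha = e$alpha, f_value = e$f_value,
         df1 = e$df1, df2 = e$df2, p_value = e$p_value, n_pairs = e$n_pairs,
         interpretation = e$interpretation)
  lapply(report$pairs, function(p) {
    out <- list(kappa = est_list(p$kappa), icc = est_list(p$icc),
                table = unclass(p$table)[seq_len(3), seq_len(3)])
    if (!is.null(p$per_patient)) out$per_patient <- p$per_patient
    out
  })
}

#' Per-patient sentiment time series
#'
#' One row per record in temporal order with the standardized automated
#' score and the standardized average-human score. Records a rater deemed
#' irrelevant carry NA (the automated analysis may still have a value —
#' disagreement about relevance is itself informative).
#'
#' @param run A `"score_run"`.
#' @param ratings Ratings data.frame (two raters).
#' @param patients Optional patient id filter (unknown ids are an error).
#' @return Data.frame: patient_id, seq, record_id, auto_z, human_avg_z.
#' @export
run_series <- function(run, ratings, patients = NULL) {
  stopifnot(inherits(run, "score_run"))
  rv <- rater_vectors(ratings)
  avg <- average_human(rv[[1]], rv[[2]])
  scored <- run$scores
  out <- data.frame(patient_id = scored$patient_id, seq = scored$seq,
                    record_id = scored$record_id,
                    auto_z = scored$z,
                    human_avg_z = unname(avg$z[scored$record_id]),
                    stringsAsFactors = FALSE)
  if (!is.null(patients)) {
    unknown <- setdiff(patients, out$patient_id)
    if (length(unknown))
      stop_data("unknown patient id(s): ", paste(unknown, collapse = ", "))
    out <- out[out$patient_id %in% patients, , drop = FALSE]
  }
  out <- out[order(out$patient_id, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write per-patient series CSVs
#'
#' @param series Data.frame from [run_series()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_series <- function(series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(series, series$patient_id), function(d) {
    p <- file.path(dir, sprintf("series_%s.csv", d$patient_id[1]))
    utils::write.csv(d, p, row.names = FALSE, na = "")
    p
  }, "")
  invisible(unname(paths))
}
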