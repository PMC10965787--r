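#' @name synthetic
#' @title Synthetic session-record corpus and rater simulation
#'
#' @description
#' The generator emulates a corpus of short clinician notes with known
#' ground truth: each record is assembled from neutral filler tokens plus
#' "sentiment units" — a lexicon word preceded by two controlled slots that
#' hold a negator, an intensifier or a filler. Because fillers carry no
#' polarity and are never modifiers, the n-gram effects on each match are
#' exactly the modifiers the generator placed, so it can book-keep the
#' expected bigram/trigram/overall score of every record in closed form,
#' independently of the scorer implementation. [simulate_raters()] adds a
#' two-rater layer with a known intraclass correlation.
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

filler_vocab <- c(
  "afspraak", "gesprek", "vandaag", "samen", "verslag", "sessie", "tijdens",
  "besproken", "huiswerk", "oefening", "volgende", "doelen", "plan",
  "contact", "situatie", "thuis", "school", "werk", "maaltijd", "dagboek",
  "vragenlijst", "afgelopen", "periode", "aandacht", "gewerkt", "benoemd",
  "gepland", "patiente", "behandeling", "traject", "evaluatie", "onderwerp")

#' Specify a synthetic corpus
#'
#' Defaults emulate a small outpatient study corpus: 8 patients with 40-75
#' records each (mean 57.5), roughly two thirds of records passing the
#' automated relevance filter, and among the relevant ones more positive
#' than negative records.
#'
#' @param n_patients Number of patients.
#' @param records_per_patient Integer (fixed) or length-2 range sampled
#'   uniformly per patient.
#' @param category_mix Named proportions over positive, negative, neutral,
#'   mixed, irrelevant; must sum to 1.
#' @param p_negation,p_intensifier Probability that a unit's prev1/prev2
#'   slot holds a negator resp. an intensifier.
#' @param p_context_word Probability that a relevant record additionally
#'   carries an out-of-lexicon context expression.
#' @param seed Mandatory RNG seed.
#' @return An object of class `"corpus_spec"`.
#' @export
corpus_spec <- function(n_patients = 8L,
                        records_per_patient = c(40L, 75L),
                        category_mix = c(positive = 0.28, negative = 0.25,
                                         neutral = 0.10, mixed = 0.055,
                                         irrelevant = 0.315),
                        p_negation = 0.2, p_intensifier = 0.2,
                        p_context_word = 0.05, seed = 1L) {
  cats <- c("positive", "negative", "neutral", "mixed", "irrelevant")
  if (!setequal(names(category_mix), cats))
    stop_data("category_mix must be named over: ", paste(cats, collapse = ", "))
  category_mix <- category_mix[cats]
  if (abs(sum(category_mix) - 1) > 1e-8)
    stop_data("category_mix must sum to 1 (got ", sum(category_mix), ")")
  if (any(category_mix < 0)) stop_data("category_mix must be non-negative")
  probs <- c(p_negation, p_intensifier, p_context_word)
  if (any(probs < 0 | probs > 1)) stop_data("probabilities must lie in [0, 1]")
  if (p_negation + p_intensifier > 1)
    stop_data("p_negation + p_intensifier must not exceed 1")
  if (is.null(seed)) stop_data("seed is mandatory")
  structure(list(n_patients = as.integer(n_patients),
                 records_per_patient = as.integer(records_per_patient),
                 category_mix = category_mix, p_negation = p_negation,
                 p_intensifier = p_intensifier,
                 p_context_word = p_context_word, seed = as.integer(seed)),
            class = "corpus_spec")
}

sample_slot <- function(spec, negators, intensifiers, fillers) {
  u <- stats::runif(1)
  if (u < spec$p_negation)
    list(token = sample(negators, 1), factor = -1)
  else if (u < spec$p_negation + spec$p_intensifier)
    list(token = sample(intensifiers, 1), factor = 2)
  else
    list(token = sample(fillers, 1), factor = 1)
}

# one sentiment unit: [prev2 slot, prev1 slot, lexicon word]
make_unit <- function(base, spec, pos_words, neg_words, negators,
                      intensifiers, fillers) {
  s2 <- sample_slot(spec, negators, intensifiers, fillers)
  s1 <- sample_slot(spec, negators, intensifiers, fillers)
  word <- if (base > 0) sample(pos_words, 1) else sample(neg_words, 1)
  list(tokens = c(s2$token, s1$token, word), base = base,
       bigram = base * s1$factor, trigram = base * s1$factor * s2$factor)
}

flip_unit <- function(u, pos_words, neg_words) {
  base <- -u$base
  u$tokens[3] <- if (base > 0) sample(pos_words, 1) else sample(neg_words, 1)
  u$base <- base; u$bigram <- -u$bigram; u$trigram <- -u$trigram
  u
}

assemble_record <- function(units, fillers, context_pool, spec) {
  tokens <- sample(fillers, sample(1:3, 1), replace = TRUE)
  for (u in units) {
    tokens <- c(tokens, u$tokens)
    tokens <- c(tokens, sample(fillers, sample(0:3, 1), replace = TRUE))
  }
  if (length(context_pool) && stats::runif(1) < spec$p_context_word)
    tokens <- c(tokens, strsplit(sample(context_pool, 1), " ", fixed = TRUE)[[1]])
  pad <- max(0, sample(8:20, 1) - length(tokens))
  c(tokens, sample(fillers, pad, replace = TRUE))
}

#' Generate a synthetic session-record corpus with ground truth
#'
#' @param spec A [corpus_spec()].
#' @param lex A [lexicon()] with at least one positive and one negative
#'   entry plus non-empty modifier lists (default: the demo lexicon).
#' @param stopwords Stopword list the downstream pipeline will use; filler
#'   vocabulary is kept disjoint from it so generated token counts survive
#'   cleaning unchanged.
#' @param context A [read_context_words()] table; only expressions whose
#'   tokens carry no lexicon polarity and are not modifiers are inserted
#'   (insertion must not perturb the book-kept score).
#' @return A list of class `"synthetic_corpus"`: `records` (data.frame
#'   record_id, patient_id, seq, text) and `truth` (record_id, patient_id,
#'   seq, category, mixed, n_matches, expected_bigram, expected_trigram,
#'   expected_overall, latent_human).
#' @export
generate_corpus <- function(spec, lex = demo_lexicon(),
                            stopwords = default_stopwords(lex),
                            context = read_context_words()) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(lex, "sentilex"))
  pos_words <- names(lex$entries)[lex$entries > 0]
  neg_words <- names(lex$entries)[lex$entries < 0]
  if (!length(pos_words) || !length(neg_words))
    stop_data("generator needs both positive and negative lexicon entries")
  if (!length(lex$negators) || !length(lex$intensifiers))
    stop_data("generator needs non-empty negator and intensifier lists")
  fillers <- setdiff(filler_vocab,
                     c(names(lex$entries), lex$negators, lex$intensifiers,
                       stopwords))
  if (length(fillers) < 10)
    stop_data("filler vocabulary too depleted by lexicon/stopword overlap")
  context_pool <- character()
  if (!is.null(context) && nrow(context)) {
    ok <- vapply(strsplit(context$expression, " ", fixed = TRUE), function(ts)
      all(polarity(lex, ts) == 0L) &&
        !any(ts %in% c(lex$negators, lex$intensifiers, stopwords)) &&
        all(nchar(ts) > 1), TRUE)
    context_pool <- context$expression[ok]
  }
  cats <- names(spec$category_mix)
  with_seed(spec$seed, {
    rec_rows <- list(); truth_rows <- list(); ridx <- 0L
    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("p%02d", p)
      n_rec <- if (length(spec$records_per_patient) == 1) spec$records_per_patient
               else sample(spec$records_per_patient[1]:spec$records_per_patient[2], 1)
      for (s in seq_len(n_rec)) {
        ridx <- ridx + 1L
        rid <- sprintf("%s-r%03d", pid, s)
        category <- sample(cats, 1, prob = spec$category_mix)
        mixed <- category == "mixed"
        if (category == "irrelevant") {
          tokens <- if (stats::runif(1) < 0.5)
            sample(fillers, sample(2:4, 1), replace = TRUE)    # too short
          else sample(fillers, sample(5:9, 1), replace = TRUE) # no matches
          units <- list()
        } else if (category %in% c("neutral", "mixed")) {
          n_pairs <- if (mixed) sample(2:3, 1) else 1L
          units <- list()
          for (q in seq_len(n_pairs)) {
            up <- make_unit(1L, spec, pos_words, neg_words, lex$negators,
                            lex$intensifiers, fillers)
            un <- flip_unit(up, pos_words, neg_words)  # mirrored modifiers
            if (!mixed) { # plain neutral: unmodified balanced pair
              up <- make_unit(1L, corpus_spec(seed = 0, p_negation = 0,
                                              p_intensifier = 0),
                              pos_words, neg_words, lex$negators,
                              lex$intensifiers, fillers)
              un <- flip_unit(up, pos_words, neg_words)
            }
            units <- c(units, list(up, un))
          }
          units <- sample(units)
        } else {
          want <- if (category == "positive") 1 else -1
          n_units <- sample(1:4, 1)
          units <- lapply(seq_len(n_units), function(q)
            make_unit(sample(c(1L, -1L), 1), spec, pos_words, neg_words,
                      lex$negators, lex$intensifiers, fillers))
          overall_of <- function(us)
            clamp((mean(vapply(us, `[[`, 0, "bigram")) +
                   mean(vapply(us, `[[`, 0, "trigram"))) / 2)
          if (sign(overall_of(units)) != want)
            units <- lapply(units, flip_unit, pos_words = pos_words,
                            neg_words = neg_words)
          if (overall_of(units) == 0)  # modifier-balanced draw: force the sign
            units <- c(units, list(make_unit(
              as.integer(want), corpus_spec(seed = 0, p_negation = 0,
                                            p_intensifier = 0),
              pos_words, neg_words, lex$negators, lex$intensifiers, fillers)))
        }
        if (length(units)) {
          tokens <- assemble_record(units, fillers, context_pool, spec)
          eb <- mean(vapply(units, `[[`, 0, "bigram"))
          et <- mean(vapply(units, `[[`, 0, "trigram"))
          eo <- clamp((eb + et) / 2)
        } else {
          eb <- et <- eo <- NA_real_
        }
        rec_rows[[ridx]] <- data.frame(record_id = rid, patient_id = pid,
                                       seq = s, text = paste(tokens, collapse = " "),
                                       stringsAsFactors = FALSE)
        truth_rows[[ridx]] <- data.frame(
          record_id = rid, patient_id = pid, seq = s, category = category,
          mixed = mixed, n_matches = length(units),
          expected_bigram = eb, expected_trigram = et, expected_overall = eo,
          latent_human = if (is.na(eo)) NA_real_ else clamp(4 + 3 * eo, 1, 7),
          stringsAsFactors = FALSE)
      }
    }
    structure(list(records = do.call(rbind, rec_rows),
                   truth = do.call(rbind, truth_rows),
                   spec = spec),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d records, %d patients (seed %d)\n",
              nrow(x$records), length(unique(x$records$patient_id)),
              x$spec$seed))
  print(table(x$truth$category))
  invisible(x)
}

#' Specify a simulated rater pair
#'
#' @param true_icc Target population ICC(A,1) of the two raters, in (0, 1).
#' @param rater_bias Length-2 systematic offsets added to each rater.
#' @param p_irrelevant_disagree Probability that a rater independently marks
#'   a relevant record irrelevant (creates realistic missingness).
#' @param latent_sd Nominal standard deviation of the latent-score
#'   distribution. When given, the noise variance is derived from it, so the
#'   simulation follows the unconditional two-way random model (the right
#'   design for studying estimator sampling behaviour). Default `NULL`:
#'   calibrate to the realized standard deviation of the supplied latent
#'   scores, which pins the target ICC to the records at hand.
#' @param seed Mandatory RNG seed.
#' @return An object of class `"rater_spec"`.
#' @export
rater_spec <- function(true_icc = 0.9, rater_bias = c(0, 0),
                       p_irrelevant_disagree = 0.05, latent_sd = NULL,
                       seed = 1L) {
  if (!(true_icc > 0 && true_icc < 1)) stop_data("true_icc must lie in (0, 1)")
  if (length(rater_bias) != 2) stop_data("rater_bias must have length 2")
  if (p_irrelevant_disagree < 0 || p_irrelevant_disagree > 1)
    stop_data("p_irrelevant_disagree must lie in [0, 1]")
  if (is.null(seed)) stop_data("seed is mandatory")
  if (!is.null(latent_sd) && latent_sd <= 0)
    stop_data("latent_sd must be positive")
  structure(list(true_icc = true_icc, rater_bias = rater_bias,
                 p_irrelevant_disagree = p_irrelevant_disagree,
                 latent_sd = latent_sd, seed = as.integer(seed)),
            class = "rater_spec")
}

#' Simulate two raters around latent record scores
#'
#' Two-way mixed model: `observed_r = latent + bias_r + noise_r`, with the
#' noise variance chosen so the population ICC(A,1) — latent variance over
#' latent + bias-heterogeneity + noise variance — equals `true_icc`.
#' Continuous observations are discretized to the 1-7 scale by equal-width
#' cuts (round to the nearest integer, clamped), mirroring how a human
#' panel quantizes an underlying impression.
#'
#' @param latent Named numeric vector of latent record scores (names =
#'   record ids; NA = the record is irrelevant to both raters).
#' @param spec A [rater_spec()].
#' @return A list of class `"rater_sim"`: `continuous` (data.frame
#'   record_id, r1, r2 — the undiscretized observations, NA where a rater
#'   abstained) and `ratings` (long data.frame record_id, rater_id, score
#'   1-7, mixed, category).
#' @export
simulate_raters <- function(latent, spec) {
  stopifnot(inherits(spec, "rater_spec"))
  if (is.null(names(latent))) names(latent) <- sprintf("r%04d", seq_along(latent))
  ok <- !is.na(latent)
  if (sum(ok) < 2) stop_data("need at least 2 non-missing latent scores")
  sigma_r2 <- if (!is.null(spec$latent_sd)) spec$latent_sd^2
              else stats::var(latent[ok])
  if (sigma_r2 == 0) stop_data("latent scores have no variance")
  k <- 2
  theta_c <- sum((spec$rater_bias - mean(spec$rater_bias))^2) / (k - 1)
  sigma_e2 <- sigma_r2 * (1 - spec$true_icc) / spec$true_icc - theta_c
  if (sigma_e2 < 0)
    stop_data("rater_bias too large for the requested true_icc")
  n <- length(latent)
  with_seed(spec$seed, {
    obs <- vapply(1:2, function(r)
      latent + spec$rater_bias[r] + stats::rnorm(n, 0, sqrt(sigma_e2)), numeric(n))
    drop <- matrix(stats::runif(2 * n) < spec$p_irrelevant_disagree, n, 2)
    obs[!ok, ] <- NA
    obs[drop] <- NA
    scores <- pmin(pmax(round(obs), 1), 7)
    ratings <- data.frame(
      record_id = rep(names(latent), 2),
      rater_id = rep(c("rater1", "rater2"), each = n),
      score = c(scores[, 1], scores[, 2]),
      mixed = FALSE, stringsAsFactors = FALSE)
    ratings$category <- categorize_human(ratings$score)
    structure(list(continuous = data.frame(record_id = names(latent),
                                           r1 = obs[, 1], r2 = obs[, 2],
                                           stringsAsFactors = FALSE),
                   ratings = ratings, spec = spec,
                   sigma_e2 = sigma_e2),
              class = "rater_sim")
  })
}
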