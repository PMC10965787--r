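# sentisess

Lexicon-based sentiment analysis for clinician-written session records, with
the inter-rater agreement machinery needed to validate it against human
raters.

## The problem

Clinicians write a free-text note after every therapy session. Across a
treatment trajectory those notes carry a signal — is the patient's situation
described in increasingly positive or negative terms? — that routine outcome
questionnaires sample only sparsely. `sentisess` implements an automated,
transparent (non-ML) sentiment pipeline for such records, plus everything
needed to ask the validation question that matters before trusting it:
*does the machine agree with human raters, and do the humans agree with each
other?* Because real session records are privacy-sensitive, the package also
ships a synthetic corpus generator and a rater simulator with known ground
truth, so every stage is testable without patient data.

## The method

**Scoring.** Records are cleaned (lowercasing; removal of stopwords, pure
numbers, single characters and underscore tokens — configured negators and
intensifiers always survive). Each token with an entry in the merged polarity
lexicon gets a base score *b* ∈ {+1, −1}. The one and two tokens preceding a
sentiment word modify it through valence-shifter factors

    f(none) = 1,   f(intensifier) = 2,   f(negator) = −1

giving a bigram score `b·f(prev1)` and a trigram score
`b·f(prev1)·f(prev2)` per match ("niet goed" → −1, "heel goed" → +2,
"niet heel goed" → −2). Channel finals are the per-record means of these
n-gram scores; the overall record score is the mean of the two channel
finals, clamped to [−1, 1]. Records with fewer than five cleaned tokens or
no sentiment word are marked irrelevant and left unscored.

**Calibration.** Overall scores are standardized (z-scores, pooled across
patients). Since a continuous scorer almost never emits exactly 0, the
"neutral" category is the data-driven band between the largest strictly
negative and smallest strictly positive z-score (e.g. [−0.03, 0.11]);
records below/above it are negative/positive. Human raters use a 1–7 scale
(<4 negative, 4 neutral, >4 positive, with a descriptive "mixed" flag).

**Validation.** Categorical agreement via weighted Cohen's kappa
(unweighted/linear/quadratic weights, Fleiss–Cohen–Everitt asymptotic CI,
Landis–Koch interpretation); continuous agreement via the intraclass
correlation ICC(A,1) — two-way model, absolute agreement, single measure —
from ANOVA mean squares with the McGraw–Wong F-based CI and Koo–Li
interpretation, overall and stratified per patient.

## Worked example

```r
library(sentisess)
lex <- demo_lexicon()   # 40 Dutch demo words + negators/intensifiers

records <- data.frame(
  record_id = c("r1", "r2", "r3"),
  patient_id = "p01", seq = 1:3,
  text = c("Vandaag ging het gesprek goed, patient was heel tevreden en rustig",
           "Patient was niet tevreden en erg somber tijdens de sessie",
           "Afspraak verzet"))
scored <- score_corpus(prepare_corpus(records, lex), lex)
scored[c("record_id", "n_matches", "bigram_final", "trigram_final",
         "overall", "relevant_auto")]
#>   record_id n_matches bigram_final trigram_final overall relevant_auto
#> 1        r1         3     1.333333      1.666667       1          TRUE
#> 2        r2         2    -1.500000     -1.500000      -1          TRUE
#> 3        r3         0           NA            NA      NA         FALSE
```

Record r1 has three positive matches, one intensified ("heel tevreden" →
+2), so the channel means exceed 1 and the overall score clamps to 1.
Record r2 shows both shifters in action ("niet tevreden" → −1, "erg somber"
→ −2); r3 fails the five-word relevance filter.

A full synthetic study — corpus, scoring, simulated raters, agreement:

```r
corp <- generate_corpus(corpus_spec(seed = 7), lex)
run  <- run_score(corp$records, lex)
run
#> <score_run> 505 records, relevant 350 (69.3%); neutral band [-0.054, 0.141]
#>   category   n  pct       label
#> 1 negative 127 36.3 127 (36.3%)
#> 2  neutral  87 24.9  87 (24.9%)
#> 3 positive 136 38.9 136 (38.9%)

sim <- simulate_raters(setNames(corp$truth$latent_human, corp$truth$record_id),
                       rater_spec(true_icc = 0.9, seed = 8))
rep <- run_agreement(run, sim$ratings)
rep$pairs$human_vs_human$icc
#> <agreement_estimate> icc_a1 = 0.879, 95% CI [0.851, 0.901], n = 327 (good)
#>   F(326, 326) = 15.559, p = 2.642e-107
rep$pairs$human_vs_human$kappa
#> <agreement_estimate> kappa_linear = 0.716, 95% CI [0.656, 0.775], n = 327 (substantial)
```

The simulated pair was built with a true ICC of 0.9; the estimate lands at
0.879 with a CI that covers it. `rep$pairs$auto_vs_rater1$per_patient`
gives the per-patient ICC table (df1 = df2 = n − 1 for two raters), and
`run_series()` exports per-patient time series of standardized automated
and averaged-human scores (humans may abstain where the machine scores —
those rows keep the automated value and a missing human value).

A thin command-line wrapper with subcommands `simulate`, `score`, `agree`,
`series` and `audit` lives at `inst/cli/sentisess.R` (YAML config; see its
header).

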