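---
title: "Scoring clinical session records: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring clinical session records: model, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentisess)
```

This vignette is the package's own account of its method: the scoring
model and its assumptions, the calibration and agreement machinery, the
design decisions that were genuinely open, and what the synthetic-data
tests do and do not establish about real data.

## The scoring model

The scorer is a deliberately transparent lexicon method, not a learned
model. After cleaning, every token with a polarity entry (+1/−1) in the
merged lexicon becomes a *match*. Two channels score each match from its
left context on the cleaned token stream:

* bigram channel: base polarity × factor of the preceding token;
* trigram channel: bigram score × factor of the token two positions back;

with factors 1 (ordinary word), 2 (intensifier) and −1 (negator). A channel
final is the channel's scores summed over matches and divided by the number
of matches; the overall record score combines the channels and is clamped
to [−1, 1].

Assumptions worth making explicit:

* **Negation scope is positional, not syntactic.** Only the two preceding
  tokens matter. "niet echt heel goed" sees only "echt heel"; clause-level
  negation ("ik zou niet zeggen dat het goed gaat") is missed.
* **Effects compose multiplicatively.** A double negation cancels; negator
  plus intensifier gives −2 in either order. This is the minimal consistent
  extension of the single-modifier rules to two slots.
* **Sentence boundaries are not marked.** N-grams may cross a sentence
  end. Cleaning removes punctuation before scoring, and short clinical
  notes rarely place a sentiment word in the first two tokens of a
  sentence following an opposite-valence modifier, so the simplification
  is cheap — but it is a simplification.
* **Record-initial matches** take factor 1 and count in the denominator.

### Combining the channels, and the clamp

With both channel formulas fixed, how they merge into one record score was
an open choice. The default, `ngram_mean`, averages the two channel finals,
preserving both printed channel definitions verbatim; `token_mean`
(averaging per-match trigram scores) is available as an alternative with
slightly different dilution behaviour (each added unmodified positive match
strictly raises a non-saturated score). An intensified match makes either
combination exceed 1 in magnitude (a lone "heel goed" record scores 2 in
both channels), so the overall score is clamped to [−1, 1]. The clamp is
symmetric, hence the sign symmetry of the scorer (flipping every lexicon
polarity negates every score) survives it.

### Relevance filtering

Records with fewer than five cleaned tokens or with no sentiment word are
marked irrelevant and left unscored. The five-word rule is counted on the
*cleaned* stream: the filter belongs to the automated tool, which sees only
its own pre-processed input. This is an interpretive choice — counting raw
words would classify a few short-but-noisy records differently.

### Stopwords and modifiers

Stopword removal happens before n-gram formation, which risks deleting the
very words the n-gram rules need: standard Dutch stopword lists contain
"niet" and "geen". The tokenizer therefore exempts all configured negators
and intensifiers from stopword removal, whatever list the user supplies.
Whether the original tooling this emulates removed stopwords before or
after n-gram formation is not documented; removing before, with the
modifier exemption, keeps negation handling intact under every stopword
configuration.

## Calibration

Raw overall scores are standardized to z-scores, pooling all relevant
records across patients (per-patient time series are plotted on a common
scale, which implies pooling; a per-patient standardization would erase
level differences between patients). The neutral category is the band
between the largest strictly negative and the smallest strictly positive
z-score — a data-driven band, since a continuous scorer essentially never
emits exactly zero. Boundary values are inclusive-neutral: "negative" and
"positive" are defined by strict inequalities. Human ratings on the 1–7
scale categorize around the midpoint (<4, =4, >4); the per-rater
categorical analysis uses the raw scores (a monotone transform of the
standardized ones, so categories coincide), and the averaged human rating —
the mean of both raters' scores on records rated by both — feeds the
continuous per-patient series. A "mixed" flag (equally many positive and
negative sentiments) is descriptive metadata and maps to neutral in all
agreement statistics.

## Agreement estimators

`weighted_kappa()` implements κ = (Po − Pe)/(1 − Pe) with agreement
weights 1 − |i−j|/(C−1) (linear, the default), 1 − ((i−j)/(C−1))²
(quadratic) or the identity (unweighted) over the ordered categories, Pe
from marginal products, and the Fleiss–Cohen–Everitt large-sample standard
error for the CI (a subject-resampling bootstrap is available). Linear
weighting is the default because the three categories are ordinal with a
single ordering and no argument for quadratic's stronger reward of
near-misses; the scheme is configurable precisely because published
analyses often leave it unstated.

`icc_a1()` implements ICC(A,1) — two-way model, absolute agreement, single
measure — from the ANOVA mean squares:

```
ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))
```

with F = MSR/MSE on (n−1, (n−1)(k−1)) df and the McGraw–Wong F-based CI.
Absolute agreement (rather than consistency) is the right estimand here:
a rater who is systematically one point more positive should be penalized,
because the question is whether the *scores* agree, not whether they
correlate. Pairwise deletion restricts each comparison to records scored
by both parties, which is also why per-patient tables report df = n − 1
with patient-specific n.

Numerical corners: exactly identical columns give estimate 1 with a
degenerate (point) interval; if the Satterthwaite denominator df for the
CI degenerates (possible for k ≥ 3 with negative estimates), the bounds
fall back to the parameter space [−1, 1] rather than NaN; bounds are
always clipped to bracket the estimate under floating point.

## The synthetic-data generator

`generate_corpus()` assembles each record from filler tokens plus
"sentiment units": a lexicon word preceded by two controlled slots holding
a negator (probability `p_negation`), an intensifier (`p_intensifier`) or
a filler. Fillers are guaranteed non-lexicon, non-modifier and
non-stopword, so the modifier effects on every match are exactly the ones
placed, and the generator can book-keep each record's expected bigram,
trigram and overall score in closed form — independently of the scorer
implementation. The agreement of scorer and generator on a default corpus
is the package's core cross-validation (exact for 100% of relevant records
in the shipped test runs; the acceptance threshold is ≥99%, sparing
documented clamping edge cases).

Default study conditions: 8 patients with 40–75 records each (mean 57.5),
and a category mix of positive 0.28, negative 0.25, neutral 0.10, mixed
0.055, irrelevant 0.315 — chosen once to emulate a realistic outpatient
corpus in which about two thirds of records pass the automated relevance
filter and positive records outnumber negative ones among the relevant.
Neutral records carry one unmodified balanced pair of matches; mixed
records carry two or three modifier-mirrored balanced pairs (both score
exactly zero; the distinction is the flag and the match count).

`simulate_raters()` adds the human layer: observed = latent + rater bias +
Gaussian noise, with the noise variance set so the population ICC(A,1) —
latent variance over latent + bias-heterogeneity + noise — equals
`true_icc`. Continuous observations are discretized to 1–7 by equal-width
cuts (round and clamp). Two calibration modes exist: by default the noise
is calibrated to the *realized* standard deviation of the supplied latent
scores, pinning the target ICC to the records at hand (right for building
fixtures); with `latent_sd` given, the nominal value is used, which is the
correct design for estimator sampling studies — realized-SD calibration
makes replicates conditionally less variable than the unconditional
two-way model and inflates CI coverage a few points above nominal.

The ICC recovery study (500 replicates, n = 250 pairs, true ICC 0.3/0.6/
0.9) uses the continuous observations, not the 1–7 scores: 7-level
quantization attenuates the ICC by design, so the discrete channel cannot
(and should not) recover the latent parameter exactly. Problem sizes in
the test suite — 1000 random token lists for the scorer oracle, 500
recovery replicates, one default-size corpus — were chosen as the smallest
sizes at which the Monte-Carlo error is comfortably below the asserted
tolerances.

### What the synthetic tests do not show

The generator's token streams are statistically controlled, not
linguistically realistic: no clause structure, no misspellings, no
out-of-lexicon sentiment beyond the inserted context expressions, no
correlation between record length and valence, no drift of a patient's
sentiment over time. Passing tests therefore establish that the pipeline
computes its defined quantities correctly — not that the lexicon method
measures clinical sentiment well. On real records, validity hinges on the
lexicons: general-purpose polarity lists mis-sign domain expressions
("sporten", "compenseren" are not positive in an eating-disorder context),
which is exactly what the audit module surfaces
(`missing_context_words()`, `polarity_conflicts()`; the bundled ED context
list is a synthetic illustrative stand-in).

## De-identification

`pseudonymize()` is a regex/gazetteer placeholder pass — emails, URLs,
phone numbers and postal codes deleted; dates, ages, gazetteer locations
and non-sentence-initial capitalized tokens replaced by numbered
placeholders. It emulates the *output format* of proper clinical
de-identification tooling so downstream code can be exercised on
placeholder-bearing text; it is a test-fixture convenience, **not** a
compliance-grade de-identifier (names at sentence starts, nicknames and
unlisted locations pass through).

## Known limitations

* Single-word lexicon entries only; multi-word expressions are visible to
  the audit module but not to the scorer.
* No 0-polarity lexicon class: a token is either a match (±1) or invisible.
* Two raters only; no Fleiss-kappa / average-measure ICC generalizations.
* The neutral band depends on the corpus via its two nearest-zero scores,
  so adding records can move the band; fix the band explicitly
  (`neutral_band(lo, hi)`) when comparability across corpora matters.
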