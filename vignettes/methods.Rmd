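---
title: "Methods: distant supervision and prediction of GRADE certainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distant supervision and prediction of GRADE certainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evidencegrader)
```

## The grading model

GRADE rates certainty in a body of evidence (BoE) — the studies informing one
outcome of one clinical question — on four levels coded here as integers:
0 = very low, 1 = low, 2 = moderate, 3 = high. Randomised-trial evidence
starts at high and is downgraded for five reasons: risk of bias, imprecision,
inconsistency, indirectness and publication bias. A single reason can remove
1 or 2 levels ("very severe" concerns), and the overall grade can fall by at
most 3, so

$$\mathrm{grade} = 3 - \min\!\big(\textstyle\sum_c s_c,\ 3\big), \qquad s_c \in \{0,1,2\}.$$

This arithmetic is the backbone of the package. It determines the label
extraction filter (`is_consistent()`), the generator's sampling scheme, and
the conversion of regression scores back to grades.

### Distant supervision

Labels are harvested from summary-of-findings (SoF) tables rather than
annotated fresh. The grade is structured data; the *reasons* are not — they
appear as free-text footnotes on the grade cell, written with inconsistent
vocabulary. `map_footnote()` recovers a downgrade vector by longest-match,
non-overlapping lexicon lookup (case- and whitespace-insensitive), with
phrases such as "two levels" acting as step multipliers when they occur
within 15 characters of a matched term. The window and the multiplier list
are package conventions, declared in the lexicon file: how 2-step downgrades
are verbalised is not standardised in real reviews, so the mechanism is
configurable and is exercised end-to-end by the generator, which renders
footnotes through the same lexicon.

Extraction is then audited arithmetically. A candidate whose extracted step
total does not explain its grade is removed from the dataset
(`extract_instances()`); high-grade evidence is skipped, since no reason is
expected there, and very-low grades accept totals above 3 because the grade
is capped while footnotes may list more reasons. Manual inspection in the
source setting attributes most filter failures to extraction *misses* (a
reason present in text but not matched), so the removed instances with at
least one detected reason keep trustworthy positive labels: they form the
supplement pool, added to *training folds only* by `supplement_training()`
for the criterion being trained. Development and test folds never pass
through that function, so their label distributions are untouched by
construction.

### Alignment to primary studies

Meta-analysis records name the studies behind each outcome, but the names
rarely match the review's study list verbatim. `align_primary_studies()`
takes an exact label match first; otherwise the minimum character-level
Levenshtein match is accepted only if the distance is at most `max_distance`
(default 3 — tolerant of suffix letters like "2004a" while too tight to
cross author names; configurable) *and* three constraints agree exactly
between the meta-analysis record and the SoF entry: type of effect, size of
the effect, and number of studies. Effect sizes are compared at 2-decimal
rounding, since exact float equality is meaningless for values re-printed
through different formats. Ties break to the lexicographically smallest
study label. Matched studies contribute support features
(`derive_study_features()`): per risk-of-bias component, the counts of
low/high/unclear judgements, the proportion of high judgements, the modal
judgement, and the concatenated methods text.

## The predictor

One architecture serves all tasks; only the output head changes
(`qoe_task()`):

* numeric features (with a parallel missing-value mask) pass through a
  3-layer feed-forward encoder with ReLU activations;
* categorical tokens are embedded with learned vectors, averaged within a
  field, and concatenated across fields;
* each text field becomes a hashed bag of 1–2-grams (deterministic
  polynomial hash), L1-normalised, and linearly projected to one vector per
  field; field vectors are concatenated. The hashing backend keeps training
  CPU-only and exactly reproducible; a pretrained transformer could stand
  behind the same one-vector-per-field contract, but nothing in the package
  requires one;
* each encoder output is layer-normalised (no learned affine), the blocks
  are aggregated by a purely linear layer (no nonlinearity), and the head
  reads the aggregate: binary sigmoid at threshold 0.5, five sigmoid units
  for the multilabel task ("units that fire" above 0.5), softmax over four
  grades with arg-max prediction (ties to the lowest grade, logged
  convention), or a scalar for regression.

Losses: binary cross-entropy, optionally weighted inversely to class
frequency with \(w_c = N/(2N_c)\) — the proportionality constant is chosen so
balanced data yields weight 1, making weighted and unweighted losses coincide
there; cross-entropy for the 4-tier task; mean squared error for regression.
Regression scores are reported raw and rounded half away from zero, clipped
to [0, 3] (`scalar_to_grade()`): the rounding convention is symmetric and is
tested explicitly.

Optimisation is Adam with minibatches, early stopping on the development
score (macro-F1 for classification heads, negative MAE for regression) with
configurable patience, returning the best-dev checkpoint. All defaults in
`model_config()` — three hidden layers of 32, embedding width 8, text
projection width 16, a 2^12-wide hash space, aggregation width 32, learning
rate 3e-3, batch 64 — are artifact constants declared once, chosen as
conventional desk-scale settings, not values tuned against any reported
number. The hash width is deliberately moderate: projections from a much
wider hash space buy little at the corpus sizes this package targets and
dominate the training cost of a pure-R implementation; the width is
configurable where more capacity is wanted. Training rows are put in
canonical (review, table, outcome) order before batching, so results depend
on the seed and the data, never on the row order a caller happens to pass.

Numeric preprocessing is min-max scaling fitted on training folds only;
out-of-range test values clip to [0, 1], constant features map to 0, and
missing values impute the scaled training median with the mask bit set.
Clipping and median imputation are robustness choices surfaced in the
preprocessor, not facts about the source setting. Unseen categorical tokens
map to a reserved unknown id.

### Baselines

The random baseline draws labels uniformly over the task's label space; an
empirical variant draws from the training distribution (both are provided
because the sampling protocol behind published random rows is ambiguous —
see *Known gaps* below). The majority baseline predicts the most frequent
training class, and for criteria tasks the most frequent label
*combination*, so rare criteria are never predicted. The logistic-regression
baselines are ridge fits at a negligible fixed penalty (glmnet) over three
input variants: numeric (`n`), plus categorical one-hot counts (`nc`), plus
text bag-of-word counts (`nct`, vocabulary = training tokens with frequency
at least 2).

`expected_baseline_metrics()` gives the closed forms these baselines must
attain in expectation — majority: \(F_1 = 2p/(1+p)\) for the predicted class
at prevalence \(p\), 0 elsewhere, \(\mathrm{MAE} = \sum_c p_c\,|c-m|\);
uniform random over \(L\) labels: \(F_1^{(c)} = 2p_c(1/L)/(p_c + 1/L)\). The
test suite verifies Monte-Carlo agreement of the evaluated predictors with
these forms at \(n = 10^5\) within chunked standard errors.

## Evaluation protocol

`grouped_kfold()` assigns whole reviews to folds (greedy size balancing,
largest review first, seeded shuffle for ties) so that near-duplicate BoEs
from one review can never straddle train and test. Each cross-validation
trial uses one fold for test, the next for development, the rest for
training. Headline metrics: per-class and macro precision/recall/F1 (a class
with no true and no predicted positives scores 0 — the convention that makes
never-predicted rare criteria score 0.00), positive-class F1 for criterion
tasks, MAE on the 0–3 scale, exact-match/micro/macro scores for the
multilabel task, and the *unscaled* median absolute deviation of each score
across folds (no 1.4826 consistency constant — the dispersion summary is
meant literally). For criteria tasks both the positive-class F1 and the
two-class macro are reported: at a prevalence of 0.59 the published majority
row (0.74) is the value of \(2p/(1+p)\), which identifies positive-class F1
as the headline quantity; the across-folds average is what the dispersion
subscript describes.

`ablation_run()` re-runs an identical evaluation per dropped feature and
reports deltas against the no-ablation reference; deltas are reported
per-feature and never assumed additive. `domain_holdout()` trains with one
medical area entirely excluded and tests on that area only.

## The synthetic corpus

`generate_corpus()` exists so every stage is testable without licensed
review data. Defaults are the study conditions the pipeline assumes: grade
marginals 14.2 / 31.5 / 33.9 / 20.4 % (high → very low), criterion positive
marginals 59.3 / 54.9 / 16.4 / 10.3 / 5.0 % (risk of bias → publication
bias), a mean of 2 SoF tables per review, 1–3 outcomes per table, and a mean
of 20 primary studies per review (negative-binomial, SD ≈ 17).

Sampling works backwards from the arithmetic so labels are true by
construction: a grade is drawn from the configured marginal, the implied
total \(T = 3 - \mathrm{grade}\) is allocated across criteria, and the grade
is recomputed from the steps. Honouring *both* the grade marginal and the
criterion marginals requires calibration: with probability `double_prob` an
allocation of \(T \ge 2\) contains one 2-step downgrade, where `double_prob`
is set so the expected number of repeated steps exactly absorbs
\(E[T] - \sum_c p_c\); the remaining steps go to distinct criteria drawn
without replacement with weights calibrated by exact enumeration and fixed
point until every induced marginal matches its target (machine precision).
Infeasible combinations — marginals that outweigh the expected total steps,
or exceed the probability of any downgrade — error at configuration time.
Very-low outcomes carry exactly 3 steps; real footnotes occasionally list
more reasons than the cap, which the generator does not emulate.

Planted signal, scaled by per-criterion log-odds coefficients
(`signal_strength`, default 2.5; 0 severs the link): imprecision shrinks
participant counts and widens confidence intervals; criterion-specific
tokens (e.g. "heterogeneity" for inconsistency) enter the outcome text at
steps-dependent rates and the review-level conclusion texts at rates driven
by the review's mean steps; the proportion of high risk-of-bias judgements
in primary studies tracks the review's mean risk-of-bias steps. Footnotes
are rendered from the same lexicon the extractor uses, with synonym noise
and occasional clause splitting, so extraction-inverts-rendering is a tested
invariant. A configurable `corrupt_fraction` of non-high outcomes drops one
reason from the footnote (never from the truth table), creating exactly the
arithmetic inconsistency the filter must catch; 0.1 is the default, a
plausible order for footnote omissions, and the filtered-out fraction is
tested to track it. Meta-analysis references are perturbed copies of study
labels (1–2 character edits with probability 0.3 by default), giving the
aligner non-trivial fuzzy matches whose ground truth is known.

Generation is deterministic given the seed, with per-review seeded
substreams, so a corpus prefix is stable regardless of how many reviews are
requested.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: natural-language footnotes and narratives (text
fields are template token bags, sufficient for bag-of-words and hashing
encoders but not for pretrained language models), inter-rater disagreement
and systematic mis-grading (corruption only deletes reasons), correlation
structure between medical areas and quality beyond what the planted model
induces, and real citation-name conventions. Results on synthetic corpora
validate the *machinery* — extraction, filtering, arithmetic, evaluation,
learnability — not clinical-domain performance.

## Problem sizes and numerical conventions

The test suite runs at deliberately moderate scales, stated here as the
package's own choices: unit fixtures of about 60 reviews (~230 outcomes),
clean corpora of ~2,000 outcomes for extraction/alignment fidelity, one
~10,000-outcome corpus for distributional checks, Monte-Carlo baseline
checks at \(n = 10^5\), and a ~5,000-outcome corpus on which both the
`nct` logistic regression and the neural model must beat the closed-form
majority positive-class F1 for risk of bias by at least 0.05 on held-out
folds (parameter recovery). Statistical assertions use 3-standard-error
bounds (chunked standard errors for ratio metrics) or chi-square
goodness-of-fit at α = 0.01.

Numerical conventions collected in one place: F1 with zero numerator and
denominator is 0; multiclass arg-max ties resolve to the lowest grade index;
majority ties resolve to the earlier class (or lexicographically smallest
combination); regression rounding is half away from zero with clipping;
layer normalisation uses ε = 1e-5 and no learned affine; binary
cross-entropy clips probabilities at 1e-12; the per-criterion step cap of 2
is enforced across all footnotes of an entry.

## Known gaps and limitations

* Published random-baseline rows are not exactly recoverable from printed
  prevalences under either a uniform or an empirical sampling reading (the
  per-class F1 ordering disagrees with both); the package implements both
  variants and asserts neither against printed rows. The majority rows, by
  contrast, reproduce exactly from the closed forms.
* Per-criterion annotation-table totals in the source setting differ from
  the dataset size without an explained base population; summaries therefore
  report criterion percentages against both the all-instance and the
  non-high-instance denominators.
* The exact optimiser schedule of the reference neural system is not public;
  `model_config()` defaults are this package's own constants.
* The aggregation layer is taken as purely linear; whether a nonlinearity
  belongs there is left open by the source description, and the linear
  reading is implemented.
* Pure-R training is practical to tens of thousands of instances; beyond
  that, the hashed text projection dominates and a compiled backend would be
  the natural extension.
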