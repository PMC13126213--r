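---
title: "Simulating AI-aided abstract screening: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating AI-aided abstract screening: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alscreen)
```

## The screening problem

Systematic reviews and meta-analyses begin with a literature search that
typically retrieves thousands of abstracts, of which only a small fraction —
often between 0.5% and 10% — turn out to be relevant. AI-aided screening
tools attack this imbalance with *active learning*: a classifier is trained
on the labels provided so far, the unscreened abstracts are ranked by
predicted relevance, the reviewer screens the top-ranked abstract, and the
new label feeds back into the next model fit. When the ranking works, almost
all relevant records surface early, and the reviewer can stop long before
the pile is exhausted.

`alscreen` implements this loop in *simulation mode*: every record carries
an oracle label (the stored inclusion decision), so the "reviewer" is
replaced by a lookup and the full screening order — the **screening trace**
— can be produced mechanically for any configuration of classifier, feature
extractor, balancing strategy and retraining interval. All performance
metrics and stopping rules are then functions of the trace, which makes
every rule comparable on identical orderings.

## Metrics

With `TP` relevant and `FP` irrelevant records among the first `n` trace
positions (and `FN`, `TN` their unscreened complements):

* **Sensitivity (recall)** = `TP / (TP + FN)`.
* **Screening cost** `SC@s` = `n*/N`, where `n*` is the smallest depth at
  which `TP >= ceiling(s * R)`. The ceiling rule is deliberate: with 20
  relevant records, missing one (19/20) sits exactly at the conventional
  95% level, and with 40, missing two (38/40) does as well.
* **Work saved over sampling** `WSS@s` = `1 - SC@s`.
* **False-positive rate** `FPR@s` = `FP / (FP + TN)` evaluated at the same
  depth `n*`; unlike SC it does not mechanically grow with prevalence, so it
  compares prevalence conditions on an equal footing.
* **Relevant records found** `RRF@p` = sensitivity at depth
  `floor(p * N)`.

Fractions such as `0.95 * 20` are guarded with a `1e-9` epsilon before
`ceiling()`/`floor()`, because their binary representations can land a hair
above the exact integer and would otherwise shift thresholds by one record.

## The active-learning engine

* **Feature extraction.** The built-in extractor is unigram TF-IDF:
  lowercased title + abstract, smoothed inverse document frequency
  `log((1 + N)/(1 + df)) + 1`, L2-normalised rows, vocabulary fitted once on
  the full collection (training plus screening records). Embedding
  extractors (doc2vec, SBERT) require pretrained models that this package
  does not download; they plug in through `register_extractor()` under the
  same row-alignment contract, and the deterministic `hashed_stub` extractor
  exercises the signed-embedding code path in tests.
* **Classifiers.** Ridge-penalised logistic regression (`glmnet`, single
  `lambda = 1/n`, convergence threshold `1e-4` — ranking needs nowhere near
  full convergence), multinomial naive Bayes with Laplace smoothing over
  nonnegative feature mass (naive Bayes cannot process the negative values
  signed embeddings produce, and `check_compatibility()` enforces this),
  a linear-kernel SVM scored by raw decision margin (ranking only — the
  certainty query needs no calibrated probabilities), a probability random
  forest (`ranger`, 200 trees), and a two-hidden-layer ReLU perceptron
  (128 units per layer, clamped to the training-set size for tiny samples,
  full-batch Adam, 200 epochs). All fits are deterministic given the run
  seed.
* **Balancing.** `dynamic_resampling` rebuilds each training set as a
  size-preserving multiset with the relevant class raised to a target share
  of 0.5: every relevant record is retained (replicated as needed) and the
  irrelevant class is subsampled. The exact weighting scheme of the
  original tooling is not published; this reconstruction matches its verbal
  description and is documented so tests can verify it arithmetically.
  Internally, multiset repetitions are collapsed to observation weights for
  classifiers that accept them — the fitted model is identical, the row
  bookkeeping far cheaper.
* **Querying.** Certainty-based: candidates are sorted by score descending
  with a *stable* tie-break on original collection order, so rankings are
  reproducible permutations.
* **Retraining interval.** The model is refit after every k-th revealed
  label; within a batch the simulator walks down the current ranking
  without re-ranking (whether the original tooling re-ranks mid-batch is
  not documented; no-re-rank is the natural reading of "updated after every
  k-th label" and is stated here as the package's choice). A full run
  therefore performs exactly `ceiling(n_candidates / k)` fits. Labeled
  records leave the candidate pool immediately, even between refits.
* **Traces run to exhaustion.** Stopping rules are evaluated post hoc, so a
  single simulated ordering serves every rule.

Two accounting conventions are supported and recorded on the trace. When
the initial training records are drawn from the collection itself
(ratio-sampling designs), they occupy positions 1..t of the trace and count
in every denominator. When the training set is disjoint from the screening
set (fixed-relevant designs), the trace covers the screening set only.

## The synthetic corpus generator

Downstream code needs labeled collections with controllable difficulty, so
the generator produces bag-of-token documents from a two-component model: a
shared background vocabulary with Zipf-shaped probabilities, plus a disjoint
block of signal tokens (5% of the vocabulary size, at least 10 types).
A relevant document draws each token from the signal block with probability
`signal_strength`, otherwise from the background; irrelevant documents draw
from the background only. Document lengths are Poisson around
`doc_length_mean` (default 120 tokens, about the length of a title plus a
typical abstract). At `signal_strength = 0` the class-conditional
distributions coincide and no classifier can beat chance — a property the
test suite verifies with cross-validated AUC over 30 seeds.

A `noise_rate` fraction of relevant documents (default 10%) is generated
from the pure background distribution. This emulates a robust finding in
real screening data: some relevant records resemble nothing in the training
set and surface only late in the ranking. Two consequences are worth
understanding:

* SC at high sensitivity levels is dominated by these hard records. Once
  the learnable relevants are exhausted, the certainty ranking works
  through records *most similar to what it has seen labeled relevant*;
  pure-background relevants resemble the irrelevant centroid and therefore
  tend to surface very late — later than uniformly at random.
* For the same reason, SC@95% is **not** a clean monotone function of
  `signal_strength` when `noise_rate > 0`: a stronger signal model finds
  the learnable records faster but defers the background-like ones even
  more. Separability checks in this package therefore fix `noise_rate = 0`
  and use a low-signal grid (0.02–0.2), where the median SC@95% of the
  reference logistic-regression pipeline falls cleanly as the signal
  strengthens.

What passing tests on this generator do *not* show: real abstracts have
correlated vocabulary, topic drift, inconsistent labeling and
near-duplicates; none of these are modelled. Synthetic results validate the
machinery (metrics, rules, designs, determinism), not the empirical
performance levels of any particular corpus.

## Manipulation designs

Two sampling designs reshape a labeled collection into experimental
conditions:

* **Ratio sampling** hits a target prevalence exactly: writing the target
  as a reduced fraction `a/b`, the largest subset with `k*a` relevant and
  `k*(b - a)` irrelevant records is drawn
  (`k = min(floor(R/a), floor(I/(b - a)))`). Excess irrelevant records are
  dropped when the original prevalence is below the target, excess relevant
  records when it is above. The source material does not state its rounding
  rule when the ratio is unattainable; the largest-exact-subset rule is
  this package's documented choice, and it reproduces the published
  fixed-relevant collection sizes.
* **Fixed-relevant sampling** holds the relevant count constant (e.g. 20 or
  40) and adjusts prevalence through the irrelevant count
  (`n_rel * (1 - p)/p`), yielding totals of 2,000/800/400 at 1%/2.5%/5%
  with 20 relevant records and 4,000/1,600/800 with 40.

Training sets are drawn uniformly per replication; in disjoint mode the
screening set is identical across training conditions, so training-set
effects are not confounded with the number of records to find.

## Seeds and reproducibility

Every source of randomness flows from one integer master seed through a
counter-based chain of MINSTD steps (`derive_seed()`), exact in double
arithmetic. Manifest rows receive sub-seeds from their factor coordinates,
so results are independent of execution order and resumable; the
artificial-collection seed is shared across algorithms and training
conditions within a replication, which keeps comparisons paired as in the
original designs. Re-running any component with the same seed is
byte-identical.

## Stopping rules

All rules are evaluated per record on the trace prefix (whether phased
protocols check per record or per batch is unstated in the source
literature; per record is the finer and stricter choice):

* **data-driven**: stop at the first run of `cutoff` consecutive irrelevant
  labels (fractional cutoffs convert to `ceiling(cutoff * N)`).
* **time-based**: stop at `ceiling(fraction * N)`.
* **key-study**: stop when the last pre-identified relevant record
  surfaces.
* **combined (all-met)**: each member counts as met from the position its
  condition first holds, permanently thereafter; the stop position is the
  maximum of the members' first-met positions. The
  "twice-the-random-phase-finds" criterion of phased protocols is available
  as `rule_min_relevant()`.
* **breakout**: a high-cutoff consecutive-irrelevant run can pre-empt the
  fallback rule; the stop position is the minimum of the two.

Every rule is tested against an independent brute-force scan on a thousand
random traces.

## Recommendation layer

The prescreening phase estimates prevalence as finds divided by random
screens (with a floor of `max(1% of N, 100)` random screens). Cutoffs are
then looked up in a prevalence-band table of which only the text-anchored
entries ship as defaults: below 2.5% prevalence a 40% time-based cutoff
with a 15% breakout run; between 2.5% and 7.5% a 35% time-based plus 5%
data-driven cutoff. The band above 7.5% is deliberately unconfigured and
the lookup fails closed rather than inventing values; users supply their
own table to fill it. Projected workload saving is
`1 - (random + time-based + data-driven)` fractions, converted to abstracts
and hours at 30 s per abstract. Multiplying estimated prevalence by the
collection size is exposed separately as `expected_relevant()` — it is an
expected count, not a prevalence.

## Desk-scale problem sizes

The package's test suite replicates the fixed-relevant factorial design at
desk scale: 9 synthetic collections (4,300 records, 50 relevant,
heterogeneous signal strength), 3 prevalence conditions (1%, 2.5%, 5%), 2
relevant-count conditions (20, 40), and 20 replications per cell with the
logistic-regression + TF-IDF algorithm. For this batch the retraining
interval is 50 and the suite uses 60-token documents with an 800-token
vocabulary — settings chosen so a full run of more than a thousand
simulations completes on a single core in minutes while leaving the
qualitative comparisons (active learning beats random screening in every
cell) untouched. For batch execution, TF-IDF features are extracted once
per source collection and row-subset per sampled sub-collection; a single
`run_simulation()` call without precomputed features still fits the
vectorizer on exactly the training-plus-screening union. The full-scale
conditions (1,000 replications, retraining after every label) remain
expressible through the same API — they are simply a larger manifest.

## Known limitations

* No hyperparameter search, no model switching mid-screening, and no
  statistical (estimated-recall) stopping criteria — heuristics only.
* Embedding extractors ship as an interface, not an implementation.
* The synthetic generator makes no attempt at realistic English text.
* The SVM scores are uncalibrated margins; anything consuming scores as
  probabilities must use the probability-producing classifiers.
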