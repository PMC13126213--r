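# alscreen

Simulation framework for **AI-aided abstract screening** in systematic
reviews and meta-analyses.

Literature searches return thousands of abstracts of which only a small
fraction (often 0.5–10%) are relevant. Active-learning screening tools rank
the unscreened abstracts by predicted relevance, retraining after each batch
of reviewer decisions, so that the relevant records surface early and
screening can stop before the pile is exhausted. Whether that works — and
when it is safe to stop — depends on the machine-learning algorithm, the
prevalence of relevant records, the collection size, and the training set.
`alscreen` is a toolbox for studying exactly those questions by simulation,
aimed at evidence-synthesis methodologists.

It provides:

* **Data model and I/O** — labeled abstract collections read and written as
  CSV or RIS, with eligibility checks for the common simulation designs.
* **Synthetic corpus generator** — two-class bag-of-token collections with
  controllable size `N`, prevalence, lexical separability
  (`signal_strength`) and a tail of hard-to-find relevant records
  (`noise_rate`), so the whole pipeline is testable without any downloads.
* **Manipulation designs** — exact-prevalence ratio subsampling and
  fixed-relevant-count sampling (e.g. 20 relevant records at 1%/2.5%/5%
  prevalence give totals of 2,000/800/400), plus seeded training-set
  selection, disjoint or in-collection.
* **Active-learning engine** — TF-IDF features (plug-in interface for
  embedding extractors), classifiers `lr`, `nb`, `svm`, `rf`, `nn2layer`,
  certainty-based querying, dynamic-resampling class balancing, and a
  configurable retraining interval; every run is deterministic given its
  seed.
* **Metrics** — screening cost `SC@s`, work saved over sampling
  `WSS@s = 1 − SC@s`, false-positive rate `FPR@s`, relevant records found
  `RRF@p`, and sensitivity `TP/(TP+FN)`, all computed from the screening
  trace with the ceiling threshold rule (`TP* = ⌈s·R⌉`, so 19/20 and 38/40
  meet `s = 0.95` exactly).
* **Stopping rules** — consecutive-irrelevant (data-driven), time-based,
  key-study, all-met combinations, and the breakout rule, evaluated post
  hoc on traces and verified against brute-force oracles.
* **Experiment orchestration** — factorial designs over collections ×
  prevalence × frequency × training sets × algorithms with deterministic
  per-run sub-seeds, replication thinning, and median/IQR/90th-percentile
  summaries.
* **Recommendations** — prevalence estimation from a random prescreening
  phase, prevalence-band cutoff lookup (fail-closed for unconfigured
  bands), and projected workload savings.

## Worked example

```r
library(alscreen)

# A 1,000-record synthetic collection with 5% prevalence
corpus <- generate_corpus(corpus_spec(n_total = 1000, prevalence = 0.05, seed = 7))
corpus
#> <abstract_collection> N = 1000, R = 50 (prevalence 5.00%), key studies = 0

# One relevant + one irrelevant training record from the collection itself,
# logistic regression on TF-IDF, re-ranking every 10 labels
parts <- sample_training_set(corpus,
  training_spec(1, 1, disjoint_from_screening = FALSE, seed = 8))
config <- al_config("lr", "tfidf", retrain_interval = 10, seed = 9)
trace <- run_simulation(parts$screening, parts$training, config)
summary(trace)
#> Screening trace over 1000 records (50 relevant)
#>   SC@95%  =  52.80%   (screened fraction to reach 95% sensitivity)
#>   WSS@95% =  47.20%   (workload saved at that sensitivity)
#>   FPR@95% =  50.53%   (irrelevant records screened at that depth)
#>   RRF@10% =  90.00%   (sensitivity after screening 10%)
```

Reading the numbers: screening the top-ranked 52.8% of this collection
identifies 95% of its relevant records (so 47.2% of the screening workload
is saved at that sensitivity level), and after screening only the first 10%
of the trace, 90% of the relevant records have already surfaced. The
default `noise_rate` makes a tenth of the relevant records lexically
indistinguishable from the irrelevant class, which is why the last few
relevant records are expensive — exactly the behaviour observed in real
screening data.

Stopping rules are evaluated on the same trace:

```r
stop_combined(trace, list(rule_time_based(0.10), rule_data_driven(50)))
#> <stop_outcome> stop at position 100 (10.0% screened), sensitivity 90.0% [time_based + data_driven]
```

And the practical recommendation layer turns a random prescreening phase
into cutoffs and a projected saving:

```r
recommend_screening(n_total = 2000, n_random_screened = 200, n_relevant_found = 6)
#> Projected workload saving: 50% of 2000 abstracts
#>   = 1000 abstracts never screened (~8 h at 30 s/abstract)
#>   screened: 10% random + 35% time-based + 5% data-driven
```

(The estimated prevalence 6/200 = 3% selects the mid band: 35% time-based
plus 5% data-driven cutoff; here 10% of the collection was spent on random
prescreening, so the projected saving is 50%.)

See `vignette("screening-simulation-methods")` for the models, the metric
definitions, the seeding scheme, and the design choices.

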