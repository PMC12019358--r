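---
title: "Methods: cohorts, extraction, topics and enrichment in switchscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohorts, extraction, topics and enrichment in switchscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscope)
```

## The problem

Why patients switch contraceptive methods is clinically important but
poorly captured by structured data: the prescription record shows *that* a
switch happened, while the *reason* — side effects, adherence, preference,
insurance — usually lives only in free-text clinical notes. `switchscope`
implements the full analysis chain for this setting:

1. build a switching cohort from structured medication orders;
2. extract (stopped, started, reason) triples from the linked notes with a
   pluggable extractor;
3. score extractions against human gold labels and structure-derived
   silver labels;
4. cluster the extracted reasons into topics;
5. score each topic's enrichment across patient subgroups.

Because real clinical notes cannot be redistributed, the package ships a
seeded synthetic EHR generator whose planted truth makes every stage
testable end to end.

## Cohort construction and switch detection

Drug products are mapped to six delivery modalities — Oral, Implant, IUD,
Injectable, Transdermal, Intravaginal — by a case-insensitive regex table
(`inst/extdata/modality_patterns.yaml`, user-editable). Exclusion patterns
(condoms, diaphragms, spermicides, pH modulators, emergency contraception)
are tested first; drug names that no pattern recognizes are dropped with a
warning rather than an error, since any shipped pattern table is
necessarily incomplete.

`apply_filters()` applies the attrition sequence in a fixed, documented
order: non-contraceptive class, exclusion patterns, unmapped names,
missing start dates, insufficient follow-up, missing note, short note
(at most 50 whitespace tokens; configurable), duplicate
(patient, encounter date, modality) rows. Each step appends one row to an
attrition report whose `remaining` column is conserved by construction.
Token counting uses whitespace tokens: the filter's semantics — drop
uninformative stubs — do not depend on a particular subword tokenizer, and
the threshold is a parameter.

Design choices the data model forces us to make explicit:

* **Follow-up window.** Six months is fixed at 183 days. The follow-up
  anchor is the *last* contraceptive order by default, with
  `followup_anchor = "first"` available; both readings appear in practice
  and the choice is material, so it is a switch, not a constant.
* **Switches are set differences.** A patient may hold several modalities
  at one encounter, so an encounter's state is a modality *set*; a switch
  is any set inequality between consecutive encounters (ordered by start
  date, ties broken by modality name for determinism), with
  `stopped = previous \ current` and `started = current \ previous`.
* **Note linking.** When an encounter has several qualifying notes the
  longest is linked.

`demographic_comparison()` produces the usual baseline table: mean (SD)
with a two-sided t-test for continuous variables; counts and percentages
among non-missing values with a chi-square test for categorical ones. The
chi-square is computed without continuity correction, i.e. the textbook
\(\sum (O-E)^2/E\) statistic, so small worked examples match hand
calculation exactly; a variable with one observed level is reported as
not-applicable rather than tested.

## Note extraction

`extract_switch_info()` is the reference extractor behind the pluggable
seam (any function `text -> (stopped, started, reason)` can replace it, so
an LLM adapter drops in without touching the evaluation code). It is a
deterministic cue-phrase rule set: stop cues (`stopped`, `discontinu…`,
`removal of`, `came off`) and start cues (`started`, `starting`,
`switching to`, `begin…`, `placed`) anchor a search for the nearest
following drug mention, which is normalized through the same pattern table
as the cohort stage; the reason is the clause after a causal cue
(`because`, `due to`, `reports`). When several sentences carry a start cue
the last wins — plans are typically stated at the end of a note. A
redaction placeholder (`[REDACTED]`) normalizes to no modality:
de-identification pipelines are known to redact brand names that resemble
person names (for example Camila or Heather), and the extractor mirrors
that failure mode instead of guessing.

Silver-standard labels (`derive_silver_labels()`) are taken from the
structured orders at the switch encounter: the event's set differences,
with the alphabetically first modality as the documented tie-break when a
set has more than one element.

## Evaluation

`micro_f1()` treats each task (started, stopped) as multi-class over the
six modalities with "none" excluded from the positive set: a none
prediction against a positive gold label is a false negative, a positive
prediction against none gold is a false positive, and a wrong positive
prediction counts once on each side. `cohens_kappa()` is
\((p_o - p_e)/(1 - p_e)\) with expected agreement from marginal products;
the restricted variant drops pairs whose reference label is none before
computing, mirroring concordance on "notes with a relevant contraceptive"
only. Both are intentionally hand-written closed forms — they are part of
the package's evaluated surface — and kappa is cross-checked in the test
suite against an independent implementation.

`learning_curve()` trains a text classifier on seeded random subsamples
(fractions of the training split) over `k` random 70/10/20 resplits and
reports mean/SD micro-F1 on the held-out test split. The text features are
bag-of-words or TF-IDF vectors including word bigrams by default: a switch
note mentions both the stopped and the started product, so unigram bags
are information-theoretically unable to tell the two tasks apart — the
direction lives in n-grams like "starting nuvaring". The built-in
classifiers are a lasso-penalized multinomial logistic regression (which
concentrates weight on the sparse discriminative n-grams) and a random
forest; anything with a `fit`/`predict` contract plugs in. Folds whose
training subsample loses a class (or reduces it to a singleton) are
skipped with a warning.

## Topic modeling of extracted reasons

Reasons are embedded as L2-normalized term-frequency vectors
(`embed_reasons()`; TF-IDF optional, and any embedding backend — e.g. a
transformer — can be substituted as a function). Notes with no extracted
reason are parked on the reserved topic `"0"` before clustering and are
excluded from enrichment by default.

Extracted reasons are short and heavily duplicated, which shapes the
clustering design. Geometry is computed on the *unique* vectors with their
multiplicities carried as density weights. Cluster labels come from a
shared-nearest-neighbor construction in the Jarvis–Patrick family: each
unique point's neighborhood is the smallest distance-ordered prefix
holding at least `min_cluster_size + 1` total multiplicity (never fewer
than `n_neighbors + 1 = 4` points); two points are linked when their
neighborhoods share at least two members; clusters are the connected
components, components lighter than `min_cluster_size` become noise, and
clusters are numbered by decreasing size. This chooses the number of
topics from the data, is exactly deterministic, and is robust both to
continuous well-separated clusters and to the discrete duplicate-heavy
distributions that extracted reasons actually have. A five-component
Laplacian-eigenmap reduction over the 3-nearest-neighbor Euclidean graph
is computed alongside and exposed as `coords` for inspection and
plotting; during development we found that clustering *inside* such a
low-dimensional map is unstable exactly in the duplicate-heavy regime
(the neighborhood graph either fragments into one component per distinct
phrase or, with soft affinities, lets small pools leak into each other),
which is why the labels are taken from the shared-neighbor graph at full
resolution instead.

Per-note topic weights \(q_{n,k}\) are inverse-distance soft memberships
to the cluster centroids, renormalized so each row sums to 1; noise notes
carry all weight on topic `"0"`. Key terms per topic use class-based
weighting: pool each topic's texts into one pseudo-document and weight
term \(t\) in topic \(c\) by
\(\mathrm{freq}(t,c)\cdot\log(1 + K/K_t)\) where \(K\) is the number of
topics and \(K_t\) the number containing \(t\). `merge_topics()` applies a
manual merge map, summing `q` columns within groups so per-note mass is
conserved exactly.

## Subgroup enrichment

For topic weights \(q\) and a binary note-by-subgroup indicator \(y\)
(race/ethnicity categories, or age bins `<21`, `21-30`, `31-40`, `40+` —
age 40 falls in `31-40` under our closed-interval reading, since the
nominal bins touch at 40), the enrichment of topic \(k\) in subgroup
\(j\) is

\[
\theta_{k,j} \;=\; N\,\frac{\sum_n q_{n,k}\, y_{n,j}}
  {\left(\sum_n q_{n,k}\right)\left(\sum_n y_{n,j}\right)},
\]

reported as the natural log. The numerator is summed over notes and the
ratio is scaled by the note count \(N\) so that the statistic is
dimensionless and independence of topics and subgroups gives
\(\theta = 1\) (\(\log\theta = 0\)) — the normalization "by total topic
weight and by subgroup size" made exact. The un-scaled ratio is available
with `scale_n = FALSE`. Cells with a zero denominator are explicit
missing values, never silently zeroed. Useful identities, all tested: a
subgroup containing every note has \(\log\theta = 0\) for all topics; the
subgroup-size-weighted average of \(\theta_{k,\cdot}\) is exactly 1 for
each topic; \(\theta\) is invariant to duplicating every note. No
significance test is attached to \(\theta\): it is a descriptive
prevalence ratio, not a causal estimate.

## The synthetic EHR generator

`generate_cohort()` simulates patients with demographics (race/ethnicity
and language frequencies, and an age distribution of mean 29, SD 8,
matching the magnitudes reported for real contraceptive cohorts), 2–5
contraceptive encounters with configurable inter-encounter gaps (the
time-to-switch distribution is exposed as configuration rather than
asserted), a 7.6% default patient-level switch probability — the rate the
reference cohort reports — and a first-modality mix dominated by oral
contraceptives. Switch notes embed the cue phrases the reference
extractor targets ("stopped X … because <reason>", "starting Y") padded
with neutral clinical filler past the 50-token threshold; dates are
integer day offsets from a synthetic epoch.

Reason topics come from a six-topic catalog (irregular bleeding,
preference, adherence, weight/mood, insurance, device discomfort). Each
pool shares a core vocabulary disjoint from every other pool's — the same
property that makes real extracted-reason clusters coherent under a term
embedding — so planted clusters are recoverable by construction, exactly
as the cue phrases make gold labels recoverable. A subgroup enrichment
plan multiplies a topic's prevalence inside a race or age subgroup by a
configurable factor (3x in the validation harness; 0 plants a depletion).

Noise is planted on *disjoint* record sets: each order receives at most
one of {missing start date, missing note, short note, duplication};
lost-to-follow-up patients are chosen first and their orders leave the
other noise pools; distractor rows (non-contraceptive and emergency
orders) go to retained patients only, because a random late encounter on
a lost patient would hand them spurious follow-up. This disjointness is
what makes the planted per-filter counts equal the attrition report
*exactly*, so the generator's bookkeeping can serve as a strict oracle.
Brand-name redaction replaces Camila/Heather mentions with `[REDACTED]`
in a configurable fraction of eligible switch notes.

What the generator does *not* emulate: realistic clinical prose, multiple
notes per encounter, within-modality product switches, comorbidities,
silver-label noise from undocumented external prescriptions. Passing
tests on synthetic data therefore demonstrate the pipeline's mechanics
and calibration, not extraction performance on real notes.

## Problem sizes and determinism

The bundled validation uses desk-scale sizes chosen to make the
statistics decisive: 1,000 notes x 100 replicates for the enrichment
null (every mean \(\log\theta\) within 0.05 of zero), 2,000 switch notes
x 100 seeded runs for planted 3x-enrichment recovery (arg-max cell), 10
seeded cohorts for reason-cluster recovery, and 1,000 random timelines
against a brute-force switch oracle. All randomness flows from explicit
seeds; `generate_cohort()` restores the caller's RNG state, and rerunning
any stage with the same configuration is bit-identical. `run_pipeline()`
writes each artifact as soon as its stage completes and records a config
hash, seeds and package version in a manifest.
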