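# switchscope

Treatment-switching analysis for contraceptive prescription records:
cohort construction and switch detection from structured medication
orders, rule-based (and pluggable) extraction of *stopped / started /
reason* triples from clinical note text, evaluation against gold and
silver-standard labels, topic clustering of free-text switching
rationales, and a topic-by-subgroup enrichment statistic.

## Who this is for

Clinical informaticians and epidemiologists studying *why* patients
switch between contraceptive delivery methods (oral, implant, IUD,
injectable, transdermal, intravaginal). The prescription record shows
that a switch happened; the reason usually lives only in free text. This
package implements the full chain from raw order/note/demographics tables
to a subgroup-enrichment matrix, and — because real clinical notes cannot
be shared — ships a seeded synthetic EHR generator with planted truth so
every stage is testable without any protected data.

## The statistics at the core

* **Switch definition.** With encounters ordered by prescription start
  date, a switch is any difference between consecutive encounters'
  modality *sets*; `stopped = previous \ current`,
  `started = current \ previous`.
* **Micro F1** over the six modalities (none excluded from the positive
  set), pooling TP/FP/FN across classes, for extraction quality;
  **Cohen's kappa** `(p_o − p_e)/(1 − p_e)` for concordance between
  silver labels and human annotation, with a restricted variant that
  drops notes lacking a relevant contraceptive.
* **Topic enrichment.** For per-note topic weights `q(n,k)` and binary
  subgroup indicators `y(n,j)`,

  ```
  θ(k,j) = N · Σₙ q(n,k)·y(n,j) / (Σₙ q(n,k) · Σₙ y(n,j))
  ```

  reported as `log θ`; independence of topic and subgroup gives 0.
  Subgroups are race/ethnicity categories or the age bins `<21`, `21–30`,
  `31–40`, `40+`.

See the methods vignette (`vignettes/switching-methods.Rmd`) for models,
assumptions, parameter defaults and known limitations.

## Worked example

```r
library(switchscope)

cfg <- sim_config(n_patients = 400, switch_probability = 0.25, seed = 2024,
                  noise_rates = list(missing_start = 0.03, duplicate = 0.05,
                                     short_note = 0.02))
res <- run_pipeline(cfg, out_dir = "run1")
res$filtered$attrition
#>             filter removed remaining patients
#>            initial       0      1471      400
#>  non_contraceptive       0      1471      400
#>   excluded_pattern       0      1471      400
#>           unmapped       0      1471      400
#>      missing_start      42      1429      400
#>        no_followup       0      1429      400
#>       missing_note       0      1429      400
#>         short_note      28      1401      400
#>          duplicate      70      1331      400
```

The attrition report mirrors a study flow diagram: 1,471 synthetic orders
enter; 42 lose their start date, 28 sit at encounters whose note is an
uninformative stub, 70 are duplicate (patient, date, modality) rows; each
removed count equals the generator's planted noise exactly.

```r
res$eval_report$started[["f1"]]   # 0.9892473
res$eval_report$stopped[["f1"]]   # 0.9892473
```

Extraction recovers all but the switches whose note was degraded by the
planted short-note noise (with all noise rates 0 both F1 values are
exactly 1). The topic stage clusters the extracted reasons — here four
topics survive the minimum-cluster-size filter, with class-based key
terms such as `forgetting/daily/doses`, `cramping/device`,
`weight/gain/mood` and `spotting/irregular/bleeding` — and the enrichment
stage scores them against demographics:

```r
round(res$enrichment$race_ethnicity$theta_log[, 1:4], 2)
#>   White Latinx Black or African American Asian
#> 1 -0.03   0.01                     -0.18 -0.07
#> 2 -0.04   0.06                      0.23  0.02
#> 3  0.16  -0.04                     -0.17 -0.13
#> 4 -0.11  -0.03                      0.07  0.17
```

With no planted enrichment the log scores hover near 0; planting a 3x
prevalence factor for one (topic, subgroup) cell makes that cell the
arg-max (`recover_planted_enrichment()`).

A thin command-line wrapper lives at `inst/cli/switchscope.R`
(`simulate` and `run` subcommands).

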