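# atcpipe

Pharmacoepidemiologic research needs drugs expressed as therapeutic
classes, and the standard vocabulary is the WHO Anatomical Therapeutic
Chemical (ATC) system. Real-world dispensing databases instead carry
operational codes and free-text names ("apo-rosuvastatin", "prolopa
50-12.5") and strengths ("50 MG", "25/100 MG") — and for some drugs the
*daily dose* decides the class: aspirin at ~81 mg/day is an antithrombotic
(B01), at 650 mg/day an analgesic (N02); high-dose folic acid is an
antianemic preparation (B03) rather than a vitamin (A11).

`atcpipe` is an R implementation of an end-to-end pipeline for assigning
second-level ATC codes (therapeutic subgroups such as B01, N02, C09) to
dispensed drugs, built for researchers who hold raw dispense records and
need classified, anonymized, statistically characterized output:

* **Daily dose strings** — dispense records are collapsed into
  irreversibly anonymized strings
  `pms-quetiapine|2 pills of 200 mg, 4 pills of 25 mg`
  (quantities summed per patient-day-drug-strength, names lower-cased,
  missing strengths imputed as `UNK`, identity and dates discarded,
  duplicates collapsed).
* **LLM classification** — each string goes to a pluggable chat-completion
  backend under a bundled chain-of-thought prompt requesting
  `<reasoning>|<best code>|<next best or NA>`; completions are parsed
  totally (statuses `ok` / `na` / `delimiter_error`) by taking the last
  two pipe-delimited fields as codes.
* **Search benchmark** — an alternative classifier queries
  `"<drug> ATC Code"`, harvests full codes matching
  `[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}` from the top-10 result titles/snippets,
  truncates to 3 characters and majority-votes.
* **Finite-population inference** — for human-graded samples drawn without
  replacement from the N distinct strings, the mostly-correct proportion
  gets the interval
  `p̂ ± z·sqrt(((N−n)/N)·p̂(1−p̂)/n)`,
  and the same formula inverted plans sample sizes.
* **Synthetic data** — a bundled formulary with dose-dependent rule-based
  truth, a deterministic mock completion backend with configurable fault
  injection, and a mock search backend, so the whole pipeline runs and is
  tested entirely offline.

## Worked example

```r
library(atcpipe)

records <- generate_drug_records(3, days = 2, seed = 7)   # synthetic dispense table
doses   <- build_dose_strings(records)
doses
#> [1] "atarax|4 pills of 25 MG"           "vitamin d2|2 pills of 1.25 mg"
#> [3] "azithromycin|4 pills of 500MG"     "ergocalciferol|2 pills of 1.25 mg"
#> [5] "cyanocobalamin|4 pills of 100 MCG"

backend <- mock_completion_backend(default_formulary(), mock_config())
parsed  <- parse_completions(classify_batch(build_batch(doses), backend))
parsed[, c("best", "next_best", "status")]
#> # A tibble: 5 × 3
#>   best  next_best status
#> 1 N05   R06       ok
#> 2 A11   NA        ok
#> 3 J01   NA        ok
#> 4 A11   NA        ok
#> 5 B03   A11       ok
```

Hydroxyzine (brand name atarax) lands in psycholeptics (N05) with
antihistamines (R06) next best; azithromycin in antibacterials (J01); the
B12 supplement at a high dose in antianemics (B03) ahead of vitamins (A11).

Inference on a graded sample of 200 drawn from a population of 12,294
distinct strings, with 185 of 200 graded at least mostly correct:

```r
finite_population_ci(185, 200, 12294, confidence = 0.80)
#> proportion estimate: 92.5% (185/200, 80% CI 90.1%-94.9%), N = 12294

classify_by_search("metformin", mock_search_backend(default_formulary()))
#> search classification: A10
#>   tally: A10:10
```

A command-line interface over the same functions ships at
`inst/cli/atcpipe.R` (subcommands `simulate`, `build-doses`, `classify`,
`benchmark-search`, `evaluate`, `sample-size`); see `?atcpipe_main`.

The methods vignette
(`vignettes/atc-classification-pipeline.Rmd`) documents the model,
the anonymization procedure, the parsing rule, the finite-population
formulas and the design of the synthetic world.

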