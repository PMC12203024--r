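---
title: "Classifying daily drug doses into second-level ATC codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying daily drug doses into second-level ATC codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atcpipe)
```

## The problem

Pharmacoepidemiologic analyses need drugs expressed as therapeutic classes,
and the de-facto standard is the WHO's Anatomical Therapeutic Chemical (ATC)
system. Real-world dispensing databases, however, carry operational codes
(NDC in the US, DIN in Canada) and free-text drug names and strengths —
"apo-rosuvastatin", "50 MG", "25/100 MG" — that do not map cleanly onto ATC
classes. Worse, for some drugs the *daily dose* decides the class: aspirin
around 81 mg/day is an antithrombotic (B01), while 650 mg/day and up is an
analgesic (N02); high-dose folic acid is an antianemic preparation (B03)
rather than a vitamin (A11).

`atcpipe` implements an end-to-end pipeline for this task:

1. **dose strings** — collapse raw dispense records into irreversibly
   anonymized daily dose strings such as
   `pms-quetiapine|2 pills of 200 mg, 4 pills of 25 mg`;
2. **LLM classification** — send each string to a prompted chat-completion
   backend that reasons step by step before emitting
   `<reasoning>|<best level-2 code>|<next best or NA>`;
3. **search benchmark** — an alternative classifier that queries a web
   search engine with `"<drug> ATC Code"`, harvests full 7-character ATC
   codes from the top-10 result titles and snippets by regular expression,
   truncates them to their first three characters, and majority-votes;
4. **evaluation** — finite-population inference on human-assigned grades,
   including CI construction and sample-size planning;
5. **synthetic data** — a formulary-driven generator and deterministic mock
   backends so that the whole pipeline runs and is tested offline.

## Anonymization by construction

A dispense record is (patient, date, drug name, strength text, pill
quantity). The daily dose string keeps only what a classifier needs:

* pill quantities are summed within (patient, date, lower-cased drug name,
  strength), with missing strengths imputed as `"UNK"` and `"0"` passing
  through;
* each strength total renders as `{q} pill(s) of {strength}` — singular
  exactly when the quantity is 1; integers bare, fractions with up to two
  decimals ("0.5");
* multiple strengths of one drug-day join into a comma-delimited list;
* the patient identifier and date are dropped and only distinct strings are
  kept, so identical regimens from different patients are one population
  member.

```{r}
records <- tibble::tibble(
  patient_id = "P1", dispense_date = "2024-03-01",
  drug_name = "PMS-Quetiapine",
  strength = rep(c("200 mg", "25 mg"), 2), quantity = rep(c(1, 2), 2))
build_dose_strings(records)
```

Two choices here were genuinely open. The ordering of a multi-strength list
is not forced by the record layout; we order by descending numeric value of
the strength's leading number (so "1 pill of 10.0 MG, 1 pill of 5.0 MG"),
with unparseable strengths following in first-appearance order — a
deterministic rule consistent with how such regimens are conventionally
written. And names are grouped *after* lower-casing, so "Aspirin" and
"aspirin" dispensed the same day sum together; grouping before
normalization would split populations on cosmetic case differences.

## The classification contract

Prompts are shipped verbatim as package resources (`build_prompt("initial")`
and `build_prompt("revised")`). The revised prompt uses few-shot examples
with chain-of-thought reasoning: the model is asked to work out the total
daily dose and the most likely indication *before* emitting its delimited
answer, which is what lets dose-dependent drugs land in the right subgroup.

Requests default to temperature 0 (consistency is the priority for a
classification pipeline) and a 1000-token completion cap — enough for a
paragraph of reasoning, a guard against runaway output. `classify_batch()`
treats the backend as a contract: transient errors are retried with bounded
backoff, permanent failures become `status = "failed"` items, and a batch
always completes.

Completions are parsed by taking the **last two** pipe-separated fields as
the candidate codes and everything before them as reasoning. This is the
only rule that survives contact with real chain-of-thought output, which
freely contains newlines and sometimes pipes inside the reasoning. Parsing
is total: every string maps to `ok`, `na` (the model declined, `|NA|NA`),
or `delimiter_error` (missing or empty fields, or a token that is not a
valid second-level code), with the raw text preserved for review.
Delimiter errors are a real failure mode of chain-of-thought prompting —
the model must stop reasoning and emit its fields — so they are first-class
outcomes, not exceptions.

## The search benchmark

`classify_by_search()` composes `build_query()` (append `" ATC Code"`), the
backend, `harvest_codes()` (scan title + snippet of at most the first 10
items for `[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}`, truncate each match to 3
characters, keep every occurrence without deduplication), and
`majority_vote()`. Ties are reported as ties — whether a tie is acceptable
depends on whether *all* tied codes are appropriate, which is a grading
decision (`grade_search_output()`), not a retrieval one. Scanning title and
snippet (rather than snippet alone) reflects where search APIs actually
surface code strings; occurrence-level counting follows from treating every
harvested string as one vote.

## Finite-population inference

The estimand is the proportion *p* of at least mostly correct
classifications (grade 1 or 2 on the 3-point scale) **in the finite
population of N distinct daily dose strings** — not in some hypothetical
superpopulation. Sampling n strings without replacement gives the estimate
$\hat p$ and the interval

$$\hat p \;\pm\; z_{1-\alpha/2}\,
  \sqrt{\frac{N-n}{N}\cdot\frac{\hat p(1-\hat p)}{n}},$$

where the finite population correction $(N-n)/N$ shrinks the standard
error and vanishes at a census. We use the $(N-n)/N$ form of the
correction; the alternative $(N-n)/(N-1)$ differs by well under the
rounding precision of any reported percentage at these sizes. The z
quantile is always computed from `qnorm()`, never hard-coded.

```{r}
finite_population_ci(185, 200, 12294, 0.80)
```

`required_sample_size()` inverts the half-width formula and then verifies
the integer boundary directly, so the returned n is the exact minimum:

```{r}
required_sample_size(margin = 0.02, p_planning = 0.95,
                     confidence = 0.80, N = 12294)
```

With these inputs the exact minimum is 192. Percentages are reported
rounded half away from zero to one decimal (`format_percent()`).

Grading itself is human work consumed as data (`read_llm_grades_csv()`,
`read_search_grades_csv()`); the package never auto-grades real drugs.
Automatic grading exists only against synthetic formulary truth, in tests.
No formal comparison test between the two arms is offered — the
cross-tabulation (`cross_tabulate()`) is descriptive by design.

## What the synthetic data emulates — and what it does not

The bundled formulary (31 entries) pairs realistic drug names, manufacturer
aliases and strength strings with *rule-based* dose-dependent truth:
aspirin ≤ 100 mg/day → B01, ≥ 325 mg/day → N02 with B01 next best;
folic acid ≥ 4 mg → B03; prednisone ≥ 40 mg → A07 ahead of H02; an
unclassifiable placeholder (`xyz-1234`) that must yield `NA|NA`. The mock
completion backend resolves aliases, computes a total daily dose by
multiplying each pill count by the leading numeral of its strength
(combination strengths such as "25/100 MG" contribute their first
component — a documented mock simplification, not pharmacology), applies
the rules, and emits a canonical chain-of-thought-shaped completion.
Fault injection is configurable: a `delimiter_error_rate` of malformed
pipe-free completions and an `unknown_drug_rate` of `|NA|NA` refusals.
Every per-input random draw is keyed by a hash of the input and the
configured seed, so mock output is deterministic and independent of call
order.

The record generator (`generate_drug_records()`) produces patients on one
to four drugs dispensed once or twice daily, with mixed-case names (20% of
regimens), two-strength regimens (15%), fractional pills (10%) and missing
strengths (5%) — rates chosen once as representative of dispensing-table
messiness. `synthesize_population()` enumerates
alias × strength × quantity combinations to any requested population size;
its default of 12,294 distinct strings is the population scale the
inference machinery is designed around.

What passing tests on this synthetic world shows: the plumbing is correct —
aggregation conserves quantities, anonymization never leaks identifiers,
parsing round-trips every canonical completion, votes match brute-force
counts, CIs cover at close to nominal rate under repeated seeded sampling.
What it cannot show: how often a *real* language model misidentifies a
*real* brand name, reasons about the wrong drug, or breaks its output
format — those error rates depend on live services and human grading and
are outside what any offline test can certify.

## Numerical and testing choices

Problem sizes were picked to keep the default test run comfortably fast
while still exercising scale: the repeated-sampling calibration uses the
full 12,294-string population with 200 replicate samples of n = 200 at
fault rates of 5% and 10%; oracle-equivalence properties run on 1,000
randomized instances per operation. Quantities are compared to integers at
a 10⁻⁹ tolerance before rendering; CI bounds are clamped to [0, 1];
`parse_completion()` never raises. The without-replacement sampler restores
the caller's RNG state, so seeded pipelines compose without surprises.

## Limitations

* Second-level validation is syntactic (14 main-group letters + two
  digits); no WHO index ships with the package, though an allow-list can
  tighten validation.
* The live completion and search backends are thin contracts; nothing is
  guaranteed about the determinism of a remote model even at temperature 0,
  and only the mock backend is covered by reproducibility tests.
* The daily-dose problem formulation itself has edge cases — weekly dosing
  regimens, drugs needing three or more plausible codes — that no amount of
  prompt engineering inside this formulation resolves.
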