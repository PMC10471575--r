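---
title: "Staged depression and suicide-risk screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged depression and suicide-risk screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

## The screening model

`depscreen` implements a two-stage triage algorithm for depression and acute
suicide risk designed for general medical practices (GMPs), plus the
cohort-level accounting needed to size the psychiatric care such screening
would generate.

**Stage 1 — hopelessness gate.** Every respondent completes the 4-item short
form of the Beck Hopelessness Scale (BHS-4). Items are scored 0–3
("not typical" … "very typical"), so the total spans 0–12. Hopelessness is an
independent and strong predictor of suicide risk, which is why it gates the
tree: a total of 6 or more signals acute suicide risk and immediate referral
to a psychiatrist, without completing the depression inventory; a total of 9
or more additionally warrants consultation about psychiatric admission, which
the triage output surfaces as a `very-high-suicide-risk` note rather than a
separate category (both totals lead to the same immediate-referral branch).

**Stage 2 — depression inventory.** Respondents in the intermediate BHS zone
complete the 9-item short form of the Beck Depression Inventory (BDI-9),
items scored 1–4, total 9–36, with severity bands 9–13 (none), 14–18 (mild),
19–24 (moderate), ≥25 (severe). Totals below 19 end screening; 19–24
indicates a structured assessment for a DSM-5 major depressive episode (MDE);
≥25 indicates immediate referral.

**Stage 3 — MDE check.** An MDE is present when at least one of the two core
symptoms (depressed mood, loss of interest) and at least four additional
DSM-5 symptoms are present. An MDE accompanied by any suicidality
qualifier — current ideation, a plan, or a previous attempt — needs treatment
by a psychiatrist; a non-suicidal MDE can be treated in the GMP; when
criteria are not met, referral should be considered, or close monitoring with
repeat screening after three months (encoded as the `monitor-3-months` action
label only; no longitudinal state is modelled).

Three protocols differing only in the stage-1 stop zone are shipped:

| Protocol | BHS ends screening | BDI-9 completed for | BHS refers |
|----------|-------------------|---------------------|------------|
| P1       | 0–1               | 2–5                 | ≥ 6        |
| P2       | 0–2               | 3–5                 | ≥ 6        |
| P3       | 0–3               | 4–5                 | ≥ 6        |

All boundary semantics are closed intervals exactly as the instruments
publish them. Evaluation order is fixed: a prior psychiatric diagnosis
excludes the record before anything else (such patients are already under
specialist care, so screening cannot be implemented for them); then BHS
missingness; then the BHS zones; then BDI missingness; then the BDI zones.
Any missing item voids its whole instrument — cohort accounting works with
whole-instrument missingness, so no prorating or imputation is attempted.

## Cohort accounting

`tabulate_cohort()` classifies every record into exactly one of eight
terminal categories and reports prevalences against the **full** cohort size,
including excluded and instrument-missing records — the convention under
which every published percentage reproduces from its count. Records routed
to the BDI stage whose BDI-9 is missing form their own category
(`BDI_MISSING`): they are neither dropped nor counted toward care need.

Two aggregates summarise care need:

* **definitive** — immediate referrals by BHS (≥6) plus by BDI-9 (≥25);
* **potential** — the BDI-9 19–24 group awaiting MDE assessment.

The 19–24 group counts as potential need *without* requiring DSM-5 flags;
when flags exist, the MDE sub-split is reported additionally, never replacing
the headline aggregation. Rounding (half away from zero, two decimals for
percentages) is applied at presentation only; aggregation always uses raw
counts.

## Extrapolation

`extrapolate_count(c, N, T)` returns `round_half_away(c * T / N)`. The two
reference targets are an average GMP of 1,600 registered adults and the
Hungarian population over 25 years of age, 7,288,433 in 2018; both are
config values, so other populations can be substituted. Properties that hold
by construction: exact scale equivariance for integer multiples of N, and
`|estimate − cT/N| ≤ 0.5`.

The canonical convention is **aggregate-then-round**: the definitive-care
estimate rounds the raw sum of the two referral counts, not the sum of two
rounded estimates. Both conventions are computed and shown in the
reconciliation note because component-wise rounding can differ by a patient
or two, and some previously circulated practice-scale aggregates appear to
arise that way.

## The synthetic cohort generator

The survey underlying the calibration (a nationally representative Hungarian
cohort of 12,668 adults interviewed in 2002) is not publicly deposited, so
`default_blueprint()` encodes its published marginal structure as exact cell
counts: 805 respondents with prior psychiatric conditions, 658 with missing
BHS, 1,097 with BHS ≥ 6, BHS-zone sizes 6,992 / 1,177 / 827 / 1,112 for
totals 0–1 / 2 / 3 / 4–5, 491 BDI-9 non-completers inside the BHS 2–5 zones,
and the published BDI-9 bands within BHS 3–5 (19–24: 45 + 190; ≥25: 41 + 137).
These cell counts *are* the study conditions; they are not tunable toward any
result.

Two allocation questions are not settled by the published marginals, and the
choices are isolated in the blueprint with `free = TRUE`:

* the 491 BDI-9 non-completers are placed inside the BDI-indicated zone
  (they are described as a subset of BHS completers, and only BDI-indicated
  records have a BDI stage to miss) and split across the BHS 2 / 3 / 4–5
  zones proportionally by zone size, remainders by largest remainder:
  186 / 130 / 175;
* the BDI bands inside the BHS = 2 zone (needed only for P1's BDI-stage
  splits, which were never published) are allocated proportionally to the
  pooled band distribution of BHS 3–5 completers: 740 below 19, 143 in
  19–24, 108 at ≥25.

Because of the second point, P1's BDI-derived categories describe a *family*
of equally calibrated cohorts, not a unique one; the reconciliation note
states this whenever P1 aggregates are reported, and no P1 BDI-split figure
is treated as exact.

`generate_cohort()` emits exactly the blueprint counts — the analysis is a
census of the sample, not a sampling experiment — so triage tables are
identical for every seed; seeds only change item-level realisations and
record order. Within a cell, item vectors are sampled uniformly over all
compositions whose total lies in the cell's range, implemented as vectorised
rejection of uniform item draws conditioned on the total (the same
distribution), with dynamic-programming composition counts providing
feasibility checks and batch sizing. `sample_stochastic_cohort()` draws cell
memberships multinomially instead and exists for robustness and power
experiments only.

What the generator does **not** emulate: the survey's cluster-randomised
sampling design, refusal mechanism and interviewer effects; demographic
structure (sex and age are uniform placeholders flagged non-calibrated); any
within-zone correlation between item patterns and demographics; and DSM-5
symptom data, which are generated only on request via the `mde` blueprint
extension because the headline accounting never uses them. Passing tests
therefore demonstrate that the algorithmic pipeline reproduces the published
accounting identities — not that it would reproduce item-level or
subgroup-level behaviour of the real cohort.

## Numerical choices and degenerate inputs

* Rounding is half away from zero everywhere a figure is printed (base R
  `round()` rounds half to even and would not reproduce the published
  estimates).
* Out-of-range item values, totals, counts or blueprint cells raise errors
  naming the item/record/cell; they are never coerced.
* An empty cohort, duplicate record ids, or an infeasible blueprint cell
  (a score range no item composition attains) are errors, not warnings.
* The problem sizes used throughout the test suite are the study's own:
  one 12,668-record cohort for the census checks, exhaustive enumeration of
  the 13 × 28 score grid for the partition and oracle properties, and 200
  multinomial draws at n = 12,668 for the stochastic-sampler calibration
  check.

## Known limitations

* No survey weighting or design-effect correction (the published proportions
  are unweighted), no demographic stratification, and no uncertainty
  intervals — the accounting is a census with point extrapolations.
* The MDE stage is exercised on synthetic and worked examples only; the
  calibration cohort carries no DSM-5 symptom data.
* Published figures that depend on the free BHS = 2 cells or on
  component-wise rounding are documented in the reconciliation note rather
  than asserted (see `reconciliation_note()`).

## Worked example

```{r example}
cohort <- generate_cohort(seed = 42)
tab <- tabulate_cohort(cohort, "P1")
tab
extrapolate_table(tab, population_target("gmp", 1600))
```
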