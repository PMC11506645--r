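---
title: "Identifying Down syndrome in administrative data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying Down syndrome in administrative data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsphenotype)
```

## The phenotyping problem

Down syndrome is a congenital condition with near-universal healthcare
contact in early childhood, which makes it a natural target for rule-based
case identification in claims data. Two administrative sources carry DS
evidence: the birth certificate (a DS check box before 2004; separate
karyotype-confirmed and karyotype-pending indications from 2004 onward) and
ICD diagnosis codes on billed encounters (758.0 in ICD-9-CM, the Q90 family
in ICD-10-CM). Neither source is reliable alone — certificates are filed
within days of birth, before most postnatal diagnoses are confirmed, and
billing codes are occasionally assigned to children who have a different
chromosomal abnormality.

The classifier therefore demands corroboration. Among children *suspected*
of DS (any certificate indication, or any DS-coded encounter before age
six), a child is classified as having DS when at least one criterion holds:

1. karyotype-confirmed DS on the birth certificate (the strongest single
   indication);
2. karyotype-pending or unspecified DS on the birth certificate **and** at
   least two DS-coded encounters before age six;
3. at least three DS-coded encounters before age six, the first and last at
   least 30 days apart — when coding stands alone, the separation
   requirement forces at least two independent care episodes and screens
   out one-off miscoding.

The criteria are evaluated independently and all flags are reported; the
final label is their disjunction, with no precedence. Validation against a
chart-review gold standard reports the positive predictive value among
algorithm-positives and the true-negative proportion among
algorithm-negatives, with Wilson score intervals, plus the
criterion-combination breakdown. Sensitivity and specificity are *not*
reported by default: a design that conditions on suspected DS cannot
observe DS children with zero coded evidence, so population-level operating
characteristics are unidentifiable. An `operating = TRUE` flag computes
them within the labelled subset only, explicitly annotated as such.

## Conventions that needed a decision

Several operational details are underdetermined by the prose definition of
the algorithm; the package fixes them as follows.

**Encounter = distinct service date.** Multiple claim lines, providers, or
codes on one date count as a single healthcare encounter. This is the
conservative reading of "independent healthcare encounters": same-day
claims usually describe one care episode.

**Follow-up window.** Follow-up ends at the earliest of the sixth birthday,
death, disenrollment, and the end of study. The window is inclusive of the
death/disenrollment/study-end date but exclusive of the sixth birthday
itself ("the first six years of life" ends the day before the birthday).

**Calendar arithmetic.** Ages use calendar-year addition; a Feb-29 birth
anniversaries on Mar-1 in non-leap years. This is deterministic and
testable, and it affects at most one day of window per leap-day birth.

**30-day separation.** `last − first ≥ 30` calendar days, inclusive — a
span of exactly 30 days satisfies criterion 3, a span of 29 does not. The
rule depends only on the extreme dates, never on intermediate ones.

**Criterion 2 and the 2004 format change.** The unspecified-DS certificate
value is only legal for pre-2004 births and karyotype-pending/confirmed
only for 2004+ births; this era constraint is enforced once, at
birth-certificate ingestion, rather than re-checked inside the classifier.
No separation requirement is applied to criterion 2's two encounters: the
certificate already provides the independent second source, and the rule's
prose states none.

**Code matching.** Codes are normalized (trimmed, upper-cased, decimal
point removed) and matched by prefix within their own ICD revision: "7580"
matches hypothetical five-digit children, "Q90" matches Q90.0–Q90.9. The
code sets are configuration (`ds_code_config()`), not constants, so the
engine generalizes to other phenotypes; with empty code sets the predicate
is constantly false.

**Missing certificates.** A child present in claims but absent from the
certificate table gets status `none` rather than an error — linkage
completeness varies across real extracts. Conversely, every encounter child
must appear in the censoring table; a violation is a hard referential
error. Continuous enrollment during infancy, the cohort inclusion rule, is
consumed as an upstream boolean column rather than recomputed from monthly
enrollment spells, for which no granularity is available.

## Validation statistics

With `s` successes in `n` trials and `z` the exact standard-normal quantile
(1.959964 at 95%, not 1.96), the Wilson interval is

$$\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}.$$

Bounds are clamped to [0, 1]; at $\hat p = 0$ or $1$ the corresponding
bound is exact. The implementation is checked in two independent ways: a
root-finding inversion of the score test $|\hat p - p| = z\sqrt{p(1-p)/n}$
(agreement to $10^{-6}$ over a grid up to $n = 1000$) and
`stats::prop.test(correct = FALSE)`. Reported percentages are rounded half
away from zero to one decimal (`round_half_up()`); base R's
round-half-to-even would print different final digits at exact ties. When a
cohort has no algorithm-positives the PPV is reported as absent (`NA`),
never 0, and the no-criterion row of the combination table carries no PPV
at all.

```{r demo}
v <- run_demo()
```

## The synthetic cohort generator

No study data ship with the package, so `simulate_ds_cohort()` generates
cohorts with the statistical structure the classifier assumes: a latent
true DS status per child, a birth date, a follow-up window with optional
early disenrollment, a DS-coded encounter stream, a background non-DS
encounter stream (filler codes exercise the negative side of code
matching), and an era-aware, imperfect birth-certificate indication. The
true status doubles as the gold-standard label, so recovery properties can
be asserted exactly.

Encounters follow homogeneous Poisson processes over the follow-up window,
with same-day collisions collapsed — the simplest stationary visit model,
matching the date-level encounter definition. ICD revision follows the
service date (ICD-9 before 2015-10-01, ICD-10 after), and generated codes
mix dotted/undotted dialects so normalization is exercised end to end.

Default parameters, chosen once as a realistic referral-style setting:

| parameter | default | rationale |
|---|---|---|
| `n_children` | 2000 | hundreds of cases at the default prevalence; comparable to a single-center validation sample |
| `ds_prevalence` | 0.10 | enriched cohort mirroring a suspected-DS validation design, not the ~1/700 birth prevalence |
| `birth_year_range` | 2000–2017 | spans both certificate eras and the ICD-9/10 transition |
| `bc_sensitivity` | 0.28 | roughly a quarter of true cases carry a certificate indication |
| `bc_confirmed_fraction` | 0.35 | confirmed-only indications are the minority of indicated certificates |
| `bc_false_positive_rate` | 0.002 | incorrect certificate indications are rare (order 1 per 100 indications) |
| `ds_visit_rate` | 2/yr | regular care with DS coded as a comorbidity |
| `miscode_rate` | 0.02/yr | occasional billing miscoding in non-DS children |
| `background_visit_rate` | 3/yr | routine pediatric utilization carrying filler codes |
| `followup_censor_prob` | 0.2 | some children disenroll early, uniformly over the window |
| `study_end` | 2020-12-31 | administrative censoring date |

What the generator does *not* emulate: comorbidity structure (the real
driver of visit frequency), non-stationary visit rates (diagnostic visits
cluster after birth), provider networks, linkage error, and death. Passing
recovery tests therefore show that the classifier behaves correctly on
data satisfying its own assumptions — they do not estimate its operating
characteristics on any real population.

## Experiments the package runs on itself

`recovery_experiment()` chains simulate → assemble → classify → validate
per replicate (replicate r uses seed + r − 1) and reports the empirical PPV
and the fraction of true-DS children classified DS. Two properties are
asserted in the test suite, both at n = 2000 children × 10 replicates
(sizes chosen to make Monte-Carlo error small relative to the effects
checked):

* with `miscode_rate = 0` and `bc_false_positive_rate = 0` there is no
  mechanism for false evidence, so the PPV is exactly 1 on every replicate;
* the detected fraction is non-decreasing over the visit-rate grid 0.25,
  0.5, 1, 2, 6 per year under a shared base seed, and exceeds 0.99 at 6/yr
  with full six-year follow-up — at 36 expected coded visits, failing to
  accumulate three dates spanning 30 days is vanishingly rare.

The classifier itself is checked against a brute-force restatement of the
three rules on 10,000 randomized small histories (all certificate statuses
× 0–6 encounter dates, with the 29/30-day boundary forced into the mix),
and the demonstration cohort reproduces the published headline statistics
(PPV 98.0%, CI 96.0–99.0%; true-negative proportion 87.7%, CI 76.8–93.9%;
criterion-3-only PPV 97.2%) through the full pipeline.

## Known limitations

* Date-level deduplication cannot distinguish two same-day visits at
  different providers; if those should count separately, the classifier is
  slightly conservative.
* The published validation counts contain one internal inconsistency (an
  abstract figure of 97.7% for the 50/57 true-negative proportion, where
  the arithmetic gives 87.7%); the package reproduces the arithmetically
  consistent value and notes, rather than silently corrects, the
  discrepancy.
* The algorithm's accuracy figures come from a referral-enriched,
  single-center population with frequent healthcare contact; in a general
  population, or among children with short follow-up, criterion 3 will
  miss cases with few coded visits. The recovery experiment makes this
  visible: detection drops steeply below ~1 coded visit per year.
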