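# dsphenotype

Rule-based identification of Down syndrome (DS) in administrative health
data, with chart-review validation statistics.

## The problem

Administrative claims and vital-records data make it cheap to assemble large
pediatric cohorts, but ICD billing codes are collected for reimbursement,
not research: a single DS code (ICD-9 758.0; ICD-10 Q90.x) on a claim is
weak evidence, and birth certificates capture only a fraction of true cases.
`dsphenotype` implements a computable phenotype that combines both sources.
A child is *suspected* of DS when they have any birth-certificate DS
indication or at least one DS-coded healthcare encounter before age six. A
suspected child is *classified* as having DS when at least one of three
criteria holds:

1. **Criterion 1** — karyotype-confirmed DS indicated on the birth
   certificate;
2. **Criterion 2** — karyotype-pending DS on the birth certificate (or the
   unspecified DS check box of the pre-2004 certificate format), plus at
   least two DS-coded encounters during the first six years of life;
3. **Criterion 3** — at least three DS-coded encounters during the first six
   years of life, with the first and last separated by at least 30 days.

An *encounter* is a distinct service date carrying at least one DS code in
any diagnostic field; same-day claim lines count once. Follow-up runs from
birth to the earliest of the sixth birthday (exclusive), death,
disenrollment, or the administrative end of study (inclusive).

Against a chart-review gold standard the package reports the positive
predictive value PPV = TP / (TP + FP) among algorithm-positives and the
true-negative proportion among algorithm-negatives, each with a Wilson
score 95% CI,

```
( p̂ + z²/2n ± z √( p̂(1−p̂)/n + z²/4n² ) ) / ( 1 + z²/n ),
```

plus a per-criterion-combination breakdown table. Sensitivity/specificity
are deliberately not reported by default: a suspected-DS design cannot see
DS children with no coded evidence.

## Worked example

The built-in demonstration cohort (411 suspected children reconstructed as
raw encounter/certificate/censoring tables) runs the full pipeline:

```r
library(dsphenotype)
run_demo()
```

```
DS algorithm validation against chart review (95% Wilson CIs)
  Suspected DS: 411 children; algorithm-positive: 354 (86.1%)
  PPV: 347/354 = 98.0% (CI: 96.0-99.0%)
  True negatives: 50/57 = 87.7% (CI: 76.8-93.9%)
  Criterion-combination breakdown:
     crit1 crit2 crit3   n confirmed_ds confirmed_no_ds    ppv
         X               1            1               0 100.0%
         X           X  34           34               0 100.0%
               X         3            3               0 100.0%
               X     X  63           63               0 100.0%
                     X 253          246               7  97.2%
                        57            7              50     NA
```

Reading: of 411 suspected children the classifier labels 354 as DS; 347 of
those are chart-confirmed (PPV 98.0%). Among the 57 it labels not-DS, 50
are confirmed non-DS (87.7%). The encounters-only stratum (criterion 3
alone, 253 children) has PPV 97.2% — ICD coding alone is nearly as good as
coding plus certificates, which matters where vital records are
inaccessible. The all-blank row is the no-criterion group, for which a PPV
is undefined.

On your own extracts:

```r
det <- run_classify("encounters.csv", "birth_certificates.csv",
                    "censoring.csv", out_dir = "out",
                    study_end = as.Date("2020-12-31"))
v <- run_validate("out/determinations.csv", "chart_review.csv", "out")
```

or from a shell via the thin wrapper `inst/cli/ds-phenotype.R`
(`simulate` / `classify` / `validate` / `demo` subcommands). Synthetic
cohorts with known truth come from `simulate_ds_cohort(sim_params(seed = 1))`,
and `recovery_experiment()` measures how often true cases are recovered.

File formats are plain CSV; see `?read_encounters`,
`?read_birth_certificates`, `?read_censoring`, `?read_chart_review`.

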