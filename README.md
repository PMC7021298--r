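# claimstroke

Rule-based identification of **acute ischemic stroke (AIS)** admission
episodes in longitudinal health-insurance claims data, with a linkage-style
validation workflow and a synthetic claims + registry generator so the whole
pipeline can be developed and tested without access to national claims data.

## The problem

ICD-10 stroke diagnosis codes (I60–I64) alone cannot separate acute ischemic
stroke admissions from hemorrhagic strokes, chronic stroke survivors, and
stroke-coded admissions for unrelated illness. `claimstroke` implements a
computable phenotype for AIS built from the claims codes generated by the
clinical workflow of acute stroke care — imaging, reperfusion therapy,
interventions, antithrombotic medication changes, and rehabilitation —
and validates it against a gold-standard registry label obtained by record
linkage. It is aimed at epidemiologists and health-services researchers who
work with admission-level claims extracts.

## What it computes

The analysis unit is the **admission episode**: an in-hospital claim
carrying I60–I64 as principal or additional diagnosis, with the patient's
surrounding claim lines attributed to it and all pre-index history kept as
lookback. For each episode the package evaluates **17 boolean key
identifiers**, each defined by a code set \(C\), a closed temporal window
\([d_\mathrm{lo}, d_\mathrm{hi}]\) in days around the index date (the start
date of the in-hospital claim), and a data scope:

* atrial fibrillation (I48\*, days 0..+30), 24-h Holter monitoring;
* brain CT, brain MRI, CT angiography (days −7..+2) and *image follow-up*
  (≥ 2 distinct imaging events, (code, date) pairs, within −7..+7);
* reperfusion therapy: IVT (alteplase, days 0..+2) and EVT (thrombectomy
  procedure codes, days 0..+2);
* interventions: carotid endarterectomy, carotid and intracranial
  angioplasty/stenting (days 0..+30);
* **new antithrombotics** at ≤ 3, ≤ 7 and ≤ 90 days: with \(L\) the set of
  antithrombotic ingredients claimed in the 180 days before index and
  \(W\) the set claimed in the window, the flag is
  \(W \neq \emptyset \land W \neq L\) (first use, added ingredient, or
  changed composition); the 90-day variant counts outpatient lines only at
  neurology/neurosurgery clinics;
* anticoagulant presence (days 0..+7), rehabilitation procedures, and
  transfer from neurology to rehabilitation within the admission.

A diagnosis-stratified **decision tree** (principal diagnosis I63 vs not,
then brain-CT status; 50 root-to-leaf trajectories) classifies every
episode as AIS / non-AIS, and a seed-keyed 7:3 development/validation split
reports sensitivity, specificity, accuracy, PPV and NPV against the linked
registry labels:

\[ \mathrm{Se} = \frac{TP}{TP+FN},\quad \mathrm{Sp} = \frac{TN}{TN+FP},\quad
\mathrm{PPV} = \frac{TP}{TP+FP},\quad \mathrm{NPV} = \frac{TN}{TN+FN}. \]

## Worked example

```r
library(claimstroke)

cohort <- generate_validation_cohort(sim_config(n_episodes = 5000, seed = 42))
calls <- cohort$claims |>
  build_episodes() |>
  apply_washout() |>
  link_registry(cohort$registry) |>
  extract_identifiers() |>
  classify_episodes()
calls
#> # A tibble: 5,000 × 5
#>   episode_id principal_dx label   trajectory_id    true_ais
#> * <chr>      <chr>        <fct>   <chr>            <lgl>
#> 1 CS0000001  R420         non_AIS C_no_mri_non_ais FALSE
#> 2 CS0000002  C719         non_AIS C_no_mri_non_ais FALSE
#> 3 CS0000003  I638         AIS     A_n3_mri_ais     TRUE
#> # i 4,997 more rows

validate_algorithm(calls, ratio = 0.7, seed = 42)
#> <stroke_validation> n = 5000 episodes, development ratio 0.7 (seed 42)
#>
#>   partition         n  sens%  spec%   acc%   PPV%   NPV%
#>   development    3500   87.8   84.7   85.7   73.4   93.5
#>   validation     1500   85.6   85.7   85.7   72.1   93.3
#>   overall        5000   87.1   85.0   85.7   73.0   93.4
```

Each row of `calls` is one admission episode with its call and the
trajectory (tree path) that produced it; the validation report shows the
five diagnostic metrics per partition. The per-node audit flow — how many
episodes entered each decision step and the fraction of true AIS among
them — is available as `flow_counts(calls)`:

```r
head(flow_counts(calls), 4)
#> # A tibble: 4 × 6
#>   node_id test                 n_in n_true n_false pct_true_ais_in
#>   <chr>   <chr>               <int>  <int>   <int>           <dbl>
#> 1 root    principal_dx ~ I63*  5000   1686    3314           0.317
#> 2 root_ct brain_ct             1686   1062     624           0.754
#> 3 A_ivt   ivt                  1062     62    1000           0.750
#> 4 A_evt   evt                  1000     25     975           0.736
```

`tidy()`, `glance()` and `autoplot()` methods summarise and plot validation
objects; `plot_identifier_summary()` shows per-identifier frequency,
sensitivity and specificity. A thin command-line wrapper over these
functions ships at `inst/cli/claimstroke.R` (subcommands `simulate`,
`episodes`, `extract`, `classify`, `validate`).

## Synthetic cohorts

Real national claims and registry data are access-restricted, so the
package ships a generator ([`sim_config()`], [`generate_blueprints()`],
[`materialize_claims()`]) that emulates the admission cohort the algorithm
assumes: 31.7 % AIS prevalence, cerebral infarction as principal diagnosis
in one third of episodes, and label-conditional identifier probabilities
inside the published envelopes. Intended flags are materialised into
window-consistent claim lines with an exact round-trip guarantee — the
extracted flags always equal the intended ones — which is what makes the
end-to-end suite meaningful. See the methods vignette
(`vignettes/claimstroke.Rmd`) for what the generator does and does not
emulate.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch at the full study
scale (40,443 synthetic admission episodes): cohort generation, episode
reconstruction, prior-stroke washout, registry linkage, extraction of the
17 identifiers, decision-tree classification, and the seeded 7:3
development/validation split with all five diagnostic metrics, then writes
its JSON result to `--out`.
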