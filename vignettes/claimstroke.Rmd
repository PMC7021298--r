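---
title: "Methods: claims-based identification of acute ischemic stroke admissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based identification of acute ischemic stroke admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimstroke)
```

## The phenotyping problem

Administrative claims record what was billed, not what was wrong with the
patient. Stroke diagnosis codes (ICD-10 / KCD I60–I64) appear on admissions
for acute ischemic stroke, but also on hemorrhagic strokes, readmissions of
chronic stroke survivors, and unrelated admissions where an old stroke is
coded as a comorbidity. `claimstroke` implements a rule-based computable
phenotype: it reconstructs admission episodes from claim lines, evaluates a
panel of temporally windowed claims-code features ("key identifiers") that
track the clinical workflow of acute stroke care, and routes each episode
through a fixed decision tree to an AIS / non-AIS call. Validation is by
linkage: an episode is a true AIS exactly when a gold-standard registry
record with the same episode key exists.

## Data model and assumptions

The atomic unit is the claim line: one billed code (diagnosis, procedure or
drug) on one date, with an in-hospital/outpatient setting flag, a
department, and — for diagnoses — a principal/additional position. An
**admission episode** is created for every in-hospital claim carrying an
I60–I64 code in principal or additional position; its index date is that
claim's start date, and its principal diagnosis is the claim's
principal-position code (which need not itself be a stroke code — stroke as
additional diagnosis is a large and important stratum).

Two conventions close gaps the source material leaves open:

* **Episode attribution.** No rule states which surrounding claims belong
  to an admission. We attribute every line of the same patient with a
  service date in `[index − 7 d, index + 90 d]` — the widest window any
  identifier uses — so episodes are self-contained for all 17 identifiers;
  each identifier then applies its own narrower window. Pre-index history
  (all lines strictly before the index date) is kept separately for
  lookback logic.
* **Washout.** Patients with any I60–I64 diagnosis before their first
  index admission are excluded (incident strokes only). The washout length
  defaults to unlimited and is configurable (`washout_days`) for data with
  truncated history. Readmissions of a surviving patient are retained:
  only history before the patient's *earliest* index date counts, which
  also makes the operation idempotent.

All downstream results are invariant to claim-line order; this is asserted
by shuffling fixtures in the test suite.

## The 17 key identifiers

Each identifier is a code set, a closed day window relative to the index
date, and a scope. Windows are read as closed intervals (`0 ~ +30` includes
both day 0 and day 30). Diagnosis code sets match by prefix (claims carry
4–6 character codes; the set lists stems such as I48), procedure and drug
codes match exactly. The catalog ships as an editable JSON config,
versioned `CRCS-K-2020`, so code-list drift is a data change:

```{r}
cat17 <- default_catalog()
cat17
cat17$identifiers$brain_ct[c("codes", "window", "scope")]
```

Three identifiers deserve comment:

* **Image follow-up** counts *distinct imaging events* — (code, service
  date) pairs over the CT, CTA and MRI sets — within −7..+7 days, and is
  true at two or more events. Two modalities on one day are two events;
  the same scan code on two days likewise. This detects TIA-like
  presentations that are lesion-negative on first imaging and re-imaged.
* **New antithrombotics** is a new-user definition. With `L` the
  antithrombotic ingredient set of the 180-day pre-index lookback ("last 6
  months" operationalised as 180 days) and `W` the set in the window, the
  flag is `W ≠ ∅ and W ≠ L`: first-ever use, an added ingredient, and a
  changed composition all qualify; unchanged therapy and pure
  discontinuation do not. Products map to ingredients through the catalog
  (the aspirin–clopidogrel combination products are mapped once, to
  clopidogrel). Note the predicate is not logically monotone from the
  3-day to the 7-day window for adversarial inputs (`L = {a, b}`,
  `W₃ = {a}`, `W₇ = {a, b}`); the synthetic generator never produces such
  histories, and the monotonicity property is asserted on generated
  cohorts, where it is an invariant of the stated world.
* The **90-day variant** restricts *outpatient* lines to neurology and
  neurosurgery departments; in-hospital lines within 0..+90 count without
  department restriction. We read the novelty condition as applying to all
  three time-point variants.

**Transfer to rehab** needs claims from both the neurology and the
rehabilitation department among in-hospital lines within 0..+30 days — any
codes, since it marks an administrative transfer rather than a specific
service.

## The decision tree

The shipped ruleset (also JSON, config-driven, validated for totality,
acyclicity and reachability) stratifies on principal diagnosis I63 and then
on brain-CT status, and cascades in clinical-flow order: reperfusion
therapy first (IVT, then EVT — near-pathognomonic for hyperacute stroke),
then interventions *combined with* a 3-day antithrombotic change
(endarterectomy and stenting are often elective, so they only count
alongside new medication), then a 3-day change combined with MRI, then
with CTA (CT stratum only — CTA without CT is unsatisfiable because the
CTA code is a subset of the CT set), and finally an MRI-gated follow-up
cascade through the 7-day change, Holter, atrial fibrillation,
anticoagulants and the 90-day outpatient change. Where atrial fibrillation
is present but neither anticoagulants nor any antithrombotic change
follows, the tree still calls AIS on a dedicated *hemorrhagic
transformation* leaf (anticoagulation withheld for a bleeding infarct),
kept as its own trajectory id for auditability. Non-I63 admissions skip
the intervention steps (clinically irrelevant there) and instead use the
3-day change combined with transfer-to-rehab, which sharpens an otherwise
weak signal in that stratum.

```{r}
rs <- default_ruleset()
rs
head(enumerate_trajectories(rs), 3)
```

The full tree topology of the source figure is not available in extracted
text, so this tree is a documented reconstruction; its 50 trajectories are
frozen in a conformance snapshot (the published count is 57, which we
report rather than assert). One structural consequence discovered by the
test suite: in the I63-with-CT stratum, the no-image-follow-up arm (5
trajectories) is unreachable from any real claims under the shipped
catalog, because entering that cascade requires both a CT and an MRI event
within −7..+2 days, which already constitute two imaging events within
−7..+7. The arm is retained (harmless, part of the reconstruction) and the
45 claims-realizable trajectories each have a generated witness episode in
the tests.

Classification is a vectorised mask walk: each episode reaches exactly one
leaf, and per-node entry/branch counts are recorded (`flow_counts()`) with
the fraction of true AIS among entrants when labels are attached — the
audit analogue of per-arrow counts on a published flow diagram.

## Validation

The development/validation split is a deterministic function of a
seed-keyed hash of the episode id (order-invariant, platform-stable,
implemented with modular double-precision arithmetic; a per-character
double-multiply plus final mixing rounds give genuine avalanche so that
near-identical ids and nearby seeds still produce unrelated partitions).
The development partition gets `floor(ratio × N)` episodes: 40,443 at 0.7
gives 28,310 / 12,133. Sensitivity, specificity, accuracy, PPV and NPV are
reported as full-precision proportions; ratios with zero denominators are
`NA`, never 0; percentage rendering (one decimal) happens only in the
print/tidy layer.

## The synthetic generator

`sim_config()` describes a stated world and its defaults are fixed, not
tuned: prevalence 0.317; principal-diagnosis mixture calibrated so the
marginal matches the published admission mix (I63 one third, intracranial
hemorrhage 6.1 %, subarachnoid hemorrhage 5.7 %, TIA ≈ 1.5 %, remainder
other) with I63 strongly enriched among AIS (P(I63 | AIS) = 0.80);
demographics 65.6 ± 15.6 years, 54 % male; and per-identifier
label-conditional probabilities placed inside the published envelopes —
imaging sensitivity 32–91 % with specificity 25–79 % (MRI better than CT
on both), reperfusion and intervention sensitivity < 10 % with specificity
> 98 %, new antithrombotics ≈ 70 %/70 %, transfer-to-rehab more specific
and less sensitive than rehab. Exact per-identifier values were not
published; the shipped numbers are therefore envelope-constrained
defaults, documented here and tunable, with no claim of matching
unpublished values.

Flags are drawn conditionally independent given the label, with three
structural implications enforced coherently (child drawn conditional on
its parent so marginals are preserved): CTA ⇒ CT, 3-day ⇒ 7-day change,
and CT ∧ MRI ⇒ image follow-up. Materialisation then emits, for every true
flag, at least one claim line satisfying its definition (codes uniform over
the set, offsets uniform over the window) and, for every false flag, no
satisfying line. The delicate cases are handled explicitly: continued
anticoagulation without novelty places the same ingredient in the lookback
so the new-user predicate fails; 3/7-day drug lines are emitted at
non-specialist outpatient settings so the 90-day neurology/neurosurgery
variant stays independently controllable; extra follow-up imaging events
are placed on days +3..+7, outside the CT/MRI windows; filler noise uses a
reserved `ZZ` code namespace that cannot collide with the catalog. The
resulting round trip — extract flags from materialised claims, compare to
intended — is exact by construction and asserted at 100 % over 10,000
episodes in the acceptance suite.

What the generator does *not* emulate: real claim layouts and
reimbursement fields, lengths of stay, hospital-level clustering,
inter-identifier correlation beyond the label (a shared-severity
correlation hook was considered and left out of the default world),
miscoding, or readmission dynamics (each synthetic episode belongs to its
own patient; readmission and washout behaviour are exercised by hand-built
fixtures instead). A green end-to-end suite therefore establishes that the
machinery is faithful to its definitions — not that the published
real-data operating point (sensitivity ≈ 81 %, specificity ≈ 82 %) would
be reproduced on national claims, which requires the restricted linked
data. The designed-performance cohort closes part of that gap: it routes
episodes to AIS leaves with designed probabilities 0.80/0.82 and the
pipeline must recover both within three binomial standard errors at the
full study size.

## Numerical choices and degenerate inputs

* Window endpoints inclusive on both ends; day offsets are whole-day
  differences `service_date − index_date`.
* "Last 6 months" = 180 days; lookback offsets −180..−1.
* Split rounding: floor for development, remainder to validation.
* Zero-denominator metrics are `NA` (e.g. sensitivity of an all-negative
  cohort), never 0.
* Empty inputs flow through: zero claims give zero episodes, an empty
  registry labels everything non-AIS, classification of zero episodes
  returns empty results with zero flow counts.
* Duplicate registry keys and episode-set mismatches between calls and
  labels are errors, not silent joins.
* The cascade order within the tree follows the narrative tie-break:
  reperfusion before interventions before imaging/medication steps.

## Known limitations

* The tree is a reconstruction; against the original figure it may differ
  in arm ordering, and its trajectory count (50) is below the published 57.
* Identifier probabilities in the generator are envelope defaults, so
  simulated metric levels (mid-80s) should not be read as predictions of
  real-data performance.
* The new-user predicate treats any set change as novelty; dose changes,
  refill stitching and adherence are out of scope.
* Multi-insurer de-duplication, costs, and privacy machinery are out of
  scope; an optional hospital `site` column is carried through unused.
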