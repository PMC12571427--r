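---
title: "Comparing rule-based diabetes phenotypes with TOST equivalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing rule-based diabetes phenotypes with TOST equivalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoequiv)
```

## The problem

Two surveillance networks can look at the same health-information-exchange
data and publish different type 2 diabetes (T2D) prevalence estimates,
because their *computable phenotypes* (CPs) — the machine-executable case
definitions — differ in which data domains they use, which diagnosis codes
they accept, and how they separate type 1 from type 2 disease. This package
implements two such phenotypes, stratified prevalence estimation over each
phenotype's own denominator, and a formal equivalence test of the resulting
proportions. Because patient-level health-exchange data cannot be shipped,
a synthetic EHR generator with known truth labels stands in for real data
in every test; the one real artifact that *is* shipped is the published
per-stratum count table, which the package regenerates cell by cell.

## The two phenotypes and how ambiguities were resolved

**CP 1** (labs + codes + medications, then T1D exclusion). A patient is
diabetic when any of four clauses holds in the two calendar years ending
with the prevalence year: (a) abnormal labs on ≥ 2 distinct dates, (b)
diabetes codes on ≥ 2 distinct dates, (c) an insulin prescription outside
every pregnancy interval, (d) any listed non-insulin antidiabetic
prescription. Decisions worth recording:

* *Pooled occasions.* The "2 or more occasions within a 2-year period"
  qualifier is applied to the three lab criteria **pooled** (an abnormal
  HbA1c in March and an abnormal fasting glucose the following January
  qualify together). The itemized layout of the source rule sheet can also
  be read per-criterion; `cp1_criteria(lab_occasions_mode =
  "per_criterion")` provides that reading. An "occasion" is a distinct
  calendar date per patient.
* *Windows are calendar years.* The 2-year window is
  `[Jan 1 of year−1, Dec 31 of year]` (and the 3-year window analogously),
  keeping both phenotypes aligned on the same prevalence year rather than
  using rolling 730-day windows.
* *Prescriptions only.* CP 1's medication clauses say "prescription", so
  dispense and administration events do not count for CP 1 (they do for
  CP 2, whose rule sheet says "prescribed, administered, or dispensed").
* *The code-type ratio.* T1D-type codes are ICD-10 `E10.x` plus ICD-9
  `250.x1`/`250.x3`; T2D-type codes are `E11.x` plus `250.x0`/`250.x2`;
  `E14.x` and four-digit `250x` count toward diabetes detection but toward
  neither side of the ratio. With zero T2D-type codes and at least one
  T1D-type code the ratio is treated as infinite (clause passes); with no
  typed codes at all the clause fails. The two printed ratio clauses
  (ratio ∧ glucagon; ratio ∧ never-prescribed-oral) are implemented as two
  separate criteria exactly as itemized.
* *"Oral hyperglycemic medications"* in the never-prescribed clause is the
  full 29-ingredient non-insulin list — no separate oral-only list is
  printed, and the source text is silent on injectables.

**CP 2** (wide net, then codes only). The wide net admits any single
abnormal lab, any diabetes-related code, or any listed medication event in
the three-year window; DM cases are then confirmed **from codes alone**;
confirmed cases are classified T2D by the type-1 code share. Decisions:

* The printed T2D rule is an OR of three clauses: ratio ≤ 0.5, OR any
  antidiabetic besides insulin/metformin, OR **no** glucagon event. The
  narrative description uses the ratio alone. Both are implemented
  (`t2d_rule_mode = "or_printed"` is the default, `"ratio_only"` the
  alternative) because the two readings genuinely disagree — the printed
  OR is a strict superset classifier (property-tested), since almost any
  record lacks glucagon.
* The printed ICD-9 patterns carry only type-2 fifth digits
  (`250.x0`/`250.x2`); type-1 fifth digits are added to the DM code set so
  that the "type 1 codes / DM codes" ratio is well-formed (numerator ⊆
  denominator) and an ICD-9-coded T1D patient is a DM case at all.
* `E09.x` appears in narrative text but not in the printed step-2 list; it
  is excluded by default (`cp2_criteria(include_e09 = TRUE)` restores it).
* Denominator eligibility is ≥ 1 encounter in the 3-year window (the
  stricter ≥ 2 variant is `min_encounters = 2`), matching the population
  description over the conflicting narrative.

Both classifiers are vectorized `data.table` implementations; the test
suite checks them label-for-label against independently written,
per-patient, plain base-R oracles on randomized populations, including a
deliberately chaotic record generator with threshold-straddling lab values
and unusual code mixes.

## Prevalence and the equivalence test

Age is completed years on December 31 of the prevalence year (the source
material never states a reference date; a fixed in-year date keeps both
denominators comparable), with closed bands 18–24, 25–34, 35–44. CP 1's
denominator is restricted to patients with an in-window encounter at one
of the catchment systems (`cp1_systems`); CP 2's uses any system.

For a stratum with counts `n1/N1` and `n2/N2` (in percent), the TOST
procedure tests `H01: p1 − p2 ≤ −δ` and `H02: p1 − p2 ≥ +δ`, each at
α = 0.05, using the unpooled Wald standard error and normal critical
values, with no continuity correction and no multiplicity adjustment
across strata. Equivalence ⇔ the 90 % interval lies **strictly** inside
(−δ, +δ) ⇔ max of the two one-sided p-values < α (the duality is
property-tested on randomized grids; a bound exactly equal to ±δ counts
as not equivalent).

Two centring conventions are provided. `analytic` (default) centres the
interval on the unrounded difference. `printed_table` centres it on the
difference of the two half-up-rounded one-decimal prevalences, which is
how published tables are laid out: for the Hispanic stratum the unrounded
difference is 2.33 pp yet the published table prints 2.4, and only the
rounded-centre convention reproduces every printed difference and CI
bound simultaneously (`reproduce_table1()` verifies all 66 derived cells).
The standard error always comes from unrounded proportions. One
corroborating detail the package computes itself: the TOST p-value for
the Hispanic row evaluates to 0.22, and for all equivalent strata to
< 0.001.

Degenerate inputs: zero denominators are an error; proportions of exactly
0 or 1 give a degenerate Wald standard error and attach a warning; δ = 0
can never yield equivalence.

## The synthetic world

`sim_config()` fixes a stated world, chosen once:

* **Demographics** follow the published denominator composition (sex
  55/45, age 25/39/36 across the three bands, race/ethnicity
  white-majority with the published minority shares).
* **True prevalence** is age-dependent — 1 %, 3 %, 6 % for T2D across the
  three age bands (bracketed by the two published estimate series), 0.5 %
  for T1D.
* **Care process**: encounters are Poisson (2/year over 3 years);
  diabetic patients receive small Poisson numbers of diagnosis dates,
  abnormal-lab dates and medication events inside the 2-year window (so
  that both phenotype windows contain them); T1D patients receive insulin,
  glucagon, T1D-typed codes, and with probability 0.5 each a C-peptide
  below 0.8 or a positive autoantibody; 10 % of women carry one pregnancy
  interval, 30 % of those a gestational insulin prescription (exercising
  the insulin-outside-pregnancy exclusion).
* **Observation**: each true lab/diagnosis/medication event is recorded
  with its domain capture probability (defaults 0.9/0.9/0.7 — medication
  feeds are the least complete in real exchanges); every diabetes code
  occurrence is type-flipped with probability 0.05. All random draws
  happen *before* thinning, so two configurations sharing a seed share
  the whole event stream and lowering a capture probability can only
  remove records — this common-random-numbers design is what makes the
  monotonicity property testable. Patients belong to the two-system
  catchment with probability 0.44 (the published CP 1 denominator is
  roughly 44 % of CP 2's).
* Unspecified-type codes (`E14.x`/`E08.x`) are available via
  `unspecified_code_prob` but default to 0: the two phenotypes treat them
  asymmetrically, and the perfect-observation world is required to be
  exactly recoverable by *both* phenotypes (which the tests assert
  label-for-label).

What a green test does and does not establish: the generator produces
separable lab values (uniform above/below the thresholds), independent
event dates, no disease progression, no care-seeking correlation with
disease severity, no geography, and no cross-system record duplication.
Perfect-capture recovery therefore validates the *rule logic*, not the
real-world accuracy of either phenotype; the degraded-capture scenario
(labs 0.7, medications 0.5, diagnoses 0.7 — all domains degraded; the
acceptance criterion names the first two, and diagnoses follow the lab
level) reproduces the *qualitative direction* that the lab-and-medication
phenotype yields higher prevalence than the codes-only one, not any
published magnitude.

## Numerical and engineering choices

* Half-up rounding (`round_half_up()`) for all displayed one-decimal
  values, matching published table conventions rather than R's
  round-half-even.
* Code matching is regex-compiled from the two printed pattern styles:
  trailing `.x` = open prefix, interior `x` = one-character wildcard;
  patterns are matched within their own code system (an ICD-9 E-code can
  never satisfy an ICD-10 pattern).
* The single-patient operations (`detect_diabetes_cp1()`,
  `wide_net_cp2()`, ...) and the bundle-level classifiers share one
  vectorized core, so the API view and the pipeline view cannot drift
  apart; independence of verification comes from the test-side oracles
  instead.
* All randomness flows from one seed through one generator; the pipeline
  manifest records config, seed and per-stage row counts sufficient to
  re-run bit-identically.

## Known limitations

* Wald intervals without continuity correction are only adequate at the
  large denominators this design targets; exact or score-based TOST
  variants are out of scope.
* The data model assumes records arrive patient-deduplicated; real
  exchanges must resolve identities upstream.
* No terminology services: medication matching is exact on normalized
  ingredient strings, code matching is purely pattern-based.
* The two published p-value conventions (abstract vs methods) cannot both
  be regenerated; the package follows the 90 % CI / α = 0.05 convention
  and reports TOST p-values, and treats the abstract's lone "95% CI"
  labelling as a typographical inconsistency left unresolved.
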