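---
title: "Evaluating pharmacogenetic warfarin dosing: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pharmacogenetic warfarin dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warfpgx)
```

This vignette is the package's account of the science it implements: the
dosing models, the rules that turn a visit history into an evaluable outcome,
the generative model behind the synthetic cohorts, and the judgement calls
made where more than one reasonable convention exists.

## The problem

Warfarin has a narrow therapeutic window monitored through the INR
(international normalized ratio), and its maintenance dose varies several-fold
across patients. Two genes carry most of the known genetic signal: *CYP2C9*,
whose \*2 and \*3 alleles slow the clearance of the active S-enantiomer, and
*VKORC1*, whose −1639G>A promoter variant lowers expression of the enzyme
warfarin inhibits. A clinic that titrates empirically — start at 5 mg/day,
adjust after each INR — leaves patients exposed to bleeding or thrombosis
until the dose settles. The retrospective question this package answers is:
given a cohort's genotypes, covariates and dose histories, how much better
would the IWPC pharmacogenetic equation have anticipated each patient's
eventual stable dose than a genotype-free equation or a fixed 35 mg/week?

## Dose-prediction models

All three comparators predict a *weekly* dose in mg/week.

The IWPC **pharmacogenetic** and **clinical** equations are linear on the
square-root-of-dose scale; the prediction is the squared linear predictor.
Age enters in decades as the continuous `age/10` (not floored to completed
decades); the choice alters predictions by under 2 % and is fixed here for
reproducibility. Genotype enters through indicator terms with their own
`unknown` categories, so partially genotyped patients remain predictable.
Race indicators are relative to a white reference; Levantine/Middle-Eastern
cohorts are mapped to the reference category, since the equations carry no
adjustment for them. The **fixed-dose** model is the constant 35 mg/week
(5 mg/day), the empirical starting practice.

Coefficients are not hard-coded: they live in
`inst/extdata/iwpc_{pgx,clinical}_coefficients.csv` and any CSV with columns
`term, estimate` can replace them (`iwpc_coefficients(model, file)`). A
negative linear predictor — possible only with pathological coefficient sets —
clamps to dose 0 with a warning rather than squaring into a spurious positive
dose.

INR is computed from prothrombin time as
$\mathrm{INR} = (PT_{patient}/PT_{normal})^{ISI}$ with defaults
$PT_{normal} = 15.0$ s and $ISI = 1.03$, the reagent calibration used in the
kind of laboratory this pipeline models; both are `inr_params()` arguments.

## From visit history to stable dose

The warfarin stable dose (WSD) is empirical, not modelled: a patient has
reached it when they stayed on one weekly dose for at least three consecutive
visits with the INR inside their personal target range (2.0–3.0 for most
patients, 2.5–3.5 after mechanical valve replacement). Three readings of the
rule were genuinely open and are resolved as follows:

* **Every INR in the run must be in range** (the stricter reading), not just
  one of them — a run containing an out-of-range INR is not stability.
* **Bounds are inclusive**: INR exactly 2.0 or 3.0 counts as in range.
* **The earliest qualifying window wins** when several exist, mirroring a
  prospective reading of the record; visits appended after the qualifying
  window can never change the WSD.

A visit with missing INR disqualifies windows containing it but not the
patient. Visits must carry at least one of PT or INR; when both are present
the stored INR must equal the PT-derived value.

## Performance statistics

For the stable-dose subset, each model is scored by:

* **MAE ± SE** — mean absolute prediction error; the uncertainty attached to
  it is the standard error of the absolute-error sample (SD/√n), the natural
  reading of "MAE ± SE" when no other definition is given.
* **Regression** — ordinary least squares of the *actual* WSD on the
  *predicted* dose (the orientation of the usual stable-versus-predicted
  scatter plot), reporting r, R², the slope F-test and its p-value on
  (1, n−2) df. The constant fixed-dose predictor has no defined regression
  and is flagged degenerate.
* **±20 % classification** — *ideal* when the prediction is within 20 % of
  the WSD; *over-/underestimation* when it is at least 20 % above/below. The
  20 % band corresponds to about 1 mg/day against the traditional 5 mg/day
  start, a difference clinicians treat as relevant. The exact-20 % boundary
  belongs to over/underestimation ("at least 20 %"), so the ideal band is
  open — the two phrasings overlap at the boundary and this resolution is
  fixed and tested.
* **ER / ARR / NNG** — the event rate is
  (under + over)/total; the absolute risk reduction between two models is
  |ER_a − ER_b|; the number needed to genotype is its reciprocal, with an
  explicit infinite flag when the ARR is zero.

Two cohort-level analyses sit alongside: the **bleeding contingency**, a 2×3
table of ever-bleeding (minor or major at least once) against the given
therapeutic dose grouped as higher/same/lower than the calculated dose, tested
with an uncorrected Pearson chi-square; and **genotype-group WSD
comparisons**, a pooled-variance t-test for two groups and one-way ANOVA for
three or more. The group comparisons accept either raw dose vectors or
published (n, mean, sd) summary triplets — the pooled t and the one-way
between/within decomposition are functions of the summaries alone, so a
published summary table can be re-tested without patient-level data.

Two more conventions worth making explicit:

* The "same as calculated" band of the bleeding table reuses the ±20 %
  classification threshold, **relative to the predicted dose** (the
  classification divides by the actual dose instead; the asymmetry is
  documented and covered by a test). No separate band definition exists in
  the field, and one consistent clinical-relevance threshold is preferable to
  two.
* The "given therapeutic dose" of a patient is the weekly dose at their last
  recorded visit; patients with no bleeding record are omitted from the
  table, as with any registry analysis of incomplete records.

## Hardy–Weinberg testing and frequencies

Allele frequencies are always derived by direct gene counting:
variant frequency = (het + 2·hom)/2n. Rounded frequencies quoted in summary
reports sometimes disagree with the counts they accompany; this package
reports only count-derived values.

The Hardy–Weinberg test is the Pearson chi-square of the observed three-class
genotype counts against n·(p², 2pq, q²) with p estimated by gene counting,
on 1 df, without continuity correction — the textbook default when no method
is named. Exact or corrected tests would shift borderline p-values slightly;
the package does not chase agreement with any particular published rounding.
A monomorphic locus (q = 0 or 1) has nothing to test and returns a flagged
chi-square 0, p 1. For CYP2C9 the six-class diplotype is reduced to the copy
number of one variant allele at a time (\*2 by default), so a \*2/\*3 carrier
counts as heterozygous for either allele; carriers of the other variant are
not excluded, which is exact when the second allele is absent (the situation
in the population modelled here) and an approximation otherwise.

## RFLP genotype calling

Each assay digests one amplicon with an enzyme that cuts exactly one allele:
AvaII cuts the wild-type CYP2C9 sequence (454 → 397 + 57 bp, so uncut 454 bp
marks \*2), KpnI cuts the \*3 variant (105 → 85 + 20 bp), MspI cuts the
VKORC1 wild-type G (290 → 167 + 123 bp). A cut-only lane is homozygous for
the cut allele, uncut-only homozygous for the other, both patterns together
heterozygous. Fragments under 60 bp (the 57 and 20 bp products) routinely
run off 2.5–3.5 % agarose gels, so a pattern missing only sub-resolution
bands still calls when unambiguous; any unrecognized band length is a no-call
with a diagnostic, never a guess. The two CYP2C9 site calls combine into the
six-class IWPC diplotype, and patterns implying more than two variant alleles
raise a record-level error.

## The synthetic-cohort generator

`simulate_cohort()` exists so that every pipeline stage is testable without
any patient-level data. Its defaults are the study conditions of the cohort
it emulates, fixed once:

* n = 101; 42.4 % male; age ~ Normal(48.8, 14.4) truncated to [16, 76] years;
  BMI ~ Normal(27.8, 5.2) kg/m², with sex-specific heights
  (Normal(172, 6.5) cm male, Normal(159, 6.5) cm female — ordinary adult
  anthropometrics chosen to reproduce the BMI distribution) and weight
  derived as BMI·height².
* Genotype class probabilities equal to the observed counts over 101:
  CYP2C9 75/25/1 (\*1/\*1, \*1/\*2, \*2/\*2; no \*3 allele), VKORC1 30/49/22
  (GG, GA, AA). The two loci are drawn independently; no linkage is imposed.
* Indication 50.5/41.4/8.1 % (thromboembolic/cardiovascular/both); a 3/101
  mechanical-valve fraction with the 2.5–3.5 INR target.
* **Dose process**: true √WSD = pharmacogenetic linear predictor +
  Normal(0, σ), squared and floored at 7 mg/week (half a 5 mg tablet every
  other day — below that, dosing schedules stop being practical). Placing the
  noise on the √dose scale matches the IWPC model's own scale, which makes
  σ = 0 an exact-recovery case: the pharmacogenetic model then has MAE 0 and
  R² 1 by construction, a clean surface for testing. The default σ = 0.9 was
  chosen once against the dose dispersion such cohorts show (stable doses
  ≈ 35 ± 14 mg/week) and yields R² ≈ 0.35–0.45 for the pharmacogenetic model
  and ≈ 0.1–0.25 for the clinical one — the regime reported for real
  Middle-Eastern cohorts.
* **Visit history**: 0–3 titration visits (35 mg/week start, then steps
  toward the true WSD in 2.5 mg increments) with sub-therapeutic INR, then
  3–5 visits at the true WSD with INR drawn around the target midpoint
  (SD 0.25) and clamped into range. Prothrombin times are back-computed from
  the INRs, so the stored pair is always consistent.
* **Bleeding**: Bernoulli with
  logit p = −0.35 + 2.5·(WSD − predicted)/predicted — a logistic form chosen
  because only an association (overdosing relative to the pharmacogenetic
  prediction raises bleeding), not a functional form, is established; both
  coefficients are exposed parameters. The intercept puts overall bleeding
  near 45 %, the slope separates the higher-dose and lower-dose groups by
  roughly 20 percentage points, matching the magnitude seen in practice;
  85 % of events are minor.
* Enzyme-inducer (2 %) and amiodarone (5 %) flags are low-prevalence
  placeholders: such co-medication is uncommon but must be exercised by
  tests.

What the generator deliberately does **not** emulate: INR
pharmacokinetics/dynamics (titration INRs are simply sub-therapeutic draws),
adherence, inter-locus linkage, measurement error in genotypes, and — most
importantly — patients who never stabilize. Every simulated patient ends in
a recoverable stable run, whereas less than half of a real empirically
titrated cohort may reach stability. Passing tests on synthetic cohorts
therefore demonstrate the pipeline's correctness and the identifiability of
the genetic signal under the stated generative model, not the field
performance of the algorithm on any real population.

## Numerical and degenerate-input conventions

* Same seed ⇒ identical cohort and byte-identical fixture files; all
  randomness flows through the single seed parameter, and analysis functions
  are seed-free.
* Zero-noise recovery is exact in memory (the generator and the predictor
  share one code path for the linear predictor). Through the CSV round-trip
  it is exact to write-precision (differences below 1e-12 mg/week).
* Degenerate inputs signal classed conditions rather than returning NaN: an
  empty cohort, a constant predictor in regression, a monomorphic locus
  (flagged result), a zero ARR (infinite NNG with flag), expected counts of
  zero in the chi-square.
* p-values are never compared as strings anywhere; tests use numeric
  tolerances at the printed precision of the reference values.

## Problem sizes used by the test-suite

The suite verifies the statistics on hand-computable examples, checks the
chi-square and Hardy–Weinberg implementations against independent oracles by
enumeration (all 2×2 tables of total ≤ 12; all polymorphic genotype triples
of total ≤ 30), and runs the Monte-Carlo genotype-benefit comparison on 200
seeded cohorts of n = 47 — the stable-subset size at which such evaluations
are typically run, large enough that the pharmacogenetic model's R² exceeds
the clinical model's in ≈ 98 % of replicates under the default noise.
Single-cohort pipeline checks use n = 25–101.

## Known limitations

* The IWPC equations are transcribed as published; the package does not
  refit them, and populations far from the source cohorts may need the
  coefficient-override path.
* The CYP2C9 Hardy–Weinberg reduction is exact only when one variant allele
  segregates (see above).
* Stable-dose determination requires literal dose equality across the run;
  registry data with noisy dose recording may need pre-rounding.
* The bleeding model is a single-covariate logistic on relative dose excess;
  it is a test harness for the contingency analysis, not a clinical risk
  model.
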