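---
title: "Methods: association rule screening of small clinical cohorts"
author: "clinrules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association rule screening of small clinical cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinrules)
```

## The screening procedure

`clinrules` screens a participant-level cohort for association rules
A → B, where the antecedent A is a conjunction of one or two dichotomized
conditions and the consequent B is a fixed outcome state (by default a low
SF-12 physical or mental component score at 1 or 2 years after knee
replacement). Writing the 2×2 cross-tabulation of "applicable" (all
antecedent conditions hold) against the consequent as counts
$a, b, c, d$ with $N = a+b+c+d$:

$$\mathrm{support} = \frac{a}{N}, \qquad
  \mathrm{confidence} = \frac{a}{a+b}, \qquad
  \mathrm{lift} = \frac{\mathrm{confidence}}{(a+c)/N}.$$

Three identities anchor the implementation and are asserted on every mined
set: support ≤ confidence; lift × prior = confidence, with
prior = $(a+c)/N$; and lift ≤ $N/(a+c)$, with equality exactly at
confidence 1. The last identity explains a pattern worth recognising in any
rule table: against a consequent with prevalence 32/44, *every* rule with
confidence 100% has lift exactly 44/32 = 1.375, so a column of identical
1.38 values is arithmetic, not coincidence.

Because the candidate space is tiny (at most a few hundred antecedents for
~16 variables), mining is exhaustive enumeration — no Apriori-style pruning,
no heuristics — which makes the brute-force oracle equivalence in the test
suite a complete check rather than a sample. Output order is fully
deterministic: lift, then confidence, then support (all descending), then
the alphabetical antecedent label; reruns are byte-identical.

## Dichotomization

Each variable contributes a *pair* of items (high and low state), so either
state may serve as a condition — "non-depressive symptoms" or "female sex"
are as legitimate antecedents as their complements. The recipes, shipped in
`inst/extdata/variables.yaml`:

| Variable | Method | High state |
|---|---|---|
| age | fixed cut-off | ≥ 60 years |
| BMI | fixed cut-off | ≥ 30 kg/m² |
| CES-D | fixed cut-off | ≥ 16 |
| CCI (comorbidities) | fixed cut-off | ≥ 1 |
| SF-12 PCS/MCS (all timepoints) | fixed cut-off | ≥ 50 (standard score) |
| sit-to-stand time, WOMAC subscales | median split | > sample median |
| sex, joint type | categorical | one item per level |

Two numerical choices deserve justification:

* **Fixed cut-offs are inclusive on the high side** (≥). This matches the
  clinical conventions the cut-offs come from: a CES-D of exactly 16 counts
  as depressive symptoms, an age of exactly 60 as old.
* **Median-split ties go low.** The high state is *strictly greater than*
  the full-sample median (for even N, the midpoint of the two central order
  statistics). With ties at the median this is the only rule that keeps the
  split as balanced as the data permit while remaining deterministic; a
  tie-free even-sized sample splits exactly in half. Medians are computed on
  the full analysis sample, never per subgroup, so the split is a property
  of the cohort, not of any rule.

Validation is strict by design: missing cells and out-of-range values are
errors naming the row and column, never imputed or clamped, because the
intended use is a complete-case cohort and silent repair would change every
downstream count.

## Testing extracted rules

Each extracted rule's applicable/non-applicable table is tested two-sided
at α = 0.05. The test is chosen by **Cochran's rule**: Fisher's exact test
when any expected cell count ($\text{row total} \times \text{column total}/N$)
is below 5, the χ² test otherwise. This convention is the standard default
where no explicit choice criterion is available, and at N = 44 with
unbalanced priors it sends most perfect-confidence rules to Fisher.
Fisher's two-sided p-value sums the probabilities of all tables with the
observed margins that are no more probable than the observed table; the
test suite checks this against direct hypergeometric summation. The χ² test
applies no Yates continuity correction by default (a flag enables it), so
either choice is reproducible. No multiplicity adjustment is applied by
default — each rule is reported with its raw p-value, as an exploratory
screen should — but Benjamini–Hochberg adjusted p-values can be requested
and are reported *alongside*, never instead of, the raw ones.

When auditing published 2×2 counts (`verify_counts()`), all metrics are
recomputed from the counts rather than trusted from printed summaries: the
identity lift × prior = confidence makes transcription errors in published
rule tables detectable, and recomputation sidesteps them.

## The synthetic cohort generator

`simulate_cohort()` emulates the schema and marginal structure of a small
knee-replacement cohort: truncated normals for age, BMI and SF-12 scores, a
log-normal for the sit-to-stand time, zero-inflated counts for the
comorbidity index, CES-D and WOMAC subscales, and categorical draws for sex
and joint type. The SF-12 location parameters are calibrated so the
below-50 prevalence equals the target group proportions (e.g. 32/44 for the
2-year PCS, 27/44 preoperatively); shapes and tails are cosmetic, because
only the binarized structure reaches the miner. All draws derive from one
root seed; identical config + seed gives an identical cohort.

**Planted rules** fix $P(\text{outcome state} \mid \text{antecedent states})$
and the baseline probability otherwise. Planting operates on the binarized
states and then maps back to a continuous value drawn from the matching
side of the outcome's marginal (e.g. a planted low PCS draws from the
truncated-below-50 component), so a planted rule survives discretization
*exactly* — a conditional probability of 1 yields confidence 1 in the mined
output, not approximately 1. Consequently planted outcomes must be
fixed-cutoff (or two-level categorical) variables; a median-split outcome
has no pre-specifiable state boundary. At most one rule may target a given
outcome variable — two would contradict each other. The default
configuration plants one deterministic comorbidity → low 2-year PCS rule
with baseline 22/34, which reproduces both the 10/44 comorbidity prevalence
and the 32/44 low-PCS prevalence in expectation.

What the generator does *not* emulate: longitudinal dropout, measurement
error, correlation among the antecedent variables (they are drawn
independently unless planted), or floor/ceiling artefacts of the real
instruments. Passing tests on synthetic cohorts therefore demonstrate that
the pipeline computes the right quantities and recovers known dependencies;
they say nothing about whether rules found in a particular real cohort
generalise.

## Parameter defaults

| Parameter | Default | Rationale |
|---|---|---|
| min confidence | 0.80 | conventional extraction gate for clinical rule screens |
| min lift | 1.1 | requires a ≥10% relative lift over the base rate |
| min support | 0 | rule tables in this literature include rules as rare as 6/44; a support floor is exposed as a knob but not imposed |
| max order | 2 | single and paired conditions; triples are out of scope |
| α | 0.05 | two-sided |
| cohort size (generator) | 44 | the cohort size the screen is designed around |

Antecedents may include postoperative conditions (e.g. the 1-year PCS state
when screening the 2-year outcome); `excluded_variables` restricts a
sensitivity analysis to preoperative-only conditions.

## Degenerate inputs and edge policies

* A consequent with prior 0 or 1 cannot be mined ("degenerate consequent");
  in the multi-consequent analysis it is reported as such rather than
  aborting the run. An *empty* rule table, by contrast, is a valid outcome
  and is written with its header.
* An antecedent that never holds ($a+b=0$) yields no rule; confidence would
  be 0/0.
* A 2×2 table with an empty row margin cannot be tested ("degenerate
  margin").
* A single-valued variable cannot be median-split.
* Printed percentages and lift are rounded **half-up** to two decimals
  (1.1875 → 1.19); base R's round-half-to-even would disagree on exact
  ties. Unrounded values are retained in every returned object; rounding is
  a display policy.

## Problem sizes used in validation

The oracle-equivalence property runs 200 random matrices of up to 50
participants × 10 variables against an independent per-participant
enumerator; parameter recovery uses one simulated cohort of 2,000
participants (binomial standard error on confidence ≈ 0.007 at an
antecedent prevalence near 0.5); the type-I-error check runs 2,000
independent 44-participant null tables through Fisher's exact test, whose
conservatism keeps the empirical rejection rate below the nominal 5% (the
suite asserts ≤ 7%). A regression band tracks the number of chance rules on
null cohorts: a 44-participant cohort with 16 independent variables admits
on the order of a hundred gate-passing rules out of ~430 candidates — a
vivid reminder that at this sample size the gates are a sieve, not an
inference, and the contingency-table test (and ideally replication) must do
the inferential work.

## Known limitations

* Exhaustive enumeration is quadratic in the number of items; it is
  instantaneous at clinical-cohort scale but not intended for
  transaction-database scale.
* The screen treats each consequent separately; no joint modelling of the
  four outcomes.
* Exact unconditional tests (Barnard/Boschloo) and regression re-analysis
  are out of scope.
* Scoring of the instruments themselves (SF-12, WOMAC, CES-D, CCI) from
  item-level responses is out of scope; the package consumes already-scored
  values.
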