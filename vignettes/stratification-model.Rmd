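---
title: "The respiratory outpatient stratification model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The respiratory outpatient stratification model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respstrat)
```

## The model

The Capacity pillar of the CMO pharmaceutical-care framework stratifies
hospital respiratory outpatients by an additive weighted checklist. Each
patient is described by 22 consensus variables in five groups —
demographic (3), clinical (5), treatment-related (8), socio-sanitary (5)
and healthcare-resource use (1) — and their total score is

$$S \;=\; \sum_{v} w_v\, x_v, \qquad x_v \in \{0, 1\},$$

with expert-consensus weights $w_v$ (the weights are not fitted from data,
and the package deliberately provides no re-estimation). The three BMI
categories (obesity 3, malnutrition 1, malnutrition with cystic fibrosis 3)
form an *exclusion set*: they measure one quantity, so at most one — the
heaviest triggered one — contributes. Group-wise maxima under the default
table are 5 / 14 / 20 / 16 / 3, total 58.

One arithmetic caveat is worth stating prominently: the prose accompanying
the consensus table gives the treatment-related group a sum of 21 points,
but the itemized weights (4+4+4+2+3+1+1+1) sum to 20. The itemized table is
taken as canonical throughout this package; we surface the discrepancy here
rather than silently adjusting any weight.

Two rules sit outside the additive score:

* **Routing.** Children aged 0–15, and under-18s followed in pediatric
  clinics, are excluded — a separate pediatric chronic-patient model covers
  them. Under-18s seen in *adult* clinics stay on the adult path.
* **Overrides.** Pregnant or postpartum patients, and the
  under-18-in-adult-clinic group, are assigned priority level 1 regardless
  of score. Overrides are classification directives, not score modifiers:
  the arithmetic total stays interpretable and bounded, and an override
  patient's score still enters cutoff calibration (a flag can exclude
  them; the original procedure does not say which was done). When both
  overrides apply, routing is decided first, so the pediatric-in-adult
  override is recorded; the classification outcome is identical either
  way.

## Flag derivation

Raw records carry demographics, diagnoses (8-disease catalog), treatment
and socio-sanitary booleans, utilisation counts and instrument responses.
Derivation rules:

* polypharmacy ⇔ more than 5 chronic drugs;
* healthcare use ⇔ ≥ 2 admissions and/or emergency visits for respiratory
  decompensation in 12 months;
* quality-of-life impairment ⇔ any EQ-5D-5L dimension at level ≥ 4.
  The source instrument speaks of "severe impairment in any dimension"
  without fixing a level; 4 (= severe problems) is the natural reading of
  the 5-level scale and is configurable via `derivation_policy()`;
* lack of adherence ⇔ OR over three sources: a direct non-adherence flag,
  a non-compliant Morisky-Green answer (any of the 4 items), or a TAI
  total below 50. The TAI threshold is likewise unstated at source; total
  = 50 is the standard TAI-10 criterion for good adherence and is
  configurable;
* the pregnancy flag covers pregnancy and the postpartum period; we adopt
  a 12-month postpartum convention at data capture (the input field is a
  single boolean);
* disease severity and the ISMP high-alert flag are *inputs*, not derived:
  their operational definitions live in supplementary material that is not
  reproducible as text.

**Missing inputs.** The default policy scores an underivable variable as
not-flagged (0 points) and records per-patient `completeness`; this
mirrors registry practice, where an absent record is not evidence of risk.
A `strict` policy aborts instead, for settings where silent zeros are
unacceptable. Nothing is ever imputed.

## Cutoff calibration

Following the Kaiser Permanente population pyramid, the top 10% of scores
form level 1 and the next 30% level 2. On a discrete score scale the
quantile is implemented as the smallest integer threshold whose upper tail
does not exceed the target:

$$c_1 = \min\{t : \Pr(S \ge t) \le f_1\}, \qquad
  c_2 = \min\{t : \Pr(S \ge t) \le f_1 + f_2\}.$$

Tie groups never split — patients with equal scores always land in the same
level — so realized shares can only undershoot the targets (the development
sample realized 10.7 / 32.5 / 56.8 against 10/30/60). Degenerate inputs are
well-defined: an all-tied cohort yields $c_1 = c_2 = \max(S)+1$ and an
empty level 1 and 2; a single patient lands in level 3.

Cutoff semantics are **inclusive minimum**: a score equal to the cutoff
enters the level. The published account gives cutoff values (final 21 and
32; an earlier pass used 20 and 31 before three variable weights were
revised) without stating ≥ versus >; with level 1 defined as highest
complexity, a lower bound is the natural reading, and we document it here
because it changes boundary patients. Only the final pair (32, 21) ships
as the default `cutoff_set`.

## Care plans and telemedicine

Interventions are *cumulative*: an entry's level is the least intensive
priority at which it activates, so plan(1) ⊇ plan(2) ⊇ plan(3). The
category structure — pharmacotherapeutic monitoring (7), patient training
and education (7), care coordination (6) — is fixed by the published
model; the individual labels and their level assignments are **not**: the
figure itemizing them is not reproducible as text, so the shipped catalog
carries editable placeholder entries that respect the category counts.
The same holds for monitoring frequencies (shipped placeholders: monthly /
quarterly / semi-annual). Both are plain YAML meant to be replaced by
local policy; tests assert only the published structure.

Telemedicine triage is skill-based: advanced digital skills → group A,
limited-but-adaptable → group B, none (or missing, which is noted) → not
eligible. The per-disease teleconsultation recommendations ship verbatim
as a lookup; that catalog intentionally covers diseases outside the
stratification model (tuberculosis, pulmonary embolism, silicosis) and
omits some model diseases — the two lists are kept decoupled.

## The synthetic generator

Real patient-level data are unavailable, so the package ships a generator
whose defaults *are* the development sample's published marginals: 22 flag
prevalences from the 197-adult descriptive table (polypharmacy 0.75,
non-respiratory comorbidity 0.71, complex medicines 0.69, …, malnutrition
0.02). No cross-correlations were published, so joint structure is a
modeling choice: a single-latent-factor threshold model (Gaussian-copula
style). Per patient, a severity factor $z \sim N(0,1)$ is shared across
flags and flag $v$ fires when $\sqrt{\rho}\,z + \sqrt{1-\rho}\,
\varepsilon_v$ exceeds the quantile preserving its marginal; one knob
$\rho \in [0,1)$ is the simplest structure that can fatten the score
distribution's upper tail the way comorbidity clustering does
(`var(S)` grows with $\rho$; a seeded test asserts this).

Two deliberate wrinkles:

* **BMI exclusivity vs. monotone association.** Obesity and malnutrition
  are mutually exclusive categories, so they cannot both associate
  positively with everything else. Malnutrition (prevalence 0.02) is drawn
  from an independent uniform with probability $p/(1 - p_{\text{obesity}})$
  and suppressed on obese records — its marginal stays exact and the
  category invariant holds, at the price of malnutrition being off-factor.
  The non-negative-association property is therefore asserted over the
  factor-loaded flags only.
* **Cystic fibrosis and low BMI.** The generator never assigns CF as a
  diagnosis to low-BMI records, so default cohorts contain plain
  malnutrition only (exact marginal); CF-malnutrition is exercised by
  hand-built records in the unit tests.

Continuous fields are filled consistently with their flags (age 65–90 vs
18–64; BMI by category; drug count 6–12 vs 0–5; admissions 2–6 vs 0–1;
instruments agree with the adherence and QoL flags) — documented as
convenience values, not epidemiology. Requested edge cases
(pediatric-clinic, pediatric-in-adult-clinic, pregnant records) overwrite
the leading rows exactly. Identical spec + seed reproduces the cohort
byte-for-byte, and generation never perturbs the caller's RNG stream.

**What passing tests do and do not show.** The generator reproduces
marginals, a tunable positive dependence, and the edge-case mechanics. It
does not reproduce the real cohort's joint distribution, its score
distribution, or its calibrated cutoffs — the published 21/64/112 level
split is not recoverable from marginals and is not a test target.

## The reconstructed development cohort

`pilot_cohort()` is a deterministic 201-record fixture: 4 pediatric-clinic
records plus 197 adults in the published priority groups (21/64/112), with
every published per-group flag count matched exactly, 3
under-18-in-adult-clinic overrides and 0 pregnant records. Within a group,
flags use a fixed fill order (the first $k$ records), since no
cross-tabulations were published — so the fixture's joint structure, and
hence its level split under the default cutoffs, is an artifact. Two
published row totals are internally inconsistent with their per-group
counts (non-respiratory comorbidity 139 vs 20+59+62 = 141; QoL 96 vs
16+49+32 = 97); the per-group counts are taken as canonical. The published
P1 age bands (9 aged 18–64, 12 aged ≥ 65) also leave no room for the three
under-18 overrides that sit in P1; the reconstruction preserves the scored
marginal (12 aged ≥ 65) and the override count, leaving 6 records aged
18–64.

## Numerical and design choices

* Scores, weights and cutoffs are integers end to end; no floating-point
  comparisons enter classification.
* Exclusion-set ties (equal triggered weights) resolve to the first entry
  in table order; with the default table this is immaterial (CF-specific
  malnutrition at 3 points supersedes generic malnutrition at 1).
* The weight table is config-first: the shipped YAML is the final
  consensus version, and users can express any variant (including the
  unpublished preliminary weighting) without code changes; loaders enforce
  the structural invariants.
* Problem sizes in the test suite are chosen for exhaustiveness where the
  space is small (all $2^{10}$ flag patterns against a dot-product oracle,
  all $5^5$ EQ-5D-5L vectors, all 16 Morisky patterns) and for stable
  binomial error otherwise (10,000-record prevalence recovery within 4
  standard errors; 4,000-record association and variance checks).

## Known limitations

* The tool's external validity is inherited from its source: weights are
  expert consensus on a Spanish hospital-outpatient population, not fitted
  or validated coefficients.
* Intervention labels, level assignments and monitoring frequencies are
  placeholders beyond the published category counts.
* Severity and high-alert definitions are input flags; sites must supply
  their own operationalization.
* The Motivation pillar (motivational interviewing) is qualitative and out
  of scope; only the Capacity pillar plus the Opportunity pillar's triage
  and lookup rules are implemented.
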