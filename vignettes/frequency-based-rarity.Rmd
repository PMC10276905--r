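---
title: "Frequency-based rare diagnoses: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-based rare diagnoses: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raredx)
```

## The procedure and its assumptions

`raredx` identifies inpatients with *frequency-based rare diagnoses*
(FB-RDx) entirely from within one dataset. The premise: when a diagnosis
code is carried by very few patients in a complete, population-scale
inpatient dataset, the underlying condition is plausibly rare — without
requiring any external rare-disease catalog. The unit of analysis is the
patient, represented by **one randomly selected stay**; selecting a single
stay prevents patients with repeated admissions from inflating (or, through
evolving coding over repeat stays, deflating) the frequency of their codes.

The assumptions worth being explicit about:

* **Completeness.** Frequencies are meaningful as rarity measures only if
  the dataset approximates the full population of stays (a national or
  near-national cohort). In a single clinic, a locally uncommon code is not
  evidence of a rare disease.
* **Coding homogeneity.** All stays must be coded in one ICD-10 dialect;
  codes are normalized (uppercase, dot stripped, clipped to 4 characters)
  before any counting, so `"E10.9"` and `"E109"` are the same code.
* **Rarest-code summarization.** A patient's rarity is the frequency of
  their *least frequent* code. One unusual code among many common ones makes
  a patient "rare"; the sensitivity variant excluding ICD-10 chapters
  XVIII–XXII exists precisely because rarely-coded symptoms, injuries and
  administrative codes are not rare *diseases*.

## The decile rule and its tie behavior

Patients are grouped by `decile(k) = ceiling(10 * F(k))` clamped to 1..10,
where `F(k)` is the proportion of patients with rarity key ≤ `k`. Keys are
small integers with enormous tie blocks (thousands of patients share key 1),
and the rule never splits a tie block: every patient with the same key gets
the same decile, so group sizes are only approximately N/10. Two
consequences a user should expect:

* If one key dominates (degenerately, all patients share one key), the whole
  block lands in the *highest* decile consistent with its cumulative
  fraction — everyone in one block means decile 10.
* In **small cohorts** the singleton block (key = 1) can itself exceed 10%
  of patients; its cumulative fraction then pushes it past decile 1, which
  comes out *empty*, and no patient is FB-RDx-flagged at the 10% cutoff.
  This is faithful behavior, not a bug: the decile definition presupposes a
  large cohort (hundreds of thousands of patients; package tests use
  20,000–50,000, where decile 1 is well populated). `classify_rarity()`
  exposes `n_quantiles` and `cutoff` for coarser groupings where cohorts are
  small.

The rarest code reported per patient breaks count ties lexicographically —
an arbitrary but deterministic choice that cannot affect the decile, since
tied codes share the count.

## Tunable parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `n_quantiles` / `cutoff` | 10 / 1 | primary definition: lowest decile; cutoffs 2–3 give the 20%/30% sensitivity variants |
| `exclude_chapters` | none | sensitivity variant dropping chapters XVIII–XXII (R, S–T, V–Y, Z, U ranges) before scoring; patients losing all codes are reported unclassifiable and dropped from that variant |
| `freq_basis` | `"patients"` | whether code frequencies count the one-stay-per-patient cohort or all stays; the methodology motivates single-stay counting, but the alternative is exposed because either is defensible |
| `n_knots` (age spline) | 5 | knots at the conventional quantiles (0.05, 0.275, 0.50, 0.725, 0.95); 5 knots give 4 age terms, flexible without overfitting |
| `age_form` | `"rcs"` | `"groups"` (18–34, 35–49, 50–64, 65–79, 80+) is the interpretable cross-check; a robustness test asserts both give the exposure OR within ±10% on synthetic data |
| trend `weighting` | unweighted | the dose–response line is OLS through the decile 1–9 point estimates; inverse-variance weighting available (`"inv_var"`) since the convention is not fixed |

## What the synthetic generator emulates — and what it does not

`generate_cohort()` is a first-class, tested module, because the intended
real data (national discharge registries) are access-restricted. Its
defaults state a world calibrated once, before any test was written, to the
published marginals of a national one-year adult inpatient cohort:

* **Code frequencies**: Zipf law with exponent 1.5 over 2,000 codes — a long
  tail with many near-singleton codes, which is what makes a bottom decile
  meaningful.
* **Stays**: 25% of patients have >1 stay (2 + geometric(0.61), ≈1.4 stays
  per patient overall); diagnoses per stay `1 + NB(size 2, mu 6)`, capped at
  50, reproducing median 6, IQR [3, 9] exactly.
* **Outcomes**: baseline risks death 2.0%, 30-day readmission 3.9%, ICU
  admission 5.2%; LOS log-normal (median 4 days, IQR ≈ [3, 7]); ICU hours
  log-normal (median 25 h). Deceased stays never carry a readmission; ICU
  hours are positive exactly for ICU stays — so the model exclusion rules
  are genuinely exercised.
* **Ground truth**: a stay is latently *rare* when its rarest code by
  generating-weight rank is in the bottom ~10% of stays. The flag is defined
  from the generating weights, not observed counts, so it is independent of
  the classifier under test. True effects default to odds ratio 1.5 per
  binary outcome and ×1.05 on LOS; covariate effects (age, sex, emergency
  admission) are small fixed log-odds, centered at the cohort mean so the
  baseline risks stay marginal.
* **Catalog**: codes enter a synthetic rare-disease catalog with probability
  increasing in rarity rank (`target_fraction = 0.15`,
  `rarity_bias = 0.75`), chosen once so that overall catalog prevalence
  (~7%) and its concentration in decile 1 (~20–30% vs 0% in decile 10) match
  the published pattern qualitatively.

Deliberately **not** emulated: comorbidity correlation between codes,
ICD-10-GM semantics, seasonal/longitudinal structure, hospital-level
clustering, and code-validity checking. A green test therefore establishes
that the pipeline's arithmetic, classification rules and estimators behave
as specified under a realistic marginal structure — not that the method's
epidemiological conclusions transfer to any particular real registry.

## Numerical and statistical choices

* **Wald intervals** throughout: `exp(coef ± 1.96·SE)`, matching the Woolf
  construction used for 2×2 tables; profile-likelihood intervals are not
  used. The covariate-free logistic fit reproduces the 2×2 cross-product OR
  to 10⁻⁶ relative tolerance (tested).
* **Restricted cubic spline**: truncated-power natural-spline basis,
  normalized by `(t_k − t_1)²`, linear beyond the boundary knots (second
  differences < 10⁻⁸, tested against an independent scalar evaluation).
* **Number-of-diagnoses covariate** excludes the codes defining the
  exposure (decile-group codes for FB-RDx models, catalog codes for RD
  models) and is binned 0 (reference), 1, …, 10, 11–12, 13–15, ≥16. The
  near-empty "0" reference bin can be quasi-separated at simulation scale;
  such degenerate *nuisance* terms are recorded in
  `fit$degenerate_terms`, while the `separation` flag (with a warning) is
  reserved for the exposure term — real separation is never silent, and
  healthy runs are not drowned in warnings.
* **30-day readmission** is `0 < days_to_readmission ≤ 30` among survivors;
  a missing value means no recorded readmission. Its model adjusts for
  `log(LOS)` (the stated adjustment is "length of stay"; the log form is
  this package's choice, consistent with how LOS is modelled as an outcome).
* **Exclusions** are applied in a fixed order (deaths → rehabilitation
  clinics → non-ICU) and counted per rule so that
  `n_included + sum(excluded) = cohort size` reconciles exactly (tested for
  all five outcomes).
* **Rounding**: printed percentages round half *up* (half away from zero) to
  1 decimal, the convention of clinical baseline tables, not R's
  round-half-to-even. Baseline p-values use chi-square without continuity
  correction and Kruskal–Wallis (tie-corrected), conventional defaults.
* **Dose–response reference** is decile 10 (the patients whose rarest code
  is still common), so deciles 1–9 each get an estimate and the reference
  is 1 by construction.

## Known limitations

* The adjusted decile-1 odds ratio is a mildly **attenuated** estimate of
  the generating odds ratio: observed decile-1 membership misclassifies
  latent rarity near the boundary (~85% concordance at 50,000 patients), so
  single-seed estimates center slightly below the true effect, while the
  fit on the latent flag itself recovers it without bias (both behaviors are
  pinned by tests). Attenuation shrinks as cohorts grow.
* Exact-match-after-truncation catalog matching: no prefix or range
  semantics, so a catalog listing 3-character categories will not match
  4-character subdivisions.
* Complete-case analysis only; no hospital-level clustering or mixed
  effects; no survival modelling of readmission times.
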