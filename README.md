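# raredx

Frequency-based rare diagnosis identification and outcome modelling for
ICD-10 coded inpatient administrative data.

## The problem

Most rare diseases have no ICD-10 code of their own, so patients with rare
conditions cannot be enumerated in large hospital datasets by matching a
catalog: code-list approaches (e.g. ORPHAcode-to-ICD-10 mappings) cover only
a fraction of known rare diseases. `raredx` implements the complementary,
catalog-free idea of *frequency-based rare diagnoses* (FB-RDx): use the
dataset's own code frequencies to find the patients whose diagnoses are
unusual *in that dataset*, and study their outcomes. It is aimed at
epidemiologists and health-services researchers working with stay-level
discharge data (one row per hospital stay, up to 50 ICD-10 codes per stay).

## The method

1. **Cohort**: keep adult stays (age ≥ 18), select **one stay per patient
   uniformly at random** (repeated stays would over- or under-represent a
   patient's codes), truncate codes to their 4-character form
   (`"E10.9" → "E109"`) and de-duplicate within the stay.
2. **Rarity**: for each code *c*, let *n(c)* be the number of patients whose
   selected stay carries it. Each patient's **rarity key** is
   *k = min n(c)* over their codes — the frequency of their least frequent
   diagnosis. Patients are grouped into deciles of *k* with the
   tie-preserving rule

   *decile(k) = ⌈10 · F(k)⌉*,  *F(k)* = fraction of patients with key ≤ *k*,

   so patients sharing a key always share a decile. **Decile 1** (the ~10%
   of patients with the rarest diagnoses) is the FB-RDx group; 20% and 30%
   cutoffs are sensitivity variants, as is recomputing keys after excluding
   non-disease ICD-10 chapters XVIII–XXII (R, S–T, V–Y, Z, U codes).
3. **Comparison**: patients are independently flagged by membership of any
   diagnosis in an ICD-10 rare-disease catalog (`has_rd`).
4. **Outcomes**: logistic regression (odds ratios, Wald 95% CIs
   `exp(β ± 1.96·SE)`) for in-hospital death, 30-day readmission and ICU
   admission; linear regression on log length-of-stay and log ICU hours
   (reported as multiplicative effects, Exp(B)). All models adjust for sex,
   Swiss citizenship, admission from home, age as a 5-knot **restricted
   cubic spline**, the binned number of *non-rare* diagnoses, admission
   type, insurance class and hospital category; the readmission model also
   adjusts for (log) LOS. LOS/ICU-LOS/readmission models exclude in-hospital
   deaths; ICU/LOS/ICU-LOS/readmission models exclude rehabilitation
   clinics. A decile dose–response analysis fits the full decile factor
   (reference: decile 10) with a linear trend through the per-decile
   estimates, and 2×2 splits get the classical cross-product OR with the
   Woolf CI `exp(ln OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`.

Because the national registry data this methodology targets are
access-restricted, the package ships a seeded **synthetic cohort generator**
(Zipf-distributed code frequencies, ~25% multi-stay patients, median 6
diagnoses per stay, realistic outcome prevalences) with known ground-truth
effect sizes, so the whole pipeline is testable offline.

## Worked example

```r
library(raredx)

cfg      <- simulation_config(n_patients = 50000, seed = 1)   # true OR 1.5
cohort   <- generate_cohort(cfg)
patients <- build_patient_table(cohort$stays, seed = 2)
rarity   <- classify_rarity(patients)
catalog  <- generate_rd_catalog(cohort$universe, seed = 3)
tab      <- analysis_table(patients, rarity, match_patients(patients, catalog))

fits_fb <- fit_all_outcomes(tab, "fb_rdx", rarity = rarity)
fits_rd <- fit_all_outcomes(tab, "has_rd", rarity = rarity, catalog = catalog)
comparison_table(fits_fb, fits_rd)
```

One run of the equivalent pipeline (`Rscript scripts/acceptance.R --seed 1`)
printed:

```
        outcome  scale           fb_rdx               rd
1         death     OR 1.22 (1.01,1.49) 1.07 (0.84,1.34)
2     readmit30     OR 1.52 (1.32,1.74) 1.42 (1.21,1.66)
3 icu_admission     OR 1.49 (1.32,1.68) 1.14 (0.99,1.32)
4       log_los Exp(B) 1.05 (1.03,1.07) 1.00 (0.97,1.02)
5   log_icu_los Exp(B) 1.08 (0.98,1.19) 0.97 (0.87,1.10)
dose-response trend slope (death): -0.021 per decile
```

Reading: patients in the rarest decile (`fb_rdx`) had 1.22 times the
adjusted odds of dying in hospital relative to deciles 2–10 (the generating
odds ratio in this synthetic world is 1.5; single-seed estimates scatter
around it, attenuated slightly because observed decile-1 membership is a
noisy proxy of latent rarity). `Exp(B) 1.05` for LOS means a 5% longer stay.
The catalog flag (`rd` column) shows the same direction of association, and
the negative dose–response slope means the odds of death fall as the
rarity decile increases (diagnoses become more common).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch at the given seed — simulation,
cohort construction, decile classification, catalog matching, all ten
adjusted models, the dose–response trend and the stratified baseline table —
printing the comparison table above and writing the (empty) machine-readable
result object to `--out`.

A thin command-line wrapper over the same functions is provided in
`inst/cli/raredx.R` (subcommands `simulate`, `build-cohort`, `classify`,
`match-catalog`, `fit`).
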