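# Shared fixtures, built in code at test time.

# Minimal hand-written stay table; diagnosis codes deliberately mix dotted /
# lowercase dialects and duplicates.
make_stays <- function() {
  df <- data.frame(
    patient_id = c("p1", "p2", "p2", "p3", "p4"),
    stay_id = c("s1", "s2", "s3", "s4", "s5"),
    age = c(45L, 70L, 71L, 17L, 30L),
    sex = c("F", "M", "M", "F", "F"),
    citizen = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    admitted_from_home = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    admission_type = c("emergency", "planned", "emergency", "planned", "other"),
    insurance_class = c("mandatory", "private", "mandatory", "mandatory",
                        "semiprivate"),
    hospital_category = c("tier1_university", "tier2_center", "tier2_center",
                          "tier3_general", "rehabilitation_clinic"),
    died = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    los_days = c(3, 10, 21, 2, 5),
    icu = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    icu_hours = c(0, 48, 0, 0, 0),
    days_to_readmission = c(12L, NA, NA, 40L, NA),
    stringsAsFactors = FALSE
  )
  df$diagnosis_codes <- list(
    c("E10.9", "e109", "I10"),   # duplicates after truncation
    c("M5499", "I10"),
    c("I10"),
    c("A00"),                    # minor, filtered out
    c("Z038", "R001")
  )
  df
}

# Build a patient-level table directly from per-patient code sets (already
# truncated), with neutral covariates; for classifier and model unit tests.
make_patients <- function(code_sets, died = NULL, ...) {
  n <- length(code_sets)
  extra <- list(...)
  df <- data.frame(
    patient_id = sprintf("p%04d", seq_len(n)),
    stay_id = sprintf("s%04d", seq_len(n)),
    age = rep(50L, n),
    sex = rep(c("F", "M"), length.out = n),
    citizen = TRUE,
    admitted_from_home = TRUE,
    admission_type = "emergency",
    insurance_class = "mandatory",
    hospital_category = "tier2_center",
    died = died %||% rep(FALSE, n),
    los_days = rep(4, n),
    icu = rep(FALSE, n),
    icu_hours = rep(0, n),
    days_to_readmission = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df$diagnosis_codes <- code_sets
  df$n_diagnoses <- lengths(code_sets)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force decile oracle: per patient, the cumulative fraction of
# patients with key <= own key, mapped through ceil(nq * F), independently
# of the package's tabulate/cumsum path.
oracle_deciles <- function(keys, nq = 10) {
  n <- length(keys)
  vapply(keys, function(k) {
    f <- sum(keys <= k) / n
    as.integer(min(max(ceiling(nq * f), 1), nq))
  }, integer(1))
}

# One moderate synthetic world with clear shared signal, reused by several
# tests (built on first use, ~15 s).
std_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_patients = 20000,
                               rarity_or = c(death = 2, readmit = 2, icu = 2),
                               rarity_los_multiplier = 1.3,
                               seed = 777)
      co <- generate_cohort(cfg)
      pt <- build_patient_table(co$stays, seed = 778)
      rar <- classify_rarity(pt)
      catg <- generate_rd_catalog(co$universe, seed = 779)
      at <- analysis_table(pt, rar, match_patients(pt, catg))
      cache <<- list(cfg = cfg, cohort = co, patients = at, rarity = rar,
                     catalog = catg)
    }
    cache
  }
})
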