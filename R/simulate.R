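# Weighted sampling without replacement for many small draws at once.
# Taking the first k distinct values of a with-replacement stream is
# distributionally identical to successive (Yates) weighted sampling without
# replacement, so with-replacement draws are batched through findInterval on
# the cumulative weights; stays left short by the oversampled batch (rare)
# fall back to a correct continuation via sample.int().
sample_codes <- function(n_dx, weights) {
  n <- length(weights)
  cumw <- cumsum(weights) / sum(weights)
  cand_n <- pmin(6L * n_dx + 24L, 40L * n)
  draws <- findInterval(stats::runif(sum(cand_n)), cumw) + 1L
  by_stay <- split(draws, rep.int(seq_along(n_dx), cand_n))
  mapply(function(d, k) {
    u <- unique.default(d)
    if (length(u) >= k) return(u[seq_len(k)])
    w2 <- weights
    w2[u] <- 0
    c(u, sample.int(n, k - length(u), prob = w2))
  }, by_stay, n_dx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# Synthetic inpatient cohort generator.
#
# Emulates the statistical structure of a national one-year adult inpatient
# dataset: a long-tailed (Zipf) diagnosis-code frequency distribution, ~25%
# of patients with multiple stays (averaging ~1.41 stays per patient
# overall), a median of 6 diagnoses per stay (IQR 3-9), and configurable
# multiplicative effects of latent diagnosis rarity on five outcomes.
# Ground truth (which stays are latently "rare") is defined from the
# generating weights, not from observed frequencies, so it is independent
# of the frequency-based classifier under test.

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults reproduce the published
#' marginals of the reference cohort where one is stated (outcome
#' prevalences, diagnoses per stay, share of multi-stay patients, LOS and
#' ICU-LOS medians/IQRs, % female); effect sizes (`rarity_or`,
#' `rarity_los_multiplier`) are free ground-truth parameters.
#'
#' @param n_patients number of patients.
#' @param n_codes number of distinct diagnosis codes in the universe (>= 20).
#' @param zipf_exponent Zipf exponent of the code frequency law (> 0).
#' @param p_multi_stay probability a patient has more than one stay.
#' @param diag_nb_size,diag_nb_mu negative-binomial parameters; diagnoses
#'   per stay = 1 + NB(size, mu), capped at 50. Defaults (2, 6) give
#'   median 6, IQR [3, 9].
#' @param age_range admission-age bounds in years (lower bound >= 18).
#' @param p_female probability of female sex.
#' @param baseline_risks named probabilities `death`, `readmit`, `icu` at the
#'   covariate mean for latently non-rare stays.
#' @param rarity_or named true odds ratios `death`, `readmit`, `icu` for the
#'   latent-rare indicator.
#' @param los_lognormal `c(mu, sigma)` of log length-of-stay (days).
#' @param icu_los_lognormal `c(mu, sigma)` of log ICU length-of-stay (hours).
#' @param rarity_los_multiplier true multiplicative effect of latent rarity
#'   on (ICU) length of stay.
#' @param covariate_effects named list of small fixed effects, applied
#'   centered at the cohort mean so `baseline_risks` stay (approximately)
#'   marginal: `age`, `female`, `emergency` on the log-odds of the binary
#'   outcomes; `los_age`, `los_emergency` on log-LOS.
#' @param seed integer RNG seed.
#' @return validated object of class `raredx_sim_config`.
#' @export
simulation_config <- function(n_patients,
                              n_codes = 2000,
                              zipf_exponent = 1.5,
                              p_multi_stay = 0.25,
                              diag_nb_size = 2,
                              diag_nb_mu = 6,
                              age_range = c(18, 100),
                              p_female = 0.56,
                              baseline_risks = c(death = 0.02, readmit = 0.039,
                                                 icu = 0.052),
                              rarity_or = c(death = 1.5, readmit = 1.5,
                                            icu = 1.5),
                              los_lognormal = c(mu = log(4), sigma = 0.63),
                              icu_los_lognormal = c(mu = log(25), sigma = 0.83),
                              rarity_los_multiplier = 1.05,
                              covariate_effects = list(age = 0.015,
                                                       female = -0.2,
                                                       emergency = 0.5,
                                                       los_age = 0.004,
                                                       los_emergency = 0.15),
                              seed = 1L) {
  stopifnot(n_patients >= 1)
  if (n_codes < 20) stop("n_codes must be >= 20", call. = FALSE)
  if (zipf_exponent <= 0) stop("zipf_exponent must be > 0", call. = FALSE)
  probs <- c(p_multi_stay = p_multi_stay, p_female = p_female, baseline_risks)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(rarity_or <= 0) || rarity_los_multiplier <= 0) {
    stop("rarity effects must be > 0", call. = FALSE)
  }
  if (age_range[1] < 18 || age_range[2] <= age_range[1]) {
    stop("age_range must be ascending with lower bound >= 18", call. = FALSE)
  }
  need <- c("death", "readmit", "icu")
  stopifnot(all(need %in% names(baseline_risks)), all(need %in% names(rarity_or)))
  structure(list(n_patients = as.integer(n_patients), n_codes = as.integer(n_codes),
                 zipf_exponent = zipf_exponent, p_multi_stay = p_multi_stay,
                 diag_nb_size = diag_nb_size, diag_nb_mu = diag_nb_mu,
                 age_range = age_range, p_female = p_female,
                 baseline_risks = baseline_risks, rarity_or = rarity_or,
                 los_lognormal = los_lognormal,
                 icu_los_lognormal = icu_los_lognormal,
                 rarity_los_multiplier = rarity_los_multiplier,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "raredx_sim_config")
}

#' Generate a Zipf-weighted ICD-10-like code universe
#'
#' Creates `n_codes` syntactically valid 4-character identifiers (letter +
#' three digits, unique) with sampling weight of the rank-r code
#' proportional to `r^-zipf_exponent`. The long tail yields many
#' near-singleton codes, which is what makes a bottom rarity decile
#' meaningful.
#'
#' @param n_codes number of codes (>= 20).
#' @param zipf_exponent Zipf exponent (> 0).
#' @param seed integer RNG seed.
#' @return object of class `raredx_universe`: data.frame with `code`,
#'   `rank` (1 = most common), `weight` (normalized), `chapter`.
#' @export
generate_code_universe <- function(n_codes, zipf_exponent = 1.5, seed = 1L) {
  if (n_codes < 20) stop("n_codes must be >= 20", call. = FALSE)
  if (n_codes > 26000) stop("at most 26,000 codes supported", call. = FALSE)
  codes <- with_seed(seed, {
    grid <- sample.int(26000L, n_codes)
    paste0(LETTERS[(grid - 1L) %/% 1000L + 1L],
           sprintf("%03d", (grid - 1L) %% 1000L))
  })
  w <- seq_len(n_codes)^(-zipf_exponent)
  structure(data.frame(code = codes,
                       rank = seq_len(n_codes),
                       weight = w / sum(w),
                       chapter = chapter_of(codes),
                       stringsAsFactors = FALSE),
            class = c("raredx_universe", "data.frame"))
}

#' Generate a synthetic stay-level cohort with known ground truth
#'
#' Each patient gets one or more hospital stays; each stay carries 1-50
#' distinct codes drawn (without replacement) from the Zipf-weighted
#' universe. A stay is latently *rare* when its rarest code - by generating
#' weight rank - falls in the bottom ~10% of stays; binary outcomes are then
#' drawn from logistic models `logit(baseline) + log(rarity_or) * rare +
#' centered covariate effects`, LOS and ICU-LOS from log-normal models with
#' the configured rarity multiplier. Deceased stays never carry a
#' readmission; ICU hours are positive exactly for ICU stays.
#'
#' @param config a `raredx_sim_config`.
#' @return object of class `raredx_cohort`: list with `stays` (observable
#'   stay table, see [build_patient_table()]), `latent` (per-stay ground
#'   truth: `rare_flag`, max weight rank, linear predictors - never part of
#'   the observable table) and `universe`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "raredx_sim_config"))
  universe <- generate_code_universe(config$n_codes, config$zipf_exponent,
                                     seed = config$seed)
  with_seed(config$seed + 1L, {
    np <- config$n_patients
    # patient-level attributes
    age <- pmin(pmax(round(stats::rnorm(np, 58, 20)),
                     config$age_range[1]), config$age_range[2])
    sex <- ifelse(stats::runif(np) < config$p_female, "F", "M")
    citizen <- stats::runif(np) < 0.785
    insurance <- sample(c("mandatory", "semiprivate", "private"), np,
                        replace = TRUE, prob = c(0.757, 0.150, 0.093))
    multi <- stats::runif(np) < config$p_multi_stay
    n_stays <- ifelse(multi, pmin(2L + stats::rgeom(np, 0.61), 12L), 1L)

    pidx <- rep.int(seq_len(np), n_stays)
    ns <- length(pidx)
    stay_seq <- sequence(n_stays)
    patient_id <- sprintf("P%07d", pidx)
    stay_id <- sprintf("%s-S%02d", patient_id, stay_seq)

    # stay-level admission context (published marginals)
    admitted_from_home <- stats::runif(ns) < 0.904
    admission_type <- sample(c("emergency", "planned", "other"), ns,
                             replace = TRUE, prob = c(0.445, 0.537, 0.018))
    hospital_category <- sample(c("tier1_university", "tier2_center",
                                  "tier3_general", "tier4_general",
                                  "tier5_general", "other_specialty",
                                  "rehabilitation_clinic", "surgical_clinic"),
                                ns, replace = TRUE,
                                prob = c(0.145, 0.533, 0.086, 0.100,
                                         0.013, 0.017, 0.033, 0.072))

    # diagnosis codes per stay: 1 + NB, capped at 50 and at the universe size
    n_dx <- pmin(1L + stats::rnbinom(ns, size = config$diag_nb_size,
                                     mu = config$diag_nb_mu),
                 50L, config$n_codes)
    code_idx <- sample_codes(n_dx, universe$weight)
    diagnosis_codes <- lapply(code_idx, function(i) universe$code[i])
    max_rank <- vapply(code_idx, max, integer(1))

    # latent rarity: bottom ~10% of stays by rarest generating-weight rank
    r_star <- stats::quantile(max_rank, 0.9, type = 1, names = FALSE)
    rare <- max_rank >= r_star

    eff <- config$covariate_effects
    age_s <- rep.int(age, n_stays)
    female_s <- rep.int(sex == "F", n_stays)
    emergency_s <- admission_type == "emergency"
    lin <- eff$age * (age_s - mean(age_s)) +
      eff$female * (female_s - mean(female_s)) +
      eff$emergency * (emergency_s - mean(emergency_s))

    lp_death <- stats::qlogis(config$baseline_risks[["death"]]) +
      log(config$rarity_or[["death"]]) * rare + lin
    lp_icu <- stats::qlogis(config$baseline_risks[["icu"]]) +
      log(config$rarity_or[["icu"]]) * rare + lin
    lp_readmit <- stats::qlogis(config$baseline_risks[["readmit"]]) +
      log(config$rarity_or[["readmit"]]) * rare + lin

    died <- stats::runif(ns) < stats::plogis(lp_death)
    icu <- stats::runif(ns) < stats::plogis(lp_icu)

    lin_los <- eff$los_age * (age_s - mean(age_s)) +
      eff$los_emergency * (emergency_s - mean(emergency_s))
    los_days <- pmax(1, round(exp(stats::rnorm(
      ns,
      config$los_lognormal[["mu"]] +
        log(config$rarity_los_multiplier) * rare + lin_los,
      config$los_lognormal[["sigma"]]))))
    icu_hours <- ifelse(icu, pmax(1, round(exp(stats::rnorm(
      ns,
      config$icu_los_lognormal[["mu"]] +
        log(config$rarity_los_multiplier) * rare + lin_los,
      config$icu_los_lognormal[["sigma"]])))), 0)

    readmitted <- !died & stats::runif(ns) < stats::plogis(lp_readmit)
    late <- !died & !readmitted & stats::runif(ns) < 0.15
    days_to_readmission <- rep(NA_integer_, ns)
    days_to_readmission[readmitted] <- sample(1:30, sum(readmitted), replace = TRUE)
    days_to_readmission[late] <- sample(31:365, sum(late), replace = TRUE)

    stays <- data.frame(patient_id = patient_id, stay_id = stay_id,
                        age = age_s,
                        sex = rep.int(sex, n_stays),
                        citizen = rep.int(citizen, n_stays),
                        admitted_from_home = admitted_from_home,
                        admission_type = admission_type,
                        insurance_class = rep.int(insurance, n_stays),
                        hospital_category = hospital_category,
                        died = died, los_days = los_days, icu = icu,
                        icu_hours = icu_hours,
                        days_to_readmission = days_to_readmission,
                        stringsAsFactors = FALSE)
    stays$diagnosis_codes <- diagnosis_codes

    latent <- data.frame(patient_id = patient_id, stay_id = stay_id,
                         rare_flag = rare, max_weight_rank = max_rank,
                         lp_death = lp_death, lp_readmit = lp_readmit,
                         lp_icu = lp_icu, stringsAsFactors = FALSE)

    structure(list(stays = stays, latent = latent, universe = universe,
                   config = config),
              class = "raredx_cohort")
  })
}

#' @export
print.raredx_cohort <- function(x, ...) {
  cat("Synthetic inpatient cohort:", x$config$n_patients, "patients,",
      nrow(x$stays), "stays,", x$config$n_codes, "codes\n")
  cat(sprintf("  latent rare stays: %.1f%%  true OR (death): %.2f\n",
              100 * mean(x$latent$rare_flag), x$config$rarity_or[["death"]]))
  invisible(x)
}

#' Generate a rarity-biased synthetic RD catalog
#'
#' Selects codes from the universe with inclusion probability increasing in
#' the code's rarity rank - `p_r` proportional to `(r/n)^rarity_bias`,
#' scaled so the expected number of selected codes is `target_fraction * n`.
#' With `rarity_bias = 0` inclusion is uniform; larger values concentrate
#' the catalog in the rare tail, so catalog-flagged patients pile up in the
#' low rarity deciles, qualitatively matching catalog-vs-decile gradients
#' observed in real data.
#'
#' @param universe a `raredx_universe`.
#' @param target_fraction expected fraction of codes selected, in (0, 1).
#' @param rarity_bias nonnegative exponent of the rank bias.
#' @param seed integer RNG seed.
#' @param name catalog label.
#' @return a `raredx_catalog`.
#' @export
generate_rd_catalog <- function(universe, target_fraction = 0.15,
                                rarity_bias = 0.75, seed = 1L,
                                name = "synthetic_rd") {
  stopifnot(inherits(universe, "raredx_universe"))
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop("target_fraction must be in (0, 1)", call. = FALSE)
  }
  if (rarity_bias < 0) stop("rarity_bias must be >= 0", call. = FALSE)
  n <- nrow(universe)
  raw <- (universe$rank / n)^rarity_bias
  p <- pmin(1, target_fraction * n * raw / sum(raw))
  selected <- with_seed(seed, stats::runif(n) < p)
  if (!any(selected)) {
    stop("no codes selected; increase target_fraction", call. = FALSE)
  }
  rd_catalog(universe$code[selected], name = name)
}
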