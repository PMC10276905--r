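# Outcome models: adjusted and unadjusted associations of the FB-RDx flag,
# the catalog RD flag, or the full decile factor with five inpatient
# outcomes. Binary outcomes (in-hospital death, 30-day readmission, ICU
# admission) use logistic regression reported as odds ratios; length of stay
# and ICU length of stay are log-transformed and fitted by linear regression
# reported as Exp(B), a multiplicative effect. All confidence intervals are
# Wald: exp(coef +/- 1.96 * SE).

.outcomes <- c("death", "readmit30", "icu_admission", "log_los", "log_icu_los")
.predictors <- c("fb_rdx", "has_rd", "decile_factor")

# Harrell's default knot placement quantiles by knot count.
.rcs_quantiles <- list(
  `3` = c(0.10, 0.50, 0.90),
  `4` = c(0.05, 0.35, 0.65, 0.95),
  `5` = c(0.05, 0.275, 0.50, 0.725, 0.95),
  `6` = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
  `7` = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975)
)

#' Default knot locations for a restricted cubic spline
#'
#' Knots at the conventional quantiles of the observed values (for 5 knots:
#' 0.05, 0.275, 0.50, 0.725, 0.95).
#'
#' @param x numeric vector.
#' @param n_knots number of knots, 3 to 7.
#' @return numeric vector of strictly increasing knots.
#' @export
rcs_knots <- function(x, n_knots = 5) {
  qs <- .rcs_quantiles[[as.character(n_knots)]]
  if (is.null(qs)) stop("n_knots must be between 3 and 7", call. = FALSE)
  knots <- unique(stats::quantile(x, qs, na.rm = TRUE, names = FALSE, type = 7))
  if (length(knots) < 3) {
    stop("too few distinct values to place ", n_knots, " spline knots", call. = FALSE)
  }
  knots
}

#' Restricted cubic spline basis
#'
#' Truncated-power natural spline basis: the first column is x itself; for
#' knots t_1 < ... < t_k, column j+1 (j = 1..k-2) is
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'        + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2,}
#' which is continuous with continuous second derivative and exactly linear
#' beyond the boundary knots. Used for flexible age adjustment: non-linear
#' confounding is absorbed without committing to arbitrary age groups.
#'
#' @param x numeric vector.
#' @param knots strictly increasing numeric vector of at least 3 knots.
#' @return numeric matrix with `length(knots) - 1` columns named
#'   `x`, `x_s1`, `x_s2`, ...
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) < 3 || is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be at least 3 strictly increasing values", call. = FALSE)
  }
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (tk - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, nrow = length(x), ncol = k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pos3(x - tj) -
                       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("x", paste0("x_s", seq_len(k - 2)))
  out
}

#' Bin the number of non-rare diagnoses
#'
#' The adjustment variable "number of diagnoses" excludes the diagnoses that
#' define the exposure (codes in the rare decile group for FB-RDx models,
#' catalog codes for RD models), so the predictor is not adjusted away by its
#' own code count. Counts are binned with single-count bins up to 10, then
#' 11-12, 13-15 and >=16; reference is 0.
#'
#' @param patients patient-level table with `diagnosis_codes`.
#' @param rare_code_set character vector of codes excluded from the count.
#' @return factor with levels 0, 1, ..., 10, 11-12, 13-15, >=16.
#' @export
n_diagnoses_covariate <- function(patients, rare_code_set = character(0)) {
  count <- vapply(patients$diagnosis_codes,
                  function(codes) sum(!(codes %in% rare_code_set)), integer(1))
  lev <- c(as.character(0:10), "11-12", "13-15", ">=16")
  lab <- ifelse(count <= 10, as.character(count),
                ifelse(count <= 12, "11-12",
                       ifelse(count <= 15, "13-15", ">=16")))
  factor(lab, levels = lev)
}

#' Outcome-specific exclusion rules
#'
#' Mirrors the analysis plan: the in-hospital death model uses the full
#' cohort; length-of-stay, ICU length-of-stay and 30-day readmission models
#' exclude in-hospital deaths; ICU admission, LOS, ICU-LOS and readmission
#' models exclude rehabilitation clinics; the ICU-LOS model is further
#' restricted to patients admitted to an ICU. Rules are applied in that
#' order and counted sequentially, so `nrow(included) + sum(excluded_counts)`
#' equals the input row count.
#'
#' @param patients patient-level analysis table.
#' @param outcome one of `"death"`, `"readmit30"`, `"icu_admission"`,
#'   `"log_los"`, `"log_icu_los"`.
#' @return list with `included` (data.frame) and `excluded_counts`
#'   (named integer vector).
#' @export
apply_exclusions <- function(patients, outcome) {
  outcome <- match.arg(outcome, .outcomes)
  df <- patients
  counts <- integer(0)
  if (outcome %in% c("readmit30", "log_los", "log_icu_los")) {
    keep <- !df$died
    counts <- c(counts, died = sum(!keep))
    df <- df[keep, , drop = FALSE]
  }
  if (outcome %in% c("icu_admission", "readmit30", "log_los", "log_icu_los")) {
    keep <- df$hospital_category != "rehabilitation_clinic"
    counts <- c(counts, rehabilitation_clinic = sum(!keep))
    df <- df[keep, , drop = FALSE]
  }
  if (outcome == "log_icu_los") {
    keep <- df$icu
    counts <- c(counts, not_in_icu = sum(!keep))
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  list(included = df, excluded_counts = counts)
}

#' Specify an outcome model
#'
#' @param outcome one of `"death"`, `"readmit30"`, `"icu_admission"`,
#'   `"log_los"`, `"log_icu_los"`.
#' @param predictor `"fb_rdx"` (first-decile flag), `"has_rd"` (catalog flag)
#'   or `"decile_factor"` (all deciles, reference = decile 10).
#' @param adjusted include the covariate set (sex, Swiss citizenship,
#'   admission from home, restricted-cubic-spline age, binned number of
#'   non-rare diagnoses, admission type, insurance class, hospital category;
#'   plus log length of stay for the readmission model)?
#' @param n_knots spline knots for age (default 5).
#' @param age_form `"rcs"` (restricted cubic spline, default) or `"groups"`
#'   (categorical age bands 18-34, 35-49, 50-64, 65-79, 80+), the
#'   interpretable alternative used to check robustness of the spline
#'   adjustment.
#' @return object of class `raredx_spec`.
#' @export
model_spec <- function(outcome, predictor = "fb_rdx", adjusted = TRUE,
                       n_knots = 5, age_form = c("rcs", "groups")) {
  outcome <- match.arg(outcome, .outcomes)
  predictor <- match.arg(predictor, .predictors)
  structure(list(outcome = outcome, predictor = predictor,
                 adjusted = adjusted, n_knots = n_knots,
                 age_form = match.arg(age_form)),
            class = "raredx_spec")
}

# Codes whose own frequency would place a patient in the flagged decile
# group; excluded from the number-of-diagnoses covariate of FB-RDx models.
rare_code_set <- function(spec, rarity = NULL, catalog = NULL) {
  if (spec$predictor == "has_rd") {
    if (is.null(catalog)) stop("has_rd models need the catalog", call. = FALSE)
    return(catalog$codes)
  }
  if (is.null(rarity)) stop("FB-RDx models need the rarity classification", call. = FALSE)
  cutoff <- if (spec$predictor == "decile_factor") 1L else rarity$cutoff
  rarity$code_table$code[rarity$code_table$code_decile <= cutoff]
}

# Assemble the model frame: outcome, predictor and (if adjusted) covariates.
build_design <- function(spec, data, rare_set) {
  y <- switch(spec$outcome,
    death = as.numeric(data$died),
    readmit30 = as.numeric(!is.na(data$days_to_readmission) &
                             data$days_to_readmission >= 1 &
                             data$days_to_readmission <= 30),
    icu_admission = as.numeric(data$icu),
    log_los = {
      bad <- which(!(data$los_days > 0))
      if (length(bad)) stop("nonpositive length of stay for patient(s) ",
                            paste(utils::head(data$patient_id[bad], 5L), collapse = ", "),
                            call. = FALSE)
      log(data$los_days)
    },
    log_icu_los = {
      bad <- which(!(data$icu_hours > 0))
      if (length(bad)) stop("nonpositive ICU hours for patient(s) ",
                            paste(utils::head(data$patient_id[bad], 5L), collapse = ", "),
                            call. = FALSE)
      log(data$icu_hours)
    })
  pred <- switch(spec$predictor,
    fb_rdx = data.frame(fb_rdx = as.numeric(data$fb_rdx)),
    has_rd = data.frame(has_rd = as.numeric(data$has_rd)),
    decile_factor = data.frame(decile = factor(data$decile,
                                               levels = c(10L, 1:9))))
  design <- cbind(data.frame(.y = y), pred)
  if (spec$adjusted) {
    age_terms <- if ((spec$age_form %||% "rcs") == "groups") {
      data.frame(age_group = cut(data$age, c(18, 35, 50, 65, 80, Inf),
                                 right = FALSE,
                                 labels = c("18-34", "35-49", "50-64",
                                            "65-79", "80+")))
    } else {
      age_basis <- rcs_basis(data$age, rcs_knots(data$age, spec$n_knots))
      colnames(age_basis) <- c("age", paste0("age_s", seq_len(ncol(age_basis) - 1)))
      as.data.frame(age_basis)
    }
    design <- cbind(design,
      data.frame(
        sex = factor(data$sex, levels = c("M", "F")),
        citizen = as.numeric(data$citizen),
        admitted_from_home = as.numeric(data$admitted_from_home),
        n_dx = n_diagnoses_covariate(data, rare_set),
        admission_type = factor(data$admission_type,
                                levels = c("emergency", "planned", "other")),
        insurance_class = factor(data$insurance_class,
                                 levels = c("mandatory", "semiprivate", "private")),
        hospital_category = factor(data$hospital_category,
                                   levels = c("tier1_university", "tier2_center",
                                              "tier3_general", "tier4_general",
                                              "tier5_general", "other_specialty",
                                              "rehabilitation_clinic", "surgical_clinic"))
      ),
      age_terms)
    if (spec$outcome == "readmit30") design$log_los <- log(data$los_days)
  }
  # drop factor levels absent after exclusions (e.g. rehabilitation clinics)
  design <- droplevels(design)
  design
}

extract_terms <- function(fit) {
  sm <- summary(fit)$coefficients
  est <- sm[, 1]; se <- sm[, 2]
  data.frame(term = rownames(sm),
             estimate = unname(est),
             se = unname(se),
             exp_estimate = unname(exp(est)),
             ci_low = unname(exp(est - 1.96 * se)),
             ci_high = unname(exp(est + 1.96 * se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

finalize_result <- function(spec, fit, excl, n_total, scale) {
  terms <- extract_terms(fit)
  degenerate <- terms$term[terms$se > 10 | abs(terms$estimate) > 15]
  pred_pattern <- if (spec$predictor == "decile_factor") "^decile" else
    paste0("^", spec$predictor)
  pred_idx <- grep(pred_pattern, terms$term)
  separation <- any(terms$se[pred_idx] > 10) ||
    any(abs(terms$estimate[pred_idx]) > 15)
  converged <- if (!is.null(fit$converged)) fit$converged else TRUE
  if (separation || !converged) {
    warning("model for outcome '", spec$outcome,
            "' flagged: possible separation or non-convergence of the ",
            "exposure term", call. = FALSE)
  }
  structure(list(outcome = spec$outcome, predictor = spec$predictor,
                 adjusted = spec$adjusted, scale = scale, terms = terms,
                 n_included = nrow(excl$included),
                 n_excluded = n_total - nrow(excl$included),
                 excluded_counts = excl$excluded_counts,
                 converged = converged, separation = separation,
                 degenerate_terms = degenerate),
            class = "raredx_fit")
}

#' Fit a logistic outcome model
#'
#' Maximum-likelihood logistic regression for a binary inpatient outcome,
#' after the outcome-specific exclusions of [apply_exclusions()]. Odds
#' ratios are `exp(coef)` with Wald 95% CIs `exp(coef +/- 1.96 SE)`.
#' Possible separation or non-convergence is flagged on the result, never
#' silent.
#'
#' @param spec a `raredx_spec` with a binary outcome.
#' @param patients patient-level analysis table (see [analysis_table()]).
#' @param rarity `raredx_rarity` classification (FB-RDx / decile models).
#' @param catalog `raredx_catalog` (RD models).
#' @return object of class `raredx_fit`.
#' @export
fit_logistic <- function(spec, patients, rarity = NULL, catalog = NULL) {
  stopifnot(inherits(spec, "raredx_spec"))
  if (!spec$outcome %in% c("death", "readmit30", "icu_admission")) {
    stop("fit_logistic requires a binary outcome", call. = FALSE)
  }
  excl <- apply_exclusions(patients, spec$outcome)
  if (nrow(excl$included) == 0L) stop("no patients left after exclusions", call. = FALSE)
  rare_set <- if (spec$adjusted) rare_code_set(spec, rarity, catalog) else character(0)
  design <- build_design(spec, excl$included, rare_set)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = design, family = stats::binomial())
  )
  finalize_result(spec, fit, excl, nrow(patients), "OR")
}

#' Fit a log-linear outcome model
#'
#' Ordinary least squares on the natural-log outcome (length of stay in
#' days, or ICU length of stay in hours), so `Exp(B) = exp(coef)` is a
#' multiplicative effect on the outcome scale. Nonpositive outcome values
#' are a data error.
#'
#' @inheritParams fit_logistic
#' @return object of class `raredx_fit` with scale `"Exp(B)"`.
#' @export
fit_log_linear <- function(spec, patients, rarity = NULL, catalog = NULL) {
  stopifnot(inherits(spec, "raredx_spec"))
  if (!spec$outcome %in% c("log_los", "log_icu_los")) {
    stop("fit_log_linear requires a log-scale outcome", call. = FALSE)
  }
  excl <- apply_exclusions(patients, spec$outcome)
  if (nrow(excl$included) == 0L) stop("no patients left after exclusions", call. = FALSE)
  rare_set <- if (spec$adjusted) rare_code_set(spec, rarity, catalog) else character(0)
  design <- build_design(spec, excl$included, rare_set)
  fit <- stats::lm(.y ~ ., data = design)
  finalize_result(spec, fit, excl, nrow(patients), "Exp(B)")
}

#' Fit one outcome model (dispatching on outcome type)
#'
#' @inheritParams fit_logistic
#' @return a `raredx_fit`.
#' @export
fit_outcome_model <- function(spec, patients, rarity = NULL, catalog = NULL) {
  if (spec$outcome %in% c("log_los", "log_icu_los")) {
    fit_log_linear(spec, patients, rarity, catalog)
  } else {
    fit_logistic(spec, patients, rarity, catalog)
  }
}

#' @export
print.raredx_fit <- function(x, ...) {
  cat(sprintf("%s model for outcome '%s' (%s predictor, %s)\n",
              if (x$scale == "OR") "Logistic" else "Log-linear",
              x$outcome, x$predictor,
              if (x$adjusted) "adjusted" else "unadjusted"))
  cat(sprintf("  n included %d, excluded %d", x$n_included, x$n_excluded))
  if (length(x$excluded_counts)) {
    cat(" (", paste(names(x$excluded_counts), x$excluded_counts,
                    sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  idx <- grep(if (x$predictor == "decile_factor") "^decile" else x$predictor,
              x$terms$term)
  show <- x$terms[idx, , drop = FALSE]
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  %-12s %s %.2f (%.2f, %.2f)\n", show$term[i], x$scale,
                show$exp_estimate[i], show$ci_low[i], show$ci_high[i]))
  }
  if (x$separation || !x$converged) cat("  ** flagged: separation/non-convergence **\n")
  invisible(x)
}

#' Unadjusted odds ratio from a 2x2 split
#'
#' Cross-product odds ratio for `a` events among `n1` exposed vs `b` events
#' among `n2` unexposed, with the Woolf confidence interval
#' `exp(ln OR +/- 1.96 * sqrt(1/a + 1/(n1-a) + 1/b + 1/(n2-b)))`.
#'
#' @param a events in group 1; `0 < a < n1`.
#' @param n1 size of group 1.
#' @param b events in group 2; `0 < b < n2`.
#' @param n2 size of group 2.
#' @return list with `or`, `ci_low`, `ci_high`, `log_or`, `se`.
#' @examples
#' unadjusted_or(3206, 83720, 13715, 746394)  # OR 2.13 (2.05, 2.21)
#' @export
unadjusted_or <- function(a, n1, b, n2) {
  if (!(a > 0 && a < n1 && b > 0 && b < n2)) {
    stop("zero or full cells: all four 2x2 cells must be positive ",
         "(continuity corrections are out of scope)", call. = FALSE)
  }
  log_or <- log((a / (n1 - a)) / (b / (n2 - b)))
  se <- sqrt(1 / a + 1 / (n1 - a) + 1 / b + 1 / (n2 - b))
  list(or = exp(log_or),
       ci_low = exp(log_or - 1.96 * se),
       ci_high = exp(log_or + 1.96 * se),
       log_or = log_or, se = se)
}

#' Decile dose-response analysis
#'
#' Fits the adjusted model with the full decile factor (reference = decile
#' 10, the patients whose rarest diagnosis is still common) and summarizes
#' the gradient with an ordinary least-squares line through the per-decile
#' point estimates (deciles 1-9), unweighted by default.
#'
#' @param patients patient-level analysis table.
#' @param outcome one of the five outcomes.
#' @param rarity `raredx_rarity` classification.
#' @param n_knots spline knots for age.
#' @param weighting `"none"` (default) or `"inv_var"` (weights `1/SE^2`).
#' @return list with `results` (decile, exp_estimate, ci_low, ci_high;
#'   decile 10 = 1 by construction), `trend` (slope, intercept), `fit`
#'   (the underlying `raredx_fit`) and `empty_deciles`.
#' @export
decile_dose_response <- function(patients, outcome, rarity, n_knots = 5,
                                 weighting = c("none", "inv_var")) {
  weighting <- match.arg(weighting)
  spec <- model_spec(outcome, "decile_factor", adjusted = TRUE, n_knots = n_knots)
  fit <- fit_outcome_model(spec, patients, rarity = rarity)
  idx <- grep("^decile", fit$terms$term)
  est <- fit$terms[idx, , drop = FALSE]
  est$decile <- as.integer(sub("^decile", "", est$term))
  present <- sort(est$decile)
  empty <- setdiff(1:9, present)
  if (length(empty)) {
    warning("decile(s) ", paste(empty, collapse = ", "),
            " empty after exclusions; trend fitted on available deciles",
            call. = FALSE)
  }
  results <- rbind(
    data.frame(decile = est$decile, estimate = est$estimate, se = est$se,
               exp_estimate = est$exp_estimate, ci_low = est$ci_low,
               ci_high = est$ci_high, reference = FALSE),
    data.frame(decile = 10L, estimate = 0, se = NA_real_, exp_estimate = 1,
               ci_low = NA_real_, ci_high = NA_real_, reference = TRUE)
  )
  results <- results[order(results$decile), ]
  rownames(results) <- NULL
  w <- if (weighting == "inv_var") 1 / est$se^2 else NULL
  tr <- stats::lm(exp_estimate ~ decile, data = est, weights = w)
  list(results = results,
       trend = c(intercept = unname(stats::coef(tr)[1]),
                 slope = unname(stats::coef(tr)[2])),
       fit = fit,
       empty_deciles = empty)
}
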