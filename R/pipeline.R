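# Convenience composition of the full analysis.

#' Join rarity and catalog flags onto the patient table
#'
#' @param patients patient-level table from [build_patient_table()].
#' @param rarity `raredx_rarity` from [classify_rarity()].
#' @param rd_match optional per-patient catalog match from [match_patients()].
#' @return the patient table with `rarity_key`, `rarest_code`, `decile`,
#'   `fb_rdx` (and `has_rd`, `n_rd` when a match is given) columns added.
#' @export
analysis_table <- function(patients, rarity, rd_match = NULL) {
  a <- rarity$assignments
  stopifnot(identical(as.character(a$patient_id),
                      as.character(patients$patient_id)))
  patients$rarity_key <- a$rarity_key
  patients$rarest_code <- a$rarest_code
  patients$decile <- a$decile
  patients$fb_rdx <- a$fb_rdx
  if (!is.null(rd_match)) {
    stopifnot(identical(as.character(rd_match$patient_id),
                        as.character(patients$patient_id)))
    patients$has_rd <- rd_match$has_rd
    patients$n_rd <- rd_match$n_rd
  }
  patients
}

#' Fit all five outcome models for one predictor
#'
#' @param patients patient-level analysis table (see [analysis_table()]).
#' @param predictor `"fb_rdx"` or `"has_rd"`.
#' @param rarity `raredx_rarity` (needed for FB-RDx models and the
#'   number-of-diagnoses covariate).
#' @param catalog `raredx_catalog` (needed for RD models).
#' @param adjusted fit the adjusted covariate set?
#' @param n_knots spline knots for age.
#' @return named list of `raredx_fit`, one per outcome.
#' @export
fit_all_outcomes <- function(patients, predictor = "fb_rdx", rarity = NULL,
                             catalog = NULL, adjusted = TRUE, n_knots = 5) {
  fits <- lapply(.outcomes, function(oc) {
    fit_outcome_model(model_spec(oc, predictor, adjusted, n_knots),
                      patients, rarity = rarity, catalog = catalog)
  })
  stats::setNames(fits, .outcomes)
}
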