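# CSV interchange. Stay and patient tables travel as wide CSV with
# diagnosis columns dx_1..dx_50 (empty cell = absent); catalogs as a
# one-column CSV `icd10_code`.

.dx_cols <- paste0("dx_", 1:50)
.stay_cols <- c("patient_id", "stay_id", "age", "sex", "citizen",
                "admitted_from_home", "admission_type", "insurance_class",
                "hospital_category", "died", "los_days", "icu", "icu_hours",
                "days_to_readmission")

#' Write a stay or patient table to CSV
#'
#' The list-column `diagnosis_codes` is spread over wide columns
#' `dx_1..dx_50`; all other columns are written as-is.
#'
#' @param stays stay- or patient-level data.frame with `diagnosis_codes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stays_csv <- function(stays, path) {
  codes <- stays$diagnosis_codes
  k <- max(lengths(codes), 1L)
  wide <- t(vapply(codes, function(x) c(x, rep("", 50 - length(x)))[1:50],
                   character(50)))
  colnames(wide) <- .dx_cols
  flat <- stays[, setdiff(names(stays), "diagnosis_codes"), drop = FALSE]
  out <- cbind(flat[, intersect(.stay_cols, names(flat)), drop = FALSE],
               as.data.frame(wide[, seq_len(max(k, 1L)), drop = FALSE],
                             stringsAsFactors = FALSE),
               flat[, setdiff(names(flat), .stay_cols), drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a stay or patient table from CSV
#'
#' Accepts the wide dialect written by [write_stays_csv()]: diagnosis
#' columns `dx_1..dx_50` with empty cells meaning absent, gathered back into
#' the `diagnosis_codes` list-column.
#'
#' @param path CSV path.
#' @return data.frame with a `diagnosis_codes` list-column.
#' @export
read_stays_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       stay_id = "character"))
  dx <- intersect(.dx_cols, names(df))
  if (length(dx) == 0L) stop("no dx_* diagnosis columns in ", path, call. = FALSE)
  m <- as.matrix(df[, dx, drop = FALSE])
  m[is.na(m)] <- ""
  codes <- apply(m, 1L, function(r) unname(r[nzchar(r)]), simplify = FALSE)
  out <- df[, setdiff(names(df), dx), drop = FALSE]
  out$diagnosis_codes <- codes
  for (col in c("citizen", "admitted_from_home", "died", "icu")) {
    if (col %in% names(out)) out[[col]] <- as.logical(out[[col]])
  }
  if ("days_to_readmission" %in% names(out)) {
    out$days_to_readmission <- as.integer(out$days_to_readmission)
  }
  out
}

#' Write per-patient rarity (and catalog) assignments to CSV
#'
#' @param rarity `raredx_rarity` classification.
#' @param path output path.
#' @param rd_match optional per-patient catalog match from [match_patients()].
#' @return `path`, invisibly.
#' @export
write_assignments_csv <- function(rarity, path, rd_match = NULL) {
  out <- rarity$assignments
  if (!is.null(rd_match)) {
    out <- merge(out, rd_match, by = "patient_id", sort = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the code frequency table to CSV
#'
#' One row per distinct code with its patient count, ICD-10 chapter, the
#' decile the code maps to, and an `in_<catalog>` flag per supplied catalog
#' (the shape of a shareable code-level supplement).
#'
#' @param rarity `raredx_rarity` classification.
#' @param path output path.
#' @param catalogs optional list of `raredx_catalog` objects.
#' @return `path`, invisibly.
#' @export
write_frequency_csv <- function(rarity, path, catalogs = list()) {
  out <- rarity$code_table
  for (cat in catalogs) {
    out[[paste0("in_", cat$name)]] <- out$code %in% cat$codes
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a catalog to a one-column CSV
#'
#' @param catalog a `raredx_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog_csv <- function(catalog, path) {
  utils::write.csv(data.frame(icd10_code = catalog$codes), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write the per-stay latent ground truth to CSV
#'
#' Kept separate from the observable stay table: downstream code must never
#' see it.
#'
#' @param cohort a `raredx_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_latent_csv <- function(cohort, path) {
  utils::write.csv(cohort$latent, path, row.names = FALSE)
  invisible(path)
}
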