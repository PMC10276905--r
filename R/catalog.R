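# Catalog-based rare disease (RD) definition: a patient has an RD when at
# least one of their truncated diagnosis codes appears in an ICD-10 coded
# reference catalog.

#' Construct a rare-disease catalog
#'
#' @param codes character vector of ICD-10 codes; normalized via
#'   [truncate_code()] and de-duplicated.
#' @param name label used in outputs when several catalogs are compared.
#' @return object of class `raredx_catalog` with elements `name`, `codes`
#'   and `n_duplicates` (codes collapsed during normalization).
#' @export
rd_catalog <- function(codes, name = "catalog") {
  norm <- truncate_code(codes)
  uniq <- sort(unique(norm))
  if (length(uniq) == 0L) stop("catalog is empty", call. = FALSE)
  n_dup <- length(norm) - length(uniq)
  if (n_dup > 0L) message("rd_catalog('", name, "'): collapsed ", n_dup,
                          " duplicate code(s) after truncation")
  structure(list(name = name, codes = uniq, n_duplicates = n_dup),
            class = "raredx_catalog")
}

#' Load a rare-disease catalog from CSV
#'
#' Expects a one-column CSV with header `icd10_code`. Codes are normalized
#' to the 4-character analysis form; duplicates arising from truncation are
#' collapsed (with a message giving the count).
#'
#' @param path path to the CSV file.
#' @param name catalog label.
#' @return a `raredx_catalog`.
#' @export
load_catalog <- function(path, name = sub("\\.csv$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"icd10_code" %in% names(df)) {
    stop("catalog file must have an 'icd10_code' column: ", path, call. = FALSE)
  }
  codes <- df$icd10_code
  bad <- which(is.na(codes) | !nzchar(trimws(codes)))
  if (length(bad)) {
    stop("malformed catalog row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  if (length(codes) == 0L) stop("catalog file is empty: ", path, call. = FALSE)
  rd_catalog(codes, name)
}

#' @export
print.raredx_catalog <- function(x, ...) {
  cat("RD catalog '", x$name, "': ", length(x$codes), " ICD-10 codes\n", sep = "")
  invisible(x)
}

#' Flag patients carrying a catalog diagnosis
#'
#' @param patients patient-level table with normalized `diagnosis_codes`.
#' @param catalog a `raredx_catalog`.
#' @return data.frame with `patient_id`, `n_rd` (number of the patient's
#'   distinct codes found in the catalog) and `has_rd` (`n_rd >= 1`).
#' @export
match_patients <- function(patients, catalog) {
  stopifnot(inherits(catalog, "raredx_catalog"))
  n_rd <- vapply(patients$diagnosis_codes,
                 function(codes) sum(codes %in% catalog$codes), integer(1))
  data.frame(patient_id = patients$patient_id,
             n_rd = n_rd,
             has_rd = n_rd >= 1L,
             stringsAsFactors = FALSE)
}
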