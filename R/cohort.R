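# Cohort construction: from raw stay-level records to the one-stay-per-patient
# analysis table.
#
# A stay table is a data.frame with one row per hospital stay and columns
#   patient_id, stay_id        identifiers (character or integer)
#   diagnosis_codes            list-column of ICD-10 code strings (1-50)
#   age                        age at admission, completed years
#   sex                        "F"/"M"
#   citizen                    logical, Swiss citizenship
#   admitted_from_home         logical
#   admission_type             "emergency"/"planned"/"other"
#   insurance_class            "mandatory"/"semiprivate"/"private"
#   hospital_category          8-level factor (tier1 ... surgical_clinic)
#   died                       logical, in-hospital death
#   los_days                   length of stay in days, > 0
#   icu                        logical, ICU admission
#   icu_hours                  ICU length of stay in hours (0 unless icu)
#   days_to_readmission        integer >= 1 or NA (no recorded readmission)

#' Normalize an ICD-10 code to its 4-character analysis form
#'
#' Uppercases, strips the dot, and clips to the first four characters, so the
#' dotted dialect ("E10.9") and the compact one ("E109") map to the same
#' code. Codes shorter than four characters after dot removal are returned
#' unchanged. This is the truncation applied to every diagnosis before
#' frequencies, catalogs or chapters are looked at.
#'
#' @param code character vector of raw ICD-10 codes.
#' @return character vector of normalized codes, same length.
#' @examples
#' truncate_code(c("M5499", "A00", "e10.9"))  # "M549" "A00" "E109"
#' @export
truncate_code <- function(code) {
  if (length(code) == 0L) return(character(0))
  bad <- is.na(code) | !nzchar(trimws(code))
  if (any(bad)) {
    stop("empty or whitespace-only diagnosis code at position ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out <- gsub(".", "", toupper(trimws(code)), fixed = TRUE)
  substr(out, 1L, 4L)
}

#' Restrict a stay table to adult inpatients
#'
#' Keeps stays with age at admission >= 18 years (inclusive boundary). The
#' number of removed rows is reported with a message and attached as
#' attribute `n_removed`.
#'
#' @param stays stay-level data.frame with an `age` column.
#' @return the filtered data.frame.
#' @export
filter_adults <- function(stays) {
  if (anyNA(stays$age)) {
    stop("missing age at admission in row(s) ",
         paste(utils::head(which(is.na(stays$age)), 5L), collapse = ", "),
         call. = FALSE)
  }
  keep <- stays$age >= 18
  out <- stays[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_removed <- sum(!keep)
  if (n_removed > 0L) message("filter_adults: removed ", n_removed, " stay(s) under 18")
  attr(out, "n_removed") <- n_removed
  out
}

#' Select one stay per patient uniformly at random
#'
#' Repeated stays of the same patient over- or under-represent that patient's
#' codes in dataset-internal frequencies, so all analyses use a single,
#' randomly selected stay per patient. Stays are ordered by (patient_id,
#' stay_id) before drawing, so the selection is reproducible regardless of
#' the storage order of the input.
#'
#' @param stays stay-level data.frame with `patient_id` and `stay_id`.
#' @param seed integer seed for the random draw.
#' @return data.frame with exactly one row per distinct patient, ordered by
#'   patient_id.
#' @export
select_random_stay <- function(stays, seed) {
  if (anyDuplicated(paste(stays$patient_id, stays$stay_id, sep = "\r"))) {
    stop("duplicate (patient_id, stay_id) pairs in stay table", call. = FALSE)
  }
  ord <- order(stays$patient_id, stays$stay_id)
  pid <- stays$patient_id[ord]
  runs <- rle(as.character(pid))
  n_per <- runs$lengths
  starts <- cumsum(c(0L, n_per[-length(n_per)]))
  picked <- with_seed(seed, {
    starts + pmin(n_per, floor(stats::runif(length(n_per)) * n_per) + 1L)
  })
  out <- stays[ord[picked], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- attr(stays, "n_removed")
  out
}

#' Build the patient-level analysis table
#'
#' Applies, in order: the adult filter (minors' stays must not influence the
#' random selection), one random stay per patient, code truncation
#' ([truncate_code()]) and within-stay de-duplication. `n_diagnoses` is the
#' size of the de-duplicated code set. The composition is idempotent: running
#' it on its own output returns the same table.
#'
#' @param stays stay-level data.frame (see [select_random_stay()]).
#' @param seed integer seed for the stay selection.
#' @return patient-level data.frame, one row per patient, with normalized
#'   `diagnosis_codes` and an `n_diagnoses` column.
#' @export
build_patient_table <- function(stays, seed) {
  if (nrow(stays) == 0L) {
    out <- stays
    out$n_diagnoses <- integer(0)
    return(out)
  }
  adults <- filter_adults(stays)
  patients <- select_random_stay(adults, seed)
  lens <- lengths(patients$diagnosis_codes)
  if (any(lens == 0L)) {
    stop("stay without any diagnosis code", call. = FALSE)
  }
  all_codes <- truncate_code(unlist(patients$diagnosis_codes, use.names = FALSE))
  codes <- lapply(split(all_codes, rep.int(seq_len(nrow(patients)), lens)),
                  function(x) sort(unique.default(x)))
  names(codes) <- NULL
  patients$diagnosis_codes <- codes
  patients$n_diagnoses <- lengths(codes)
  patients
}
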