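# Frequency-based rare diagnosis (FB-RDx) classification.
#
# The rarity of a diagnosis is defined entirely within the analysis dataset:
# a code's frequency is the number of patients (one selected stay each)
# whose stay carries it. Each patient's rarity key is the minimum frequency
# over their codes, and patients are grouped into deciles of that key; the
# first decile holds the ~10% of patients with the rarest diagnoses.

# ICD-10 chapter boundaries keyed by leading letter; a letter can span two
# chapters (D, H) and several letters can share one (S-T, V-Y).
.chapter_table <- data.frame(
  letter = c("A", "B", "C", "D", "D", "E", "F", "G", "H", "H", "I", "J", "K",
             "L", "M", "N", "O", "P", "Q", "R", "S", "T", "U", "V", "W", "X",
             "Y", "Z"),
  lo = c(0, 0, 0, 0, 50, 0, 0, 0, 0, 60, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
         0, 1, 0, 0, 0, 0),
  hi = c(99, 99, 99, 48, 89, 90, 99, 99, 59, 95, 99, 99, 93, 99, 99, 99, 99,
         96, 99, 99, 99, 98, 99, 99, 99, 99, 98, 99),
  chapter = c("I", "I", "II", "II", "III", "IV", "V", "VI", "VII", "VIII",
              "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII",
              "XVIII", "XIX", "XIX", "XXII", "XX", "XX", "XX", "XX", "XXI"),
  stringsAsFactors = FALSE
)

#' ICD-10 chapter of a truncated code
#'
#' Chapter membership is determined from the leading letter and, where a
#' letter spans two chapters (D: II/III, H: VII/VIII), the two-digit numeric
#' part. Codes outside all defined ranges map to `"unknown"`.
#'
#' @param code character vector of truncated codes.
#' @return character vector of chapter labels ("I" .. "XXII" or "unknown").
#' @examples
#' chapter_of(c("Z038", "S720", "U071"))  # "XXI" "XIX" "XXII"
#' @export
chapter_of <- function(code) {
  letter <- substr(code, 1L, 1L)
  num <- suppressWarnings(as.integer(substr(code, 2L, 3L)))
  out <- rep("unknown", length(code))
  ok <- !is.na(num) & letter %in% .chapter_table$letter
  for (i in seq_len(nrow(.chapter_table))) {
    row <- .chapter_table[i, ]
    hit <- ok & letter == row$letter & num >= row$lo & num <= row$hi
    out[hit] <- row$chapter
  }
  out
}

# Chapters a sensitivity analysis may exclude: symptoms/findings (XVIII),
# injury/poisoning (XIX), external causes (XX), health-service contact (XXI),
# special purposes (XXII).
.excludable_chapters <- c("XVIII", "XIX", "XX", "XXI", "XXII")

validate_chapter_filter <- function(exclude_chapters) {
  if (is.null(exclude_chapters) || length(exclude_chapters) == 0L) return(character(0))
  bad <- setdiff(exclude_chapters, .excludable_chapters)
  if (length(bad)) {
    stop("excludable chapters are ", paste(.excludable_chapters, collapse = ", "),
         "; got ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unique(exclude_chapters)
}

#' Dataset-internal diagnosis code frequencies
#'
#' Counts, for each truncated code, the number of patients whose selected
#' stay carries it (codes are de-duplicated within a stay, so a patient
#' contributes at most 1 to each code).
#'
#' @param patients patient-level table from [build_patient_table()].
#' @return an object of class `raredx_freq`: a data.frame with columns
#'   `code` and `count`, plus attributes `total_patients` and
#'   `n_distinct_codes`.
#' @export
compute_code_frequencies <- function(patients) {
  if (nrow(patients) == 0L) stop("empty cohort: no patients to count", call. = FALSE)
  all_codes <- unlist(patients$diagnosis_codes, use.names = FALSE)
  tab <- table(all_codes)
  out <- data.frame(code = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$code), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            total_patients = nrow(patients),
            n_distinct_codes = nrow(out),
            class = c("raredx_freq", "data.frame"))
}

#' @export
print.raredx_freq <- function(x, ...) {
  cat("Diagnosis code frequency table:", attr(x, "n_distinct_codes"),
      "distinct codes over", attr(x, "total_patients"), "patients\n")
  print.data.frame(utils::head(x[order(x$count), , drop = FALSE], 5), ...)
  invisible(x)
}

#' Per-patient rarity keys
#'
#' The rarity key is the minimum, over the patient's (optionally
#' chapter-filtered) codes, of the code's patient count. Ties on the rarest
#' code are broken lexicographically. Patients whose codes are all removed
#' by the chapter filter are returned with `classifiable = FALSE` and NA key.
#'
#' @param patients patient-level table.
#' @param freq frequency table from [compute_code_frequencies()].
#' @param exclude_chapters optional subset of `c("XVIII","XIX","XX","XXI","XXII")`
#'   removed before taking the minimum (sensitivity variant).
#' @return data.frame with `patient_id`, `rarity_key`, `rarest_code`,
#'   `classifiable`.
#' @export
patient_rarity_keys <- function(patients, freq, exclude_chapters = NULL) {
  exclude_chapters <- validate_chapter_filter(exclude_chapters)
  np <- nrow(patients)
  lens <- lengths(patients$diagnosis_codes)
  all_codes <- unlist(patients$diagnosis_codes, use.names = FALSE)
  pos <- match(all_codes, freq$code)
  if (anyNA(pos)) {
    stop("code(s) absent from frequency table: ",
         paste(utils::head(unique(all_codes[is.na(pos)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  cnt <- freq$count[pos]
  grp <- rep.int(seq_len(np), lens)
  if (length(exclude_chapters)) {
    keep <- !(chapter_of(all_codes) %in% exclude_chapters)
    all_codes <- all_codes[keep]; cnt <- cnt[keep]; grp <- grp[keep]
  }
  # per-patient min count, rarest code by lexicographic tie-break
  o <- order(grp, cnt, all_codes, method = "radix")
  first <- !duplicated(grp[o])
  key <- rep(NA_integer_, np)
  rarest <- rep(NA_character_, np)
  g1 <- grp[o][first]
  key[g1] <- cnt[o][first]
  rarest[g1] <- all_codes[o][first]
  data.frame(patient_id = patients$patient_id,
             rarity_key = key,
             rarest_code = rarest,
             classifiable = !is.na(key),
             stringsAsFactors = FALSE)
}

#' Group patients into quantiles of the rarity key
#'
#' Patients are assigned `decile = ceiling(n_quantiles * F(key))`, clamped to
#' `[1, n_quantiles]`, where `F(key)` is the proportion of classifiable
#' patients with rarity key `<= key`. All patients sharing a key share a
#' decile (tie blocks are never split), so group sizes are only approximately
#' equal. Decile 1 collects the patients with the rarest diagnoses.
#'
#' @param keys vector of rarity keys (NA allowed: unclassifiable, returned NA).
#' @param n_quantiles number of groups (10 = deciles).
#' @return integer vector of quantile indices in `1..n_quantiles`.
#' @export
assign_deciles <- function(keys, n_quantiles = 10) {
  if (!is.numeric(n_quantiles) || length(n_quantiles) != 1L || n_quantiles < 2) {
    stop("n_quantiles must be a single integer >= 2", call. = FALSE)
  }
  ok <- !is.na(keys)
  if (!any(ok)) stop("no classifiable patients to group", call. = FALSE)
  k <- keys[ok]
  n <- length(k)
  # F(key) via cumulative counts over the sorted unique keys
  uk <- sort(unique(k))
  cum_f <- cumsum(tabulate(match(k, uk), nbins = length(uk))) / n
  dec_of_uk <- pmin(pmax(ceiling(n_quantiles * cum_f), 1L), n_quantiles)
  out <- rep(NA_integer_, length(keys))
  out[ok] <- as.integer(dec_of_uk[match(k, uk)])
  out
}

#' Flag frequency-based rare diagnoses
#'
#' A patient is FB-RDx-positive when their decile is at or below the cutoff:
#' cutoff 1 is the primary 10% definition; cutoffs 2 and 3 are the 20% and
#' 30% sensitivity variants.
#'
#' @param decile integer vector of quantile indices.
#' @param cutoff_quantiles flag deciles `<= cutoff_quantiles`.
#' @param n_quantiles total number of quantile groups (for validation).
#' @return logical vector (NA where decile is NA).
#' @export
flag_fb_rdx <- function(decile, cutoff_quantiles = 1, n_quantiles = 10) {
  if (cutoff_quantiles < 1 || cutoff_quantiles > n_quantiles) {
    stop("cutoff_quantiles must be in [1, ", n_quantiles, "]", call. = FALSE)
  }
  decile <= cutoff_quantiles
}

#' Classify a patient cohort by diagnosis rarity
#'
#' One-call composition of the FB-RDx pipeline: compute dataset-internal
#' code frequencies, per-patient rarity keys (optionally after excluding
#' non-disease ICD-10 chapters XVIII-XXII), quantile assignment, and the
#' FB-RDx flag. Frequencies are computed on the one-stay-per-patient cohort
#' by default; `freq_basis = "stays"` instead counts stays in a full stay
#' table supplied via `stays` (the dataset-ambiguous alternative).
#'
#' @param patients patient-level table from [build_patient_table()].
#' @param n_quantiles number of rarity groups (default 10, i.e. deciles).
#' @param cutoff FB-RDx cutoff in quantile groups (default 1 = lowest 10%).
#' @param exclude_chapters optional chapters XVIII-XXII to drop before scoring.
#' @param freq_basis `"patients"` (default) or `"stays"`.
#' @param stays stay-level table, required when `freq_basis = "stays"`.
#' @return an object of class `raredx_rarity`: list with `assignments`
#'   (patient_id, rarity_key, rarest_code, classifiable, decile, fb_rdx),
#'   `freq` (the `raredx_freq` table), `code_table` (per-code count, chapter
#'   and the decile a patient would get if this were their rarest code),
#'   `n_quantiles`, `cutoff`, `n_unclassifiable`.
#' @export
classify_rarity <- function(patients, n_quantiles = 10, cutoff = 1,
                            exclude_chapters = NULL,
                            freq_basis = c("patients", "stays"), stays = NULL) {
  freq_basis <- match.arg(freq_basis)
  if (freq_basis == "stays") {
    if (is.null(stays)) stop("freq_basis = 'stays' requires the stay table", call. = FALSE)
    stays_norm <- stays
    stays_norm$diagnosis_codes <- lapply(stays$diagnosis_codes,
                                         function(x) unique(truncate_code(x)))
    freq <- compute_code_frequencies(stays_norm)
  } else {
    freq <- compute_code_frequencies(patients)
  }
  keys <- patient_rarity_keys(patients, freq, exclude_chapters)
  n_unclassifiable <- sum(!keys$classifiable)
  if (n_unclassifiable > 0L) {
    message("classify_rarity: ", n_unclassifiable,
            " patient(s) unclassifiable after chapter exclusion")
  }
  keys$decile <- assign_deciles(keys$rarity_key, n_quantiles)
  keys$fb_rdx <- flag_fb_rdx(keys$decile, cutoff, n_quantiles)

  # decile a code maps to, via the patient-level ECDF of rarity keys
  ok <- keys$classifiable
  ecdf_keys <- sort(keys$rarity_key[ok])
  n <- length(ecdf_keys)
  code_decile <- {
    f <- findInterval(freq$count, ecdf_keys) / n
    as.integer(pmin(pmax(ceiling(n_quantiles * f), 1L), n_quantiles))
  }
  code_table <- data.frame(code = freq$code, count = freq$count,
                           chapter = chapter_of(freq$code),
                           code_decile = code_decile,
                           stringsAsFactors = FALSE)
  structure(list(assignments = keys, freq = freq, code_table = code_table,
                 n_quantiles = n_quantiles, cutoff = cutoff,
                 n_unclassifiable = n_unclassifiable,
                 exclude_chapters = exclude_chapters %||% character(0)),
            class = "raredx_rarity")
}

#' @export
print.raredx_rarity <- function(x, ...) {
  a <- x$assignments
  cat("FB-RDx classification of", nrow(a), "patients\n")
  cat("  distinct codes:", attr(x$freq, "n_distinct_codes"),
      " quantile groups:", x$n_quantiles, " cutoff:", x$cutoff, "\n")
  if (length(x$exclude_chapters)) {
    cat("  excluded chapters:", paste(x$exclude_chapters, collapse = ", "),
        "(", x$n_unclassifiable, "unclassifiable )\n")
  }
  cat("  FB-RDx flagged:", sum(a$fb_rdx, na.rm = TRUE),
      sprintf("(%.1f%%)", 100 * mean(a$fb_rdx, na.rm = TRUE)), "\n")
  invisible(x)
}
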