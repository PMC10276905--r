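# Paper-shaped deliverables: a stratified baseline table with group
# comparison tests, the FB-RDx vs catalog-RD comparison table, and the
# decile dose-response figure.

#' Baseline characteristics stratified by rarity decile groups
#'
#' Summarizes the cohort overall and in the asymmetric decile strata
#' (decile 1 | deciles 2-9 | decile 10). Categorical variables are shown as
#' percentage (frequency) with a chi-square test (no continuity correction)
#' across strata; continuous variables as median [IQR] with a Kruskal-Wallis
#' test. Percentages are rounded half-up to one decimal.
#'
#' @param patients patient-level analysis table with a `decile` column.
#' @param vars character vector of column names to summarize; numeric
#'   columns are treated as continuous, everything else (factor, character,
#'   logical) as categorical. Logicals are shown as a single `TRUE` row.
#' @return object of class `raredx_baseline`: formatted data.frame with one
#'   row per variable level and one column per stratum, a `p_value` column,
#'   stratum sizes in attribute `strata_n`, and the unformatted numbers in
#'   attribute `numeric` (long data.frame with freq/pct or quartiles per
#'   stratum).
#' @export
baseline_table <- function(patients, vars = c("age", "sex", "n_diagnoses",
                                              "insurance_class", "citizen",
                                              "admitted_from_home",
                                              "admission_type",
                                              "hospital_category", "died",
                                              "los_days", "icu")) {
  stopifnot("decile" %in% names(patients))
  vars <- intersect(vars, names(patients))
  strat <- ifelse(patients$decile == 1L, "decile_1",
                  ifelse(patients$decile == 10L, "decile_10", "decile_2_9"))
  strat <- factor(strat, levels = c("decile_1", "decile_2_9", "decile_10"))
  empty <- levels(strat)[table(strat) == 0L]
  if (length(empty)) {
    warning("omitting empty stratum/strata: ", paste(empty, collapse = ", "),
            call. = FALSE)
    strat <- droplevels(strat)
  }
  strata <- c("overall", levels(strat))
  idx_of <- c(list(overall = seq_len(nrow(patients))),
              split(seq_len(nrow(patients)), strat))

  rows <- list(); num <- list()
  for (v in vars) {
    x <- patients[[v]]
    if (is.numeric(x)) {
      cells <- vapply(strata, function(s) fmt_median_iqr(x[idx_of[[s]]]), character(1))
      p <- if (nlevels(strat) > 1) stats::kruskal.test(x, strat)$p.value else NA_real_
      rows[[length(rows) + 1L]] <- c(variable = v, level = "median [IQR]",
                                     cells, p_value = format.pval(p, digits = 3))
      for (s in strata) {
        q <- stats::quantile(x[idx_of[[s]]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                             names = FALSE)
        num[[length(num) + 1L]] <- data.frame(variable = v, level = "median [IQR]",
                                              stratum = s, freq = NA_real_,
                                              pct = NA_real_, q1 = q[1],
                                              median = q[2], q3 = q[3])
      }
    } else {
      xf <- if (is.logical(x)) factor(x, levels = c(FALSE, TRUE)) else factor(x)
      show_levels <- if (is.logical(x)) "TRUE" else levels(xf)
      p <- if (nlevels(strat) > 1) {
        stats::chisq.test(table(xf, strat), correct = FALSE)$p.value
      } else NA_real_
      for (lv in show_levels) {
        cells <- vapply(strata, function(s) {
          n_s <- length(idx_of[[s]])
          fmt_pct(sum(xf[idx_of[[s]]] == lv, na.rm = TRUE), n_s)
        }, character(1))
        rows[[length(rows) + 1L]] <- c(variable = v, level = lv, cells,
                                       p_value = format.pval(p, digits = 3))
        for (s in strata) {
          n_s <- length(idx_of[[s]])
          f <- sum(xf[idx_of[[s]]] == lv, na.rm = TRUE)
          num[[length(num) + 1L]] <- data.frame(variable = v, level = lv,
                                                stratum = s, freq = f,
                                                pct = round_half_up(100 * f / n_s, 1),
                                                q1 = NA_real_, median = NA_real_,
                                                q3 = NA_real_)
        }
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  structure(out,
            strata_n = vapply(idx_of, length, integer(1)),
            numeric = do.call(rbind, num),
            class = c("raredx_baseline", "data.frame"))
}

#' @export
print.raredx_baseline <- function(x, ...) {
  n <- attr(x, "strata_n")
  cat("Baseline characteristics (", paste(names(n), n, sep = " = ", collapse = ", "),
      ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Side-by-side comparison of FB-RDx and catalog-RD associations
#'
#' Builds the two-column table contrasting, for each of the five outcomes,
#' the adjusted effect of the first-decile FB-RDx flag with that of the
#' catalog rare-disease flag, each formatted as `estimate (low, high)` to
#' two decimals.
#'
#' @param results_fb named list of `raredx_fit` (predictor `fb_rdx`), one
#'   per outcome.
#' @param results_rd named list of `raredx_fit` (predictor `has_rd`).
#' @return data.frame with columns `outcome`, `scale`, `fb_rdx`, `rd`, and
#'   the exclusion-rule footnotes in attribute `footnotes`.
#' @export
comparison_table <- function(results_fb, results_rd) {
  fmt <- function(fit, term) {
    row <- fit$terms[fit$terms$term == term, ]
    if (nrow(row) != 1L) stop("predictor term '", term, "' not found", call. = FALSE)
    sprintf("%.2f (%.2f,%.2f)", row$exp_estimate, row$ci_low, row$ci_high)
  }
  rows <- lapply(.outcomes, function(oc) {
    if (is.null(results_fb[[oc]])) stop("missing FB-RDx result for outcome '",
                                        oc, "'", call. = FALSE)
    if (is.null(results_rd[[oc]])) stop("missing RD result for outcome '",
                                        oc, "'", call. = FALSE)
    data.frame(outcome = oc, scale = results_fb[[oc]]$scale,
               fb_rdx = fmt(results_fb[[oc]], "fb_rdx"),
               rd = fmt(results_rd[[oc]], "has_rd"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "footnotes") <- c(
    "LOS, 30-day readmission and ICU-LOS models exclude in-hospital deaths",
    "ICU admission, LOS, ICU-LOS and readmission models exclude rehabilitation clinics",
    "30-day readmission additionally adjusted for (log) length of stay",
    "ICU-LOS restricted to patients admitted to an ICU")
  out
}

#' Dose-response figure for one outcome
#'
#' Per-decile effect estimates with 95% CI bars against the decile index
#' (reference decile 10 = 1), overlaid with the fitted linear trend through
#' the decile 1-9 point estimates.
#'
#' @param dr result of [decile_dose_response()].
#' @param outcome label used for the axis/title.
#' @param file optional path; when given the figure is written there
#'   (format from the extension, e.g. `.png`, `.svg`).
#' @return the ggplot object, invisibly.
#' @export
dose_response_plot <- function(dr, outcome = dr$fit$outcome, file = NULL) {
  df <- dr$results
  ylab <- if (dr$fit$scale == "OR") "Odds ratio vs decile 10" else "Exp(B) vs decile 10"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$decile, y = .data$exp_estimate)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_abline(intercept = dr$trend[["intercept"]],
                         slope = dr$trend[["slope"]], colour = "blue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "Rarity decile (1 = rarest diagnoses)", y = ylab,
                  title = paste0("Dose-response: ", outcome)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
  invisible(p)
}

#' Write a JSON run manifest
#'
#' Records seeds, configuration and exclusion accounting for reproducibility.
#'
#' @param path output path.
#' @param seed integer seed of the run.
#' @param config optional `raredx_sim_config`.
#' @param fits optional named list of `raredx_fit` whose exclusion counts are
#'   recorded.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, seed, config = NULL, fits = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write a run manifest", call. = FALSE)
  }
  manifest <- list(seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(config)) {
    manifest$config <- unclass(config)
    manifest$config$covariate_effects <- unlist(config$covariate_effects)
  }
  if (!is.null(fits)) {
    manifest$models <- lapply(fits, function(f) {
      list(outcome = f$outcome, predictor = f$predictor,
           n_included = f$n_included, n_excluded = f$n_excluded,
           excluded_counts = as.list(f$excluded_counts),
           converged = f$converged, separation = f$separation)
    })
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
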