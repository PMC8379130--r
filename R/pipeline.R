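#' Analysis configuration
#'
#' Bundles the knobs of [run_full_analysis()] into a validated, serializable
#' object. Unknown fields are rejected so that a saved configuration always
#' round-trips.
#'
#' @param threshold DPAR dichotomization: the fixed value 120, any other
#'   fixed number, or `"auto"` to select it from the ROC curve
#'   ([select_threshold()] consensus).
#' @param blr_covariates Covariates for the logistic model, a subset of
#'   `c("dpar", "margins", "diameter")` (`"dpar"` enters dichotomized at the
#'   working threshold).
#' @param seed Integer seed used by any stochastic step.
#' @param calibration_preset Name recorded in provenance (the default
#'   calibration is [default_calibration()]).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(threshold = 120, blr_covariates = c("dpar", "margins"),
                            seed = 20160101L, calibration_preset = "default") {
  if (!(identical(threshold, "auto") || (is.numeric(threshold) && length(threshold) == 1L))) {
    stop("threshold must be a single number or \"auto\"", call. = FALSE)
  }
  bad <- setdiff(blr_covariates, c("dpar", "margins", "diameter"))
  if (length(bad) > 0L) stop("unknown BLR covariate(s): ", paste(bad, collapse = ", "),
                             call. = FALSE)
  structure(list(threshold = threshold, blr_covariates = blr_covariates,
                 seed = as.integer(seed), calibration_preset = calibration_preset),
            class = "analysis_config")
}

#' Save / load an analysis configuration
#'
#' JSON serialization with exact round-trip; loading rejects unknown keys.
#'
#' @param config An [analysis_config()].
#' @param path File path.
#' @return `save_config` returns `path` invisibly; `load_config` returns the
#'   `analysis_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("threshold", "blr_covariates", "seed", "calibration_preset")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) stop("unknown config key(s): ",
                                 paste(unknown, collapse = ", "), call. = FALSE)
  do.call(analysis_config, raw)
}

lesion_csv_cols <- c("lesion_id", "patient_id", "hu_lesion_ue", "hu_lesion_art",
                     "hu_lesion_del", "hu_liver_art_1", "hu_liver_art_2",
                     "hu_liver_del_1", "hu_liver_del_2", "margins",
                     "diameter_mm", "location", "response")

#' Read / write the lesion-table CSV
#'
#' The on-disk dialect is UTF-8 comma-separated with a header, `.` decimal
#' mark, and the columns `lesion_id, patient_id, hu_lesion_ue, hu_lesion_art,
#' hu_lesion_del, hu_liver_art_1, hu_liver_art_2, hu_liver_del_1,
#' hu_liver_del_2, margins, diameter_mm, location, response`. Lines starting
#' with `#` are provenance comments. `read_lesion_csv` validates the schema
#' and the value domains of `margins`, `location` and `response`, reporting
#' offending rows.
#'
#' @param data Lesion table.
#' @param path CSV file path.
#' @param provenance Optional character vector written as leading `#`
#'   comment lines.
#' @return `read_lesion_csv`: a validated tibble. `write_lesion_csv`: `path`,
#'   invisibly.
#' @export
read_lesion_csv <- function(path) {
  d <- tibble::as_tibble(read.csv(path, comment.char = "#",
                                  stringsAsFactors = FALSE, encoding = "UTF-8"))
  assert_cols(d, lesion_csv_cols, basename(path))
  check_domain <- function(col, allowed) {
    bad <- which(!is.na(d[[col]]) & !(d[[col]] %in% allowed))
    if (length(bad) > 0L) {
      stop(sprintf("%s: invalid %s in row(s) %s (allowed: %s)", basename(path),
                   col, paste(head(bad, 5), collapse = ", "),
                   paste(allowed, collapse = ", ")), call. = FALSE)
    }
  }
  check_domain("margins", c("smooth", "other"))
  check_domain("location", c("right", "median", "left"))
  check_domain("response", c("CR", "PR", "SD", "PD"))
  hu_cols <- grep("^hu_", lesion_csv_cols, value = TRUE)
  for (col in hu_cols) {
    bad <- which(!is.na(d[[col]]) & (d[[col]] < -1000 | d[[col]] > 3000))
    if (length(bad) > 0L) {
      stop(sprintf("%s: %s outside [-1000, 3000] HU in row(s) %s", basename(path),
                   col, paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  d
}

#' @rdname read_lesion_csv
#' @export
write_lesion_csv <- function(data, path, provenance = NULL) {
  data <- tibble::as_tibble(data)
  assert_cols(data, lesion_csv_cols, "lesion table")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  write.csv(data[lesion_csv_cols], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Runs [generate_cohort()] and writes the lesion CSV with a provenance
#' header; optionally also writes phantom image series with truth sidecars.
#'
#' @param path Output CSV path.
#' @param n_lesions,mode,seed,calibration Passed to [generate_cohort()].
#' @param n_phantoms Number of phantom series to also write (files
#'   `<path-sans-ext>_phantom<i>_<phase>.tif` + truth JSONs); requires the
#'   tiff package.
#' @param force Overwrite existing files.
#' @return Invisibly, the paths written.
#' @export
simulate_cohort_files <- function(path, n_lesions = 129L,
                                  mode = c("exact_counts", "sampled"),
                                  seed = 20160101L,
                                  calibration = default_calibration(),
                                  n_phantoms = 0L, force = FALSE) {
  mode <- match.arg(mode)
  if (file.exists(path) && !force) {
    stop("output exists (use force = TRUE): ", path, call. = FALSE)
  }
  cohort <- generate_cohort(n_lesions, mode, seed, calibration)
  gen <- attr(cohort, "generator")
  write_lesion_csv(cohort, path, provenance = c(
    sprintf("washoutCT %s synthetic cohort", gen$version),
    sprintf("mode=%s n=%d seed=%d", gen$mode, nrow(cohort), gen$seed)
  ))
  files <- path
  if (n_phantoms > 0L) {
    idx <- add_enhancement_indices(cohort)
    seeds <- derive_seeds(seed, n_phantoms)
    for (i in seq_len(n_phantoms)) {
      row <- idx[i, ]
      ph <- generate_phantom_series(cer = row$cer, llc = row$llc,
                                    wo_rel = row$wo_rel, dpar = row$dpar,
                                    ue_anchor = row$hu_lesion_ue,
                                    noise_sigma = c(3, 5, 4), seed = seeds[i])
      files <- c(files, write_phantom_series(
        ph, paste0(sub("\\.csv$", "", path), "_phantom", i)))
    }
  }
  invisible(files)
}

#' Run the full predictive analysis
#'
#' End-to-end orchestration: enhancement indices, the group comparison
#' (quantitative variables by Mann-Whitney, categorical by Fisher), phase
#' dispersion (unscaled MAD per phase), ROC analysis of DPAR with threshold
#' selection, dichotomized effect measures, the four-cell stratification,
#' binary logistic regression, and (when a second reader is supplied) the
#' inter-reader agreement table. Deterministic given (input, config).
#'
#' @param data Lesion table (tibble or path to a lesion CSV).
#' @param config An [analysis_config()].
#' @param reader2 Optional second-reader lesion table for the agreement
#'   section.
#' @return An `analysis_report` list with elements `cohort_summary`,
#'   `univariate`, `dispersion`, `roc`, `threshold_selection`, `threshold`,
#'   `effect_measures`, `stratification`, `logistic`, `agreement`,
#'   `provenance`, `warnings`. Use [report_json()] to serialize.
#' @export
run_full_analysis <- function(data, config = analysis_config(), reader2 = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(data)) data <- read_lesion_csv(data)
  data <- add_enhancement_indices(tibble::as_tibble(data))
  notes <- character(0)

  if (all(is.na(data$dpar))) stop("all DPAR values are non-evaluable", call. = FALSE)
  n_ne <- sum(is.na(data$dpar))
  if (n_ne > 0) notes <- c(notes, sprintf("%d lesion(s) with non-evaluable DPAR excluded", n_ne))

  data$cr <- dichotomize_response(data$response)
  is_cr <- data$cr == "CR+"
  small_n <- sum(is_cr) < 2 || sum(!is_cr) < 2
  if (small_n) notes <- c(notes, "insufficient n: inferential statistics omitted")

  # Table-2-style summary: median (Q1;Q3) per group for quantitative variables
  qvars <- c("diameter_mm", "cer", "llc", "wo_abs", "wo_rel", "dpar")
  qvars <- intersect(qvars, names(data))
  summarise_group <- function(sel) {
    purrr::map_dfr(qvars, function(v) {
      x <- data[[v]][sel & !is.na(data[[v]])]
      tibble::tibble(variable = v, n = length(x),
                     median = median(x), q1 = quantile(x, 0.25, names = FALSE),
                     q3 = quantile(x, 0.75, names = FALSE))
    })
  }
  cohort_summary <- dplyr::bind_rows(
    dplyr::mutate(summarise_group(is_cr), group = "CR+"),
    dplyr::mutate(summarise_group(!is_cr), group = "CR-")
  )

  univariate <- if (small_n) NULL else {
    rows <- purrr::map_dfr(qvars, function(v) {
      x <- data[[v]][is_cr]; y <- data[[v]][!is_cr]
      tibble::tibble(variable = v,
                     p_value = mann_whitney_u(x[!is.na(x)], y[!is.na(y)])$p_value,
                     test = "mann_whitney")
    })
    if ("margins" %in% names(data)) {
      sm <- data$margins == "smooth"
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        variable = "margins",
        p_value = fisher_exact_2x2(sum(sm & is_cr), sum(sm & !is_cr),
                                   sum(!sm & is_cr), sum(!sm & !is_cr))$p_value,
        test = "fisher"))
    }
    rows
  }

  dispersion <- tibble::tibble(
    phase = c("UE", "ART", "DEL"),
    mad = c(mad_unscaled(data$hu_lesion_ue, na.rm = TRUE),
            mad_unscaled(data$hu_lesion_art, na.rm = TRUE),
            mad_unscaled(data$hu_lesion_del, na.rm = TRUE))
  )

  roc <- threshold_selection <- NULL
  threshold <- if (identical(config$threshold, "auto")) NA_real_ else config$threshold
  if (!small_n) {
    roc_data <- data[!is.na(data$dpar), ]
    roc <- roc_auc(roc_data, dpar, cr, positive = "CR+")
    threshold_selection <- select_threshold(roc)
    if (identical(config$threshold, "auto")) {
      threshold <- threshold_selection$consensus
      notes <- c(notes, sprintf("auto threshold selected: %s", fmt1(threshold)))
    }
  } else if (identical(config$threshold, "auto")) {
    stop("auto threshold requires both response classes with n >= 2", call. = FALSE)
  }

  effect_measures <- stratification <- logistic <- NULL
  if (!small_n) {
    hi <- dichotomize_dpar(data$dpar, threshold) == "high"
    a <- sum(hi & is_cr, na.rm = TRUE); b <- sum(hi & !is_cr, na.rm = TRUE)
    c_ <- sum(!hi & is_cr, na.rm = TRUE); d_ <- sum(!hi & !is_cr, na.rm = TRUE)
    effect_measures <- dplyr::bind_cols(
      tibble::tibble(comparison = "CR by DPAR dichotomized",
                     a = a, b = b, c = c_, d = d_,
                     fisher_p = fisher_exact_2x2(a, b, c_, d_)$p_value),
      odds_ratio(a, b, c_, d_)
    )
    stratification <- stratify_lesions(data, threshold)

    covs <- config$blr_covariates
    data$dpar_high <- hi
    data$smooth <- if ("margins" %in% names(data)) data$margins == "smooth" else NULL
    terms <- c(dpar = "dpar_high", margins = "smooth", diameter = "diameter_mm")[covs]
    fml <- stats::reformulate(unname(terms), response = "cr")
    logistic <- tryCatch(logistic_fit(data, fml),
                         error = function(e) {
                           notes <<- c(notes, paste("logistic fit failed:",
                                                    conditionMessage(e)))
                           NULL
                         })
  }

  agreement <- if (!is.null(reader2)) {
    if (is.character(reader2)) reader2 <- read_lesion_csv(reader2)
    agreement_table(data, reader2)
  }

  structure(
    list(cohort_summary = cohort_summary, univariate = univariate,
         dispersion = dispersion, roc = roc,
         threshold_selection = threshold_selection, threshold = threshold,
         effect_measures = effect_measures, stratification = stratification,
         logistic = logistic, agreement = agreement,
         provenance = list(
           package = "washoutCT",
           version = as.character(utils::packageVersion("washoutCT")),
           schema = "washoutCT-report/1",
           n_lesions = nrow(data), seed = config$seed,
           threshold_mode = if (identical(config$threshold, "auto")) "auto" else "fixed",
           config = unclass(config)),
         warnings = notes),
    class = "analysis_report"
  )
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  x <- report
  if (!is.null(x$roc)) x$roc <- glance(x$roc)
  if (!is.null(x$logistic)) x$logistic <- tidy(x$logistic)
  if (!is.null(x$stratification)) {
    x$stratification <- list(cells = x$stratification$cells,
                             pooled_one_predictor = x$stratification$pooled_one_predictor,
                             odds_ratio = x$stratification$odds_ratio,
                             risk_ratio = x$stratification$risk_ratio,
                             n_excluded = x$stratification$n_excluded,
                             threshold = x$stratification$threshold)
  }
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = 10, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("washoutCT analysis report (", x$provenance$n_lesions, " lesions)\n", sep = "")
  if (!is.null(x$roc)) {
    cat("  DPAR AUC = ", fmt2(x$roc$auc), " (", fmt2(x$roc$conf_low), "-",
        fmt2(x$roc$conf_high), "); threshold ", fmt1(x$threshold),
        " [", x$provenance$threshold_mode, "]\n", sep = "")
  }
  if (!is.null(x$effect_measures)) {
    cat("  DPAR >= ", fmt1(x$threshold), ": OR ", fmt1(x$effect_measures$or),
        " (", fmt1(x$effect_measures$conf_low), "; ",
        fmt1(x$effect_measures$conf_high), "), Fisher p ",
        fmt_p(x$effect_measures$fisher_p), "\n", sep = "")
  }
  if (!is.null(x$stratification)) print(x$stratification)
  for (w in x$warnings) cat("  note: ", w, "\n", sep = "")
  invisible(x)
}
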