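#' @name io
#' @title Cohort tables, configuration and reports
#'
#' @description
#' Cohort tables travel as delimited text (comma or tab, auto-detected,
#' header mandatory). Enum tokens are case-insensitive on input and written
#' canonical lower-case. Reports carry the cascade block, the association
#' blocks and per-patient decisions, plus provenance (configuration echo,
#' package version, input checksum) so every reported percentage is
#' recomputable from the counts in the same report.
NULL

#' Pipeline configuration
#'
#' @param msi_min_informative Minimum informative MSI markers for an MSS
#'   call (see [call_msi()]). Default 3.
#' @param methylation_threshold Methylation-ratio threshold (see
#'   [call_methylation()]). Default 0.15.
#' @param ci_method Odds-ratio interval: `"auto"` (exact when any cell < 5),
#'   `"woolf"` or `"exact"`.
#' @param continuity_correction Yates correction for chi-squared tests.
#'   Default `FALSE` (the uncorrected Pearson statistic).
#' @param zero_cell_correction Apply the Haldane-Anscombe +0.5 correction to
#'   zero-cell tables instead of erroring. Default `FALSE`.
#' @param decimals Decimals for percentages in reports. Default 1.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(msi_min_informative = 3,
                            methylation_threshold = 0.15,
                            ci_method = c("auto", "woolf", "exact"),
                            continuity_correction = FALSE,
                            zero_cell_correction = FALSE,
                            decimals = 1) {
  ci_method <- match.arg(ci_method)
  if (!is_scalar_number(methylation_threshold) ||
      methylation_threshold <= 0 || methylation_threshold >= 1) {
    stop_input("methylation_threshold must be in (0, 1)")
  }
  if (!is_scalar_number(msi_min_informative) || msi_min_informative < 0 ||
      msi_min_informative > 5) {
    stop_input("msi_min_informative must be between 0 and 5")
  }
  if (!is_scalar_number(decimals) || decimals < 0) {
    stop_input("decimals must be >= 0")
  }
  structure(list(msi_min_informative = msi_min_informative,
                 methylation_threshold = methylation_threshold,
                 ci_method = ci_method,
                 continuity_correction = isTRUE(continuity_correction),
                 zero_cell_correction = isTRUE(zero_cell_correction),
                 decimals = decimals),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path; `.json` is parsed with jsonlite, anything else as
#'   YAML (requires the yaml package).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("reading YAML config requires the yaml package")
    }
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_input("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

cohort_enum_cols <- function() {
  list(msi = paste0("msi_", msi_markers),
       ihc = paste0("ihc_", tolower(mmr_proteins)),
       meth = c("meth_tumor_probe3", "meth_tumor_probe4",
                "meth_blood_probe3", "meth_blood_probe4"),
       germline = paste0("germline_", tolower(ls_genes)))
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop_input("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_comma <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_comma) "\t" else ","
}

#' Read a cohort table
#'
#' Reads a delimited cohort table (one row per patient, header mandatory),
#' validates the assay columns and canonicalises enum tokens. All row-level
#' validation problems are collected and reported together, with row and
#' column references. Unknown columns are preserved untouched.
#'
#' @param path File path.
#' @param delim `"auto"` (default, chooses between tab and comma from the
#'   header line), `"tab"` or `"comma"`.
#' @return A cohort data.frame.
#' @export
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' write_cohort(paper_fixture(), path)
#' cohort <- read_cohort(path)
read_cohort <- function(path, delim = c("auto", "tab", "comma")) {
  delim <- match.arg(delim)
  if (!file.exists(path)) stop_input("cohort file not found: ", path)
  sep <- switch(delim, auto = detect_delim(path), tab = "\t", comma = ",")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  cols <- cohort_enum_cols()
  mandatory <- c(cols$msi, cols$ihc, cols$meth)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop_input("cohort file is missing mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  }

  problems <- character(0)
  note <- function(row, col, msg) {
    problems <<- c(problems, sprintf("row %d, column %s: %s", row, col, msg))
  }
  check_enum <- function(col, allowed, allow_na = FALSE) {
    v <- fold_token(raw[[col]])
    bad <- which(!(v %in% allowed) & !(allow_na & is.na(v)))
    if (!allow_na) bad <- union(bad, which(is.na(v)))
    for (r in sort(bad)) {
      note(r, col, paste0("'", raw[[col]][r],
                          "' not one of ", paste(allowed, collapse = "|")))
    }
    v
  }
  for (col in cols$msi) raw[[col]] <- check_enum(col, msi_statuses)
  for (col in cols$ihc) raw[[col]] <- check_enum(col, ihc_statuses)
  for (col in cols$meth) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    for (r in bad) note(r, col, "not a number")
    neg <- which(!is.na(v) & v < 0)
    for (r in neg) note(r, col, "negative probe ratio")
    raw[[col]] <- v
  }
  for (col in intersect(cols$germline, names(raw))) {
    raw[[col]] <- check_enum(col, germline_outcomes, allow_na = TRUE)
    raw[[col]][is.na(raw[[col]])] <- "not_done"
  }
  if ("age" %in% names(raw)) {
    raw$age <- suppressWarnings(as.numeric(raw$age))
  }
  for (col in intersect(c("rbg", "amii", "til", "lvi", "lus", "sync_ovarian"),
                        names(raw))) {
    raw[[col]] <- as.logical(toupper(raw[[col]]))
  }
  if ("grade" %in% names(raw)) {
    raw$grade <- suppressWarnings(as.integer(raw$grade))
  }
  if ("patient_id" %in% names(raw) && anyDuplicated(raw$patient_id)) {
    problems <- c(problems, "duplicate patient_id values")
  }
  if (length(problems)) {
    stop_input("cohort validation failed:\n  ",
               paste(problems, collapse = "\n  "))
  }
  raw
}

#' Write a cohort or decisions table
#'
#' Writes tab- or comma-delimited text with a header, `NA` as empty fields
#' and enum tokens in canonical lower case.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @param delim `"tab"` (default) or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, delim = c("tab", "comma")) {
  delim <- match.arg(delim)
  # free-text fields (variant labels) may contain commas: quote under CSV
  utils::write.table(x, path, sep = if (delim == "tab") "\t" else ",",
                     row.names = FALSE, quote = (delim == "comma"), na = "")
  invisible(path)
}

#' Build a structured screening report
#'
#' Assembles the cascade block, the standard association blocks (currently
#' age under 50 and synchronous ovarian cancer, suspected vs non-suspected,
#' when the cohort carries those columns) and the per-patient decisions,
#' with provenance (configuration echo, package version, input checksum).
#'
#' @param cohort Cohort data.frame (as from [read_cohort()] /
#'   [paper_fixture()]).
#' @param decisions Optional decision table; computed with [triage_cohort()]
#'   when omitted.
#' @param config A [pipeline_config()].
#' @param checksum Optional input checksum string echoed into provenance.
#' @return A list of class `screening_report`.
#' @export
#' @examples
#' rep <- build_report(paper_fixture())
#' rep$cascade$n_pathogenic
build_report <- function(cohort, decisions = NULL,
                         config = pipeline_config(), checksum = NULL) {
  if (is.null(decisions)) decisions <- triage_cohort(cohort, config)
  cascade <- cascade_summary(decisions, cohort)
  d <- config$decimals

  suspected <- decisions$label == "suspected_ls"
  associations <- list()
  add_assoc <- function(name, yes1, no1, yes2, no2) {
    t <- contingency_2x2(yes1, no1, yes2, no2)
    ar <- odds_ratio(t, method = config$ci_method)
    test <- chi_squared(t, correct = config$continuity_correction)
    associations[[name]] <<- list(
      variable = name, a = yes1, b = no1, c = yes2, d = no2,
      odds_ratio = ar$odds_ratio, ci_low = ar$ci_low, ci_high = ar$ci_high,
      ci_method = ar$method, chi2 = test$statistic, p = test$p)
  }
  if ("age" %in% names(cohort)) {
    young <- cohort$age < 50
    add_assoc("age_under_50",
              sum(suspected & young), sum(suspected & !young),
              sum(!suspected & young), sum(!suspected & !young))
  }
  if ("sync_ovarian" %in% names(cohort)) {
    ov <- cohort$sync_ovarian
    add_assoc("synchronous_ovarian",
              sum(suspected & ov, na.rm = TRUE),
              sum(suspected & !ov, na.rm = TRUE),
              sum(!suspected & ov, na.rm = TRUE),
              sum(!suspected & !ov, na.rm = TRUE))
  }

  cascade_block <- unclass(cascade)
  cascade_block$pattern_counts <- as.list(cascade$pattern_counts)
  cascade_block$pct_deficient <- pct(cascade$n_mmr_deficient,
                                     cascade$n_total, d)
  cascade_block$pct_mlh1_loss <- pct(cascade$n_mlh1_loss, cascade$n_total, d)
  cascade_block$pct_methylated_of_mlh1_loss <-
    pct(cascade$n_mlh1_methylated, cascade$n_mlh1_loss, d)
  cascade_block$pct_suspected <- pct(cascade$n_suspected, cascade$n_total, d)
  cascade_block$pct_pathogenic_of_tested <-
    if (cascade$n_tested > 0) pct(cascade$n_pathogenic, cascade$n_tested, d)
    else NA_real_
  cascade_block$pct_prevalence_observed <-
    round_half_up(100 * cascade$prevalence_observed, d)
  cascade_block$pct_predictive_frequency <-
    round_half_up(100 * cascade$predictive_frequency, d)
  cascade_block$pct_concordant <- pct(cascade$n_concordant, cascade$n_total, d)

  structure(list(
    cascade = cascade_block,
    associations = associations,
    decisions = decisions,
    provenance = list(
      package = "lynchscreen",
      version = as.character(utils::packageVersion("lynchscreen")),
      config = unclass(config),
      n_patients = nrow(cohort),
      input_checksum = checksum %||% NA_character_,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "screening_report")
}

#' Write a screening report
#'
#' @param report A `screening_report` from [build_report()].
#' @param path Output path.
#' @param format `"json"` (schema-stable, machine-parseable) or `"text"`
#'   (cascade narrative with counts and percentages at the configured
#'   precision).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "screening_report"))
  if (format == "json") {
    out <- unclass(report)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows", pretty = TRUE)
  } else {
    cs <- report$cascade
    d <- report$provenance$config$decimals
    fmt_pct <- function(x) sprintf(paste0("%.", d, "f%%"), x)
    lines <- c(
      sprintf("Screened %d patients with endometrial cancer.", cs$n_total),
      sprintf("%d patients (%s) had abnormal IHC or MSI results (MMR-deficient).",
              cs$n_mmr_deficient, fmt_pct(cs$pct_deficient)),
      sprintf("Loss of MLH1 expression in %d patients (%s); %d (%s) showed MLH1 tumor hypermethylation and were considered sporadic.",
              cs$n_mlh1_loss, fmt_pct(cs$pct_mlh1_loss),
              cs$n_mlh1_methylated, fmt_pct(cs$pct_methylated_of_mlh1_loss)),
      sprintf("%d cases (%s) were suspected of Lynch syndrome.",
              cs$n_suspected, fmt_pct(cs$pct_suspected)),
      sprintf("%d pursued genetic testing; %d carried a pathogenic mutation (%s of tested).",
              cs$n_tested, cs$n_pathogenic,
              fmt_pct(cs$pct_pathogenic_of_tested)),
      sprintf("Observed prevalence %s; predictive frequency %s.",
              fmt_pct(cs$pct_prevalence_observed),
              fmt_pct(cs$pct_predictive_frequency)),
      sprintf("IHC/MSI concordance in %s of cases (%d/%d).",
              fmt_pct(cs$pct_concordant), cs$n_concordant, cs$n_total))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a JSON screening report
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return The report as a list (class `screening_report`).
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(out, class = "screening_report")
}

#' Checksum of an input file (reproducibility provenance)
#'
#' MD5 digest of the file bytes; recorded in report provenance so a report
#' can be tied to its exact input.
#'
#' @param path File path.
#' @return A character scalar like `"md5:9e107d9d..."`.
#' @export
file_checksum <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  paste0("md5:", unname(tools::md5sum(path)))
}
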