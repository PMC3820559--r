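#' @name assay-calls
#' @title Per-tumor assay calls: MSI, IHC loss pattern, MLH1 methylation
#'
#' @description
#' Raw molecular observations on one tumor are turned into the categorical
#' calls the triage decision tree consumes:
#'
#' * [call_msi()] — microsatellite instability from the five mononucleotide
#'   markers BAT26, BAT25, NR21, NR24 and NR27; a tumor is MSI when two or
#'   more markers show an altered (unstable) pattern.
#' * [call_ihc_pattern()] — which of the four mismatch-repair proteins
#'   (MLH1, MSH2, MSH6, PMS2) show loss of expression by
#'   immunohistochemistry; stains without concurrent internal positive
#'   control are "unreliable" and never counted as loss.
#' * [methylation_ratio()] / [call_methylation()] — the MS-MLPA methylation
#'   ratio as the mean of the MLH1 promoter probes MLH1-3 and MLH1-4, with
#'   a 15% threshold separating methylated from unmethylated.
NULL

# canonical vocabulary
msi_markers <- c("bat26", "bat25", "nr21", "nr24", "nr27")
mmr_proteins <- c("MLH1", "MSH2", "MSH6", "PMS2")
msi_statuses <- c("stable", "unstable", "failed")
ihc_statuses <- c("retained", "lost", "unreliable")

#' Construct a five-marker microsatellite panel
#'
#' @param bat26,bat25,nr21,nr24,nr27 Marker status, one of `"stable"`,
#'   `"unstable"`, `"failed"`. Case-insensitive.
#' @return A named character vector of class `msi_panel`.
#' @export
#' @examples
#' msi_panel(bat26 = "unstable", bat25 = "unstable")
msi_panel <- function(bat26 = "stable", bat25 = "stable", nr21 = "stable",
                      nr24 = "stable", nr27 = "stable") {
  x <- fold_token(c(bat26 = bat26, bat25 = bat25, nr21 = nr21,
                    nr24 = nr24, nr27 = nr27))
  bad <- !(x %in% msi_statuses)
  if (any(is.na(x)) || any(bad)) {
    stop_input("invalid MSI marker status for ",
               paste(msi_markers[is.na(x) | bad], collapse = ", "),
               " (allowed: stable, unstable, failed)")
  }
  structure(x, class = "msi_panel")
}

#' Construct a four-protein mismatch-repair IHC panel
#'
#' @param mlh1,msh2,msh6,pms2 Protein expression status, one of `"retained"`,
#'   `"lost"`, `"unreliable"`. Case-insensitive.
#' @return A named character vector of class `ihc_panel`.
#' @export
#' @examples
#' ihc_panel(mlh1 = "lost", pms2 = "lost")
ihc_panel <- function(mlh1 = "retained", msh2 = "retained",
                      msh6 = "retained", pms2 = "retained") {
  x <- fold_token(c(mlh1 = mlh1, msh2 = msh2, msh6 = msh6, pms2 = pms2))
  bad <- !(x %in% ihc_statuses)
  if (any(is.na(x)) || any(bad)) {
    stop_input("invalid IHC status for ",
               paste(tolower(mmr_proteins)[is.na(x) | bad], collapse = ", "),
               " (allowed: retained, lost, unreliable)")
  }
  structure(x, class = "ihc_panel")
}

#' Construct an MS-MLPA methylation measurement
#'
#' Probe ratios come from the two MLH1 promoter probes (MLH1-3 covering the
#' C region, MLH1-4 the D region). Either probe may be missing, not both.
#' Ratios above 1 can occur after MS-MLPA normalisation; values above 1.5
#' trigger a validation warning but are kept.
#'
#' @param probe3,probe4 Methylation ratio of probe MLH1-3 / MLH1-4 in
#'   `[0, 1.5]`; `NA` when the probe failed or was not run.
#' @param tissue Sample tissue: `"tumor"`, `"blood"` or
#'   `"normal_endometrium"`.
#' @return A list of class `methylation_measurement`.
#' @export
#' @examples
#' methylation_measurement(0.30, 0.20)
methylation_measurement <- function(probe3 = NA_real_, probe4 = NA_real_,
                                    tissue = c("tumor", "blood",
                                               "normal_endometrium")) {
  tissue <- match.arg(tissue)
  probes <- c(probe3 = as.numeric(probe3), probe4 = as.numeric(probe4))
  if (all(is.na(probes))) {
    stop_input("at least one of probe3/probe4 must be present")
  }
  if (any(probes < 0, na.rm = TRUE)) {
    stop_input("probe ratios must be non-negative")
  }
  if (any(probes > 1.5, na.rm = TRUE)) {
    warning("probe ratio above 1.5; check MS-MLPA normalisation",
            call. = FALSE)
  }
  structure(list(probe3 = probes[["probe3"]], probe4 = probes[["probe4"]],
                 tissue = tissue),
            class = "methylation_measurement")
}

#' Call microsatellite instability from a five-marker panel
#'
#' A tumor is MSI when at least two markers show an altered pattern,
#' regardless of how many markers failed. Failed markers are excluded from
#' the informative count; with fewer than `min_informative` informative
#' markers and fewer than two unstable ones, the panel cannot support a
#' confident MSS call and the status is `"indeterminate"`.
#'
#' @param panel An [msi_panel()] (or a named vector/list coercible to one).
#' @param min_informative Minimum number of informative (non-failed) markers
#'   required to call MSS. Default 3.
#' @return A list of class `msi_call` with elements `status` (`"MSI"`,
#'   `"MSS"` or `"indeterminate"`), `n_unstable` and `n_informative`.
#' @export
#' @examples
#' call_msi(msi_panel(bat26 = "unstable", bat25 = "unstable"))
call_msi <- function(panel, min_informative = 3) {
  panel <- as_msi_panel(panel)
  n_unstable <- sum(panel == "unstable")
  n_informative <- sum(panel != "failed")
  status <- if (n_unstable >= 2) {
    "MSI"
  } else if (n_informative < min_informative) {
    "indeterminate"
  } else {
    "MSS"
  }
  structure(list(status = status, n_unstable = n_unstable,
                 n_informative = n_informative),
            class = "msi_call")
}

as_msi_panel <- function(x) {
  if (inherits(x, "msi_panel")) return(x)
  x <- as.list(x)
  if (is.null(names(x)) || !all(msi_markers %in% names(x))) {
    stop_input("MSI panel needs named statuses for all of: ",
               paste(msi_markers, collapse = ", "))
  }
  do.call(msi_panel, x[msi_markers])
}

#' Derive the IHC loss pattern from a four-protein panel
#'
#' Only proteins explicitly scored `"lost"` (absent tumor staining with a
#' positive internal control) enter the loss set; `"unreliable"` stains are
#' flagged but never treated as loss, so a fully unreliable panel yields an
#' empty pattern and downstream mismatch-repair status rests on MSI alone.
#'
#' @param panel An [ihc_panel()] (or a named vector/list coercible to one).
#' @return A list of class `ihc_pattern` with elements `lost` (character
#'   vector of protein names, subset of MLH1/MSH2/MSH6/PMS2) and
#'   `any_unreliable` (logical).
#' @export
#' @examples
#' call_ihc_pattern(ihc_panel(mlh1 = "lost", pms2 = "lost"))
call_ihc_pattern <- function(panel) {
  panel <- as_ihc_panel(panel)
  structure(list(lost = mmr_proteins[panel == "lost"],
                 any_unreliable = any(panel == "unreliable")),
            class = "ihc_pattern")
}

as_ihc_panel <- function(x) {
  if (inherits(x, "ihc_panel")) return(x)
  x <- as.list(x)
  nm <- tolower(mmr_proteins)
  if (is.null(names(x)) || !all(nm %in% names(x))) {
    stop_input("IHC panel needs named statuses for all of: ",
               paste(nm, collapse = ", "))
  }
  do.call(ihc_panel, x[nm])
}

#' MS-MLPA methylation ratio (two-probe mean)
#'
#' The methylation ratio is the mean of the MLH1-3 and MLH1-4 probe ratios;
#' when only one probe is available its value is used and a warning records
#' the single-probe call.
#'
#' @param m A [methylation_measurement()].
#' @return The methylation ratio, a single non-negative number.
#' @export
#' @examples
#' methylation_ratio(methylation_measurement(0.30, 0.20))
methylation_ratio <- function(m) {
  m <- as_methylation_measurement(m)
  probes <- c(m$probe3, m$probe4)
  if (anyNA(probes)) {
    warning("methylation ratio from a single probe", call. = FALSE)
  }
  mean(probes, na.rm = TRUE)
}

as_methylation_measurement <- function(x) {
  if (inherits(x, "methylation_measurement")) return(x)
  if (is.numeric(x) && length(x) == 2L) {
    return(methylation_measurement(x[[1]], x[[2]]))
  }
  x <- as.list(x)
  do.call(methylation_measurement, x)
}

#' Call MLH1 promoter methylation status
#'
#' The tumor (or blood) is called methylated when the two-probe mean
#' methylation ratio is at or above the threshold. The published threshold
#' is 15%; a ratio of exactly 0.15 is methylated, so the threshold value
#' itself is actionable.
#'
#' @param m A [methylation_measurement()].
#' @param threshold Methylation ratio at or above which the sample is called
#'   methylated. Default 0.15.
#' @return `"methylated"` or `"unmethylated"`.
#' @export
#' @examples
#' call_methylation(methylation_measurement(0.30, 0.20))
call_methylation <- function(m, threshold = 0.15) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    stop_input("threshold must be a single number in (0, 1)")
  }
  if (methylation_ratio(m) >= threshold) "methylated" else "unmethylated"
}

#' @export
print.msi_call <- function(x, ...) {
  cat(sprintf("MSI call: %s (%d unstable / %d informative markers)\n",
              x$status, x$n_unstable, x$n_informative))
  invisible(x)
}

#' @export
print.ihc_pattern <- function(x, ...) {
  lost <- if (length(x$lost)) paste(x$lost, collapse = "/") else "none"
  cat(sprintf("IHC loss pattern: %s%s\n", lost,
              if (x$any_unreliable) " (some stains unreliable)" else ""))
  invisible(x)
}
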