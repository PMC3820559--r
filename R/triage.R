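#' @name triage
#' @title Decision tree for suspected Lynch syndrome
#'
#' @description
#' The decision tree combines the tumor's MSI call, IHC loss pattern and
#' MLH1 promoter methylation status into a mismatch-repair (MMR) status, a
#' sporadic/suspected-Lynch label, and an ordered, conditional germline
#' gene-testing plan. Rules fire in a fixed order and every rule fired is
#' recorded in the decision's rationale trail (stable identifiers R1--R7;
#' E1/E2 mark unresolvable or pending states):
#'
#' * R1 — MMR proficient: no further action.
#' * R2 — MLH1 lost and tumor methylated: sporadic (somatic MLH1 promoter
#'   hypermethylation), unless blood is also methylated, which raises
#'   suspicion of a constitutional epimutation.
#' * R3 — MLH1 lost, tumor unmethylated: suspected Lynch, test MLH1.
#' * R4 — MSH2 lost: suspected Lynch, test MSH2, then MSH6, then EPCAM
#'   (large rearrangements), each conditional on the previous being negative.
#' * R5 — MSH6 lost with MSH2 retained: suspected Lynch, test MSH6.
#' * R6 — PMS2 lost with MLH1 retained: suspected Lynch, test PMS2 (merged
#'   with R5's plan when both fire).
#' * R7 — MSI with fully retained IHC: suspected Lynch, test all four MMR
#'   genes in order MLH1, MSH2, MSH6, PMS2.
NULL

ls_genes <- c("MLH1", "MSH2", "MSH6", "PMS2", "EPCAM")
germline_outcomes <- c("pathogenic", "vus", "negative", "not_done")
triage_labels <- c("proficient", "sporadic_methylated", "suspected_ls",
                   "constitutional_epimutation_suspected",
                   "pending_methylation", "unresolvable")

#' Mismatch-repair status from MSI and IHC calls
#'
#' A tumor is MMR-deficient when it is MSI and/or shows loss of expression
#' of any MMR protein; MSS with fully preserved expression is proficient.
#' An indeterminate MSI call with no IHC loss cannot be resolved and is
#' flagged for review rather than silently defaulted.
#'
#' @param msi An `msi_call` from [call_msi()].
#' @param pattern An `ihc_pattern` from [call_ihc_pattern()].
#' @return `"deficient"`, `"proficient"` or `"unresolvable"`.
#' @export
#' @examples
#' mmr_status(call_msi(msi_panel()), call_ihc_pattern(ihc_panel(msh6 = "lost")))
mmr_status <- function(msi, pattern) {
  stopifnot(inherits(msi, "msi_call"), inherits(pattern, "ihc_pattern"))
  if (length(pattern$lost) > 0) return("deficient")
  switch(msi$status,
         MSI = "deficient",
         MSS = "proficient",
         indeterminate = "unresolvable",
         stop_input("unknown MSI status: ", msi$status))
}

#' Triage one patient through the decision tree
#'
#' @param pattern An `ihc_pattern` from [call_ihc_pattern()].
#' @param msi An `msi_call` from [call_msi()].
#' @param meth_tumor,meth_blood Methylation call for tumor / blood DNA
#'   (`"methylated"`, `"unmethylated"`) or `NA` when not measured. Tumor
#'   methylation is required whenever MLH1 is lost; a missing blood sample
#'   after a methylated tumor still yields `sporadic_methylated`, with a
#'   `"blood unconfirmed"` note (blood testing is optional in practice).
#' @return A `triage_decision`: list with `mmr`, `label`, `gene_plan`
#'   (ordered character vector, non-empty iff `label == "suspected_ls"`),
#'   `rationale` (rule identifiers fired, in order) and `notes`.
#' @export
#' @examples
#' triage_patient(call_ihc_pattern(ihc_panel(mlh1 = "lost", pms2 = "lost")),
#'                call_msi(msi_panel(bat26 = "unstable", bat25 = "unstable")),
#'                meth_tumor = "unmethylated")
triage_patient <- function(pattern, msi, meth_tumor = NA_character_,
                           meth_blood = NA_character_) {
  stopifnot(inherits(msi, "msi_call"), inherits(pattern, "ihc_pattern"))
  meth_tumor <- check_meth_call(meth_tumor, "meth_tumor")
  meth_blood <- check_meth_call(meth_blood, "meth_blood")

  mmr <- mmr_status(msi, pattern)
  decision <- function(label, plan = character(0), rationale = character(0),
                       notes = character(0)) {
    structure(list(mmr = mmr, label = label, gene_plan = plan,
                   rationale = rationale, notes = notes),
              class = "triage_decision")
  }

  if (mmr == "unresolvable") {
    return(decision("unresolvable", rationale = "E1",
                    notes = "indeterminate MSI with no IHC loss"))
  }
  if (mmr == "proficient") {
    return(decision("proficient", rationale = "R1"))
  }

  lost <- pattern$lost
  plan <- character(0)
  fired <- character(0)
  notes <- character(0)

  if ("MLH1" %in% lost) {
    if (is.na(meth_tumor)) {
      return(decision("pending_methylation", rationale = "E2",
                      notes = "MLH1 lost; tumor methylation not measured"))
    }
    if (meth_tumor == "methylated") {
      # methylation explains the MLH1 loss; MLH1-branch takes precedence
      # over any co-occurring loss, so no gene plan is opened here
      if (!is.na(meth_blood) && meth_blood == "methylated") {
        return(decision("constitutional_epimutation_suspected",
                        rationale = "R2",
                        notes = "MLH1 methylation present in blood"))
      }
      if (is.na(meth_blood)) notes <- "blood unconfirmed"
      return(decision("sporadic_methylated", rationale = "R2",
                      notes = notes))
    }
    plan <- "MLH1"
    fired <- "R3"
  }
  if ("MSH2" %in% lost) {
    plan <- c(plan, "MSH2", "MSH6", "EPCAM")
    fired <- c(fired, "R4")
  }
  if ("MSH6" %in% lost && !("MSH2" %in% lost)) {
    plan <- c(plan, "MSH6")
    fired <- c(fired, "R5")
  }
  if ("PMS2" %in% lost && !("MLH1" %in% lost)) {
    plan <- c(plan, "PMS2")
    fired <- c(fired, "R6")
  }
  if (length(lost) == 0 && msi$status == "MSI") {
    plan <- c("MLH1", "MSH2", "MSH6", "PMS2")
    fired <- "R7"
  }
  decision("suspected_ls", plan = unique(plan), rationale = fired,
           notes = notes)
}

check_meth_call <- function(x, what) {
  if (length(x) != 1L) stop_input(what, " must be a single value")
  if (is.na(x)) return(NA_character_)
  x <- fold_token(x)
  if (!x %in% c("methylated", "unmethylated")) {
    stop_input(what, " must be 'methylated', 'unmethylated' or NA")
  }
  x
}

#' Next gene to test under a conditional testing plan
#'
#' Gene plans are worked through in order: a gene is sequenced only after
#' every earlier gene in the plan returned negative. A pathogenic result
#' anywhere closes the plan. A non-negative, non-pathogenic earlier result
#' (a variant of unknown significance) halts the automated plan — further
#' testing is a clinical-review call, not a rule.
#'
#' @param decision A `triage_decision` with label `"suspected_ls"`.
#' @param results Germline results so far: a data.frame with columns `gene`
#'   and `outcome` (`"pathogenic"`, `"vus"`, `"negative"`, `"not_done"`), or
#'   a named character vector `c(MSH2 = "negative", ...)`. Genes must belong
#'   to the decision's plan.
#' @return The gene symbol to test next, or `"done"`.
#' @export
#' @examples
#' d <- triage_patient(call_ihc_pattern(ihc_panel(msh2 = "lost", msh6 = "lost")),
#'                     call_msi(msi_panel(bat26 = "unstable", bat25 = "unstable")))
#' next_gene(d, c(MSH2 = "negative"))
next_gene <- function(decision, results = NULL) {
  stopifnot(inherits(decision, "triage_decision"))
  if (decision$label != "suspected_ls") {
    stop_input("next_gene applies only to suspected_ls decisions")
  }
  plan <- decision$gene_plan
  outcomes <- stats::setNames(rep("not_done", length(plan)), plan)
  if (!is.null(results)) {
    if (is.data.frame(results)) {
      res <- stats::setNames(as.character(results$outcome),
                             as.character(results$gene))
    } else {
      res <- stats::setNames(as.character(results), names(results))
    }
    bad_gene <- setdiff(names(res), plan)
    if (length(bad_gene)) {
      stop_input("results reference genes outside the plan: ",
                 paste(bad_gene, collapse = ", "))
    }
    bad_out <- setdiff(fold_token(res), germline_outcomes)
    if (length(bad_out)) {
      stop_input("unknown germline outcome: ", paste(bad_out, collapse = ", "))
    }
    outcomes[names(res)] <- fold_token(res)
  }
  if (any(outcomes == "pathogenic")) return("done")
  todo <- which(outcomes == "not_done")
  if (length(todo) == 0) return("done")
  i <- todo[1]
  if (i > 1 && !all(outcomes[seq_len(i - 1)] == "negative")) return("done")
  plan[i]
}

#' Two-antibody IHC screen (PMS2 + MSH6)
#'
#' PMS2 and MSH6 are the obligate, degradation-prone partners of the
#' MLH1-PMS2 and MSH2-MSH6 heterodimers, so loss of either captures loss of
#' any of the four proteins under the usual co-loss biology. This comparator
#' screens with those two stains only.
#'
#' @param panel An [ihc_panel()].
#' @return `"abnormal"`, `"normal"`, or `"indeterminate"` when both PMS2 and
#'   MSH6 stains are unreliable.
#' @export
#' @examples
#' two_antibody_triage(ihc_panel(mlh1 = "lost", pms2 = "lost"))
two_antibody_triage <- function(panel) {
  panel <- as_ihc_panel(panel)
  p <- panel[["pms2"]]
  m <- panel[["msh6"]]
  if (p == "unreliable" && m == "unreliable") return("indeterminate")
  if (p == "lost" || m == "lost") "abnormal" else "normal"
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("Triage decision: MMR %s -> %s\n", x$mmr, x$label))
  if (length(x$gene_plan)) {
    cat("  gene plan:", paste(x$gene_plan, collapse = " -> "), "\n")
  }
  cat("  rules fired:", paste(x$rationale, collapse = ", "), "\n")
  if (length(x$notes) && any(nzchar(x$notes))) {
    cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Triage every patient in a cohort table
#'
#' Runs the assay calls and the decision tree over a cohort table (see
#' [read_cohort()] for the expected columns) and returns one decision row
#' per patient.
#'
#' @param cohort A cohort data.frame with the assay columns
#'   `msi_bat26 ... msi_nr27`, `ihc_mlh1 ... ihc_pms2` and the
#'   `meth_tumor_probe3/4`, `meth_blood_probe3/4` ratios (NA = not
#'   measured).
#' @param config A [pipeline_config()].
#' @return A data.frame with one row per patient: `patient_id`,
#'   `msi_status`, `n_unstable`, `ihc_lost` (slash-joined protein names,
#'   `""` for none), `any_unreliable`, `meth_tumor`, `meth_blood`,
#'   `mmr_status`, `label`, `pattern` (screening-pattern category),
#'   `gene_plan` and `rationale` (semicolon-joined), `notes`.
#' @export
#' @examples
#' cohort <- paper_fixture()
#' decisions <- triage_cohort(cohort)
#' table(decisions$label)
triage_cohort <- function(cohort, config = pipeline_config()) {
  stopifnot(is.data.frame(cohort))
  need <- c(paste0("msi_", msi_markers), paste0("ihc_", tolower(mmr_proteins)))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop_input("cohort is missing assay columns: ",
               paste(missing_cols, collapse = ", "))
  }
  n <- nrow(cohort)
  ids <- if ("patient_id" %in% names(cohort)) {
    as.character(cohort$patient_id)
  } else {
    sprintf("P%03d", seq_len(n))
  }
  meth_col <- function(nm) {
    if (nm %in% names(cohort)) as.numeric(cohort[[nm]]) else rep(NA_real_, n)
  }
  tp3 <- meth_col("meth_tumor_probe3"); tp4 <- meth_col("meth_tumor_probe4")
  bp3 <- meth_col("meth_blood_probe3"); bp4 <- meth_col("meth_blood_probe4")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    msi <- call_msi(
      msi_panel(cohort$msi_bat26[i], cohort$msi_bat25[i], cohort$msi_nr21[i],
                cohort$msi_nr24[i], cohort$msi_nr27[i]),
      min_informative = config$msi_min_informative)
    pat <- call_ihc_pattern(
      ihc_panel(cohort$ihc_mlh1[i], cohort$ihc_msh2[i], cohort$ihc_msh6[i],
                cohort$ihc_pms2[i]))
    mt <- meth_call_from_probes(tp3[i], tp4[i], config$methylation_threshold)
    mb <- meth_call_from_probes(bp3[i], bp4[i], config$methylation_threshold)
    d <- triage_patient(pat, msi, meth_tumor = mt, meth_blood = mb)
    rows[[i]] <- data.frame(
      patient_id = ids[i],
      msi_status = msi$status,
      n_unstable = msi$n_unstable,
      ihc_lost = paste(pat$lost, collapse = "/"),
      any_unreliable = pat$any_unreliable,
      meth_tumor = mt,
      meth_blood = mb,
      mmr_status = d$mmr,
      label = d$label,
      pattern = screening_pattern(pat$lost, msi$status, mt),
      gene_plan = paste(d$gene_plan, collapse = ";"),
      rationale = paste(d$rationale, collapse = ";"),
      notes = paste(d$notes, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# mean-of-available-probes call; NA when neither probe was measured
meth_call_from_probes <- function(p3, p4, threshold) {
  if (is.na(p3) && is.na(p4)) return(NA_character_)
  ratio <- mean(c(p3, p4), na.rm = TRUE)
  if (ratio >= threshold) "methylated" else "unmethylated"
}

# screening-pattern category used for the per-pattern suspected counts
screening_pattern <- function(lost, msi_status, meth_tumor) {
  if ("MLH1" %in% lost) {
    if (is.na(meth_tumor)) return("mlh1_loss_pending")
    return(if (meth_tumor == "methylated") "mlh1_methylated"
           else "mlh1_unmethylated")
  }
  if ("MSH2" %in% lost) return("msh2_msh6")
  if (all(c("MSH6", "PMS2") %in% lost)) return("msh6_pms2")
  if ("MSH6" %in% lost) return("msh6")
  if ("PMS2" %in% lost) return("pms2")
  if (identical(msi_status, "MSI")) return("msi_normal_ihc")
  "none"
}
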