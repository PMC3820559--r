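#' @name synthetic-cohort
#' @title Reference fixture and seeded cohort simulator
#'
#' @description
#' Two cohort generators back the package's tests and examples:
#'
#' * [paper_fixture()] — a fully deterministic 173-patient endometrial-cancer
#'   cohort whose assay results, ages, family-history flags and germline
#'   outcomes reproduce every published screening margin (58 IHC loss, 47
#'   MSI, 61 MMR-deficient, 44 MLH1 loss with 34 tumor-methylated, 27
#'   suspected Lynch in the published per-pattern counts, 19 tested, 8
#'   pathogenic carriers with their published genes, ages and variants).
#' * [simulate_cohort()] — a seeded hierarchical simulator
#'   (deficiency -> loss pattern -> methylation -> testing attrition ->
#'   germline outcome) whose defaults ([default_params()]) are the published
#'   frequencies, for property and parameter-recovery testing.
NULL

screening_categories <- c("mlh1_methylated", "mlh1_unmethylated", "msh2_msh6",
                          "msh6", "pms2", "msh6_pms2", "msi_normal_ihc",
                          "proficient")

# deterministic integer "ages": n values summing to `total`, centred on
# total/n with a fixed zero-sum jitter, all within [lo, hi]
spread_ages <- function(n, total, lo, hi) {
  base <- total %/% n
  v <- rep(base, n)
  r <- total - base * n
  if (r > 0) v[seq_len(r)] <- v[seq_len(r)] + 1
  half <- n %/% 2
  if (half > 0) {
    k <- (seq_len(half) * 5) %% 13
    v[seq_len(half)] <- v[seq_len(half)] + k
    v[n + 1 - seq_len(half)] <- v[n + 1 - seq_len(half)] - k
  }
  stopifnot(sum(v) == total, all(v >= lo), all(v <= hi))
  as.integer(v)
}

#' Deterministic reference cohort (173 screened endometrial cancers)
#'
#' Builds, without any randomness, a cohort table whose margins equal the
#' published universal-screening study: the funnel
#' 173 -> 61 MMR-deficient -> 44 MLH1 loss -> 34 tumor-methylated ->
#' 27 suspected -> 19 tested -> 8 pathogenic; the suspected-pattern counts
#' (10 MLH1-loss unmethylated, 5 MSH2/MSH6, 7 MSH6, 1 PMS2, 1 MSH6/PMS2,
#' 3 MSI with intact IHC); 14 discordant loss+MSS and 3 MSI+intact tumors;
#' and the eight carriers' published identifiers, ages, MSI status, IHC
#' patterns, genes and variant labels. Group mean ages reproduce the
#' published comparison (57.70 suspected vs 64.31 otherwise; carrier mean
#' 49). Family-history availability (87 patients) encodes 38 patients
#' fulfilling only the revised Bethesda guidelines plus 4 fulfilling
#' Amsterdam II (and hence also Bethesda, reconciling the published counts
#' of 38 and 42), and 45 fulfilling neither.
#'
#' Details the publication leaves per-patient (which tumors among the MLH1
#' group are MSS, which methylated cases had blood tested, pathology-field
#' assignments) are fixed deterministically, lowest patient index first;
#' they are package choices, not published data.
#'
#' @return A cohort data.frame, one row per patient, with demographic,
#'   pathology, family-history, assay (`msi_*`, `ihc_*`, `meth_*`) and
#'   germline (`germline_*`) columns. Byte-identical across calls.
#' @export
#' @examples
#' cohort <- paper_fixture()
#' nrow(cohort)
paper_fixture <- function() {
  # group sizes along the screening funnel
  sizes <- c(mlh1_methylated = 34L, mlh1_unmethylated = 10L, msh2_msh6 = 5L,
             msh6 = 7L, pms2 = 1L, msh6_pms2 = 1L, msi_normal_ihc = 3L,
             proficient = 112L)
  n <- sum(sizes)                       # 173
  grp <- rep(names(sizes), sizes)
  gi <- unlist(lapply(sizes, seq_len), use.names = FALSE)  # index within group

  # the eight published carriers: group, row within group, and attributes
  carriers <- data.frame(
    id = c("End131", "End111", "End091", "End003", "End014", "End088",
           "End137", "End034"),
    group = c("mlh1_unmethylated", "msh2_msh6", "msh2_msh6", "msh2_msh6",
              "msh6", "msh6", "msi_normal_ihc", "pms2"),
    within = c(1L, 1L, 2L, 3L, 1L, 2L, 1L, 1L),
    age = c(41L, 45L, 40L, 60L, 61L, 45L, 56L, 44L),
    rbg = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    gene = c("MLH1", "MSH2", "MSH2", "MSH2", "MSH6", "MSH6", "MSH6", "PMS2"),
    variant = c("c.2154_2157insAACA (p.His718Glnfs*5)",
                "c.1-?_645+?del (deletion of exons 1-3)",
                "c.1226_1227delAG (p.Gln409Argfs*7)",
                "c.1387-?_1661del (deletion of exons 9-10)",
                "c.2731C>T (p.Arg911*)",
                "c.1367G>A (p.Trp456*)",
                "c.1367G>A (p.Trp456*)",
                "c.538-?_705+?del (deletion of exon 6)"),
    stringsAsFactors = FALSE)
  carrier_row <- match(paste(carriers$group, carriers$within),
                       paste(grp, gi))
  is_carrier <- seq_len(n) %in% carrier_row

  # patient identifiers: carriers keep their published IDs; everyone else is
  # numbered consecutively, skipping the carriers' numbers
  carrier_nums <- as.integer(sub("End", "", carriers$id))
  free_nums <- setdiff(seq_len(n + length(carrier_nums)), carrier_nums)
  patient_id <- character(n)
  patient_id[carrier_row] <- carriers$id
  patient_id[!is_carrier] <- sprintf("End%03d", free_nums[seq_len(n - 8L)])

  suspected_grp <- grp %in% c("mlh1_unmethylated", "msh2_msh6", "msh6",
                              "pms2", "msh6_pms2", "msi_normal_ihc")

  # --- MSI status ------------------------------------------------------------
  # 47 MSI / 126 MSS overall; 14 IHC-loss tumors are MSS: the published MSS
  # carriers End088 (MSH6) and End034 (PMS2), the two MSH6 VUS cases, and 10
  # tumors in the MLH1-methylated sporadic group (package choice)
  msi_status <- rep("MSI", n)
  msi_status[grp == "proficient"] <- "MSS"
  msi_status[grp == "mlh1_methylated" & gi > 24L] <- "MSS"   # 10 of 34
  msi_status[grp == "msh6" & gi %in% c(2L, 3L, 4L)] <- "MSS" # End088 + 2 VUS
  msi_status[grp == "pms2"] <- "MSS"                         # End034

  # markers: MSI tumors have BAT26+BAT25 unstable (every third also NR21)
  stable <- rep("stable", n)
  msi_bat26 <- msi_bat25 <- msi_nr21 <- msi_nr24 <- msi_nr27 <- stable
  is_msi <- msi_status == "MSI"
  msi_bat26[is_msi] <- "unstable"
  msi_bat25[is_msi] <- "unstable"
  third <- is_msi & (cumsum(is_msi) %% 3L == 0L)
  msi_nr21[third] <- "unstable"

  # --- IHC -------------------------------------------------------------------
  # heterodimer co-loss conventions: MLH1 loss is encoded as MLH1+PMS2,
  # MSH2 loss as MSH2+MSH6
  retained <- rep("retained", n)
  ihc_mlh1 <- ihc_msh2 <- ihc_msh6 <- ihc_pms2 <- retained
  mlh1_grp <- grp %in% c("mlh1_methylated", "mlh1_unmethylated")
  ihc_mlh1[mlh1_grp] <- "lost"
  ihc_pms2[mlh1_grp | grp %in% c("pms2", "msh6_pms2")] <- "lost"
  ihc_msh2[grp == "msh2_msh6"] <- "lost"
  ihc_msh6[grp %in% c("msh2_msh6", "msh6", "msh6_pms2")] <- "lost"

  # --- MLH1 methylation (MS-MLPA probe ratios) -------------------------------
  meth_tumor_probe3 <- meth_tumor_probe4 <- rep(NA_real_, n)
  meth_blood_probe3 <- meth_blood_probe4 <- rep(NA_real_, n)
  meth_tumor_probe3[grp == "mlh1_methylated"] <- 0.35
  meth_tumor_probe4[grp == "mlh1_methylated"] <- 0.45
  meth_tumor_probe3[grp == "mlh1_unmethylated"] <- 0.04
  meth_tumor_probe4[grp == "mlh1_unmethylated"] <- 0.06
  # blood DNA was available for nine methylated cases, all blood-unmethylated
  blood_tested <- grp == "mlh1_methylated" & gi <= 9L
  meth_blood_probe3[blood_tested] <- 0.01
  meth_blood_probe4[blood_tested] <- 0.03

  # --- germline testing ------------------------------------------------------
  # per-pattern tested counts 6/4/5/1/1/2 (pathogenic 1/3/2/1/0/1); the
  # tested are the lowest rows of each group, carriers first
  gl <- matrix("not_done", nrow = n, ncol = 5,
               dimnames = list(NULL, c("MLH1", "MSH2", "MSH6", "PMS2",
                                       "EPCAM")))
  germline_variant <- rep(NA_character_, n)
  gl[carrier_row, ] <- "not_done"
  for (k in seq_len(nrow(carriers))) {
    r <- carrier_row[k]
    plan <- switch(carriers$group[k],
                   mlh1_unmethylated = "MLH1",
                   msh2_msh6 = c("MSH2", "MSH6", "EPCAM"),
                   msh6 = "MSH6",
                   pms2 = "PMS2",
                   msi_normal_ihc = c("MLH1", "MSH2", "MSH6", "PMS2"))
    hit <- match(carriers$gene[k], plan)
    if (hit > 1) gl[r, plan[seq_len(hit - 1)]] <- "negative"
    gl[r, carriers$gene[k]] <- "pathogenic"
    germline_variant[r] <- carriers$variant[k]
  }
  # non-carrier tested rows
  set_gl <- function(group, within, genes, outcome) {
    r <- which(grp == group & gi == within)
    gl[r, genes] <<- outcome
  }
  for (w in 2:6) set_gl("mlh1_unmethylated", w, "MLH1", "negative")
  set_gl("msh2_msh6", 4L, c("MSH2", "MSH6", "EPCAM"), "negative")
  set_gl("msh6", 3L, "MSH6", "vus")
  set_gl("msh6", 4L, "MSH6", "vus")
  set_gl("msh6", 5L, "MSH6", "negative")
  set_gl("msh6_pms2", 1L, c("MSH6", "PMS2"), "negative")
  set_gl("msi_normal_ihc", 2L, c("MLH1", "MSH2", "MSH6", "PMS2"), "negative")
  germline_variant[which(grp == "msh6" & gi == 3L)] <-
    "c.116G>A (p.Gly39Glu), unknown significance"
  germline_variant[which(grp == "msh6" & gi == 4L)] <-
    "c.1109T>C (p.Leu370Ser), unknown significance"

  # --- ages ------------------------------------------------------------------
  # suspected group: carriers keep published ages; the 19 remaining ages are
  # fixed so the group mean is exactly 57.70 with 7 patients under 50
  age <- integer(n)
  age[carrier_row] <- carriers$age
  non_carrier_susp <- which(suspected_grp & !is_carrier)
  age[non_carrier_susp] <- c(46L, 48L, 52L, 54L, 56L, 58L, 60L, 61L, 62L,
                             63L, 64L, 65L, 66L, 67L, 68L, 70L, 72L, 74L,
                             60L)
  # non-suspected: 16 patients under 50 and a deterministic spread of 130
  # ages >= 50, group mean 64.31
  young <- c(29L, 33L, 35L, 37L, 39L, 40L, 41L, 42L, 43L, 44L, 45L, 46L,
             47L, 48L, 49L, 44L)
  old <- spread_ages(130L, 9389L - sum(young), 50L, 90L)
  age[grp == "mlh1_methylated"] <- old[1:34]
  age[grp == "proficient"] <- c(young, old[35:130])

  # --- family history (87 patients evaluable) --------------------------------
  # carriers + the 60 lowest non-suspected + the 19 non-carrier suspected;
  # 42 fulfil revised Bethesda, of whom 4 also fulfil Amsterdam II
  rbg <- rep(NA, n)
  amii <- rep(NA, n)
  rbg[carrier_row] <- carriers$rbg
  amii[carrier_row] <- FALSE
  ncs <- non_carrier_susp
  rbg[ncs] <- rep(c(TRUE, FALSE), c(8L, 11L))
  amii[ncs] <- rep(c(FALSE, TRUE, FALSE), c(5L, 3L, 11L))
  other_avail <- which(!suspected_grp)[1:60]
  rbg[other_avail] <- rep(c(TRUE, FALSE), c(28L, 32L))
  amii[other_avail] <- rep(c(FALSE, TRUE, FALSE), c(27L, 1L, 32L))

  # --- pathology fields (published margins; joint distribution with the
  # suspected label follows the published comparison table) ------------------
  susp_idx <- which(suspected_grp)
  other_idx <- which(!suspected_grp)
  fill2 <- function(n_susp_yes, n_susp_no, n_other_yes, n_other_no,
                    yes = TRUE, no = FALSE, force_yes = integer(0),
                    force_no = integer(0)) {
    v <- rep(if (is.character(yes)) NA_character_ else NA, n)
    v[force_yes] <- yes
    v[force_no] <- no
    s <- setdiff(susp_idx, c(force_yes, force_no))
    ky <- n_susp_yes - sum(force_yes %in% susp_idx)
    kn <- n_susp_no - sum(force_no %in% susp_idx)
    v[s[seq_len(ky)]] <- yes
    v[s[ky + seq_len(kn)]] <- no
    v[other_idx[seq_len(n_other_yes)]] <- yes
    v[other_idx[n_other_yes + seq_len(n_other_no)]] <- no
    v
  }
  grade_high <- fill2(9L, 18L, 40L, 106L)
  grade <- ifelse(grade_high, 3L, NA_integer_)
  low <- which(!grade_high)                      # 124 tumors: 95 G1 + 29 G2
  grade[low] <- rep(c(1L, 2L), c(95L, 29L))
  histology_type <- fill2(5L, 22L, 23L, 123L, yes = "type_ii", no = "type_i")
  histology <- rep(NA_character_, n)
  histology[histology_type == "type_i"] <-
    rep(c("endometrioid", "poorly_differentiated"), c(137L, 8L))
  histology[histology_type == "type_ii"] <-
    rep(c("papillary_serous", "clear_cell", "mixed_mullerian"),
        c(13L, 11L, 4L))
  myo <- fill2(6L, 18L, 32L, 90L, yes = "gt50", no = "le50")
  myo[which(myo == "le50" & !suspected_grp)[1:15]] <- "none"
  til <- fill2(9L, 18L, 38L, 95L)
  lvi <- fill2(7L, 16L, 17L, 94L)
  lus <- fill2(4L, 23L, 12L, 134L)
  # synchronous ovarian cancers: carriers End091 and End088 are two of the
  # five suspected cases; the other carriers' synchronous lesions were not
  # ovarian
  ov_carriers <- carriers$id %in% c("End091", "End088")
  sync_ov <- fill2(5L, 22L, 22L, 103L,
                   force_yes = carrier_row[ov_carriers],
                   force_no = carrier_row[!ov_carriers])
  stage <- rep(NA_character_, n)
  stage[1:158] <- rep(c("I", "II", "III", "IV"), c(119L, 6L, 31L, 2L))
  hist_crc <- rep("none", n)
  hist_crc[carrier_row[carriers$id == "End111"]] <- "colon_cancer"
  hist_crc[carrier_row[carriers$id == "End131"]] <- "polyp"
  free <- which(hist_crc == "none")
  hist_crc[free[1:6]] <- rep(c("colon_cancer", "polyp"), c(5L, 1L))
  hist_other <- rep("none", n)
  free <- which(hist_crc == "none")
  hist_other[free[1:15]] <- rep(c("breast", "lung", "pleura", "thyroid",
                                  "urothelial"), c(10L, 2L, 1L, 1L, 1L))

  data.frame(
    patient_id = patient_id, age = as.integer(age), rbg = rbg, amii = amii,
    stage = stage, histology = histology, histology_type = histology_type,
    grade = grade, myometrial_invasion = myo, til = til, lvi = lvi,
    lus = lus, sync_ovarian = sync_ov,
    history_colorectal = hist_crc, history_other = hist_other,
    msi_bat26 = msi_bat26, msi_bat25 = msi_bat25, msi_nr21 = msi_nr21,
    msi_nr24 = msi_nr24, msi_nr27 = msi_nr27,
    ihc_mlh1 = ihc_mlh1, ihc_msh2 = ihc_msh2, ihc_msh6 = ihc_msh6,
    ihc_pms2 = ihc_pms2,
    meth_tumor_probe3 = meth_tumor_probe3,
    meth_tumor_probe4 = meth_tumor_probe4,
    meth_blood_probe3 = meth_blood_probe3,
    meth_blood_probe4 = meth_blood_probe4,
    germline_mlh1 = gl[, "MLH1"], germline_msh2 = gl[, "MSH2"],
    germline_msh6 = gl[, "MSH6"], germline_pms2 = gl[, "PMS2"],
    germline_epcam = gl[, "EPCAM"],
    germline_variant = germline_variant,
    stringsAsFactors = FALSE)
}

#' Simulation parameters for the cohort simulator
#'
#' @param n_patients Cohort size.
#' @param p_deficient Probability a tumor is MMR-deficient.
#' @param p_mlh1_loss_given_deficient Probability a deficient tumor shows
#'   MLH1 loss.
#' @param p_methylated_given_mlh1_loss Probability an MLH1-loss tumor is
#'   promoter-methylated (sporadic).
#' @param pattern_weights Named weights (summing to 1) over the non-MLH1
#'   deficiency patterns `msh2_msh6`, `msh6`, `pms2`, `msh6_pms2`,
#'   `msi_normal_ihc`.
#' @param p_mss_given_loss Probability an IHC-loss tumor is nonetheless MSS
#'   (IHC/MSI discordance).
#' @param p_blood_tested_given_methylated Probability blood DNA is analysed
#'   after a methylated tumor.
#' @param p_blood_methylated_given_tested Probability that analysed blood is
#'   methylated (constitutional epimutation).
#' @param p_tested_given_suspected Probability a suspected patient completes
#'   germline testing (counseling attrition).
#' @param p_pathogenic_given_tested Probability a tested patient carries a
#'   pathogenic mutation.
#' @param age_suspected_mean,age_suspected_sd,age_other_mean,age_other_sd
#'   Normal age moments for suspected vs non-suspected patients (years).
#' @param age_min,age_max Ages outside this range are resampled.
#' @param seed Default seed used by [simulate_cohort()].
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 173,
                              p_deficient = 61 / 173,
                              p_mlh1_loss_given_deficient = 44 / 61,
                              p_methylated_given_mlh1_loss = 34 / 44,
                              pattern_weights = c(msh2_msh6 = 5 / 17,
                                                  msh6 = 7 / 17,
                                                  pms2 = 1 / 17,
                                                  msh6_pms2 = 1 / 17,
                                                  msi_normal_ihc = 3 / 17),
                              p_mss_given_loss = 14 / 58,
                              p_blood_tested_given_methylated = 9 / 34,
                              p_blood_methylated_given_tested = 0,
                              p_tested_given_suspected = 19 / 27,
                              p_pathogenic_given_tested = 8 / 19,
                              age_suspected_mean = 57.70,
                              age_suspected_sd = 12.45,
                              age_other_mean = 64.31,
                              age_other_sd = 12.12,
                              age_min = 29, age_max = 90,
                              seed = 1L) {
  p <- list(n_patients = n_patients, p_deficient = p_deficient,
            p_mlh1_loss_given_deficient = p_mlh1_loss_given_deficient,
            p_methylated_given_mlh1_loss = p_methylated_given_mlh1_loss,
            pattern_weights = pattern_weights,
            p_mss_given_loss = p_mss_given_loss,
            p_blood_tested_given_methylated = p_blood_tested_given_methylated,
            p_blood_methylated_given_tested = p_blood_methylated_given_tested,
            p_tested_given_suspected = p_tested_given_suspected,
            p_pathogenic_given_tested = p_pathogenic_given_tested,
            age_suspected_mean = age_suspected_mean,
            age_suspected_sd = age_suspected_sd,
            age_other_mean = age_other_mean,
            age_other_sd = age_other_sd,
            age_min = age_min, age_max = age_max, seed = seed)
  probs <- grep("^p_", names(p), value = TRUE)
  bad <- probs[!vapply(p[probs], is_probability, logical(1))]
  if (!is_scalar_number(p$n_patients) || p$n_patients < 1 ||
      p$n_patients != round(p$n_patients)) {
    bad <- c(bad, "n_patients")
  }
  w <- p$pattern_weights
  if (!is.numeric(w) || is.null(names(w)) ||
      !setequal(names(w), c("msh2_msh6", "msh6", "pms2", "msh6_pms2",
                            "msi_normal_ihc")) ||
      any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    bad <- c(bad, "pattern_weights")
  }
  if (!is_scalar_number(p$age_suspected_sd) || p$age_suspected_sd <= 0) {
    bad <- c(bad, "age_suspected_sd")
  }
  if (!is_scalar_number(p$age_other_sd) || p$age_other_sd <= 0) {
    bad <- c(bad, "age_other_sd")
  }
  if (p$age_min >= p$age_max) bad <- c(bad, "age_min/age_max")
  if (length(bad)) {
    stop_input("invalid simulation parameter(s): ",
               paste(unique(bad), collapse = ", "))
  }
  structure(p, class = "simulation_params")
}

#' Default simulation parameters (published frequencies)
#'
#' The published cohort frequencies as simulator defaults: 61/173 deficient,
#' 44/61 MLH1 loss among deficient, 34/44 methylated, 19/27 tested, 8/19
#' pathogenic, 14/58 loss-with-MSS discordance, and the published group age
#' moments.
#'
#' @return A `simulation_params` object.
#' @export
#' @examples
#' default_params()$p_pathogenic_given_tested   # 8/19
default_params <- function() simulation_params()

#' Simulate a screening cohort
#'
#' Draws patients through the hierarchical scheme deficiency -> loss
#' pattern -> methylation -> (triage-implied) suspicion -> testing
#' attrition -> germline outcome. Assay observations (marker statuses,
#' probe ratios) are drawn so that the assay calls reproduce the assigned
#' category; ages come from the group-specific truncated normal
#' distributions. Fully reproducible from the seed.
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A cohort data.frame with `patient_id`, `age`, the assay and
#'   germline columns of [paper_fixture()], plus `sim_category`, the true
#'   generating category of each patient.
#' @export
#' @examples
#' sim <- simulate_cohort(default_params(), seed = 7)
#' table(sim$sim_category)
simulate_cohort <- function(params = default_params(), seed = params$seed) {
  if (!inherits(params, "simulation_params")) {
    params <- do.call(simulation_params, as.list(params))
  }
  set.seed(seed)
  n <- as.integer(params$n_patients)

  rtrunc_age <- function(n, mean, sd) {
    out <- round(stats::rnorm(n, mean, sd))
    bad <- which(out < params$age_min | out > params$age_max)
    while (length(bad)) {
      out[bad] <- round(stats::rnorm(length(bad), mean, sd))
      bad <- which(out < params$age_min | out > params$age_max)
    }
    as.integer(out)
  }

  deficient <- stats::runif(n) < params$p_deficient
  category <- rep("proficient", n)
  for (i in which(deficient)) {
    if (stats::runif(1) < params$p_mlh1_loss_given_deficient) {
      category[i] <- if (stats::runif(1) <
                           params$p_methylated_given_mlh1_loss) {
        "mlh1_methylated"
      } else {
        "mlh1_unmethylated"
      }
    } else {
      category[i] <- sample(names(params$pattern_weights), 1,
                            prob = params$pattern_weights)
    }
  }

  loss_cat <- category %in% c("mlh1_methylated", "mlh1_unmethylated",
                              "msh2_msh6", "msh6", "pms2", "msh6_pms2")
  msi_status <- ifelse(category == "proficient", "MSS", "MSI")
  discordant <- loss_cat & stats::runif(n) < params$p_mss_given_loss
  msi_status[discordant] <- "MSS"

  blank <- function(fill) rep(fill, n)
  msi_mk <- matrix("stable", n, 5,
                   dimnames = list(NULL, paste0("msi_", msi_markers)))
  for (i in which(msi_status == "MSI")) {
    k <- sample(2:5, 1, prob = c(0.35, 0.35, 0.2, 0.1))
    msi_mk[i, sample(5, k)] <- "unstable"
  }

  ihc <- matrix("retained", n, 4,
                dimnames = list(NULL, paste0("ihc_", tolower(mmr_proteins))))
  ihc[category %in% c("mlh1_methylated", "mlh1_unmethylated"),
      c("ihc_mlh1", "ihc_pms2")] <- "lost"
  ihc[category == "msh2_msh6", c("ihc_msh2", "ihc_msh6")] <- "lost"
  ihc[category %in% c("msh6", "msh6_pms2"), "ihc_msh6"] <- "lost"
  ihc[category %in% c("pms2", "msh6_pms2"), "ihc_pms2"] <- "lost"

  tp3 <- blank(NA_real_); tp4 <- blank(NA_real_)
  bp3 <- blank(NA_real_); bp4 <- blank(NA_real_)
  meth <- category == "mlh1_methylated"
  unmeth <- category == "mlh1_unmethylated"
  tp3[meth] <- stats::runif(sum(meth), 0.18, 0.80)
  tp4[meth] <- stats::runif(sum(meth), 0.18, 0.80)
  tp3[unmeth] <- stats::runif(sum(unmeth), 0, 0.10)
  tp4[unmeth] <- stats::runif(sum(unmeth), 0, 0.10)
  blood <- meth & stats::runif(n) < params$p_blood_tested_given_methylated
  blood_meth <- blood & stats::runif(n) < params$p_blood_methylated_given_tested
  bp3[blood] <- stats::runif(sum(blood), 0, 0.10)
  bp4[blood] <- stats::runif(sum(blood), 0, 0.10)
  bp3[blood_meth] <- stats::runif(sum(blood_meth), 0.18, 0.80)
  bp4[blood_meth] <- stats::runif(sum(blood_meth), 0.18, 0.80)

  suspected_cat <- category %in% c("mlh1_unmethylated", "msh2_msh6", "msh6",
                                   "pms2", "msh6_pms2", "msi_normal_ihc") &
    !(blood_meth)
  tested <- suspected_cat & stats::runif(n) < params$p_tested_given_suspected
  pathogenic <- tested & stats::runif(n) < params$p_pathogenic_given_tested

  gl <- matrix("not_done", n, 5,
               dimnames = list(NULL, paste0("germline_", tolower(ls_genes))))
  plan_for <- function(cat) {
    switch(cat,
           mlh1_unmethylated = "MLH1",
           msh2_msh6 = c("MSH2", "MSH6", "EPCAM"),
           msh6 = "MSH6",
           pms2 = "PMS2",
           msh6_pms2 = c("MSH6", "PMS2"),
           msi_normal_ihc = c("MLH1", "MSH2", "MSH6", "PMS2"))
  }
  for (i in which(tested)) {
    plan <- plan_for(category[i])
    cols <- paste0("germline_", tolower(plan))
    if (pathogenic[i]) {
      gl[i, cols[1]] <- "pathogenic"
    } else {
      gl[i, cols] <- "negative"
    }
  }

  age <- integer(n)
  age[suspected_cat] <- rtrunc_age(sum(suspected_cat),
                                   params$age_suspected_mean,
                                   params$age_suspected_sd)
  age[!suspected_cat] <- rtrunc_age(sum(!suspected_cat),
                                    params$age_other_mean,
                                    params$age_other_sd)

  cbind(
    data.frame(patient_id = sprintf("S%04d", seq_len(n)), age = age,
               sim_category = category, stringsAsFactors = FALSE),
    as.data.frame(msi_mk, stringsAsFactors = FALSE),
    as.data.frame(ihc, stringsAsFactors = FALSE),
    data.frame(meth_tumor_probe3 = tp3, meth_tumor_probe4 = tp4,
               meth_blood_probe3 = bp3, meth_blood_probe4 = bp4),
    as.data.frame(gl, stringsAsFactors = FALSE),
    data.frame(germline_variant = rep(NA_character_, n),
               stringsAsFactors = FALSE))
}
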