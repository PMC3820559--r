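cohort <- paper_fixture()
decisions <- triage_cohort(cohort)
cascade <- cascade_summary(decisions, cohort)

test_that("reference cohort reproduces every published assay margin", {
  expect_identical(nrow(cohort), 173L)
  any_loss <- cohort$ihc_mlh1 == "lost" | cohort$ihc_msh2 == "lost" |
    cohort$ihc_msh6 == "lost" | cohort$ihc_pms2 == "lost"
  expect_identical(sum(any_loss), 58L)
  expect_identical(sum(decisions$msi_status == "MSI"), 47L)
  expect_identical(cascade$n_mmr_deficient, 61L)
  expect_identical(cascade$n_loss_mss, 14L)
  expect_identical(cascade$n_msi_intact, 3L)
  expect_identical(cascade$n_mlh1_loss, 44L)
  expect_identical(cascade$n_mlh1_methylated, 34L)
  # nine methylated cases had blood analysed, none blood-methylated
  blood <- !is.na(cohort$meth_blood_probe3) | !is.na(cohort$meth_blood_probe4)
  expect_identical(sum(blood), 9L)
  expect_identical(sum(blood & decisions$meth_tumor == "methylated"), 9L)
  expect_identical(sum(decisions$meth_blood == "methylated", na.rm = TRUE), 0L)
  # suspected patterns
  expect_identical(unname(cascade$pattern_counts),
                   c(10L, 5L, 7L, 1L, 1L, 3L))
  expect_identical(cascade$n_suspected, 27L)
  expect_identical(cascade$n_tested, 19L)
  expect_identical(cascade$n_pathogenic, 8L)
  expect_identical(cascade$n_concordant, 156L)
})

test_that("reference cohort reproduces the published carrier table", {
  carriers <- data.frame(
    id = c("End131", "End111", "End091", "End003", "End014", "End088",
           "End137", "End034"),
    age = c(41, 45, 40, 60, 61, 45, 56, 44),
    msi = c("MSI", "MSI", "MSI", "MSI", "MSI", "MSS", "MSI", "MSS"),
    lost = c("MLH1/PMS2", "MSH2/MSH6", "MSH2/MSH6", "MSH2/MSH6", "MSH6",
             "MSH6", "", "PMS2"),
    gene = c("MLH1", "MSH2", "MSH2", "MSH2", "MSH6", "MSH6", "MSH6", "PMS2"),
    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(carriers))) {
    i <- match(carriers$id[k], cohort$patient_id)
    expect_false(is.na(i))
    expect_identical(cohort$age[i], as.integer(carriers$age[k]))
    j <- match(carriers$id[k], decisions$patient_id)
    expect_identical(decisions$msi_status[j], carriers$msi[k])
    expect_identical(decisions$ihc_lost[j], carriers$lost[k])
    expect_identical(cohort[[paste0("germline_",
                                    tolower(carriers$gene[k]))]][i],
                     "pathogenic")
    expect_identical(decisions$label[j], "suspected_ls")
  }
  expect_equal(mean(carriers$age), 49)
  # gene spectrum: 1 MLH1, 3 MSH2, 3 MSH6, 1 PMS2
  expect_identical(sum(cohort$germline_mlh1 == "pathogenic"), 1L)
  expect_identical(sum(cohort$germline_msh2 == "pathogenic"), 3L)
  expect_identical(sum(cohort$germline_msh6 == "pathogenic"), 3L)
  expect_identical(sum(cohort$germline_pms2 == "pathogenic"), 1L)
})

test_that("reference cohort reproduces the clinical-table margins", {
  # family history available for 87; 38 Bethesda-only, 4 Amsterdam II
  # (also Bethesda), 45 neither
  expect_identical(sum(!is.na(cohort$rbg)), 87L)
  expect_identical(sum(cohort$rbg & !cohort$amii, na.rm = TRUE), 38L)
  expect_identical(sum(cohort$amii, na.rm = TRUE), 4L)
  expect_identical(sum(cohort$rbg, na.rm = TRUE), 42L)
  expect_identical(sum(!cohort$rbg & !cohort$amii, na.rm = TRUE), 45L)
  # pathology margins with their published denominators
  expect_identical(as.integer(table(cohort$stage)[c("I", "II", "III", "IV")]),
                   c(119L, 6L, 31L, 2L))
  expect_identical(sum(!is.na(cohort$stage)), 158L)
  expect_identical(sum(cohort$histology == "endometrioid"), 137L)
  expect_identical(as.integer(table(cohort$grade)[c("1", "2", "3")]),
                   c(95L, 29L, 49L))
  myo <- table(cohort$myometrial_invasion)
  expect_identical(as.integer(myo[c("none", "le50", "gt50")]), c(15L, 93L, 38L))
  expect_identical(sum(!is.na(cohort$myometrial_invasion)), 146L)
  expect_identical(sum(cohort$til, na.rm = TRUE), 47L)
  expect_identical(sum(!is.na(cohort$til)), 160L)
  expect_identical(sum(cohort$lvi, na.rm = TRUE), 24L)
  expect_identical(sum(!is.na(cohort$lvi)), 134L)
  expect_identical(sum(cohort$lus), 16L)
  expect_identical(sum(!is.na(cohort$sync_ovarian)), 152L)
  expect_identical(sum(cohort$history_colorectal == "colon_cancer"), 6L)
  expect_identical(sum(cohort$history_colorectal == "polyp"), 2L)
  expect_identical(sum(cohort$history_other == "breast"), 10L)
  # ages: published group means and range
  suspected <- decisions$label == "suspected_ls"
  expect_equal(round_half_up(mean(cohort$age[suspected]), 2), 57.70)
  expect_equal(round_half_up(mean(cohort$age[!suspected]), 2), 64.31)
  expect_identical(sum(suspected & cohort$age < 50), 7L)
  expect_identical(sum(!suspected & cohort$age < 50), 16L)
  expect_true(all(cohort$age >= 29 & cohort$age <= 90))
  # published joint distribution with the suspected label
  expect_identical(sum(suspected & cohort$sync_ovarian, na.rm = TRUE), 5L)
  expect_identical(sum(!suspected & cohort$sync_ovarian, na.rm = TRUE), 22L)
  expect_identical(sum(suspected & cohort$grade == 3), 9L)
  expect_identical(sum(suspected & cohort$til, na.rm = TRUE), 9L)
  expect_identical(sum(suspected & cohort$lvi, na.rm = TRUE), 7L)
  expect_identical(sum(suspected & cohort$lus), 4L)
  expect_identical(sum(suspected & cohort$rbg, na.rm = TRUE), 14L)
})

test_that("reference cohort and its triage are deterministic", {
  expect_identical(cohort, paper_fixture())
  expect_identical(decisions, triage_cohort(paper_fixture()))
})

test_that("simulator respects degenerate and extreme parameters", {
  p0 <- simulation_params(p_deficient = 0, n_patients = 60)
  sim <- simulate_cohort(p0, seed = 3)
  expect_true(all(sim$sim_category == "proficient"))
  cs <- cascade_summary(triage_cohort(sim), sim)
  expect_identical(cs$n_mmr_deficient, 0L)
  expect_identical(cs$n_suspected, 0L)
  expect_equal(cs$prevalence_observed, 0)
  # full testing uptake and yield: prevalence equals the suspected fraction
  p1 <- simulation_params(p_tested_given_suspected = 1,
                          p_pathogenic_given_tested = 1)
  sim1 <- simulate_cohort(p1, seed = 4)
  cs1 <- cascade_summary(triage_cohort(sim1), sim1)
  expect_identical(cs1$n_tested, cs1$n_suspected)
  expect_equal(cs1$prevalence_observed, cs1$n_suspected / cs1$n_total)
})

test_that("simulator is seed-deterministic and parameters are validated", {
  params <- default_params()
  expect_identical(simulate_cohort(params, seed = 42),
                   simulate_cohort(params, seed = 42))
  s1 <- simulate_cohort(params, seed = 1)
  s2 <- simulate_cohort(params, seed = 2)
  expect_false(identical(s1, s2))
  expect_error(simulation_params(p_deficient = 1.2), "p_deficient")
  expect_error(simulation_params(p_deficient = -0.1, n_patients = 0),
               "p_deficient.*n_patients|n_patients.*p_deficient")
  expect_error(simulation_params(pattern_weights = c(msh6 = 1)),
               "pattern_weights")
  expect_error(simulation_params(age_suspected_sd = 0), "age_suspected_sd")
})

test_that("default parameters are the published frequencies", {
  p <- default_params()
  expect_equal(p$p_pathogenic_given_tested, 8 / 19)
  expect_equal(p$p_methylated_given_mlh1_loss, 34 / 44)
  expect_equal(p$p_deficient, 61 / 173)
  expect_equal(p$p_tested_given_suspected, 19 / 27)
  expect_equal(sum(p$pattern_weights), 1)
  # validates against its own invariants
  expect_s3_class(do.call(simulation_params, unclass(p)),
                  "simulation_params")
})

test_that("simulated cascade counts sit within binomial sampling error", {
  params <- default_params()
  n <- params$n_patients
  sim <- simulate_cohort(params, seed = 12)
  cs <- cascade_summary(triage_cohort(sim), sim)
  # marginal probabilities implied by the hierarchical scheme
  p_def <- params$p_deficient
  p_susp <- p_def * (params$p_mlh1_loss_given_deficient *
                       (1 - params$p_methylated_given_mlh1_loss) +
                       (1 - params$p_mlh1_loss_given_deficient))
  p_path <- p_susp * params$p_tested_given_suspected *
    params$p_pathogenic_given_tested
  within3se <- function(obs, p) {
    abs(obs - n * p) <= 3 * sqrt(n * p * (1 - p)) + 1e-9
  }
  expect_true(within3se(cs$n_mmr_deficient, p_def))
  expect_true(within3se(cs$n_suspected, p_susp))
  expect_true(within3se(cs$n_pathogenic, p_path))
})

test_that("methylated-sporadic simulated patients are never called suspected", {
  params <- default_params()
  for (seed in 1:20) {
    sim <- simulate_cohort(params, seed = seed)
    dec <- triage_cohort(sim)
    meth <- sim$sim_category == "mlh1_methylated"
    expect_false(any(dec$label[meth] == "suspected_ls"))
    # and assay calls always reproduce the generating category
    expect_identical(dec$meth_tumor[meth] == "methylated",
                     rep(TRUE, sum(meth)))
    susp_cat <- sim$sim_category %in% c("mlh1_unmethylated", "msh2_msh6",
                                        "msh6", "pms2", "msh6_pms2",
                                        "msi_normal_ihc")
    expect_identical(dec$label == "suspected_ls", susp_cat)
  }
})
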