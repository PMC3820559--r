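# helpers shared across test files

# one cohort row with every assay column, defaulting to a proficient tumor
make_row <- function(id = "P1", age = 60,
                     msi = c("stable", "stable", "stable", "stable", "stable"),
                     ihc = c("retained", "retained", "retained", "retained"),
                     tumor_probes = c(NA, NA), blood_probes = c(NA, NA),
                     germline = rep("not_done", 5)) {
  data.frame(patient_id = id, age = age,
             msi_bat26 = msi[1], msi_bat25 = msi[2], msi_nr21 = msi[3],
             msi_nr24 = msi[4], msi_nr27 = msi[5],
             ihc_mlh1 = ihc[1], ihc_msh2 = ihc[2], ihc_msh6 = ihc[3],
             ihc_pms2 = ihc[4],
             meth_tumor_probe3 = as.numeric(tumor_probes[1]),
             meth_tumor_probe4 = as.numeric(tumor_probes[2]),
             meth_blood_probe3 = as.numeric(blood_probes[1]),
             meth_blood_probe4 = as.numeric(blood_probes[2]),
             germline_mlh1 = germline[1], germline_msh2 = germline[2],
             germline_msh6 = germline[3], germline_pms2 = germline[4],
             germline_epcam = germline[5],
             stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows)) rows[[i]]$patient_id <- sprintf("P%02d", i)
  do.call(rbind, rows)
}

# an MSI panel with the given number of unstable and failed markers
panel_with <- function(n_unstable, n_failed = 0) {
  status <- rep("stable", 5)
  if (n_unstable > 0) status[seq_len(n_unstable)] <- "unstable"
  if (n_failed > 0) status[n_unstable + seq_len(n_failed)] <- "failed"
  do.call(msi_panel, as.list(status))
}

# random valid 2x2 with non-degenerate margins
random_table <- function(max_cell = 8) {
  repeat {
    t <- sample(0:max_cell, 4, replace = TRUE)
    if ((t[1] + t[2]) > 0 && (t[3] + t[4]) > 0 &&
        (t[1] + t[3]) > 0 && (t[2] + t[4]) > 0) {
      return(contingency_2x2(t[1], t[2], t[3], t[4]))
    }
  }
}

# construct a vector with exactly the given sample mean and sd
vector_with_moments <- function(n, mean, sd) {
  x <- seq_len(n)
  mean + sd * as.numeric(scale(x))
}
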