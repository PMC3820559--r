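#' @name cohort-stats
#' @title Cohort-level accounting and association statistics
#'
#' @description
#' Screening-funnel accounting ([cascade_summary()], [predictive_frequency()])
#' and the 2x2 association statistics used to compare suspected-Lynch with
#' MMR-proficient patients: odds ratios with Woolf (log-OR normal) or exact
#' conditional confidence intervals, the Pearson chi-squared test without
#' continuity correction, and a pooled-variance Student t-test computed from
#' group summary statistics.
NULL

#' Construct a 2x2 contingency table
#'
#' Layout: `a`, `b` are exposure yes/no in group 1; `c`, `d` exposure yes/no
#' in group 2, so the odds ratio is `a*d / (b*c)`.
#'
#' @param a,b,c,d Non-negative counts.
#' @return A named numeric vector of class `table2x2`.
#' @export
#' @examples
#' contingency_2x2(7, 20, 16, 130)
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (!is.numeric(x) || length(x) != 4L || anyNA(x)) {
    stop_input("a, b, c, d must be single non-missing numbers")
  }
  if (any(x < 0)) stop_input("counts must be non-negative")
  if (sum(x) <= 0) stop_input("table total must be positive")
  structure(as.numeric(x), names = c("a", "b", "c", "d"), class = "table2x2")
}

as_table2x2 <- function(t) {
  if (inherits(t, "table2x2")) return(t)
  if (is.matrix(t) && all(dim(t) == 2L)) {
    return(contingency_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
  }
  if (is.numeric(t) && length(t) == 4L) {
    return(contingency_2x2(t[1], t[2], t[3], t[4]))
  }
  stop_input("expected a table2x2, a 2x2 matrix, or a length-4 numeric")
}

haldane <- function(t) contingency_2x2(t[1] + 0.5, t[2] + 0.5,
                                       t[3] + 0.5, t[4] + 0.5)

association_result <- function(odds_ratio, ci_low, ci_high, chi2, p, method,
                               conf_level, table, extra = list()) {
  structure(c(list(odds_ratio = odds_ratio, ci_low = ci_low,
                   ci_high = ci_high, chi2 = chi2, p = p, method = method,
                   conf_level = conf_level, table = table), extra),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.0f%% CI %.2f-%.2f), p = %.3g [%s]\n",
              x$odds_ratio, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$p, x$method))
  invisible(x)
}

#' Odds ratio with Woolf (log-OR normal) confidence interval
#'
#' `OR = ad/(bc)` with
#' `CI = exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' The accompanying test is the Pearson chi-squared (see [chi_squared()]).
#' Zero cells make the Woolf interval undefined; with
#' `zero_cell = "haldane"` the Haldane-Anscombe correction adds 0.5 to every
#' cell (never silently: the result's `corrected` flag records it).
#'
#' @param t A [contingency_2x2()] (or 2x2 matrix / length-4 vector `a,b,c,d`).
#' @param alpha Two-sided significance level; default 0.05 for a 95% CI.
#' @param zero_cell `"error"` (default) or `"haldane"`.
#' @return An `association_result`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `chi2`, `p`, `method = "woolf"`.
#' @export
#' @examples
#' odds_ratio_woolf(contingency_2x2(7, 20, 16, 130))
odds_ratio_woolf <- function(t, alpha = 0.05,
                             zero_cell = c("error", "haldane")) {
  t <- as_table2x2(t)
  zero_cell <- match.arg(zero_cell)
  corrected <- FALSE
  if (any(t == 0)) {
    if (zero_cell == "error") {
      stop_input("zero cell (", paste(names(t)[t == 0], collapse = ", "),
                 ") makes the Woolf interval undefined; ",
                 "use zero_cell = \"haldane\" or an exact method")
    }
    t <- haldane(t)
    corrected <- TRUE
  }
  or <- (t["a"] * t["d"]) / (t["b"] * t["c"])
  se <- sqrt(sum(1 / t))
  z <- stats::qnorm(1 - alpha / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  test <- tryCatch(chi_squared(t), error = function(e) list(statistic = NA_real_,
                                                            p = NA_real_))
  association_result(unname(or), ci[1], ci[2], test$statistic, test$p,
                     "woolf", 1 - alpha, t, extra = list(corrected = corrected))
}

# --- conditional (noncentral hypergeometric) machinery -----------------------
# Conditioning on both margins, the first cell X follows Fisher's noncentral
# hypergeometric distribution with odds-ratio parameter psi. The Haldane
# correction yields non-integer tables; the binomial coefficients extend
# continuously through lgamma, and the unit lattice is anchored at the lower
# support bound, so a corrected observation may sit between lattice points
# (its tails are then the lattice mass at or beyond it).
lchoose_cont <- function(n, k) {
  lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
}

ncp_support <- function(t) {
  m1 <- t["a"] + t["b"]; m2 <- t["c"] + t["d"]; k <- t["a"] + t["c"]
  lo <- max(0, k - m2); hi <- min(k, m1)
  x <- unname(lo + seq(0, floor(hi - lo + 1e-9)))
  list(x = x, lw = lchoose_cont(m1, x) + lchoose_cont(m2, k - x),
       a_obs = unname(t["a"]))
}

ncp_probs <- function(sup, log_psi) {
  lp <- sup$lw + sup$x * log_psi
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Odds ratio with exact conditional confidence interval
#'
#' Inverts the tails of Fisher's noncentral hypergeometric distribution
#' (conditional on both margins) at `alpha/2` per side, the construction
#' behind [stats::fisher.test()]'s interval; suited to sparse tables where
#' the Woolf interval is unreliable. The reported point estimate is the
#' familiar cross-product `ad/(bc)` (the conditional maximum-likelihood
#' estimate is returned alongside as `or_cmle`); `p` is the two-sided exact
#' probability at odds ratio 1.
#'
#' @inheritParams odds_ratio_woolf
#' @param zero_cell `"none"` (default; exact intervals tolerate zero cells,
#'   giving a 0 or infinite bound) or `"haldane"` to add 0.5 to every cell,
#'   which keeps both bounds finite.
#' @return An `association_result` with `method = "exact"` and an extra
#'   `or_cmle` element.
#' @export
#' @examples
#' odds_ratio_exact(contingency_2x2(5, 3, 1, 10))
odds_ratio_exact <- function(t, alpha = 0.05,
                             zero_cell = c("none", "haldane")) {
  t <- as_table2x2(t)
  zero_cell <- match.arg(zero_cell)
  if ((t["a"] + t["b"]) == 0 || (t["c"] + t["d"]) == 0 ||
      (t["a"] + t["c"]) == 0 || (t["b"] + t["d"]) == 0) {
    stop_input("degenerate margin: every row and column must have counts")
  }
  corrected <- FALSE
  if (zero_cell == "haldane" && any(t == 0)) {
    t <- haldane(t)
    corrected <- TRUE
  }
  sup <- ncp_support(t)
  or_sample <- unname((t["a"] * t["d"]) / (t["b"] * t["c"]))

  if (length(sup$x) == 1L) {
    # margins determine the table; no information about the odds ratio
    return(association_result(or_sample, 0, Inf, NA_real_, 1, "exact",
                              1 - alpha, t,
                              extra = list(or_cmle = NA_real_,
                                           corrected = corrected)))
  }

  a_obs <- sup$a_obs
  eps <- 1e-9
  lo_sup <- min(sup$x); hi_sup <- max(sup$x)
  solve_logpsi <- function(f, target) {
    # f(log_psi) is increasing in log_psi for the functionals used here
    g <- function(lp) f(lp) - target
    lo <- -1; hi <- 1
    while (g(lo) > 0 && lo > -745) lo <- lo * 2
    while (g(hi) < 0 && hi < 745) hi <- hi * 2
    stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  }
  cond_mean <- function(lp) sum(sup$x * ncp_probs(sup, lp))
  or_cmle <- if (a_obs >= hi_sup - eps) {
    Inf
  } else if (a_obs <= lo_sup + eps) {
    0
  } else {
    exp(solve_logpsi(cond_mean, a_obs))
  }
  # upper tail P(X >= a_obs) increases with psi; lower tail decreases
  p_upper <- function(lp) sum(ncp_probs(sup, lp)[sup$x >= a_obs - eps])
  p_lower <- function(lp) sum(ncp_probs(sup, lp)[sup$x <= a_obs + eps])
  ci_low <- if (a_obs <= lo_sup + eps) 0 else
    exp(solve_logpsi(p_upper, alpha / 2))
  ci_high <- if (a_obs >= hi_sup - eps) Inf else
    exp(solve_logpsi(function(lp) 1 - p_lower(lp), 1 - alpha / 2))
  # two-sided exact p at psi = 1: probabilities no larger than the one at
  # the observed cell (nearest lattice point for corrected tables)
  p0 <- ncp_probs(sup, 0)
  i_obs <- which.min(abs(sup$x - a_obs))
  p_two <- sum(p0[p0 <= p0[i_obs] * (1 + 1e-7)])
  association_result(or_sample, ci_low, ci_high, NA_real_, min(1, p_two),
                     "exact", 1 - alpha, t,
                     extra = list(or_cmle = or_cmle, corrected = corrected))
}

#' Odds ratio with automatic interval selection
#'
#' Uses the Woolf interval for well-filled tables and switches to the exact
#' conditional interval when any cell is below `sparse_below` (default 5),
#' where the normal approximation behind Woolf degrades.
#'
#' @inheritParams odds_ratio_woolf
#' @param method `"auto"` (default), `"woolf"` or `"exact"`.
#' @param sparse_below Cell-count threshold triggering the exact method
#'   under `method = "auto"`.
#' @return An `association_result`; its `method` element records the method
#'   actually used.
#' @export
#' @examples
#' odds_ratio(contingency_2x2(5, 22, 22, 103))$method   # sparse -> exact
odds_ratio <- function(t, alpha = 0.05, method = c("auto", "woolf", "exact"),
                       sparse_below = 5) {
  t <- as_table2x2(t)
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (any(t < sparse_below)) "exact" else "woolf"
  }
  if (method == "woolf") odds_ratio_woolf(t, alpha)
  else odds_ratio_exact(t, alpha)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' The uncorrected Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom. No Yates
#' continuity correction is applied by default; set `correct = TRUE` for the
#' corrected version.
#'
#' @inheritParams odds_ratio_woolf
#' @param correct Apply the Yates continuity correction. Default `FALSE`.
#' @return A list with `statistic`, `df` (always 1) and `p`.
#' @export
#' @examples
#' chi_squared(contingency_2x2(7, 20, 16, 130))
chi_squared <- function(t, correct = FALSE) {
  t <- as_table2x2(t)
  n <- sum(t)
  margins <- c(t["a"] + t["b"], t["c"] + t["d"], t["a"] + t["c"],
               t["b"] + t["d"])
  if (any(margins == 0)) {
    stop_input("zero margin: chi-squared test undefined")
  }
  num <- abs(t["a"] * t["d"] - t["b"] * t["c"])
  if (correct) num <- max(0, num - n / 2)
  stat <- unname(n * num^2 / prod(margins))
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Group summary statistics
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (positive).
#' @param n Group size (at least 2).
#' @return A list of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  if (!is_scalar_number(mean) || !is_scalar_number(sd) ||
      !is_scalar_number(n)) {
    stop_input("mean, sd and n must be single numbers")
  }
  if (sd <= 0) stop_input("sd must be positive")
  if (n < 2 || n != round(n)) stop_input("n must be an integer >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

#' Pooled-variance Student t-test from summary statistics
#'
#' Two-sided Student t-test comparing two group means given only each
#' group's mean, standard deviation and size, with the pooled variance
#' estimate and `n1 + n2 - 2` degrees of freedom.
#'
#' @param g1,g2 [summary_stats()] objects (or lists with `mean`, `sd`, `n`).
#' @return A list with `t`, `df` and `p`.
#' @export
#' @examples
#' t_test_summary(summary_stats(57.70, 12.45, 27),
#'                summary_stats(64.31, 12.12, 146))
t_test_summary <- function(g1, g2) {
  g1 <- do.call(summary_stats, unclass(g1)[c("mean", "sd", "n")])
  g2 <- do.call(summary_stats, unclass(g2)[c("mean", "sd", "n")])
  df <- g1$n + g2$n - 2L
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df))
}

#' Screening-cascade summary
#'
#' Tallies the screening funnel from the per-patient triage decisions:
#' total screened, MMR-deficient, MLH1 loss, MLH1 loss with tumor
#' methylation (sporadic), suspected Lynch (with per-pattern counts),
#' germline-tested, pathogenic carriers — plus observed prevalence,
#' attrition-corrected predictive frequency and IHC/MSI concordance.
#'
#' @param decisions Decision table from [triage_cohort()].
#' @param germline Optional germline outcomes: either the cohort table with
#'   wide columns `germline_mlh1 ... germline_epcam` (values `pathogenic`,
#'   `vus`, `negative`, `not_done`), or a long data.frame with columns
#'   `patient_id`, `gene`, `outcome`. Outcomes attached to non-suspected
#'   patients raise a warning and are excluded from the funnel.
#' @return A list of class `cascade_summary` with the funnel counts
#'   (`n_total`, `n_mmr_deficient`, `n_mlh1_loss`, `n_mlh1_methylated`,
#'   `n_sporadic_methylated`, `n_epimutation_suspected`, `n_unresolved`,
#'   `n_suspected`, `n_tested`, `n_pathogenic`), `pattern_counts` (suspected
#'   patients per screening pattern), concordance counts, and the
#'   `prevalence_observed` / `predictive_frequency` fractions.
#' @export
#' @examples
#' cohort <- paper_fixture()
#' cascade_summary(triage_cohort(cohort), cohort)
cascade_summary <- function(decisions, germline = NULL) {
  stopifnot(is.data.frame(decisions))
  n_total <- nrow(decisions)
  if (n_total == 0) stop_input("empty cohort: no decisions to summarise")

  lost_sets <- strsplit(decisions$ihc_lost, "/", fixed = TRUE)
  mlh1_lost <- vapply(lost_sets, function(s) "MLH1" %in% s, logical(1))
  any_loss <- nzchar(decisions$ihc_lost)
  msi <- decisions$msi_status == "MSI"
  suspected <- decisions$label == "suspected_ls"

  pattern_levels <- c("mlh1_unmethylated", "msh2_msh6", "msh6", "pms2",
                      "msh6_pms2", "msi_normal_ihc")
  pattern_counts <- vapply(pattern_levels, function(p) {
    sum(suspected & decisions$pattern == p)
  }, integer(1))

  tested_ids <- pathogenic_ids <- character(0)
  if (!is.null(germline)) {
    g <- germline_outcomes_by_patient(germline)
    g <- g[g$outcome != "not_done", , drop = FALSE]
    stray <- setdiff(unique(g$patient_id),
                     decisions$patient_id[suspected])
    if (length(stray)) {
      warning("germline results for non-suspected patients excluded ",
              "from the funnel: ", paste(stray, collapse = ", "),
              call. = FALSE)
      g <- g[!g$patient_id %in% stray, , drop = FALSE]
    }
    tested_ids <- unique(g$patient_id)
    pathogenic_ids <- unique(g$patient_id[g$outcome == "pathogenic"])
  }

  concordant <- (any_loss & msi) | (!any_loss & decisions$msi_status == "MSS")
  out <- structure(list(
    n_total = n_total,
    n_mmr_deficient = sum(decisions$mmr_status == "deficient"),
    n_mlh1_loss = sum(mlh1_lost),
    n_mlh1_methylated = sum(mlh1_lost &
                              !is.na(decisions$meth_tumor) &
                              decisions$meth_tumor == "methylated"),
    n_sporadic_methylated = sum(decisions$label == "sporadic_methylated"),
    n_epimutation_suspected =
      sum(decisions$label == "constitutional_epimutation_suspected"),
    n_unresolved = sum(decisions$label %in%
                         c("pending_methylation", "unresolvable")),
    n_suspected = sum(suspected),
    n_tested = length(tested_ids),
    n_pathogenic = length(pathogenic_ids),
    pattern_counts = pattern_counts,
    n_concordant = sum(concordant),
    n_discordant = n_total - sum(concordant),
    n_loss_mss = sum(any_loss & decisions$msi_status == "MSS"),
    n_msi_intact = sum(!any_loss & msi)
  ), class = "cascade_summary")
  out$prevalence_observed <- out$n_pathogenic / out$n_total
  out$predictive_frequency <- if (out$n_tested > 0) {
    predictive_frequency(out)
  } else {
    NA_real_
  }
  out
}

# normalise wide (germline_* columns) or long (patient_id/gene/outcome)
# germline input to a long data.frame
germline_outcomes_by_patient <- function(germline) {
  stopifnot(is.data.frame(germline))
  if (all(c("patient_id", "gene", "outcome") %in% names(germline))) {
    return(data.frame(patient_id = as.character(germline$patient_id),
                      gene = toupper(germline$gene),
                      outcome = fold_token(germline$outcome),
                      stringsAsFactors = FALSE))
  }
  cols <- paste0("germline_", tolower(ls_genes))
  have <- intersect(cols, names(germline))
  if (length(have) == 0 || !"patient_id" %in% names(germline)) {
    stop_input("germline input needs patient_id plus germline_<gene> ",
               "columns, or patient_id/gene/outcome columns")
  }
  long <- do.call(rbind, lapply(have, function(cl) {
    data.frame(patient_id = as.character(germline$patient_id),
               gene = toupper(sub("germline_", "", cl)),
               outcome = fold_token(germline[[cl]]),
               stringsAsFactors = FALSE)
  }))
  long$outcome[is.na(long$outcome)] <- "not_done"
  bad <- setdiff(unique(long$outcome), germline_outcomes)
  if (length(bad)) {
    stop_input("unknown germline outcome value(s): ",
               paste(bad, collapse = ", "))
  }
  long
}

#' Attrition-corrected (predictive) mutation frequency
#'
#' Extrapolates the mutation yield observed among tested patients to every
#' suspected patient (assuming those lost to testing carry mutations at the
#' same rate), then divides by the cohort size:
#' `(n_suspected * n_pathogenic / n_tested) / n_total`.
#'
#' @param s A `cascade_summary` (or list with `n_suspected`, `n_pathogenic`,
#'   `n_tested`, `n_total`).
#' @return The predicted prevalence as a fraction.
#' @export
#' @examples
#' cohort <- paper_fixture()
#' predictive_frequency(cascade_summary(triage_cohort(cohort), cohort))
predictive_frequency <- function(s) {
  if (is.null(s$n_tested) || s$n_tested == 0) {
    stop_input("predictive frequency undefined with no tested patients")
  }
  (s$n_suspected * s$n_pathogenic / s$n_tested) / s$n_total
}

#' @export
print.cascade_summary <- function(x, digits = 1, ...) {
  p <- function(num, den) sprintf("%s%%", format(pct(num, den, digits)))
  cat(sprintf("Screening cascade over %d patients:\n", x$n_total))
  cat(sprintf("  MMR-deficient (IHC loss and/or MSI): %d (%s)\n",
              x$n_mmr_deficient, p(x$n_mmr_deficient, x$n_total)))
  cat(sprintf("  MLH1 loss: %d (%s); tumor-methylated: %d (%s of MLH1 loss)\n",
              x$n_mlh1_loss, p(x$n_mlh1_loss, x$n_total),
              x$n_mlh1_methylated, p(x$n_mlh1_methylated, x$n_mlh1_loss)))
  cat(sprintf("  suspected Lynch syndrome: %d (%s)\n",
              x$n_suspected, p(x$n_suspected, x$n_total)))
  cat(sprintf("  germline-tested: %d; pathogenic mutation: %d (%s of tested)\n",
              x$n_tested, x$n_pathogenic,
              if (x$n_tested > 0) p(x$n_pathogenic, x$n_tested) else "-"))
  cat(sprintf("  observed prevalence: %s; predictive frequency: %s\n",
              p(x$n_pathogenic, x$n_total),
              if (is.na(x$predictive_frequency)) "-" else
                sprintf("%s%%", format(round_half_up(
                  100 * x$predictive_frequency, digits)))))
  cat(sprintf("  IHC/MSI concordance: %d (%s); discordant: %d\n",
              x$n_concordant, p(x$n_concordant, x$n_total), x$n_discordant))
  invisible(x)
}
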