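#' Window admissions to a patient's study timeframe
#'
#' Keeps non-elective admissions whose admission date falls between 6 months
#' (183 days) before the patient's intervention start and 183 days after the
#' intervention end, inclusive at both ends. Membership is keyed on the
#' admission date only, so a stay straddling a boundary counts if it began
#' inside the window.
#'
#' @param admissions Data frame of admission records (`patient_id`,
#'   `admit_date`, `discharge_date`, `elective`).
#' @param profile One-row data frame (or list) with `intervention_start` and
#'   `intervention_end`.
#' @param margin_days Window margin in days (default 183).
#' @return The kept admission rows.
#' @export
filter_admissions_window <- function(admissions, profile, margin_days = 183L) {
  if (!nrow(admissions)) return(admissions)
  lo <- as.Date(profile$intervention_start) - margin_days
  hi <- as.Date(profile$intervention_end) + margin_days
  adm <- as.Date(admissions$admit_date)
  elective <- if ("elective" %in% names(admissions))
    as.logical(admissions$elective) else rep(FALSE, nrow(admissions))
  out <- admissions[!elective & adm >= lo & adm <= hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average length of stay per admission
#'
#' Cumulative length of stay (discharge minus admission, in whole days; a
#' same-day discharge contributes 0) divided by the number of admissions.
#'
#' @param admissions Data frame of (windowed) admission records.
#' @return Days per admission (numeric scalar).
#' @export
average_los <- function(admissions) {
  if (!nrow(admissions))
    stop(errorCondition("average LOS undefined for zero admissions",
                        class = "telefocus_degenerate"))
  los <- as.numeric(as.Date(admissions$discharge_date) -
                      as.Date(admissions$admit_date))
  if (any(los < 0)) stop("negative length of stay")
  mean(los)
}

#' Per-patient utilization summary
#'
#' Combines windowed admissions with focus-call labels into the per-patient
#' indicators used by the association analyses: the number of (non-elective,
#' in-window) admissions, the average length of stay per admission (NA when
#' the patient had no admissions), and the number of lifestyle-focused calls.
#'
#' @param cohort A `telecare_cohort` with an admissions table.
#' @param partition A [focus_partition()] fit on the same cohort.
#' @return A data frame with one row per patient: `patient_id`,
#'   `n_admissions`, `avg_los`, `n_focus_calls`, `has_focus_call`.
#' @export
utilization_summary <- function(cohort, partition) {
  stopifnot(inherits(cohort, "telecare_cohort"),
            inherits(partition, "focus_partition"))
  p <- cohort$patients
  adm <- cohort$admissions
  if (is.null(adm)) stop("cohort has no admissions table")
  lab <- partition$labels
  out <- lapply(seq_len(nrow(p)), function(i) {
    pid <- p$patient_id[i]
    w <- filter_admissions_window(adm[adm$patient_id == pid, , drop = FALSE],
                                  p[i, ])
    nf <- sum(lab$patient_id == pid & lab$group == "lifestyle_focused")
    data.frame(patient_id = pid, n_admissions = nrow(w),
               avg_los = if (nrow(w)) average_los(w) else NA_real_,
               n_focus_calls = nf, has_focus_call = nf > 0)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Associate focus-call counts with inpatient utilization
#'
#' Spearman rank tests of the per-patient number of lifestyle-focused calls
#' against (a) the average length of stay per admission and (b) the number of
#' admissions, with a joint Holm-Bonferroni adjustment over the two
#' p-values. Patients without admissions are excluded from the LOS test
#' (their average LOS is undefined) but enter the admission-count test with
#' count 0.
#'
#' @param summaries A data frame from [utilization_summary()].
#' @return A list of class `utilization_association` with elements `avg_los`
#'   and `n_admissions`, each carrying `rho`, `p_value`, `p_adjusted`, `n`.
#' @export
associate_focus_with_utilization <- function(summaries) {
  los_ok <- !is.na(summaries$avg_los)
  if (sum(los_ok) < 3 || nrow(summaries) < 3)
    stop("need at least 3 patients with defined indicators per test")
  t_los <- spearman_test(summaries$n_focus_calls[los_ok],
                         summaries$avg_los[los_ok])
  t_adm <- spearman_test(summaries$n_focus_calls, summaries$n_admissions)
  adj <- holm_bonferroni(c(t_los$p_value, t_adm$p_value))$adjusted
  t_los$p_adjusted <- adj[1]
  t_adm$p_adjusted <- adj[2]
  structure(list(avg_los = t_los, n_admissions = t_adm),
            class = "utilization_association")
}

#' @export
print.utilization_association <- function(x, ...) {
  cat("Association of focus-call count with utilization (Spearman):\n")
  for (nm in names(x))
    cat(sprintf("  %-13s rho = %6.3f, p = %.3g, p_adj = %.3g (n = %d)\n",
                nm, x[[nm]]$rho, x[[nm]]$p_value, x[[nm]]$p_adjusted,
                x[[nm]]$n))
  invisible(x)
}

#' Compare utilization between patients with and without focus calls
#'
#' Descriptive comparison (group means, SDs, and Cohen's d) of average
#' length of stay and admission counts between patients with at least one
#' lifestyle-focused call and patients with none.
#'
#' @param summaries A data frame from [utilization_summary()].
#' @return A list of class `focus_group_comparison` with `avg_los` and
#'   `n_admissions` elements, each a [cohens_d()] result (groups ordered
#'   focused-minus-not).
#' @export
compare_focus_groups <- function(summaries) {
  g1 <- summaries[summaries$has_focus_call, , drop = FALSE]
  g0 <- summaries[!summaries$has_focus_call, , drop = FALSE]
  if (!nrow(g1) || !nrow(g0)) stop("both groups must be non-empty")
  structure(list(
    avg_los = cohens_d(g1$avg_los[!is.na(g1$avg_los)],
                       g0$avg_los[!is.na(g0$avg_los)]),
    n_admissions = cohens_d(g1$n_admissions, g0$n_admissions),
    n_per_group = c(focused = nrow(g1), not_focused = nrow(g0))),
    class = "focus_group_comparison")
}

#' @export
print.focus_group_comparison <- function(x, ...) {
  cat("Utilization by focus-call group (>=1 focused call vs none):\n")
  for (nm in c("avg_los", "n_admissions"))
    cat(sprintf("  %-13s d = %6.3f (means %.2f vs %.2f)\n", nm, x[[nm]]$d,
                x[[nm]]$group_means[1], x[[nm]]$group_means[2]))
  invisible(x)
}
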