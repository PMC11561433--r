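#' Per-call dialogue-act counts by category
#'
#' Counts dialogue acts per call, overall and within each high-level
#' category of the vocabulary. Multiple acts may be annotated within a single
#' utterance; every act is counted.
#'
#' @param cohort A `telecare_cohort`.
#' @return A data frame with one row per call: `call_id`, `overall`, and one
#'   column per dialogue-act category.
#' @export
dialogue_act_counts <- function(cohort) {
  stopifnot(inherits(cohort, "telecare_cohort"))
  u <- cohort$utterances
  cat_of <- vocab_act_category(cohort$vocab)
  cats <- names(cohort$vocab$dialogue_acts)
  acts <- split_labels(u$dialogue_acts)
  n_acts <- lengths(acts)
  out <- data.frame(call_id = cohort$calls$call_id)
  m <- matrix(0L, nrow(out), length(cats), dimnames = list(NULL, cats))
  if (any(n_acts > 0)) {
    long <- data.frame(call_id = rep(u$call_id, n_acts),
                       category = unname(cat_of[unlist(acts, use.names = FALSE)]))
    tab <- table(factor(long$call_id, levels = out$call_id),
                 factor(long$category, levels = cats))
    m <- unclass(tab)
  }
  out$overall <- as.integer(rowSums(m))
  for (cc in cats) out[[cc]] <- as.integer(m[, cc])
  out
}

#' Compare content and structure between focus-call groups
#'
#' Compares lifestyle-focused calls against calls with lifestyle-management
#' content (not focused) on the number of dialogue acts (overall and per
#' category) and on the number of utterances per call. Each comparison is a
#' two-group OLS with patient-clustered (CR1) standard errors; the
#' dialogue-act comparisons (overall plus the categories) form one
#' Holm-Bonferroni family, while the utterance-count comparison is reported
#' unadjusted.
#'
#' @param cohort A `telecare_cohort`.
#' @param partition A [focus_partition()] fit on the cohort.
#' @return An object of class `content_comparison`: a data frame with one
#'   row per outcome (`outcome`, group means/SDs/medians, `estimate`,
#'   `ci_low`, `ci_high`, `p_value`, `p_adjusted`) plus the underlying
#'   `cluster_ols` fits in attribute `fits`.
#' @export
compare_call_content <- function(cohort, partition) {
  stopifnot(inherits(partition, "focus_partition"))
  lab <- partition$labels
  keep <- lab$group %in% c("lifestyle_focused", "content_not_focused")
  lab <- lab[keep, , drop = FALSE]
  if (!any(lab$group == "lifestyle_focused") ||
      !any(lab$group == "content_not_focused"))
    stop("both call groups must be non-empty for the content comparison")
  acts <- dialogue_act_counts(cohort)
  idx <- match(lab$call_id, acts$call_id)
  grp <- lab$group == "lifestyle_focused"
  cl <- lab$patient_id

  outcomes <- c("overall", names(cohort$vocab$dialogue_acts))
  fits <- lapply(outcomes, function(o)
    ols_cluster_robust(acts[[o]][idx], grp, cl, outcome_name = o))
  utt_fit <- ols_cluster_robust(lab$total_count, grp, cl,
                                outcome_name = "utterances")
  adj <- holm_bonferroni(vapply(fits, `[[`, numeric(1), "p_value"))$adjusted

  row_of <- function(f, p_adj) data.frame(
    outcome = f$outcome_name,
    n_focused = f$n_per_group[["focused"]],
    n_not_focused = f$n_per_group[["not_focused"]],
    mean_focused = f$group_means[["focused"]],
    sd_focused = f$group_sds[["focused"]],
    median_focused = f$group_medians[["focused"]],
    mean_not_focused = f$group_means[["not_focused"]],
    sd_not_focused = f$group_sds[["not_focused"]],
    median_not_focused = f$group_medians[["not_focused"]],
    estimate = f$estimate, ci_low = f$ci_low, ci_high = f$ci_high,
    p_value = f$p_value, p_adjusted = p_adj)
  tab <- do.call(rbind, c(Map(row_of, fits, adj),
                          list(row_of(utt_fit, NA_real_)),
                          list(make.row.names = FALSE)))
  structure(tab, fits = c(fits, list(utt_fit)), class = c("content_comparison",
                                                          "data.frame"))
}

#' @export
print.content_comparison <- function(x, ...) {
  cat("Content and structure comparison (focused vs content-not-focused):\n")
  df <- as.data.frame(x)
  show <- data.frame(outcome = df$outcome,
                     `mean (SD) focused` = sprintf("%.1f (%.1f)",
                                                   df$mean_focused, df$sd_focused),
                     `mean (SD) not focused` = sprintf("%.1f (%.1f)",
                                                       df$mean_not_focused,
                                                       df$sd_not_focused),
                     estimate = sprintf("%.1f", df$estimate),
                     `95% CI` = sprintf("%.1f to %.1f", df$ci_low, df$ci_high),
                     p = sprintf("%.3f", df$p_value),
                     p_adj = ifelse(is.na(df$p_adjusted), "",
                                    sprintf("%.3f", df$p_adjusted)),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}
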