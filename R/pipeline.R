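#' Run the full telecare analysis pipeline
#'
#' Orchestrates the complete analysis with a single configuration: load (or
#' synthesize) the cohort, merge same-day calls and window calls to the
#' patient timeframe, compute topic-ratio trajectories and partition calls
#' into focus groups, compare content and structure between call groups,
#' tabulate expert concerns (when concern records are present), and
#' associate focus-call counts with inpatient utilization. Stages with
#' missing optional inputs are skipped with a warning.
#'
#' @param config Either a path to a YAML run configuration or a list. Keys:
#'   `synthetic` (a list of [synthetic_config()] arguments, activating
#'   synthetic mode) or `input` (a list of paths `calls`, `patients`,
#'   optionally `admissions`, `concerns`); optional `focus_detection` (a
#'   list of [focus_control()] arguments); optional `seed` (overrides the
#'   synthetic seed); optional logical toggles `content_comparison`,
#'   `expert_eval`, `utilization_association` (default `TRUE`).
#' @param out_dir Optional output directory; when supplied, reports are
#'   written via [emit_reports()].
#' @return An object of class `telefocus_report`: a list with `cohort`,
#'   `summary`, `partition`, `content` (or `NULL`), `concerns` (or `NULL`),
#'   `utilization` (summaries, association, group comparison, or `NULL`),
#'   and the resolved `config`.
#' @examples
#' rep <- run_full_analysis(list(synthetic = list(n_patients = 8, seed = 3)))
#' rep
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(config$synthetic) == !is.null(config$input))
    stop("exactly one of 'synthetic' or 'input' must be configured")
  toggles <- function(key) !isFALSE(config[[key]])
  vocab <- if (!is.null(config$vocabulary)) read_vocabulary(config$vocabulary)
           else read_vocabulary()

  truth <- NULL
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (!is.null(config$seed)) args$seed <- config$seed
    gen <- generate_cohort(do.call(synthetic_config, args), vocab = vocab)
    cohort <- gen$cohort
    truth <- gen$truth
  } else {
    cohort <- do.call(load_corpus, c(config$input, list(vocab = vocab)))
  }

  cohort <- merge_same_day_calls(cohort)
  cohort <- filter_calls_window(cohort)
  control <- do.call(focus_control, as.list(config$focus_detection))
  partition <- focus_partition(cohort, control)
  summ <- corpus_summary(cohort)

  content <- NULL
  if (toggles("content_comparison")) {
    content <- tryCatch(compare_call_content(cohort, partition),
                        error = function(e) {
                          warning("content comparison skipped: ",
                                  conditionMessage(e))
                          NULL
                        })
  }

  concerns <- NULL
  if (toggles("expert_eval")) {
    if (is.null(cohort$concerns) || !nrow(cohort$concerns)) {
      warning("no concern records; expert-evaluation stage skipped")
    } else {
      con <- cohort$concerns[cohort$concerns$call_id %in%
                               partition$labels$call_id, , drop = FALSE]
      concerns <- tabulate_concerns(con, partition, vocab)
    }
  }

  utilization <- NULL
  if (toggles("utilization_association")) {
    if (is.null(cohort$admissions)) {
      warning("no admissions; utilization stage skipped")
    } else {
      summaries <- utilization_summary(cohort, partition)
      assoc <- tryCatch(associate_focus_with_utilization(summaries),
                        error = function(e) NULL)
      comp <- tryCatch(compare_focus_groups(summaries),
                       error = function(e) NULL)
      utilization <- list(summaries = summaries, association = assoc,
                          comparison = comp)
    }
  }

  report <- structure(list(cohort = cohort, summary = summ,
                           partition = partition, content = content,
                           concerns = concerns, utilization = utilization,
                           truth = truth, config = config),
                      class = "telefocus_report")
  if (!is.null(out_dir)) emit_reports(report, out_dir)
  report
}

#' @export
print.telefocus_report <- function(x, ...) {
  cat("=== telefocus analysis report ===\n")
  print(x$summary)
  cat("\n")
  print(x$partition)
  if (!is.null(x$content)) { cat("\n"); print(x$content) }
  if (!is.null(x$concerns)) {
    cat(sprintf("\nExpert evaluation: %.1f%% of calls flagged (%.1f%% of focused calls)\n",
                flagged_proportion(x$concerns, "all"),
                tryCatch(flagged_proportion(x$concerns, "lifestyle_focused"),
                         error = function(e) NA_real_)))
  }
  if (!is.null(x$utilization)) {
    cat("\n")
    if (!is.null(x$utilization$association)) print(x$utilization$association)
    if (!is.null(x$utilization$comparison)) print(x$utilization$comparison)
  }
  invisible(x)
}

#' Write the report bundle as CSV files
#'
#' Writes deterministic, fixed-format CSV reports: focus labels and review
#' queue, per-patient group counts, the content-comparison table (means and
#' SDs to 1 decimal, p-values to 3 decimals), the concern table, and the
#' utilization summaries and association results. File names are fixed;
#' writing the same report twice produces byte-identical files.
#'
#' @param report A `telefocus_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
emit_reports <- function(report, out_dir) {
  stopifnot(inherits(report, "telefocus_report"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  if (!isTRUE(file.create(probe, showWarnings = FALSE)))
    stop("output directory not writable: ", out_dir)
  unlink(probe)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  fmt1 <- function(x) sprintf("%.1f", x)
  fmt3 <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))

  write_focus_labels(report$partition, file.path(out_dir, "focus_labels.csv"),
                     file.path(out_dir, "review_queue.csv"))
  files <- c(files, file.path(out_dir, c("focus_labels.csv", "review_queue.csv")))
  emit(report$partition$counts, "group_counts.csv")

  if (!is.null(report$content)) {
    df <- as.data.frame(report$content)
    out <- data.frame(
      outcome = df$outcome,
      n_focused = df$n_focused, n_not_focused = df$n_not_focused,
      mean_sd_focused = sprintf("%s (%s)", fmt1(df$mean_focused),
                                fmt1(df$sd_focused)),
      mean_sd_not_focused = sprintf("%s (%s)", fmt1(df$mean_not_focused),
                                    fmt1(df$sd_not_focused)),
      estimate = fmt1(df$estimate),
      ci_95 = sprintf("%s to %s", fmt1(df$ci_low), fmt1(df$ci_high)),
      p_value = fmt3(df$p_value), p_adjusted = fmt3(df$p_adjusted))
    emit(out, "content_comparison.csv")
  }
  if (!is.null(report$concerns)) {
    write_concern_table(report$concerns, file.path(out_dir, "concern_table.csv"))
    files <- c(files, file.path(out_dir, "concern_table.csv"))
  }
  if (!is.null(report$utilization)) {
    emit(report$utilization$summaries, "utilization_summary.csv")
    if (!is.null(report$utilization$association)) {
      a <- report$utilization$association
      emit(data.frame(indicator = c("avg_los", "n_admissions"),
                      rho = sprintf("%.3f", c(a$avg_los$rho, a$n_admissions$rho)),
                      p_value = fmt3(c(a$avg_los$p_value, a$n_admissions$p_value)),
                      p_adjusted = fmt3(c(a$avg_los$p_adjusted,
                                          a$n_admissions$p_adjusted)),
                      n = c(a$avg_los$n, a$n_admissions$n)),
           "utilization_association.csv")
    }
  }
  if (!length(files)) message("no results to write")
  invisible(files)
}
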