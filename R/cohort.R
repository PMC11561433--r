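#' Construct a validated telecare cohort dataset
#'
#' A `telecare_cohort` bundles the four record types the analyses operate on,
#' each held as a plain data frame:
#' \describe{
#'   \item{patients}{one row per patient: `patient_id`, `age`, `gender`,
#'     `ethnicity`, `hf`, `t2dm`, `intervention_start`, `intervention_end`.}
#'   \item{calls}{one row per call: `call_id`, `patient_id`, `date`
#'     (calendar date, no time of day), `scheduled`.}
#'   \item{utterances}{one row per utterance: `call_id`, `index` (0-based,
#'     contiguous within a call), `speaker`, `topic` (exactly one label),
#'     `dialogue_acts` and `attributes` (semicolon-joined label lists, empty
#'     string for none), optional `text`.}
#'   \item{admissions}{one row per inpatient stay: `patient_id`,
#'     `admit_date`, `discharge_date`, `cause`, `elective`.}
#'   \item{concerns}{optional expert evaluations: `call_id`, `rater_id`,
#'     `concern_areas` (semicolon-joined, empty for no concern), `follow_up`,
#'     `remarks`.}
#' }
#' Validation enforces the schema: every call has at least one utterance with
#' unique, contiguous 0-based indices; every topic / speaker / dialogue-act /
#' attribute label belongs to the vocabulary; every call and admission
#' references a known patient; discharge dates do not precede admission
#' dates.
#'
#' @param patients,calls,utterances,admissions,concerns Data frames as
#'   described above; `admissions` and `concerns` may be `NULL`.
#' @param vocab A `telecare_vocabulary`, see [read_vocabulary()].
#' @param validate Set `FALSE` to skip validation (internal use).
#' @return An object of class `telecare_cohort`.
#' @export
telecare_cohort <- function(patients, calls, utterances, admissions = NULL,
                            concerns = NULL, vocab = read_vocabulary(),
                            validate = TRUE) {
  x <- structure(list(patients = as.data.frame(patients),
                      calls = as.data.frame(calls),
                      utterances = as.data.frame(utterances),
                      admissions = if (!is.null(admissions)) as.data.frame(admissions),
                      concerns = if (!is.null(concerns)) as.data.frame(concerns),
                      vocab = vocab),
                 class = "telecare_cohort")
  if (validate) validate_cohort(x)
  x
}

#' @rdname telecare_cohort
#' @param x A `telecare_cohort`.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "telecare_cohort"))
  p <- x$patients; cl <- x$calls; u <- x$utterances
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table missing columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  need(p, c("patient_id", "intervention_start", "intervention_end"), "patients")
  need(cl, c("call_id", "patient_id", "date"), "calls")
  need(u, c("call_id", "index", "speaker", "topic"), "utterances")
  if (anyDuplicated(p$patient_id)) stop("duplicate patient_id in patients table")
  if (anyDuplicated(cl$call_id)) stop("duplicate call_id in calls table")
  if (any(as.Date(p$intervention_end) < as.Date(p$intervention_start)))
    stop("intervention_end precedes intervention_start")

  orphan <- setdiff(cl$patient_id, p$patient_id)
  if (length(orphan))
    stop("referential error: calls reference unknown patient_id: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  if (nrow(cl)) {
    no_utt <- setdiff(cl$call_id, u$call_id)
    if (length(no_utt))
      stop("calls without utterances: ", paste(utils::head(no_utt, 5), collapse = ", "))
  }
  orphan_u <- setdiff(u$call_id, cl$call_id)
  if (length(orphan_u))
    stop("referential error: utterances reference unknown call_id: ",
         paste(utils::head(orphan_u, 5), collapse = ", "))

  check_labels(u$topic, x$vocab$topics, "topic")
  check_labels(u$speaker, x$vocab$speakers, "speaker")
  check_multi_labels(u$dialogue_acts, vocab_acts(x$vocab), "dialogue act")
  check_multi_labels(u$attributes, vocab_attributes(x$vocab), "attribute")

  # utterance indices unique and contiguous from 0 within each call
  if (nrow(u)) {
    bad <- vapply(split(u$index, u$call_id), function(ix)
      !identical(sort(as.integer(ix)), seq_len(length(ix)) - 1L), logical(1))
    if (any(bad))
      stop("utterance indices not contiguous from 0 in call(s): ",
           paste(utils::head(names(bad)[bad], 5), collapse = ", "))
  }

  if (!is.null(x$admissions) && nrow(x$admissions)) {
    a <- x$admissions
    need(a, c("patient_id", "admit_date", "discharge_date"), "admissions")
    orphan_a <- setdiff(a$patient_id, p$patient_id)
    if (length(orphan_a))
      stop("referential error: admissions reference unknown patient_id: ",
           paste(utils::head(orphan_a, 5), collapse = ", "))
    if (any(as.Date(a$discharge_date) < as.Date(a$admit_date)))
      stop("discharge_date precedes admit_date")
  }
  if (!is.null(x$concerns) && nrow(x$concerns)) {
    need(x$concerns, c("call_id", "concern_areas", "follow_up"), "concerns")
    check_multi_labels(x$concerns$concern_areas, x$vocab$concern_areas,
                       "concern area")
    fu <- x$concerns$follow_up
    check_labels(fu[!is.na(fu) & nzchar(fu)], x$vocab$follow_up_levels,
                 "follow-up level")
  }
  invisible(x)
}

check_labels <- function(values, allowed, what) {
  bad <- setdiff(unique(values), allowed)
  if (length(bad))
    stop("vocabulary error: unknown ", what, " label(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

check_multi_labels <- function(values, allowed, what) {
  if (is.null(values)) return(invisible(TRUE))
  values <- values[!is.na(values) & nzchar(values)]
  if (!length(values)) return(invisible(TRUE))
  check_labels(unique(unlist(strsplit(values, ";", fixed = TRUE))), allowed, what)
}

split_labels <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' @export
print.telecare_cohort <- function(x, ...) {
  cat("telecare_cohort:",
      nrow(x$patients), "patients,",
      nrow(x$calls), "calls,",
      nrow(x$utterances), "utterances\n")
  if (!is.null(x$admissions))
    cat("  admissions:", nrow(x$admissions), "\n")
  if (!is.null(x$concerns))
    cat("  concern records:", nrow(x$concerns), "\n")
  invisible(x)
}

#' Merge calls made to the same patient on the same day
#'
#' Multiple calls recorded for one patient on the same calendar day (for
#' example after a dropped connection, or separate calls with the patient and
#' a caregiver) are counted as a single conversation. Utterances are
#' concatenated in their original within-day order (file order) and renumbered
#' contiguously from 0; the merged call keeps the first call's identifier.
#' The operation is idempotent and preserves the total utterance count.
#'
#' @param cohort A `telecare_cohort`.
#' @return A `telecare_cohort` whose calls table has one row per
#'   (patient, date), sorted by patient then date.
#' @export
merge_same_day_calls <- function(cohort) {
  stopifnot(inherits(cohort, "telecare_cohort"))
  cl <- cohort$calls
  u <- cohort$utterances
  if (!nrow(cl)) return(cohort)
  key <- paste(cl$patient_id, as.character(cl$date), sep = "\r")
  # map every call to the first call id of its (patient, date) group,
  # preserving file order within the day
  first_id <- cl$call_id[!duplicated(key)]
  names(first_id) <- key[!duplicated(key)]
  new_id <- unname(first_id[key])
  id_map <- stats::setNames(new_id, cl$call_id)

  merged_calls <- cl[!duplicated(key), , drop = FALSE]
  if ("scheduled" %in% names(cl))
    merged_calls$scheduled <- as.logical(
      tapply(cl$scheduled, key, any)[key[!duplicated(key)]])
  merged_calls <- merged_calls[order(merged_calls$patient_id,
                                     as.Date(merged_calls$date)), , drop = FALSE]
  rownames(merged_calls) <- NULL

  # concatenate utterances in (file order of calls, index) order, renumber
  call_rank <- stats::setNames(seq_len(nrow(cl)), cl$call_id)
  u <- u[order(call_rank[as.character(u$call_id)], u$index), , drop = FALSE]
  u$call_id <- unname(id_map[as.character(u$call_id)])
  u$index <- stats::ave(seq_along(u$call_id), u$call_id,
                        FUN = seq_along) - 1L
  rownames(u) <- NULL

  out <- cohort
  out$calls <- merged_calls
  out$utterances <- u
  out
}

#' Summarize a telecare call corpus
#'
#' Produces the cohort-level descriptors used to characterise a corpus: call
#' and patient counts, the distribution of utterances per call
#' (min/median/max), and the share of utterances per topic.
#'
#' @param cohort A `telecare_cohort`.
#' @return A `telecare_summary` list with elements `n_patients`, `n_calls`,
#'   `n_utterances`, `utterances_per_call` (named vector min/median/max) and
#'   `topic_shares` (data frame with topic, count, share).
#' @examples
#' cfg <- synthetic_config(n_patients = 3, seed = 1)
#' corpus_summary(generate_cohort(cfg)$cohort)
#' @export
corpus_summary <- function(cohort) {
  stopifnot(inherits(cohort, "telecare_cohort"))
  if (!nrow(cohort$calls))
    stop(errorCondition("empty dataset: no calls to summarize",
                        class = "telefocus_empty"))
  upc <- table(cohort$utterances$call_id)
  n_utt <- nrow(cohort$utterances)
  counts <- table(factor(cohort$utterances$topic, levels = cohort$vocab$topics))
  shares <- data.frame(topic = names(counts),
                       count = as.integer(counts),
                       share = as.numeric(counts) / n_utt,
                       row.names = NULL)
  structure(list(n_patients = nrow(cohort$patients),
                 n_calls = nrow(cohort$calls),
                 n_utterances = n_utt,
                 utterances_per_call = c(min = min(upc),
                                         median = stats::median(as.numeric(upc)),
                                         max = max(upc)),
                 topic_shares = shares),
            class = "telecare_summary")
}

#' @export
print.telecare_summary <- function(x, digits = 3, ...) {
  cat("Corpus summary:", x$n_patients, "patients,", x$n_calls, "calls,",
      x$n_utterances, "utterances\n")
  cat("Utterances per call: min", x$utterances_per_call["min"],
      "/ median", x$utterances_per_call["median"],
      "/ max", x$utterances_per_call["max"], "\n")
  top <- x$topic_shares[order(-x$topic_shares$share), ]
  top <- top[top$count > 0, ]
  cat("Topic shares (non-zero):\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-26s %6d  (%s%%)\n", top$topic[i], top$count[i],
                format(round(100 * top$share[i], 2), nsmall = 2)))
  invisible(x)
}

#' Restrict calls to each patient's observation window
#'
#' Keeps calls dated between the patient's intervention start and 6 months
#' (183 days) after the intervention end, the window over which call data were
#' tracked.
#'
#' @param cohort A `telecare_cohort`.
#' @param post_days Days after intervention end to retain (default 183).
#' @return A `telecare_cohort` with out-of-window calls (and their
#'   utterances) removed.
#' @export
filter_calls_window <- function(cohort, post_days = 183L) {
  stopifnot(inherits(cohort, "telecare_cohort"))
  p <- cohort$patients
  start <- as.Date(p$intervention_start)[match(cohort$calls$patient_id, p$patient_id)]
  end <- as.Date(p$intervention_end)[match(cohort$calls$patient_id, p$patient_id)]
  d <- as.Date(cohort$calls$date)
  keep <- d >= start & d <= end + post_days
  out <- cohort
  out$calls <- cohort$calls[keep, , drop = FALSE]
  out$utterances <- cohort$utterances[
    cohort$utterances$call_id %in% out$calls$call_id, , drop = FALSE]
  rownames(out$calls) <- rownames(out$utterances) <- NULL
  out
}
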