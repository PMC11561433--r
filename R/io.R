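#' Read and write telecare cohort interchange files
#'
#' The interchange format is one JSON Lines file for calls (one call object
#' per line holding its ordered utterances) and headered CSV files for
#' patients, admissions, and expert concern records. Dates are ISO-8601
#' (`YYYY-MM-DD`). `load_corpus()` reads any subset of these files into a
#' validated [telecare_cohort()]; `write_cohort()` writes the full set so that
#' a write/load round trip is lossless.
#'
#' @param calls Path to a calls JSON Lines file.
#' @param patients Path to a patients CSV file.
#' @param admissions,concerns Optional paths to admissions / concern CSVs.
#' @param vocab A `telecare_vocabulary` used for validation.
#' @return `load_corpus()` returns a validated `telecare_cohort`.
#' @export
load_corpus <- function(calls, patients, admissions = NULL, concerns = NULL,
                        vocab = read_vocabulary()) {
  pat <- read_patients_csv(patients)
  cl <- read_calls_jsonl(calls)
  adm <- if (!is.null(admissions)) read_admissions_csv(admissions)
  con <- if (!is.null(concerns)) read_concerns_csv(concerns)
  telecare_cohort(patients = pat, calls = cl$calls, utterances = cl$utterances,
                  admissions = adm, concerns = con, vocab = vocab)
}

read_calls_jsonl <- function(path) {
  if (!file.exists(path)) stop("calls file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(list(calls = empty_calls_df(), utterances = empty_utterances_df()))
  calls <- vector("list", length(lines))
  utts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("parse error in ", path, " line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    for (f in c("call_id", "patient_id", "date", "utterances"))
      if (is.null(obj[[f]]))
        stop("parse error in ", path, " line ", i, ": missing field '", f, "'",
             call. = FALSE)
    calls[[i]] <- data.frame(
      call_id = as.character(obj$call_id),
      patient_id = as.character(obj$patient_id),
      date = as.Date(obj$date),
      scheduled = isTRUE(obj$scheduled))
    us <- obj$utterances
    join <- function(field) vapply(us, function(u)
      paste(as.character(unlist(u[[field]])), collapse = ";"), character(1))
    utts[[i]] <- data.frame(
      call_id = as.character(obj$call_id),
      index = vapply(us, function(u) as.integer(u$index), integer(1)),
      speaker = vapply(us, function(u) as.character(u$speaker), character(1)),
      topic = vapply(us, function(u) as.character(u$topic), character(1)),
      dialogue_acts = join("dialogue_acts"),
      attributes = join("attributes"),
      text = vapply(us, function(u)
        if (is.null(u$text)) NA_character_ else as.character(u$text), character(1)))
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))) %||%
         empty_calls_df(),
       utterances = do.call(rbind, c(utts, list(make.row.names = FALSE))) %||%
         empty_utterances_df())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_calls_df <- function() data.frame(
  call_id = character(), patient_id = character(),
  date = as.Date(character()), scheduled = logical())

empty_utterances_df <- function() data.frame(
  call_id = character(), index = integer(), speaker = character(),
  topic = character(), dialogue_acts = character(), attributes = character(),
  text = character())

read_patients_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  p$intervention_start <- as.Date(p$intervention_start)
  p$intervention_end <- as.Date(p$intervention_end)
  p
}

read_admissions_csv <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  a$admit_date <- as.Date(a$admit_date)
  a$discharge_date <- as.Date(a$discharge_date)
  if (!"elective" %in% names(a)) a$elective <- FALSE
  a$elective <- as.logical(a$elective)
  a
}

read_concerns_csv <- function(path) {
  con <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(call_id = "character"))
  if (!"concern_areas" %in% names(con))
    stop("concerns file lacks a concern_areas column")
  con$concern_areas[is.na(con$concern_areas)] <- ""
  con
}

#' @rdname load_corpus
#' @param cohort A `telecare_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` invisibly returns the paths written, named
#'   `calls`, `patients`, and (when present) `admissions`, `concerns`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "telecare_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(calls = file.path(dir, "calls.jsonl"),
             patients = file.path(dir, "patients.csv"))
  write_calls_jsonl(cohort, paths["calls"])
  utils::write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  if (!is.null(cohort$admissions)) {
    paths["admissions"] <- file.path(dir, "admissions.csv")
    utils::write.csv(cohort$admissions, paths["admissions"], row.names = FALSE)
  }
  if (!is.null(cohort$concerns)) {
    paths["concerns"] <- file.path(dir, "concerns.csv")
    utils::write.csv(cohort$concerns, paths["concerns"], row.names = FALSE)
  }
  invisible(paths)
}

write_calls_jsonl <- function(cohort, path) {
  u_by_call <- split(cohort$utterances, cohort$utterances$call_id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  cl <- cohort$calls
  for (i in seq_len(nrow(cl))) {
    u <- u_by_call[[as.character(cl$call_id[i])]]
    u <- u[order(u$index), , drop = FALSE]
    utt_list <- lapply(seq_len(nrow(u)), function(j) {
      rec <- list(index = u$index[j], speaker = u$speaker[j], topic = u$topic[j],
                  dialogue_acts = split_labels(u$dialogue_acts[j])[[1]],
                  attributes = split_labels(u$attributes[j])[[1]])
      if (!is.null(u$text) && !is.na(u$text[j])) rec$text <- u$text[j]
      rec
    })
    obj <- list(call_id = cl$call_id[i], patient_id = cl$patient_id[i],
                date = format(as.Date(cl$date[i])),
                scheduled = isTRUE(cl$scheduled[i]),
                utterances = utt_list)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}
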