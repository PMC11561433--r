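#' Tabulate expert concern evaluations by area and follow-up level
#'
#' Cross-tabulates expert concern records into counts per (concern area,
#' follow-up level), for all assessed calls and for the lifestyle-focused
#' stratum. A call carrying several concern areas is counted once in every
#' area it carries (overlaps preserved), so area totals can exceed the number
#' of flagged calls. When several raters assessed the same call (pilot
#' phase), their records are resolved by taking the union of the concern
#' areas and the most escalated follow-up level.
#'
#' @param records Data frame of concern records: `call_id`, `rater_id`,
#'   `concern_areas` (semicolon-joined labels, empty for no concern),
#'   `follow_up`.
#' @param labels Either a [focus_partition()] or a data frame with `call_id`
#'   and `group`; every assessed call must have a label.
#' @param vocab A `telecare_vocabulary`.
#' @return An object of class `concern_table`: for each stratum (`all`,
#'   `lifestyle_focused`) a follow-up-level x area count matrix, per-area
#'   call totals, the number of flagged and assessed calls, and the
#'   call-level area sets.
#' @export
tabulate_concerns <- function(records, labels, vocab = read_vocabulary()) {
  if (inherits(labels, "focus_partition")) labels <- labels$labels
  stopifnot(all(c("call_id", "group") %in% names(labels)))
  records <- as.data.frame(records)
  records$concern_areas[is.na(records$concern_areas)] <- ""
  check_multi_labels(records$concern_areas, vocab$concern_areas, "concern area")
  unlabeled <- setdiff(records$call_id, labels$call_id)
  if (length(unlabeled))
    stop("calls without a focus label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "))

  levels_ord <- vocab$follow_up_levels
  # resolve duplicate ratings per call: union of areas, most escalated level
  area_sets <- tapply(records$concern_areas, records$call_id, function(v)
    unique(unlist(split_labels(v))), simplify = FALSE)
  fu <- tapply(records$follow_up, records$call_id, function(v) {
    v <- v[!is.na(v) & nzchar(v)]
    if (!length(v)) NA_character_ else levels_ord[max(match(v, levels_ord))]
  })
  call_ids <- names(area_sets)
  grp <- labels$group[match(call_ids, labels$call_id)]

  strata <- list(all = rep(TRUE, length(call_ids)),
                 lifestyle_focused = grp == "lifestyle_focused")
  make_stratum <- function(keep) {
    ids <- call_ids[keep]
    sets <- area_sets[keep]
    lev <- fu[keep]
    tab <- matrix(0L, nrow = length(levels_ord), ncol = length(vocab$concern_areas),
                  dimnames = list(levels_ord, vocab$concern_areas))
    for (k in seq_along(ids)) {
      if (!length(sets[[k]]) || is.na(lev[k])) next
      tab[lev[k], sets[[k]]] <- tab[lev[k], sets[[k]]] + 1L
    }
    flagged <- sum(lengths(sets) > 0)
    list(table = tab, area_totals = colSums(tab), n_flagged = flagged,
         n_assessed = length(ids),
         call_areas = stats::setNames(sets, ids))
  }
  out <- lapply(strata, make_stratum)
  structure(c(out, list(vocab = vocab)), class = "concern_table")
}

#' @export
print.concern_table <- function(x, ...) {
  for (s in c("all", "lifestyle_focused")) {
    st <- x[[s]]
    cat(sprintf("%s calls (n = %d): %d flagged (%.1f%%)\n",
                if (s == "all") "All" else "Lifestyle-focused",
                st$n_assessed, st$n_flagged,
                100 * st$n_flagged / max(1, st$n_assessed)))
    print(st$table)
    cat("\n")
  }
  invisible(x)
}

#' Proportion of assessed calls flagged with at least one concern
#'
#' @param table A `concern_table`.
#' @param stratum `"all"` or `"lifestyle_focused"`.
#' @return The flagged percentage, rounded to one decimal (e.g. 24.2).
#' @export
flagged_proportion <- function(table, stratum = c("all", "lifestyle_focused")) {
  stratum <- match.arg(stratum)
  st <- table[[stratum]]
  if (!st$n_assessed)
    stop(errorCondition("no assessed calls in stratum",
                        class = "telefocus_degenerate"))
  round(100 * st$n_flagged / st$n_assessed, 1)
}

#' Union size of calls carrying any of several concern areas
#'
#' Inclusion-exclusion on per-area call counts using pairwise overlaps only:
#' |A u B| = |A| + |B| - |A n B|. For one area the union is its own count.
#' Overlap counts may be supplied (as published alongside marginal counts) or
#' are computed from the table's call-level area sets when omitted. More than
#' two areas require call-level sets, since pairwise terms alone do not
#' determine the union.
#'
#' @param table A `concern_table`.
#' @param areas Character vector of concern-area labels.
#' @param overlaps For two areas, the number of calls carrying both; `NULL`
#'   to compute from the table.
#' @param stratum `"all"` or `"lifestyle_focused"`.
#' @return Integer union count.
#' @export
union_concern_count <- function(table, areas, overlaps = NULL,
                                stratum = c("all", "lifestyle_focused")) {
  stratum <- match.arg(stratum)
  st <- table[[stratum]]
  check_labels(areas, table$vocab$concern_areas, "concern area")
  areas <- unique(areas)
  counts <- st$area_totals[areas]
  if (length(areas) == 1) return(as.integer(counts))
  if (is.null(overlaps)) {
    hit <- vapply(st$call_areas, function(s) any(areas %in% s), logical(1))
    return(as.integer(sum(hit)))
  }
  if (length(areas) > 2)
    stop("pairwise overlaps do not determine the union of >2 areas; ",
         "omit 'overlaps' to count from call-level sets")
  if (overlaps > min(counts) || overlaps < 0)
    stop("contract error: overlap count inconsistent with area counts")
  as.integer(sum(counts) - overlaps)
}

#' Synthetic concern records matching a published expert-review tabulation
#'
#' A synthetic reconstruction of 120 expert-assessed calls (30 of them
#' lifestyle-focused) whose area-by-follow-up-level cross-tabulation for all
#' calls, per-area totals (12, 6, 3, 12, 7, 4, 3, 1), flagged proportions
#' (29/120 overall, 9/30 within focused calls), and stated pairwise overlaps
#' (5 calls with both HF-symptom and vitals concerns; all lifestyle-concern
#' calls also carrying vitals concerns) reproduce the published summary of a
#' heart-failure telecare expert review. Individual call assignments are
#' synthetic: only the published marginals and overlap statements constrain
#' them, and the focused-stratum cell layout is approximate (the published
#' focused-stratum cells are not mutually consistent with the prose overlap
#' statements).
#'
#' @return A list with `records` (concern records, one per call) and
#'   `labels` (call_id and focus group for the 120 assessed calls).
#' @examples
#' ex <- example_concern_records()
#' tab <- tabulate_concerns(ex$records, ex$labels)
#' flagged_proportion(tab, "all")       # 24.2
#' flagged_proportion(tab, "lifestyle_focused")  # 30
#' @export
example_concern_records <- function() {
  a <- function(...) paste(c(...), collapse = ";")
  hf <- "hf_symptoms"; fl <- "influenza_symptoms"; gi <- "gastrointestinal_symptoms"
  vi <- "vitals"; co <- "comorbidities"; ls <- "lifestyle_management"
  md <- "medication_management"; ot <- "others"
  flagged <- data.frame(
    concern_areas = c(
      a(ls, vi, hf), a(ls, vi), a(ls, vi), a(ls, vi),           # case review
      a(hf, fl), a(hf, fl), a(hf, fl), a(hf, fl),
      a(hf, co), a(gi, co), a(gi, co), a(md, co), a(md),
      a(hf, vi), a(vi), a(md), a(ot),                           # business as usual
      a(hf, vi), a(vi), a(vi), a(co), a(co), a(co),             # call patient
      a(hf, vi), a(hf, vi), a(vi), a(hf, fl), a(hf, fl), a(gi)  # advise GP
    ),
    follow_up = rep(c("case_review", "business_as_usual", "call_patient",
                      "advise_gp_polyclinic"), c(13, 4, 6, 6)))
  flagged$call_id <- sprintf("EC%03d", seq_len(29))
  focused_flagged <- c("EC001", "EC002", "EC005", "EC009", "EC010",
                       "EC016", "EC019", "EC021", "EC024")
  unflagged <- data.frame(call_id = sprintf("EC%03d", 30:120),
                          concern_areas = "", follow_up = NA_character_)
  records <- rbind(flagged[, c("call_id", "concern_areas", "follow_up")],
                   unflagged)
  records$rater_id <- rep_len(c("R1", "R2"), nrow(records))
  records$remarks <- NA_character_
  focused <- c(focused_flagged, sprintf("EC%03d", 30:50))  # 9 + 21 = 30 focused
  labels <- data.frame(call_id = records$call_id,
                       group = ifelse(records$call_id %in% focused,
                                      "lifestyle_focused", "content_not_focused"))
  list(records = records[, c("call_id", "rater_id", "concern_areas",
                             "follow_up", "remarks")],
       labels = labels)
}

#' Write a concern table as CSV
#'
#' @param table A `concern_table`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_concern_table <- function(table, path) {
  rows <- list()
  for (s in c("all", "lifestyle_focused")) {
    st <- table[[s]]
    m <- as.data.frame(st$table)
    m <- cbind(stratum = s, follow_up = rownames(st$table), m)
    tot <- cbind(stratum = s, follow_up = "total",
                 as.data.frame(t(st$area_totals)))
    rows[[s]] <- rbind(m, tot)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
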