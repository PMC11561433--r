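#' Control parameters for lifestyle-focus detection
#'
#' The detection rule has two qualitative ingredients that must be made
#' operational: what counts as a "substantially heightened" topic ratio
#' relative to the previous call, and how much a ratio may drop while still
#' counting as "remained heightened" after a prior increase. Both are
#' expressed on the absolute ratio scale, which is natural when the baseline
#' topic share is low (around 2\% of utterances).
#'
#' @param topic Target topic label (default `"lifestyle_management"`).
#' @param delta_jump Minimum absolute ratio increase over the previous call
#'   for the jump rule (default 0.05).
#' @param delta_sustain Maximum permitted absolute ratio drop from the
#'   previous call for the sustain rule (default 0.02).
#' @param min_calls_for_fit Minimum trajectory length for fitting the median
#'   regression trend; shorter trajectories fall back to a constant line at
#'   the median ratio (default 4).
#' @return A list of class `focus_control`.
#' @export
focus_control <- function(topic = "lifestyle_management", delta_jump = 0.05,
                          delta_sustain = 0.02, min_calls_for_fit = 4L) {
  stopifnot(delta_jump >= 0, delta_sustain >= 0, min_calls_for_fit >= 2)
  structure(list(topic = topic, delta_jump = delta_jump,
                 delta_sustain = delta_sustain,
                 min_calls_for_fit = as.integer(min_calls_for_fit)),
            class = "focus_control")
}

#' Per-call topic utterance ratios along patient trajectories
#'
#' The utterance ratio of a topic in a call is the number of utterances
#' carrying that topic divided by the total number of utterances in the call
#' (across all topics). Calls are ordered by date within each patient and
#' indexed by a 0-based `order` column, which is the abscissa used for the
#' per-patient trend fit.
#'
#' @param cohort A `telecare_cohort` whose same-day calls have been merged
#'   (see [merge_same_day_calls()]).
#' @param topic Topic label; defaults to lifestyle management.
#' @return A data frame with one row per call: `patient_id`, `call_id`,
#'   `date`, `order`, `topic_count`, `total_count`, `ratio`.
#' @export
topic_ratios <- function(cohort, topic = "lifestyle_management") {
  stopifnot(inherits(cohort, "telecare_cohort"))
  check_labels(topic, cohort$vocab$topics, "topic")
  cl <- cohort$calls
  if (!nrow(cl))
    return(data.frame(patient_id = character(), call_id = character(),
                      date = as.Date(character()), order = integer(),
                      topic_count = integer(), total_count = integer(),
                      ratio = numeric()))
  u <- cohort$utterances
  total <- table(u$call_id)
  on_topic <- table(u$call_id[u$topic == topic])
  cl <- cl[order(cl$patient_id, as.Date(cl$date)), , drop = FALSE]
  tc <- as.integer(on_topic[as.character(cl$call_id)])
  tc[is.na(tc)] <- 0L
  tot <- as.integer(total[as.character(cl$call_id)])
  out <- data.frame(patient_id = cl$patient_id, call_id = cl$call_id,
                    date = as.Date(cl$date),
                    order = stats::ave(seq_len(nrow(cl)), cl$patient_id,
                                       FUN = seq_along) - 1L,
                    topic_count = tc, total_count = tot, ratio = tc / tot)
  rownames(out) <- NULL
  out
}

#' Fit the median (L1) regression trend of a ratio trajectory
#'
#' Fits the tau = 0.5 quantile regression line of ratio on call order — the
#' line minimising the sum of absolute residuals. The minimiser is found
#' exactly: for two or more distinct abscissae an L1-optimal line passes
#' through at least two data points, so all lines through point pairs are
#' enumerated and the one with the smallest absolute-residual sum returned
#' (first such line on ties; the L1 minimiser need not be unique, so
#' comparisons of fits should use the objective value, not coefficients).
#' Trajectories shorter than `min_calls_for_fit` get a constant line at the
#' median ratio, since a near-interpolating fit would leave no call strictly
#' above trend.
#'
#' @param ratio Numeric vector of per-call topic ratios.
#' @param order Call order abscissa (default `0:(n-1)`).
#' @param control A [focus_control()] list.
#' @return A list of class `trend_line`: `intercept`, `slope`, `fit_method`
#'   (`"median_regression"` or `"constant_median"`), and `objective` (the
#'   attained sum of absolute residuals).
#' @export
fit_median_trend <- function(ratio, order = seq_along(ratio) - 1,
                             control = focus_control()) {
  n <- length(ratio)
  stopifnot(n >= 1, length(order) == n)
  constant <- function() {
    m <- stats::median(ratio)
    structure(list(intercept = m, slope = 0,
                   fit_method = "constant_median",
                   objective = sum(abs(ratio - m))),
              class = "trend_line")
  }
  if (n < control$min_calls_for_fit) return(constant())
  best <- NULL
  best_loss <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- order[j] - order[i]
      if (dx == 0) next
      b <- (ratio[j] - ratio[i]) / dx
      a <- ratio[i] - b * order[i]
      loss <- sum(abs(ratio - (a + b * order)))
      if (loss < best_loss - 1e-12) {
        best_loss <- loss
        best <- c(a, b)
      }
    }
  }
  if (is.null(best)) return(constant())
  structure(list(intercept = best[1], slope = best[2],
                 fit_method = "median_regression", objective = best_loss),
            class = "trend_line")
}

#' @export
print.trend_line <- function(x, ...) {
  cat(sprintf("trend_line (%s): intercept %.4f, slope %.5f, L1 objective %.4f\n",
              x$fit_method, x$intercept, x$slope, x$objective))
  invisible(x)
}

#' @export
coef.trend_line <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

# strict/loose comparison tolerance for ratio arithmetic on decimal inputs
.ratio_eps <- 1e-9

#' Classify the calls of one patient trajectory
#'
#' Applies the three-way classification to an ordered ratio trajectory given
#' its fitted trend: a call is \emph{lifestyle-focused} when it has on-topic
#' content, its ratio lies strictly above the trend line at its order, and
#' either (jump rule) the ratio rose by at least `delta_jump` relative to the
#' previous call — the ratio before the first call is taken as 0 — or
#' (sustain rule) the previous call was itself focused and the ratio dropped
#' by no more than `delta_sustain`. Calls with on-topic content failing the
#' criteria are \emph{content, not focused}; calls with no on-topic
#' utterances are \emph{no content}.
#'
#' @param points Data frame with columns `ratio`, `order`, `topic_count`
#'   (and optionally `call_id`), ordered by `order`.
#' @param trend A `trend_line` fitted on these points.
#' @param control A [focus_control()] list.
#' @return A data frame with per-call `group`
#'   (`lifestyle_focused` / `content_not_focused` / `no_content`),
#'   `rule_fired` (`jump` / `sustained` / `none`) and `above_trend`.
#' @export
classify_focus_calls <- function(points, trend, control = focus_control()) {
  stopifnot(inherits(trend, "trend_line"),
            all(c("ratio", "order", "topic_count") %in% names(points)))
  points <- points[order(points$order), , drop = FALSE]
  n <- nrow(points)
  pred <- trend$intercept + trend$slope * points$order
  above <- points$ratio > pred + .ratio_eps
  group <- character(n)
  rule <- character(n)
  for (i in seq_len(n)) {
    prev_ratio <- if (i == 1) 0 else points$ratio[i - 1]
    jump <- (points$ratio[i] - prev_ratio) >= control$delta_jump - .ratio_eps
    sustained <- i > 1 && group[i - 1] == "lifestyle_focused" &&
      points$ratio[i] >= prev_ratio - control$delta_sustain - .ratio_eps
    if (points$topic_count[i] == 0) {
      group[i] <- "no_content"; rule[i] <- "none"
    } else if (above[i] && (jump || sustained)) {
      group[i] <- "lifestyle_focused"
      rule[i] <- if (jump) "jump" else "sustained"
    } else {
      group[i] <- "content_not_focused"; rule[i] <- "none"
    }
  }
  out <- points
  out$group <- group
  out$rule_fired <- rule
  out$above_trend <- above
  rownames(out) <- NULL
  out
}

#' Partition a cohort's calls into focus groups
#'
#' The main fitting function of the package. For every patient it merges
#' same-day calls, computes the topic ratio trajectory, fits the per-patient
#' median regression trend, and classifies each call as lifestyle-focused,
#' content-not-focused, or no-content. Borderline calls — above the trend
#' line with on-topic content but failing both the jump and sustain rules —
#' are collected into a review queue for manual inspection.
#'
#' @param cohort A `telecare_cohort`.
#' @param control A [focus_control()] list.
#' @return An object of class `focus_partition` with components
#'   \describe{
#'     \item{labels}{per-call data frame: `patient_id`, `call_id`, `date`,
#'       `order`, `ratio`, `topic_count`, `total_count`, `group`,
#'       `rule_fired`, `above_trend`.}
#'     \item{trends}{per-patient trend coefficients and fit method.}
#'     \item{counts}{per-patient group counts with a cohort total row.}
#'     \item{review_queue}{borderline calls, as a data frame.}
#'     \item{control}{the control list used.}
#'   }
#' @examples
#' gen <- generate_cohort(synthetic_config(n_patients = 5, seed = 7))
#' fit <- focus_partition(gen$cohort)
#' fit
#' head(summary(fit))
#' @export
focus_partition <- function(cohort, control = focus_control()) {
  stopifnot(inherits(cohort, "telecare_cohort"))
  cohort <- merge_same_day_calls(cohort)
  pts <- topic_ratios(cohort, control$topic)
  lab_list <- list()
  trend_list <- list()
  for (pid in unique(pts$patient_id)) {
    p <- pts[pts$patient_id == pid, , drop = FALSE]
    trend <- fit_median_trend(p$ratio, p$order, control)
    lab_list[[pid]] <- classify_focus_calls(p, trend, control)
    trend_list[[pid]] <- data.frame(patient_id = pid,
                                    intercept = trend$intercept,
                                    slope = trend$slope,
                                    fit_method = trend$fit_method)
  }
  labels <- do.call(rbind, c(lab_list, list(make.row.names = FALSE))) %||%
    cbind(pts, group = character(), rule_fired = character(),
          above_trend = logical())
  trends <- do.call(rbind, c(trend_list, list(make.row.names = FALSE))) %||%
    data.frame(patient_id = character(), intercept = numeric(),
               slope = numeric(), fit_method = character())
  counts <- partition_counts(labels)
  queue <- labels[labels$above_trend & labels$topic_count > 0 &
                    labels$group != "lifestyle_focused", , drop = FALSE]
  rownames(queue) <- NULL
  structure(list(labels = labels, trends = trends, counts = counts,
                 review_queue = queue, control = control),
            class = "focus_partition")
}

focus_groups <- c("lifestyle_focused", "content_not_focused", "no_content")

partition_counts <- function(labels) {
  tab <- table(labels$patient_id, factor(labels$group, levels = focus_groups))
  df <- as.data.frame.matrix(tab)
  df <- cbind(patient_id = rownames(df), df, n_calls = rowSums(df))
  rownames(df) <- NULL
  total <- data.frame(patient_id = "<cohort>",
                      t(colSums(df[, focus_groups, drop = FALSE])),
                      n_calls = sum(df$n_calls), check.names = FALSE)
  rbind(df, total)
}

#' @export
print.focus_partition <- function(x, ...) {
  tot <- x$counts[x$counts$patient_id == "<cohort>", ]
  cat("focus_partition of", nrow(x$trends), "patients,",
      tot$n_calls, "calls\n")
  cat(sprintf("  lifestyle-focused:    %d\n", tot$lifestyle_focused))
  cat(sprintf("  content, not focused: %d\n", tot$content_not_focused))
  cat(sprintf("  no content:           %d\n", tot$no_content))
  cat("  review queue:", nrow(x$review_queue), "borderline call(s)\n")
  invisible(x)
}

#' @export
summary.focus_partition <- function(object, ...) {
  object$counts
}

#' @export
plot.focus_partition <- function(x, patient_id, ...) {
  lab <- x$labels[x$labels$patient_id == patient_id, , drop = FALSE]
  if (!nrow(lab)) stop("no calls for patient ", patient_id)
  tr <- x$trends[x$trends$patient_id == patient_id, ]
  graphics::plot(lab$order, lab$ratio, type = "b",
                 xlab = "call order", ylab = "topic utterance ratio",
                 main = paste("Patient", patient_id), ...)
  graphics::abline(a = tr$intercept, b = tr$slope, lty = 2)
  foc <- lab$group == "lifestyle_focused"
  if (any(foc))
    graphics::points(lab$order[foc], lab$ratio[foc], pch = 19,
                     col = "firebrick")
  invisible(x)
}

#' Export focus labels and the review queue as CSV
#'
#' @param partition A `focus_partition`.
#' @param path Output CSV path for the labels.
#' @param queue_path Optional output CSV path for the review queue.
#' @return Invisibly, the label path.
#' @export
write_focus_labels <- function(partition, path, queue_path = NULL) {
  stopifnot(inherits(partition, "focus_partition"))
  cols <- c("patient_id", "call_id", "order", "ratio", "group",
            "rule_fired", "above_trend")
  utils::write.csv(partition$labels[, cols], path, row.names = FALSE)
  if (!is.null(queue_path))
    utils::write.csv(partition$review_queue[, cols], queue_path,
                     row.names = FALSE)
  invisible(path)
}
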