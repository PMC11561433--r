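#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a nurse-led
#' heart-failure telesupport corpus: per-patient sequences of 11-15 scheduled
#' calls over about 12 months; calls of 11-1289 utterances (log-uniform);
#' a low lifestyle-management topic share (2\% of utterances in calls that
#' touch the topic at all, with roughly a fifth of non-event calls carrying
#' such content) punctuated by planted focus events that raise the expected
#' share by `focus_ratio_boost`; dialogue-act counts that differ between
#' planted-focus and other content calls (negative-binomial with means 17.5
#' and 10.1 and a patient-level frailty inducing within-patient correlation);
#' and admissions whose average length of stay is coupled to the planted
#' focus-call count through a Gaussian copula targeting a Spearman rank
#' correlation of -0.3.
#'
#' @param n_patients Number of patients (default 50).
#' @param calls_range Integer range of calls per patient (default 11-15).
#' @param utterance_range Truncation range of utterances per call
#'   (default 11-1289).
#' @param utterance_median,utterance_sdlog Median and log-scale SD of the
#'   log-normal utterance-count distribution (defaults 178 and 1.0), chosen
#'   to match the published per-call utterance statistics (min 11,
#'   median 178, max 1289).
#' @param baseline_topic_share Expected lifestyle-management utterance share
#'   in content calls (default 0.02).
#' @param content_rate Probability that a non-event call carries lifestyle
#'   content at all (default 0.22).
#' @param focus_events_range Integer range of planted focus events per
#'   patient (default 0-4).
#' @param focus_events_probs Probabilities over the event counts in
#'   `focus_events_range`. The default (0.40, 0.05, 0.10, 0.15, 0.30) mirrors
#'   the published cohort: 40\% of patients with no focus calls and roughly
#'   2 focus calls per patient on average with an SD near 1.9.
#' @param focus_ratio_boost Added expected topic share during an event
#'   (default 0.10).
#' @param event_duration_probs Probabilities of event durations of 1 and 2
#'   consecutive calls (default 0.7 / 0.3).
#' @param dialogue_act_means,dialogue_act_sds Per-call dialogue-act count
#'   mean and SD for planted-focus vs other content calls (defaults
#'   17.5/10.1 and 12.4/7.7).
#' @param act_frailty_cv Coefficient of variation of the patient-level
#'   multiplicative frailty on dialogue-act counts (default 0.15).
#' @param utilization_coupling Target Spearman correlation between planted
#'   focus-call count and average LOS (default -0.3).
#' @param admission_mean,admission_sd Mean and SD of per-patient admission
#'   counts (default 3.4 / 2.8, negative binomial).
#' @param los_mean,los_sd Mean and SD of the patient-level average LOS
#'   (default 6.5 / 2.4 days, gamma marginal).
#' @param concern_flag_rate Target overall fraction of assessed calls flagged
#'   with at least one concern (default 0.242).
#' @param concern_flag_rate_focused Flag rate within focused calls
#'   (default 0.30).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 50L,
                             calls_range = c(11L, 15L),
                             utterance_range = c(11L, 1289L),
                             utterance_median = 178,
                             utterance_sdlog = 1.0,
                             baseline_topic_share = 0.02,
                             content_rate = 0.22,
                             focus_events_range = c(0L, 4L),
                             focus_events_probs = c(0.40, 0.05, 0.10, 0.15, 0.30),
                             focus_ratio_boost = 0.10,
                             event_duration_probs = c(`1` = 0.7, `2` = 0.3),
                             dialogue_act_means = c(focused = 17.5, not_focused = 10.1),
                             dialogue_act_sds = c(focused = 12.4, not_focused = 7.7),
                             act_frailty_cv = 0.15,
                             utilization_coupling = -0.3,
                             admission_mean = 3.4, admission_sd = 2.8,
                             los_mean = 6.5, los_sd = 2.4,
                             concern_flag_rate = 0.242,
                             concern_flag_rate_focused = 0.30,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              calls_range = as.integer(calls_range),
              utterance_range = as.integer(utterance_range),
              utterance_median = utterance_median,
              utterance_sdlog = utterance_sdlog,
              baseline_topic_share = baseline_topic_share,
              content_rate = content_rate,
              focus_events_range = as.integer(focus_events_range),
              focus_events_probs = focus_events_probs,
              focus_ratio_boost = focus_ratio_boost,
              event_duration_probs = event_duration_probs,
              dialogue_act_means = dialogue_act_means,
              dialogue_act_sds = dialogue_act_sds,
              act_frailty_cv = act_frailty_cv,
              utilization_coupling = utilization_coupling,
              admission_mean = admission_mean, admission_sd = admission_sd,
              los_mean = los_mean, los_sd = los_sd,
              concern_flag_rate = concern_flag_rate,
              concern_flag_rate_focused = concern_flag_rate_focused,
              seed = as.integer(seed))
  frac <- c(cfg$baseline_topic_share, cfg$content_rate, cfg$concern_flag_rate,
            cfg$concern_flag_rate_focused)
  if (any(frac < 0 | frac > 1)) stop("config error: fractions must lie in [0, 1]")
  if (cfg$baseline_topic_share + cfg$focus_ratio_boost > 1)
    stop("config error: boost pushes topic share above 1")
  if (diff(cfg$calls_range) < 0 || diff(cfg$utterance_range) < 0 ||
      diff(cfg$focus_events_range) < 0)
    stop("config error: empty range")
  if (length(cfg$focus_events_probs) != diff(cfg$focus_events_range) + 1L)
    stop("config error: focus_events_probs must match the events range")
  if (abs(cfg$utilization_coupling) > 1)
    stop("config error: |utilization_coupling| must be <= 1")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Inject focus events into a topic-share trajectory
#'
#' Adds `boost` to the expected topic share of the calls covered by each
#' event (a start position and a duration in calls), capping at 1.
#' Overlapping or abutting event extents are merged. Non-event calls are
#' unchanged.
#'
#' @param shares Numeric vector of per-call expected topic shares.
#' @param events Data frame with `position` (1-based call index) and
#'   `duration` (calls); may have zero rows.
#' @param boost Added share (fraction).
#' @return A list: `shares` (modified vector) and `planted` (logical vector
#'   marking event calls).
#' @export
inject_focus_events <- function(shares, events, boost) {
  n <- length(shares)
  planted <- rep(FALSE, n)
  if (nrow(events)) {
    if (any(events$position < 1 | events$position > n))
      stop("event position outside trajectory")
    for (k in seq_len(nrow(events))) {
      idx <- events$position[k]:min(n, events$position[k] + events$duration[k] - 1)
      planted[idx] <- TRUE
    }
  }
  shares[planted] <- pmin(1, shares[planted] + boost)
  list(shares = shares, planted = planted)
}

# Patient-level background topic mixture: a fixed realistic base mixture over
# the 12 non-target topics, Dirichlet-perturbed per patient.
base_topic_mixture <- function(topics, target) {
  others <- setdiff(topics, target)
  w <- stats::setNames(rep(1, length(others)), others)
  heavy <- intersect(c("symptom_checking", "telemonitoring", "vitals",
                       "social_chatting", "medication_management"), others)
  w[heavy] <- 4
  w / sum(w)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic telecare cohort with ground truth
#'
#' Draws a full cohort dataset (patients, annotated calls with utterance
#' topics, speakers, dialogue acts and attributes, admissions, expert concern
#' records) under the model described in [synthetic_config()], together with
#' the planted ground truth used for recovery testing: which calls carry an
#' injected focus event, and the patient-level latent average-LOS target of
#' the Gaussian-copula coupling.
#'
#' @param config A [synthetic_config()].
#' @param vocab A `telecare_vocabulary`.
#' @return A list with components:
#'   \describe{
#'     \item{cohort}{a validated [telecare_cohort()].}
#'     \item{truth}{per-call data frame: `call_id`, `patient_id`, `order`,
#'       `is_planted_focus`.}
#'     \item{patient_truth}{per-patient data frame: `patient_id`,
#'       `n_events`, `n_planted_calls`, `los_target`.}
#'   }
#' @export
generate_cohort <- function(config = synthetic_config(),
                            vocab = read_vocabulary()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  np <- config$n_patients
  target <- "lifestyle_management"
  base_mix <- base_topic_mixture(vocab$topics, target)
  others <- names(base_mix)
  act_cat_probs <- list(
    focused = c(exchanging_information = 531, understanding_information = 146,
                performing_action = 39, evaluation_of_health_condition = 21,
                social_emotional = 29, incomplete_dialogue_act = 68, others = 25),
    not_focused = c(exchanging_information = 557, understanding_information = 154,
                    performing_action = 15, evaluation_of_health_condition = 16,
                    social_emotional = 15, incomplete_dialogue_act = 30, others = 21))
  act_cat_probs <- lapply(act_cat_probs, function(x) x / sum(x))
  nb_size <- function(mu, sd) {
    v <- sd^2
    if (v <= mu) Inf else mu^2 / (v - mu)
  }
  size_f <- nb_size(config$dialogue_act_means["focused"],
                    config$dialogue_act_sds["focused"])
  size_nf <- nb_size(config$dialogue_act_means["not_focused"],
                     config$dialogue_act_sds["not_focused"])
  cv <- config$act_frailty_cv

  pids <- sprintf("P%03d", seq_len(np))
  start <- as.Date("2015-01-01") + sample.int(365, np, replace = TRUE) - 1
  patients <- data.frame(
    patient_id = pids, age = pmin(95, pmax(25, round(stats::rnorm(np, 59, 14.3)))),
    gender = sample(c("male", "female"), np, TRUE, prob = c(0.74, 0.26)),
    ethnicity = sample(c("chinese", "malay", "indian", "others"), np, TRUE,
                       prob = c(0.58, 0.16, 0.14, 0.12)),
    hf = TRUE, t2dm = sample(c(TRUE, FALSE), np, TRUE),
    intervention_start = start, intervention_end = start + 365)

  calls_l <- list(); call_pid <- list(); truth_l <- list()
  utt_call <- list(); utt_topic <- list(); utt_acts <- list()
  n_events <- integer(np); n_planted <- integer(np)
  call_counter <- 0L

  for (i in seq_len(np)) {
    nc <- sample(seq(config$calls_range[1], config$calls_range[2]), 1)
    day_span <- 365 + 183
    days <- sort(sample.int(day_span, nc))
    dates <- patients$intervention_start[i] + days - 1

    # expected lifestyle share per call, then planted events on top
    content <- stats::runif(nc) < config$content_rate
    shares <- ifelse(content, config$baseline_topic_share, 0)
    ev_support <- seq(config$focus_events_range[1], config$focus_events_range[2])
    ne <- sample(ev_support, 1, prob = config$focus_events_probs)
    ne <- min(ne, nc)
    events <- if (ne > 0)
      data.frame(position = sort(sample.int(nc, ne)),
                 duration = sample(as.integer(names(config$event_duration_probs)),
                                   ne, TRUE, prob = config$event_duration_probs))
    else data.frame(position = integer(), duration = integer())
    # event calls are content calls over their whole extent
    extent <- inject_focus_events(shares, events, 0)$planted
    shares[extent] <- config$baseline_topic_share
    inj <- inject_focus_events(shares, events, config$focus_ratio_boost)
    n_events[i] <- nrow(events)
    n_planted[i] <- sum(inj$planted)

    mix_p <- rdirichlet1(50 * base_mix)  # patient-level background mixture
    frailty <- stats::rgamma(1, shape = 1 / cv^2, rate = 1 / cv^2)

    ids <- sprintf("C%05d", call_counter + seq_len(nc))
    call_counter <- call_counter + nc
    calls_l[[i]] <- data.frame(call_id = ids, patient_id = pids[i],
                               date = dates, scheduled = TRUE)
    truth_l[[i]] <- data.frame(call_id = ids, patient_id = pids[i],
                               order = seq_len(nc) - 1L,
                               is_planted_focus = inj$planted)

    n_u <- pmin(config$utterance_range[2],
                pmax(config$utterance_range[1],
                     round(stats::rlnorm(nc, log(config$utterance_median),
                                         config$utterance_sdlog))))
    for (j in seq_len(nc)) {
      s <- inj$shares[j]
      probs <- c(s, (1 - s) * mix_p)
      counts <- stats::rmultinom(1, n_u[j], probs)[, 1]
      topics_vec <- sample(rep.int(c(target, others), counts))
      acts_vec <- character(length(topics_vec))
      lifestyle_idx <- which(topics_vec == target)
      if (length(lifestyle_idx)) {
        grp <- if (inj$planted[j]) "focused" else "not_focused"
        mu <- config$dialogue_act_means[grp] * frailty
        size <- if (grp == "focused") size_f else size_nf
        total_acts <- if (is.finite(size)) stats::rnbinom(1, mu = mu, size = size)
                      else stats::rpois(1, mu)
        if (total_acts > 0) {
          cats <- sample(names(act_cat_probs[[grp]]), total_acts, TRUE,
                         prob = act_cat_probs[[grp]])
          acts <- vapply(cats, function(cc)
            sample(vocab$dialogue_acts[[cc]], 1)[[1]], character(1))
          slot <- sample(seq_along(lifestyle_idx), total_acts, replace = TRUE)
          joined <- vapply(split(acts, slot), paste, character(1), collapse = ";")
          acts_vec[lifestyle_idx[as.integer(names(joined))]] <- joined
        }
      }
      utt_call[[length(utt_call) + 1L]] <- rep(ids[j], length(topics_vec))
      utt_topic[[length(utt_topic) + 1L]] <- topics_vec
      utt_acts[[length(utt_acts) + 1L]] <- acts_vec
    }
  }

  utt_topic_v <- unlist(utt_topic, use.names = FALSE)
  n_total <- length(utt_topic_v)
  utt_call_v <- unlist(utt_call, use.names = FALSE)
  utterances <- data.frame(
    call_id = utt_call_v,
    index = stats::ave(integer(n_total), utt_call_v, FUN = seq_along) - 1L,
    speaker = sample(vocab$speakers, n_total, TRUE,
                     prob = c(0.48, 0.42, 0.08, 0.02)),
    topic = utt_topic_v,
    dialogue_acts = unlist(utt_acts, use.names = FALSE),
    attributes = "", text = NA_character_)
  # sprinkle attributes on topically matching utterances
  attr_groups <- list(symptom_checking = vocab$attributes$symptom,
                      lifestyle_management = vocab$attributes$lifestyle,
                      vitals = vocab$attributes$vitals)
  for (tp in names(attr_groups)) {
    idx <- which(utterances$topic == tp)
    pick <- idx[stats::runif(length(idx)) < 0.3]
    if (length(pick))
      utterances$attributes[pick] <- sample(attr_groups[[tp]], length(pick),
                                            replace = TRUE)
  }

  calls <- do.call(rbind, c(calls_l, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(truth_l, list(make.row.names = FALSE)))

  adm <- generate_admissions(patients, n_planted, config)
  patient_truth <- data.frame(patient_id = pids, n_events = n_events,
                              n_planted_calls = n_planted,
                              los_target = adm$los_target)

  concerns <- generate_expert_evaluations_impl(truth$call_id,
                                               truth$is_planted_focus,
                                               config, vocab)

  cohort <- telecare_cohort(patients = patients, calls = calls,
                            utterances = utterances,
                            admissions = adm$admissions,
                            concerns = concerns, vocab = vocab)
  list(cohort = cohort, truth = truth, patient_truth = patient_truth)
}

# Admissions with a Gaussian-copula coupling between the planted focus-call
# count and the patient-level average-LOS target.
generate_admissions <- function(patients, n_planted, config) {
  np <- nrow(patients)
  r <- 2 * sin(pi * config$utilization_coupling / 6)  # Spearman -> Pearson (copula)
  z1 <- stats::qnorm((rank(n_planted, ties.method = "random") - 0.5) / np)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(np)
  shape <- (config$los_mean / config$los_sd)^2
  rate <- config$los_mean / config$los_sd^2
  los_target <- stats::qgamma(stats::pnorm(z2), shape = shape, rate = rate)

  v <- config$admission_sd^2
  n_adm <- if (v > config$admission_mean)
    stats::rnbinom(np, mu = config$admission_mean,
                   size = config$admission_mean^2 / (v - config$admission_mean))
  else stats::rpois(np, config$admission_mean)

  rows <- list()
  for (i in seq_len(np)) {
    if (n_adm[i] > 0) {
      los <- pmax(0, round(los_target[i] + stats::rnorm(n_adm[i], 0, 1)))
      lo <- patients$intervention_start[i] - 183
      hi <- patients$intervention_end[i] + 183
      admit <- lo + sample.int(as.integer(hi - lo) + 1L, n_adm[i],
                               replace = TRUE) - 1
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patients$patient_id[i], admit_date = admit,
        discharge_date = admit + los,
        cause = sample(c("hf_related", "cvd_related", "all_cause"), n_adm[i],
                       TRUE, prob = c(0.5, 0.2, 0.3)),
        elective = FALSE)
    }
    if (stats::runif(1) < 0.15) {  # an elective stay, excluded by windowing
      admit <- patients$intervention_start[i] + sample.int(300, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patients$patient_id[i], admit_date = admit,
        discharge_date = admit, cause = "all_cause", elective = TRUE)
    }
    if (stats::runif(1) < 0.15) {  # an out-of-window stay
      admit <- patients$intervention_start[i] - 184 - sample.int(120, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patients$patient_id[i], admit_date = admit,
        discharge_date = admit + 3, cause = "all_cause", elective = FALSE)
    }
  }
  admissions <- do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(patient_id = character(), admit_date = as.Date(character()),
               discharge_date = as.Date(character()), cause = character(),
               elective = logical())
  list(admissions = admissions, los_target = los_target)
}

#' Generate synthetic expert concern evaluations
#'
#' Draws one concern record per call. Focused calls are flagged at
#' `concern_flag_rate_focused`; the rate for other calls is chosen so the
#' overall flag rate targets `concern_flag_rate` given the realized focused
#' fraction. Flagged calls receive one or (with probability 0.3) two concern
#' areas with marginal weights mirroring the published area mix, and a
#' follow-up level drawn from the published level mix; unflagged calls carry
#' no areas and no level.
#'
#' @param cohort A `telecare_cohort` (only call identifiers are used).
#' @param labels A [focus_partition()] or data frame with `call_id`, `group`.
#' @param config A [synthetic_config()].
#' @param vocab A `telecare_vocabulary`.
#' @return A concern-records data frame.
#' @export
generate_expert_evaluations <- function(cohort, labels,
                                        config = synthetic_config(),
                                        vocab = read_vocabulary()) {
  if (inherits(labels, "focus_partition")) labels <- labels$labels
  ids <- cohort$calls$call_id
  grp <- labels$group[match(ids, labels$call_id)]
  if (anyNA(grp)) stop("labels do not cover the sampled calls")
  generate_expert_evaluations_impl(ids, grp == "lifestyle_focused", config, vocab)
}

generate_expert_evaluations_impl <- function(call_ids, focused, config, vocab) {
  n <- length(call_ids)
  f <- mean(focused)
  rate_other <- if (f < 1)
    min(1, max(0, (config$concern_flag_rate -
                     f * config$concern_flag_rate_focused) / (1 - f)))
  else config$concern_flag_rate_focused
  p_flag <- ifelse(focused, config$concern_flag_rate_focused, rate_other)
  flagged <- stats::runif(n) < p_flag
  area_w <- c(hf_symptoms = 12, influenza_symptoms = 6,
              gastrointestinal_symptoms = 3, vitals = 12, comorbidities = 7,
              lifestyle_management = 4, medication_management = 3, others = 1)
  lvl_w <- c(business_as_usual = 4, case_review = 13, call_patient = 6,
             advise_gp_polyclinic = 6)
  areas <- character(n)
  fu <- rep(NA_character_, n)
  for (k in which(flagged)) {
    n_areas <- 1 + (stats::runif(1) < 0.3)
    areas[k] <- paste(sample(names(area_w), n_areas, prob = area_w),
                      collapse = ";")
    fu[k] <- sample(names(lvl_w), 1, prob = lvl_w)
  }
  data.frame(call_id = call_ids, rater_id = "R1", concern_areas = areas,
             follow_up = fu, remarks = NA_character_)
}
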