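# Fixture builders and independent oracles used across the suite.

voc <- read_vocabulary()

# Build an utterance table from a character vector of topics for one call.
make_utts <- function(call_id, topics, acts = "", attrs = "", text = NA_character_) {
  data.frame(call_id = call_id, index = seq_along(topics) - 1L,
             speaker = rep_len(c("nurse_telecarer", "patient"), length(topics)),
             topic = topics, dialogue_acts = rep_len(acts, length(topics)),
             attributes = rep_len(attrs, length(topics)),
             text = rep_len(text, length(topics)))
}

# A call with n_topic lifestyle-management utterances out of n_total.
lifestyle_topics <- function(n_topic, n_total) {
  c(rep("lifestyle_management", n_topic),
    rep("symptom_checking", n_total - n_topic))
}

make_patients <- function(ids, start = as.Date("2015-03-01")) {
  data.frame(patient_id = ids, age = 60, gender = "male", ethnicity = "chinese",
             hf = TRUE, t2dm = TRUE, intervention_start = start,
             intervention_end = start + 365)
}

# Cohort with one patient and per-call lifestyle counts given as a list of
# c(topic_count, total_count); calls on consecutive days.
ratio_cohort <- function(counts, patient_id = "P1",
                         start = as.Date("2015-03-10")) {
  ids <- sprintf("%s_c%d", patient_id, seq_along(counts))
  calls <- data.frame(call_id = ids, patient_id = patient_id,
                      date = start + seq_along(counts) - 1, scheduled = TRUE)
  utts <- do.call(rbind, Map(function(id, ct)
    make_utts(id, lifestyle_topics(ct[1], ct[2])), ids, counts))
  telecare_cohort(make_patients(patient_id), calls, utts, vocab = voc)
}

# --- independent oracles ---------------------------------------------------

# Literal re-implementation of the classification rule text, written
# independently of classify_focus_calls.
brute_classify <- function(ratio, topic_count, intercept, slope,
                           dj = 0.05, ds = 0.02) {
  eps <- 1e-9
  n <- length(ratio)
  grp <- character(n); rule <- character(n)
  for (i in seq_len(n)) {
    if (topic_count[i] == 0) { grp[i] <- "no_content"; rule[i] <- "none"; next }
    above <- ratio[i] > intercept + slope * (i - 1) + eps
    prev <- if (i == 1) 0 else ratio[i - 1]
    heightened_jump <- ratio[i] - prev >= dj - eps
    remained <- i > 1 && grp[i - 1] == "lifestyle_focused" &&
      ratio[i] >= prev - ds - eps
    if (above && heightened_jump) { grp[i] <- "lifestyle_focused"; rule[i] <- "jump" }
    else if (above && remained) { grp[i] <- "lifestyle_focused"; rule[i] <- "sustained" }
    else { grp[i] <- "content_not_focused"; rule[i] <- "none" }
  }
  data.frame(group = grp, rule_fired = rule)
}

# Dense grid search over (intercept, slope) minimising the L1 check loss.
grid_l1_min <- function(ratio, order) {
  a_grid <- seq(min(ratio) - 0.05, max(ratio) + 0.05, by = 0.002)
  b_grid <- seq(-0.1, 0.1, by = 0.001)
  best <- Inf
  for (b in b_grid) {
    res <- outer(a_grid, b * order, `+`)      # predictions: grid x points
    loss <- rowSums(abs(sweep(res, 2, ratio, function(p, y) p - y)))
    best <- min(best, min(loss))
  }
  best
}

# Textbook Fleiss kappa, computed along a different code path.
fleiss_oracle <- function(m) {
  N <- nrow(m); n <- sum(m[1, ])
  P_i <- apply(m, 1, function(x) (sum(x * (x - 1))) / (n * (n - 1)))
  p_j <- colSums(m) / (N * n)
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# Pearson correlation of hand-computed midranks.
spearman_oracle <- function(x, y) {
  mid <- function(v) vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
  rx <- mid(x); ry <- mid(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Hand-expanded CR1 sandwich SE of the group coefficient.
sandwich_oracle <- function(y, g, cluster) {
  X <- cbind(1, g)
  n <- length(y); K <- 2
  bread <- solve(t(X) %*% X)
  beta <- bread %*% t(X) %*% y
  u <- y - X %*% beta
  meat <- matrix(0, 2, 2)
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    s <- t(X[idx, , drop = FALSE]) %*% u[idx]
    meat <- meat + s %*% t(s)
  }
  G <- length(unique(cluster))
  V <- (G / (G - 1)) * ((n - 1) / (n - K)) * bread %*% meat %*% bread
  sqrt(V[2, 2])
}

# Detection performance of a fitted partition against planted truth.
detection_stats <- function(gen, fit) {
  m <- merge(fit$labels, gen$truth[, c("call_id", "is_planted_focus")],
             by = "call_id")
  det <- m$group == "lifestyle_focused"
  c(recall = sum(det & m$is_planted_focus) / sum(m$is_planted_focus),
    precision = sum(det & m$is_planted_focus) / max(1, sum(det)),
    queue_capture = sum((det | m$call_id %in% fit$review_queue$call_id) &
                          m$is_planted_focus) / sum(m$is_planted_focus))
}
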