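test_that("the generator is deterministic in its seed and respects ranges", {
  cfg <- synthetic_config(n_patients = 10, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (tab in c("patients", "calls", "utterances", "admissions", "concerns"))
    expect_identical(a$cohort[[tab]], b$cohort[[tab]])
  expect_identical(a$truth, b$truth)
  expect_identical(a$patient_truth, b$patient_truth)
  expect_true(nrow(a$cohort$calls) >= 110 && nrow(a$cohort$calls) <= 150)
  upc <- table(a$cohort$utterances$call_id)
  expect_true(all(upc >= 11 & upc <= 1289))
  # closed loop with corpus validation
  expect_silent(validate_cohort(a$cohort))
})

test_that("config validation rejects infeasible settings", {
  expect_error(synthetic_config(baseline_topic_share = 0.95,
                                focus_ratio_boost = 0.10),
               "config error")
  expect_error(synthetic_config(focus_events_probs = c(0.5, 0.5)),
               "focus_events_probs")
  expect_error(synthetic_config(concern_flag_rate = 1.2), "config error")
})

test_that("focus events are injected additively with merge of overlaps", {
  shares <- rep(0.02, 10)
  none <- inject_focus_events(shares, data.frame(position = 3, duration = 1), 0)
  expect_equal(none$shares, shares)
  one <- inject_focus_events(shares, data.frame(position = 3, duration = 1), 0.10)
  expect_equal(one$shares[3], 0.12)
  expect_equal(one$shares[-3], shares[-3])
  expect_equal(which(one$planted), 3)
  overlap <- inject_focus_events(shares,
                                 data.frame(position = c(3, 4), duration = c(2, 2)),
                                 0.10)
  expect_equal(which(overlap$planted), 3:5)
  expect_equal(max(overlap$shares), 0.12)   # overlapping events merge, not stack
  capped <- inject_focus_events(rep(0.95, 3), data.frame(position = 1, duration = 1),
                                0.10)
  expect_equal(capped$shares[1], 1)
  expect_error(inject_focus_events(shares, data.frame(position = 12, duration = 1),
                                   0.1),
               "outside")
})

test_that("realized event-call topic shares concentrate at baseline plus boost", {
  shares <- c()
  for (s in 1:3) {
    gen <- generate_cohort(synthetic_config(n_patients = 30, seed = 100 + s))
    pts <- topic_ratios(merge_same_day_calls(gen$cohort))
    m <- merge(pts, gen$truth[, c("call_id", "is_planted_focus")], by = "call_id")
    shares <- c(shares, m$ratio[m$is_planted_focus])
  }
  expect_gt(length(shares), 150)
  expect_equal(mean(shares), 0.12, tolerance = 0.02 / 0.12)
})

test_that("concern generation targets the configured flag rate", {
  gen <- generate_cohort(synthetic_config(n_patients = 40, seed = 77))
  con <- gen$cohort$concerns
  expect_gt(nrow(con), 400)
  flag_rate <- mean(nzchar(con$concern_areas))
  expect_lt(abs(flag_rate - 0.242), 0.04)
  # degenerate rates
  cfg0 <- synthetic_config(n_patients = 5, concern_flag_rate = 0,
                           concern_flag_rate_focused = 0, seed = 1)
  g0 <- generate_cohort(cfg0)
  expect_true(all(!nzchar(g0$cohort$concerns$concern_areas)))
  cfg1 <- synthetic_config(n_patients = 5, concern_flag_rate = 1,
                           concern_flag_rate_focused = 1, seed = 1)
  g1 <- generate_cohort(cfg1)
  expect_true(all(nzchar(g1$cohort$concerns$concern_areas)))
})

test_that("planted dialogue-act means differ by the configured amounts", {
  gen <- generate_cohort(synthetic_config(seed = 31))
  acts <- dialogue_act_counts(gen$cohort)
  pts <- topic_ratios(merge_same_day_calls(gen$cohort))
  m <- merge(merge(acts, pts[, c("call_id", "topic_count")], by = "call_id"),
             gen$truth[, c("call_id", "is_planted_focus")], by = "call_id")
  m <- m[m$topic_count > 0, ]
  mf <- mean(m$overall[m$is_planted_focus])
  mn <- mean(m$overall[!m$is_planted_focus])
  expect_equal(mf, 17.5, tolerance = 0.25)
  expect_equal(mn, 10.1, tolerance = 0.25)
})
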