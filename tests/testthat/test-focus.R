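test_that("topic ratios are per-call shares in trajectory order", {
  ds <- ratio_cohort(list(c(0, 100), c(200, 200), c(10, 200)))
  pts <- topic_ratios(ds)
  expect_equal(pts$order, 0:2)
  expect_equal(pts$ratio, c(0, 1, 0.05))
  expect_equal(pts$topic_count / pts$total_count, pts$ratio)
})

test_that("median trend fitting is exact on clean cases and grid-minimal on noise", {
  flat <- fit_median_trend(rep(0.05, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$objective, 0)
  expect_equal(flat$intercept, 0.05)

  ord <- 0:5
  line <- fit_median_trend(0.01 + 0.002 * ord, ord)
  expect_equal(unname(coef(line)), c(0.01, 0.002), tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:5) {
    y <- pmax(0, 0.02 + 0.003 * ord + rnorm(6, 0, 0.02))
    fit <- fit_median_trend(y, ord)
    expect_lte(fit$objective, grid_l1_min(y, ord) + 1e-9)
    # cross-check against an established quantile-regression routine
    rq <- quantreg::rq(y ~ ord, tau = 0.5)
    expect_equal(fit$objective, sum(abs(resid(rq))), tolerance = 1e-8)
  }

  short <- fit_median_trend(c(0.1, 0.4, 0.2))
  expect_equal(short$fit_method, "constant_median")
  expect_equal(short$slope, 0)
  expect_equal(short$intercept, 0.2)
})

test_that("classification follows the jump and sustain rules", {
  ds <- ratio_cohort(list(c(1, 100), c(2, 100), c(10, 100), c(9, 100), c(1, 100)))
  fit <- focus_partition(ds)
  lab <- fit$labels
  expect_equal(lab$group[lab$order %in% c(2, 3)],
               rep("lifestyle_focused", 2))
  expect_equal(lab$rule_fired[lab$order == 2], "jump")
  expect_equal(lab$rule_fired[lab$order == 3], "sustained")
  expect_equal(lab$group[lab$order %in% c(0, 1, 4)],
               rep("content_not_focused", 3))

  # all-zero trajectory: everything no_content
  zero <- focus_partition(ratio_cohort(list(c(0, 10), c(0, 20), c(0, 30))))
  expect_true(all(zero$labels$group == "no_content"))

  # single call exactly on its constant-median trend is not strictly above
  single <- focus_partition(ratio_cohort(list(c(2, 10))))
  expect_equal(single$labels$group, "content_not_focused")
})

test_that("labels on short trajectories match the brute-force rule text", {
  ctrl <- focus_control()
  set.seed(7)
  ratio_values <- seq(0, 0.3, by = 0.01)
  for (case in 1:300) {
    n <- sample(1:8, 1)
    ratio <- sample(ratio_values, n, replace = TRUE)
    total <- sample(c(10, 50, 200), n, replace = TRUE)
    tc <- round(ratio * total)
    ratio <- tc / total
    pts <- data.frame(ratio = ratio, order = 0:(n - 1), topic_count = tc)
    trend <- fit_median_trend(ratio, pts$order, ctrl)
    got <- classify_focus_calls(pts, trend, ctrl)
    want <- brute_classify(ratio, tc, trend$intercept, trend$slope)
    expect_identical(got$group, want$group)
    expect_identical(got$rule_fired, want$rule_fired)
  }
})

test_that("raising the jump threshold never adds focused calls", {
  set.seed(11)
  ds <- generate_cohort(synthetic_config(n_patients = 6, seed = 11))$cohort
  prev <- Inf
  for (dj in c(0.01, 0.03, 0.05, 0.1, 0.2)) {
    ctrl <- focus_control(delta_jump = dj, delta_sustain = 0)
    k <- sum(focus_partition(ds, ctrl)$labels$group == "lifestyle_focused")
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("labels are invariant to scaling all utterance counts in a call", {
  counts <- list(c(1, 50), c(2, 50), c(7, 50), c(6, 50), c(0, 50))
  a <- focus_partition(ratio_cohort(counts))
  b <- focus_partition(ratio_cohort(lapply(counts, `*`, 4L)))
  expect_equal(a$labels$group, b$labels$group)
  expect_equal(a$labels$ratio, b$labels$ratio)
})

test_that("the partition covers every call exactly once", {
  gen <- generate_cohort(synthetic_config(n_patients = 10, seed = 3))
  fit <- focus_partition(gen$cohort)
  counts <- fit$counts
  per_patient <- counts[counts$patient_id != "<cohort>", ]
  expect_equal(per_patient$lifestyle_focused + per_patient$content_not_focused +
                 per_patient$no_content, per_patient$n_calls)
  expect_equal(sum(per_patient$n_calls), nrow(gen$cohort$calls))
  total <- counts[counts$patient_id == "<cohort>", ]
  expect_equal(total$n_calls, sum(per_patient$n_calls))
  # no-content cohort
  noc <- focus_partition(ratio_cohort(list(c(0, 5), c(0, 5), c(0, 5))))
  tot <- noc$counts[noc$counts$patient_id == "<cohort>", ]
  expect_equal(c(tot$lifestyle_focused, tot$content_not_focused, tot$no_content),
               c(0, 0, 3))
})
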