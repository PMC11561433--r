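profile1 <- list(intervention_start = as.Date("2015-03-01"),
                 intervention_end = as.Date("2016-03-01"))

test_that("admission windowing keeps the stated closed interval, non-elective only", {
  adm <- data.frame(
    patient_id = "P1",
    admit_date = as.Date("2015-03-01") + c(-183, -184, 0, 100, 549, 550),
    discharge_date = as.Date("2015-03-01") + c(-180, -180, 4, 103, 551, 560),
    elective = FALSE)
  kept <- filter_admissions_window(adm, profile1)
  expect_equal(kept$admit_date,
               as.Date("2015-03-01") + c(-183, 0, 100, 549))
  elec <- adm; elec$elective <- TRUE
  expect_equal(nrow(filter_admissions_window(elec, profile1)), 0)

  set.seed(17)
  rand <- data.frame(patient_id = "P1",
                     admit_date = as.Date("2015-03-01") + sample(-400:900, 60),
                     elective = runif(60) < 0.3)
  rand$discharge_date <- rand$admit_date + sample(0:10, 60, replace = TRUE)
  got <- filter_admissions_window(rand, profile1)
  lo <- as.Date("2015-03-01") - 183; hi <- as.Date("2016-03-01") + 183
  want <- rand[!rand$elective & rand$admit_date >= lo & rand$admit_date <= hi, ]
  expect_equal(got$admit_date, want$admit_date)
})

test_that("average LOS is bed days per admission in whole days", {
  one <- data.frame(admit_date = as.Date("2015-04-01"),
                    discharge_date = as.Date("2015-04-06"))
  expect_equal(average_los(one), 5)
  two <- data.frame(admit_date = as.Date(c("2015-04-01", "2015-05-01")),
                    discharge_date = as.Date(c("2015-04-03", "2015-05-07")))
  expect_equal(average_los(two), 4)
  same_day <- data.frame(admit_date = as.Date("2015-04-01"),
                         discharge_date = as.Date("2015-04-01"))
  expect_equal(average_los(same_day), 0)
  expect_error(average_los(one[0, ]), class = "telefocus_degenerate")
})

test_that("associations: perfect monotone case, exclusions, permutation invariance", {
  s <- data.frame(patient_id = sprintf("P%d", 1:6),
                  n_admissions = c(2, 3, 1, 4, 0, 2),
                  avg_los = c(10, 8, 6, 4, NA, 2),
                  n_focus_calls = c(0, 1, 2, 3, 4, 5),
                  has_focus_call = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  a <- associate_focus_with_utilization(s)
  expect_equal(a$avg_los$rho, -1)
  expect_equal(a$avg_los$n, 5)        # zero-admission patient excluded
  expect_equal(a$n_admissions$n, 6)   # but included with count 0
  expect_gte(a$avg_los$p_adjusted, a$avg_los$p_value)
  perm <- s[sample(nrow(s)), ]
  b <- associate_focus_with_utilization(perm)
  expect_equal(b$avg_los$rho, a$avg_los$rho)
  expect_equal(b$n_admissions$rho, a$n_admissions$rho)
  expect_equal(b$avg_los$p_adjusted, a$avg_los$p_adjusted)
})

test_that("group comparison reproduces a pooled-SD hand computation", {
  s <- data.frame(patient_id = sprintf("P%d", 1:4),
                  n_admissions = c(2, 4, 3, 5),
                  avg_los = c(3, 5, 6, 8),
                  n_focus_calls = c(1, 2, 0, 0),
                  has_focus_call = c(TRUE, TRUE, FALSE, FALSE))
  comp <- compare_focus_groups(s)
  # focused avg_los (3,5): mean 4, var 2; not focused (6,8): mean 7, var 2
  expect_equal(comp$avg_los$d, (4 - 7) / sqrt(2))
  expect_equal(comp$n_admissions$d, (3 - 4) / sqrt(2))
  expect_equal(unname(comp$n_per_group), c(2, 2))

  same <- s; same$avg_los <- 5; same$n_admissions <- 3
  comp2 <- compare_focus_groups(same)
  expect_equal(comp2$avg_los$d, 0)
  expect_equal(comp2$n_admissions$d, 0)
})

test_that("utilization summaries are invariant to admission record order", {
  gen <- generate_cohort(synthetic_config(n_patients = 12, seed = 5))
  fit <- focus_partition(gen$cohort)
  a <- utilization_summary(gen$cohort, fit)
  shuffled <- gen$cohort
  set.seed(1)
  shuffled$admissions <- shuffled$admissions[sample(nrow(shuffled$admissions)), ]
  b <- utilization_summary(shuffled, fit)
  expect_equal(a, b, ignore_attr = TRUE)
})
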