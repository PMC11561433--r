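test_that("load_corpus handles empty call files and rejects unknown labels", {
  dir <- withr::local_tempdir()
  writeLines(character(), file.path(dir, "calls.jsonl"))
  write.csv(make_patients("P1"), file.path(dir, "patients.csv"), row.names = FALSE)
  ds <- load_corpus(file.path(dir, "calls.jsonl"), file.path(dir, "patients.csv"))
  expect_s3_class(ds, "telecare_cohort")
  expect_equal(nrow(ds$calls), 0)

  bad <- paste0('{"call_id":"c1","patient_id":"P1","date":"2015-04-01",',
                '"scheduled":true,"utterances":[{"index":0,',
                '"speaker":"patient","topic":"telemonitoringg",',
                '"dialogue_acts":[],"attributes":[]}]}')
  writeLines(bad, file.path(dir, "calls.jsonl"))
  expect_error(load_corpus(file.path(dir, "calls.jsonl"),
                           file.path(dir, "patients.csv")),
               "vocabulary error.*telemonitoringg")

  writeLines("{not json", file.path(dir, "calls.jsonl"))
  expect_error(load_corpus(file.path(dir, "calls.jsonl"),
                           file.path(dir, "patients.csv")),
               "parse error.*line 1")
})

test_that("a small corpus round-trips through write and load unchanged", {
  calls <- data.frame(call_id = c("c1", "c2", "c3"),
                      patient_id = c("P1", "P1", "P2"),
                      date = as.Date(c("2015-04-01", "2015-05-02", "2015-04-20")),
                      scheduled = c(TRUE, FALSE, TRUE))
  utts <- rbind(
    make_utts("c1", lifestyle_topics(2, 5), acts = "inform;acknowledge",
              attrs = "frequency", text = "hello"),
    make_utts("c2", lifestyle_topics(0, 3)),
    make_utts("c3", c("vitals", "lifestyle_management"),
              acts = c("", "request_inform"), attrs = c("blood_pressure", "")))
  adm <- data.frame(patient_id = "P2", admit_date = as.Date("2015-06-01"),
                    discharge_date = as.Date("2015-06-04"),
                    cause = "hf_related", elective = FALSE)
  ds <- telecare_cohort(make_patients(c("P1", "P2")), calls, utts, adm,
                        vocab = voc)
  dir <- withr::local_tempdir()
  paths <- write_cohort(ds, dir)
  back <- load_corpus(paths["calls"], paths["patients"], paths["admissions"])
  for (tab in c("calls", "utterances", "admissions"))
    expect_equal(back[[tab]], ds[[tab]], ignore_attr = TRUE)
  expect_equal(back$patients$patient_id, ds$patients$patient_id)
})

test_that("validation enforces referential and structural invariants", {
  calls <- data.frame(call_id = "c1", patient_id = "P9",
                      date = as.Date("2015-04-01"), scheduled = TRUE)
  utts <- make_utts("c1", lifestyle_topics(1, 3))
  expect_error(telecare_cohort(make_patients("P1"), calls, utts, vocab = voc),
               "referential error")
  calls$patient_id <- "P1"
  bad_utts <- utts
  bad_utts$index <- c(0L, 2L, 3L)  # gap
  expect_error(telecare_cohort(make_patients("P1"), calls, bad_utts, vocab = voc),
               "not contiguous")
  adm <- data.frame(patient_id = "P1", admit_date = as.Date("2015-06-05"),
                    discharge_date = as.Date("2015-06-01"), elective = FALSE)
  expect_error(telecare_cohort(make_patients("P1"), calls, utts, adm, vocab = voc),
               "discharge_date precedes")
})

test_that("same-day calls merge in order, idempotently, preserving utterances", {
  d <- as.Date("2015-04-07")
  calls <- data.frame(call_id = c("a", "b", "c", "d"),
                      patient_id = "P1",
                      date = c(d, d, d, d + 5), scheduled = TRUE)
  utts <- rbind(make_utts("a", rep("vitals", 10)),
                make_utts("b", rep("symptom_checking", 15)),
                make_utts("c", rep("lifestyle_management", 4)),
                make_utts("d", rep("others", 2)))
  ds <- telecare_cohort(make_patients("P1"), calls, utts, vocab = voc)
  merged <- merge_same_day_calls(ds)
  expect_equal(nrow(merged$calls), 2)
  expect_equal(nrow(merged$utterances), nrow(utts))
  first <- merged$utterances[merged$utterances$call_id == "a", ]
  # within-day order preserved: a's block, then b's, then c's
  expect_equal(first$topic, c(rep("vitals", 10), rep("symptom_checking", 15),
                              rep("lifestyle_management", 4)))
  expect_equal(first$index, 0:28)
  # idempotent
  again <- merge_same_day_calls(merged)
  expect_equal(again$calls, merged$calls)
  expect_equal(again$utterances, merged$utterances)
  # distinct dates untouched
  distinct <- ds
  distinct$calls$date <- d + seq_len(4)
  expect_equal(nrow(merge_same_day_calls(distinct)$calls), 4)
})

test_that("corpus summary reports counts and exact planted topic shares", {
  ds <- ratio_cohort(list(c(2, 11)))
  s <- corpus_summary(ds)
  expect_equal(unname(s$utterances_per_call), c(11, 11, 11))
  plan <- c(lifestyle_management = 7, symptom_checking = 13, vitals = 20)
  utts <- make_utts("c1", rep(names(plan), plan))
  calls <- data.frame(call_id = "c1", patient_id = "P1",
                      date = as.Date("2015-04-01"), scheduled = TRUE)
  ds2 <- telecare_cohort(make_patients("P1"), calls, utts, vocab = voc)
  s2 <- corpus_summary(ds2)
  got <- s2$topic_shares
  expect_equal(got$share[match(names(plan), got$topic)],
               as.numeric(plan) / sum(plan))
  # per-call topic counts sum to the call total
  expect_equal(sum(got$count), s2$n_utterances)
  empty <- telecare_cohort(make_patients("P1"), empty_calls <- data.frame(
    call_id = character(), patient_id = character(),
    date = as.Date(character()), scheduled = logical()),
    make_utts("x", "vitals")[0, ], vocab = voc)
  expect_error(corpus_summary(empty), class = "telefocus_empty")
})
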