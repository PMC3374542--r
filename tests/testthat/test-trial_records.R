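test_that("a minimal well-formed long-layout file pair reads into a cohort", {
  dir <- withr::local_tempdir()
  writeLines(c("id,condition,gender,mde_history,language,quit_date_offset_days",
               "p1,1,male,none,en,0"),
             file.path(dir, "participants.csv"))
  writeLines(c("participant_id,wave_months,responded,abstinent7,abstinent30",
               "p1,1,true,true,true"),
             file.path(dir, "outcomes.csv"))
  co <- read_cohort(dir, layout = "long")
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co$participants), 1)
  expect_equal(nrow(co$outcomes), 1)
  expect_true(co$outcomes$abstinent7)
})

test_that("aggregate layout reads the pooled month-12 cell faithfully", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("condition,wave_months,window,n_assigned,n_responded,n_answered,n_quit",
               "ALL,12,7-day,16430,3606,3292,1361"), path)
  wc <- read_cohort(path, layout = "aggregate")
  expect_equal(nrow(wc), 1)
  expect_equal(wc$n_assigned, 16430L)
  expect_equal(wc$n_quit, 1361L)
})

test_that("schema and consistency violations are rejected with named errors", {
  dir <- withr::local_tempdir()
  writeLines(c("id,condition,gender,mde_history,language,quit_date_offset_days",
               "p1,1,male,none,en,0"),
             file.path(dir, "participants.csv"))
  # 30-day abstinence without 7-day abstinence is contradictory
  writeLines(c("participant_id,wave_months,responded,abstinent7,abstinent30",
               "p1,1,true,false,true"),
             file.path(dir, "outcomes.csv"))
  expect_error(read_cohort(dir, layout = "long"),
               class = "cessbounds_consistency_error")
  expect_error(read_cohort(dir, layout = "long"), "row 1")
  # missing required column names the column
  writeLines(c("participant_id,wave_months,responded,abstinent7",
               "p1,1,true,true"),
             file.path(dir, "outcomes.csv"))
  expect_error(read_cohort(dir, layout = "long"), "abstinent30",
               class = "cessbounds_schema_error")
  # answers present although the follow-up was not completed
  expect_error(
    outcome_records("p1", 1L, responded = FALSE, abstinent7 = TRUE),
    class = "cessbounds_consistency_error")
})

test_that("wave_counts enforces the count ordering invariant", {
  expect_error(wave_counts("ALL", 1L, "7-day", 100L, 50L, 60L, 10L),
               class = "cessbounds_consistency_error")
  expect_error(wave_counts("ALL", 1L, "7-day", 100L, 50L, 40L, 45L),
               class = "cessbounds_consistency_error")
  ok <- wave_counts("ALL", 1L, "7-day", 100L, 50L, 40L, 10L)
  expect_equal(nrow(ok), 1)
})

test_that("tabulate counts a fully responding, fully quitting cohort exactly", {
  p <- participants(id = letters[1:4], condition = 1:4)
  o <- outcome_records(letters[1:4], 1L, responded = TRUE,
                       abstinent7 = TRUE, abstinent30 = TRUE)
  tc <- tabulate_cohort(cohort(p, o), waves = 1L)
  all7 <- tc[tc$condition == "ALL" & tc$window == "7-day", ]
  expect_equal(all7$n_quit, 4L)
  expect_equal(all7$n_answered, 4L)
  expect_equal(all7$n_responded, 4L)
})

test_that("tabulate matches a brute-force per-record recount on random cohorts", {
  set.seed(421)
  for (rep in 1:5) {
    co <- random_cohort(n = 50L)
    tc <- tabulate_cohort(co)
    # independent oracle: explicit loop over every record
    cond_of <- stats::setNames(co$participants$condition, co$participants$id)
    for (i in sample.int(nrow(tc), 10)) {
      row <- tc[i, ]
      n_resp <- 0L; n_ans <- 0L; n_quit <- 0L
      for (j in seq_len(nrow(co$outcomes))) {
        rec <- co$outcomes[j, ]
        in_cell <- rec$wave_months == row$wave_months &&
          (row$condition == "ALL" ||
             cond_of[[rec$participant_id]] == as.integer(row$condition))
        if (!in_cell) next
        if (rec$responded) n_resp <- n_resp + 1L
        ans <- if (row$window == "7-day") rec$abstinent7 else rec$abstinent30
        if (!is.na(ans)) {
          n_ans <- n_ans + 1L
          if (ans) n_quit <- n_quit + 1L
        }
      }
      expect_equal(row$n_responded, n_resp)
      expect_equal(row$n_answered, n_ans)
      expect_equal(row$n_quit, n_quit)
    }
  }
})

test_that("tabulate is permutation-invariant and arm counts sum to ALL", {
  set.seed(99)
  co <- random_cohort(n = 40L)
  shuffled <- cohort(co$participants[sample.int(nrow(co$participants)), ],
                     co$outcomes[sample.int(nrow(co$outcomes)), ],
                     arms = co$arms, waves = co$waves)
  expect_equal(tabulate_cohort(co), tabulate_cohort(shuffled))
  tc <- tabulate_cohort(co)
  arm_assigned <- tc$n_assigned[tc$condition != "ALL" & tc$wave_months == 1 &
                                  tc$window == "7-day"]
  expect_equal(sum(arm_assigned),
               tc$n_assigned[tc$condition == "ALL" & tc$wave_months == 1 &
                               tc$window == "7-day"])
})

test_that("write/read round trip reproduces identical tallies", {
  set.seed(5)
  co <- random_cohort(n = 30L)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir, layout = "long", arms = co$arms, waves = co$waves)
  expect_equal(tabulate_cohort(back), tabulate_cohort(co))
  # aggregate round trip is exact
  path <- withr::local_tempfile(fileext = ".csv")
  write_wave_counts(tabulate_cohort(co), path)
  expect_equal(read_cohort(path, layout = "aggregate"), tabulate_cohort(co))
})

test_that("empty cohort tallies to zero counts, not an error", {
  co <- cohort(participants(character(), integer()),
               outcome_records(character(), integer(), logical()))
  tc <- tabulate_cohort(co)
  expect_true(all(tc$n_quit == 0L))
  expect_true(all(tc$n_assigned == 0L))
})
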