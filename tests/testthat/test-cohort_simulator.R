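test_that("eligibility is the conjunction of the five screening criteria", {
  expect_false(eligibility_filter(17, 10, 7, TRUE, TRUE)) # under 18
  expect_false(eligibility_filter(30, 4, 7, TRUE, TRUE))  # under 5 cigarettes/day
  expect_false(eligibility_filter(30, 20, 0, TRUE, TRUE)) # no weekly access
  expect_false(eligibility_filter(30, 20, 7, FALSE, TRUE))
  expect_false(eligibility_filter(30, 20, 7, TRUE, FALSE))
  expect_true(eligibility_filter(30, 20, 7, TRUE, TRUE))
  expect_equal(eligibility_filter(c(17, 30), c(10, 10), 7, TRUE, TRUE),
               c(FALSE, TRUE))
})

test_that("one full block of stratified randomization fills every arm once", {
  p <- participants(id = letters[1:4], condition = 1L, gender = "male",
                    mde_history = "none")
  assign <- stratified_randomize(p, arms = 4L, seed = 42L)
  expect_setequal(assign, 1:4)
})

test_that("stratified randomization balances arms within strata and is seed-deterministic", {
  set.seed(8)
  n <- 1000L
  p <- participants(
    id = sprintf("s%04d", 1:n), condition = 1L,
    gender = sample(c("male", "female"), n, TRUE, prob = c(0.53, 0.47)),
    mde_history = sample(c("none", "past", "current"), n, TRUE,
                         prob = c(0.69, 0.18, 0.13)))
  a1 <- stratified_randomize(p, arms = 4L, seed = 7L)
  a2 <- stratified_randomize(p, arms = 4L, seed = 7L)
  expect_identical(a1, a2)
  # within each stratum, arm sizes differ by at most 1 (truncated blocks)
  strata <- interaction(p$gender, p$mde_history, drop = TRUE)
  for (s in levels(strata)) {
    sizes <- table(factor(a1[strata == s], levels = 1:4))
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # total imbalance is at most the number of strata
  total <- table(factor(a1, levels = 1:4))
  expect_lte(max(total) - min(total), nlevels(strata))
})

test_that("simulated cohorts are seed-reproducible down to the exported bytes", {
  cfg <- small_config(seed = 123L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("participants.csv", "outcomes.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  c3 <- simulate_cohort(small_config(seed = 124L))
  expect_false(identical(c1$outcomes, c3$outcomes))
})

test_that("responded records always carry truthful answers", {
  co <- simulate_cohort(small_config(seed = 5L))
  merged <- dplyr::inner_join(co$outcomes, co$truth,
                              by = c("participant_id", "wave_months"))
  resp <- merged[merged$responded, ]
  expect_equal(resp$abstinent7, resp$true_abstinent7)
  expect_equal(resp$abstinent30, resp$true_abstinent30)
  nonresp <- merged[!merged$responded, ]
  expect_true(all(is.na(nonresp$abstinent7)))
  # 30-day abstinence only within 7-day abstinence
  expect_true(all(!resp$abstinent30 | resp$abstinent7))
})

test_that("with zero MNAR shift the observed rate is unbiased for the truth", {
  set.seed(61)
  gaps <- replicate(100, {
    cfg <- simulation_config(n_per_arm = 100L, seed = sample.int(1e7, 1),
                             response_quit_logodds_shift = 0,
                             true_quit_prob = 0.25)
    co <- simulate_cohort(cfg)
    tc <- tabulate_cohort(co, waves = 12L)
    cell <- tc[tc$condition == "ALL" & tc$window == "7-day", ]
    cell$n_quit / cell$n_answered - true_quit_rate(co, 12L)
  })
  # Monte-Carlo error of the mean gap is ~0.005; the mean should sit near 0
  expect_lt(abs(mean(gaps)), 0.01)
})

test_that("a positive MNAR shift inflates the observed rate above the truth", {
  set.seed(62)
  mean_gap <- function(shift, reps = 200) {
    mean(replicate(reps, {
      cfg <- simulation_config(n_per_arm = 50L, seed = sample.int(1e7, 1),
                               response_quit_logodds_shift = shift,
                               true_quit_prob = 0.25)
      co <- simulate_cohort(cfg)
      tc <- tabulate_cohort(co, waves = 12L)
      cell <- tc[tc$condition == "ALL" & tc$window == "7-day", ]
      cell$n_quit / cell$n_answered - true_quit_rate(co, 12L)
    }))
  }
  gaps <- vapply(c(0, 0.5, 1.0), mean_gap, numeric(1))
  expect_gt(gaps[3], 0.02)            # responders over-quit
  expect_true(all(diff(gaps) > 0))    # monotone in the MNAR strength
})

test_that("base log-odds calibration hits the wave response targets in expectation", {
  cfg <- simulation_config(seed = 1L)
  b <- calibrate_response_logodds(cfg)
  for (w in seq_along(cfg$waves)) {
    qbar <- mean(cfg$true_quit_prob[, w])
    expected <- (1 - qbar) * plogis(b[w]) +
      qbar * plogis(b[w] + cfg$response_quit_logodds_shift)
    expect_equal(expected, cfg$response_target[w], tolerance = 1e-6)
  }
})

test_that("fixture tables carry the published counts and round-trip through CSV", {
  t2 <- fixture_table2()
  m1 <- t2[t2$wave_months == 1 & t2$window == "7-day", ]
  expect_equal(c(m1$n_assigned, m1$n_responded, m1$n_answered, m1$n_quit),
               c(16430L, 6563L, 6189L, 2239L))
  t3 <- fixture_table3()
  c2m6 <- t3[t3$condition == "2" & t3$wave_months == 6, ]
  expect_equal(c(c2m6$n_quit, c2m6$n_answered), c(395L, 893L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_wave_counts(t2, path)
  expect_equal(read_cohort(path, layout = "aggregate"), t2)
})

test_that("coverage experiment records a premise violation for mismatched true rates", {
  cfg <- small_config(seed = 3L)
  ref <- reference_config(cfg)
  ref$true_quit_prob <- ref$true_quit_prob * 0.5
  ce <- coverage_experiment(cfg, ref_config = ref, replicates = 2L)
  expect_match(ce$premise_warning, "identical-intervention")
})
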