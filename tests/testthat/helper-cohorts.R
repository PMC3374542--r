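# shared builders for small in-code fixtures

# a tiny fully-specified cohort: 4 participants, two waves
tiny_cohort <- function() {
  p <- participants(
    id = c("a", "b", "c", "d"),
    condition = c(1L, 2L, 3L, 4L),
    gender = c("male", "female", "male", "unknown"),
    mde_history = c("none", "past", "current", "unknown"),
    language = c("en", "es", "en", "other"))
  o <- outcome_records(
    participant_id = c("a", "b", "c", "d", "a", "b"),
    wave_months = c(1L, 1L, 1L, 1L, 3L, 3L),
    responded = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    abstinent7 = c(TRUE, TRUE, FALSE, NA, FALSE, NA),
    abstinent30 = c(TRUE, FALSE, FALSE, NA, FALSE, NA))
  cohort(p, o)
}

# random valid count cell: n_quit <= n_answered <= n_responded <= n_assigned
random_counts <- function(n, max_assigned = 500L) {
  n_assigned <- sample.int(max_assigned, n, replace = TRUE)
  n_responded <- vapply(n_assigned, function(k) sample.int(k + 1L, 1L) - 1L, integer(1))
  n_answered <- vapply(n_responded, function(k) sample.int(k + 1L, 1L) - 1L, integer(1))
  n_quit <- vapply(n_answered, function(k) sample.int(k + 1L, 1L) - 1L, integer(1))
  tibble::tibble(n_assigned = n_assigned, n_responded = n_responded,
                 n_answered = n_answered, n_quit = n_quit)
}

# random small cohort with arbitrary response/abstinence pattern
random_cohort <- function(n = 50L, arms = 4L, waves = c(1L, 3L)) {
  p <- participants(
    id = sprintf("r%03d", seq_len(n)),
    condition = sample.int(arms, n, replace = TRUE),
    gender = sample(c("male", "female", "unknown"), n, replace = TRUE),
    mde_history = sample(c("none", "past", "current", "unknown"), n, replace = TRUE),
    language = sample(c("en", "es", "other"), n, replace = TRUE))
  rows <- expand.grid(participant_id = p$id, wave_months = waves,
                      stringsAsFactors = FALSE)
  responded <- runif(nrow(rows)) < 0.5
  a7 <- ifelse(responded, runif(nrow(rows)) < 0.4, NA)
  a30 <- ifelse(!is.na(a7) & a7, runif(nrow(rows)) < 0.7, ifelse(is.na(a7), NA, FALSE))
  o <- outcome_records(rows$participant_id, rows$wave_months, responded, a7, a30)
  cohort(p, o, arms = arms, waves = waves)
}

# small, fast simulator config for property tests
small_config <- function(seed = 1L, ...) {
  simulation_config(n_per_arm = 60L, arms = 4L, seed = seed, ...)
}
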