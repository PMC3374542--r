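#' @importFrom rlang .data
NULL

# controlled vocabularies for participant records
GENDER_LEVELS <- c("male", "female", "unknown")
MDE_LEVELS <- c("none", "past", "current", "unknown")
LANGUAGE_LEVELS <- c("en", "es", "other")

#' Default follow-up waves (months after quit date)
#' @export
DEFAULT_WAVES <- c(1L, 3L, 6L, 12L)

WINDOWS <- c("7-day", "30-day")

#' Build a validated participant table
#'
#' One row per randomized participant. `condition` is the trial arm
#' (1..arms); `gender` and `mde_history` (history of major depressive
#' episodes) are the stratification variables used at randomization.
#'
#' @param id character vector of unique participant ids.
#' @param condition integer arm assignment, 1..`arms`.
#' @param gender one of `"male"`, `"female"`, `"unknown"`.
#' @param mde_history one of `"none"`, `"past"`, `"current"`, `"unknown"`.
#' @param language one of `"en"`, `"es"`, `"other"`.
#' @param quit_date_offset_days non-negative integer days from enrollment to
#'   the chosen quit date.
#' @param arms number of trial arms (default 4).
#' @return a tibble of participants.
#' @export
participants <- function(id, condition, gender = "unknown",
                         mde_history = "unknown", language = "other",
                         quit_date_offset_days = 0L, arms = 4L) {
  df <- tibble::tibble(
    id = as.character(id),
    condition = as.integer(condition),
    gender = as.character(gender),
    mde_history = as.character(mde_history),
    language = as.character(language),
    quit_date_offset_days = as.integer(quit_date_offset_days)
  )
  validate_participants(df, arms = arms)
}

validate_participants <- function(df, arms = 4L) {
  required <- c("id", "condition", "gender", "mde_history", "language",
                "quit_date_offset_days")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    cb_abort(sprintf("participants table is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")), "schema_error")
  }
  if (anyDuplicated(df$id)) {
    cb_abort("participant ids must be unique within a cohort.", "consistency_error")
  }
  if (any(is.na(df$condition)) || any(!df$condition %in% seq_len(arms))) {
    cb_abort(sprintf("condition must be an integer in 1..%d.", arms), "consistency_error")
  }
  for (col in c("gender", "mde_history", "language")) {
    levels <- switch(col, gender = GENDER_LEVELS, mde_history = MDE_LEVELS,
                     language = LANGUAGE_LEVELS)
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad)) {
      cb_abort(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")),
               "schema_error")
    }
  }
  if (any(is.na(df$quit_date_offset_days)) || any(df$quit_date_offset_days < 0)) {
    cb_abort("quit_date_offset_days must be a non-negative integer.", "schema_error")
  }
  tibble::as_tibble(df)
}

#' Build a validated follow-up outcome table
#'
#' One row per participant x follow-up wave. `responded` records whether the
#' participant completed that follow-up at all; the abstinence answers are
#' `NA` ("absent") when not given, which also represents item nonresponse
#' within a completed follow-up.
#'
#' @param participant_id character.
#' @param wave_months follow-up wave in months (must be among `waves`).
#' @param responded logical: completed this follow-up.
#' @param abstinent7,abstinent30 logical or `NA`: self-reported 7-day and
#'   30-day point-prevalence abstinence.
#' @param waves allowed wave schedule (default `DEFAULT_WAVES`).
#' @return a tibble of outcome records.
#' @export
outcome_records <- function(participant_id, wave_months, responded,
                            abstinent7 = NA, abstinent30 = NA,
                            waves = DEFAULT_WAVES) {
  df <- tibble::tibble(
    participant_id = as.character(participant_id),
    wave_months = as.integer(wave_months),
    responded = as.logical(responded),
    abstinent7 = as.logical(abstinent7),
    abstinent30 = as.logical(abstinent30)
  )
  validate_outcomes(df, waves = waves)
}

validate_outcomes <- function(df, waves = DEFAULT_WAVES) {
  required <- c("participant_id", "wave_months", "responded", "abstinent7",
                "abstinent30")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    cb_abort(sprintf("outcomes table is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")), "schema_error")
  }
  bad_wave <- which(!df$wave_months %in% waves)
  if (length(bad_wave)) {
    cb_abort(sprintf("row %d: wave_months %s is not in the wave schedule (%s).",
                     bad_wave[1], df$wave_months[bad_wave[1]],
                     paste(waves, collapse = ", ")), "schema_error")
  }
  if (any(is.na(df$responded))) {
    cb_abort("responded must be true/false, never absent.", "schema_error")
  }
  # nonresponse carries no answers
  bad <- which(!df$responded & (!is.na(df$abstinent7) | !is.na(df$abstinent30)))
  if (length(bad)) {
    cb_abort(sprintf("row %d: abstinence answers present although responded is false.",
                     bad[1]), "consistency_error")
  }
  # 30-day abstinence implies 7-day abstinence
  bad <- which(!is.na(df$abstinent30) & df$abstinent30 &
                 (is.na(df$abstinent7) | !df$abstinent7))
  if (length(bad)) {
    cb_abort(sprintf("row %d: abstinent30 is true but abstinent7 is not.", bad[1]),
             "consistency_error")
  }
  tibble::as_tibble(df)
}

#' Assemble a cohort from participant and outcome tables
#'
#' @param participants table as returned by [participants()].
#' @param outcomes table as returned by [outcome_records()].
#' @param arms number of trial arms.
#' @param waves wave schedule in months.
#' @return an object of class `"cohort"`: a list with elements
#'   `participants`, `outcomes`, `arms`, `waves`.
#' @export
cohort <- function(participants, outcomes, arms = 4L, waves = DEFAULT_WAVES) {
  participants <- validate_participants(participants, arms = arms)
  outcomes <- validate_outcomes(outcomes, waves = waves)
  orphan <- setdiff(outcomes$participant_id, participants$id)
  if (length(orphan)) {
    cb_abort(sprintf("outcome records refer to unknown participant id(s): %s",
                     paste(utils::head(orphan, 3), collapse = ", ")),
             "consistency_error")
  }
  if (anyDuplicated(outcomes[, c("participant_id", "wave_months")])) {
    cb_abort("at most one outcome record per participant and wave.",
             "consistency_error")
  }
  structure(list(participants = participants, outcomes = outcomes,
                 arms = as.integer(arms), waves = as.integer(waves)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d arms, waves {%s} months, %d outcome records\n",
              nrow(x$participants), x$arms, paste(x$waves, collapse = ","),
              nrow(x$outcomes)))
  invisible(x)
}

#' Build a validated aggregate count table
#'
#' The aggregate ("WaveCounts") layout carries, per (condition, wave,
#' abstinence window) cell: participants randomized (`n_assigned`),
#' completed follow-ups (`n_responded`), answered the window's abstinence
#' item (`n_answered`) and reported abstinent (`n_quit`). The two
#' denominators are kept distinct because completed follow-ups can exceed
#' answered items (item nonresponse).
#'
#' @param condition arm label as character (`"1"`..`"4"`) or `"ALL"`.
#' @param wave_months follow-up wave in months.
#' @param window `"7-day"` or `"30-day"`.
#' @param n_assigned,n_responded,n_answered,n_quit non-negative counts with
#'   `n_quit <= n_answered <= n_responded <= n_assigned`.
#' @return a tibble of aggregate counts.
#' @export
wave_counts <- function(condition, wave_months, window, n_assigned,
                        n_responded, n_answered, n_quit) {
  df <- tibble::tibble(
    condition = as.character(condition),
    wave_months = as.integer(wave_months),
    window = as.character(window),
    n_assigned = as.integer(n_assigned),
    n_responded = as.integer(n_responded),
    n_answered = as.integer(n_answered),
    n_quit = as.integer(n_quit)
  )
  validate_wave_counts(df)
}

validate_wave_counts <- function(df) {
  required <- c("condition", "wave_months", "window", "n_assigned",
                "n_responded", "n_answered", "n_quit")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    cb_abort(sprintf("aggregate table is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")), "schema_error")
  }
  bad <- setdiff(unique(df$window), WINDOWS)
  if (length(bad)) {
    cb_abort(sprintf("invalid window value(s): %s (expected 7-day/30-day)",
                     paste(bad, collapse = ", ")), "schema_error")
  }
  for (col in c("n_assigned", "n_responded", "n_answered", "n_quit")) {
    check_count(df[[col]], col)
  }
  bad <- which(!(df$n_quit <= df$n_answered & df$n_answered <= df$n_responded &
                   df$n_responded <= df$n_assigned))
  if (length(bad)) {
    cb_abort(sprintf("row %d: counts must satisfy n_quit <= n_answered <= n_responded <= n_assigned.",
                     bad[1]), "consistency_error")
  }
  tibble::as_tibble(df)
}

parse_csv_bool <- function(x, column, allow_absent = TRUE) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x == "true"] <- TRUE
  out[x == "false"] <- FALSE
  bad <- which(!(x %in% c("true", "false")) & !(allow_absent & x == ""))
  if (length(bad)) {
    cb_abort(sprintf("row %d: column %s has value '%s' (expected true/false%s).",
                     bad[1], column, x[bad[1]],
                     if (allow_absent) " or empty" else ""), "schema_error")
  }
  out
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) {
    cb_abort(sprintf("file not found: %s", path), "io_error")
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    cb_abort(sprintf("%s is missing required column(s): %s", basename(path),
                     paste(missing_cols, collapse = ", ")), "schema_error")
  }
  df
}

#' Read a cohort or an aggregate count table from CSV
#'
#' Two layouts are supported. `layout = "long"` expects a directory with
#' `participants.csv` (id,condition,gender,mde_history,language,
#' quit_date_offset_days) and `outcomes.csv` (participant_id,wave_months,
#' responded,abstinent7,abstinent30; booleans written `true`/`false`,
#' absent answers as empty fields) and returns a [cohort()].
#' `layout = "aggregate"` expects a single CSV with the [wave_counts()]
#' columns and returns the validated count table. Rows violating the type
#' invariants are rejected with an error naming the row, never coerced.
#'
#' @param path directory (long layout) or CSV file (aggregate layout).
#' @param layout `"long"` or `"aggregate"`.
#' @param arms,waves trial shape used for validation.
#' @return a `cohort` or a `wave_counts` tibble.
#' @export
read_cohort <- function(path, layout = c("long", "aggregate"), arms = 4L,
                        waves = DEFAULT_WAVES) {
  layout <- match.arg(layout)
  if (layout == "aggregate") {
    df <- read_checked_csv(path, c("condition", "wave_months", "window",
                                   "n_assigned", "n_responded", "n_answered",
                                   "n_quit"))
    for (col in c("wave_months", "n_assigned", "n_responded", "n_answered", "n_quit")) {
      suppressWarnings(df[[col]] <- as.integer(df[[col]]))
      if (anyNA(df[[col]])) {
        cb_abort(sprintf("column %s contains non-integer values.", col), "schema_error")
      }
    }
    return(validate_wave_counts(tibble::as_tibble(df)))
  }
  ppath <- file.path(path, "participants.csv")
  opath <- file.path(path, "outcomes.csv")
  pdf <- read_checked_csv(ppath, c("id", "condition", "gender", "mde_history",
                                   "language", "quit_date_offset_days"))
  odf <- read_checked_csv(opath, c("participant_id", "wave_months", "responded",
                                   "abstinent7", "abstinent30"))
  suppressWarnings({
    pdf$condition <- as.integer(pdf$condition)
    pdf$quit_date_offset_days <- as.integer(pdf$quit_date_offset_days)
    odf$wave_months <- as.integer(odf$wave_months)
  })
  odf$responded <- parse_csv_bool(odf$responded, "responded", allow_absent = FALSE)
  odf$abstinent7 <- parse_csv_bool(odf$abstinent7, "abstinent7")
  odf$abstinent30 <- parse_csv_bool(odf$abstinent30, "abstinent30")
  cohort(tibble::as_tibble(pdf), tibble::as_tibble(odf), arms = arms, waves = waves)
}

format_csv_bool <- function(x) {
  out <- rep("", length(x))
  out[isTRUE_v(x)] <- "true"
  out[!is.na(x) & !x] <- "false"
  out
}

isTRUE_v <- function(x) !is.na(x) & x

write_plain_csv <- function(df, path) {
  # fixed, quote-free formatting so identical data yields identical bytes
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to participants.csv and outcomes.csv
#'
#' Inverse of [read_cohort()] (long layout): booleans as `true`/`false`,
#' absent answers as empty fields. Output is byte-stable for identical
#' cohorts.
#'
#' @param x a `cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plain_csv(x$participants, file.path(dir, "participants.csv"))
  o <- x$outcomes
  o$responded <- ifelse(o$responded, "true", "false")
  o$abstinent7 <- format_csv_bool(x$outcomes$abstinent7)
  o$abstinent30 <- format_csv_bool(x$outcomes$abstinent30)
  write_plain_csv(o, file.path(dir, "outcomes.csv"))
  invisible(dir)
}

#' Write an aggregate count table to CSV
#'
#' @param counts a `wave_counts` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_wave_counts <- function(counts, path) {
  counts <- validate_wave_counts(counts)
  write_plain_csv(counts, path)
  invisible(path)
}

#' Tally a cohort into aggregate counts
#'
#' Produces one [wave_counts()] row per (condition and pooled `"ALL"`) x
#' wave x abstinence window. `n_answered` counts records whose answer for
#' the window is present; `n_quit` counts affirmative answers. Exact
#' tallies; an empty cohort yields zero counts. Invariant to the order of
#' records.
#'
#' @param x a `cohort`.
#' @param waves waves to tabulate (default: the cohort's schedule).
#' @return a `wave_counts` tibble sorted by condition, wave, window.
#' @export
tabulate_cohort <- function(x, waves = NULL) {
  stopifnot(inherits(x, "cohort"))
  waves <- if (is.null(waves)) x$waves else as.integer(waves)
  joined <- dplyr::left_join(x$outcomes,
                             x$participants[, c("id", "condition")],
                             by = c(participant_id = "id"))
  assigned <- c(table(factor(x$participants$condition, levels = seq_len(x$arms))))

  tally_one <- function(cond_label, keep) {
    n_assigned <- if (identical(cond_label, "ALL")) nrow(x$participants)
                  else unname(assigned[[cond_label]])
    out <- lapply(waves, function(w) {
      rows <- joined[keep & joined$wave_months == w, ]
      tibble::tibble(
        condition = cond_label,
        wave_months = w,
        window = WINDOWS,
        n_assigned = n_assigned,
        n_responded = sum(rows$responded),
        n_answered = c(sum(!is.na(rows$abstinent7)), sum(!is.na(rows$abstinent30))),
        n_quit = c(sum(isTRUE_v(rows$abstinent7)), sum(isTRUE_v(rows$abstinent30)))
      )
    })
    dplyr::bind_rows(out)
  }

  per_cond <- lapply(seq_len(x$arms), function(k) {
    tally_one(as.character(k), !is.na(joined$condition) & joined$condition == k)
  })
  res <- dplyr::bind_rows(c(per_cond, list(tally_one("ALL", rep(TRUE, nrow(joined))))))
  res <- res[order(res$condition, res$wave_months, res$window), ]
  validate_wave_counts(res)
}
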