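#' Observed abstinence rate
#'
#' Quitters divided by those who answered the abstinence item; missing
#' observations are excluded. Upward-biased when responders quit more than
#' nonresponders.
#'
#' @param n_quit reported quitters.
#' @param n_answered participants who answered the item (must be >= 1).
#' @return proportion quit.
#' @export
#' @examples
#' observed_rate(2239, 6189) # 0.3618
observed_rate <- function(n_quit, n_answered) {
  check_count(n_quit, "n_quit"); check_count(n_answered, "n_answered")
  if (any(n_answered == 0)) {
    cb_abort("observed rate is undefined when n_answered = 0.", "undefined_rate")
  }
  if (any(n_quit > n_answered)) {
    cb_abort("n_quit cannot exceed n_answered.", "input_error")
  }
  n_quit / n_answered
}

#' Missing = smoking (M=S) abstinence rate
#'
#' The conservative intent-to-treat variant: every participant without an
#' answer is presumed smoking, so the denominator is everyone randomized.
#'
#' @param n_quit reported quitters.
#' @param n_assigned participants randomized (must be >= 1).
#' @return proportion quit under M=S.
#' @export
#' @examples
#' ms_rate(1361, 16430) # 0.0828...
ms_rate <- function(n_quit, n_assigned) {
  check_count(n_quit, "n_quit"); check_count(n_assigned, "n_assigned")
  if (any(n_assigned == 0)) {
    cb_abort("M=S rate is undefined when n_assigned = 0.", "undefined_rate")
  }
  if (any(n_quit > n_assigned)) {
    cb_abort("n_quit cannot exceed n_assigned.", "input_error")
  }
  n_quit / n_assigned
}

#' Missing = quit (M=Quit) abstinence rate
#'
#' The opposite extreme of M=S: every missing observation is presumed quit,
#' so the numerator is reported quitters plus all missing. Together with
#' M=S this brackets the true rate (worst-case bounds).
#'
#' @param n_quit reported quitters.
#' @param n_answered participants who answered the item.
#' @param n_assigned participants randomized (must be >= 1).
#' @return proportion quit under M=Quit.
#' @export
#' @examples
#' mquit_rate(1361, 3292, 16430) # 0.8825
mquit_rate <- function(n_quit, n_answered, n_assigned) {
  check_count(n_quit, "n_quit"); check_count(n_answered, "n_answered")
  check_count(n_assigned, "n_assigned")
  if (any(n_assigned == 0)) {
    cb_abort("M=Quit rate is undefined when n_assigned = 0.", "undefined_rate")
  }
  if (any(n_quit > n_answered) || any(n_answered > n_assigned)) {
    cb_abort("counts must satisfy n_quit <= n_answered <= n_assigned.", "input_error")
  }
  (n_quit + n_assigned - n_answered) / n_assigned
}

#' Follow-up completion rate
#'
#' @param n_responded participants who completed the follow-up.
#' @param n_assigned participants randomized (must be >= 1).
#' @return proportion followed up.
#' @export
followup_rate <- function(n_responded, n_assigned) {
  check_count(n_responded, "n_responded"); check_count(n_assigned, "n_assigned")
  if (any(n_assigned == 0)) {
    cb_abort("follow-up rate is undefined when n_assigned = 0.", "undefined_rate")
  }
  if (any(n_responded > n_assigned)) {
    cb_abort("n_responded cannot exceed n_assigned.", "input_error")
  }
  n_responded / n_assigned
}

#' All three outcome conventions for one cell
#'
#' Returns the observed, M=S and M=Quit rates with their defining counts.
#' For any cell with at least one answer the ordering
#' `m_s <= observed <= m_quit` holds, with equality only under full
#' ascertainment.
#'
#' @param n_quit,n_answered,n_assigned counts with
#'   `n_quit <= n_answered <= n_assigned`.
#' @return a one-row (per input element) tibble with columns `n_assigned`,
#'   `n_answered`, `n_quit`, `observed`, `m_s`, `m_quit`.
#' @export
convention_rates <- function(n_quit, n_answered, n_assigned) {
  tibble::tibble(
    n_assigned = as.integer(n_assigned),
    n_answered = as.integer(n_answered),
    n_quit = as.integer(n_quit),
    observed = observed_rate(n_quit, n_answered),
    m_s = ms_rate(n_quit, n_assigned),
    m_quit = mquit_rate(n_quit, n_answered, n_assigned)
  )
}

# denominator for "missing": answered-item (default) or completed-follow-up
missing_count <- function(counts, missing_from) {
  switch(missing_from,
         answered = counts$n_answered,
         responded = counts$n_responded,
         cb_abort("missing_from must be 'answered' or 'responded'.", "config_error"))
}

#' Overall convention table (pooled arms)
#'
#' Replicates the trial-report layout: for each wave x abstinence window of
#' the pooled (`condition == "ALL"`) counts, the follow-up completion rate
#' and the three convention rates. Requested cells absent from `counts` are
#' returned with `missing_cell = TRUE` and `NA` rates — never silently 0.
#'
#' @param counts a [wave_counts()] tibble.
#' @param waves waves to report (default: those present).
#' @param windows abstinence windows to report.
#' @param missing_from denominator defining "missing": `"answered"`
#'   (default; missing = assigned - answered item) or `"responded"`
#'   (missing = assigned - completed follow-up).
#' @return tibble with one row per (wave, window): counts, `followup`,
#'   `observed`, `m_s`, `m_quit`, `missing_cell`.
#' @export
convention_table <- function(counts, waves = NULL, windows = WINDOWS,
                             missing_from = c("answered", "responded")) {
  missing_from <- match.arg(missing_from)
  counts <- validate_wave_counts(counts)
  pooled <- counts[counts$condition == "ALL", ]
  if (is.null(waves)) waves <- sort(unique(pooled$wave_months))
  grid <- expand.grid(wave_months = as.integer(waves), window = windows,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- pooled[pooled$wave_months == grid$wave_months[i] &
                     pooled$window == grid$window[i], ]
    if (nrow(cell) == 0) {
      return(tibble::tibble(
        wave_months = grid$wave_months[i], window = grid$window[i],
        n_assigned = NA_integer_, n_responded = NA_integer_,
        n_answered = NA_integer_, n_quit = NA_integer_,
        followup = NA_real_, observed = NA_real_, m_s = NA_real_,
        m_quit = NA_real_, missing_cell = TRUE))
    }
    n_miss_base <- missing_count(cell, missing_from)
    tibble::tibble(
      wave_months = cell$wave_months, window = cell$window,
      n_assigned = cell$n_assigned, n_responded = cell$n_responded,
      n_answered = cell$n_answered, n_quit = cell$n_quit,
      followup = followup_rate(cell$n_responded, cell$n_assigned),
      observed = observed_rate(cell$n_quit, cell$n_answered),
      m_s = ms_rate(cell$n_quit, cell$n_assigned),
      m_quit = mquit_rate(cell$n_quit, n_miss_base, cell$n_assigned),
      missing_cell = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Per-condition convention table
#'
#' Replicates the by-arm quit-rate layout: for each condition x wave of one
#' abstinence window, the observed and M=S (and M=Quit) rates. Missing
#' cells are flagged, not zero-filled.
#'
#' @param counts a [wave_counts()] tibble.
#' @param window abstinence window (default `"7-day"`).
#' @param waves waves to report (default: those present).
#' @param missing_from see [convention_table()].
#' @return tibble with one row per (condition, wave).
#' @export
condition_table <- function(counts, window = "7-day", waves = NULL,
                            missing_from = c("answered", "responded")) {
  missing_from <- match.arg(missing_from)
  counts <- validate_wave_counts(counts)
  by_cond <- counts[counts$condition != "ALL" & counts$window == window, ]
  conditions <- sort(unique(by_cond$condition))
  if (is.null(waves)) waves <- sort(unique(by_cond$wave_months))
  grid <- expand.grid(condition = conditions, wave_months = as.integer(waves),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- by_cond[by_cond$condition == grid$condition[i] &
                      by_cond$wave_months == grid$wave_months[i], ]
    if (nrow(cell) == 0) {
      return(tibble::tibble(
        condition = grid$condition[i], wave_months = grid$wave_months[i],
        window = window, n_assigned = NA_integer_, n_answered = NA_integer_,
        n_quit = NA_integer_, observed = NA_real_, m_s = NA_real_,
        m_quit = NA_real_, missing_cell = TRUE))
    }
    tibble::tibble(
      condition = cell$condition, wave_months = cell$wave_months,
      window = window, n_assigned = cell$n_assigned,
      n_answered = cell$n_answered, n_quit = cell$n_quit,
      observed = observed_rate(cell$n_quit, cell$n_answered),
      m_s = ms_rate(cell$n_quit, cell$n_assigned),
      m_quit = mquit_rate(cell$n_quit, missing_count(cell, missing_from),
                          cell$n_assigned),
      missing_cell = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Format a convention or condition table for display
#'
#' Renders rate columns as `"n_quit/denominator (xx.xx%)"` strings, the
#' style used in trial reports. Display-only; never feed the result back
#' into computations.
#'
#' @param tbl output of [convention_table()] or [condition_table()].
#' @return tibble with character display columns.
#' @export
format_rate_table <- function(tbl) {
  fmt <- function(num, den, rate) {
    ifelse(is.na(rate), "-",
           sprintf("%d/%d (%.2f%%)", num, den, as_pct(rate)))
  }
  out <- tbl[, intersect(c("condition", "wave_months", "window"), names(tbl))]
  if ("followup" %in% names(tbl)) {
    out$followup <- fmt(tbl$n_responded, tbl$n_assigned, tbl$followup)
  }
  out$observed <- fmt(tbl$n_quit, tbl$n_answered, tbl$observed)
  out$m_s <- fmt(tbl$n_quit, tbl$n_assigned, tbl$m_s)
  out$m_quit <- ifelse(is.na(tbl$m_quit), "-", sprintf("%.2f%%", as_pct(tbl$m_quit)))
  out
}
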