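#' Construct a quit-rate interval
#'
#' @param lower,upper proportions with `0 <= lower <= upper <= 1`.
#' @param method `"worst_case"` or `"reference_anchored"`.
#' @param provenance free-text audit note recording how the endpoints were
#'   obtained and the assumptions they carry.
#' @return an object of class `"quit_rate_interval"`.
#' @export
quit_rate_interval <- function(lower, upper,
                               method = c("worst_case", "reference_anchored"),
                               provenance = "") {
  method <- match.arg(method)
  check_proportion(lower, "lower"); check_proportion(upper, "upper")
  if (lower > upper) {
    cb_abort("interval lower bound exceeds upper bound.", "input_error")
  }
  structure(list(lower = lower, upper = upper, method = method,
                 provenance = provenance),
            class = "quit_rate_interval")
}

#' @export
print.quit_rate_interval <- function(x, digits = 2, ...) {
  cat(sprintf("<quit rate interval, %s> [%.*f%%, %.*f%%]\n", x$method,
              digits, as_pct(x$lower, digits), digits, as_pct(x$upper, digits)))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
format.quit_rate_interval <- function(x, digits = 0, ...) {
  sprintf("[%.*f%%, %.*f%%]", digits, as_pct(x$lower, digits),
          digits, as_pct(x$upper, digits))
}

#' Worst-case bounds on the true quit rate
#'
#' With a binary outcome, the unknown outcomes of nonresponders are
#' bracketed by the two extremes all-smoking and all-quit, so the true quit
#' rate is certain to lie in `[m_s, m_quit]`. The interval width equals the
#' missingness fraction, so it is wide exactly when attrition is severe —
#' guaranteed coverage, little information.
#'
#' @param rates a one-row [convention_rates()] tibble (or any list with
#'   `m_s` and `m_quit` and the counts).
#' @return a `quit_rate_interval` with `method = "worst_case"`.
#' @export
#' @examples
#' worst_case_bounds(convention_rates(1361, 3292, 16430)) # [8.28%, 88.25%]
worst_case_bounds <- function(rates) {
  if (is.data.frame(rates) && nrow(rates) != 1) {
    cb_abort("worst_case_bounds expects a single cell of convention rates.",
             "input_error")
  }
  quit_rate_interval(
    rates$m_s, rates$m_quit, method = "worst_case",
    provenance = sprintf(
      "M=S %d/%d to M=Quit (%d quit + %d missing)/%d; assumes only that outcomes are binary.",
      rates$n_quit, rates$n_assigned, rates$n_quit,
      rates$n_assigned - rates$n_answered, rates$n_assigned))
}

#' Summary of a reference trial with intensive follow-up
#'
#' Holds the published rates of a smaller, identically conducted trial
#' whose live (for example phone) follow-up achieved much higher
#' completion. Its M=S and observed rates anchor the narrowed interval for
#' the automated trial. The responder quit rates by follow-up mode
#' (automated vs live) quantify how much automated responders over-report
#' quitting, the argument for taking the reference observed rate as an
#' upper bound.
#'
#' @param ms_rate,observed_rate,mquit_rate reference-trial rates under the
#'   three conventions (`mquit_rate` optional, used for the intermediate
#'   bound).
#' @param automated_responder_quit_rate,live_responder_quit_rate optional
#'   quit rates among reference-trial responders reached by automated email
#'   vs live follow-up.
#' @return an object of class `"reference_trial_summary"`.
#' @export
reference_trial_summary <- function(ms_rate, observed_rate, mquit_rate = NA_real_,
                                    automated_responder_quit_rate = NA_real_,
                                    live_responder_quit_rate = NA_real_) {
  check_proportion(ms_rate, "ms_rate")
  check_proportion(observed_rate, "observed_rate")
  if (!is.na(mquit_rate)) check_proportion(mquit_rate, "mquit_rate")
  if (ms_rate > observed_rate ||
      (!is.na(mquit_rate) && observed_rate > mquit_rate)) {
    cb_abort("reference rates must satisfy m_s <= observed <= m_quit.",
             "invalid_reference")
  }
  structure(list(ms_rate = ms_rate, observed_rate = observed_rate,
                 mquit_rate = mquit_rate,
                 automated_responder_quit_rate = automated_responder_quit_rate,
                 live_responder_quit_rate = live_responder_quit_rate),
            class = "reference_trial_summary")
}

#' Reference-anchored bounds on the true quit rate
#'
#' Anchors the automated trial's true quit rate on a reference trial that
#' ran the identical intervention with intensive follow-up. The
#' intermediate stage takes the reference trial's own worst-case interval
#' `[m_s, m_quit]`; the final stage tightens the upper bound to the
#' reference observed rate, on the argument that automated-only responders
#' over-report quitting relative to the full (automated + live) responder
#' pool, so the automated trial's observed rate overshoots while the
#' reference observed rate still bounds the truth from above.
#'
#' @param reference a [reference_trial_summary()].
#' @param stage `"final"` (lower = reference M=S, upper = reference
#'   observed) or `"intermediate"` (upper = reference M=Quit).
#' @return a `quit_rate_interval` with `method = "reference_anchored"`.
#' @export
#' @examples
#' ref <- reference_trial_summary(0.21, 0.30, 0.52)
#' reference_bounds(ref)                        # [21%, 30%]
#' reference_bounds(ref, stage = "intermediate") # [21%, 52%]
reference_bounds <- function(reference, stage = c("final", "intermediate")) {
  stage <- match.arg(stage)
  if (!inherits(reference, "reference_trial_summary")) {
    reference <- do.call(reference_trial_summary, as.list(reference))
  }
  if (stage == "intermediate") {
    if (is.na(reference$mquit_rate)) {
      cb_abort("intermediate bounds need the reference M=Quit rate.", "config_error")
    }
    return(quit_rate_interval(
      reference$ms_rate, reference$mquit_rate, method = "reference_anchored",
      provenance = "Reference trial's own worst-case interval [M=S, M=Quit]; assumes identical intervention."))
  }
  quit_rate_interval(
    reference$ms_rate, reference$observed_rate, method = "reference_anchored",
    provenance = paste("Lower: reference M=S (missing presumed smoking).",
                       "Upper: reference observed rate; automated-only responders over-report quitting,",
                       "so the automated trial's observed rate is an overestimate."))
}

#' Projected M=S rate under incomplete follow-up
#'
#' If responders are representative of the cohort, a trial whose true quit
#' rate is `true_rate` but which reaches only a fraction
#' `followup_completeness` of participants reports an M=S rate of
#' `true_rate * followup_completeness`: the convention measures follow-up
#' success as much as efficacy. Monotone increasing in both arguments.
#'
#' @param true_rate true quit proportion.
#' @param followup_completeness fraction of participants providing data.
#' @return projected M=S proportion.
#' @export
#' @examples
#' projected_ms_rate(0.20, c(1, 0.7, 0.4)) # 0.20 0.14 0.08
projected_ms_rate <- function(true_rate, followup_completeness) {
  check_proportion(true_rate, "true_rate")
  check_proportion(followup_completeness, "followup_completeness")
  true_rate * followup_completeness
}

#' Relative excess of automated over live responder quit rates
#'
#' How much more often responders reached by automated email report
#' quitting than responders reached by live follow-up, as a relative
#' excess: `(automated - live) / live`. A positive excess is direct
#' evidence that follow-up response is related to abstinence status
#' (missing-not-at-random attrition).
#'
#' @param automated_rate quit rate among automated responders.
#' @param live_rate quit rate among live-follow-up responders (> 0).
#' @return unitless relative excess (0.663 means "about 70% higher").
#' @export
#' @examples
#' responder_excess(0.163, 0.098) # 0.663
responder_excess <- function(automated_rate, live_rate) {
  check_proportion(automated_rate, "automated_rate")
  check_proportion(live_rate, "live_rate")
  if (any(live_rate == 0)) {
    cb_abort("responder excess is undefined when live_rate = 0.", "undefined_ratio")
  }
  (automated_rate - live_rate) / live_rate
}

#' The three-stage interval chain for one outcome cell
#'
#' Runs the full narrowing argument: the automated trial's worst-case
#' interval, then the reference trial's worst-case interval, then the
#' final reference-anchored interval.
#'
#' @param rates a one-row [convention_rates()] cell from the automated trial.
#' @param reference a [reference_trial_summary()] with `mquit_rate` set.
#' @return an object of class `"interval_chain"`: list of three
#'   `quit_rate_interval`s (`worst_case`, `reference_intermediate`,
#'   `reference_final`).
#' @export
interval_chain <- function(rates, reference) {
  chain <- list(
    worst_case = worst_case_bounds(rates),
    reference_intermediate = reference_bounds(reference, stage = "intermediate"),
    reference_final = reference_bounds(reference, stage = "final")
  )
  structure(chain, class = "interval_chain")
}

#' @export
print.interval_chain <- function(x, ...) {
  cat("Most likely range of the true quit rate, narrowed in three stages:\n")
  cat(sprintf("  1. worst case (this trial):          %s\n", format(x$worst_case)))
  cat(sprintf("  2. reference trial worst case:       %s\n", format(x$reference_intermediate)))
  cat(sprintf("  3. reference anchored (final):       %s\n", format(x$reference_final)))
  invisible(x)
}

#' Serialize an interval chain to JSON
#'
#' @param chain an [interval_chain()].
#' @param path optional file to write; if `NULL`, the JSON string is
#'   returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
interval_chain_json <- function(chain, path = NULL) {
  payload <- list(
    worst_case = list(lower = chain$worst_case$lower,
                      upper = chain$worst_case$upper),
    reference_intermediate = list(lower = chain$reference_intermediate$lower,
                                  upper = chain$reference_intermediate$upper),
    reference_final = list(lower = chain$reference_final$lower,
                           upper = chain$reference_final$upper),
    assumptions = c(chain$worst_case$provenance,
                    chain$reference_intermediate$provenance,
                    chain$reference_final$provenance)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
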