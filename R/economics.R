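#' Cost per successful quitter
#'
#' @param total_cost total intervention cost (currency units).
#' @param n_quitters number of participants who reported quitting (>= 1).
#' @return cost per quitter.
#' @export
cost_per_quitter <- function(total_cost, n_quitters) {
  if (any(total_cost < 0)) cb_abort("total_cost must be >= 0.", "input_error")
  check_count(n_quitters, "n_quitters")
  if (any(n_quitters == 0)) {
    cb_abort("cost per quitter is undefined when n_quitters = 0.",
             "undefined_cost")
  }
  total_cost / n_quitters
}

#' Per-protocol cost per quitter for a consumable treatment
#'
#' For a treatment costing `unit_daily_cost` per day over `duration_days`,
#' with a success probability of `quit_rate`, the expected cost per
#' successful quitter is `unit_daily_cost * duration_days / quit_rate`.
#' The benchmark case — nicotine patch at US $3.91/day for 10 weeks (70
#' days) with a 20% quit rate — comes to about US $1370.
#'
#' @param unit_daily_cost cost per day.
#' @param duration_days treatment duration in days.
#' @param quit_rate success proportion (> 0).
#' @return cost per quitter. Strictly decreasing in `quit_rate`, linear in
#'   the other two arguments.
#' @export
#' @examples
#' per_protocol_cost_per_quitter(3.91, 70, 0.20) # 1368.5
per_protocol_cost_per_quitter <- function(unit_daily_cost, duration_days,
                                          quit_rate) {
  if (any(unit_daily_cost < 0) || any(duration_days < 0)) {
    cb_abort("costs and durations must be >= 0.", "input_error")
  }
  check_proportion(quit_rate, "quit_rate")
  if (any(quit_rate == 0)) {
    cb_abort("cost per quitter is undefined when quit_rate = 0.",
             "undefined_cost")
  }
  unit_daily_cost * duration_days / quit_rate
}

#' Quitters per week over the life of a study
#'
#' Converts a quitter total over a study period in months to a weekly
#' rate, using 52/12 weeks per month.
#'
#' @param n_quitters number of quitters.
#' @param duration_months study duration in months (> 0).
#' @return quitters per week.
#' @export
#' @examples
#' weekly_quitter_rate(3489, 45) # 17.9, "about 18 per week"
weekly_quitter_rate <- function(n_quitters, duration_months) {
  check_count(n_quitters, "n_quitters")
  if (any(duration_months <= 0)) {
    cb_abort("duration_months must be > 0.", "input_error")
  }
  n_quitters / (duration_months * 52 / 12)
}

#' Round a cost to the nearest unit for "about" figures
#'
#' @param x cost.
#' @param unit rounding unit (default 10, the convention for quoted
#'   "about US $..." amounts).
#' @return rounded value.
#' @export
round_cost <- function(x, unit = 10) round_half_up(x / unit) * unit
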