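#' @keywords internal
write_report_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full outcome analysis and write paper-shaped reports
#'
#' Orchestrates the pipeline on either participant-level or aggregate
#' data: tallies counts, builds the pooled convention table and the
#' per-condition table, runs the chi-square homogeneity tests of quit
#' counts across conditions, and — if a reference trial summary is
#' supplied — computes the three-stage interval chain for the latest wave.
#' All numeric output carries its numerator/denominator alongside, and
#' every file embeds a hash of the run configuration; identical inputs
#' produce identical outputs.
#'
#' @param input path to a cohort directory (`layout = "long"`) or an
#'   aggregate CSV (`layout = "aggregate"`). Ignored if `counts` given.
#' @param layout input layout, see [read_cohort()].
#' @param counts a [wave_counts()] tibble (alternative to `input`).
#' @param reference optional [reference_trial_summary()] enabling the
#'   interval chain. Anything else (for example `TRUE`) is a
#'   configuration error.
#' @param alpha significance threshold for association tests.
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with `convention`, `condition`,
#'   `association`, `chain` (or `NULL`), and the config `hash`.
#' @export
run_analysis <- function(input = NULL, layout = c("long", "aggregate"),
                         counts = NULL, reference = NULL, alpha = 0.01,
                         outdir = ".") {
  layout <- match.arg(layout)
  if (is.null(counts)) {
    if (is.null(input)) {
      cb_abort("provide either `input` or `counts`.", "config_error")
    }
    loaded <- read_cohort(input, layout = layout)
    counts <- if (inherits(loaded, "cohort")) tabulate_cohort(loaded) else loaded
  } else {
    counts <- validate_wave_counts(counts)
  }
  if (!is.null(reference) && !inherits(reference, "reference_trial_summary")) {
    cb_abort("`reference` must be a reference_trial_summary (the anchor rates are required).",
             "config_error")
  }
  hash <- rlang::hash(list(counts, reference, alpha,
                           as.character(utils::packageVersion("cessbounds"))))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  conv <- convention_table(counts)
  write_report_csv(format_rate_table(conv),
                   file.path(outdir, "convention_table.csv"), hash)
  cond <- condition_table(counts)
  write_report_csv(format_rate_table(cond),
                   file.path(outdir, "condition_table.csv"), hash)

  # homogeneity of quit counts across conditions, per wave (M=S counts:
  # quitters vs everyone else randomized)
  assoc <- NULL
  by_cond <- cond[!cond$missing_cell, ]
  if (nrow(by_cond) && length(unique(by_cond$condition)) >= 2) {
    assoc <- dplyr::bind_rows(lapply(sort(unique(by_cond$wave_months)), function(w) {
      cells <- by_cond[by_cond$wave_months == w, ]
      tab <- rbind(quit = cells$n_quit, other = cells$n_assigned - cells$n_quit)
      res <- chi_square_homogeneity(tab, alpha = alpha)
      tibble::tibble(wave_months = w, statistic = res$statistic, df = res$df,
                     p_value = res$p_value, significant = res$significant)
    }))
    write_report_csv(assoc, file.path(outdir, "association.csv"), hash)
  }

  chain <- NULL
  if (!is.null(reference)) {
    last_wave <- max(conv$wave_months[!conv$missing_cell])
    cell <- conv[conv$wave_months == last_wave & conv$window == "7-day" &
                   !conv$missing_cell, ]
    chain <- interval_chain(
      convention_rates(cell$n_quit, cell$n_answered, cell$n_assigned),
      reference)
    interval_chain_json(chain, file.path(outdir, "intervals.json"))
    txt <- utils::capture.output(print(chain))
    writeLines(c(sprintf("# config %s", hash), txt),
               file.path(outdir, "intervals.txt"))
  }

  writeLines(c(sprintf("config hash: %s", hash),
               sprintf("package: cessbounds %s",
                       as.character(utils::packageVersion("cessbounds"))),
               sprintf("alpha: %g", alpha),
               sprintf("reference anchors: %s",
                       if (is.null(reference)) "none" else
                         sprintf("M=S %.4f, observed %.4f, M=Quit %.4f",
                                 reference$ms_rate, reference$observed_rate,
                                 reference$mquit_rate))),
             file.path(outdir, "run_log.txt"))
  invisible(list(convention = conv, condition = cond, association = assoc,
                 chain = chain, hash = hash))
}

#' Run the bounds coverage simulation study and write its report
#'
#' Thin orchestration around [coverage_experiment()]: runs it and writes
#' the per-replicate table and a human-readable summary, both embedding
#' the config hash.
#'
#' @param config automated-trial [simulation_config()].
#' @param ref_config optional reference-trial config.
#' @param replicates number of replicates (>= 1).
#' @param wave,window outcome cell analyzed.
#' @param outdir output directory.
#' @return invisibly, the `coverage_experiment` object.
#' @export
run_simulation_study <- function(config, ref_config = NULL, replicates = 50L,
                                 wave = 12L, window = "7-day", outdir = ".") {
  if (replicates < 1) cb_abort("replicates must be >= 1.", "config_error")
  exp <- coverage_experiment(config, ref_config = ref_config,
                             replicates = replicates, wave = wave,
                             window = window)
  hash <- rlang::hash(list(config[setdiff(names(config), "seed")],
                           config$seed, replicates, wave, window))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_report_csv(exp$replicates, file.path(outdir, "coverage.csv"), hash)
  txt <- utils::capture.output(print(exp))
  writeLines(c(sprintf("# config %s", hash), txt),
             file.path(outdir, "coverage_summary.txt"))
  invisible(exp)
}
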