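# Pipeline entry points tying the stages together. These are the
# functions the command-line wrapper (inst/cli/lettercue.R) dispatches to.

.write_log <- function(path, lines) {
  writeLines(c(paste("#", format(Sys.time(), "%Y-%m-%d %H:%M:%S")), lines),
             path)
}

#' Simulate a cohort and write the trial table
#'
#' Simulates the full two-session experiment (exogenous then endogenous)
#' for the configured cohort and writes the tidy trial table plus a
#' sidecar log recording the seed and parameter echo.
#'
#' @param config A `run_config` from [read_run_config()] (defaults used
#'   when `NULL`).
#' @param out_path Output CSV path.
#' @return The trial table, invisibly.
#' @export
run_simulate <- function(config = NULL, out_path) {
  if (is.null(config)) config <- read_run_config()
  trials <- simulate_experiment(
    config$params, config$specs,
    n_subjects = config$n_subjects, seed = config$seed,
    settings = sdt_settings(config$analysis$m_alternatives)
  )
  write_trial_table(trials, out_path)
  .write_log(paste0(out_path, ".log"), c(
    paste("seed:", config$seed),
    paste("n_subjects:", config$n_subjects),
    paste("rows:", nrow(trials)),
    paste("s0:", paste(config$params$s0, collapse = " ")),
    paste("subject_sd:", config$params$subject_sd),
    paste("lapse:", config$params$lapse)
  ))
  invisible(trials)
}

#' Analyse a trial table and write result tables
#'
#' Runs the full analysis battery on a trial table: schema validation,
#' condition cells (pooled over positions and per position), per-subject
#' cue effects, the cue-benefit function with hemifield and crowding
#' aggregates, the neutral-cue serial position function, error profiles
#' and probit-linearised delta errors, split-half reliability, and
#' Bonferroni-adjusted position-wise benefit contrasts. Each result is
#' written as a comma-separated table in `out_dir`.
#'
#' @param trials A trial table tibble or the path to one.
#' @param config A `run_config`; defaults used when `NULL`.
#' @param out_dir Output directory, created if needed. `NULL` skips
#'   writing and just returns the results.
#' @return A named list of result tibbles, invisibly when writing.
#' @export
run_analyze <- function(trials, config = NULL, out_dir = NULL) {
  if (is.null(config)) config <- read_run_config()
  if (is.character(trials)) trials <- read_trial_table(trials)
  if (!nrow(trials)) stop("empty trial table", call. = FALSE)
  check <- validate_trial_table(trials)
  if (check$n_invalid > 0) {
    stop("trial table failed validation at ", check$n_invalid, " row(s); ",
         "first problems: ",
         paste(utils::head(unique(check$problems$problem), 3),
               collapse = "; "), call. = FALSE)
  }
  settings <- sdt_settings(config$analysis$m_alternatives)
  benefit_ctoa <- unlist(config$analysis$benefit_ctoa)

  cells_ctoa <- aggregate_cells(
    trials, c("subject", "cue_type", "validity", "ctoa"), settings)
  cells_pos <- aggregate_cells(
    trials, c("subject", "cue_type", "validity", "ctoa", "position"),
    settings)

  effects_ctoa <- cue_effects(cells_ctoa)
  effects_pos <- cue_effects(cells_pos)

  summary_pos <- benefit_function(effects_pos, benefit_ctoa)
  serial <- serial_position_dprime(cells_pos |>
    dplyr::filter(.data$ctoa_ms == benefit_ctoa[.data$cue_type]))

  profiles <- error_profile(trials, c("cue_type", "validity", "position"),
                            ctoa_restrict = benefit_ctoa)
  deltas <- delta_error(
    profiles |> dplyr::filter(.data$validity == "neutral") |>
      dplyr::select(-"validity"),
    profiles |> dplyr::filter(.data$validity == "valid") |>
      dplyr::select(-"validity")
  )

  reliability <- split_half_reliability(
    trials, method = config$analysis$correlation, settings = settings)

  pos_contrasts <- effects_pos |>
    dplyr::filter(.data$ctoa_ms == benefit_ctoa[.data$cue_type]) |>
    dplyr::group_by(.data$cue_type) |>
    dplyr::group_modify(~ positionwise_contrasts(.x)) |>
    dplyr::ungroup()

  results <- list(
    condition_cells = cells_ctoa,
    condition_cells_by_position = cells_pos,
    cue_effects = effects_ctoa,
    cue_effects_by_position = effects_pos,
    benefit_by_position = summary_pos$benefit_by_position,
    hemifield_benefit = summary_pos$hemifield_benefit,
    crowding_benefit = summary_pos$crowding_benefit,
    serial_position = serial,
    error_profile = profiles,
    delta_error = deltas,
    reliability = reliability,
    positionwise_contrasts = pos_contrasts
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      utils::write.csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    .write_log(file.path(out_dir, "analysis.log"), c(
      paste("rows:", nrow(trials)),
      paste("benefit_ctoa:", paste(names(benefit_ctoa), benefit_ctoa,
                                   sep = "=", collapse = " ")),
      paste("correlation:", config$analysis$correlation),
      paste("invalid_rows:", check$n_invalid)
    ))
    return(invisible(results))
  }
  results
}
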