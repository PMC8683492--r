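# Error taxonomy for incorrect reports. A transposition is a report of a
# letter presented at a string position adjacent to the target (positions
# 3 and 4 count as neighbours: the string is one contiguous 6-letter
# sequence spanning the fixation gap). A misidentification is a report of
# a letter absent from the string. Reports of presented but non-adjacent
# letters fall in a separate other_intrusion class, which the two-type
# taxonomy leaves unnamed; it is reported on its own and never merged.

#' Classify responses into the error taxonomy
#'
#' Adds an `error_class` column to a trial table, one of `correct`,
#' `transposition`, `misidentification` or `other_intrusion`. The four
#' classes partition all trials.
#'
#' @param trials Trial table with `letters`, `post_cue_pos`, `response`
#'   columns (`letters` as 6-character strings).
#' @return The input tibble with `error_class` appended.
#' @examples
#' tr <- tibble::tibble(letters = "KNBTYP", post_cue_pos = 5L,
#'                      response = c("Y", "T", "V", "K"))
#' classify_response(tr)$error_class
#' # "correct" "transposition" "misidentification" "other_intrusion"
#' @export
classify_response <- function(trials) {
  stopifnot(all(c("letters", "post_cue_pos", "response") %in% names(trials)))
  bad <- which(!trials$response %in% letter_alphabet)
  if (length(bad)) {
    stop("response outside the 12-letter response set at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  }
  target <- substr(trials$letters, trials$post_cue_pos, trials$post_cue_pos)
  # position of the response within the string; 0 when absent
  resp_pos <- mapply(function(s, r) {
    p <- regexpr(r, s, fixed = TRUE)
    if (p < 0) 0L else as.integer(p)
  }, trials$letters, trials$response, USE.NAMES = FALSE)
  cls <- ifelse(
    trials$response == target, "correct",
    ifelse(resp_pos == 0L, "misidentification",
           ifelse(abs(resp_pos - trials$post_cue_pos) == 1L,
                  "transposition", "other_intrusion"))
  )
  dplyr::mutate(trials, error_class = cls)
}

#' Error profile per condition cell
#'
#' Proportions of correct responses and of each error class, computed per
#' cell as count divided by the cell's total trial count (not by its error
#' count), so the four proportions sum to 1.
#'
#' @param trials Trial table; classified with [classify_response()] first
#'   if an `error_class` column is absent.
#' @param grouping Grouping factors as in [aggregate_cells()]; defaults to
#'   `c("cue_type", "validity", "position")` (pooled over subjects).
#' @param ctoa_restrict Optional named vector mapping cue type to a single
#'   CTOA to analyse (e.g. `c(exogenous = 50, endogenous = 600)`); `NULL`
#'   keeps all CTOAs.
#' @return A tibble with `n_trials`, `p_correct`, `p_transposition`,
#'   `p_misidentification`, `p_other_intrusion` per cell.
#' @export
error_profile <- function(trials,
                          grouping = c("cue_type", "validity", "position"),
                          ctoa_restrict = NULL) {
  if (!"error_class" %in% names(trials)) {
    trials <- classify_response(trials)
  }
  if (!is.null(ctoa_restrict)) {
    trials <- trials[trials$ctoa_ms == ctoa_restrict[trials$cue_type], ]
  }
  bad <- setdiff(grouping, names(.grouping_cols))
  if (length(bad)) {
    stop("unknown grouping factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cols <- unname(.grouping_cols[grouping])
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cols))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      p_correct = mean(.data$error_class == "correct"),
      p_transposition = mean(.data$error_class == "transposition"),
      p_misidentification = mean(.data$error_class == "misidentification"),
      p_other_intrusion = mean(.data$error_class == "other_intrusion"),
      .groups = "drop"
    )
}

#' Probit-linearised error difference (neutral minus valid)
#'
#' Error proportions are non-linear, so before differencing they are
#' linearised through the inverse cumulative normal. Each proportion is
#' first floor/ceiling-corrected with its own cell's trial count
#' ([clamp_proportion()]); the statistic is
#' `delta = qnorm(err_neutral) - qnorm(err_valid)` per cue type x error
#' type x position.
#'
#' @param profile_neutral,profile_valid Error profiles from
#'   [error_profile()], matched on `cue_type` (and `post_cue_pos` when
#'   present).
#' @param error_types Error classes to linearise.
#' @return A tibble with `cue_type`, `error_type`, `post_cue_pos`,
#'   corrected proportions and `delta`.
#' @export
delta_error <- function(profile_neutral, profile_valid,
                        error_types = c("transposition",
                                        "misidentification")) {
  keys <- intersect(c("cue_type", "post_cue_pos"), names(profile_neutral))
  joined <- dplyr::inner_join(profile_neutral, profile_valid, by = keys,
                              suffix = c("_neutral", "_valid"))
  out <- lapply(error_types, function(et) {
    pn <- clamp_proportion(joined[[paste0("p_", et, "_neutral")]],
                           joined$n_trials_neutral)
    pv <- clamp_proportion(joined[[paste0("p_", et, "_valid")]],
                           joined$n_trials_valid)
    tibble::tibble(
      joined[keys],
      error_type = et,
      p_neutral_corrected = pn,
      p_valid_corrected = pv,
      delta = stats::qnorm(pn) - stats::qnorm(pv)
    )
  })
  dplyr::bind_rows(out)
}
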