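# Trial-table and configuration I/O. Tables are comma-separated UTF-8
# text with a header row and "." as decimal separator; letter strings are
# serialised as uppercase strings without separators.

.trial_columns <- c("subject_id", "trial_index", "cue_type", "ctoa_ms",
                    "validity", "cued_side", "post_cue_pos", "letters",
                    "response", "response_set", "correct")

#' Write a trial table
#'
#' @param trials Trial table tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- trials[.trial_columns]
  out$correct <- as.integer(out$correct)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table
#'
#' @param path CSV file written by [write_trial_table()] or conforming to
#'   its schema.
#' @return A tibble with `correct` as logical.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  missing_cols <- setdiff(.trial_columns, names(tab))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$correct <- as.logical(tab$correct)
  tab$post_cue_pos <- as.integer(tab$post_cue_pos)
  tibble::as_tibble(tab)
}

#' Validate a trial table
#'
#' Checks column presence, enum domains, the letter-set invariants (6
#' distinct string letters from the alphabet, response in the response
#' set, response set equal to the alphabet), consistency of the `correct`
#' flag with response and target, validity/cued-side coherence, and
#' duplicated `(subject_id, trial_index)` keys.
#'
#' @param x A trial table tibble or a path to one.
#' @return A list of class `trial_validation` with `n_rows`, `n_valid`,
#'   `n_invalid` and a tibble of `problems` (row index + message).
#' @export
validate_trial_table <- function(x) {
  trials <- if (is.character(x)) read_trial_table(x) else x
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  problems <- list()
  flag <- function(rows, msg) {
    if (length(rows)) {
      problems[[length(problems) + 1]] <<-
        tibble::tibble(row = rows, problem = msg)
    }
  }

  flag(which(!trials$cue_type %in% c("exogenous", "endogenous")),
       "unknown cue_type")
  flag(which(!trials$validity %in% c("valid", "invalid", "neutral")),
       "unknown validity")
  flag(which(!trials$cued_side %in% c("left", "right", "both")),
       "unknown cued_side")
  flag(which(!(trials$post_cue_pos %in% 1:6)), "post_cue_pos outside 1..6")
  flag(which(trials$validity == "neutral" & trials$cued_side != "both"),
       "neutral trials must have cued_side = both")

  letters_split <- strsplit(trials$letters, "")
  ok_letters <- vapply(letters_split, function(l) {
    length(l) == 6L && !anyDuplicated(l) && all(l %in% letter_alphabet)
  }, logical(1))
  flag(which(!ok_letters), "letters must be 6 distinct alphabet letters")

  flag(which(!trials$response %in% letter_alphabet),
       "response outside the response set")

  sorted_alphabet <- paste(sort(letter_alphabet), collapse = "")
  rs_ok <- vapply(strsplit(trials$response_set, ""), function(l) {
    paste(sort(l), collapse = "") == sorted_alphabet
  }, logical(1))
  flag(which(!rs_ok), "response_set must equal the alphabet as a set")

  target <- substr(trials$letters, trials$post_cue_pos, trials$post_cue_pos)
  flag(which(trials$correct != (trials$response == target)),
       "correct flag contradicts response/target")

  key <- paste(trials$subject_id, trials$trial_index)
  flag(which(duplicated(key) | duplicated(key, fromLast = TRUE)),
       "duplicated (subject_id, trial_index)")

  problems <- if (length(problems)) dplyr::bind_rows(problems) else
    tibble::tibble(row = integer(), problem = character())
  structure(
    list(
      n_rows = nrow(trials),
      n_invalid = length(unique(problems$row)),
      n_valid = nrow(trials) - length(unique(problems$row)),
      problems = problems
    ),
    class = "trial_validation"
  )
}

#' @export
print.trial_validation <- function(x, ...) {
  cat("<trial_validation>", x$n_valid, "valid /", x$n_rows, "rows\n")
  if (nrow(x$problems)) {
    print(utils::head(x$problems, 20))
  }
  invisible(x)
}

# ---- run configuration -----------------------------------------------------

.default_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_subjects = 28L),
    design = list(
      exogenous = list(trials_per_cell = 10L),
      endogenous = list(trials_per_cell = 10L)
    ),
    observer = list(),
    analysis = list(
      m_alternatives = 12L,
      benefit_ctoa = list(exogenous = 50, endogenous = 600),
      correlation = "pearson"
    )
  )
}

.merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", paste0(path, key), call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- .merge_config(base[[key]], override[[key]],
                                   paste0(path, key, "."))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a run configuration
#'
#' Reads a YAML configuration with sections `seed`, `cohort`, `design`
#' (per cue type, [design_spec()] fields), `observer` ([observer_params()]
#' fields) and `analysis`. Missing keys fall back to the defaults; unknown
#' keys are rejected.
#'
#' @param path YAML file, or `NULL` for the package defaults.
#' @return A validated `run_config` list with instantiated `design_spec`
#'   and `observer_params` objects.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    # design/observer sections accept the full field sets of their objects
    cfg$design$exogenous <- utils::modifyList(
      list(ctoas = NULL, validities = NULL, trials_per_cell = 10L,
           letter_height_deg = 0.5, spacing_deg = 0.58,
           stimulus_duration_ms = 120, exo_cue_duration_ms = 50),
      cfg$design$exogenous)
    cfg$design$endogenous <- utils::modifyList(
      cfg$design$exogenous, list())
    obs_defaults <- unclass(observer_params())
    cfg$observer <- obs_defaults[setdiff(names(obs_defaults), "")]
    cfg <- .merge_config(cfg, user)
  }
  specs <- lapply(c(exogenous = "exogenous", endogenous = "endogenous"),
                  function(ct) {
                    do.call(design_spec, c(list(cue_type = ct),
                                           .spec_args(cfg$design[[ct]])))
                  })
  params <- do.call(observer_params, .params_args(cfg$observer))
  structure(
    list(
      seed = as.integer(cfg$seed),
      n_subjects = as.integer(cfg$cohort$n_subjects),
      specs = specs,
      params = params,
      analysis = cfg$analysis
    ),
    class = "run_config"
  )
}

.spec_args <- function(x) {
  allowed <- c("ctoas", "validities", "trials_per_cell", "alphabet",
               "letter_height_deg", "spacing_deg", "stimulus_duration_ms",
               "exo_cue_duration_ms")
  x <- x[intersect(names(x), allowed)]
  x[!vapply(x, is.null, logical(1))]
}

.params_args <- function(x) {
  allowed <- c("s0", "subject_sd", "gain_valid", "cost_invalid", "tau0",
               "tau_modifier", "lapse")
  x <- x[intersect(names(x), allowed)]
  lapply(x, function(v) if (is.list(v)) lapply(v, unlist) else unlist(v))
}
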