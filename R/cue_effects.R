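# Aggregation of trial tables into condition cells and the cue-effect
# statistics: benefit = d'(valid) - d'(neutral), cost = d'(neutral) -
# d'(invalid) (exogenous only), total effect = d'(valid) - d'(invalid).

.grouping_cols <- c(
  subject = "subject_id", cue_type = "cue_type", validity = "validity",
  ctoa = "ctoa_ms", position = "post_cue_pos"
)

#' Aggregate trials into condition cells
#'
#' Groups the trial table by the requested factors, counts trials and
#' correct responses, applies the floor/ceiling correction
#' ([clamp_proportion()]) with each cell's own trial count, and converts
#' the corrected proportion to d' ([dprime_from_pc()]).
#'
#' @param trials Trial table (as from [simulate_experiment()] or
#'   [read_trial_table()]).
#' @param grouping Character vector drawn from
#'   `c("subject", "cue_type", "validity", "ctoa", "position")`.
#' @param settings An [sdt_settings()] object.
#' @return A tibble of condition cells with `n_trials`, `n_correct`,
#'   `pc_corrected` and `dprime` columns.
#' @examples
#' \dontrun{
#' cells <- aggregate_cells(trials, c("subject", "cue_type", "validity"))
#' }
#' @export
aggregate_cells <- function(trials,
                            grouping = c("subject", "cue_type", "validity",
                                         "ctoa"),
                            settings = sdt_settings()) {
  bad <- setdiff(grouping, names(.grouping_cols))
  if (length(bad)) {
    stop("unknown grouping factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cols <- unname(.grouping_cols[grouping])
  missing_cols <- setdiff(cols, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.logical(trials$correct)) {
    stop("column 'correct' must be logical", call. = FALSE)
  }
  cells <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cols))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      .groups = "drop"
    )
  cells$pc_corrected <- clamp_proportion(cells$n_correct / cells$n_trials,
                                         cells$n_trials)
  upc <- unique(cells$pc_corrected)
  cells$dprime <- dprime_from_pc(upc, settings)[match(cells$pc_corrected, upc)]
  cells
}

#' Per-subject cue-effect statistics
#'
#' Computes, for each subject x cue type x CTOA (x position, when the
#' cells carry one), the cue benefit `d'(valid) - d'(neutral)`; for the
#' exogenous cue type also the cue cost `d'(neutral) - d'(invalid)` and
#' the total cue effect `d'(valid) - d'(invalid)`. A statistic whose
#' validity levels are absent from the cells is returned as `NA`, never 0.
#'
#' @param cells Condition cells from [aggregate_cells()]; must be grouped
#'   by `validity` (and normally `subject`).
#' @return A tibble with `benefit`, `cost` and `total_effect` columns.
#' @export
cue_effects <- function(cells) {
  if (!"validity" %in% names(cells)) {
    stop("cells must be aggregated by validity", call. = FALSE)
  }
  keys <- intersect(c("subject_id", "cue_type", "ctoa_ms", "post_cue_pos"),
                    names(cells))
  wide <- cells |>
    dplyr::select(dplyr::all_of(c(keys, "validity", "dprime"))) |>
    tidyr::pivot_wider(names_from = "validity", values_from = "dprime")
  for (lv in c("valid", "neutral", "invalid")) {
    if (!lv %in% names(wide)) wide[[lv]] <- NA_real_
  }
  out <- wide |>
    dplyr::mutate(
      benefit = .data$valid - .data$neutral,
      cost = .data$neutral - .data$invalid,
      total_effect = .data$valid - .data$invalid
    ) |>
    dplyr::select(dplyr::all_of(keys), "benefit", "cost", "total_effect")
  if ("cue_type" %in% names(out)) {
    # cost/total are defined for the exogenous system only
    endo <- out$cue_type == "endogenous"
    out$cost[endo] <- NA_real_
    out$total_effect[endo] <- NA_real_
  }
  out
}

.equal_weight_mean <- function(df, value, member_col, sets) {
  vapply(sets, function(members) {
    per_pos <- vapply(members, function(p) {
      mean(df[[value]][df[[member_col]] == p], na.rm = TRUE)
    }, numeric(1))
    mean(per_pos)
  }, numeric(1))
}

#' Cue-benefit function over letter positions
#'
#' Group-mean cue benefit per post-cued position, restricted by default to
#' the CTOA at which each attention system peaks (50 ms exogenous, 600 ms
#' endogenous), plus equal-weight hemifield (positions 1-3 vs 4-6) and
#' crowding (positions 2,5 vs 1,6) aggregates. Positions 3 and 4 are
#' excluded from the crowding contrast.
#'
#' @param effects Per-subject effect records from [cue_effects()], resolved
#'   by position (cells aggregated with `"position"` in the grouping).
#' @param ctoa_restrict Named numeric vector mapping cue type to the CTOA
#'   analysed; use `NULL` to keep all CTOAs.
#' @return A list of class `position_summary` with tibbles
#'   `benefit_by_position`, `hemifield_benefit` and `crowding_benefit`.
#' @export
benefit_function <- function(effects,
                             ctoa_restrict = c(exogenous = 50,
                                               endogenous = 600)) {
  stopifnot("post_cue_pos" %in% names(effects))
  if (!is.null(ctoa_restrict)) {
    keep <- effects$ctoa_ms == ctoa_restrict[effects$cue_type]
    effects <- effects[keep, ]
  }
  by_pos <- effects |>
    dplyr::group_by(.data$cue_type, .data$post_cue_pos) |>
    dplyr::summarise(
      mean_benefit = mean(.data$benefit, na.rm = TRUE),
      se_benefit = stats::sd(.data$benefit, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$benefit))),
      n = sum(!is.na(.data$benefit)),
      .groups = "drop"
    )
  agg_sets <- function(labels, label_col, sets) {
    dplyr::bind_rows(lapply(split(by_pos, by_pos$cue_type), function(df) {
      out <- tibble::tibble(
        cue_type = df$cue_type[1],
        mean_benefit = .equal_weight_mean(df, "mean_benefit",
                                          "post_cue_pos", sets)
      )
      out[[label_col]] <- labels
      out[, c("cue_type", label_col, "mean_benefit")]
    }))
  }
  hemi <- agg_sets(c("left", "right"), "hemifield",
                   list(.left_positions, .right_positions))
  crowd <- agg_sets(c("crowded", "uncrowded"), "crowding",
                    list(.crowded_positions, .uncrowded_positions))
  structure(
    list(benefit_by_position = by_pos,
         hemifield_benefit = hemi,
         crowding_benefit = crowd),
    class = "position_summary"
  )
}

#' @export
print.position_summary <- function(x, ...) {
  cat("<position_summary>\n")
  cat("benefit by position:\n")
  print(x$benefit_by_position, n = 12)
  cat("hemifield:\n"); print(x$hemifield_benefit)
  cat("crowding (positions 2,5 vs 1,6):\n"); print(x$crowding_benefit)
  invisible(x)
}

#' Group-mean serial position function
#'
#' Mean d' per letter position across subjects, by cue type, for a chosen
#' validity condition (neutral by default, the attention-free baseline).
#'
#' @param cells Condition cells aggregated by at least
#'   `c("subject", "cue_type", "validity", "position")`.
#' @param validity Validity level to profile.
#' @return A tibble with `cue_type`, `post_cue_pos`, `mean_dprime`,
#'   `se_dprime`, `n`.
#' @export
serial_position_dprime <- function(cells, validity = "neutral") {
  stopifnot(all(c("post_cue_pos", "validity") %in% names(cells)))
  cells |>
    dplyr::filter(.data$validity == !!validity) |>
    dplyr::group_by(.data$cue_type, .data$post_cue_pos) |>
    dplyr::summarise(
      mean_dprime = mean(.data$dprime),
      se_dprime = stats::sd(.data$dprime) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}

.formula_vocabulary <- c(
  "cue_validity", "CTOA", "subject", "position", "cue_type",
  "error_type", "letter_crowding", "hemifield"
)

#' Mixed-model formula string
#'
#' Emits the lme4-style formula used for the accuracy analyses, e.g.
#' `"d' = cue_validity + CTOA + (cue_validity + CTOA | subject)"`
#' (with a typographic apostrophe in the response label).
#' Fitting is delegated to an external mixed-model routine; this function
#' only normalises and validates the terms.
#'
#' @param fixed Character vector of fixed-effect terms.
#' @param random Character vector of random-effect terms of the form
#'   `"term1 + term2 | group"`; may be empty.
#' @param response Left-hand-side label.
#' @return The formula as a single string; duplicate terms are dropped,
#'   preserving first appearance.
#' @export
mixed_model_formula <- function(fixed, random = character(),
                                response = "d\u2019") {
  check_terms <- function(terms) {
    bad <- setdiff(terms, .formula_vocabulary)
    if (length(bad)) {
      stop("unknown model term(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  fixed <- unique(fixed)
  check_terms(fixed)
  rhs <- paste(fixed, collapse = " + ")
  for (r in random) {
    parts <- strsplit(r, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("random term must have the form 'terms | group': ", r,
           call. = FALSE)
    }
    terms <- unique(trimws(strsplit(parts[1], "+", fixed = TRUE)[[1]]))
    group <- trimws(parts[2])
    check_terms(c(terms, group))
    rhs <- paste0(rhs, " + (", paste(terms, collapse = " + "), " | ",
                  group, ")")
  }
  paste(response, "=", rhs)
}
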