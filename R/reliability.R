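# Split-half reliability of d' and simple paired contrasts.

#' Per-subject odd/even split-half d'
#'
#' Splits each subject's trials by presentation-order parity
#' (`trial_index` odd vs even) within subject x cue type x validity,
#' computes the floor/ceiling-corrected proportion correct on each half
#' with that half's own trial count, and converts to d'.
#'
#' @param trials Trial table with a `trial_index` column.
#' @param settings An [sdt_settings()] object.
#' @return A tibble with one row per subject x cue type x validity and
#'   columns `n_odd`, `n_even`, `dprime_odd`, `dprime_even`.
#' @export
split_half_dprime <- function(trials, settings = sdt_settings()) {
  stopifnot(all(c("subject_id", "trial_index", "correct") %in% names(trials)))
  halves <- trials |>
    dplyr::mutate(parity = ifelse(.data$trial_index %% 2 == 1, "odd",
                                  "even")) |>
    dplyr::group_by(.data$subject_id, .data$cue_type, .data$validity,
                    .data$parity) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     .groups = "drop")
  halves$pc <- clamp_proportion(halves$n_correct / halves$n, halves$n)
  upc <- unique(halves$pc)
  halves$dprime <- dprime_from_pc(upc, settings)[match(halves$pc, upc)]
  wide <- tidyr::pivot_wider(
    halves,
    id_cols = c("subject_id", "cue_type", "validity"),
    names_from = "parity",
    values_from = c("n", "dprime")
  )
  for (col in c("n_odd", "n_even", "dprime_odd", "dprime_even")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide
}

#' Spearman-Brown correction
#'
#' Adjusts a split-half correlation for the halved test length:
#' `r_sb = 2 r / (1 + r)`.
#'
#' @param r Correlation(s) in (-1, 1].
#' @return Corrected reliability; strictly increasing in `r`.
#' @examples
#' spearman_brown(0.8)  # 8/9
#' @export
spearman_brown <- function(r) {
  if (any(r <= -1 | r > 1, na.rm = TRUE)) {
    stop("r must lie in (-1, 1]", call. = FALSE)
  }
  2 * r / (1 + r)
}

#' Split-half reliability of d'
#'
#' Correlates the odd-half and even-half d' across subjects, per cue type
#' x validity, and applies the Spearman-Brown correction. Subjects with an
#' empty half are excluded from the correlation and counted.
#'
#' @param trials Trial table, or a pre-computed table from
#'   [split_half_dprime()].
#' @param method Correlation type, `"pearson"` (conventional for
#'   reliability) or `"spearman"`.
#' @param settings An [sdt_settings()] object.
#' @return A tibble with `cue_type`, `validity`, `n_subjects`,
#'   `n_excluded`, `r_split`, `r_sb`.
#' @export
split_half_reliability <- function(trials, method = c("pearson", "spearman"),
                                   settings = sdt_settings()) {
  method <- match.arg(method)
  pairs <- if (all(c("dprime_odd", "dprime_even") %in% names(trials))) {
    trials
  } else {
    split_half_dprime(trials, settings)
  }
  pairs |>
    dplyr::group_by(.data$cue_type, .data$validity) |>
    dplyr::summarise(
      n_subjects = sum(stats::complete.cases(.data$dprime_odd,
                                             .data$dprime_even)),
      n_excluded = dplyr::n() - .data$n_subjects,
      r_split = {
        ok <- stats::complete.cases(.data$dprime_odd, .data$dprime_even)
        if (sum(ok) < 2) {
          stop("split-half correlation needs at least 2 subjects",
               call. = FALSE)
        }
        stats::cor(.data$dprime_odd[ok], .data$dprime_even[ok],
                   method = method)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(r_sb = spearman_brown(.data$r_split))
}

#' Paired contrast (two-sided t test on per-subject differences)
#'
#' @param values_a,values_b Equal-length per-subject vectors.
#' @param label Contrast label carried into the result.
#' @return A one-row tibble with the mean difference, its standard error,
#'   `t`, `df = n - 1` and the two-sided p value. When the differences
#'   have zero variance the result carries `degenerate = TRUE` (with
#'   `t = 0` if the mean difference is also 0, `NA` otherwise).
#' @export
paired_contrast <- function(values_a, values_b, label = "") {
  stopifnot(length(values_a) == length(values_b))
  d <- values_a - values_b
  d <- d[stats::complete.cases(d)]
  n <- length(d)
  if (n < 2) stop("paired contrast needs at least 2 pairs", call. = FALSE)
  m <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  degenerate <- se == 0
  t_stat <- if (!degenerate) m / se else if (m == 0) 0 else NA_real_
  p <- if (!degenerate) 2 * stats::pt(-abs(t_stat), df = n - 1) else
    if (m == 0) 1 else NA_real_
  tibble::tibble(
    label = label, n = n, mean_diff = m, se = se,
    t = t_stat, df = n - 1, p_value = p, degenerate = degenerate
  )
}

#' Position-wise paired contrasts with Bonferroni adjustment
#'
#' Runs [paired_contrast()] for each letter position (values pivoted from
#' per-subject records) and Bonferroni-adjusts the p values with family
#' size equal to the number of positions tested.
#'
#' @param records Per-subject records with `subject_id`, `post_cue_pos`
#'   and a value column.
#' @param value Name of the column contrasted against zero per position.
#' @return A tibble of contrasts with `p_adjusted`.
#' @export
positionwise_contrasts <- function(records, value = "benefit") {
  stopifnot(all(c("subject_id", "post_cue_pos", value) %in% names(records)))
  positions <- sort(unique(records$post_cue_pos))
  out <- lapply(positions, function(p) {
    v <- records[[value]][records$post_cue_pos == p]
    v <- v[stats::complete.cases(v)]
    res <- paired_contrast(v, rep(0, length(v)),
                           label = paste0("position_", p))
    res$post_cue_pos <- p
    res
  })
  out <- dplyr::bind_rows(out)
  out$p_adjusted <- pmin(out$p_value * length(positions), 1)
  out
}
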