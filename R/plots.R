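# Figure panels for the standard summaries.

#' Plot the serial position function
#'
#' @param serial Output of [serial_position_dprime()].
#' @return A ggplot object (d' vs letter position, one panel per cue type).
#' @export
plot_serial_position <- function(serial) {
  ggplot2::ggplot(serial,
                  ggplot2::aes(x = .data$post_cue_pos,
                               y = .data$mean_dprime)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_dprime - .data$se_dprime,
                   ymax = .data$mean_dprime + .data$se_dprime)) +
    ggplot2::facet_wrap(~cue_type) +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    ggplot2::labs(x = "letter position", y = "d'",
                  title = "Serial position function") +
    ggplot2::theme_minimal()
}

#' Plot the cue benefit function
#'
#' @param summary_pos A `position_summary` from [benefit_function()].
#' @return A ggplot object (mean benefit vs position per cue type).
#' @export
plot_benefit_function <- function(summary_pos) {
  ggplot2::ggplot(summary_pos$benefit_by_position,
                  ggplot2::aes(x = .data$post_cue_pos,
                               y = .data$mean_benefit)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_benefit - .data$se_benefit,
                   ymax = .data$mean_benefit + .data$se_benefit)) +
    ggplot2::facet_wrap(~cue_type) +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    ggplot2::labs(x = "post-cued letter position",
                  y = "cue benefit (d' valid - neutral)",
                  title = "Cue benefit function") +
    ggplot2::theme_minimal()
}

#' Plot the attentional time course
#'
#' Mean cue benefit (and, for the exogenous system, cost and total
#' effect) as a function of CTOA.
#'
#' @param effects Per-subject effect records from [cue_effects()]
#'   aggregated over positions (CTOA-level cells).
#' @return A ggplot object.
#' @export
plot_time_course <- function(effects) {
  long <- effects |>
    tidyr::pivot_longer(dplyr::all_of(c("benefit", "cost", "total_effect")),
                        names_to = "statistic", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$cue_type, .data$ctoa_ms, .data$statistic) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ctoa_ms, y = .data$mean,
                                     colour = .data$statistic)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~cue_type, scales = "free_x") +
    ggplot2::labs(x = "CTOA (ms)", y = "d' difference",
                  title = "Time course of cue effects") +
    ggplot2::theme_minimal()
}
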