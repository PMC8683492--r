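# Shared fixtures built in code.

# Monte-Carlo oracle for M-AFC percent correct: one signal channel
# Normal(d', 1) against M-1 independent Normal(0, 1) noise channels; the
# observer is correct when the signal draw is the maximum.
mc_pc_oracle <- function(dprime, m, n_draws = 2e5) {
  signal <- rnorm(n_draws, mean = dprime)
  noise_max <- rep(-Inf, n_draws)
  for (k in seq_len(m - 1)) {
    noise_max <- pmax(noise_max, rnorm(n_draws))
  }
  mean(signal > noise_max)
}

# a single-condition design spec useful for focused observer tests
mono_spec <- function(trials_per_cell = 10L, cue_type = "exogenous",
                      ctoas = 100, validities = "neutral") {
  design_spec(cue_type, ctoas = ctoas, validities = validities,
              trials_per_cell = trials_per_cell)
}

# observer with all attentional modulation switched off
null_observer <- function(...) {
  observer_params(
    gain_valid = list(
      exogenous = c("50" = 0, "100" = 0, "300" = 0),
      endogenous = c("100" = 0, "300" = 0, "600" = 0)
    ),
    cost_invalid = list(exogenous = c("50" = 0, "100" = 0, "300" = 0)),
    tau_modifier = list(
      exogenous = c(valid = 1, invalid = 1, neutral = 1),
      endogenous = c(valid = 1, neutral = 1)
    ),
    ...
  )
}

both_specs <- function(trials_per_cell = 10L) {
  list(design_spec("exogenous", trials_per_cell = trials_per_cell),
       design_spec("endogenous", trials_per_cell = trials_per_cell))
}

# hand-built trial table with perfectly repeatable halves: each subject
# alternates a fixed correct/incorrect pattern so odd and even trials are
# identical by construction
deterministic_trials <- function(n_subjects = 6, n_pairs = 20) {
  rows <- lapply(seq_len(n_subjects), function(s) {
    n_correct_per_half <- s + 4  # accuracy varies across subjects
    pattern <- rep(c(TRUE, FALSE), times = c(n_correct_per_half,
                                             n_pairs - n_correct_per_half))
    correct <- rep(pattern, each = 2)  # odd trial k and even trial k match
    string <- paste(letter_alphabet[1:6], collapse = "")
    target <- substr(string, 3, 3)
    tibble::tibble(
      subject_id = sprintf("S%02d", s),
      trial_index = seq_len(2 * n_pairs),
      cue_type = "exogenous",
      ctoa_ms = 100,
      validity = "neutral",
      cued_side = "both",
      post_cue_pos = 3L,
      letters = string,
      response = ifelse(correct, target, "Z"),
      response_set = paste(letter_alphabet, collapse = ""),
      correct = correct
    )
  })
  dplyr::bind_rows(rows)
}
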