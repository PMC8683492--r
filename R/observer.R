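# Parametric generative observer for the partial-report cueing task.
#
# Sensitivity is additive in d' units: a W-shaped positional baseline plus
# a per-subject intercept, plus a validity x CTOA attention gain (valid)
# or minus a cost (invalid, exogenous only). Responses on error trials are
# a two-branch mixture: with probability tau_eff the observer confuses
# letter position and reports an adjacent letter (transposition), else it
# reports one of the six letters absent from the string
# (misidentification). A small lapse rate yields uniform guesses over the
# 12 alternatives.

#' Generative observer parameters
#'
#' Defaults emulate the adult cohort the task was designed around:
#' W-shaped positional sensitivity (outer letters near ceiling, flanked
#' inner letters lowest, a right-hemifield advantage), transient exogenous
#' attention (largest valid-cue gain at the 50 ms CTOA, decaying by
#' 300 ms, with an invalid-cue cost of similar time course), ramping
#' endogenous attention (gain growing to its maximum at 600 ms), a
#' transposition propensity that peaks at the crowded positions 2 and 5,
#' and a strongly reduced transposition propensity under valid endogenous
#' cues (voluntary attention protects letter-position coding).
#'
#' @param s0 Numeric length-6 baseline sensitivity (d' units) per position.
#' @param subject_sd SD of the per-subject additive sensitivity intercept.
#' @param gain_valid Named list `exogenous`/`endogenous`, each a named
#'   numeric vector mapping CTOA (ms) to the additive d' gain on valid
#'   trials.
#' @param cost_invalid Named list with an `exogenous` entry mapping CTOA to
#'   the additive d' loss on invalid trials.
#' @param tau0 Numeric length-6 transposition propensity per position: the
#'   probability, given a non-lapse error, that the error is an
#'   adjacent-position confusion rather than an absent-letter report.
#' @param tau_modifier Named list `exogenous`/`endogenous`, each a named
#'   numeric vector over validity levels giving a multiplicative factor on
#'   `tau0`.
#' @param lapse Probability of a uniform random response over the 12
#'   alternatives.
#' @return An `observer_params` object.
#' @export
observer_params <- function(
    s0 = c(3.5, 1.7, 2.1, 2.8, 1.8, 3.6),
    subject_sd = 0.6,
    gain_valid = list(
      exogenous = c("50" = 0.45, "100" = 0.22, "300" = 0.06),
      endogenous = c("100" = 0.18, "300" = 0.36, "600" = 0.62)
    ),
    cost_invalid = list(
      exogenous = c("50" = 0.50, "100" = 0.46, "300" = 0.15)
    ),
    tau0 = c(0.45, 0.85, 0.65, 0.65, 0.85, 0.45),
    tau_modifier = list(
      exogenous = c(valid = 1, invalid = 1, neutral = 1),
      endogenous = c(valid = 0.25, neutral = 1)
    ),
    lapse = 0.01) {
  params <- structure(
    list(
      s0 = s0, subject_sd = subject_sd,
      gain_valid = gain_valid, cost_invalid = cost_invalid,
      tau0 = tau0, tau_modifier = tau_modifier, lapse = lapse
    ),
    class = "observer_params"
  )
  validate_observer_params(params)
  params
}

#' Validate observer parameters
#'
#' @param params An `observer_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_observer_params <- function(params) {
  stopifnot(inherits(params, "observer_params"))
  with(params, {
    if (length(s0) != 6L || any(!is.finite(s0)) || any(s0 < 0)) {
      stop("field 's0': must be 6 finite non-negative sensitivities",
           call. = FALSE)
    }
    if (!is.finite(subject_sd) || subject_sd < 0) {
      stop("field 'subject_sd': must be >= 0", call. = FALSE)
    }
    if (length(tau0) != 6L || any(tau0 < 0 | tau0 > 1)) {
      stop("field 'tau0': must be 6 probabilities in [0, 1]", call. = FALSE)
    }
    if (lapse < 0 || lapse > 1) {
      stop("field 'lapse': must be in [0, 1]", call. = FALSE)
    }
    for (ct in names(gain_valid)) {
      if (any(!is.finite(gain_valid[[ct]]))) {
        stop("field 'gain_valid$", ct, "': gains must be finite",
             call. = FALSE)
      }
    }
    for (ct in names(tau_modifier)) {
      if (any(tau_modifier[[ct]] < 0)) {
        stop("field 'tau_modifier$", ct, "': must be non-negative",
             call. = FALSE)
      }
    }
  })
  invisible(params)
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat("  s0 (d' by position):", paste(x$s0, collapse = " "), "\n")
  cat("  subject_sd:", x$subject_sd, " lapse:", x$lapse, "\n")
  for (ct in names(x$gain_valid)) {
    cat("  gain_valid", ct, ":",
        paste(names(x$gain_valid[[ct]]), x$gain_valid[[ct]], sep = "=",
              collapse = " "), "\n")
  }
  cat("  tau0:", paste(x$tau0, collapse = " "), "\n")
  invisible(x)
}

.lookup_gain <- function(map, cue_type, ctoa_ms, what) {
  tab <- map[[cue_type]]
  key <- as.character(ctoa_ms)
  if (is.null(tab) || any(!key %in% names(tab))) {
    stop("no ", what, " entry for cue_type=", cue_type, ", ctoa_ms=",
         paste(unique(ctoa_ms[!key %in% names(tab)]), collapse = ","),
         call. = FALSE)
  }
  unname(tab[key])
}

#' Effective sensitivity on a trial
#'
#' The generative d' for a trial: positional baseline plus subject
#' intercept, plus the validity x CTOA attention gain (valid trials),
#' minus the cost (invalid trials), clamped at 0.
#'
#' @param params An [observer_params()] object.
#' @param subject_intercept Additive per-subject sensitivity offset.
#' @param template Data frame of trial templates with columns `cue_type`,
#'   `ctoa_ms`, `validity`, `post_cue_pos` (as from [build_design()]).
#' @return Numeric vector of effective d' values, one per template row.
#' @export
effective_dprime <- function(params, subject_intercept, template) {
  base <- params$s0[template$post_cue_pos] + subject_intercept
  delta <- numeric(nrow(template))
  iv <- template$validity == "valid"
  if (any(iv)) {
    delta[iv] <- .lookup_gain(params$gain_valid, template$cue_type[iv][1],
                              template$ctoa_ms[iv], "gain_valid")
  }
  ii <- template$validity == "invalid"
  if (any(ii)) {
    delta[ii] <- -.lookup_gain(params$cost_invalid, template$cue_type[ii][1],
                               template$ctoa_ms[ii], "cost_invalid")
  }
  pmax(base + delta, 0)
}

.tau_eff <- function(params, template) {
  mods <- vapply(seq_len(nrow(template)), function(i) {
    m <- params$tau_modifier[[template$cue_type[i]]]
    if (is.null(m) || !template$validity[i] %in% names(m)) 1
    else unname(m[template$validity[i]])
  }, numeric(1))
  pmin(params$tau0[template$post_cue_pos] * mods, 1)
}

# simulate responses for a block of templates sharing one subject intercept;
# strings is a n x 6 character matrix
.simulate_block <- function(params, subject_intercept, template, strings,
                            settings = sdt_settings()) {
  n <- nrow(template)
  dp <- effective_dprime(params, subject_intercept, template)
  # map unique d' values through the quadrature once
  udp <- unique(dp)
  pc <- pc_from_dprime(udp, settings)[match(dp, udp)]
  tau <- .tau_eff(params, template)

  pos <- template$post_cue_pos
  target <- strings[cbind(seq_len(n), pos)]
  response <- character(n)

  is_lapse <- stats::runif(n) < params$lapse
  is_correct <- stats::runif(n) < pc      # drawn for all; used on non-lapse
  is_transpo <- stats::runif(n) < tau     # used on non-lapse errors

  # non-lapse correct: report the target
  idx <- which(!is_lapse & is_correct)
  response[idx] <- target[idx]

  # non-lapse transposition: uniform over the 1-2 adjacent letters
  idx <- which(!is_lapse & !is_correct & is_transpo)
  if (length(idx)) {
    pick_right <- stats::runif(length(idx)) < 0.5
    nb <- ifelse(pos[idx] == 1L, 2L,
          ifelse(pos[idx] == 6L, 5L,
                 ifelse(pick_right, pos[idx] + 1L, pos[idx] - 1L)))
    response[idx] <- strings[cbind(idx, nb)]
  }

  # non-lapse misidentification: uniform over the 6 absent letters
  idx <- which(!is_lapse & !is_correct & !is_transpo)
  if (length(idx)) {
    slot <- sample.int(6L, length(idx), replace = TRUE)
    response[idx] <- vapply(seq_along(idx), function(j) {
      setdiff(letter_alphabet, strings[idx[j], ])[slot[j]]
    }, character(1))
  }

  # lapse: uniform over the full 12-letter response set
  idx <- which(is_lapse)
  if (length(idx)) {
    response[idx] <- letter_alphabet[sample.int(12L, length(idx),
                                                replace = TRUE)]
  }

  tibble::tibble(
    template,
    letters = apply(strings, 1, paste, collapse = ""),
    response = response,
    response_set = paste(letter_alphabet, collapse = ""),
    correct = response == target
  )
}

#' Simulate a single trial
#'
#' Convenience wrapper around the vectorised simulator for one template
#' row; mostly useful for tests and illustration. [simulate_experiment()]
#' is the efficient cohort-level entry point.
#'
#' @param params An [observer_params()] object.
#' @param subject_intercept Per-subject sensitivity offset.
#' @param template One-row data frame of a trial template.
#' @param string Character vector of 6 presented letters.
#' @param settings An [sdt_settings()] object.
#' @return A one-row tibble trial record.
#' @export
simulate_trial <- function(params, subject_intercept, template, string,
                           settings = sdt_settings()) {
  stopifnot(nrow(template) == 1L, length(string) == 6L)
  .simulate_block(params, subject_intercept, template,
                  matrix(string, nrow = 1), settings)
}

#' Simulate a cohort performing the task
#'
#' For each subject: draws a sensitivity intercept from
#' `Normal(0, subject_sd)`, builds a freshly shuffled session for each
#' design, samples a new 6-letter string per trial, and simulates every
#' trial. Identical `(params, specs, n_subjects, seed)` give a
#' bit-identical table.
#'
#' @param params An [observer_params()] object.
#' @param specs A [design_spec()] or list of them (e.g. exogenous and
#'   endogenous sessions).
#' @param n_subjects Number of subjects (default 28).
#' @param seed Integer seed for all randomness.
#' @param settings An [sdt_settings()] object.
#' @return A tidy tibble of trial records: `subject_id`, `trial_index`,
#'   `cue_type`, `ctoa_ms`, `validity`, `cued_side`, `post_cue_pos`,
#'   `letters`, `response`, `response_set`, `correct`.
#' @examples
#' tab <- simulate_experiment(observer_params(),
#'                            design_spec("exogenous"),
#'                            n_subjects = 2, seed = 1)
#' nrow(tab)  # 2 * 540
#' @export
simulate_experiment <- function(params, specs, n_subjects = 28L, seed = 1L,
                                settings = sdt_settings()) {
  validate_observer_params(params)
  if (inherits(specs, "design_spec")) specs <- list(specs)
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    intercept <- stats::rnorm(1, 0, params$subject_sd)
    per_spec <- lapply(specs, function(spec) {
      templ <- build_design(spec)
      strings <- t(vapply(seq_len(nrow(templ)),
                          function(i) sample_string(spec$alphabet),
                          character(6)))
      .simulate_block(params, intercept, templ, strings, settings)
    })
    tab <- dplyr::bind_rows(per_spec)
    # sessions run back to back: keep trial_index unique within subject
    tab$trial_index <- seq_len(nrow(tab))
    out[[s]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%02d", s)), tab
    )
  }
  dplyr::bind_rows(out)
}
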