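#' Specify the factorial cueing design
#'
#' Builds the design specification for one cue type of the partial-report
#' letter task. Defaults reproduce the published protocol: 6 letter
#' positions, 10 trials per (position x CTOA x validity) cell, exogenous
#' pre-cues at CTOAs of 50/100/300 ms with valid/invalid/neutral trials in
#' equal proportion, and endogenous pre-cues at 100/300/600 ms with half
#' valid and half neutral trials.
#'
#' @param cue_type `"exogenous"` or `"endogenous"`.
#' @param ctoas Cue-target onset asynchronies in ms. Defaults to
#'   `c(50, 100, 300)` (exogenous) or `c(100, 300, 600)` (endogenous).
#' @param validities Cue validity levels. Defaults to
#'   `c("valid", "invalid", "neutral")` (exogenous) or
#'   `c("valid", "neutral")` (endogenous).
#' @param trials_per_cell Trials per (position x CTOA x validity) cell.
#' @param alphabet Stimulus letter set; must contain 12 distinct letters.
#' @param n_positions Number of letter slots (fixed at 6).
#' @param letter_height_deg Letter height in degrees of visual angle;
#'   glyphs are treated as square, so this is also the letter width.
#' @param spacing_deg Centre-to-centre letter spacing in degrees.
#' @param stimulus_duration_ms Target string duration (metadata only).
#' @param exo_cue_duration_ms Exogenous cue flash duration (metadata only).
#' @return An object of class `design_spec`.
#' @examples
#' spec <- design_spec("exogenous")
#' nrow(build_design(spec, seed = 1))  # 540
#' @export
design_spec <- function(cue_type = c("exogenous", "endogenous"),
                        ctoas = NULL,
                        validities = NULL,
                        trials_per_cell = 10L,
                        alphabet = letter_alphabet,
                        n_positions = 6L,
                        letter_height_deg = 0.5,
                        spacing_deg = 0.58,
                        stimulus_duration_ms = 120,
                        exo_cue_duration_ms = 50) {
  cue_type <- match.arg(cue_type)
  if (is.null(ctoas)) {
    ctoas <- if (cue_type == "exogenous") c(50, 100, 300) else c(100, 300, 600)
  }
  if (is.null(validities)) {
    validities <- if (cue_type == "exogenous") {
      c("valid", "invalid", "neutral")
    } else {
      c("valid", "neutral")
    }
  }
  spec <- structure(
    list(
      cue_type = cue_type,
      ctoas = as.numeric(ctoas),
      validities = validities,
      trials_per_cell = as.integer(trials_per_cell),
      alphabet = toupper(alphabet),
      n_positions = as.integer(n_positions),
      letter_height_deg = letter_height_deg,
      spacing_deg = spacing_deg,
      stimulus_duration_ms = stimulus_duration_ms,
      exo_cue_duration_ms = exo_cue_duration_ms
    ),
    class = "design_spec"
  )
  validate_design_spec(spec)
  spec
}

#' Validate a design specification
#'
#' Checks the structural invariants of a [design_spec()]: a 12-letter
#' distinct alphabet, 6 positions, at least one trial per cell, validity
#' levels compatible with the cue type (invalid cues exist only in the
#' exogenous design), and positive geometry.
#'
#' @param spec A `design_spec` object.
#' @return `spec`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_design_spec <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (length(spec$alphabet) != 12L || anyDuplicated(spec$alphabet)) {
    stop("field 'alphabet': must contain exactly 12 distinct letters",
         call. = FALSE)
  }
  if (spec$n_positions != 6L) {
    stop("field 'n_positions': must be 6", call. = FALSE)
  }
  if (spec$trials_per_cell < 1L) {
    stop("field 'trials_per_cell': must be >= 1", call. = FALSE)
  }
  bad <- setdiff(spec$validities, c("valid", "invalid", "neutral"))
  if (length(bad)) {
    stop("field 'validities': unknown level(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (spec$cue_type == "endogenous" && "invalid" %in% spec$validities) {
    stop("field 'validities': 'invalid' is not defined for the endogenous ",
         "cue type (endogenous cues are 100% informative)", call. = FALSE)
  }
  if (!length(spec$ctoas) || any(spec$ctoas <= 0)) {
    stop("field 'ctoas': must be positive", call. = FALSE)
  }
  if (spec$spacing_deg < 0 || spec$letter_height_deg < 0) {
    stop("field 'spacing_deg'/'letter_height_deg': invalid geometry",
         call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>", x$cue_type, "\n")
  cat("  CTOAs (ms):   ", paste(x$ctoas, collapse = ", "), "\n")
  cat("  validities:   ", paste(x$validities, collapse = ", "), "\n")
  cat("  trials/cell:  ", x$trials_per_cell, "->",
      x$trials_per_cell * x$n_positions * length(x$ctoas) *
        length(x$validities), "trials\n")
  cat("  geometry:      letter", x$letter_height_deg, "deg, spacing",
      x$spacing_deg, "deg\n")
  invisible(x)
}

.side_of_position <- function(position) {
  ifelse(position <= 3L, "left", "right")
}

#' Build the balanced trial list
#'
#' Crosses position (1..6) x CTOA x validity with `trials_per_cell`
#' repeats, assigns the cued side implied by each trial's validity (valid:
#' same side as the post-cued target; invalid: opposite side; neutral: both
#' sides), and shuffles the whole session with a single Fisher-Yates pass.
#'
#' @param spec A [design_spec()].
#' @param seed Optional integer seed for the shuffle. If `NULL`, the
#'   current RNG state is used.
#' @return A tibble of trial templates with columns `trial_index`,
#'   `cue_type`, `ctoa_ms`, `validity`, `cued_side`, `post_cue_pos`.
#' @examples
#' nrow(build_design(design_spec("endogenous"), seed = 1))  # 360
#' @export
build_design <- function(spec, seed = NULL) {
  validate_design_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(
    rep = seq_len(spec$trials_per_cell),
    post_cue_pos = seq_len(spec$n_positions),
    ctoa_ms = spec$ctoas,
    validity = spec$validities,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  side <- .side_of_position(grid$post_cue_pos)
  cued_side <- ifelse(
    grid$validity == "neutral", "both",
    ifelse(grid$validity == "valid", side,
           ifelse(side == "left", "right", "left"))
  )
  out <- tibble::tibble(
    cue_type = spec$cue_type,
    ctoa_ms = grid$ctoa_ms,
    validity = grid$validity,
    cued_side = cued_side,
    post_cue_pos = as.integer(grid$post_cue_pos)
  )
  out <- out[sample.int(nrow(out)), ]
  out$trial_index <- seq_len(nrow(out))
  out[, c("trial_index", "cue_type", "ctoa_ms", "validity", "cued_side",
          "post_cue_pos")]
}

#' Sample a stimulus string
#'
#' Draws 6 distinct letters uniformly without replacement from the
#' alphabet, left-to-right.
#'
#' @param alphabet Letter set of at least 6 distinct letters.
#' @param n_letters Number of letters to draw (default 6).
#' @return Character vector of `n_letters` distinct letters.
#' @export
sample_string <- function(alphabet = letter_alphabet, n_letters = 6L) {
  if (length(alphabet) < n_letters) {
    stop("alphabet must contain at least ", n_letters, " letters",
         call. = FALSE)
  }
  sample(alphabet, n_letters)
}

#' Build the 12-alternative response set
#'
#' The response alternatives offered after each trial comprise the 6
#' presented letters plus the 6 alphabet letters absent from the string, so
#' the response set always equals the full alphabet as a set.
#'
#' @param string Character vector of 6 presented letters.
#' @param alphabet The 12-letter alphabet.
#' @return Character vector of 12 letters: the presented 6 followed by the
#'   absent 6.
#' @export
build_response_set <- function(string, alphabet = letter_alphabet) {
  if (!all(string %in% alphabet)) {
    stop("string contains letters outside the alphabet: ",
         paste(setdiff(string, alphabet), collapse = ", "), call. = FALSE)
  }
  if (length(alphabet) != 12L) {
    stop("alphabet must contain 12 letters", call. = FALSE)
  }
  c(string, setdiff(alphabet, string))
}

#' Letter eccentricity
#'
#' Centre eccentricity of each letter slot. Slots sit at signed indices
#' (-3,-2,-1,+1,+2,+3) spacing units from fixation, so the inner, middle
#' and outer letters on each side lie at 1, 2 and 3 times the
#' centre-to-centre spacing (0.58, 1.16 and 1.74 degrees by default).
#'
#' @param position Integer vector of positions in 1..6.
#' @param spec A [design_spec()] supplying `spacing_deg`.
#' @return Numeric vector of eccentricities in degrees.
#' @export
letter_eccentricity <- function(position, spec = design_spec("exogenous")) {
  if (!all(position %in% 1:6)) {
    stop("position must be in 1..6", call. = FALSE)
  }
  abs(.signed_slot[position]) * spec$spacing_deg
}

#' Horizontal extent of the six-letter string
#'
#' Twice the outer-letter eccentricity plus one letter width (glyphs are
#' square, width = height). The default geometry gives 3.98 degrees.
#'
#' @param spec A [design_spec()].
#' @return Extent in degrees.
#' @export
string_extent <- function(spec = design_spec("exogenous")) {
  outer_ecc <- 3 * spec$spacing_deg
  2 * (outer_ecc + spec$letter_height_deg / 2)
}

#' Bouma's-law crowding predicate
#'
#' A letter is flagged as crowded when its neighbours fall within the
#' critical spacing of half its eccentricity, i.e. when
#' `spacing < eccentricity / 2`.
#'
#' @param position Integer vector of positions in 1..6.
#' @param spec A [design_spec()].
#' @return Logical vector.
#' @export
bouma_crowded <- function(position, spec = design_spec("exogenous")) {
  spec$spacing_deg < 0.5 * letter_eccentricity(position, spec)
}

#' Geometry report for a design
#'
#' @param spec A [design_spec()].
#' @return A list with per-position eccentricities, the string extent, the
#'   spacing-to-letter-width ratio, and the Bouma crowding flags.
#' @export
geometry_report <- function(spec = design_spec("exogenous")) {
  ecc <- letter_eccentricity(1:6, spec)
  names(ecc) <- as.character(1:6)
  crowded <- bouma_crowded(1:6, spec)
  names(crowded) <- as.character(1:6)
  list(
    eccentricities_deg = ecc,
    string_extent_deg = string_extent(spec),
    spacing_ratio = spec$spacing_deg / spec$letter_height_deg,
    bouma_crowded = crowded
  )
}
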