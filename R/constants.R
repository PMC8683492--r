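# Shared layout constants for the six-letter partial-report task.
# Positions are indexed 1..6 left-to-right; the string straddles fixation,
# so the left hemifield holds positions 1-3 and the right holds 4-6.

#' Stimulus alphabet
#'
#' The 12 consonants used as stimuli, matched on perimetric complexity.
#' Every trial's string is a 6-permutation of this set, and every response
#' set equals this set.
#'
#' @format Character vector of length 12.
#' @export
letter_alphabet <- c("B", "F", "H", "K", "L", "N", "P", "T", "V", "X", "Y", "Z")

# slot indices signed about fixation: positions 1..6 sit at -3,-2,-1,+1,+2,+3
# spacing units from the fixation-cross centre (the inner pair is one full
# spacing out; the fixation cross occupies the central gap)
.signed_slot <- c(-3L, -2L, -1L, 1L, 2L, 3L)

.left_positions <- 1:3
.right_positions <- 4:6

# crowding contrast sets used throughout the results: the flanked inner
# positions adjacent to the outermost letters vs the outermost letters
# themselves (the fovea-adjacent pair 3/4 is excluded from the contrast)
.crowded_positions <- c(2L, 5L)
.uncrowded_positions <- c(1L, 6L)

#' Hemifield of a letter position
#'
#' @param position Integer vector of positions in 1..6.
#' @return Character vector, `"left"` for positions 1-3, `"right"` for 4-6.
#' @export
position_hemifield <- function(position) {
  stopifnot(all(position %in% 1:6))
  ifelse(position <= 3L, "left", "right")
}
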