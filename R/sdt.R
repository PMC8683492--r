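# M-alternative forced-choice signal detection for an unbiased observer.
# P(correct | d') is the probability that the signal channel, distributed
# Normal(d', 1), exceeds all M-1 independent Normal(0, 1) noise channels:
#   P = integral over t of phi(t - d') * Phi(t)^(M-1) dt.

#' SDT settings
#'
#' Numerical settings for the proportion-correct / d-prime conversions.
#'
#' @param m_alternatives Number of response alternatives M (default 12).
#' @param quad_tolerance Absolute tolerance of the quadrature.
#' @param invert_tolerance Round-trip tolerance of the inversion, in
#'   proportion-correct units.
#' @return An `sdt_settings` list.
#' @export
sdt_settings <- function(m_alternatives = 12L,
                         quad_tolerance = 1e-10,
                         invert_tolerance = 1e-8) {
  stopifnot(m_alternatives >= 2, quad_tolerance > 0, invert_tolerance > 0)
  structure(
    list(
      m_alternatives = as.integer(m_alternatives),
      quad_tolerance = quad_tolerance,
      invert_tolerance = invert_tolerance
    ),
    class = "sdt_settings"
  )
}

#' Proportion correct from d-prime (M-AFC, unbiased observer)
#'
#' Computes `P(correct)` for an unbiased observer choosing the maximum of
#' one signal channel Normal(d', 1) and M-1 noise channels Normal(0, 1),
#' by deterministic quadrature of `phi(t - dprime) * Phi(t)^(M-1)`. The
#' integrand is truncated to `[min(dprime, 0) - 8.5, max(dprime, 0) + 8.5]`,
#' outside which its mass is below 1e-12.
#'
#' @param dprime Numeric vector of sensitivities (finite; may be negative).
#' @param settings An [sdt_settings()] object.
#' @return Proportion correct in (0, 1), strictly increasing in `dprime`.
#'   At `dprime = 0` this is chance, `1/M`.
#' @examples
#' pc_from_dprime(0)            # 1/12
#' pc_from_dprime(2.33)         # ~0.74
#' @export
pc_from_dprime <- function(dprime, settings = sdt_settings()) {
  if (any(!is.finite(dprime))) {
    stop("dprime must be finite", call. = FALSE)
  }
  m <- settings$m_alternatives
  vapply(dprime, function(d) {
    stats::integrate(
      function(t) stats::dnorm(t - d) * stats::pnorm(t)^(m - 1),
      lower = min(d, 0) - 8.5,
      upper = max(d, 0) + 8.5,
      abs.tol = settings$quad_tolerance
    )$value
  }, numeric(1))
}

#' d-prime from proportion correct (M-AFC, unbiased observer)
#'
#' Numerical inverse of [pc_from_dprime()] by bracketed root finding. The
#' bracket starts at `[-5, 10]` and expands geometrically if the root lies
#' outside; strict monotonicity guarantees uniqueness. Proportions of
#' exactly 0 or 1 are rejected: apply [clamp_proportion()] first.
#'
#' @param pc Numeric vector of proportions correct, strictly inside (0, 1).
#' @param settings An [sdt_settings()] object.
#' @return Numeric vector of d-prime values (negative when `pc < 1/M`).
#' @examples
#' dprime_from_pc(1 / 12)   # 0
#' @export
dprime_from_pc <- function(pc, settings = sdt_settings()) {
  if (any(!is.finite(pc)) || any(pc <= 0) || any(pc >= 1)) {
    stop("pc must lie strictly inside (0, 1); apply clamp_proportion() ",
         "to floor/ceiling cells first", call. = FALSE)
  }
  vapply(pc, function(p) {
    f <- function(d) pc_from_dprime(d, settings) - p
    lo <- -5; hi <- 10
    while (f(lo) > 0) lo <- lo * 2
    while (f(hi) < 0) hi <- hi * 2
    stats::uniroot(f, c(lo, hi),
                   tol = settings$invert_tolerance / 10)$root
  }, numeric(1))
}

#' Floor/ceiling correction for observed proportions
#'
#' Cells at 0% or 100% correct are corrected as if twice as many trials
#' had been run with one discordant outcome: 0 becomes `1/(2n)` and 1
#' becomes `1 - 1/(2n)`. Interior proportions pass through unchanged, so
#' the correction is idempotent.
#'
#' @param pc Numeric vector of observed proportions in \[0, 1\].
#' @param n_trials Trial counts behind each proportion (recycled).
#' @return Corrected proportions, strictly inside (0, 1) whenever
#'   `n_trials >= 1`.
#' @examples
#' clamp_proportion(c(0, 0.5, 1), 30)  # 1/60, 0.5, 59/60
#' @export
clamp_proportion <- function(pc, n_trials) {
  stopifnot(all(pc >= 0 & pc <= 1), all(n_trials >= 1))
  lo <- rep_len(1 / (2 * n_trials), length(pc))
  out <- pc
  out[pc == 0] <- lo[pc == 0]
  out[pc == 1] <- 1 - lo[pc == 1]
  out
}
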