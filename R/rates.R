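#' Convert a per-person-year rate to a one-year transition risk
#'
#' Assumes a constant hazard within the one-year cycle, so a rate
#' \eqn{r} maps to an annual risk \eqn{q = 1 - e^{-r}}.  This is the
#' standard conversion used to fit incidence rates into a Markov model
#' with yearly cycles; it is strictly increasing in \code{rate} and
#' bounded below 1 for any finite rate.
#'
#' @param rate Numeric vector of non-negative per-person-year rates.
#' @return Numeric vector of annual risks in \code{[0, 1)}.
#' @seealso [annual_risk_to_rate()] for the inverse, [apply_smr()] for
#'   hazard-scale mortality adjustment.
#' @examples
#' rate_to_annual_risk(1.5e-4)   # incidence of 1.5 per 10,000
#' rate_to_annual_risk(c(0, 1, 10))
#' @export
rate_to_annual_risk <- function(rate) {
  if (!is.numeric(rate) || anyNA(rate) || any(rate < 0)) {
    stop("`rate` must be non-negative and finite", call. = FALSE)
  }
  -expm1(-rate)
}

#' Convert a one-year transition risk back to a per-person-year rate
#'
#' Inverse of [rate_to_annual_risk()]: \eqn{r = -\ln(1 - q)}.  Needed
#' wherever a probability has to be manipulated on the hazard scale,
#' notably when multiplying background mortality by a standardized
#' mortality ratio.
#'
#' @param q Numeric vector of annual risks in \code{[0, 1)}.
#' @return Numeric vector of non-negative rates.
#' @export
annual_risk_to_rate <- function(q) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0) || any(q >= 1)) {
    stop("`q` must be a probability in [0, 1)", call. = FALSE)
  }
  -log1p(-q)
}

#' Apply a standardized mortality ratio to an annual death probability
#'
#' The SMR multiplies the mortality hazard, not the probability: the
#' background annual risk is converted to a rate, scaled by the SMR,
#' and converted back.  This keeps the adjusted probability inside
#' \code{[0, 1)} for any positive SMR, which naive multiplication of
#' probabilities does not.
#'
#' @param q_background Annual death probability in \code{[0, 1)} from a
#'   general-population life table.
#' @param smr Positive standardized mortality ratio (1 leaves the
#'   probability unchanged).
#' @return Adjusted annual death probability in \code{[0, 1)}.
#' @examples
#' apply_smr(0.01, 2.8)  # schizophrenia excess mortality at SMR 2.8
#' @export
apply_smr <- function(q_background, smr) {
  if (!is.numeric(smr) || anyNA(smr) || any(smr <= 0)) {
    stop("`smr` must be positive", call. = FALSE)
  }
  rate_to_annual_risk(smr * annual_risk_to_rate(q_background))
}
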