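# Generalized alpha-investing substrate: the decision rule, the wealth
# ledger W(t) = W(t-1) - phi_t + R_t * psi_t, the GAI++ payout cap, and the
# FDP-hat estimators that the statistical-perspective algorithms keep below
# alpha.

#' Online decision rule
#'
#' Rejects the current hypothesis iff its p-value is at most the emitted test
#' level; ties reject. Vectorized.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param alpha_t test level(s) in `[0, 1]`.
#' @return integer 0/1 rejection indicator(s).
#' @export
decide <- function(p, alpha_t) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (any(!is.finite(alpha_t)) || any(alpha_t < 0) || any(alpha_t > 1)) {
    stop("test levels must lie in [0, 1]")
  }
  as.integer(p <= alpha_t)
}

#' Wealth update
#'
#' One step of the alpha-wealth ledger: pay the price `phi` for testing, earn
#' the payout `psi` if the hypothesis was rejected. The price may never
#' exceed the available wealth.
#'
#' @param wealth current wealth `W(t-1)` (non-negative).
#' @param phi price paid for the test, `0 <= phi <= wealth`.
#' @param psi payout earned on rejection.
#' @param reject 0/1 rejection indicator.
#' @return the new wealth `W(t)`.
#' @export
update_wealth <- function(wealth, phi, psi, reject) {
  if (phi < 0) stop("price must be non-negative")
  if (phi > wealth + 1e-15) {
    stop(sprintf("price %.6g exceeds available wealth %.6g", phi, wealth))
  }
  wealth - phi + (if (reject) psi else 0)
}

#' GAI++ payout cap
#'
#' The largest payout a GAI++ rule may award for a rejection at price `phi`
#' and level `alpha_t`: \eqn{\psi_t \le \min\{\phi_t + b_t,\;
#' \phi_t/\alpha_t + b_t - 1\}}, where \eqn{b_t = \alpha - w_0 1\{R(t-1)=0\}}.
#' Degenerate cases (the cap going negative at zero price, or `alpha_t = 0`
#' making the second bound infinite) are clamped at 0 and flagged via the
#' `"degenerate"` attribute.
#'
#' @param phi price paid, `phi >= 0`.
#' @param alpha_t test level; if 0, only the first bound applies.
#' @param b_t reward bound \eqn{b_t}.
#' @return the maximum admissible payout (clamped below at 0).
#' @export
gai_pp_payout_cap <- function(phi, alpha_t, b_t) {
  if (phi < 0) stop("price must be non-negative")
  cap <- if (alpha_t > 0) {
    min(phi + b_t, phi / alpha_t + b_t - 1)
  } else {
    phi + b_t
  }
  degenerate <- cap < 0
  structure(max(cap, 0), degenerate = degenerate)
}

#' FDP estimate used by LORD-type rules
#'
#' \eqn{\widehat{\mathrm{FDP}}(t) = \sum_{j \le t} \alpha_j / (R(t) \vee 1)}:
#' the alpha-wealth spent so far over the rejection count, denominator
#' floored at one.
#'
#' @param levels numeric vector of emitted test levels \eqn{\alpha_1..\alpha_t}.
#' @param rejections number of rejections `R(t)`.
#' @return the estimate.
#' @export
fdp_hat_lord <- function(levels, rejections) {
  sum(levels) / max(rejections, 1)
}

#' FDP estimate used by SAFFRON-type rules
#'
#' \eqn{\widehat{\mathrm{FDP}}(t) = \sum_{j \le t} \alpha_j
#' 1\{P_j > \lambda\}/(1-\lambda) \,/\, (R(t) \vee 1)}: only non-candidate
#' tests spend, at an inflated rate \eqn{1/(1-\lambda)}.
#'
#' @param levels emitted test levels.
#' @param candidates logical/0-1 vector, `TRUE` where \eqn{P_j \le \lambda}.
#' @param lambda candidate threshold in (0, 1).
#' @param rejections number of rejections `R(t)`.
#' @return the estimate.
#' @export
fdp_hat_saffron <- function(levels, candidates, lambda, rejections) {
  if (lambda <= 0 || lambda >= 1) stop("`lambda` must be in (0, 1)")
  sum(levels * (1 - as.numeric(candidates))) / (1 - lambda) /
    max(rejections, 1)
}
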