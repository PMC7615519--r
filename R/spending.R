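# Spending sequences: the weight schedules {gamma_t} that online procedures
# use to spread alpha-wealth over future tests. A sequence is non-negative,
# non-increasing and sums to one, either over an infinite horizon or — for
# the bounded variants — over the first M indices after renormalization.

.seq_cache <- new.env(parent = emptyenv())

# unnormalized default-LORD weight u_t = log(t v 2) / (t * exp(sqrt(log t)))
lord_default_u <- function(t) log(pmax(t, 2)) / (t * exp(sqrt(log(t))))

#' Normalization constant of the default LORD sequence
#'
#' Sum of \eqn{u_t = \log(t \vee 2) / (t e^{\sqrt{\log t}})} over
#' \eqn{t \ge 1}. The series converges very slowly, so the sum is computed by
#' direct summation up to `cutoff` plus a closed-form tail: substituting
#' \eqn{u = \sqrt{\log t}} turns the tail integral into an incomplete gamma
#' integral \eqn{\int_U^\infty 2u^3 e^{-u}\,du = 2e^{-U}(U^3+3U^2+6U+6)},
#' to which the first Euler-Maclaurin correction terms are added. The result
#' is cutoff-independent to well below `rtol`.
#'
#' @param cutoff number of terms summed directly (default `1e6`).
#' @param rtol relative tolerance used to cross-check two cutoffs.
#' @return the constant, approximately 12.6451078728718.
#' @export
lord_default_norm_const <- function(cutoff = 1e6, rtol = 1e-10) {
  key <- sprintf("lordnorm_%g", cutoff)
  if (!is.null(.seq_cache[[key]])) return(.seq_cache[[key]])
  total <- function(N) {
    S <- sum(lord_default_u(seq_len(N))[N:1]) # ascending-magnitude summation
    a <- N + 1
    U <- sqrt(log(a))
    f <- lord_default_u(a)
    fp <- f * (1 / (a * log(a)) - 1 / a - 1 / (2 * a * sqrt(log(a))))
    S + 2 * exp(-U) * (U^3 + 3 * U^2 + 6 * U + 6) + f / 2 - fp / 12
  }
  val <- total(cutoff)
  if (abs(val - total(cutoff / 10)) > rtol * val) {
    stop("lord-default normalization did not converge at the given cutoff")
  }
  .seq_cache[[key]] <- val
  val
}

# Hurwitz-style power sum: sum_{j=start}^{inf} (j + offset)^(-s), start chosen
# so that the first term is 1 (i.e. j + offset = 1). Euler-Maclaurin tail.
power_law_norm_const <- function(s, cutoff = 1e5) {
  key <- sprintf("pow_%.12g", s)
  if (!is.null(.seq_cache[[key]])) return(.seq_cache[[key]])
  t <- seq_len(cutoff)
  a <- cutoff + 1
  val <- sum(t^(-s)) + a^(1 - s) / (s - 1) + a^(-s) / 2 - s * a^(-s - 1) / 12
  .seq_cache[[key]] <- val
  val
}

#' Construct a spending sequence
#'
#' @param kind one of `"lord-default"` (\eqn{\gamma_t \propto \log(t \vee 2) /
#'   (t e^{\sqrt{\log t}})}, the default schedule for LORD-type rules),
#'   `"power"` (\eqn{\gamma \propto} index\eqn{{}^{-s}}) or `"uniform"`
#'   (\eqn{1/M} up to the bound, which must be finite).
#' @param s power-law exponent; must exceed 1 when `bound` is infinite
#'   (summability), any positive value is allowed for finite bounds.
#' @param index_from first index of the sequence: 1 for LORD/SAFFRON-style
#'   schedules, 0 for the ADDIS schedule \eqn{\gamma_j \propto (j+1)^{-1.6}},
#'   \eqn{j \ge 0}.
#' @param bound finite horizon M, or `Inf`. Bounded sequences are
#'   *renormalized*: the first M proportional weights are divided by their own
#'   sum (not merely zeroed past the bound), so they sum to exactly 1.
#' @return an object of class `"spending_sequence"`.
#' @examples
#' g <- spending_sequence("power", s = 1.6, bound = 20)
#' sum(seq_weights(g, 20)) # 1
#' @export
spending_sequence <- function(kind = c("lord-default", "power", "uniform"),
                              s = 1.6, index_from = 1L, bound = Inf) {
  kind <- match.arg(kind)
  if (!index_from %in% c(0L, 1L)) stop("`index_from` must be 0 or 1")
  index_from <- as.integer(index_from)
  if (!(is.infinite(bound) || (bound >= 1 && bound == floor(bound)))) {
    stop("`bound` must be a positive integer or Inf")
  }
  if (kind == "uniform" && is.infinite(bound)) {
    stop("a uniform spending sequence requires a finite bound M")
  }
  if (kind == "power") {
    if (is.infinite(bound) && s <= 1) {
      stop("power-law sequences with an infinite horizon require s > 1")
    }
    if (s <= 0) stop("power-law exponent must be positive")
  }
  if (kind != "power" && index_from != 1L) {
    stop("only power-law sequences may be indexed from 0")
  }
  structure(
    list(kind = kind, s = if (kind == "power") s else NULL,
         index_from = index_from, bound = bound),
    class = "spending_sequence"
  )
}

#' @export
print.spending_sequence <- function(x, ...) {
  desc <- switch(x$kind,
    "lord-default" = "lord-default",
    power = sprintf("power-law (index + %d)^-%g from index %d",
                    1L - x$index_from, x$s, x$index_from),
    uniform = "uniform")
  cat(sprintf("<spending_sequence> %s, bound = %s\n", desc,
              if (is.infinite(x$bound)) "Inf" else format(x$bound)))
  invisible(x)
}

# raw proportional weight at sequence index i (vectorized, i on the
# sequence's own index domain, i >= index_from)
seq_u <- function(seq, i) {
  switch(seq$kind,
    "lord-default" = lord_default_u(i),
    power = (i + (1L - seq$index_from))^(-seq$s),
    uniform = rep(1, length(i))
  )
}

seq_norm <- function(seq) {
  if (is.finite(seq$bound)) {
    idx <- seq$index_from + seq_len(seq$bound) - 1L
    sum(seq_u(seq, idx))
  } else {
    switch(seq$kind,
      "lord-default" = lord_default_norm_const(),
      power = power_law_norm_const(seq$s),
      uniform = stop("unreachable")
    )
  }
}

#' Weights of a spending sequence
#'
#' `seq_weights(seq, n)` returns the first `n` normalized weights, starting at
#' the sequence's first index. `seq_weight(seq, t)` returns the weight at
#' index `t` (vectorized); indices past a finite bound give 0.
#'
#' @param seq a [spending_sequence()].
#' @param n number of leading weights.
#' @param t index or indices on the sequence's own domain (from
#'   `seq$index_from`).
#' @return numeric vector of weights in `[0, 1]`.
#' @export
seq_weights <- function(seq, n) {
  seq_weight(seq, seq$index_from + seq_len(n) - 1L)
}

#' @rdname seq_weights
#' @export
seq_weight <- function(seq, t) {
  if (any(t < seq$index_from)) {
    stop(sprintf("sequence index below first index %d", seq$index_from))
  }
  w <- seq_u(seq, t) / seq_norm(seq)
  if (is.finite(seq$bound)) {
    w[t > seq$bound + seq$index_from - 1L] <- 0
  }
  w
}

#' Default LORD spending weights
#'
#' \eqn{\gamma_t \propto \log(t \vee 2)/(t e^{\sqrt{\log t}})}, normalized
#' over indices `1..M` (renormalized truncation) for finite `M`, or over the
#' infinite horizon otherwise.
#'
#' @param t index (vectorized), `t >= 1`.
#' @param M horizon bound, positive integer or `Inf`.
#' @return normalized weight(s).
#' @examples
#' lord_default_gamma(8, M = 20) # ~0.0336
#' @export
lord_default_gamma <- function(t, M = Inf) {
  if (any(t < 1)) stop("`t` must be >= 1")
  seq_weight(spending_sequence("lord-default", bound = M), t)
}

#' Power-law spending weights
#'
#' \eqn{\gamma_t \propto (t + \mathrm{offset})^{-s}}. With `offset = 0` the
#' sequence is indexed from 1 (the SAFFRON default has `s = 1.6`); with
#' `offset = 1` it is indexed from 0 (the ADDIS default, \eqn{(j+1)^{-1.6}}).
#'
#' @param t index (vectorized), on the sequence's domain.
#' @param s exponent; `s > 1` required when `M` is infinite.
#' @param offset 0 or 1.
#' @param M horizon bound, positive integer or `Inf`.
#' @return normalized weight(s).
#' @export
power_law_gamma <- function(t, s = 1.6, offset = 0L, M = Inf) {
  seq_weight(spending_sequence("power", s = s, index_from = 1L - as.integer(offset),
                               bound = M), t)
}

#' Uniform spending weights
#'
#' \eqn{\gamma_t = 1/M} for `t` in `1..M`, 0 past the bound. Requires a
#' finite `M`.
#'
#' @param t index (vectorized), `t >= 1`.
#' @param M finite horizon bound.
#' @return weight(s).
#' @export
uniform_gamma <- function(t, M) {
  if (any(t < 1)) stop("`t` must be >= 1")
  seq_weight(spending_sequence("uniform", bound = M), t)
}

#' Parse a spending-sequence specification string
#'
#' Accepted forms: `"lord-default"`, `"power:1.6"` (indexed from 1),
#' `"power+1:1.6"` (weights \eqn{(j+1)^{-s}} indexed from 0, the ADDIS
#' convention) and `"uniform"`.
#'
#' @param spec specification string.
#' @param bound horizon bound M, positive integer or `Inf`.
#' @return a [spending_sequence()].
#' @export
parse_spending <- function(spec, bound = Inf) {
  if (identical(spec, "lord-default")) {
    return(spending_sequence("lord-default", bound = bound))
  }
  if (identical(spec, "uniform")) {
    return(spending_sequence("uniform", bound = bound))
  }
  m <- regmatches(spec, regexec("^power(\\+1)?:([0-9.]+)$", spec))[[1]]
  if (length(m)) {
    return(spending_sequence("power", s = as.numeric(m[3]),
                             index_from = if (nzchar(m[2])) 0L else 1L,
                             bound = bound))
  }
  stop(sprintf("cannot parse spending-sequence spec '%s'", spec))
}
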