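# Independent, non-incremental reference implementations used as oracles.
# Each one re-evaluates the closed-form level formula from scratch at every
# step (quadratic), with its own candidate/selection bookkeeping, so it
# shares no state machinery with the package's single-pass recursions.

seq2 <- function(a, b) if (a > b) integer(0) else a:b

# independently normalized bounded gamma lookup: g(i) on 1-based indices
oracle_gamma <- function(kind, M, s = 1.6, from = 1L) {
  idx <- seq2(from, from + M - 1L)
  u <- switch(kind,
    lord = log(pmax(idx, 2)) / (idx * exp(sqrt(log(idx)))),
    power = (idx + (1L - from))^(-s),
    uniform = rep(1, M))
  w <- u / sum(u)
  function(i) {
    out <- numeric(length(i))
    ok <- i >= from & i <= from + M - 1L
    out[ok] <- w[i[ok] - from + 1L]
    out
  }
}

oracle_lord <- function(p, alpha, w0, b0, g) {
  T <- length(p)
  lev <- numeric(T + 1)
  for (t in 1:(T + 1)) {
    past <- seq2(1, t - 1)
    tau <- past[p[past] <= lev[past]]
    lev[t] <- w0 * g(t) + b0 * sum(g(t - tau))
  }
  lev
}

oracle_lordpp <- function(p, alpha, w0, g) {
  T <- length(p)
  lev <- numeric(T + 1)
  for (t in 1:(T + 1)) {
    past <- seq2(1, t - 1)
    tau <- past[p[past] <= lev[past]]
    a <- w0 * g(t)
    if (length(tau) >= 1) a <- a + (alpha - w0) * g(t - tau[1])
    if (length(tau) >= 2) a <- a + alpha * sum(g(t - tau[-1]))
    lev[t] <- a
  }
  lev
}

oracle_saffron <- function(p, alpha, w0, lambda, g) {
  T <- length(p)
  lev <- numeric(T + 1)
  for (t in 1:(T + 1)) {
    past <- seq2(1, t - 1)
    tau <- past[p[past] <= lev[past]]
    cand <- p <= lambda
    C0 <- sum(cand[past])
    Cj <- vapply(tau, function(tj) sum(cand[seq2(tj + 1, t - 1)]), numeric(1))
    b <- w0 * g(t - C0)
    if (length(tau) >= 1) b <- b + (alpha - w0) * g(t - tau[1] - Cj[1])
    if (length(tau) >= 2) b <- b + alpha * sum(g(t - tau[-1] - Cj[-1]))
    lev[t] <- min(lambda, (1 - lambda) * b)
  }
  lev
}

oracle_addis <- function(p, alpha, w0, lambda, eta, g0) {
  # g0 takes 0-based indices
  T <- length(p)
  lev <- numeric(T + 1)
  for (t in 1:(T + 1)) {
    past <- seq2(1, t - 1)
    tau <- past[p[past] <= lev[past]]
    sel <- p <= eta
    cand <- p <= lambda # candidates are always selected (lambda < eta)
    St <- sum(sel[past])
    C0 <- sum(cand[past])
    selat <- vapply(tau, function(tj) sum(sel[seq2(1, tj)]), numeric(1))
    Cj <- vapply(tau, function(tj) sum(cand[seq2(tj + 1, t - 1)]), numeric(1))
    b <- w0 * g0(St - C0)
    if (length(tau) >= 1) b <- b + (alpha - w0) * g0(St - selat[1] - Cj[1])
    if (length(tau) >= 2) b <- b + alpha * sum(g0(St - selat[-1] - Cj[-1]))
    lev[t] <- min(lambda, (eta - lambda) * b)
  }
  lev
}

oracle_ai <- function(p, alpha, w0, g) {
  T <- length(p)
  lev <- numeric(T + 1)
  for (t in 1:(T + 1)) {
    past <- seq2(1, t - 1)
    tau <- past[p[past] <= lev[past]]
    cand <- logical(length(p))
    cand[past] <- p[past] <= lev[past] # self-candidacy: candidate iff rejected
    C0 <- sum(cand[past])
    Cj <- vapply(tau, function(tj) sum(cand[seq2(tj + 1, t - 1)]), numeric(1))
    b <- w0 * g(t - C0)
    if (length(tau) >= 1) b <- b + (alpha - w0) * g(t - tau[1] - Cj[1])
    if (length(tau) >= 2) b <- b + alpha * sum(g(t - tau[-1] - Cj[-1]))
    lev[t] <- b / (1 + b)
  }
  lev
}

# brute-force BH: scan every observed p-value as a candidate threshold s and
# take the largest with n * s / |R(s)| <= alpha
oracle_bh <- function(p, alpha) {
  n <- length(p)
  if (!n) return(integer(0))
  ok <- vapply(p, function(s) {
    R <- sum(p <= s)
    R > 0 && n * s / R <= alpha
  }, logical(1))
  if (!any(ok)) return(integer(0))
  sort(which(p <= max(p[ok])))
}

# random streams with a mix of strong signals and uniform noise
rand_stream <- function(n, prop_signal = 0.3) {
  sig <- runif(n) < prop_signal
  p <- runif(n)
  p[sig] <- p[sig]^4
  p
}

stampede_p <- c(0.450, 0.006, 0.022, 0.847, 0.130, 0.001, 0.266)
stampede_ids <- c("B", "C", "E", "D", "F", "G", "H")
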