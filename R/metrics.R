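# Error-rate and power estimators over decision logs with known ground
# truth (simulation). FDP/FDR/mFDR/FDX/FWER and power, each with a
# Monte-Carlo standard error across replicates.

#' Labeled decision log
#'
#' Pairs the rejection indicators of one run with the ground-truth labels of
#' the simulated hypotheses.
#'
#' @param reject 0/1 (or logical) rejection indicators, or a `decision_log`
#'   from [run_stream()] (its `reject` column is used).
#' @param nonnull logical vector, `TRUE` where the hypothesis is non-null.
#' @return an object of class `"labeled_log"`.
#' @export
labeled_log <- function(reject, nonnull) {
  if (inherits(reject, "decision_log")) reject <- reject$reject
  reject <- as.integer(as.logical(reject))
  nonnull <- as.logical(nonnull)
  if (length(reject) != length(nonnull)) {
    stop("`reject` and `nonnull` must have the same length")
  }
  structure(list(reject = reject, nonnull = nonnull), class = "labeled_log")
}

log_counts <- function(log, t = NULL) {
  if (is.null(t)) t <- length(log$reject)
  if (t > length(log$reject)) stop("`t` exceeds the log length")
  idx <- seq_len(t)
  r <- log$reject[idx]
  list(V = sum(r & !log$nonnull[idx]), R = sum(r),
       n1 = sum(log$nonnull[idx]), TP = sum(r & log$nonnull[idx]))
}

#' False discovery proportion of one run
#'
#' \eqn{\mathrm{FDP}(t) = V(t)/(R(t) \vee 1)}.
#'
#' @param log a [labeled_log()].
#' @param t evaluate at time `t` (default: full length).
#' @return the proportion.
#' @export
fdp <- function(log, t = NULL) {
  cc <- log_counts(log, t)
  cc$V / max(cc$R, 1)
}

running_max_fdp <- function(log, t = NULL) {
  if (is.null(t)) t <- length(log$reject)
  r <- log$reject[seq_len(t)]
  V <- cumsum(r & !log$nonnull[seq_len(t)])
  R <- cumsum(r)
  if (!t) return(0)
  max(V / pmax(R, 1))
}

mc_mean_se <- function(x) {
  n <- length(x)
  list(estimate = mean(x),
       se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}

#' Monte-Carlo standard error of a proportion
#'
#' The binomial standard error \eqn{\sqrt{p(1-p)/n}} — e.g. 0.005 for a
#' proportion of 0.5 at \eqn{10^4} replicates.
#'
#' @param p proportion in `[0, 1]`.
#' @param n number of replicates.
#' @return the standard error.
#' @export
mc_se_proportion <- function(p, n) sqrt(p * (1 - p) / n)

#' Monte-Carlo error-rate and power estimators
#'
#' Each estimator takes a list of [labeled_log()] replicates and returns a
#' list with `estimate`, `se` (Monte-Carlo standard error) and `n`.
#'
#' \describe{
#'   \item{`fdr_estimate()`}{mean of per-replicate FDPs; SE is the sample
#'     SD over \eqn{\sqrt{n}}.}
#'   \item{`mfdr_estimate()`}{marginal FDR \eqn{E[V]/E[R \vee 1]} — the
#'     ratio of means, not the mean of ratios; SE by the delta method.}
#'   \item{`fdx_estimate()`}{fraction of replicates whose running maximum
#'     FDP reaches `epsilon`; binomial SE.}
#'   \item{`fwer_estimate()`}{fraction of replicates with at least one false
#'     rejection; binomial SE.}
#'   \item{`power_estimate()`}{mean per-replicate fraction of non-null
#'     hypotheses rejected (denominator floored at 1, so a replicate without
#'     non-nulls contributes 0).}
#' }
#'
#' @param logs list of [labeled_log()] objects.
#' @param t evaluate at time `t` (default: full length).
#' @param epsilon FDX exceedance threshold.
#' @return list with `estimate`, `se`, `n`.
#' @name metrics
NULL

as_log_list <- function(logs) {
  if (inherits(logs, "labeled_log")) logs <- list(logs)
  if (!length(logs) || !all(vapply(logs, inherits, logical(1), "labeled_log"))) {
    stop("`logs` must be a non-empty list of labeled_log objects")
  }
  logs
}

#' @rdname metrics
#' @export
fdr_estimate <- function(logs, t = NULL) {
  logs <- as_log_list(logs)
  mc_mean_se(vapply(logs, fdp, numeric(1), t = t))
}

#' @rdname metrics
#' @export
mfdr_estimate <- function(logs, t = NULL) {
  logs <- as_log_list(logs)
  V <- vapply(logs, function(l) log_counts(l, t)$V, numeric(1))
  Rf <- vapply(logs, function(l) max(log_counts(l, t)$R, 1), numeric(1))
  n <- length(logs)
  est <- mean(V) / mean(Rf)
  se <- if (n > 1) {
    # delta method for a ratio of means
    mv <- mean(V); mr <- mean(Rf)
    vv <- stats::var(V) / n; vr <- stats::var(Rf) / n
    cvr <- stats::cov(V, Rf) / n
    sqrt(max(vv / mr^2 + mv^2 * vr / mr^4 - 2 * mv * cvr / mr^3, 0))
  } else NA_real_
  list(estimate = est, se = se, n = n)
}

#' @rdname metrics
#' @export
fdx_estimate <- function(logs, epsilon, t = NULL) {
  logs <- as_log_list(logs)
  hit <- vapply(logs, function(l) running_max_fdp(l, t) >= epsilon, logical(1))
  p <- mean(hit)
  list(estimate = p, se = mc_se_proportion(p, length(logs)), n = length(logs))
}

#' @rdname metrics
#' @export
fwer_estimate <- function(logs, t = NULL) {
  logs <- as_log_list(logs)
  hit <- vapply(logs, function(l) log_counts(l, t)$V >= 1, logical(1))
  p <- mean(hit)
  list(estimate = p, se = mc_se_proportion(p, length(logs)), n = length(logs))
}

#' @rdname metrics
#' @export
power_estimate <- function(logs, t = NULL) {
  logs <- as_log_list(logs)
  pw <- vapply(logs, function(l) {
    cc <- log_counts(l, t)
    cc$TP / max(cc$n1, 1)
  }, numeric(1))
  mc_mean_se(pw)
}

#' Full metrics report across replicates
#'
#' @param logs list of [labeled_log()] objects.
#' @param epsilon FDX threshold (default 0.1).
#' @param t evaluate at time `t`.
#' @return a data frame with one row per metric (`fdr`, `mfdr`, `fdx`,
#'   `fwer`, `power`), columns `estimate` and `se`.
#' @export
metrics_report <- function(logs, epsilon = 0.1, t = NULL) {
  ests <- list(fdr = fdr_estimate(logs, t),
               mfdr = mfdr_estimate(logs, t),
               fdx = fdx_estimate(logs, epsilon, t),
               fwer = fwer_estimate(logs, t),
               power = power_estimate(logs, t))
  data.frame(metric = names(ests),
             estimate = vapply(ests, `[[`, numeric(1), "estimate"),
             se = vapply(ests, `[[`, numeric(1), "se"),
             row.names = NULL)
}
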