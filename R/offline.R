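# Offline comparators: the Benjamini-Hochberg step-up procedure and
# uncorrected (fixed-level) testing, each returning a rejection set.

new_rejection_set <- function(indices, threshold, pvals) {
  structure(list(indices = indices, threshold = threshold,
                 n = length(pvals)),
            class = "rejection_set")
}

#' @export
print.rejection_set <- function(x, ...) {
  cat(sprintf("<rejection_set> %d of %d rejected (threshold %.6g)\n",
              length(x$indices), x$n, x$threshold))
  invisible(x)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Rejects the hypotheses whose p-values fall at or below
#' \eqn{\hat{s} = \max\{s : n\,s/|R(s)| \le \alpha\}}, where \eqn{R(s)} is
#' the set of p-values at most `s` — equivalently, the classical step-up scan
#' from the largest index over the sorted p-values. Ties are handled by the
#' step-up scan itself; no randomization.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha target FDR level.
#' @return a `rejection_set` with the rejected `indices` (positions in
#'   `pvals`) and the rejection `threshold` used (0 when nothing is
#'   rejected).
#' @examples
#' bh_procedure(c(0.450, 0.006, 0.022, 0.847, 0.130, 0.001, 0.266), 0.05)
#' @export
bh_procedure <- function(pvals, alpha) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(pvals)
  if (n == 0) return(new_rejection_set(integer(0), 0, pvals))
  o <- order(pvals)
  ps <- pvals[o]
  k <- which(ps <= alpha * seq_len(n) / n)
  if (!length(k)) return(new_rejection_set(integer(0), 0, pvals))
  thr <- ps[max(k)]
  new_rejection_set(sort(o[seq_len(max(k))]), thr, pvals)
}

#' Uncorrected fixed-level testing (offline view)
#'
#' @param pvals numeric vector of p-values.
#' @param alpha fixed level; every p-value at most `alpha` is rejected.
#' @return a `rejection_set`.
#' @export
uncorrected_rejections <- function(pvals, alpha) {
  new_rejection_set(which(pvals <= alpha), alpha, pvals)
}
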