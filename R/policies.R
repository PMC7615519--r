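# Online testing policies. Each constructor returns a policy object holding
# the target level alpha, its hyperparameters and a spending sequence;
# `compute_levels()` runs the per-step recursion over a p-value stream and
# `run_stream()` wraps the result into an auditable decision log with the
# generalized alpha-investing wealth ledger.

new_policy <- function(name, ..., class) {
  fields <- list(...)
  if (!is.null(fields$alpha) && (fields$alpha <= 0 || fields$alpha >= 1)) {
    stop("`alpha` must lie in (0, 1)")
  }
  structure(c(list(name = name), fields),
            class = c(class, "alphastream_policy"))
}

#' @export
print.alphastream_policy <- function(x, ...) {
  pars <- x[setdiff(names(x), c("name", "gamma"))]
  pars <- pars[!vapply(pars, is.null, logical(1))]
  cat(sprintf("<policy> %s (%s)\n", x$name,
              paste(names(pars), unlist(pars), sep = " = ", collapse = ", ")))
  if (!is.null(x$gamma)) print(x$gamma)
  invisible(x)
}

#' Online testing policies
#'
#' Constructors for the level-emitting policies understood by
#' [run_stream()]. All take the target error level `alpha` and, where
#' relevant, a [spending_sequence()] `gamma` and a finite horizon `bound`
#' (passing `bound` with `gamma = NULL` selects the policy's default
#' sequence, renormalized over the first `bound` indices).
#'
#' \describe{
#'   \item{`uncorrected()`}{tests every hypothesis at level `alpha`; no error
#'     rate control. Comparator only.}
#'   \item{`alpha_spending()`}{Bonferroni-type online FWER control,
#'     \eqn{\alpha_t = \alpha\gamma_t}. Default sequence: `lord-default`
#'     (use a `"uniform"` sequence for the classical \eqn{\alpha/M} bound).}
#'   \item{`online_sidak()`}{online Sidak FWER control,
#'     \eqn{\alpha_t = 1 - (1-\alpha)^{\gamma_t}}; pointwise at least as
#'     large as alpha-spending on the same sequence.}
#'   \item{`lord()`}{the original LORD rule: \eqn{\alpha_t = w_0\gamma_t +
#'     b_0\sum_{j:\tau_j < t}\gamma_{t-\tau_j}}, requiring
#'     \eqn{w_0 + b_0 \le \alpha}.}
#'   \item{`lordpp()`}{LORD++: awards \eqn{\alpha - w_0} for the first
#'     rejection and \eqn{\alpha} for each one after. Default
#'     `w0 = alpha/10`, `lord-default` sequence.}
#'   \item{`saffron()`}{adaptive rule; p-values above the candidate
#'     threshold `lambda` never spend wealth, and emitted levels are capped
#'     at `lambda`. Default `w0 = alpha/2`, `lambda = 0.5`,
#'     \eqn{\gamma_t \propto t^{-1.6}}.}
#'   \item{`addis()`}{adaptive rule that additionally *discards* p-values
#'     above `eta` (they leave all future levels unchanged). Requires
#'     `lambda < eta`. Default `w0 = alpha/2`, `lambda = 0.25`, `eta = 0.5`,
#'     \eqn{\gamma_j \propto (j+1)^{-1.6}} indexed from 0.}
#'   \item{`alpha_investing()`}{monotone alpha-investing: the SAFFRON
#'     recursion with per-step self-candidacy (\eqn{C_j = 1\{P_j \le
#'     \alpha_j\}}), so \eqn{\alpha_t = b_t/(1+b_t)} where \eqn{b_t} is the
#'     allocated wealth, matching the classical choice \eqn{\alpha_t =
#'     \phi_t/(1+\phi_t)}.}
#' }
#'
#' @param alpha target error level in (0, 1).
#' @param w0 initial wealth; `0 <= w0 <= alpha` (and `w0 + b0 <= alpha` for
#'   `lord()`).
#' @param b0 payout per rejection for the original LORD rule.
#' @param lambda candidate threshold in (0, 1).
#' @param eta discarding threshold in (0, 1], `eta > lambda` (`eta = 1`
#'   disables discarding, recovering SAFFRON).
#' @param gamma a [spending_sequence()], or `NULL` for the policy default.
#' @param bound finite horizon M for bounded variants, or `Inf`.
#' @return a policy object for [run_stream()] / [compute_levels()].
#' @examples
#' run_stream(c(0.01, 0.4, 0.001), saffron(alpha = 0.05))
#' @name policies
NULL

default_gamma <- function(gamma, kind, bound, index_from = 1L, s = 1.6) {
  if (is.null(gamma)) {
    gamma <- spending_sequence(kind, s = s, index_from = index_from,
                               bound = bound)
  }
  if (!inherits(gamma, "spending_sequence")) {
    stop("`gamma` must be a spending_sequence (see parse_spending())")
  }
  gamma
}

#' @rdname policies
#' @export
uncorrected <- function(alpha = 0.05) {
  new_policy("uncorrected", alpha = alpha, class = "uncorrected_policy")
}

#' @rdname policies
#' @export
alpha_spending <- function(alpha = 0.05, gamma = NULL, bound = Inf) {
  gamma <- default_gamma(gamma, "lord-default", bound)
  new_policy("alpha-spending", alpha = alpha, gamma = gamma,
             class = "spending_policy")
}

#' @rdname policies
#' @export
online_sidak <- function(alpha = 0.05, gamma = NULL, bound = Inf) {
  gamma <- default_gamma(gamma, "lord-default", bound)
  new_policy("sidak", alpha = alpha, gamma = gamma, class = "sidak_policy")
}

#' @rdname policies
#' @export
lord <- function(alpha = 0.05, w0 = alpha / 2, b0 = alpha - w0,
                 gamma = NULL, bound = Inf) {
  if (w0 < 0 || b0 < 0) stop("`w0` and `b0` must be non-negative")
  if (w0 + b0 > alpha + 1e-12) stop("LORD requires w0 + b0 <= alpha")
  gamma <- default_gamma(gamma, "lord-default", bound)
  new_policy("lord", alpha = alpha, w0 = w0, b0 = b0, gamma = gamma,
             class = "lord_policy")
}

#' @rdname policies
#' @export
lordpp <- function(alpha = 0.05, w0 = alpha / 10, gamma = NULL, bound = Inf) {
  if (w0 < 0 || w0 > alpha) stop("LORD++ requires 0 <= w0 <= alpha")
  gamma <- default_gamma(gamma, "lord-default", bound)
  new_policy("lordpp", alpha = alpha, w0 = w0, gamma = gamma,
             class = "lordpp_policy")
}

#' @rdname policies
#' @export
saffron <- function(alpha = 0.05, w0 = alpha / 2, lambda = 0.5,
                    gamma = NULL, bound = Inf) {
  if (w0 < 0 || w0 > alpha) stop("SAFFRON requires 0 <= w0 <= alpha")
  if (lambda <= 0 || lambda >= 1) stop("`lambda` must be in (0, 1)")
  gamma <- default_gamma(gamma, "power", bound)
  new_policy("saffron", alpha = alpha, w0 = w0, lambda = lambda,
             gamma = gamma, class = "saffron_policy")
}

#' @rdname policies
#' @export
addis <- function(alpha = 0.05, w0 = alpha / 2, lambda = 0.25, eta = 0.5,
                  gamma = NULL, bound = Inf) {
  if (w0 < 0 || w0 > alpha) stop("ADDIS requires 0 <= w0 <= alpha")
  if (lambda <= 0 || lambda >= 1 || eta <= 0 || eta > 1) {
    stop("`lambda` must be in (0, 1) and `eta` in (0, 1]")
  }
  if (lambda >= eta) stop("ADDIS requires lambda < eta")
  gamma <- default_gamma(gamma, "power", bound, index_from = 0L)
  new_policy("addis", alpha = alpha, w0 = w0, lambda = lambda, eta = eta,
             gamma = gamma, class = "addis_policy")
}

#' @rdname policies
#' @export
alpha_investing <- function(alpha = 0.05, w0 = alpha / 2, gamma = NULL,
                            bound = Inf) {
  if (w0 < 0 || w0 > alpha) stop("alpha-investing requires 0 <= w0 <= alpha")
  gamma <- default_gamma(gamma, "power", bound)
  new_policy("alpha-investing", alpha = alpha, w0 = w0, gamma = gamma,
             class = "ai_policy")
}

# materialize gamma as a flat lookup vector covering every index a length-T
# run can touch (T + 1 leading weights)
gamma_lookup <- function(policy, T) {
  seq_weights(policy$gamma, T + 1L)
}

#' Run a policy over a p-value stream
#'
#' `compute_levels()` returns the raw per-step quantities; most users want
#' [run_stream()], which adds ids and the wealth ledger.
#'
#' @param policy a policy object (see [policies]).
#' @param p numeric vector of p-values in `[0, 1]`, in arrival order.
#' @return a list with `levels` (one per hypothesis), `next_level` (the level
#'   a further hypothesis would receive), `reject`, and — per policy —
#'   `candidate`/`selected` indicators and the ledger vectors `phi`, `psi`,
#'   `wealth` (wealth after each step, starting from `wealth0`).
#' @export
compute_levels <- function(policy, p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad)) {
    stop(sprintf("invalid p-value at index %d", bad[1]))
  }
  UseMethod("compute_levels")
}

#' @export
compute_levels.default <- function(policy, p) {
  stop("unknown policy class")
}

finish_run <- function(policy, p, levels_full, reject, phi, psi, wealth0,
                       candidate = NULL, selected = NULL) {
  T <- length(p)
  wealth <- wealth0 - cumsum(phi) + cumsum(reject * psi)
  list(levels = levels_full[seq_len(T)],
       next_level = levels_full[T + 1L],
       reject = as.integer(reject),
       candidate = candidate, selected = selected,
       phi = phi, psi = psi, wealth0 = wealth0, wealth = wealth)
}

#' @export
compute_levels.uncorrected_policy <- function(policy, p) {
  T <- length(p)
  lev <- rep(policy$alpha, T + 1L)
  finish_run(policy, p, lev, as.integer(p <= policy$alpha),
             phi = rep(0, T), psi = rep(0, T), wealth0 = policy$alpha)
}

#' @export
compute_levels.spending_policy <- function(policy, p) {
  T <- length(p)
  g <- gamma_lookup(policy, T)
  lev <- policy$alpha * g
  finish_run(policy, p, lev, as.integer(p <= lev[seq_len(T)]),
             phi = lev[seq_len(T)], psi = rep(0, T), wealth0 = policy$alpha)
}

#' @export
compute_levels.sidak_policy <- function(policy, p) {
  T <- length(p)
  g <- gamma_lookup(policy, T)
  lev <- 1 - (1 - policy$alpha)^g
  # the Sidak budget spends the gamma_t share of the log-scale budget; the
  # ledger records the nominal linear-scale spend alpha * gamma_t
  finish_run(policy, p, lev, as.integer(p <= lev[seq_len(T)]),
             phi = policy$alpha * g[seq_len(T)], psi = rep(0, T),
             wealth0 = policy$alpha)
}

#' @export
compute_levels.lord_policy <- function(policy, p) {
  T <- length(p)
  r <- run_lord_cpp(p, gamma_lookup(policy, T), policy$alpha, policy$w0,
                    policy$b0)
  finish_run(policy, p, r$levels, r$reject,
             phi = r$levels[seq_len(T)], psi = rep(policy$b0, T),
             wealth0 = policy$w0)
}

first_rejection_payout <- function(reject, alpha, w0, scale = 1) {
  # payout b_t = alpha - w0 * 1{no rejection before or at t ... }: the reward
  # for the first rejection is alpha - w0, then alpha; `scale` applies the
  # SAFFRON (1 - lambda) or ADDIS (eta - lambda) factor
  first <- cumsum(reject) == 1 & reject == 1
  scale * ifelse(first, alpha - w0, alpha)
}

#' @export
compute_levels.lordpp_policy <- function(policy, p) {
  T <- length(p)
  r <- run_lordpp_cpp(p, gamma_lookup(policy, T), policy$alpha, policy$w0)
  finish_run(policy, p, r$levels, r$reject,
             phi = r$levels[seq_len(T)],
             psi = first_rejection_payout(r$reject, policy$alpha, policy$w0),
             wealth0 = policy$w0)
}

#' @export
compute_levels.saffron_policy <- function(policy, p) {
  T <- length(p)
  r <- run_saffron_cpp(p, gamma_lookup(policy, T), policy$alpha, policy$w0,
                       policy$lambda)
  lam <- policy$lambda
  finish_run(policy, p, r$levels, r$reject,
             phi = (1 - r$candidate) * r$levels[seq_len(T)],
             psi = first_rejection_payout(r$reject, policy$alpha, policy$w0,
                                          scale = 1 - lam),
             wealth0 = (1 - lam) * policy$w0, candidate = r$candidate)
}

#' @export
compute_levels.addis_policy <- function(policy, p) {
  T <- length(p)
  r <- run_addis_cpp(p, gamma_lookup(policy, T), policy$alpha, policy$w0,
                     policy$lambda, policy$eta)
  sc <- policy$eta - policy$lambda
  finish_run(policy, p, r$levels, r$reject,
             phi = r$selected * (1 - r$candidate) * r$levels[seq_len(T)],
             psi = first_rejection_payout(r$reject, policy$alpha, policy$w0,
                                          scale = sc),
             wealth0 = sc * policy$w0,
             candidate = r$candidate, selected = r$selected)
}

#' @export
compute_levels.ai_policy <- function(policy, p) {
  T <- length(p)
  r <- run_ai_cpp(p, gamma_lookup(policy, T), policy$alpha, policy$w0)
  lev <- r$levels[seq_len(T)]
  finish_run(policy, p, r$levels, r$reject,
             phi = (1 - r$candidate) * lev / (1 - lev),
             psi = first_rejection_payout(r$reject, policy$alpha, policy$w0),
             wealth0 = policy$w0, candidate = r$candidate)
}

#' @rdname compute_levels
#' @param ids optional character vector of hypothesis identifiers.
#' @param batch optional batch labels, carried through for provenance only.
#' @return `run_stream()` returns a `decision_log`: a data frame with columns
#'   `index`, `id`, `pval`, `alpha`, `reject`, `wealth` and attributes
#'   `next_level` (level for a further hypothesis), `policy`, and the ledger
#'   vectors.
#' @export
run_stream <- function(p, policy, ids = NULL, batch = NULL) {
  if (!inherits(policy, "alphastream_policy")) stop("`policy` is not a policy")
  T <- length(p)
  if (is.null(ids)) ids <- if (T) as.character(seq_len(T)) else character(0)
  if (length(ids) != T) stop("`ids` must match the stream length")
  r <- compute_levels(policy, p)
  log <- data.frame(index = seq_len(T), id = ids, pval = as.numeric(p),
                    alpha = r$levels, reject = r$reject, wealth = r$wealth,
                    stringsAsFactors = FALSE)
  if (!is.null(batch)) {
    if (length(batch) != T) stop("`batch` must match the stream length")
    log$batch <- as.character(batch)
  }
  structure(log, next_level = r$next_level, policy = policy,
            candidate = r$candidate, selected = r$selected,
            phi = r$phi, psi = r$psi, wealth0 = r$wealth0,
            class = c("decision_log", "data.frame"))
}

#' Level for the next hypothesis after a logged run
#'
#' @param log a `decision_log` from [run_stream()].
#' @return the test level that would apply to hypothesis `T + 1`.
#' @export
next_level <- function(log) attr(log, "next_level")

#' Rejected hypothesis ids of a logged run
#'
#' @param log a `decision_log` from [run_stream()].
#' @return character vector of ids with `reject == 1`.
#' @export
rejected_ids <- function(log) log$id[log$reject == 1]

#' @export
print.decision_log <- function(x, ...) {
  pol <- attr(x, "policy")
  cat(sprintf("Decision log: %d hypotheses, %d rejection(s) [%s, alpha = %g]\n",
              nrow(x), sum(x$reject), pol$name, pol$alpha))
  print.data.frame(x, digits = 4)
  cat(sprintf("next-hypothesis level: %.6g (rounded: %.4f)\n",
              next_level(x), round(next_level(x), 4)))
  invisible(x)
}
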