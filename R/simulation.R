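# Gaussian simulation testbed: streams of one-sided p-values
# P_t = Phi(-Z_t), Z_t ~ N(mu_t, 1), where mu_t is drawn from a two-group
# mixture — a null law F0 (point mass at 0, or a Gaussian centered below 0
# giving conservative nulls) with probability 1 - pi1, and an alternative
# law F1 = N(3, 1) with probability pi1.

#' Simulation configuration
#'
#' @param T stream length (hypotheses per replicate).
#' @param pi1 probability a hypothesis is non-null, in `[0, 1]`.
#' @param null null-mean law: `"gauss"` for \eqn{N}(`null_mean`,
#'   `null_sd`\eqn{^2}) or `"point"` for a point mass at 0 (exact-uniform
#'   nulls).
#' @param null_mean,null_sd parameters of the Gaussian null-mean law. The
#'   default `N(-0.5, sd = 0.1)` puts essentially all null means below zero,
#'   the conservative-nulls regime. (`null_sd = sqrt(0.1)` gives the
#'   variance-0.1 reading of the same law.)
#' @param alt_mean,alt_sd parameters of the alternative-mean law, default
#'   `N(3, 1)`.
#' @param reps number of Monte-Carlo replicates.
#' @param seed master seed; replicate `r` gets an independent substream seed
#'   derived from it, so any single replicate is reproducible in isolation.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(T = 1000L, pi1 = 0.1, null = c("gauss", "point"),
                       null_mean = -0.5, null_sd = 0.1,
                       alt_mean = 3, alt_sd = 1, reps = 2000L, seed = 1L) {
  null <- match.arg(null)
  if (pi1 < 0 || pi1 > 1) stop("`pi1` must lie in [0, 1]")
  if (T < 1) stop("`T` must be >= 1")
  if (null_sd < 0 || alt_sd < 0) stop("standard deviations must be >= 0")
  structure(list(T = as.integer(T), pi1 = pi1, null = null,
                 null_mean = null_mean, null_sd = null_sd,
                 alt_mean = alt_mean, alt_sd = alt_sd,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "sim_config")
}

# independent substream seeds derived from the master seed
replicate_seeds <- function(config, n = config$reps) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max, n)
}

#' Generate one labeled p-value stream
#'
#' @param config a [sim_config()].
#' @param seed seed for this stream (bit-reproducible given the seed).
#' @return a list with `p` (p-values in (0, 1)), `nonnull` (logical truth
#'   labels) and `mu` (the drawn means), class `"sim_stream"`.
#' @export
generate_stream <- function(config, seed) {
  set.seed(seed)
  T <- config$T
  nonnull <- runif(T) < config$pi1
  mu <- numeric(T)
  n1 <- sum(nonnull)
  if (n1) mu[nonnull] <- rnorm(n1, config$alt_mean, config$alt_sd)
  n0 <- T - n1
  if (n0) {
    mu[!nonnull] <- if (config$null == "point") 0 else
      rnorm(n0, config$null_mean, config$null_sd)
  }
  z <- rnorm(T, mean = mu, sd = 1)
  structure(list(p = pnorm(-z), nonnull = nonnull, mu = mu),
            class = "sim_stream")
}

# map an algorithm name to its default policy at level alpha
policy_by_name <- function(name, alpha = 0.05, bound = Inf) {
  switch(name,
    "uncorrected" = uncorrected(alpha),
    "alpha-spending" = alpha_spending(alpha, bound = bound),
    "sidak" = online_sidak(alpha, bound = bound),
    "lord" = lord(alpha, bound = bound),
    "lordpp" = lordpp(alpha, bound = bound),
    "saffron" = saffron(alpha, bound = bound),
    "addis" = addis(alpha, bound = bound),
    "ai" = alpha_investing(alpha, bound = bound),
    stop(sprintf("unknown algorithm '%s'", name))
  )
}

#' Run a simulation experiment over a grid
#'
#' For every combination of `pi1` and algorithm, generates `config$reps`
#' labeled streams (shared across algorithms within a replicate, so
#' algorithm contrasts are paired) and estimates power, FDR and mFDR with
#' Monte-Carlo standard errors.
#'
#' @param config a [sim_config()]; its `pi1` is overridden by the `pi1`
#'   grid argument.
#' @param algorithms character vector of algorithm names (see
#'   [run_stream()] policies): any of `"uncorrected"`, `"alpha-spending"`,
#'   `"sidak"`, `"lord"`, `"lordpp"`, `"saffron"`, `"addis"`, `"ai"`.
#' @param pi1 grid of non-null probabilities (default: the single value in
#'   `config`).
#' @param alpha target level passed to every policy.
#' @return a data frame with columns `pi1`, `algorithm`, `power`,
#'   `power_se`, `fdr`, `fdr_se`, `mfdr`, `reps`.
#' @export
run_experiment <- function(config, algorithms = c("lordpp", "saffron", "addis",
                                                  "alpha-spending"),
                           pi1 = config$pi1, alpha = 0.05) {
  policies <- lapply(algorithms, policy_by_name, alpha = alpha)
  names(policies) <- algorithms
  reps <- config$reps
  out <- list()
  for (pp in pi1) {
    cfg <- config
    cfg$pi1 <- pp
    # one seed block per pi1 so cells are independent across the grid
    seeds <- replicate_seeds(sim_config(seed = config$seed + match(pp, pi1),
                                        reps = reps))
    fdps <- matrix(0, reps, length(policies))
    pows <- matrix(0, reps, length(policies))
    Vs <- matrix(0, reps, length(policies))
    Rs <- matrix(0, reps, length(policies))
    for (r in seq_len(reps)) {
      s <- generate_stream(cfg, seeds[r])
      for (k in seq_along(policies)) {
        res <- compute_levels(policies[[k]], s$p)
        ll <- labeled_log(res$reject, s$nonnull)
        cc <- log_counts(ll)
        fdps[r, k] <- cc$V / max(cc$R, 1)
        pows[r, k] <- cc$TP / max(cc$n1, 1)
        Vs[r, k] <- cc$V
        Rs[r, k] <- max(cc$R, 1)
      }
    }
    for (k in seq_along(policies)) {
      out[[length(out) + 1L]] <- data.frame(
        pi1 = pp, algorithm = names(policies)[k],
        power = mean(pows[, k]), power_se = sd(pows[, k]) / sqrt(reps),
        fdr = mean(fdps[, k]), fdr_se = sd(fdps[, k]) / sqrt(reps),
        mfdr = mean(Vs[, k]) / mean(Rs[, k]), reps = reps,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
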