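# Error-rate and power estimators against brute-force counting oracles.

rand_labeled <- function(n) {
  labeled_log(reject = runif(n) < 0.3, nonnull = runif(n) < 0.4)
}

test_that("fdp floors the denominator and matches exhaustive counting", {
  expect_equal(fdp(labeled_log(rep(0, 5), rep(FALSE, 5))), 0) # V=0, R=0
  expect_equal(fdp(labeled_log(c(1, 1, 1, 1), c(FALSE, TRUE, TRUE, TRUE))),
               0.25)
  set.seed(301)
  for (i in 1:20) {
    l <- rand_labeled(50)
    t <- sample(50, 1)
    V <- sum(l$reject[1:t] == 1 & !l$nonnull[1:t])
    R <- sum(l$reject[1:t])
    expect_equal(fdp(l, t), V / max(R, 1))
  }
  expect_error(fdp(rand_labeled(5), t = 9), "exceeds")
})

test_that("the proportion SE is exact: 0.005 at p = 0.5 and 1e4 replicates", {
  expect_identical(mc_se_proportion(0.5, 1e4), 0.005)
})

test_that("FDR estimate is the mean FDP with sd/sqrt(n) standard error", {
  set.seed(302)
  logs <- lapply(1:40, function(i) rand_labeled(30))
  est <- fdr_estimate(logs)
  fdps <- vapply(logs, fdp, numeric(1))
  expect_equal(est$estimate, mean(fdps))
  expect_equal(est$se, sd(fdps) / sqrt(40))
  # single null hypothesis under uncorrected testing is Bernoulli(alpha)
  set.seed(303)
  one <- lapply(1:4000, function(i) {
    labeled_log(runif(1) <= 0.05, FALSE)
  })
  e1 <- fdr_estimate(one)
  expect_lt(abs(e1$estimate - 0.05), 3 * mc_se_proportion(0.05, 4000))
})

test_that("mFDR is the ratio of means, not the mean of ratios", {
  set.seed(304)
  logs <- lapply(1:30, function(i) rand_labeled(25))
  V <- vapply(logs, function(l) sum(l$reject & !l$nonnull), numeric(1))
  R <- vapply(logs, function(l) max(sum(l$reject), 1), numeric(1))
  expect_equal(mfdr_estimate(logs)$estimate, mean(V) / mean(R))
  # single replicate: V / (R v 1)
  l <- rand_labeled(25)
  expect_equal(mfdr_estimate(list(l))$estimate, fdp(l))
  # no rejections anywhere: 0
  none <- lapply(1:5, function(i) labeled_log(rep(0, 10), rep(FALSE, 10)))
  expect_equal(mfdr_estimate(none)$estimate, 0)
  # mFDR and FDR agree when every replicate has the same R > 0
  same <- lapply(1:10, function(i) {
    labeled_log(c(1, 1, rep(0, 8)), c(runif(2) < 0.5, rep(FALSE, 8)))
  })
  expect_equal(mfdr_estimate(same)$estimate, fdr_estimate(same)$estimate)
})

test_that("FDX matches a per-step scan and is monotone in epsilon", {
  set.seed(305)
  logs <- lapply(1:25, function(i) rand_labeled(40))
  brute <- function(l, eps) {
    V <- cumsum(l$reject & !l$nonnull); R <- cumsum(l$reject)
    any(V / pmax(R, 1) >= eps)
  }
  for (eps in c(0.1, 0.3, 0.7)) {
    expect_equal(fdx_estimate(logs, eps)$estimate,
                 mean(vapply(logs, brute, logical(1), eps = eps)))
  }
  # epsilon = 0 with at least one rejection everywhere: always exceeded
  rej <- lapply(1:5, function(i) labeled_log(rep(1, 5), rep(TRUE, 5)))
  expect_equal(fdx_estimate(rej, 0)$estimate, 1)
  expect_equal(fdx_estimate(logs, 1.5)$estimate, 0)
  curve <- vapply(seq(0, 1, 0.1), function(e) fdx_estimate(logs, e)$estimate,
                  numeric(1))
  expect_true(all(diff(curve) <= 0))
})

test_that("FWER is the fraction of replicates with any false rejection", {
  clean <- lapply(1:5, function(i) labeled_log(rep(1, 5), rep(TRUE, 5)))
  expect_equal(fwer_estimate(clean)$estimate, 0)
  dirty <- lapply(1:5, function(i) labeled_log(c(1, rep(0, 4)),
                                               c(FALSE, rep(TRUE, 4))))
  expect_equal(fwer_estimate(dirty)$estimate, 1)
  set.seed(306)
  logs <- lapply(1:25, function(i) rand_labeled(40))
  expect_equal(fwer_estimate(logs)$estimate,
               mean(vapply(logs, function(l) any(l$reject & !l$nonnull),
                           logical(1))))
})

test_that("power is the mean fraction of non-nulls rejected", {
  # no non-nulls: contributes 0 by the floor convention
  expect_equal(power_estimate(list(labeled_log(rep(1, 5),
                                               rep(FALSE, 5))))$estimate, 0)
  expect_equal(power_estimate(list(labeled_log(rep(1, 5),
                                               rep(TRUE, 5))))$estimate, 1)
  set.seed(307)
  logs <- lapply(1:25, function(i) rand_labeled(40))
  brute <- vapply(logs, function(l) {
    n1 <- sum(l$nonnull)
    sum(l$reject & l$nonnull) / max(n1, 1)
  }, numeric(1))
  expect_equal(power_estimate(logs)$estimate, mean(brute))
})

test_that("metrics_report assembles all five estimates", {
  set.seed(308)
  logs <- lapply(1:10, function(i) rand_labeled(20))
  rep_ <- metrics_report(logs, epsilon = 0.2)
  expect_identical(rep_$metric, c("fdr", "mfdr", "fdx", "fwer", "power"))
  expect_true(all(rep_$estimate >= 0 & rep_$estimate <= 1))
  expect_true(all(rep_$se >= 0))
})
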