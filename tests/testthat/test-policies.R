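# Online FDR policies: recursive implementation vs independent closed-form
# oracles, structural reductions between algorithms, monotonicity, and the
# run_stream contract.

test_that("recursions match the non-incremental closed-form oracles (bounded)", {
  set.seed(101)
  M <- 50
  g_lord <- oracle_gamma("lord", M)
  g_pow <- oracle_gamma("power", M, s = 1.6)
  g_pow0 <- oracle_gamma("power", M, s = 1.6, from = 0L)
  for (i in 1:12) {
    p <- rand_stream(sample(1:200, 1))
    a <- 0.05
    cases <- list(
      list(pol = lord(a, w0 = 0.02, b0 = 0.03,
                      gamma = spending_sequence("lord-default", bound = M)),
           orc = oracle_lord(p, a, 0.02, 0.03, g_lord)),
      list(pol = lordpp(a, bound = M),
           orc = oracle_lordpp(p, a, a / 10, g_lord)),
      list(pol = saffron(a, bound = M),
           orc = oracle_saffron(p, a, a / 2, 0.5, g_pow)),
      list(pol = addis(a, bound = M),
           orc = oracle_addis(p, a, a / 2, 0.25, 0.5,
                              function(k) g_pow0(k))),
      list(pol = alpha_investing(a, bound = M),
           orc = oracle_ai(p, a, a / 2, g_pow))
    )
    for (cs in cases) {
      got <- compute_levels(cs$pol, p)
      expect_equal(c(got$levels, got$next_level), cs$orc, tolerance = 1e-12)
    }
  }
})

test_that("recursions match the oracles on infinite-horizon sequences", {
  set.seed(102)
  # share the package's normalization constant; the recursion bookkeeping is
  # what is under test here
  gl <- spending_sequence("lord-default")
  gp <- spending_sequence("power", s = 1.6)
  g_lord <- function(i) ifelse(i >= 1, seq_weight(gl, pmax(i, 1)), 0)
  g_pow <- function(i) ifelse(i >= 1, seq_weight(gp, pmax(i, 1)), 0)
  for (i in 1:5) {
    p <- rand_stream(150)
    got <- compute_levels(lordpp(0.05), p)
    expect_equal(c(got$levels, got$next_level),
                 oracle_lordpp(p, 0.05, 0.005, g_lord), tolerance = 1e-12)
    got <- compute_levels(saffron(0.05), p)
    expect_equal(c(got$levels, got$next_level),
                 oracle_saffron(p, 0.05, 0.025, 0.5, g_pow), tolerance = 1e-12)
  }
})

test_that("LORD++ with no rejections is alpha-spending at rate w0", {
  p <- rep(1, 40)
  got <- compute_levels(lordpp(0.05, bound = 20), p)
  expect_equal(got$levels, 0.005 * lord_default_gamma(1:40, M = 20))
  expect_equal(sum(got$reject), 0L)
})

test_that("SAFFRON without candidates is the (1-lambda)-scaled LORD++ skeleton", {
  # all p above lambda: nothing is a candidate and nothing can be rejected,
  # so the levels collapse to (1 - lambda) * w0 * gamma_t
  p <- runif(30, 0.6, 1)
  gam <- spending_sequence("power", s = 1.6, bound = 25)
  s <- compute_levels(saffron(0.05, w0 = 0.02, lambda = 0.5, gamma = gam), p)
  l <- compute_levels(lordpp(0.05, w0 = 0.02, gamma = gam), p)
  expect_equal(s$levels, 0.5 * l$levels, tolerance = 1e-14)
  # first level with no history: (1 - lambda) * w0 * gamma_1
  expect_equal(s$levels[1], 0.5 * 0.02 * power_law_gamma(1, M = 25))
})

test_that("ADDIS with eta = 1 reproduces SAFFRON exactly", {
  set.seed(103)
  for (i in 1:5) {
    p <- rand_stream(100)
    ad <- compute_levels(addis(0.05, lambda = 0.5, eta = 1, bound = 40), p)
    sa <- compute_levels(saffron(0.05, lambda = 0.5, bound = 40), p)
    expect_equal(ad$levels, sa$levels, tolerance = 1e-14)
    expect_identical(ad$reject, sa$reject)
  }
})

test_that("p-values above eta are invisible to ADDIS", {
  set.seed(104)
  for (i in 1:5) {
    p <- rand_stream(60)
    k <- sample(60, 1)
    p2 <- append(p, 0.9, after = k - 1) # 0.9 > eta = 0.5: discarded
    r1 <- compute_levels(addis(0.05, bound = 30), p)
    r2 <- compute_levels(addis(0.05, bound = 30), p2)
    expect_equal(r2$levels[-k], r1$levels, tolerance = 1e-14)
    expect_equal(r2$next_level, r1$next_level, tolerance = 1e-14)
  }
})

test_that("levels are monotone under an added rejection", {
  set.seed(105)
  mk <- list(
    function() lordpp(0.05, bound = 50),
    function() saffron(0.05, bound = 50),
    function() addis(0.05, bound = 50),
    function() alpha_investing(0.05, bound = 50)
  )
  for (f in mk) {
    for (i in 1:5) {
      p <- rand_stream(80)
      r1 <- compute_levels(f(), p)
      nr <- which(r1$reject == 0)
      k <- nr[sample(length(nr), 1)]
      p2 <- p
      p2[k] <- 0 # force a rejection at k, all else equal
      r2 <- compute_levels(f(), p2)
      later <- seq2(k + 1, length(p))
      expect_true(all(r2$levels[later] >= r1$levels[later] - 1e-13))
      expect_gte(r2$next_level, r1$next_level - 1e-13)
    }
  }
})

test_that("emitted levels stay inside their admissible ranges", {
  set.seed(106)
  p <- rand_stream(300)
  expect_true(all(compute_levels(saffron(0.05), p)$levels <= 0.5))
  expect_true(all(compute_levels(addis(0.05), p)$levels <= 0.25))
  for (pol in list(lordpp(0.05), lord(0.05), alpha_investing(0.05))) {
    lv <- compute_levels(pol, p)$levels
    expect_true(all(lv >= 0 & lv <= 1))
  }
})

test_that("wealth never goes negative on random streams", {
  set.seed(107)
  pols <- list(lord(0.05), lordpp(0.05), saffron(0.05), addis(0.05),
               alpha_investing(0.05), lordpp(0.05, bound = 30),
               saffron(0.05, bound = 30), addis(0.05, bound = 30))
  for (i in 1:10) {
    p <- rand_stream(sample(50:400, 1))
    for (pol in pols) {
      r <- compute_levels(pol, p)
      expect_gte(min(r$wealth), -1e-12)
    }
  }
})

test_that("original LORD follows its formula and enforces w0 + b0 <= alpha", {
  gam <- spending_sequence("uniform", bound = 20)
  # rejection at t = 1 forced by a tiny p-value; alpha_3 = w0*g3 + b0*g2
  p <- c(1e-6, 0.9, 0.9)
  r <- compute_levels(lord(0.05, w0 = 0.025, b0 = 0.025, gamma = gam), p)
  expect_equal(r$levels[3], 0.025 * 0.05 + 0.025 * 0.05)
  # without rejections the level is w0 * gamma_t
  r0 <- compute_levels(lord(0.05, w0 = 0.02, b0 = 0.02, gamma = gam),
                       rep(1, 5))
  expect_equal(r0$levels, 0.02 * uniform_gamma(1:5, 20))
  expect_error(lord(0.05, w0 = 0.03, b0 = 0.03), "w0 \\+ b0 <= alpha")
})

test_that("alpha-investing solves its first-step fixed point", {
  pol <- alpha_investing(0.05, w0 = 0.025, bound = 20)
  a1 <- compute_levels(pol, 0.9)$levels[1]
  # oracle: bisection on a = (1 - a) * w0 * gamma_1
  g1 <- power_law_gamma(1, M = 20)
  f <- function(a) a - (1 - a) * 0.025 * g1
  lo <- 0; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(a1, lo, tolerance = 1e-12)
})

test_that("FDP-hat stays below alpha along LORD++ and SAFFRON runs", {
  set.seed(108)
  for (i in 1:5) {
    p <- rand_stream(400)
    r <- compute_levels(lordpp(0.05), p)
    est <- cumsum(r$levels) / pmax(cumsum(r$reject), 1)
    expect_true(all(est <= 0.05 + 1e-12))
    r <- compute_levels(saffron(0.05), p)
    est <- cumsum(r$levels * (1 - r$candidate)) / (1 - 0.5) /
      pmax(cumsum(r$reject), 1)
    expect_true(all(est <= 0.05 + 1e-12))
  }
})

test_that("run_stream validates input and reports the next level", {
  log <- run_stream(stampede_p, uncorrected(0.05), ids = stampede_ids)
  expect_identical(rejected_ids(log), c("C", "E", "G"))
  expect_equal(next_level(log), 0.05)
  # empty stream: empty log, next level = first-step level
  e <- run_stream(numeric(0), lordpp(0.05, bound = 20))
  expect_identical(nrow(e), 0L)
  expect_equal(next_level(e), 0.005 * lord_default_gamma(1, M = 20))
  expect_error(run_stream(c(0.2, 1.7, 0.3), lordpp(0.05)),
               "invalid p-value at index 2")
  expect_error(run_stream(c(0.2, NA, 0.3), lordpp(0.05)), "index 2")
  expect_error(run_stream(c(0.1, 0.2), lordpp(0.05), ids = "a"),
               "match the stream length")
  # reject column is exactly 1{p <= alpha}
  lg <- run_stream(rand_stream(50), saffron(0.05, bound = 20))
  expect_identical(lg$reject, as.integer(lg$pval <= lg$alpha))
})
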