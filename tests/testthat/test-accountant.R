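test_that("log-moments match the Gaussian closed form at q = 1", {
  # E[(mu1/mu0)^lam] under mu1 is exp(lam(lam+1)/(2 s^2))
  for (s in c(0.5, 4, 12)) {
    spec <- mechanism_spec(q = 1, noise_std = s)
    for (lam in c(1L, 8L, 32L, 100L)) {
      expect_equal(log_moment(spec, lam), lam * (lam + 1) / (2 * s^2),
                   tolerance = 1e-6)
    }
  }
})

test_that("log-moments vanish at q = 0 and match Monte Carlo at q = 0.1", {
  spec0 <- mechanism_spec(q = 0, noise_std = 4)
  for (lam in c(1L, 10L, 100L)) expect_identical(log_moment(spec0, lam), 0)

  alpha <- log_moment(mechanism_spec(0.1, 4), 8)
  set.seed(99)
  n <- 1e6
  x <- ifelse(runif(n) < 0.1, rnorm(n, 1, 4), rnorm(n, 0, 4))
  ratio <- exp(8 * log(0.9 + 0.1 * exp((2 * x - 1) / 32)))
  est <- mean(ratio)
  se <- sd(ratio) / sqrt(n)
  expect_lt(abs(alpha - log(est)), 3 * se / est)
})

test_that("moments are non-negative and non-decreasing in q", {
  for (s in c(1, 4)) {
    prev <- 0
    for (q in c(0, 0.05, 0.2, 0.5, 1)) {
      a <- log_moment(mechanism_spec(q, s), 12)
      expect_gte(a, prev - 1e-10)
      prev <- a
    }
  }
})

test_that("composition is additive over devices and rounds", {
  spec <- mechanism_spec(1, 12)
  led <- accumulate_moments(moment_ledger(1:20), spec)
  expect_equal(led$totals,
               vapply(1:20, function(l) log_moment(spec, l), 0))
  two <- accumulate_moments(led, spec)
  expect_equal(two$totals, 2 * led$totals)           # Thm-1 additivity
  k20 <- accumulate_moments(moment_ledger(1:20), spec, devices = 20)
  expect_equal(k20$totals, 20 * led$totals)          # sum over devices
  # accumulate(A) then accumulate(B) == accumulate(A union B)
  sp2 <- mechanism_spec(0.3, 5)
  ab <- accumulate_moments(accumulate_moments(moment_ledger(1:20), spec,
                                              devices = 3),
                           sp2, devices = 2)
  ba <- accumulate_moments(accumulate_moments(moment_ledger(1:20), sp2,
                                              devices = 2),
                           spec, devices = 3)
  expect_equal(ab$totals, ba$totals)
  # parallel composition counts rounds only
  par_led <- accumulate_moments(moment_ledger(1:20, "rounds_only"), spec,
                                devices = 20)
  expect_equal(par_led$totals, led$totals)
})

test_that("tail-bound inversion matches an exhaustive grid search", {
  led <- moment_ledger(1:100)
  expect_identical(epsilon_for_delta(led, 1e-4), 0)  # empty ledger
  # alpha(lambda) = 0 on a non-empty ledger: eps = log(1/delta)/lambda_max
  led0 <- accumulate_moments(moment_ledger(1:100), mechanism_spec(0, 4))
  led0$n_entries <- 1L
  expect_equal(epsilon_for_delta(led0, 1e-4), log(1e4) / 100)
  # analytic alpha grid vs independent exhaustive minimisation
  led1 <- accumulate_moments(moment_ledger(1:100), mechanism_spec(1, 4))
  oracle <- min(sapply(1:100, function(l)
    (l * (l + 1) / 32 + log(1e4)) / l))
  expect_equal(epsilon_for_delta(led1, 1e-4), oracle, tolerance = 1e-6)
  # doubling all moments never decreases epsilon
  led2 <- led1; led2$totals <- 2 * led1$totals
  expect_gte(epsilon_for_delta(led2, 1e-4), epsilon_for_delta(led1, 1e-4))
})

test_that("budget exhaustion flips exactly once as rounds accrue", {
  budget <- privacy_budget(epsilon = 3, delta = 1e-4)
  led <- moment_ledger(1:100)
  expect_false(is_exhausted(budget, led))            # empty ledger
  spec <- mechanism_spec(1, 12)                      # C = 3, sigma = 4
  states <- logical(100)
  for (t in 1:100) {
    led <- accumulate_moments(led, spec, devices = 20)
    states[t] <- is_exhausted(budget, led)
  }
  expect_identical(sum(diff(states) != 0), 1L)       # one FALSE->TRUE flip
  expect_true(states[100])
  expect_true(is_exhausted(privacy_budget(epsilon = 0),
                           accumulate_moments(moment_ledger(1:100),
                                              mechanism_spec(1, 4))))
})

test_that("printed-convention moments depend on C_t, normalized ones do not", {
  sigma <- 4
  a_small <- log_moment(mechanism_spec(1, 0.5 * sigma,
                                       mode = "paper_printed"), 8)
  a_large <- log_moment(mechanism_spec(1, 3 * sigma,
                                       mode = "paper_printed"), 8)
  expect_gt(a_small, a_large)          # shrinking C_t spends MORE budget
  n1 <- log_moment(mechanism_spec(1, sigma, mode = "normalized"), 8)
  n2 <- log_moment(mechanism_spec(1, sigma, mode = "normalized"), 8)
  expect_identical(n1, n2)             # independent of the threshold
})
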