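test_that("stratum log-likelihood matches naive direct summation", {
  expect_equal(stratum_loglik(0.5, 3, 5, 1, 4),
               oracle_loglik(0.5, 3, 5, 1, 4), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    beta <- runif(1, -3, 3)
    expect_equal(stratum_loglik(beta, a, n1, b, n2),
                 oracle_loglik(beta, a, n1, b, n2), tolerance = 1e-12)
  }
})

test_that("at beta = 0 the stratum likelihood is central hypergeometric", {
  # P(X = a) for X ~ Hypergeometric drawing t from n1 'index' of n1+n2
  expect_equal(stratum_loglik(0, 3, 5, 1, 4),
               dhyper(3, 5, 4, 4, log = TRUE), tolerance = 1e-12)
  expect_lte(stratum_loglik(0, 2, 6, 3, 5), 0)
})

test_that("strata with no or all events carry zero information", {
  expect_identical(stratum_loglik(-2, 0, 3, 0, 4), 0)
  expect_identical(stratum_loglik(7, 3, 3, 4, 4), 0)
  base <- data.frame(index_events = c(3, 1), index_trials = c(5, 3),
                     comparison_events = c(1, 2), comparison_trials = c(4, 4))
  fit0 <- fit_clogit_et(base)
  padded <- rbind(base,
                  data.frame(index_events = 0, index_trials = 2,
                             comparison_events = 0, comparison_trials = 3),
                  data.frame(index_events = 4, index_trials = 4,
                             comparison_events = 2, comparison_trials = 2))
  fit1 <- fit_clogit_et(padded)
  expect_identical(fit1$beta_hat, fit0$beta_hat)
  expect_identical(fit1$se, fit0$se)
  expect_equal(fit1$n_informative_strata, fit0$n_informative_strata)
})

test_that("invalid stratum counts are rejected", {
  expect_error(stratum_loglik(0, 4, 3, 0, 2), "invalid stratum")
  expect_error(stratum_loglik(0, -1, 3, 0, 2), "invalid stratum")
  expect_error(fit_clogit_et(data.frame(index_events = 0, index_trials = 3,
                                        comparison_events = 0,
                                        comparison_trials = 2)),
               "no informative stratum")
})

test_that("balanced arms give an odds ratio of exactly 1", {
  s <- data.frame(index_events = c(2, 1), index_trials = c(4, 3),
                  comparison_events = c(2, 1), comparison_trials = c(4, 3))
  fit <- fit_clogit_et(s)
  expect_true(fit$converged)
  expect_equal(fit$beta_hat, 0, tolerance = 1e-8)
  expect_equal(fit$or_hat, 1, tolerance = 1e-8)
  expect_true(fit$ci_low < 1 && fit$ci_high > 1)
})

test_that("the Newton optimum matches grid maximisation", {
  s1 <- data.frame(index_events = 3, index_trials = 5,
                   comparison_events = 1, comparison_trials = 4)
  expect_lt(abs(fit_clogit_et(s1)$beta_hat - oracle_grid_beta(s1)), 2e-4)
  set.seed(22)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    n1 <- sample(1:6, k, TRUE); n2 <- sample(1:6, k, TRUE)
    s <- data.frame(index_events = rbinom(k, n1, 0.6), index_trials = n1,
                    comparison_events = rbinom(k, n2, 0.4),
                    comparison_trials = n2)
    f <- fit_clogit_et(s)
    if (f$converged)
      expect_lt(abs(f$beta_hat - oracle_grid_beta(s)), 2e-4)
  }
})

test_that("swapping arms negates the log odds ratio exactly", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(1:4, 1)
    n1 <- sample(2:6, k, TRUE); n2 <- sample(2:6, k, TRUE)
    s <- data.frame(index_events = rbinom(k, n1, 0.7), index_trials = n1,
                    comparison_events = rbinom(k, n2, 0.3),
                    comparison_trials = n2)
    f <- fit_clogit_et(s)
    if (!f$converged) next
    sw <- data.frame(index_events = s$comparison_events,
                     index_trials = s$comparison_trials,
                     comparison_events = s$index_events,
                     comparison_trials = s$index_trials)
    g <- fit_clogit_et(sw)
    expect_equal(g$beta_hat, -f$beta_hat, tolerance = 1e-7)
    expect_equal(g$se, f$se, tolerance = 1e-7)
  }
})

test_that("complete separation is flagged, not 'converged'", {
  f <- fit_clogit_et(data.frame(index_events = 5, index_trials = 5,
                                comparison_events = 0,
                                comparison_trials = 4))
  expect_false(f$converged)
  expect_identical(f$beta_hat, Inf)
  g <- fit_clogit_et(data.frame(index_events = 0, index_trials = 5,
                                comparison_events = 4,
                                comparison_trials = 4))
  expect_false(g$converged)
  expect_identical(g$beta_hat, -Inf)
})

test_that("the score equation holds at the optimum (single stratum)", {
  a <- 3; n1 <- 5; b <- 1; n2 <- 4
  f <- fit_clogit_et(data.frame(index_events = a, index_trials = n1,
                                comparison_events = b,
                                comparison_trials = n2))
  t <- a + b
  u <- max(0, t - n2):min(n1, t)
  w <- choose(n1, u) * choose(n2, t - u) * exp(f$beta_hat * u)
  expect_equal(sum(w * u) / sum(w), a, tolerance = 1e-6)
})

test_that("estimates agree with survival's exact conditional logistic", {
  skip_if_not_installed("survival")
  set.seed(24)
  k <- 12
  n1 <- sample(2:6, k, TRUE); n2 <- sample(2:6, k, TRUE)
  s <- data.frame(index_events = rbinom(k, n1, 0.6), index_trials = n1,
                  comparison_events = rbinom(k, n2, 0.4),
                  comparison_trials = n2)
  f <- fit_clogit_et(s)
  long <- do.call(rbind, lapply(seq_len(k), function(i) {
    with(s[i, ], data.frame(
      stratum = i,
      y = c(rep(1, index_events), rep(0, index_trials - index_events),
            rep(1, comparison_events),
            rep(0, comparison_trials - comparison_events)),
      x = rep(c(1, 0), c(index_trials, comparison_trials))))
  }))
  cl <- survival::coxph(
    survival::Surv(rep(1, nrow(long)), y) ~ x + survival::strata(stratum),
    data = long, method = "exact")
  expect_equal(unname(coef(cl)), f$beta_hat, tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(cl)))), f$se, tolerance = 1e-6)
})
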