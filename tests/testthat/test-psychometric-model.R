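test_that("psi evaluates the four-parameter logistic correctly", {
  # midpoint identities
  pp <- psychometric_params(0.5, 0.1, 0.2, 0.8)
  expect_equal(psi(pp, 0.5), (0.2 + 0.8) / 2)
  expect_equal(psi(psychometric_params(0.5, 0.1), 0.5), 0.5)
  # independent hand evaluation: floor + (ceiling - floor) * logistic(2)
  pp2 <- psychometric_params(0.5, 0.1, 0.05, 0.95)
  expect_equal(psi(pp2, 0.7), 0.05 + 0.9 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(psi(pp2, 0.7), 0.8427173701800941, tolerance = 1e-12)
  expect_error(psychometric_params(0.5, 0), "positive")
  expect_error(psi(pp, 1.5), "0, 1")
})

test_that("psi is monotone in p, m and ceiling, and reaches the step limit", {
  set.seed(1)
  p <- seq(0, 1, 0.05)
  for (i in 1:20) {
    m <- runif(1, -0.2, 1.2); w <- runif(1, 0.02, 0.5)
    fl <- runif(1, 0, 0.4); ce <- runif(1, 0.6, 1)
    v <- psi(psychometric_params(m, w, fl, ce), p)
    expect_true(all(diff(v) > 0))
    expect_true(all(v > fl & v < ce))
    # decreasing in m, increasing in ceiling
    expect_true(all(psi(psychometric_params(m + 0.1, w, fl, ce), p) < v))
    expect_true(all(psi(psychometric_params(m, w, fl, min(ce + 0.01, 1)), p) >=
                      v))
  }
  # w -> 0+ gives floor below m, ceiling above m, midpoint at m
  stp <- psychometric_params(0.5, 1e-9, 0.1, 0.9)
  expect_equal(psi(stp, 0.4), 0.1)
  expect_equal(psi(stp, 0.6), 0.9)
  expect_equal(psi(stp, 0.5), 0.5)
})

test_that("the likelihood matches a per-trial Bernoulli product", {
  expect_equal(log_likelihood(psychometric_params(0.5, 0.1),
                              tibble::tibble(cue_prob = numeric(),
                                             k = integer(), n = integer())),
               0)
  expect_equal(log_likelihood(psychometric_params(0.5, 0.1),
                              tibble::tibble(cue_prob = 0.5, k = 1, n = 1)),
               log(0.5))
  set.seed(2)
  for (i in 1:10) {
    pp <- psychometric_params(runif(1, 0, 1), runif(1, 0.05, 0.3),
                              runif(1, 0, 0.3), runif(1, 0.7, 1))
    counts <- tibble::tibble(cue_prob = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             n = sample(1:40, 5, replace = TRUE)) |>
      dplyr::mutate(k = rbinom(5, n, 0.5))
    expect_equal(log_likelihood(pp, counts), loglik_per_trial(pp, counts),
                 tolerance = 1e-12)
    # invariant to level ordering
    expect_equal(log_likelihood(pp, counts[sample(5), ]),
                 log_likelihood(pp, counts), tolerance = 1e-12)
  }
})

test_that("saturated psychometric values give -Inf, never NaN", {
  stp <- psychometric_params(0.5, 1e-4, 0, 1)
  counts <- tibble::tibble(cue_prob = 0.1, k = 1, n = 2)
  expect_identical(log_likelihood(stp, counts), -Inf)
  expect_identical(deviance_psy(stp, counts), Inf)
})

test_that("the log posterior is the likelihood plus a flat-prior constant", {
  prior <- prior_spec()
  counts <- tibble::tibble(cue_prob = c(0.3, 0.7), k = c(3, 12), n = c(16, 16))
  const <- log_prior(psychometric_params(0.5, 0.1, 0.1, 0.9), prior)
  set.seed(3)
  for (i in 1:10) {
    pp <- psychometric_params(runif(1, -0.2, 1.2), runif(1, 0.02, 0.9),
                              runif(1, 0, 0.45), runif(1, 0.55, 1))
    expect_equal(log_posterior(pp, counts, prior) - log_likelihood(pp, counts),
                 const, tolerance = 1e-12)
  }
  outside <- psychometric_params(2, 0.1)  # m beyond the prior box
  expect_identical(log_posterior(outside, counts, prior), -Inf)
  expect_identical(log_prior(outside, prior), -Inf)
})

test_that("deviance is minimised at the grid likelihood maximiser", {
  counts <- tibble::tibble(cue_prob = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           k = c(2, 5, 16, 27, 30), n = rep(32, 5))
  grid <- expand.grid(m = seq(0.05, 0.95, length.out = 10),
                      w = seq(0.02, 0.5, length.out = 10),
                      fl = seq(0, 0.45, length.out = 10),
                      ce = seq(0.55, 1, length.out = 10))
  dev <- vapply(seq_len(nrow(grid)), function(i) {
    deviance_psy(psychometric_params(grid$m[i], grid$w[i], grid$fl[i],
                                     grid$ce[i]), counts)
  }, numeric(1))
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    loglik_per_trial(psychometric_params(grid$m[i], grid$w[i], grid$fl[i],
                                         grid$ce[i]), counts)
  }, numeric(1))
  expect_lte(dev[which.max(ll)], min(dev) + 1e-8)
  expect_true(all(dev >= dev[which.max(ll)] - 1e-8))
  expect_true(all(dev >= 0))
})
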