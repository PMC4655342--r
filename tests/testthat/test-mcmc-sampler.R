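make_counts <- function(params = psychometric_params(0.5, 0.1, 0.05, 0.95),
                        n_per_level = 32L, seed = 1L) {
  withr::with_seed(seed, {
    p <- c(0.1, 0.3, 0.5, 0.7, 0.9)
    tibble::tibble(cue_prob = p, n = n_per_level,
                   k = rbinom(5, n_per_level, psi(params, p)))
  })
}

test_that("sampling is deterministic given identical inputs", {
  counts <- make_counts()
  cfg <- quick_cfg(seed = 5)
  a <- sample_posterior(counts, config = cfg)
  b <- sample_posterior(counts, config = cfg)
  expect_identical(a$draws, b$draws)
  d <- sample_posterior(counts, config = quick_cfg(seed = 6))
  expect_false(identical(a$draws, d$draws))
})

test_that("with no data the posterior reproduces the prior", {
  empty <- tibble::tibble(cue_prob = numeric(), k = integer(), n = integer())
  prior <- prior_spec()
  fit <- sample_posterior(empty, prior,
                          sampler_config(n_chains = 4, n_warmup = 500,
                                         n_draws = 3000, seed = 2))
  s <- tidy(fit)
  prior_mean <- rowMeans(prior$bounds)
  for (j in seq_len(4)) {
    mcse <- s$sd[j] / sqrt(s$ess[j])
    expect_lt(abs(s$mean[j] - prior_mean[j]), 3 * mcse + 1e-3)
  }
  # stationarity: the m marginal should be uniform over its prior box
  u <- (fit$draws$m - prior$bounds["m", 1]) / diff(prior$bounds["m", ])
  d_ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(d_ks, 0.08)
})

test_that("every draw respects the parameter constraints and stored values", {
  counts <- make_counts()
  fit <- sample_posterior(counts, config = quick_cfg(seed = 3))
  d <- fit$draws
  expect_true(all(d$w > 0))
  expect_true(all(d$floor >= 0 & d$floor < d$ceiling & d$ceiling <= 1))
  # deviance and log_post recomputable from each draw (C++ vs R likelihood)
  idx <- seq(1, nrow(d), by = 50)
  const <- log_prior(psychometric_params(0.5, 0.1, 0.1, 0.9))
  for (i in idx) {
    pp <- psychometric_params(d$m[i], d$w[i], d$floor[i], d$ceiling[i])
    ll <- log_likelihood(pp, counts)
    expect_equal(d$deviance[i], -2 * ll, tolerance = 1e-10)
    expect_equal(d$log_post[i], ll + const, tolerance = 1e-10)
  }
})

test_that("proposal scales are frozen after warmup", {
  fit <- sample_posterior(make_counts(), config = quick_cfg(seed = 4))
  expect_identical(fit$scales, fit$scales_final)
})

test_that("degenerate all-or-nothing data triggers a warning but still runs", {
  counts <- tibble::tibble(cue_prob = c(0.1, 0.5, 0.9), k = c(0L, 0L, 16L),
                           n = c(16L, 16L, 16L))
  expect_warning(fit <- sample_posterior(counts, config = quick_cfg(seed = 1)),
                 "degenerate")
  expect_equal(nrow(fit$draws), 2 * 500)
})

test_that("diagnostics behave on known chain configurations", {
  expect_error(sampler_config(n_chains = 1), "at least 2")
  # i.i.d. chains from one distribution: rhat about 1
  withr::with_seed(9, {
    iid <- fake_draws(lapply(1:4, function(i) matrix(rnorm(2000 * 4), 2000)))
    dg <- diagnostics(iid)
    expect_true(all(dg$rhat <= 1.01))
    # chains with disjoint supports: rhat far above the failure threshold
    far <- fake_draws(list(matrix(rnorm(500 * 4), 500),
                           matrix(rnorm(500 * 4, mean = 50), 500)))
    dg2 <- diagnostics(far)
    expect_true(all(dg2$rhat > 1.05))
    expect_false(dg2$converged)
  })
  one <- fake_draws(list(matrix(rnorm(100 * 4), 100)))
  expect_error(diagnostics(one), "n_chains >= 2")
})

test_that("effective sample size matches the AR(1) closed form and coda", {
  withr::with_seed(10, {
    rho <- 0.5
    n <- 20000L
    chains <- lapply(1:2, function(i) {
      x <- as.numeric(stats::arima.sim(list(ar = rho), n))
      matrix(rep(x, 4), n)
    })
    dg <- diagnostics(fake_draws(chains))
    expected <- 2 * n * (1 - rho) / (1 + rho)
    expect_lt(abs(dg$ess[["m"]] - expected) / expected, 0.2)
    # cross-check against coda on the pooled chains
    cd <- sum(vapply(chains, function(ch) {
      unname(coda::effectiveSize(coda::mcmc(ch[, 1])))
    }, numeric(1)))
    expect_lt(abs(dg$ess[["m"]] - cd) / cd, 0.3)
  })
})

test_that("posterior marginals agree with dense-grid integration on small data", {
  counts <- make_counts(n_per_level = 16L, seed = 21)
  prior <- prior_spec()
  fit <- sample_posterior(counts, prior,
                          sampler_config(n_chains = 4, n_warmup = 800,
                                         n_draws = 3000, seed = 7))
  oracle <- grid_marginals(counts, prior, n_coarse = 21L, n_fine = 41L)
  s <- tidy(fit)
  for (j in seq_len(4)) {
    st <- oracle$stats[[s$term[j]]]
    mcse <- s$sd[j] / sqrt(s$ess[j])
    expect_lt(abs(s$mean[j] - st$mean), 0.03 + 3 * mcse)
    expect_lt(abs(s$q5[j] - st$q5), 0.05)
    expect_lt(abs(s$q95[j] - st$q95), 0.05)
  }
})
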