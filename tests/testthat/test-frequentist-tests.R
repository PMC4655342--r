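test_that("mid-P handles degenerate margins and symmetries", {
  z <- fisher_midp(c(0, 0, 5, 7))
  expect_true(z$degenerate)
  expect_equal(z$midp, 0.5)
  expect_true(fisher_midp(c(3, 0, 4, 0))$degenerate)

  tab <- matrix(c(9, 3, 2, 11), 2, byrow = TRUE)
  p0 <- fisher_midp(tab)$midp
  expect_equal(fisher_midp(t(tab))$midp, p0, tolerance = 1e-14)
  expect_equal(fisher_midp(tab[2:1, 2:1])$midp, p0, tolerance = 1e-14)
  expect_error(fisher_midp(c(1, -1, 2, 3)), "non-negative")
})

test_that("mid-P equals the enumeration oracle and undercuts the exact test", {
  expect_equal(fisher_midp(c(8, 2, 2, 8))$midp, midp_oracle(8, 2, 2, 8),
               tolerance = 1e-14)
  # spot grid of tables, exact agreement and ordering vs fisher.test
  for (a in 0:6) for (b in 0:4) for (cc in 0:4) for (d in 0:6) {
    if (a + b + cc + d == 0) next
    res <- fisher_midp(c(a, b, cc, d))
    expect_equal(res$midp, midp_oracle(a, b, cc, d), tolerance = 1e-14)
    if (!res$degenerate) {
      pf <- stats::fisher.test(matrix(c(a, b, cc, d), 2,
                                      byrow = TRUE))$p.value
      expect_lte(res$midp, pf + 1e-12)
    }
  }
})

test_that("per-level tests match the oracle and flag untestable levels", {
  # hand-built single-level session: off 10/54 risky, on 30/34 risky
  tr <- trials_from_counts(0.5, k_off = 10, n_off = 64, k_on = 30, n_on = 64)
  out <- per_level_tests(tr)
  expect_equal(nrow(out), 1L)
  expect_equal(out$midp, midp_oracle(10, 54, 30, 34), tolerance = 1e-14)
  expect_equal(out$tier,
               if (out$midp < 0.001) "***" else if (out$midp < 0.01) "**"
               else if (out$midp < 0.05) "*" else "")

  # a level absent in one condition is flagged untestable
  tr2 <- dplyr::bind_rows(
    tr, trials_from_counts(0.9, k_off = 5, n_off = 8))
  out2 <- per_level_tests(tr2)
  expect_false(out2$testable[out2$cue_prob == 0.9])
  expect_true(is.na(out2$midp[out2$cue_prob == 0.9]))
  expect_error(per_level_tests(dplyr::filter(tr, condition == "off")),
               "both conditions")
})

test_that("a strong simulated shift at one level is reliably starred", {
  hits <- 0L
  for (s in 1:20) {
    withr::with_seed(300 + s, {
      k_off <- rbinom(1, 64, 0.15)
      k_on <- rbinom(1, 64, 0.55)
    })
    out <- per_level_tests(
      trials_from_counts(0.3, k_off = k_off, n_off = 64,
                         k_on = k_on, n_on = 64))
    if (!is.na(out$tier) && out$tier != "") hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})

test_that("mid-P is calibrated under the null", {
  withr::with_seed(77, {
    ps <- replicate(1000, {
      k1 <- rbinom(1, 64, 0.3)
      k2 <- rbinom(1, 64, 0.3)
      fisher_midp(c(k1, 64 - k1, k2, 64 - k2))$midp
    })
  })
  d_ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(d_ks, 0.1)
  expect_gte(mean(ps < 0.05), 0.03)
  expect_lte(mean(ps < 0.05), 0.07)
})

test_that("the reaction-time ANOVA matches an independent Type II oracle", {
  tr <- balanced_rt_trials()
  out <- rt_anova(tr)
  dat <- dplyr::filter(tr, choice != "omit") |>
    dplyr::mutate(condition = factor(condition), choice = factor(choice),
                  cue_prob = factor(cue_prob))
  oracle <- car::Anova(stats::lm(rt_ms ~ condition * choice * cue_prob,
                                 data = dat), type = 2)
  onames <- rownames(oracle)
  for (term in setdiff(out$term, "Residuals")) {
    i <- match(term, onames)
    row <- out[out$term == term, ]
    expect_equal(row$sumsq, oracle[i, "Sum Sq"], tolerance = 1e-8)
    expect_equal(row$statistic, oracle[i, "F value"], tolerance = 1e-8)
    expect_equal(row$p.value, oracle[i, "Pr(>F)"], tolerance = 1e-8)
    expect_equal(row$df, oracle[i, "Df"])
  }
  # the injected stimulation effect is detected; a relabeling changes nothing
  expect_lt(out$p.value[out$term == "condition"], 1e-6)
  flipped <- dplyr::mutate(tr, condition = ifelse(condition == "on",
                                                  "off", "on"))
  expect_equal(rt_anova(flipped)$statistic, out$statistic, tolerance = 1e-10)
})

test_that("Type II sums of squares decompose total variance on balanced data", {
  tr <- balanced_rt_trials(seed = 5)
  out <- rt_anova(tr)
  total_ss <- sum((tr$rt_ms - mean(tr$rt_ms))^2)
  expect_equal(sum(out$sumsq), total_ss, tolerance = 1e-8)
})

test_that("degenerate and deficient designs are handled", {
  tr <- balanced_rt_trials(n_cell = 4L, seed = 2)
  const <- dplyr::mutate(tr, rt_ms = 700)
  out <- rt_anova(const)
  eff <- dplyr::filter(out, term != "Residuals")
  expect_true(all(eff$sumsq == 0))
  expect_true(all(eff$p.value == 1))

  # an empty cell reduces the interaction df instead of failing
  holey <- dplyr::filter(tr, !(condition == "on" & choice == "risky" &
                                 cue_prob == 0.9))
  out2 <- rt_anova(holey)
  expect_lt(out2$df[out2$term == "condition:choice:cue_prob"], 4L)

  # no replication at all: no residual degrees of freedom
  singleton <- dplyr::distinct(tr, condition, choice, cue_prob,
                               .keep_all = TRUE)
  expect_error(rt_anova(singleton), "residual")
  expect_error(rt_anova(dplyr::filter(tr, condition == "off")),
               "both conditions")
})
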