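# near-step choice agent: deterministic risky above m, safe below
step_agent <- function(m = 0.5, omission_rate = 0) {
  pp <- psychometric_params(m = m, w = 1e-3, floor = 0, ceiling = 1)
  agent_params(params_off = pp, params_on = pp,
               omission_rate = omission_rate)
}

# identical behaviour in both conditions (null agent)
null_agent <- function(m = 0.55, w = 0.10, floor = 0.05, ceiling = 0.95,
                       omission_rate = 0.033) {
  pp <- psychometric_params(m, w, floor, ceiling)
  agent_params(params_off = pp, params_on = pp,
               omission_rate = omission_rate)
}

# small-but-adequate sampler settings for tests that only need draws
quick_cfg <- function(seed = 1L, n_draws = 500L) {
  sampler_config(n_chains = 2L, n_warmup = 300L, n_draws = n_draws,
                 seed = seed)
}

# build a trial tibble directly from per-level risky/safe counts
trials_from_counts <- function(levels, k_off, n_off, k_on = NULL,
                               n_on = NULL, rt = 700) {
  mk <- function(cond, k, n, block) {
    purrr::map_dfr(seq_along(levels), function(i) {
      ch <- c(rep("risky", k[i]), rep("safe", n[i] - k[i]))
      tibble::tibble(block = block, trial = seq_len(n[i]), condition = cond,
                     cue_prob = levels[i], choice = ch,
                     outcome = ifelse(ch == "risky", 50, 10),
                     rt_ms = rt)
    })
  }
  out <- mk("off", k_off, n_off, 1L)
  if (!is.null(k_on)) out <- dplyr::bind_rows(out, mk("on", k_on, n_on, 3L))
  out
}

# wrap a bare draws tibble as a posterior_draws object for diagnostics tests
fake_draws <- function(mat_list) {
  draws <- purrr::imap_dfr(mat_list, function(mat, ch) {
    tibble::tibble(chain = as.integer(ch), iter = seq_len(nrow(mat)),
                   m = mat[, 1], w = mat[, 2], floor = mat[, 3],
                   ceiling = mat[, 4], log_post = 0, deviance = 0)
  })
  structure(list(draws = draws, accept_rate = rep(0.35, 4),
                 config = list(n_chains = length(mat_list),
                               n_draws = nrow(mat_list[[1]]))),
            class = "posterior_draws")
}

# balanced factorial reaction times with a pure additive condition effect
balanced_rt_trials <- function(effect_ms = 30, sd_ms = 50, n_cell = 48L,
                               seed = 1L) {
  cells <- tidyr::expand_grid(condition = c("off", "on"),
                              choice = c("risky", "safe"),
                              cue_prob = c(0.1, 0.3, 0.5, 0.7, 0.9))
  withr::with_seed(seed, {
    purrr::pmap_dfr(cells, function(condition, choice, cue_prob) {
      mu <- 600 + if (condition == "on") effect_ms else 0
      tibble::tibble(block = ifelse(condition == "on", 3L, 1L),
                     trial = seq_len(n_cell), condition = condition,
                     cue_prob = cue_prob, choice = choice,
                     outcome = ifelse(choice == "risky", 50, 10),
                     rt_ms = rnorm(n_cell, mu, sd_ms))
    })
  })
}
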