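#' Fit the psychometric model to one stimulation condition
#'
#' Aggregates the condition's responded trials into per-level counts, draws
#' from the posterior with [sample_posterior()], runs the posterior-predictive
#' goodness-of-fit check, and classifies the fit: `"ok"` when the chains
#' converged and the predictive check passed, `"poor_fit"` when the check
#' fails at the 0.05 level (or diagnostics flag non-convergence), and
#' `"unfittable"` when the check fails at 0.005 — the regime of grossly
#' non-monotonic choice behaviour that a monotone psychometric function
#' cannot capture.
#'
#' @param trials A trial tibble.
#' @param condition `"off"` or `"on"`.
#' @param prior A [prior_spec()].
#' @param config A [sampler_config()]; its seed also drives the predictive
#'   check (offset per condition, so the two fits use distinct streams).
#' @param ppc_draws Number of posterior draws used in the predictive check.
#'
#' @return An object of class `psychometric_fit`: the condition, the
#'   `posterior_draws`, the per-level `counts`, the predictive-check p-value
#'   `ppc_p`, and `status`.
#' @examples
#' fit <- fit_condition(simulate_session(seed = 1), "off",
#'                      config = sampler_config(n_draws = 300))
#' fit$status
#' @export
fit_condition <- function(trials, condition = c("off", "on"),
                          prior = prior_spec(), config = sampler_config(),
                          ppc_draws = 500L) {
  condition <- match.arg(condition)
  counts <- choice_counts(trials, condition)
  if (nrow(counts) == 0L || sum(counts$n) == 0L) {
    stop("No responded trials in condition '", condition, "'.", call. = FALSE)
  }
  cfg <- config
  cfg$seed <- .derive_seed(config$seed, paste0("fit_", condition))
  draws <- sample_posterior(counts, prior, cfg)
  fit <- structure(
    list(condition = condition, draws = draws, counts = counts,
         ppc_p = NA_real_, status = "ok"),
    class = "psychometric_fit")
  fit$ppc_p <- posterior_predictive_check(
    fit, counts, n_rep = ppc_draws,
    seed = .derive_seed(config$seed, paste0("ppc_", condition)))
  fit$status <- if (fit$ppc_p < 0.005) "unfittable"
    else if (fit$ppc_p < 0.05 || max(draws$rhat) > 1.05) "poor_fit"
    else "ok"
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> condition '%s', status '%s' (ppc p = %.3f)\n",
              x$condition, x$status, x$ppc_p))
  print(tidy(x$draws), ...)
  invisible(x)
}

#' @rdname tidy.posterior_draws
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tidy(x$draws, ...) |>
    dplyr::mutate(condition = x$condition, .before = 1)
}

#' @rdname glance.posterior_draws
#' @export
glance.psychometric_fit <- function(x, ...) {
  glance(x$draws, ...) |>
    dplyr::mutate(condition = x$condition, ppc_p = x$ppc_p,
                  status = x$status, .before = 1)
}

#' Posterior-predictive goodness-of-fit check
#'
#' For a subsample of posterior draws, compares a chi-square-style discrepancy
#' \eqn{T = \sum_\ell (k_\ell - n_\ell\psi_\ell)^2 /
#' (n_\ell\psi_\ell(1-\psi_\ell))} between the observed counts and counts
#' replicated from the fitted model at the same draw. The returned tail
#' probability `P(T_rep >= T_obs)` is small when the observed choice pattern
#' is less compatible with a monotone psychometric function than its own
#' replicates — the operational signature of unfittable behaviour.
#'
#' @param fit A `psychometric_fit` (or `posterior_draws`) object.
#' @param counts Per-level counts the model was fitted to.
#' @param n_rep Number of posterior draws to use.
#' @param seed Integer seed for draw subsampling and replication.
#' @return The posterior-predictive p-value.
#' @export
posterior_predictive_check <- function(fit, counts = fit$counts,
                                       n_rep = 500L, seed = 1L) {
  draws <- if (inherits(fit, "psychometric_fit")) fit$draws else fit
  stopifnot(inherits(draws, "posterior_draws"))
  .check_counts(counts)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  d <- draws$draws
  idx <- sample.int(nrow(d), min(n_rep, nrow(d)))
  nlev <- nrow(counts)
  t_obs <- t_rep <- numeric(length(idx))
  for (i in seq_along(idx)) {
    r <- d[idx[i], ]
    ps <- r$floor + (r$ceiling - r$floor) *
      stats::plogis((counts$cue_prob - r$m) / r$w)
    denom <- pmax(counts$n * ps * (1 - ps), 1e-12)
    t_obs[i] <- sum((counts$k - counts$n * ps)^2 / denom)
    k_rep <- stats::rbinom(nlev, counts$n, ps)
    t_rep[i] <- sum((k_rep - counts$n * ps)^2 / denom)
  }
  mean(t_rep >= t_obs)
}

#' Posterior inference on the stimulation-induced threshold shift
#'
#' Pairs independent posterior draws of the threshold from the off and on
#' fits by a seeded random pairing and summarises the difference
#' `delta_m = m_on - m_off`. The headline quantity is
#' `prob_left_shift = P(delta_m < 0)`: the posterior probability that
#' stimulation moved the threshold leftward, i.e. toward greater
#' risk-seeking.
#'
#' @param fit_off,fit_on `psychometric_fit` objects for the two conditions.
#' @param seed Integer seed for the draw pairing.
#' @return An object of class `threshold_shift` with the paired `delta_m`
#'   draws, `prob_left_shift`, posterior mean and 90% interval, the two fit
#'   statuses, an `available` flag (FALSE when both fits are unfittable), and
#'   a `flagged` flag (TRUE when either fit is not `"ok"`).
#' @examples
#' \donttest{
#' tr <- simulate_session(seed = 2)
#' cfg <- sampler_config(n_chains = 2, n_warmup = 300, n_draws = 500)
#' sh <- threshold_shift(fit_condition(tr, "off", config = cfg),
#'                       fit_condition(tr, "on", config = cfg))
#' tidy(sh)
#' }
#' @export
threshold_shift <- function(fit_off, fit_on, seed = 1L) {
  stopifnot(inherits(fit_off, "psychometric_fit"),
            inherits(fit_on, "psychometric_fit"))
  if (fit_off$condition == fit_on$condition) {
    warning("Both fits carry the same condition label.", call. = FALSE)
  }
  available <- !(fit_off$status == "unfittable" &&
                   fit_on$status == "unfittable")
  flagged <- fit_off$status != "ok" || fit_on$status != "ok"
  out <- structure(
    list(delta_m = numeric(0), prob_left_shift = NA_real_,
         mean = NA_real_, q5 = NA_real_, q95 = NA_real_,
         status_off = fit_off$status, status_on = fit_on$status,
         available = available, flagged = flagged, seed = as.integer(seed)),
    class = "threshold_shift")
  if (!available) return(out)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  m_off <- fit_off$draws$draws$m
  m_on <- fit_on$draws$draws$m
  npair <- min(length(m_off), length(m_on))
  delta <- m_on[sample.int(length(m_on), npair)] -
    m_off[sample.int(length(m_off), npair)]
  out$delta_m <- delta
  out$prob_left_shift <- mean(delta < 0)
  out$mean <- mean(delta)
  out$q5 <- unname(stats::quantile(delta, 0.05))
  out$q95 <- unname(stats::quantile(delta, 0.95))
  out
}

#' @export
print.threshold_shift <- function(x, ...) {
  cat("<threshold_shift>\n")
  if (!x$available) {
    cat("  unavailable: both condition fits were unfittable\n")
    return(invisible(x))
  }
  cat(sprintf("  delta_m (on - off): mean %.3f, 90%% CI [%.3f, %.3f]\n",
              x$mean, x$q5, x$q95))
  cat(sprintf("  P(left shift) = %.3f\n", x$prob_left_shift))
  if (x$flagged) {
    cat(sprintf("  flagged: fit status off = '%s', on = '%s'\n",
                x$status_off, x$status_on))
  }
  invisible(x)
}

#' @rdname tidy.posterior_draws
#' @export
tidy.threshold_shift <- function(x, ...) {
  tibble::tibble(
    term = "delta_m", mean = x$mean, q5 = x$q5, q95 = x$q95,
    prob_left_shift = x$prob_left_shift,
    status_off = x$status_off, status_on = x$status_on,
    available = x$available, flagged = x$flagged)
}

# deterministic small seed derived from a master seed and a stage label
.derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 48271 + h * 9973) %% 2147483629L)
}
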