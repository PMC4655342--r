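#' Sampler configuration
#'
#' Settings for the adaptive random-walk Metropolis sampler. Proposal scales
#' adapt toward `target_accept` during warmup only (Robbins--Monro), then
#' freeze so the retained chain is Markov. The defaults (4 chains, 1000
#' warmup, 2000 retained draws) are comfortable for this 4-dimensional
#' posterior; `target_accept = 0.35` suits component-wise proposals.
#'
#' @param n_chains Number of chains (>= 2, so split-Rhat is defined).
#' @param n_warmup Warmup (adaptation) iterations per chain.
#' @param n_draws Retained draws per chain.
#' @param thin Thinning interval (>= 1).
#' @param target_accept Target acceptance rate in (0, 1).
#' @param seed Integer seed governing initialisation and all proposals.
#'
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_warmup = 1000L, n_draws = 2000L,
                           thin = 1L, target_accept = 0.35, seed = 1L) {
  n_chains <- as.integer(n_chains); n_warmup <- as.integer(n_warmup)
  n_draws <- as.integer(n_draws); thin <- as.integer(thin)
  if (n_chains < 2L) stop("`n_chains` must be at least 2.", call. = FALSE)
  if (n_draws < 1L || thin < 1L || n_warmup < 0L) {
    stop("Need n_draws >= 1, thin >= 1, n_warmup >= 0.", call. = FALSE)
  }
  if (target_accept <= 0 || target_accept >= 1) {
    stop("`target_accept` must be in (0, 1).", call. = FALSE)
  }
  structure(list(n_chains = n_chains, n_warmup = n_warmup, n_draws = n_draws,
                 thin = thin, target_accept = target_accept,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

.param_names <- c("m", "w", "floor", "ceiling")

# coarse maximum-posterior grid point on the prior box, used to initialise
.grid_init <- function(counts, prior, n_per_dim = 11L) {
  b <- prior$bounds
  axes <- lapply(seq_len(4), function(j) {
    u <- seq(0.5, n_per_dim - 0.5) / n_per_dim  # interior points only
    b[j, 1] + (b[j, 2] - b[j, 1]) * u
  })
  grid <- as.matrix(expand.grid(axes))
  lp <- .loglik_matrix(grid, counts)
  grid[which.max(lp), ]
}

# vectorised Bernoulli log likelihood over a matrix of (m, w, floor, ceiling)
.loglik_matrix <- function(theta, counts) {
  ll <- numeric(nrow(theta))
  if (nrow(counts) == 0L) return(ll)
  for (i in seq_len(nrow(counts))) {
    ps <- theta[, 3] + (theta[, 4] - theta[, 3]) *
      stats::plogis((counts$cue_prob[i] - theta[, 1]) / theta[, 2])
    k <- counts$k[i]; r <- counts$n[i] - k
    term <- (if (k > 0) k * log(ps) else 0) +
      (if (r > 0) r * log1p(-ps) else 0)
    ll <- ll + term
  }
  ll[is.nan(ll)] <- -Inf
  ll
}

#' Draw posterior samples of the psychometric parameters
#'
#' Runs a self-contained component-wise adaptive random-walk Metropolis
#' sampler on the scaled-logit transform of each parameter over its prior
#' support. Chains start from the maximum-posterior point of a coarse
#' 11^4 grid, jittered independently per chain. The sampler is fully
#' deterministic given `(counts, prior, config)`.
#'
#' @param counts Per-level choice counts ([choice_counts()]); zero rows give
#'   draws from the prior.
#' @param prior A [prior_spec()].
#' @param config A [sampler_config()].
#'
#' @return An object of class `posterior_draws`: a list with `draws` (a tibble
#'   with columns `chain`, `iter`, `m`, `w`, `floor`, `ceiling`, `log_post`,
#'   `deviance`), `accept_rate`, `scales` (per chain, frozen post-warmup),
#'   `rhat`, `ess`, `degenerate_data` flag, and the inputs used.
#' @examples
#' cc <- tibble::tibble(cue_prob = c(0.1, 0.5, 0.9), k = c(2, 16, 30),
#'                      n = c(32, 32, 32))
#' fit <- sample_posterior(cc, config = sampler_config(n_draws = 200))
#' tidy(fit)
#' @export
sample_posterior <- function(counts, prior = prior_spec(),
                             config = sampler_config()) {
  .check_counts(counts)
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "sampler_config"))
  degenerate <- nrow(counts) > 0L &&
    all(counts$k == 0L | counts$k == counts$n)
  if (degenerate) {
    warning("All levels are degenerate (k = 0 or k = n); ",
            "the posterior is dominated by the prior tails.", call. = FALSE)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  b <- prior$bounds
  theta0 <- .grid_init(counts, prior)
  # transform to the unconstrained scale
  z0 <- stats::qlogis((theta0 - b[, 1]) / (b[, 2] - b[, 1]))
  p <- counts$cue_prob; k <- as.numeric(counts$k); n <- as.numeric(counts$n)
  lp_const <- -sum(log(b[, 2] - b[, 1]))

  chains <- vector("list", config$n_chains)
  accept <- matrix(NA_real_, config$n_chains, 4,
                   dimnames = list(NULL, .param_names))
  scales <- matrix(NA_real_, config$n_chains, 4,
                   dimnames = list(NULL, .param_names))
  scales_final <- scales
  for (ch in seq_len(config$n_chains)) {
    z <- NULL
    for (try in seq_len(100L)) {
      zj <- z0 + stats::rnorm(4, 0, 0.2)
      th <- b[, 1] + (b[, 2] - b[, 1]) * stats::plogis(zj)
      if (is.finite(.loglik_matrix(matrix(th, 1), counts))) { z <- zj; break }
    }
    if (is.null(z)) {
      stop("Could not find a finite initial log posterior after 100 jittered ",
           "restarts.", call. = FALSE)
    }
    res <- rwm_chain(p, k, n, b, z, config$n_warmup, config$n_draws,
                     config$thin, config$target_accept, rep(log(0.5), 4))
    dr <- res$draws
    colnames(dr) <- .param_names
    chains[[ch]] <- tibble::as_tibble(dr) |>
      dplyr::mutate(chain = ch, iter = dplyr::row_number(),
                    log_post = res$loglik + lp_const,
                    deviance = -2 * res$loglik, .before = 1) |>
      dplyr::relocate("chain", "iter")
    accept[ch, ] <- res$accept_rate
    scales[ch, ] <- res$scales_postwarmup
    scales_final[ch, ] <- res$scales_final
  }
  draws <- dplyr::bind_rows(chains) |>
    dplyr::relocate("chain", "iter", dplyr::all_of(.param_names),
                    "log_post", "deviance")

  out <- structure(
    list(draws = draws,
         accept_rate = colMeans(accept),
         accept_rate_by_chain = accept,
         scales = scales, scales_final = scales_final,
         degenerate_data = degenerate,
         counts = counts, prior = prior, config = config),
    class = "posterior_draws")
  dg <- diagnostics(out)
  out$rhat <- dg$rhat
  out$ess <- dg$ess
  out$converged <- dg$converged
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d chains x %d draws\n",
              x$config$n_chains, x$config$n_draws))
  print(tidy(x), ...)
  if (!isTRUE(x$converged)) cat("  warning: convergence diagnostics flagged\n")
  invisible(x)
}

.chain_matrix <- function(x, param) {
  matrix(x$draws[[param]], ncol = max(x$draws$chain))
}

# split-Rhat (each chain halved, potential scale reduction factor)
.split_rhat <- function(mat) {
  n2 <- floor(nrow(mat) / 2)
  halves <- cbind(mat[seq_len(n2), , drop = FALSE],
                  mat[n2 + seq_len(n2), , drop = FALSE])
  w <- mean(apply(halves, 2, stats::var))
  bn <- stats::var(colMeans(halves))  # B/n
  if (w == 0) return(if (bn == 0) 1 else Inf)
  sqrt((n2 - 1) / n2 + bn / w)
}

# multi-chain effective sample size via pooled autocovariance with Geyer's
# initial positive-sequence truncation
.ess <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4L) return(NA_real_)
  acovs <- apply(mat, 2, function(x)
    stats::acf(x, lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  mean_acov <- rowMeans(acovs)
  w <- mean_acov[1] * n / (n - 1)
  bn <- if (m > 1) stats::var(colMeans(mat)) else 0
  var_plus <- (n - 1) / n * w + bn
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (w - mean_acov) / var_plus  # rho[1] is lag 0
  # sum consecutive pairs while positive
  s <- 0
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(m * n / (1 + 2 * s), 1e-8)
}

#' Convergence diagnostics for posterior draws
#'
#' Split-Rhat and effective sample size per parameter, plus per-parameter
#' acceptance rates. Convergence is flagged as failed when any Rhat exceeds
#' 1.05 or any effective sample size falls below 400.
#'
#' @param x A `posterior_draws` object (>= 2 chains).
#' @return A list with numeric vectors `rhat`, `ess`, `accept_rate` (named by
#'   parameter) and a logical `converged`.
#' @export
diagnostics <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  if (max(x$draws$chain) < 2L) {
    stop("Diagnostics require at least 2 chains; rerun with n_chains >= 2.",
         call. = FALSE)
  }
  rhat <- vapply(.param_names, function(pp) .split_rhat(.chain_matrix(x, pp)),
                 numeric(1))
  ess <- vapply(.param_names, function(pp) .ess(.chain_matrix(x, pp)),
                numeric(1))
  list(rhat = rhat, ess = ess, accept_rate = x$accept_rate,
       converged = all(rhat <= 1.05, na.rm = TRUE) &&
         all(ess >= 400, na.rm = TRUE))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summarise posterior marginals
#'
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean, median, sd,
#'   5% and 95% quantiles, split-Rhat, and effective sample size.
#' @export
tidy.posterior_draws <- function(x, ...) {
  purrr::map_dfr(.param_names, function(pp) {
    v <- x$draws[[pp]]
    tibble::tibble(
      term = pp, mean = mean(v), median = stats::median(v),
      sd = stats::sd(v),
      q5 = unname(stats::quantile(v, 0.05)),
      q95 = unname(stats::quantile(v, 0.95)),
      rhat = unname(x$rhat[pp]), ess = unname(x$ess[pp]))
  })
}

#' One-row sampler summary
#'
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return A tibble with chain/draw counts, worst Rhat, smallest effective
#'   sample size, mean acceptance rate, and the convergence flag.
#' @export
glance.posterior_draws <- function(x, ...) {
  tibble::tibble(
    n_chains = x$config$n_chains, n_draws = x$config$n_draws,
    max_rhat = max(x$rhat), min_ess = min(x$ess),
    mean_accept = mean(x$accept_rate), converged = x$converged)
}

#' Write posterior draws to a flat CSV
#'
#' Columns `chain,iter,m,w,floor,ceiling,log_post,deviance`.
#'
#' @param x A `posterior_draws` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(x, path) {
  stopifnot(inherits(x, "posterior_draws"))
  readr::write_csv(x$draws, path)
  invisible(path)
}
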