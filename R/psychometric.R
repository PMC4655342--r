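#' Four-parameter logistic psychometric function
#'
#' Maps a cued reward probability to the probability of choosing the risky
#' option:
#' \deqn{\psi(p) = \mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor})
#'   \,/\, (1 + e^{-(p - m)/w}).}
#' The threshold `m` locates the midpoint between the asymptotes; the scale
#' `w` sets the steepness (smaller is steeper); `floor` and `ceiling` are
#' probability-independent biases toward the risky and safe option.
#'
#' @param params A [psychometric_params()].
#' @param p Vector of reward probabilities in \[0, 1\].
#'
#' @return A numeric vector of choice probabilities, strictly inside
#'   `(floor, ceiling)`.
#' @examples
#' psi(psychometric_params(0.5, 0.1), c(0.1, 0.5, 0.9))
#' @export
psi <- function(params, p) {
  stopifnot(inherits(params, "psychometric_params"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("`p` must lie in [0, 1].", call. = FALSE)
  }
  params$floor + (params$ceiling - params$floor) *
    stats::plogis((p - params$m) / params$w)
}

#' Independent uniform priors for the psychometric parameters
#'
#' Box priors over `(m, w, floor, ceiling)`. The defaults are weakly
#' informative: the threshold may sit beyond the tested cue-probability range
#' (shifts past 0.1 or 0.9 stay identifiable), the scale is bounded away from
#' a degenerate step, and `floor < 0.5 < ceiling` keeps the two asymptotes
#' identified.
#'
#' @param m_bounds,w_bounds,floor_bounds,ceiling_bounds Length-2 numeric
#'   vectors giving the lower and upper bound of each uniform prior.
#'
#' @return An object of class `prior_spec` holding a 4 x 2 bounds matrix.
#' @examples
#' prior_spec()
#' @export
prior_spec <- function(m_bounds = c(-0.25, 1.25),
                       w_bounds = c(0.01, 1),
                       floor_bounds = c(0, 0.5),
                       ceiling_bounds = c(0.5, 1)) {
  b <- rbind(m = m_bounds, w = w_bounds, floor = floor_bounds,
             ceiling = ceiling_bounds)
  colnames(b) <- c("lower", "upper")
  if (any(b[, 2] <= b[, 1])) {
    stop("Each prior upper bound must exceed its lower bound.", call. = FALSE)
  }
  if (b["w", 1] <= 0) stop("The `w` prior must have a positive lower bound.",
                           call. = FALSE)
  if (b["floor", 1] < 0 || b["ceiling", 2] > 1 ||
      b["floor", 2] > b["ceiling", 1]) {
    stop("Prior supports must satisfy 0 <= floor < ceiling <= 1.",
         call. = FALSE)
  }
  structure(list(bounds = b), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> independent uniforms\n")
  for (nm in rownames(x$bounds)) {
    cat(sprintf("  %-8s ~ U(%g, %g)\n", nm, x$bounds[nm, 1], x$bounds[nm, 2]))
  }
  invisible(x)
}

.in_support <- function(params, prior) {
  th <- c(params$m, params$w, params$floor, params$ceiling)
  all(th >= prior$bounds[, 1] & th <= prior$bounds[, 2]) &&
    params$floor < params$ceiling
}

#' Log prior density
#'
#' Natural-log density of the independent uniform prior; `-Inf` outside the
#' support.
#'
#' @param params A [psychometric_params()].
#' @param prior A [prior_spec()].
#' @return A scalar log density.
#' @export
log_prior <- function(params, prior = prior_spec()) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!.in_support(params, prior)) return(-Inf)
  -sum(log(prior$bounds[, 2] - prior$bounds[, 1]))
}

#' Bernoulli log likelihood of per-level choice counts
#'
#' Each responded trial is an independent Bernoulli draw with success
#' probability \eqn{\psi(p_\ell)}, so the log likelihood over levels is
#' \eqn{\sum_\ell k_\ell \log\psi_\ell + (n_\ell - k_\ell)\log(1-\psi_\ell)}.
#' Omissions never enter (they carry no choice). When \eqn{\psi} underflows to
#' 0 or 1 against discordant counts the function returns `-Inf` rather than
#' `NaN`.
#'
#' @param params A [psychometric_params()].
#' @param counts A tibble with columns `cue_prob`, `k`, `n` as produced by
#'   [choice_counts()]; may have zero rows (log likelihood 0).
#' @return A scalar log likelihood.
#' @examples
#' cc <- tibble::tibble(cue_prob = 0.5, k = 1, n = 1)
#' log_likelihood(psychometric_params(0.5, 0.1), cc)  # log(0.5)
#' @export
log_likelihood <- function(params, counts) {
  .check_counts(counts)
  if (nrow(counts) == 0L) return(0)
  ps <- psi(params, counts$cue_prob)
  ll <- sum(ifelse(counts$k > 0, counts$k * log(ps), 0) +
              ifelse(counts$n - counts$k > 0,
                     (counts$n - counts$k) * log1p(-ps), 0))
  if (is.nan(ll)) -Inf else ll
}

.check_counts <- function(counts) {
  need <- c("cue_prob", "k", "n")
  if (!all(need %in% names(counts))) {
    stop("Choice counts need columns cue_prob, k, n.", call. = FALSE)
  }
  if (nrow(counts)) {
    if (any(counts$k < 0 | counts$k > counts$n)) {
      stop("Counts must satisfy 0 <= k <= n.", call. = FALSE)
    }
    if (any(counts$cue_prob <= 0 | counts$cue_prob >= 1) ||
        anyDuplicated(counts$cue_prob)) {
      stop("Cue probabilities must be distinct and in (0, 1).", call. = FALSE)
    }
  }
  invisible(counts)
}

#' Log posterior density
#'
#' `log_likelihood + log_prior`; `-Inf` outside the prior support.
#'
#' @inheritParams log_likelihood
#' @param prior A [prior_spec()].
#' @return A scalar log density.
#' @export
log_posterior <- function(params, counts, prior = prior_spec()) {
  lp <- log_prior(params, prior)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(params, counts)
}

#' Deviance of a parameter set
#'
#' `-2 * log_likelihood`; used to weight plotted posterior curves by fit
#' quality.
#'
#' @inheritParams log_likelihood
#' @return A scalar deviance (non-negative for Bernoulli data).
#' @export
deviance_psy <- function(params, counts) {
  -2 * log_likelihood(params, counts)
}
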