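# ---- independent oracles used across the suite ----

# two-sided mid-P by explicit enumeration with lchoose arithmetic
midp_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(0.5)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(n - r1, c1 - xs) - lchoose(n, c1)
  pr <- exp(logp)
  p_obs <- pr[xs == a]
  eq <- abs(pr - p_obs) <= 1e-12 * pmax(pr, p_obs)
  sum(pr[pr < p_obs & !eq]) + 0.5 * sum(pr[eq])
}

# per-trial Bernoulli product log likelihood (expands counts to trials)
loglik_per_trial <- function(params, counts) {
  tot <- 0
  for (i in seq_len(nrow(counts))) {
    ps <- psi(params, counts$cue_prob[i])
    outcomes <- c(rep(1, counts$k[i]), rep(0, counts$n[i] - counts$k[i]))
    tot <- tot + sum(stats::dbinom(outcomes, 1, ps, log = TRUE))
  }
  tot
}

# ---- dense-grid posterior integration oracle ----
# Two-stage midpoint-rule integration over the uniform prior box: a coarse
# pass over the whole box locates the high-posterior region, then a fine
# grid over that region yields per-parameter marginal pmfs, means and
# quantiles. Everything here is plain R, independent of the sampler.
grid_marginals <- function(counts, prior, n_coarse = 25L, n_fine = 61L) {
  b <- prior$bounds
  axes_on <- function(lims, n) {
    lapply(seq_len(4), function(j) {
      lims[j, 1] + (lims[j, 2] - lims[j, 1]) * (seq_len(n) - 0.5) / n
    })
  }

  pass <- function(axes) {
    nw <- length(axes[[2]]); nf <- length(axes[[3]]); nc <- length(axes[[4]])
    g <- expand.grid(w = axes[[2]], fl = axes[[3]], ce = axes[[4]])
    bad <- g$fl >= g$ce
    slice_ll <- function(mv) {
      ll <- numeric(nrow(g))
      for (i in seq_len(nrow(counts))) {
        ps <- g$fl + (g$ce - g$fl) *
          stats::plogis((counts$cue_prob[i] - mv) / g$w)
        k <- counts$k[i]; r <- counts$n[i] - k
        ll <- ll + (if (k > 0) k * log(ps) else 0) +
          (if (r > 0) r * log1p(-ps) else 0)
      }
      ll[is.nan(ll) | bad] <- -Inf
      ll
    }
    gmax <- max(vapply(axes[[1]], function(mv) max(slice_ll(mv)), numeric(1)))
    marg <- list(numeric(length(axes[[1]])), numeric(nw), numeric(nf),
                 numeric(nc))
    for (j in seq_along(axes[[1]])) {
      v <- exp(slice_ll(axes[[1]][j]) - gmax)
      arr <- array(v, c(nw, nf, nc))
      marg[[1]][j] <- sum(v)
      marg[[2]] <- marg[[2]] + rowSums(arr, dims = 1)
      tmp <- colSums(arr)                       # nf x nc
      marg[[3]] <- marg[[3]] + rowSums(tmp)
      marg[[4]] <- marg[[4]] + colSums(tmp)
    }
    tot <- sum(marg[[1]])
    lapply(marg, function(x) x / tot)
  }

  coarse <- pass(axes_on(b, n_coarse))
  co_axes <- axes_on(b, n_coarse)
  lims <- b
  for (j in seq_len(4)) {
    keep <- which(coarse[[j]] > 1e-10)
    lo <- max(min(keep) - 2L, 1L); hi <- min(max(keep) + 2L, n_coarse)
    half <- (b[j, 2] - b[j, 1]) / (2 * n_coarse)
    lims[j, ] <- c(co_axes[[j]][lo] - half, co_axes[[j]][hi] + half)
  }
  axes <- axes_on(lims, n_fine)
  marg <- pass(axes)

  stat <- function(ax, p) {
    cm <- cumsum(p)
    list(mean = sum(ax * p),
         q5 = ax[which(cm >= 0.05)[1]],
         q95 = ax[which(cm >= 0.95)[1]])
  }
  names(axes) <- names(marg) <- c("m", "w", "floor", "ceiling")
  list(axes = axes, marginals = marg,
       stats = purrr::map2(axes, marg, stat))
}

# total variation between a grid pmf and binned posterior draws, on the
# grid's own cells
tv_against_draws <- function(axis, pmf, draws) {
  mids <- (axis[-1] + axis[-length(axis)]) / 2
  bins <- cut(draws, breaks = c(-Inf, mids, Inf), labels = FALSE)
  emp <- tabulate(bins, nbins = length(axis)) / length(draws)
  0.5 * sum(abs(emp - pmf))
}
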