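#' Psychometric curves with posterior uncertainty, by condition
#'
#' Draws the posterior-mean psychometric function for each condition (black
#' for off, red for on), a sample of posterior curves rendered with opacity
#' decreasing in their deviance (better-fitting draws are more opaque), the
#' observed per-level risky-choice proportions as circles, and the per-level
#' mid-P significance asterisks along the top.
#'
#' @param fit_off,fit_on `psychometric_fit` objects.
#' @param trials The trial tibble the fits came from (for observed
#'   proportions and mid-P stars); omit to plot curves only.
#' @param n_curves Number of posterior sample curves per condition.
#' @param seed Seed for the curve subsample.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(fit_off, fit_on, trials = NULL,
                              n_curves = 20L, seed = 1L) {
  stopifnot(inherits(fit_off, "psychometric_fit"),
            inherits(fit_on, "psychometric_fit"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  pgrid <- seq(0.01, 0.99, length.out = 101)

  curve_df <- function(fit, label) {
    d <- fit$draws$draws
    idx <- sample.int(nrow(d), min(n_curves, nrow(d)))
    samp <- purrr::map_dfr(seq_along(idx), function(i) {
      r <- d[idx[i], ]
      tibble::tibble(
        condition = label, curve = i, cue_prob = pgrid,
        prob_risky = r$floor + (r$ceiling - r$floor) *
          stats::plogis((pgrid - r$m) / r$w),
        deviance = r$deviance)
    })
    # opacity falls off with deviance relative to the best sampled draw
    dev0 <- min(samp$deviance)
    samp$alpha <- 0.5 * exp(-(samp$deviance - dev0) / 10)
    samp
  }
  mean_df <- function(fit, label) {
    s <- tidy(fit$draws)
    pm <- stats::setNames(s$mean, s$term)
    tibble::tibble(
      condition = label, cue_prob = pgrid,
      prob_risky = pm["floor"] + (pm["ceiling"] - pm["floor"]) *
        stats::plogis((pgrid - pm["m"]) / pm["w"]))
  }
  curves <- dplyr::bind_rows(curve_df(fit_off, "off"), curve_df(fit_on, "on"))
  means <- dplyr::bind_rows(mean_df(fit_off, "off"), mean_df(fit_on, "on"))

  gg <- ggplot2::ggplot(means,
                        ggplot2::aes(x = .data$cue_prob, y = .data$prob_risky,
                                     colour = .data$condition)) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(group = interaction(.data$condition, .data$curve),
                   alpha = .data$alpha),
      linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::scale_colour_manual(values = c(off = "black", on = "red")) +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::labs(x = "cued reward probability",
                  y = "P(choose risky)", colour = NULL) +
    ggplot2::theme_minimal()

  if (!is.null(trials)) {
    obs <- summarize_session(trials) |>
      dplyr::filter(.data$n_responded > 0)
    gg <- gg + ggplot2::geom_point(
      data = obs,
      ggplot2::aes(y = .data$prop_risky, size = .data$n_responded),
      shape = 1, show.legend = FALSE)
    stars <- per_level_tests(trials) |>
      dplyr::filter(!is.na(.data$tier), .data$tier != "")
    if (nrow(stars)) {
      gg <- gg + ggplot2::geom_text(
        data = stars,
        ggplot2::aes(x = .data$cue_prob, label = .data$tier),
        y = 1.04, colour = "grey30", inherit.aes = FALSE)
    }
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Marginal posterior densities of the psychometric parameters
#'
#' @param object A `posterior_draws` object.
#' @param ... Unused.
#' @return A ggplot object with one panel per parameter.
#' @export
autoplot.posterior_draws <- function(object, ...) {
  long <- object$draws |>
    tidyr::pivot_longer(dplyr::all_of(.param_names),
                        names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Posterior distribution of the threshold shift
#'
#' @param object A `threshold_shift` object.
#' @param ... Unused.
#' @return A ggplot object showing the density of `delta_m = m_on - m_off`
#'   with the 90% interval and zero marked.
#' @export
autoplot.threshold_shift <- function(object, ...) {
  if (!object$available) stop("Shift unavailable: both fits unfittable.",
                              call. = FALSE)
  df <- tibble::tibble(delta_m = object$delta_m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_m)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(object$q5, object$q95),
                        colour = "red", linetype = 3) +
    ggplot2::labs(
      x = expression(Delta * m == m[on] - m[off]),
      y = "posterior density",
      subtitle = sprintf("P(left shift) = %.3f", object$prob_left_shift)) +
    ggplot2::theme_minimal()
}
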