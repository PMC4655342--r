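#' Two-sided mid-P Fisher exact test for a 2x2 table
#'
#' Enumerates the hypergeometric distribution over every table consistent
#' with the observed margins. The two-sided mid-P value sums the point
#' probabilities strictly below the observed table's and adds half the
#' probability of the tables whose point probability equals it (to relative
#' tolerance 1e-12). The mid-P construction halves the weight of the observed
#' outcome class, removing the conservatism of the ordinary exact test while
#' keeping its exactness under fixed margins.
#'
#' @param x A 2x2 matrix of counts, rows = condition (off/on), columns =
#'   choice (risky/safe), or a length-4 vector `c(a, b, c, d)` read row-wise.
#' @return A list of class `fisher_midp` with elements `midp`, `degenerate`
#'   (TRUE when a zero margin leaves a single possible table; `midp` is then
#'   0.5), and `table`.
#' @examples
#' fisher_midp(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))$midp
#' @export
fisher_midp <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("`x` must be 2x2.", call. = FALSE)
    tab <- x
  } else if (length(x) == 4L) {
    tab <- matrix(as.numeric(x), 2L, 2L, byrow = TRUE)
  } else {
    stop("`x` must be a 2x2 matrix or a length-4 count vector.", call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("Counts must be non-negative integers.", call. = FALSE)
  }
  n <- sum(tab)
  if (n == 0) stop("The table is empty.", call. = FALSE)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    return(structure(list(midp = 0.5, degenerate = TRUE, table = tab),
                     class = "fisher_midp"))
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  equal <- abs(pr - p_obs) <= 1e-12 * pmax(pr, p_obs)
  midp <- sum(pr[pr < p_obs & !equal]) + 0.5 * sum(pr[equal])
  structure(list(midp = min(max(midp, 0), 1), degenerate = FALSE,
                 table = tab),
            class = "fisher_midp")
}

#' @export
print.fisher_midp <- function(x, ...) {
  cat(sprintf("<fisher_midp> two-sided mid-P = %.4g%s\n", x$midp,
              if (x$degenerate) " (degenerate margins)" else ""))
  invisible(x)
}

.sig_tier <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

#' Per-level mid-P tests of the stimulation effect on choice
#'
#' For each cue probability, tests whether the risky/safe split differs
#' between the off and on conditions with the two-sided mid-P Fisher exact
#' test. Omissions are excluded. Significance tiers mirror the usual
#' asterisk convention (strict inequalities at 0.05, 0.01, 0.001).
#'
#' @param trials A trial tibble spanning both conditions.
#' @return A tibble with one row per cue probability: the four cell counts,
#'   `midp`, `tier`, `degenerate`, and `testable` (FALSE when a level has no
#'   responded trials in one condition).
#' @examples
#' per_level_tests(simulate_session(seed = 1))
#' @export
per_level_tests <- function(trials) {
  .check_trials(trials)
  if (length(unique(trials$condition)) < 2L) {
    stop("Trials must span both conditions.", call. = FALSE)
  }
  resp <- dplyr::filter(trials, .data$choice != "omit")
  levels_all <- sort(unique(trials$cue_prob))
  purrr::map_dfr(levels_all, function(pl) {
    sub <- dplyr::filter(resp, .data$cue_prob == pl)
    cell <- function(cond, ch) {
      sum(sub$condition == cond & sub$choice == ch)
    }
    a <- cell("off", "risky"); b <- cell("off", "safe")
    cc <- cell("on", "risky"); d <- cell("on", "safe")
    testable <- (a + b) > 0 && (cc + d) > 0
    if (testable) {
      ft <- fisher_midp(c(a, b, cc, d))
      midp <- ft$midp; degen <- ft$degenerate
    } else {
      midp <- NA_real_; degen <- NA
    }
    tibble::tibble(cue_prob = pl, off_risky = a, off_safe = b,
                   on_risky = cc, on_safe = d,
                   midp = midp, tier = .sig_tier(midp),
                   degenerate = degen, testable = testable)
  })
}

# terms of the full three-way factorial, in display order
.anova_terms <- c("condition", "choice", "cue_prob",
                  "condition:choice", "condition:cue_prob",
                  "choice:cue_prob", "condition:choice:cue_prob")

.term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Factorial ANOVA on reaction times
#'
#' Fits a fixed-effects full-factorial linear model of reaction time on
#' stimulation condition, choice, and cue probability (all treated as
#' categorical factors) and reports Type II sums of squares: each term is
#' tested against the model containing every other term that does not include
#' it, respecting marginality. Empty cells are tolerated — aliased columns
#' drop out and the degrees of freedom shrink accordingly. Omissions carry no
#' reaction time and are excluded.
#'
#' @param trials A trial tibble.
#' @return A tibble of class `rt_anova` with one row per effect plus a
#'   `Residuals` row: `term`, `df`, `sumsq`, `meansq`, `statistic` (F), and
#'   `p.value`.
#' @examples
#' rt_anova(simulate_session(seed = 1))
#' @export
rt_anova <- function(trials) {
  .check_trials(trials)
  dat <- trials |>
    dplyr::filter(.data$choice != "omit", !is.na(.data$rt_ms)) |>
    dplyr::transmute(
      rt = .data$rt_ms,
      condition = factor(.data$condition),
      choice = factor(.data$choice),
      cue_prob = factor(.data$cue_prob))
  if (nlevels(dat$condition) < 2L || nlevels(dat$choice) < 2L ||
      nlevels(dat$cue_prob) < 2L) {
    stop("The ANOVA needs both conditions, both choices, and at least two ",
         "cue probabilities among responded trials.", call. = FALSE)
  }

  fit_rss <- function(terms) {
    f <- if (length(terms)) {
      stats::reformulate(terms, response = "rt")
    } else rt ~ 1
    fit <- stats::lm(f, data = dat)
    list(rss = sum(stats::residuals(fit)^2), df = stats::df.residual(fit))
  }

  full <- fit_rss(.anova_terms)
  if (full$df <= 0) {
    stop("No residual degrees of freedom: the design has no replication.",
         call. = FALSE)
  }
  tot <- fit_rss(character(0))
  constant_rt <- tot$rss <= 1e-10 * max(1, mean(dat$rt)^2)
  mse <- full$rss / full$df

  rows <- purrr::map_dfr(.anova_terms, function(term) {
    fct <- .term_factors(term)
    others <- .anova_terms[!vapply(
      .anova_terms, function(tt) all(fct %in% .term_factors(tt)), logical(1))]
    m0 <- fit_rss(others)
    m1 <- fit_rss(c(others, term))
    ss <- max(m0$rss - m1$rss, 0)
    df <- m0$df - m1$df
    if (constant_rt) {
      tibble::tibble(term = term, df = df, sumsq = 0, meansq = 0,
                     statistic = 0, p.value = 1)
    } else if (df <= 0) {
      tibble::tibble(term = term, df = 0L, sumsq = 0, meansq = NA_real_,
                     statistic = NA_real_, p.value = NA_real_)
    } else {
      f <- (ss / df) / mse
      tibble::tibble(term = term, df = df, sumsq = ss, meansq = ss / df,
                     statistic = f,
                     p.value = stats::pf(f, df, full$df, lower.tail = FALSE))
    }
  })
  out <- dplyr::bind_rows(
    rows,
    tibble::tibble(term = "Residuals", df = full$df,
                   sumsq = if (constant_rt) 0 else full$rss,
                   meansq = if (constant_rt) 0 else mse,
                   statistic = NA_real_, p.value = NA_real_))
  class(out) <- c("rt_anova", class(out))
  out
}
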