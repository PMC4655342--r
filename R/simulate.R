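#' Simulate a blocked on/off risky-choice session
#'
#' Generates one complete trial log under a [session_design()] and an
#' [agent_params()] agent. Within each block every cue probability appears
#' equally often in a seeded shuffled order; the condition is "on" exactly in
#' the design's stimulation blocks. On each trial an independent omission draw
#' is made first; responded trials then draw the risky/safe choice from the
#' condition's psychometric value at the cue probability, the risky outcome
#' from a Bernoulli at the cued probability, and the reaction time from a
#' log-normal law truncated at the deadline. Identical
#' `(design, agent, seed)` yields an identical trial log.
#'
#' @param design A [session_design()].
#' @param agent An [agent_params()].
#' @param seed Integer seed; all randomness in the session flows from it.
#'
#' @return A tibble with one row per trial and columns `block`, `trial`
#'   (1-based within block), `condition` (`"off"`/`"on"`), `cue_prob`,
#'   `choice` (`"risky"`/`"safe"`/`"omit"`), `outcome` (points), and `rt_ms`
#'   (`NA` for omissions).
#' @examples
#' trials <- simulate_session(seed = 1)
#' dplyr::count(trials, condition, choice)
#' @export
simulate_session <- function(design = session_design(),
                             agent = agent_params(),
                             seed = 1L) {
  stopifnot(inherits(design, "session_design"), inherits(agent, "agent_params"))
  n_levels <- length(design$probability_levels)
  if (design$trials_per_block %% n_levels != 0L) {
    stop("`trials_per_block` (", design$trials_per_block,
         ") must be divisible by the number of probability levels (",
         n_levels, ") for a balanced block.", call. = FALSE)
  }
  reps <- design$trials_per_block %/% n_levels

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  blocks <- purrr::map(seq_len(design$n_blocks), function(b) {
    on <- b %in% design$stim_blocks
    pp <- if (on) agent$params_on else agent$params_off
    cue <- sample(rep(design$probability_levels, reps))
    nt <- design$trials_per_block
    omitted <- stats::runif(nt) < agent$omission_rate
    risky <- stats::runif(nt) < psi(pp, cue)
    won <- stats::runif(nt) < cue
    choice <- ifelse(omitted, "omit", ifelse(risky, "risky", "safe"))
    outcome <- dplyr::case_when(
      choice == "omit" ~ 0,
      choice == "safe" ~ design$safe_points,
      won ~ design$risky_win_points,
      .default = design$risky_loss_points
    )
    loc <- if (on) agent$rt_location_on else agent$rt_location_off
    # inverse-CDF draw from the log-normal truncated at the deadline
    u <- stats::runif(nt) * stats::plnorm(design$deadline_ms, loc, agent$rt_scale)
    rt <- stats::qlnorm(u, loc, agent$rt_scale)
    tibble::tibble(
      block = b,
      trial = seq_len(nt),
      condition = if (on) "on" else "off",
      cue_prob = cue,
      choice = choice,
      outcome = outcome,
      rt_ms = ifelse(omitted, NA_real_, rt)
    )
  })
  dplyr::bind_rows(blocks)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

.check_trials <- function(trials, call = sys.call(-1)) {
  need <- c("block", "trial", "condition", "cue_prob", "choice", "outcome",
            "rt_ms")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("Trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("Trial table is empty.", call. = FALSE)
  bad_cond <- setdiff(unique(trials$condition), c("off", "on"))
  if (length(bad_cond)) {
    stop("Unknown condition label(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  bad_choice <- setdiff(unique(trials$choice), c("risky", "safe", "omit"))
  if (length(bad_choice)) {
    stop("Unknown choice label(s): ", paste(bad_choice, collapse = ", "),
         call. = FALSE)
  }
  invisible(trials)
}

#' Tabulate choices per condition and cue probability
#'
#' Counts risky, safe, and omitted trials for each stimulation condition and
#' cue probability, with the proportion of risky choices among responded
#' trials (omissions are non-choices and are excluded from the proportion).
#'
#' @param trials A trial tibble as produced by [simulate_session()] or
#'   [read_trials()].
#'
#' @return A tibble with columns `condition`, `cue_prob`, `n_risky`, `n_safe`,
#'   `n_omit`, `n_responded`, `prop_risky`.
#' @examples
#' summarize_session(simulate_session(seed = 1))
#' @export
summarize_session <- function(trials) {
  .check_trials(trials)
  trials |>
    dplyr::count(.data$condition, .data$cue_prob, .data$choice) |>
    tidyr::pivot_wider(names_from = "choice", values_from = "n",
                       values_fill = 0L) |>
    .ensure_cols(c("risky", "safe", "omit")) |>
    dplyr::transmute(
      .data$condition, .data$cue_prob,
      n_risky = .data$risky, n_safe = .data$safe, n_omit = .data$omit,
      n_responded = .data$risky + .data$safe,
      prop_risky = ifelse(.data$n_responded > 0,
                          .data$risky / .data$n_responded, NA_real_)
    ) |>
    dplyr::arrange(.data$condition, .data$cue_prob)
}

.ensure_cols <- function(df, cols) {
  for (cl in setdiff(cols, names(df))) df[[cl]] <- 0L
  df
}

#' Aggregate responded trials of one condition into per-level counts
#'
#' Builds the per-level binomial dataset the psychometric likelihood consumes:
#' for each cue probability, the number of risky choices `k` out of `n`
#' responded trials. Omissions are excluded.
#'
#' @param trials A trial tibble.
#' @param condition Which condition to keep, `"off"` or `"on"`.
#'
#' @return A tibble with columns `cue_prob`, `k`, `n`, sorted by `cue_prob`.
#' @examples
#' choice_counts(simulate_session(seed = 1), "off")
#' @export
choice_counts <- function(trials, condition = c("off", "on")) {
  condition <- match.arg(condition)
  .check_trials(trials)
  trials |>
    dplyr::filter(.data$condition == !!condition, .data$choice != "omit") |>
    dplyr::summarise(k = sum(.data$choice == "risky"), n = dplyr::n(),
                     .by = "cue_prob") |>
    dplyr::arrange(.data$cue_prob)
}
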