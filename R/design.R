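#' Describe the block structure of a risky-choice session
#'
#' A session design is an immutable description of the task: how many blocks
#' are run, how many trials each contains, which blocks carry stimulation,
#' which cued reward probabilities appear, the point values at stake, and the
#' response deadline. The default instance is the blocked on/off design this
#' package analyses: 960 trials in six blocks of 160, stimulation delivered
#' during blocks 3 and 5, cue probabilities 0.1--0.9, a risky outcome of 50 or
#' 0 points against a certain 10 points, and a 1 s response deadline.
#'
#' @param n_blocks Number of blocks (>= 1).
#' @param trials_per_block Trials per block (>= 1); must be divisible by the
#'   number of probability levels so each block is balanced.
#' @param stim_blocks Integer vector of 1-based block indices run with
#'   stimulation on.
#' @param probability_levels Strictly increasing cued reward probabilities,
#'   each in (0, 1).
#' @param risky_win_points,risky_loss_points,safe_points Point outcomes for a
#'   rewarded risky choice, an unrewarded risky choice, and a safe choice.
#' @param deadline_ms Response deadline in milliseconds.
#'
#' @return An object of class `session_design`.
#' @examples
#' session_design()
#' @export
session_design <- function(n_blocks = 6L,
                           trials_per_block = 160L,
                           stim_blocks = c(3L, 5L),
                           probability_levels = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           risky_win_points = 50,
                           risky_loss_points = 0,
                           safe_points = 10,
                           deadline_ms = 1000) {
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  stim_blocks <- as.integer(stim_blocks)
  if (n_blocks < 1L) stop("`n_blocks` must be at least 1.", call. = FALSE)
  if (trials_per_block < 1L) stop("`trials_per_block` must be at least 1.", call. = FALSE)
  if (length(stim_blocks) && (anyNA(stim_blocks) ||
      any(stim_blocks < 1L | stim_blocks > n_blocks))) {
    stop("`stim_blocks` must be block indices in 1..n_blocks.", call. = FALSE)
  }
  if (anyDuplicated(stim_blocks)) {
    stop("`stim_blocks` must not contain duplicates.", call. = FALSE)
  }
  if (length(probability_levels) < 1L ||
      any(probability_levels <= 0 | probability_levels >= 1) ||
      is.unsorted(probability_levels, strictly = TRUE)) {
    stop("`probability_levels` must be strictly increasing and in (0, 1).",
         call. = FALSE)
  }
  pts <- c(risky_win_points, risky_loss_points, safe_points)
  if (any(pts < 0)) stop("Point values must be non-negative.", call. = FALSE)
  if (deadline_ms <= 0) stop("`deadline_ms` must be positive.", call. = FALSE)
  structure(
    list(
      n_blocks = n_blocks,
      trials_per_block = trials_per_block,
      stim_blocks = sort(stim_blocks),
      probability_levels = as.numeric(probability_levels),
      risky_win_points = as.numeric(risky_win_points),
      risky_loss_points = as.numeric(risky_loss_points),
      safe_points = as.numeric(safe_points),
      deadline_ms = as.numeric(deadline_ms)
    ),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat("<session_design>\n")
  cat(sprintf("  %d blocks x %d trials (%d total)\n",
              x$n_blocks, x$trials_per_block, x$n_blocks * x$trials_per_block))
  cat("  stimulation on in blocks:",
      if (length(x$stim_blocks)) paste(x$stim_blocks, collapse = ", ") else "none", "\n")
  cat("  cue probabilities:", paste(x$probability_levels, collapse = ", "), "\n")
  cat(sprintf("  outcomes: risky %g/%g, safe %g points; deadline %g ms\n",
              x$risky_win_points, x$risky_loss_points, x$safe_points,
              x$deadline_ms))
  invisible(x)
}

#' Four-parameter logistic psychometric parameters
#'
#' Bundles the threshold `m`, logistic scale `w` (smaller is steeper), and the
#' lower/upper asymptotes `floor` and `ceiling` of the probability of choosing
#' the risky option as a function of cued reward probability.
#'
#' @param m Threshold, in reward-probability units: the cue probability at
#'   which the choice probability sits midway between floor and ceiling.
#' @param w Logistic scale (> 0), reward-probability units.
#' @param floor,ceiling Lower and upper asymptotes, with
#'   `0 <= floor < ceiling <= 1`.
#'
#' @return An object of class `psychometric_params`.
#' @examples
#' psychometric_params(m = 0.55, w = 0.1)
#' @export
psychometric_params <- function(m, w, floor = 0, ceiling = 1) {
  if (!is.finite(m)) stop("`m` must be finite.", call. = FALSE)
  if (!is.finite(w) || w <= 0) stop("`w` must be positive.", call. = FALSE)
  if (floor < 0 || ceiling > 1 || floor >= ceiling) {
    stop("Need 0 <= floor < ceiling <= 1.", call. = FALSE)
  }
  structure(
    list(m = as.numeric(m), w = as.numeric(w),
         floor = as.numeric(floor), ceiling = as.numeric(ceiling)),
    class = "psychometric_params"
  )
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf("<psychometric_params> m = %g, w = %g, floor = %g, ceiling = %g\n",
              x$m, x$w, x$floor, x$ceiling))
  invisible(x)
}

#' Parametric choice agent for the task simulator
#'
#' An agent holds one set of psychometric parameters per stimulation condition,
#' an omission rate, and a log-normal reaction-time law (location per
#' condition, shared scale, truncated at the deadline). Defaults emulate the
#' study conditions: risk-averse baseline behaviour (threshold 0.55) with a
#' left threshold shift of 0.2 under stimulation, a 3.3% omission rate, and
#' reaction times around 700 ms with mild slowing when stimulated.
#'
#' @param params_off,params_on [psychometric_params()] governing choice in the
#'   off and on conditions.
#' @param omission_rate Probability in \[0, 1) that a trial times out with no
#'   response.
#' @param rt_location_off,rt_location_on Log-millisecond locations of the
#'   log-normal reaction-time law per condition.
#' @param rt_scale Log-scale dispersion (> 0) of the reaction-time law.
#'
#' @return An object of class `agent_params`.
#' @examples
#' agent_params()
#' @export
agent_params <- function(params_off = psychometric_params(0.55, 0.10, 0.05, 0.95),
                         params_on  = psychometric_params(0.35, 0.10, 0.05, 0.95),
                         omission_rate = 0.033,
                         rt_location_off = log(680),
                         rt_location_on = log(700),
                         rt_scale = 0.20) {
  stopifnot(inherits(params_off, "psychometric_params"),
            inherits(params_on, "psychometric_params"))
  if (omission_rate < 0 || omission_rate >= 1) {
    stop("`omission_rate` must be in [0, 1).", call. = FALSE)
  }
  if (rt_scale <= 0) stop("`rt_scale` must be positive.", call. = FALSE)
  structure(
    list(params_off = params_off, params_on = params_on,
         omission_rate = as.numeric(omission_rate),
         rt_location_off = as.numeric(rt_location_off),
         rt_location_on = as.numeric(rt_location_on),
         rt_scale = as.numeric(rt_scale)),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params>\n  off:")
  cat(sprintf(" m = %g, w = %g, floor = %g, ceiling = %g\n",
              x$params_off$m, x$params_off$w, x$params_off$floor,
              x$params_off$ceiling))
  cat("  on: ")
  cat(sprintf(" m = %g, w = %g, floor = %g, ceiling = %g\n",
              x$params_on$m, x$params_on$w, x$params_on$floor,
              x$params_on$ceiling))
  cat(sprintf("  omission rate %g; RT exp(N(%.3f/%.3f, %g^2)) ms\n",
              x$omission_rate, x$rt_location_off, x$rt_location_on, x$rt_scale))
  invisible(x)
}
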