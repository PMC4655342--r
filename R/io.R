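.trial_cols <- c("block", "trial", "condition", "cue_prob", "choice",
                 "outcome", "rt_ms")

#' Read and validate a trial-log CSV
#'
#' The dialect is a UTF-8 CSV with header
#' `block,trial,condition,cue_prob,choice,outcome,rt_ms`, `"."` as decimal
#' separator, `condition` in `off`/`on`, `choice` in `risky`/`safe`/`omit`
#' (case-sensitive), and `rt_ms` empty exactly for omissions. All validation
#' failures are collected and reported together with their row numbers.
#'
#' @param path Path to the CSV file.
#' @param design A [session_design()] providing the deadline and block range
#'   used in validation.
#' @return A validated trial tibble.
#' @export
read_trials <- function(path, design = session_design()) {
  if (!file.exists(path)) {
    stop("Trial file not found: ", path, call. = FALSE)
  }
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(hdr, .trial_cols)) {
    stop("Header must be exactly: ", paste(.trial_cols, collapse = ","),
         call. = FALSE)
  }
  trials <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      block = readr::col_integer(), trial = readr::col_integer(),
      condition = readr::col_character(), cue_prob = readr::col_double(),
      choice = readr::col_character(), outcome = readr::col_double(),
      rt_ms = readr::col_double()))
  probs <- .validate_rows(trials, design)
  if (length(probs)) {
    stop("Invalid trial log (", length(probs), " problem row(s)):\n  ",
         paste(utils::head(probs, 20), collapse = "\n  "),
         if (length(probs) > 20) "\n  ..." else "", call. = FALSE)
  }
  trials
}

.validate_rows <- function(trials, design) {
  probs <- character(0)
  add <- function(rows, what) {
    if (length(rows)) {
      c(probs, sprintf("row %d: %s", rows, what))
    } else probs
  }
  rown <- seq_len(nrow(trials))
  probs <- add(rown[!trials$condition %in% c("off", "on")],
               "condition must be 'off' or 'on'")
  probs <- add(rown[!trials$choice %in% c("risky", "safe", "omit")],
               "choice must be 'risky', 'safe' or 'omit'")
  probs <- add(rown[is.na(trials$block) | trials$block < 1 |
                      trials$block > design$n_blocks],
               sprintf("block must be in 1..%d", design$n_blocks))
  probs <- add(rown[is.na(trials$cue_prob) | trials$cue_prob <= 0 |
                      trials$cue_prob >= 1],
               "cue_prob must be in (0, 1)")
  omit <- trials$choice == "omit" & !is.na(trials$choice)
  probs <- add(rown[omit & !is.na(trials$rt_ms)],
               "rt_ms must be empty for omissions")
  probs <- add(rown[!omit & is.na(trials$rt_ms)],
               "rt_ms missing for a responded trial")
  probs <- add(rown[!is.na(trials$rt_ms) & trials$rt_ms >= design$deadline_ms],
               sprintf("rt_ms must be below the %g ms deadline",
                       design$deadline_ms))
  sort(probs)
}

#' Write a trial tibble to the trial-log CSV dialect
#'
#' @param trials A trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  .check_trials(trials)
  readr::write_csv(trials[, .trial_cols], path, na = "")
  invisible(path)
}

#' Relabel conditions by block membership
#'
#' Overwrites the condition column: `"on"` exactly where the block index is in
#' `on_blocks`. Running the full pipeline after partitioning an unstimulated
#' control session this way (e.g. blocks 3 and 5 as "on") provides a negative
#' control for the stimulation analysis.
#'
#' @param trials A trial tibble.
#' @param on_blocks Integer vector of 1-based block indices to label "on";
#'   may be empty (everything "off").
#' @param n_blocks Number of blocks in the design (defaults to the largest
#'   block index present).
#' @return The trial tibble with `condition` reassigned.
#' @examples
#' partition_by_block(simulate_session(seed = 1), c(2, 4))
#' @export
partition_by_block <- function(trials, on_blocks,
                               n_blocks = max(trials$block)) {
  .check_trials(trials)
  on_blocks <- as.integer(on_blocks)
  if (length(on_blocks) &&
      (anyNA(on_blocks) || any(on_blocks < 1L | on_blocks > n_blocks))) {
    stop("`on_blocks` must be block indices in 1..", n_blocks, call. = FALSE)
  }
  dplyr::mutate(trials,
                condition = ifelse(.data$block %in% on_blocks, "on", "off"))
}

#' Assemble a run configuration
#'
#' Bundles everything one analysis run needs: the session design, the
#' simulation agent, the prior, the sampler settings, an optional input
#' trial-log path (when absent, a session is simulated), the output
#' directory, and one master seed from which every stage seed is derived.
#'
#' @param design A [session_design()].
#' @param agent An [agent_params()] (used only when simulating).
#' @param prior A [prior_spec()].
#' @param sampler A [sampler_config()] (its own seed field is ignored; stage
#'   seeds derive from `seed`).
#' @param input Optional path to a trial-log CSV.
#' @param out_dir Output directory for artifacts.
#' @param seed Master integer seed.
#' @param make_figure Whether [run_pipeline()] saves the psychometric figure.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = session_design(), agent = agent_params(),
                       prior = prior_spec(), sampler = sampler_config(),
                       input = NULL, out_dir = "riskshift-out", seed = 1L,
                       make_figure = FALSE) {
  stopifnot(inherits(design, "session_design"),
            inherits(agent, "agent_params"),
            inherits(prior, "prior_spec"),
            inherits(sampler, "sampler_config"))
  structure(list(design = design, agent = agent, prior = prior,
                 sampler = sampler, input = input, out_dir = out_dir,
                 seed = as.integer(seed), make_figure = isTRUE(make_figure)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The file mirrors the sections of [run_config()]; [write_config()] and
#' `read_config()` round-trip losslessly.
#'
#' @param path Path to a YAML configuration file.
#' @return A `run_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  pp <- function(x) psychometric_params(x$m, x$w, x$floor, x$ceiling)
  run_config(
    design = do.call(session_design, y$design),
    agent = agent_params(
      params_off = pp(y$agent$off), params_on = pp(y$agent$on),
      omission_rate = y$agent$omission_rate,
      rt_location_off = y$agent$rt_location_off,
      rt_location_on = y$agent$rt_location_on,
      rt_scale = y$agent$rt_scale),
    prior = prior_spec(y$prior$m, y$prior$w, y$prior$floor, y$prior$ceiling),
    sampler = do.call(sampler_config, y$sampler),
    input = y$input, out_dir = y$out_dir, seed = y$seed,
    make_figure = isTRUE(y$make_figure))
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  d <- config$design
  ag <- config$agent
  pb <- config$prior$bounds
  sc <- config$sampler
  pl <- function(p) list(m = p$m, w = p$w, floor = p$floor,
                         ceiling = p$ceiling)
  y <- list(
    seed = config$seed,
    design = list(
      n_blocks = d$n_blocks, trials_per_block = d$trials_per_block,
      stim_blocks = d$stim_blocks, probability_levels = d$probability_levels,
      risky_win_points = d$risky_win_points,
      risky_loss_points = d$risky_loss_points,
      safe_points = d$safe_points, deadline_ms = d$deadline_ms),
    agent = list(off = pl(ag$params_off), on = pl(ag$params_on),
                 omission_rate = ag$omission_rate,
                 rt_location_off = ag$rt_location_off,
                 rt_location_on = ag$rt_location_on,
                 rt_scale = ag$rt_scale),
    prior = list(m = unname(pb["m", ]), w = unname(pb["w", ]),
                 floor = unname(pb["floor", ]),
                 ceiling = unname(pb["ceiling", ])),
    sampler = list(n_chains = sc$n_chains, n_warmup = sc$n_warmup,
                   n_draws = sc$n_draws, thin = sc$thin,
                   target_accept = sc$target_accept, seed = sc$seed),
    input = config$input, out_dir = config$out_dir,
    make_figure = config$make_figure)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a session, fits the psychometric model to each
#' condition, infers the threshold shift, runs the per-level mid-P tests and
#' the reaction-time ANOVA, and writes all artifacts to `config$out_dir`:
#' the trial log (when simulated), one posterior-draw CSV per condition, a
#' diagnostics JSON, the shift-report JSON, and optionally the psychometric
#' figure. Everything is deterministic given the configuration: stage seeds
#' are derived from the single master seed.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress and timings to stderr.
#' @return The report (class `shift_report`), invisibly.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, t0) {
    if (verbose) {
      message(sprintf("[riskshift] %s done in %.2fs", stage,
                      as.numeric(Sys.time()) - t0))
    }
  }
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e) {
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(name, t0)
    res
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  simulated <- is.null(config$input)
  trials <- stage("load", {
    if (simulated) {
      simulate_session(config$design, config$agent,
                       seed = .derive_seed(config$seed, "simulate"))
    } else {
      read_trials(config$input, config$design)
    }
  })
  if (simulated) {
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
  }

  smp <- config$sampler
  fit_off <- stage("fit_off", {
    smp$seed <- config$seed
    fit_condition(trials, "off", config$prior, smp)
  })
  fit_on <- stage("fit_on", fit_condition(trials, "on", config$prior, smp))
  write_draws(fit_off$draws, file.path(config$out_dir, "posterior_off.csv"))
  write_draws(fit_on$draws, file.path(config$out_dir, "posterior_on.csv"))

  shift <- stage("shift",
                 threshold_shift(fit_off, fit_on,
                                 seed = .derive_seed(config$seed, "shift")))
  level_tests <- stage("per_level_tests", per_level_tests(trials))
  anova_tab <- stage("rt_anova", rt_anova(trials))

  report <- shift_report(config$design, fit_off, fit_on, shift, level_tests,
                         anova_tab, seed = config$seed,
                         simulated = simulated)
  write_report(report, file.path(config$out_dir, "shift_report.json"))
  jsonlite::write_json(
    list(off = diagnostics(fit_off$draws)[c("rhat", "ess", "accept_rate")],
         on = diagnostics(fit_on$draws)[c("rhat", "ess", "accept_rate")]),
    file.path(config$out_dir, "diagnostics.json"),
    auto_unbox = FALSE, digits = NA)
  if (config$make_figure) {
    p <- plot_psychometric(fit_off, fit_on, trials)
    ggplot2::ggsave(file.path(config$out_dir, "psychometric.pdf"), p,
                    width = 6, height = 5)
  }
  invisible(report)
}

#' Assemble the per-session shift report
#'
#' @param design The [session_design()] analysed.
#' @param fit_off,fit_on The two condition fits.
#' @param shift The [threshold_shift()] result.
#' @param level_tests The [per_level_tests()] table.
#' @param anova_tab The [rt_anova()] table.
#' @param seed The master seed used.
#' @param simulated Whether the trials were simulated.
#' @return An object of class `shift_report`.
#' @export
shift_report <- function(design, fit_off, fit_on, shift, level_tests,
                         anova_tab, seed = NA_integer_, simulated = NA) {
  structure(
    list(report_version = "1",
         design = design, seed = seed, simulated = simulated,
         fit_off = fit_off, fit_on = fit_on, shift = shift,
         level_tests = level_tests, anova = anova_tab),
    class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat("<shift_report>\n")
  cat(sprintf("  fit status: off '%s', on '%s'\n",
              x$fit_off$status, x$fit_on$status))
  print(x$shift)
  cat("  per-level mid-P tests:\n")
  print(x$level_tests, ...)
  cat("  reaction-time ANOVA (Type II):\n")
  print(x$anova, ...)
  invisible(x)
}

#' Serialise a shift report to JSON
#'
#' Writes a schema-versioned JSON document (schema shipped at
#' `system.file("extdata", "shift-report-schema.json", package =
#' "riskshift")`). The output is a pure function of the analysis inputs, so
#' identical configurations produce identical files.
#'
#' @param report A `shift_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "shift_report"))
  fit_block <- function(fit) {
    list(status = fit$status, ppc_p = fit$ppc_p,
         posterior = tidy(fit$draws),
         counts = fit$counts)
  }
  sh <- report$shift
  doc <- list(
    report_version = report$report_version,
    seed = report$seed,
    simulated = report$simulated,
    design = unclass(report$design),
    fits = list(off = fit_block(report$fit_off),
                on = fit_block(report$fit_on)),
    shift = list(available = sh$available, flagged = sh$flagged,
                 mean = sh$mean, q5 = sh$q5, q95 = sh$q95,
                 prob_left_shift = sh$prob_left_shift,
                 status_off = sh$status_off, status_on = sh$status_on),
    per_level_tests = report$level_tests,
    rt_anova = as.data.frame(report$anova))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
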