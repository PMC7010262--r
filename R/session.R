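# Two-choice instrumental conditioning with reversal: trial, session and
# cohort runners.

#' Session schedule and cohort configuration
#'
#' Defaults follow the standard protocol: 500 trials, action 1 rewarded
#' on trials 1-199, action 2 from trial 200 on (the reversal), 25-trial
#' performance windows, cohorts of 10 simulated animals. An optional
#' `treatment_trial` ablates the basal-ganglia output to premotor cortex
#' (see [apply_treatment()]) from that trial onward.
#'
#' @param n_trials Number of trials per session.
#' @param reversal_trial First trial on which action 2 is rewarded.
#' @param treatment_trial Optional trial from which the BG output is
#'   ablated; `NULL` for none.
#' @param condition Condition name or a [bg_params()] object.
#' @param seed Integer seed for the session (cohort member k runs with
#'   `seed + k - 1`).
#' @param window Performance window length in trials.
#' @param n_animals Cohort size.
#' @param noise Logical; apply the within-trial noise forcing.
#' @return A `bg_session_config` list.
#' @export
session_config <- function(n_trials = 500, reversal_trial = 200,
                           treatment_trial = NULL, condition = "healthy",
                           seed = 1, window = 25, n_animals = 10,
                           noise = TRUE) {
  cfg <- list(n_trials = as.integer(n_trials),
              reversal_trial = as.integer(reversal_trial),
              treatment_trial = if (!is.null(treatment_trial))
                as.integer(treatment_trial),
              condition = condition, seed = as.integer(seed),
              window = as.integer(window),
              n_animals = as.integer(n_animals), noise = noise)
  if (cfg$n_trials < 1 || cfg$window < 1 || cfg$n_animals < 1)
    stop("n_trials, window and n_animals must be >= 1")
  if (cfg$reversal_trial < 1 || cfg$reversal_trial > cfg$n_trials)
    stop("reversal_trial must lie within the session")
  if (!is.null(cfg$treatment_trial) &&
      (cfg$treatment_trial < 1 || cfg$treatment_trial > cfg$n_trials))
    stop("treatment_trial must lie within the session")
  structure(cfg, class = "bg_session_config")
}

#' Rewarded action at a given trial
#'
#' @param j Trial index (vectorized).
#' @param reversal_trial First trial on which action 2 is rewarded.
#' @return Integer vector of rewarded actions (1 or 2).
#' @export
rewarded_action <- function(j, reversal_trial = 200) {
  ifelse(j >= reversal_trial, 2L, 1L)
}

#' Run one trial: integrate, select, reward, learn
#'
#' Draws random initial activities, integrates the 750 ms trial, reads
#' out the selected action, assigns reward under the current
#' contingency, computes the dopamine signal, and applies the
#' expectation update and both plasticity rules. On trials with no
#' selected action the reward is 0 and all updates still run with the
#' end-of-trial activities.
#'
#' @param j Trial index.
#' @param rewarded Rewarded action on this trial (1 or 2).
#' @param weights Current plastic weight vector.
#' @param expected_reward Current expected reward.
#' @param params A [bg_params()] object (post-treatment if applicable).
#' @param noise Logical; within-trial noise forcing.
#' @return A list with `record` (one-row tibble), `weights`,
#'   `expected_reward` and `init` (the drawn initial state).
#' @export
run_trial <- function(j, rewarded, weights, expected_reward, params,
                      noise = TRUE) {
  init <- random_initial_state(params)
  end <- integrate_trial(params, weights, init = init, noise = noise)
  chosen <- select_action(end, params$selection_threshold)
  rew <- as.integer(!is.na(chosen) && chosen == rewarded)
  snc <- compute_rpe(rew, expected_reward, params$da_gain)
  rates <- params$plasticity
  deltas <- c(corticostriatal_deltas(snc, end, weights, rates),
              cortical_deltas(end, weights, rates))
  new_w <- apply_updates(weights, deltas)
  record <- tibble::tibble(
    trial = as.integer(j), rewarded_action = as.integer(rewarded),
    chosen = chosen, R = rew, Re = expected_reward, SNc = snc
  )
  record <- dplyr::bind_cols(record,
                             tibble::as_tibble(as.list(end)),
                             tibble::as_tibble(as.list(new_w)))
  list(record = record,
       weights = new_w,
       expected_reward = update_expected_reward(expected_reward, rew,
                                                rates$alpha),
       init = init)
}

#' Run a full conditioning session for one simulated animal
#'
#' Seeds the RNG, initializes plastic weights (corticostriatal uniform
#' on `[0, 0.001]`, cortical at 0) and the reward expectation at 1, then
#' iterates [run_trial()] over the schedule, switching the rewarded
#' action at `reversal_trial` and ablating the BG output from
#' `treatment_trial` (if set). Deterministic given the configuration.
#'
#' @param config A [session_config()]; further arguments override its
#'   fields via `...` passed to [session_config()] when `config` is
#'   omitted.
#' @param ... Convenience overrides forwarded to [session_config()].
#' @return A `bg_session` object: list with `trials` (tibble, one row
#'   per trial: indices, choices, reward bookkeeping, 13 end-of-trial
#'   activities and the 6 post-update plastic weights), `config`,
#'   `params`, `seed` and `initial_states` (matrix of the random trial
#'   starts, used by the cortical-takeover probe).
#' @export
#' @examples
#' \donttest{
#' s <- run_session(session_config(n_trials = 50, reversal_trial = 40))
#' performance_curve(s)
#' }
run_session <- function(config = session_config(), ...) {
  if (!inherits(config, "bg_session_config"))
    stop("config must be a session_config()")
  if (length(list(...))) config <- do.call(session_config,
                                           utils::modifyList(unclass(config),
                                                             list(...)))
  params <- condition_parameters(config$condition)
  treated <- if (!is.null(config$treatment_trial)) apply_treatment(params)
  set.seed(config$seed)
  weights <- init_plastic_weights(params)
  expected <- 1
  records <- vector("list", config$n_trials)
  inits <- matrix(NA_real_, config$n_trials, 13,
                  dimnames = list(NULL, bg_unit_names()))
  for (j in seq_len(config$n_trials)) {
    p_j <- if (!is.null(config$treatment_trial) &&
               j >= config$treatment_trial) treated else params
    out <- run_trial(j, rewarded_action(j, config$reversal_trial),
                     weights, expected, p_j, noise = config$noise)
    records[[j]] <- out$record
    inits[j, ] <- out$init
    weights <- out$weights
    expected <- out$expected_reward
  }
  trials <- dplyr::bind_rows(records)
  trials <- dplyr::mutate(trials, seed = config$seed,
                          condition = params$condition, .after = "trial")
  structure(list(trials = trials, config = config, params = params,
                 seed = config$seed, initial_states = inits),
            class = "bg_session")
}

#' Run a cohort of simulated animals
#'
#' Runs `n_animals` sessions with seeds `seed, seed + 1, ...` so a whole
#' cohort is reproducible from one integer.
#'
#' @inheritParams run_session
#' @return A `bg_cohort` object (list of `bg_session`).
#' @export
run_cohort <- function(config = session_config(), ...) {
  if (length(list(...))) config <- do.call(session_config,
                                           utils::modifyList(unclass(config),
                                                             list(...)))
  sessions <- purrr::map(seq_len(config$n_animals) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    run_session(cfg)
  })
  structure(list(sessions = sessions, config = config),
            class = "bg_cohort")
}

session_trials <- function(x) {
  if (inherits(x, "bg_session")) x$trials
  else if (inherits(x, "bg_cohort"))
    dplyr::bind_rows(purrr::map(x$sessions, "trials"))
  else if (is.data.frame(x)) {
    if (!"seed" %in% names(x)) x$seed <- NA_integer_
    x
  }
  else stop("expected a bg_session, bg_cohort or trials tibble")
}

#' Windowed performance curve
#'
#' Fraction of trials per non-overlapping window on which the chosen
#' action was the rewarded one. Trials with no selected action count as
#' incorrect; their rate is reported separately. A trailing incomplete
#' window is kept with its actual trial count.
#'
#' @param x A `bg_session`, `bg_cohort` or trials tibble.
#' @param window Window length in trials (default 25).
#' @return A tibble with `seed`, `window_start`, `window_end`,
#'   `n_trials`, `frac_correct`, `frac_none`; for cohorts one row per
#'   session and window.
#' @export
performance_curve <- function(x, window = 25) {
  tr <- session_trials(x)
  tr |>
    dplyr::mutate(correct = !is.na(.data$chosen) &
                    .data$chosen == .data$rewarded_action,
                  window_start = (.data$trial - 1L) %/%
                    as.integer(window) * as.integer(window) + 1L) |>
    dplyr::group_by(.data$seed, .data$window_start) |>
    dplyr::summarise(window_end = max(.data$trial),
                     n_trials = dplyr::n(),
                     frac_correct = mean(.data$correct),
                     frac_none = mean(is.na(.data$chosen)),
                     .groups = "drop")
}

#' Cohort-mean performance curve
#'
#' @inheritParams performance_curve
#' @return A tibble with one row per window: mean and standard deviation
#'   of the per-session correct fractions.
#' @export
cohort_performance <- function(x, window = 25) {
  performance_curve(x, window) |>
    dplyr::group_by(.data$window_start) |>
    dplyr::summarise(window_end = max(.data$window_end),
                     n_sessions = dplyr::n(),
                     mean_correct = mean(.data$frac_correct),
                     sd_correct = stats::sd(.data$frac_correct),
                     mean_none = mean(.data$frac_none),
                     .groups = "drop")
}

#' Write per-trial records to CSV
#'
#' One row per trial with the choice, reward bookkeeping, end-of-trial
#' activities and plastic-weight snapshot.
#'
#' @param x A `bg_session` or `bg_cohort`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(x, path) {
  cols <- c("trial", "seed", "condition", "rewarded_action", "chosen",
            "R", "Re", "SNc", bg_unit_names(), plastic_weight_names())
  utils::write.csv(session_trials(x)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.bg_session <- function(x, ...) {
  cat("<bg_session>", x$params$condition, "condition,",
      nrow(x$trials), "trials, seed", x$seed, "\n")
  correct <- mean(!is.na(x$trials$chosen) &
                    x$trials$chosen == x$trials$rewarded_action)
  cat(sprintf("  overall correct: %.1f%%; reversal at trial %d\n",
              100 * correct, x$config$reversal_trial))
  invisible(x)
}

#' @export
print.bg_cohort <- function(x, ...) {
  cat("<bg_cohort>", length(x$sessions), "sessions,",
      "seeds", x$config$seed, "..",
      x$config$seed + x$config$n_animals - 1L, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-trial records
#'
#' @param x A `bg_session` or `bg_cohort`.
#' @param ... Unused.
#' @return The per-trial tibble (sessions bound together for cohorts).
#' @export
tidy.bg_session <- function(x, ...) x$trials

#' @rdname tidy.bg_session
#' @export
tidy.bg_cohort <- function(x, ...) session_trials(x)

#' One-row session summary
#'
#' @param x A `bg_session`.
#' @param ... Unused.
#' @return Tibble with overall, pre- and post-reversal correct
#'   fractions and the no-choice rate.
#' @export
glance.bg_session <- function(x, ...) {
  tr <- x$trials
  correct <- !is.na(tr$chosen) & tr$chosen == tr$rewarded_action
  pre <- tr$trial < x$config$reversal_trial
  tibble::tibble(
    condition = x$params$condition, seed = x$seed,
    n_trials = nrow(tr),
    frac_correct = mean(correct),
    frac_correct_initial = mean(correct[pre]),
    frac_correct_reversal = mean(correct[!pre]),
    frac_none = mean(is.na(tr$chosen))
  )
}

#' @rdname glance.bg_session
#' @export
glance.bg_cohort <- function(x, ...)
  dplyr::bind_rows(purrr::map(x$sessions, glance))
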