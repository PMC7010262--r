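# Post-hoc analyses: within-trial oscillation detection, exploration
# phase detection, weight-trajectory summaries and cohort summaries.

#' Dominant within-trial oscillation of an activity trace
#'
#' Detrends the analysis window (mean and linear trend, so residual
#' equilibration transients do not masquerade as slow oscillations),
#' computes the sample autocorrelation, and takes its global maximum
#' beyond the first zero crossing as the dominant periodicity. An
#' oscillation is declared when that peak's autocorrelation exceeds
#' `acf_threshold` (default 0.2) and the peak-to-trough amplitude of
#' the detrended window exceeds `amp_threshold` (default 0.05). The
#' reported period is then refined by a least-squares sinusoid fit
#' bracketed around the autocorrelation peak, which removes the
#' peak-location bias of the truncated autocorrelation on short
#' (600 ms) windows. Chosen over spectral peak-picking for robustness
#' at two to four cycles per window.
#'
#' @param x Activity series: a numeric vector sampled at `dt`, or a
#'   trace tibble from [trial_trace()] (then `unit` picks the column).
#' @param dt Sampling step in ms (taken from the trace tibble if given).
#' @param window Analysis window in ms as `c(from, to)`; default the
#'   last 600 ms of the trace, skipping the initial transient.
#' @param unit Unit column to analyze when `x` is a trace tibble.
#' @param max_period Largest candidate period (ms); the window must
#'   cover at least two of these.
#' @param acf_threshold,amp_threshold Detection thresholds.
#' @return One-row tibble: `detected`, `period_ms`, `frequency_hz`,
#'   `amplitude` (period and frequency are `NA` when not detected).
#' @export
#' @examples
#' t <- seq(0, 749)
#' dominant_oscillation(0.5 + 0.1 * sin(2 * pi * t / 150), dt = 1)
dominant_oscillation <- function(x, dt = 1, window = NULL,
                                 unit = "PMC_1", max_period = 300,
                                 acf_threshold = 0.2,
                                 amp_threshold = 0.05) {
  if (is.data.frame(x)) {
    stopifnot(all(c("t_ms", unit) %in% names(x)))
    t_ms <- x$t_ms
    dt <- t_ms[2] - t_ms[1]
    y <- x[[unit]]
  } else {
    y <- as.numeric(x)
    t_ms <- seq(0, by = dt, length.out = length(y))
  }
  if (is.null(window)) window <- c(max(t_ms) - 600, max(t_ms))
  keep <- t_ms >= window[1] & t_ms <= window[2]
  y <- y[keep]
  n <- length(y)
  if (n * dt < 2 * max_period)
    stop("analysis window shorter than two candidate periods")
  tt <- seq_len(n)
  y <- y - (stats::lm.fit(cbind(1, tt), y)$fitted.values)
  amplitude <- max(y) - min(y)
  if (stats::sd(y) < 1e-12)
    return(tibble::tibble(detected = FALSE, period_ms = NA_real_,
                          frequency_hz = NA_real_, amplitude = amplitude))
  max_lag <- min(n - 1, floor(max_period / dt))
  ac <- stats::acf(y, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  # candidate period = global autocorrelation maximum beyond the first
  # zero crossing (excludes the zero-lag main lobe and its ripples)
  period <- NA_real_
  zc <- which(ac < 0)[1]
  if (!is.na(zc) && zc < length(ac)) {
    k <- zc + which.max(ac[(zc + 1):length(ac)])   # index: lag k - 1
    if (ac[k] > acf_threshold && k > 2) {
      rss <- function(p) {
        X <- cbind(1, tt, sin(2 * pi * tt / p), cos(2 * pi * tt / p))
        sum(stats::lm.fit(X, y)$residuals^2)
      }
      p0 <- k - 1
      period <- stats::optimize(rss, c(0.8 * p0, 1.25 * p0))$minimum * dt
    }
  }
  detected <- !is.na(period) && amplitude > amp_threshold
  tibble::tibble(
    detected = detected,
    period_ms = if (detected) period else NA_real_,
    frequency_hz = if (detected) 1000 / period else NA_real_,
    amplitude = amplitude
  )
}

binary_entropy <- function(p) {
  if (is.na(p) || p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Detect the end of an exploratory phase
#'
#' Scans non-overlapping windows within a phase of the session and
#' returns the first trial of the first window from which the phase's
#' rewarded action is chosen in at least `criterion` of trials in every
#' remaining window of the phase. Also reports the per-window binary
#' choice entropy (computed over decided choices; the no-choice rate is
#' reported separately, since choice blockade and random choice are
#' different failure modes).
#'
#' @param session A `bg_session`.
#' @param phase Trial range `c(from, to)`; default the reversal phase
#'   (`reversal_trial` to the last trial).
#' @param criterion Required correct fraction, in `(0.5, 1]`.
#' @param window Window length in trials.
#' @return A list of class `bg_exploration`:
#'   `exploration_end_trial` (first trial of sustained criterion
#'   performance, `NA` if never reached) and `windows`, a tibble with
#'   `window_start`, `n_trials`, `frac_correct`, `frac_none`, `entropy`.
#' @export
detect_exploration_end <- function(session, phase = NULL,
                                   criterion = 0.75, window = 25) {
  stopifnot(inherits(session, "bg_session"),
            criterion > 0.5, criterion <= 1)
  tr <- session$trials
  if (is.null(phase))
    phase <- c(session$config$reversal_trial, max(tr$trial))
  stopifnot(phase[1] >= min(tr$trial), phase[2] <= max(tr$trial),
            phase[1] < phase[2])
  tr <- tr[tr$trial >= phase[1] & tr$trial <= phase[2], ]
  if (phase[2] - phase[1] + 1 < window)
    return(structure(list(exploration_end_trial = NA_integer_,
                          windows = tibble::tibble(
                            window_start = integer(), n_trials = integer(),
                            frac_correct = numeric(), frac_none = numeric(),
                            entropy = numeric()),
                          phase = phase, criterion = criterion,
                          window = window),
                     class = "bg_exploration"))
  starts <- seq(phase[1], phase[2] - window + 1, by = window)
  win <- purrr::map(starts, function(s0) {
    block <- tr[tr$trial >= s0 & tr$trial < s0 + window, ]
    correct <- !is.na(block$chosen) &
      block$chosen == block$rewarded_action
    p1 <- {
      decided <- block$chosen[!is.na(block$chosen)]
      if (length(decided)) mean(decided == 1L) else NA_real_
    }
    tibble::tibble(window_start = as.integer(s0),
                   n_trials = nrow(block),
                   frac_correct = mean(correct),
                   frac_none = mean(is.na(block$chosen)),
                   entropy = binary_entropy(p1))
  }) |> dplyr::bind_rows()
  meets <- win$frac_correct >= criterion
  sustained <- rev(cumprod(rev(meets))) == 1
  end_trial <- if (any(sustained))
    win$window_start[which(sustained)[1]] else NA_integer_
  structure(list(exploration_end_trial = end_trial, windows = win,
                 phase = phase, criterion = criterion, window = window),
            class = "bg_exploration")
}

#' @export
print.bg_exploration <- function(x, ...) {
  cat("<bg_exploration> phase", x$phase[1], "-", x$phase[2],
      "criterion", x$criterion, "\n  exploration ends at trial:",
      x$exploration_end_trial, "\n")
  invisible(x)
}

#' Plastic-weight trajectories and the cortical-takeover probe
#'
#' Returns the per-trial series of the six plastic weights together
#' with two derived markers: the trial of peak total corticostriatal
#' weight, and the "cortical takeover" trial — the first trial from
#' which the direct PFC-to-PMC weights alone sustain the rewarded
#' choice through the end of the phase. For each trial's weight
#' snapshot the probe integrates one noise-free trial with the
#' corticostriatal weights zeroed, starting from a neutral near-rest
#' state (every unit at the midpoint of the initial-condition range)
#' in which the *opposing* premotor unit is given a head start of one
#' selection threshold (0.1, the model's noise level). The probe is
#' deterministic and asks whether the cortical
#' weights alone overcome a noise-sized initial disadvantage; a
#' perfectly symmetric start would let an arbitrarily small cortical
#' bias win and date the takeover at the first trial.
#'
#' @param session A `bg_session`.
#' @param phase Trial range for the probe; default the initial-learning
#'   phase (trial 1 to `reversal_trial - 1`).
#' @param probe Logical; run the takeover probe (the weight series is
#'   returned either way).
#' @param probe_handicap Head-start activity given to the opposing
#'   premotor unit in the probe; defaults to the selection threshold.
#' @return A list of class `bg_weights`: `weights` (long tibble:
#'   `trial`, `weight`, `value`), `msn_peak_trial` (trial of peak total
#'   corticostriatal weight within `phase`), `takeover_trial`
#'   (`NA` if the probe never succeeds sustainedly) and `probe`
#'   (per-trial probe outcomes when run).
#' @export
weight_trajectories <- function(session, phase = NULL, probe = TRUE,
                                probe_handicap = NULL) {
  stopifnot(inherits(session, "bg_session"))
  tr <- session$trials
  if (is.null(phase))
    phase <- c(1L, session$config$reversal_trial - 1L)
  wts <- tr |>
    dplyr::select("trial", dplyr::all_of(plastic_weight_names())) |>
    tidyr::pivot_longer(-"trial", names_to = "weight",
                        values_to = "value")
  in_phase <- tr$trial >= phase[1] & tr$trial <= phase[2]
  msn_total <- rowSums(tr[, c("w_pfc_d1_1", "w_pfc_d1_2",
                              "w_pfc_d2_1", "w_pfc_d2_2")])
  msn_peak <- tr$trial[in_phase][which.max(msn_total[in_phase])]
  takeover <- NA_integer_
  probe_tbl <- NULL
  if (probe) {
    params <- session$params
    if (is.null(probe_handicap))
      probe_handicap <- params$selection_threshold
    idx <- which(tr$trial >= phase[1] & tr$trial <= phase[2])
    ok <- vapply(idx, function(i) {
      w <- plastic_weights(
        pmc = c(tr$w_pfc_pmc_1[i], tr$w_pfc_pmc_2[i]))
      rewarded <- tr$rewarded_action[i]
      base <- params$init_max / 2
      init <- stats::setNames(rep(base, 13), bg_unit_names())
      init[paste0("PMC_", 3L - rewarded)] <- base + probe_handicap
      end <- integrate_trial(params, w, init = init, noise = FALSE)
      ch <- select_action(end, params$selection_threshold)
      !is.na(ch) && ch == rewarded
    }, logical(1))
    sustained <- rev(cumprod(rev(ok))) == 1
    if (any(sustained)) takeover <- tr$trial[idx[which(sustained)[1]]]
    probe_tbl <- tibble::tibble(trial = tr$trial[idx], probe_ok = ok)
  }
  structure(list(weights = wts, msn_peak_trial = msn_peak,
                 takeover_trial = takeover, probe = probe_tbl,
                 phase = phase),
            class = "bg_weights")
}

#' @export
print.bg_weights <- function(x, ...) {
  cat("<bg_weights> corticostriatal peak at trial", x$msn_peak_trial,
      "; cortical takeover at trial", x$takeover_trial, "\n")
  invisible(x)
}

#' Summarize a cohort of sessions
#'
#' Early/late window performance for the initial-learning and reversal
#' phases, exploration ends for both phases, and (optionally) the
#' cortical-takeover markers, as mean, standard deviation and median
#' across the cohort.
#'
#' @param cohort A `bg_cohort` (or single `bg_session`).
#' @param window Performance window length.
#' @param takeover Logical; also run the takeover probe per session
#'   (adds noise-free replays).
#' @return A list of class `bg_summary` with elements `condition`,
#'   `seeds`, `performance` (tibble of phase x early/late cohort
#'   statistics), `exploration` (tibble of per-session end trials for
#'   both phases) and `takeover_trials`. Serializable with
#'   [write_summary_json()].
#' @export
summarize_cohort <- function(cohort, window = 25, takeover = FALSE) {
  if (inherits(cohort, "bg_session"))
    cohort <- structure(list(sessions = list(cohort),
                             config = cohort$config), class = "bg_cohort")
  stopifnot(inherits(cohort, "bg_cohort"))
  cfg <- cohort$config
  rev_t <- cfg$reversal_trial
  n <- cfg$n_trials
  perf <- performance_curve(cohort, window) |>
    dplyr::mutate(phase = ifelse(.data$window_start < rev_t,
                                 "initial", "reversal"))
  block_of <- function(p) {
    dplyr::group_by(p, .data$seed, .data$phase) |>
      dplyr::summarise(
        early = .data$frac_correct[which.min(.data$window_start)],
        late = .data$frac_correct[which.max(.data$window_start)],
        .groups = "drop")
  }
  perf_stats <- block_of(perf) |>
    tidyr::pivot_longer(c("early", "late"), names_to = "block",
                        values_to = "frac_correct") |>
    dplyr::group_by(.data$phase, .data$block) |>
    dplyr::summarise(mean = mean(.data$frac_correct),
                     sd = stats::sd(.data$frac_correct),
                     median = stats::median(.data$frac_correct),
                     .groups = "drop")
  expl <- purrr::map(cohort$sessions, function(s) {
    tibble::tibble(
      seed = s$seed,
      initial_end = detect_exploration_end(
        s, phase = c(1L, rev_t - 1L), window = window
      )$exploration_end_trial,
      reversal_end = detect_exploration_end(
        s, phase = c(rev_t, n), window = window
      )$exploration_end_trial)
  }) |> dplyr::bind_rows()
  takeover_trials <- if (takeover)
    vapply(cohort$sessions,
           function(s) weight_trajectories(s)$takeover_trial,
           integer(1))
  structure(list(
    condition = condition_parameters(cfg$condition)$condition,
    seeds = vapply(cohort$sessions, function(s) s$seed, integer(1)),
    n_trials = n, reversal_trial = rev_t, window = window,
    performance = perf_stats, exploration = expl,
    takeover_trials = takeover_trials
  ), class = "bg_summary")
}

#' @export
print.bg_summary <- function(x, ...) {
  cat("<bg_summary>", x$condition, "cohort,", length(x$seeds),
      "sessions\n")
  print(x$performance)
  invisible(x)
}

#' Write a cohort summary as JSON
#'
#' @param summary A `bg_summary` from [summarize_cohort()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "bg_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
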