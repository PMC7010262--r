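test_that("the oscillation detector recovers a constructed sinusoid and rejects constants", {
  t <- seq(0, 749)
  o <- dominant_oscillation(0.5 + 0.1 * sin(2 * pi * t / 150), dt = 1)
  expect_true(o$detected)
  expect_equal(o$period_ms, 150, tolerance = 1 / 150)
  expect_equal(o$frequency_hz, 1000 / o$period_ms)
  expect_false(dominant_oscillation(rep(0.4, 750), dt = 1)$detected)
  expect_error(dominant_oscillation(rep(0.4, 100), dt = 1),
               "candidate periods")
})

test_that("detector is calibrated within 2 steps across periods 50-300 ms under uniform noise", {
  set.seed(17)
  t <- seq(0, 749)
  for (period in c(50, 80, 120, 150, 200, 250, 300)) {
    # sinusoid at the amplitude scale of the Parkinsonian oscillation
    y <- 0.5 + 0.2 * sin(2 * pi * t / period) + runif(750, 0, 0.1)
    o <- dominant_oscillation(y, dt = 1)
    expect_true(o$detected)
    expect_lte(abs(o$period_ms - period), 2)
  }
})

test_that("detector false-positive rate on noise-only traces is below 5%", {
  set.seed(23)
  hits <- replicate(100, {
    dominant_oscillation(0.5 + runif(750, 0, 0.1), dt = 1)$detected
  })
  expect_lt(mean(hits), 0.05)
})

test_that("detector separates Parkinsonian from healthy within-trial dynamics", {
  pd <- parkinsonian_parameters()
  h <- healthy_parameters()
  set.seed(29)
  pd_hits <- replicate(10, {
    st <- integrate_trial(pd, init = random_initial_state(pd),
                          noise = TRUE, record_trace = TRUE)
    dominant_oscillation(trial_trace(st))$detected
  })
  h_hits <- replicate(10, {
    st <- integrate_trial(h, init = random_initial_state(h),
                          noise = TRUE, record_trace = TRUE)
    dominant_oscillation(trial_trace(st))$detected
  })
  expect_gte(sum(pd_hits), 9)
  expect_lte(sum(h_hits), 1)
})

# build a minimal synthetic session for the pure bookkeeping analyses
synthetic_session <- function(chosen, rewarded = rewarded_action(
                                seq_along(chosen), reversal),
                              reversal = length(chosen) + 1L,
                              pmc = NULL) {
  n <- length(chosen)
  tr <- tibble::tibble(
    trial = seq_len(n), seed = 1L, condition = "healthy",
    rewarded_action = as.integer(rewarded), chosen = as.integer(chosen),
    R = as.integer(!is.na(chosen) & chosen == rewarded),
    Re = 1, SNc = 0
  )
  for (u in bg_unit_names()) tr[[u]] <- 0.5
  for (w in c("w_pfc_d1_1", "w_pfc_d1_2", "w_pfc_d2_1", "w_pfc_d2_2"))
    tr[[w]] <- 0
  tr$w_pfc_pmc_1 <- if (is.null(pmc)) 0 else pmc[, 1]
  tr$w_pfc_pmc_2 <- if (is.null(pmc)) 0 else pmc[, 2]
  structure(list(trials = tr,
                 config = session_config(n_trials = n,
                                         reversal_trial = min(reversal, n),
                                         seed = 1, n_animals = 1),
                 params = healthy_parameters(), seed = 1L,
                 initial_states = matrix(0.5, n, 13,
                                         dimnames = list(NULL,
                                                         bg_unit_names()))),
            class = "bg_session")
}

test_that("exploration end detection handles the degenerate patterns", {
  s_all <- synthetic_session(rep(1L, 100))
  e <- detect_exploration_end(s_all, phase = c(1L, 100L))
  expect_equal(e$exploration_end_trial, 1L)
  expect_equal(e$windows$frac_correct, rep(1, 4))
  expect_equal(e$windows$entropy, rep(0, 4))

  s_alt <- synthetic_session(rep(c(1L, 2L), 50))
  e2 <- detect_exploration_end(s_alt, phase = c(1L, 100L))
  expect_true(is.na(e2$exploration_end_trial))
  # near-maximal choice entropy (windows of 25 cannot split evenly)
  expect_equal(e2$windows$entropy, rep(1, 4), tolerance = 0.01)

  # criterion met only from the second window on
  s_mix <- synthetic_session(c(rep(2L, 25), rep(1L, 75)))
  e3 <- detect_exploration_end(s_mix, phase = c(1L, 100L))
  expect_equal(e3$exploration_end_trial, 26L)
  expect_error(detect_exploration_end(s_all, phase = c(1L, 100L),
                                      criterion = 0.4))
  # a phase shorter than one window has no complete windows
  e4 <- detect_exploration_end(s_all, phase = c(90L, 100L))
  expect_true(is.na(e4$exploration_end_trial))
  expect_equal(nrow(e4$windows), 0)
})

test_that("the takeover probe responds to injected cortical bias and to its absence", {
  # all-zero weights: the probe never succeeds
  s0 <- synthetic_session(rep(1L, 60))
  w0 <- weight_trajectories(s0, phase = c(1L, 60L))
  expect_true(is.na(w0$takeover_trial))

  # a manifestly sufficient bias injected from trial 20 onward
  k <- 20L
  pmc <- cbind(c(rep(0, k - 1), rep(0.5, 41)), rep(0, 60))
  s1 <- synthetic_session(rep(1L, 60), pmc = pmc)
  w1 <- weight_trajectories(s1, phase = c(1L, 60L))
  expect_lte(w1$takeover_trial, k)
  expect_false(any(w1$probe$probe_ok[seq_len(k - 1)]))
  # weight series is the long per-trial table
  expect_equal(nrow(w1$weights), 60 * 6)
})

test_that("takeover marker in a learned healthy session tracks the cortical weight crossing", {
  s <- run_session(session_config(seed = 2))
  wt <- weight_trajectories(s)
  expect_false(is.na(wt$takeover_trial))
  # the probe threshold sits where the premotor weight advantage
  # overcomes a noise-sized handicap; before the marker the advantage
  # must be smaller than at the marker itself
  tr <- s$trials
  adv <- tr$w_pfc_pmc_1 - tr$w_pfc_pmc_2
  expect_gt(adv[wt$takeover_trial], adv[10])
  # corticostriatal weights peak before the cortical takeover completes
  expect_lt(wt$msn_peak_trial, 199)
})

test_that("cohort summaries aggregate performance, exploration and seeds", {
  co <- run_cohort(session_config(n_trials = 100, reversal_trial = 60,
                                  seed = 11, n_animals = 3))
  sm <- summarize_cohort(co)
  expect_s3_class(sm, "bg_summary")
  expect_equal(sm$seeds, 11:13)
  expect_equal(nrow(sm$performance), 4)   # initial/reversal x early/late
  expect_equal(nrow(sm$exploration), 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_summary_json(sm, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$condition, "healthy")
  expect_length(back$seeds, 3)

  # a single synthetic session, all-correct pre-reversal, summarizes to
  # 100% late initial windows
  sm1 <- summarize_cohort(synthetic_session(rep(1L, 100),
                                            reversal = 76L))
  late <- sm1$performance$mean[sm1$performance$block == "late" &
                                 sm1$performance$phase == "initial"]
  expect_equal(late, 1)
})
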