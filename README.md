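# bgloop

A firing-rate simulator of the cortico-basal-ganglia-thalamo-cortical
loop learning a two-choice instrumental conditioning task with
mid-session reversal, in healthy, mild Parkinsonian and Grade 2
Huntington's disease parameterizations, including in-silico ablation of
the basal-ganglia output (GPi lesion / deep-brain-stimulation
analogue).

It is written for computational and systems neuroscientists who want a
small, fully inspectable model of how action selection and
reinforcement learning interact across the basal ganglia and cortex,
and how that interaction degenerates in disease.

## The model in brief

Two action channels share a 13-unit loop (PFC; per channel D1- and
D2-MSNs, GPe, STN, GPi/SNr, PMC/thalamus). Each unit's normalized rate
obeys

    tau dA/dt = sigma(I) - A + N(t),      sigma(I) = max(tanh(I), 0)

with per-unit time constants (STN 12.8 ms, GPe 20 ms, else 15 ms) and
uniform noise on [0, 0.1]. The direct pathway disinhibits a channel's
premotor unit, the indirect pathway inhibits it, and the premotor units
inhibit each other (winner-take-all). An action is selected when one
premotor rate exceeds the other by 0.1 at the end of a 750 ms trial.

Between trials, the nigral dopamine signal `SNc = g_DA (R - Re)` — the
reward-prediction error, with `Re` an exponential average of past
rewards (`alpha = 0.15`) — gates corticostriatal plasticity
(potentiating PFC→D1 on positive errors and PFC→D2 on omissions, D2 at
half the D1 rate), while PFC→PMC weights grow by reward-independent
Hebbian co-activity. Learning therefore migrates: striatal weights
acquire the choice fast and decay once the reward is predicted;
cortical weights slowly take over its expression.

Disease states are parameter deltas: Parkinsonian (dopamine output
suppressed 70%, striatal excitation shifted toward the indirect
pathway) turns the loop into a ~150 ms / 6.7 Hz theta oscillator and
cripples learning; Huntington (indirect pathway weakened, cortical
drive reduced) leaves learning intact but lets the model keep switching
to the unrewarded option.

## Worked example

```r
library(bgloop)

s <- run_session(session_config(condition = "healthy", seed = 1))
s
#> <bg_session> healthy condition, 500 trials, seed 1
#>   overall correct: 90.0%; reversal at trial 200

performance_curve(s)[c(1, 8, 9, 12, 20), ]
#>    seed window_start window_end n_trials frac_correct frac_none
#> 1     1            1         25       25         0.84         0
#> 2     1          176        200       25         0.96         0
#> 3     1          201        225       25         0.60         0
#> 4     1          276        300       25         0.72         0
#> 5     1          476        500       25         1.00         0
```

The model acquires action 1 within the first window (84% correct),
locks it (96% just before reversal), drops to chance when the reward
moves to action 2 at trial 200, and relearns by trial ~300.

```r
weight_trajectories(s)
#> <bg_weights> corticostriatal peak at trial 49 ; cortical takeover at trial 53
```

Striatal weights peak near trial 49 and decay as the reward becomes
predicted; from trial 53 the direct cortical weights alone survive a
noise-sized handicap in a probe trial (the choice has been "copied" to
cortex).

```r
set.seed(1)
pd <- parkinsonian_parameters()
st <- integrate_trial(pd, init = random_initial_state(pd),
                      noise = TRUE, record_trace = TRUE)
dominant_oscillation(trial_trace(st))
#> # A tibble: 1 × 4
#>   detected period_ms frequency_hz amplitude
#> 1 TRUE          150.         6.68     0.561
```

A single Parkinsonian trial oscillates at a 150 ms period (6.7 Hz,
theta band) instead of settling — the within-trial signature that makes
Parkinsonian choices phase-random and learning unreliable.

`autoplot()` works on sessions and cohorts; `tidy()`/`glance()` return
per-trial and per-session tibbles. A command-line front end lives at
`inst/scripts/bg_simulate.R`. The methods vignette
(`vignettes/bgloop-methods.Rmd`) documents the model, every calibrated
constant and the package's design choices.

## Acceptance script

    Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json

recomputes, from freshly run simulations: the Parkinsonian oscillation
period (median over 10 noisy trials), the healthy noise-free
equilibration time (worst of 20 random starts), the Parkinsonian
sustained-criterion onset, the healthy reversal exploration end
(median over a 10-animal cohort), and the healthy-minus-Huntington
late-learning performance gap, writing one JSON number per quantity.
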