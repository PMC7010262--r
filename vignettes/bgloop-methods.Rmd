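---
title: "Model and methods: a rate model of the basal-ganglia loop in reward learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a rate model of the basal-ganglia loop in reward learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgloop)
```

## The circuit

`bgloop` simulates a firing-rate model of the cortico-basal-ganglia-
thalamo-cortical loop performing two-choice instrumental conditioning.
The loop is duplicated into two *channels*, one per candidate action.
Thirteen units are modelled: a prefrontal unit (PFC) encoding the
conditioning stimulus, and per channel the D1- and D2-receptor medium
spiny neurons of striatum (direct and indirect pathway entry points),
external pallidum (GPe), subthalamic nucleus (STN), the output nucleus
(GPi, lumped with SNr) and a premotor/thalamic unit (PMC). Each unit's
normalized rate $A \in [0, 1)$ obeys

$$\tau \frac{dA}{dt} = \sigma(I) - A + N(t),$$

with $\sigma(I) = 0$ for $I \le 0$ and $\tanh(I)$ otherwise, unit time
constants of 12.8 ms (STN), 20 ms (GPe) and 15 ms elsewhere, and a
uniform noise forcing $N$. The synaptic input $I$ of each unit combines
tonic drives and weighted rates of its afferents: the direct pathway
(PFC/PMC → D1 → GPi) disinhibits the channel's premotor unit, the
indirect pathway (PFC/PMC → D2 → GPe → STN → GPi) inhibits it, a
hyperdirect PMC → STN projection feeds the subthalamic nucleus, and the
two premotor units inhibit each other reciprocally, implementing the
winner-take-all action competition. An action is *selected* when, at
the end of a 750 ms trial, one premotor rate exceeds the other by more
than 0.1 (the noise level).

## Learning rules

The substantia nigra pars compacta is not integrated as a rate unit;
its dopamine output is the reward-prediction error
$\mathrm{SNc} = g_{DA}\,(R - R^e_j)$, where $R \in \{0, 1\}$ is the
delivered reward, $R^e_j$ the expected reward (initialized at 1 —
subjects are pre-trained — and updated as
$R^e_{j+1} = \alpha R_j + (1-\alpha) R^e_j$ with $\alpha = 0.15$), and
$g_{DA}$ the dopamine gain (1 healthy, 0.3 Parkinsonian).

Between trials, two rules update the six plastic weights using
end-of-trial rates:

* **Dopamine-gated corticostriatal rule.** PFC→D1 weights are
  potentiated by positive dopamine signals, PFC→D2 weights by negative
  ones (reward omission), each proportionally to pre- and postsynaptic
  rates and subject to decay $d$. D2 plasticity runs at half the D1
  rate. Channel selectivity emerges from the postsynaptic factor: the
  channel that won the trial has the more active striatal units.
* **Hebbian cortico-cortical rule.** PFC→PMC weights grow with PFC×PMC
  co-activity, reward-independently, with decay $d_{CM}$. They track
  the running frequency of each choice and are bounded by
  $\lambda_{CM}/d_{CM}$.

Weights are clamped at zero from below. On trials with no selected
action the reward is 0 and all updates still run.

## Parameters that matter, and why these defaults

* `dt = 1` ms, forward Euler, 750 steps per trial. The integrator is
  first order; a dt-halving test guards accuracy. On the Parkinsonian
  limit cycle, pointwise states cannot agree across step sizes (the
  phase drifts), so consistency is asserted on the cycle period there.
* **Noise**: $N$ drawn i.i.d. per unit per step, uniform on
  $[0, 0.1]$, entering the right-hand side as a forcing term (not an
  SDE increment). A zero-mean variant (`noise_symmetric`) is available;
  it lengthens the Parkinsonian period (~164 ms vs the reference
  150 ms), so the positive-support convention is the default.
* **Initial activities**: uniform on $[0, 1]$ per unit per trial
  (`init_max` configurable). This is what makes early choices random.
  We examined narrower ranges (down to $[0, 0.1]$): they let very small
  cortical biases decide the competition, which collapses the
  exploration phases (reversal then completes immediately), so the wide
  default is retained even though it prevents the
  basal-ganglia-ablation experiments from locking onto the previously
  learned choice (see *Known limitations*).
* **Learning rates** $\lambda_{D1} = \lambda_{CM} = 5\times10^{-4}$,
  $\lambda_{D2} = \lambda_{D1}/2$. These are per-integration-step
  scales; the corticostriatal update applied once per trial is scaled
  by `update_gain = 750`, i.e. the rule accumulated over every 1 ms
  step of the 750 ms trial. This puts striatal weights at the
  order-one scale (peaks ≈ 0.5–1 in healthy learning, ≈ 0.7 around
  late initial learning) at which the striatal pathways actually steer
  the premotor competition. The Hebbian rule is *not* gain-boosted
  (`update_gain_cm = 1`): cortical weights must stay on the
  few-hundredths scale, because a cortical bias an order of magnitude
  larger would permanently lock the first learned choice and make
  reversal impossible.
* **Decays** `decay_d = 0.02`, `decay_cm = 0.01` per trial. The
  striatal decay makes PFC–MSN weights rise during acquisition and
  relax toward zero before trial 200 once the reward is fully
  predicted. The cortical decay sets both the Hebbian equilibrium
  ($\lambda_{CM} \cdot \mathrm{PFC} \cdot \mathrm{PMC}/d_{CM} \approx
  0.04$) and the ~100-trial timescale on which the unrewarded
  channel's cortical weight catches up after reversal; with a decay
  five times smaller the catch-up does not finish within the session
  and reversal learning never consolidates.
* **Disease states** are deltas on the healthy set: the Parkinsonian
  state suppresses dopamine output by 70% and shifts striatal
  excitation toward the indirect pathway plus the documented
  pallido-subthalamic changes; the Huntington state weakens D2→GPe by
  75%, D1→GPi by ~35% and reduces cortical drive. `apply_treatment()`
  models a GPi lesion / DBS analogue by zeroing the GPi→PMC weight
  only — the basal ganglia keep running, disconnected.

## What the simulations produce

In the healthy state the model acquires the rewarded action within a
few trials (subjects are pre-trained, and a single reward omission
already moves weights appreciably), locks it, and hands the choice over
from the decaying striatal weights to the slowly growing cortical ones.
After reversal at trial 200 the indirect pathway of the formerly
rewarded channel is potentiated, the system re-enters exploration, and
consistent choice of the new action emerges when the cortical weights
of the two channels cross — near trial 300 (median sustained-criterion
onset 275 across ten seeds in the packaged tests).

The Parkinsonian set turns the loop into a ~150 ms (6.7 Hz, theta
band) oscillator within single trials; the healthy set equilibrates
well before trial end. Because action readout samples the anti-phase
premotor oscillation at the trial end, Parkinsonian choices are nearly
phase-random, no-choice trials (both premotor units suppressed) become
common, and learning is severely impaired — the rewarded option comes
to be chosen more often than the alternative, but never reliably. The
oscillation is a distributed property of the parameter changes:
restoring any single Parkinsonian parameter to its healthy value
(including the premotor-to-D2 weight) does not abolish it; only the
full healthy set is quiescent.

The Huntington set leaves learning largely intact (weights develop the
healthy pattern, persistently elevated because errors keep the
prediction error alive) but the weakened indirect pathway cannot veto
the positive direct-pathway feedback, so the model keeps switching to
the unrewarded option on roughly a third of trials — an exploration
phase that never ends.

## Analysis methods

* **Oscillation detection** removes mean and linear trend from the
  last 600 ms of a trace (the linear term keeps residual equilibration
  transients from masquerading as slow oscillations), takes the global
  autocorrelation maximum beyond the first zero crossing, declares an
  oscillation when that peak exceeds 0.2 and the peak-to-trough
  amplitude exceeds 0.05, and refines the period by a least-squares
  sinusoid fit bracketed around the peak (the truncated
  autocorrelation's peak location is biased by several milliseconds at
  two to three cycles per window; the fit is calibrated to ±2 ms over
  periods 50–300 ms in the test suite).
* **Exploration end** is the first trial of the first 25-trial window
  in which the phase's rewarded action is chosen at least 75% of the
  time with all later windows in the phase also meeting the criterion —
  a concrete stand-in for "consistently chooses". Windowed binary
  choice entropy is reported alongside, with no-choice trials tallied
  separately: random choice and choice blockade are different failure
  modes.
* **Cortical takeover probe.** For each trial's weight snapshot we
  integrate one noise-free trial with corticostriatal weights zeroed,
  starting from a neutral state in which the opposing premotor unit
  receives a head start of one selection threshold (0.1, the model's
  noise scale). The marker is the first trial from which this probe
  succeeds through the end of the phase. The head start is the probe's
  hardness scale and 0.1 is the only scale the model itself supplies: a
  perfectly symmetric start would let an arbitrarily small bias win
  (dating takeover at trial one), while replaying each trial's actual
  random start makes the probe insensitive (the start, not the weights,
  decides about a third of replays regardless of bias). Under the
  packaged calibration the marker falls near trial 50, when the
  cortical weight difference crosses the ~0.013 needed to beat the
  handicap.

## What a green test does and does not establish

The synthetic world is the model itself; there is no external data.
Green tests establish that the implementation reproduces the circuit's
published qualitative regimes (equilibration vs theta oscillation,
acquisition, reversal asymmetry, disease phenotypes) and the printed
quantitative anchors (parameter tables, oscillation period, reversal
timing). They do not establish anything about real basal ganglia
beyond the model's own claims, and quantities that depend on the
unprinted plasticity decay constants (exact weight magnitudes,
takeover timing, the size of the Huntington deficit) carry the
uncertainty of our calibration choices above.

## Known limitations

* The basal-ganglia-ablation ("treatment") experiments do not lock the
  previously rewarded choice in this calibration. Locking requires the
  cortical weight difference (bounded by the 0.04 Hebbian equilibrium)
  to dominate the premotor competition against trial-start variability
  on the $[0,1]$ scale, which measured choice probabilities show to
  require a bias near 0.1. The ablation does reproduce the other half
  of the published treatment result: the within-trial premotor
  variability and the Parkinsonian oscillation vanish completely once
  the pallido-cortical projection is removed. A narrower
  initial-condition range restores lock-in but destroys the
  exploration phases, so within this model family the two published
  behaviors appear mutually exclusive; we kept the exploration-faithful
  default.
* The Parkinsonian model never attains a sustained 75%-correct window:
  its asymptotic correct rate is capped near 0.7 by phase-random
  readout and no-choice trials. The published description ("does not
  reliably choose the rewarded option") matches this behavior; a
  75%-window criterion does not.
* Eligibility traces, spiking dynamics, synaptic delays, GPe lateral
  inhibition, separate thalamic populations and multi-stimulus tasks
  are out of scope.

## Reproducibility

Sessions are deterministic given `session_config()` (one integer seed;
cohort member $k$ uses seed $+\,k-1$). The compiled integrator draws
from R's RNG, so compiled and pure-R engines produce bit-identical
trajectories from the same seed, which the test suite asserts.
`scripts/acceptance.R` recomputes the headline quantities from scratch
for any seed.
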