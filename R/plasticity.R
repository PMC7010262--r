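# Dopamine reward-prediction-error signal and the two between-trial
# learning rules: DA-gated corticostriatal and Hebbian cortico-cortical.

#' Dopamine reward-prediction-error signal
#'
#' The nigral dopamine signal is the difference between the received and
#' the expected reward, scaled by the dopamine output gain (1 healthy,
#' 0.3 in the mild Parkinsonian state, i.e. 70% suppression).
#'
#' @param reward Received reward, 0 or 1 (0 also when no action was
#'   selected).
#' @param expected_reward Current expected reward in `[0, 1]`.
#' @param da_gain Dopamine output gain in `[0, 1]`.
#' @return The signed dopamine signal; its magnitude never exceeds
#'   `da_gain`.
#' @export
#' @examples
#' compute_rpe(0, 1)          # omission of a fully expected reward
#' compute_rpe(0, 1, 0.3)     # same under 70% dopamine suppression
compute_rpe <- function(reward, expected_reward, da_gain = 1) {
  stopifnot(reward %in% c(0, 1),
            expected_reward >= 0, expected_reward <= 1)
  da_gain * (reward - expected_reward)
}

#' Update the expected reward
#'
#' Exponentially weighted running average of received rewards:
#' `Re <- alpha * R + (1 - alpha) * Re`. The expectation starts at 1
#' (animals are pre-trained on a single-choice task and expect reward)
#' and stays in `[0, 1]` for any reward sequence.
#'
#' @inheritParams compute_rpe
#' @param alpha Update rate (default 0.15).
#' @return The new expected reward.
#' @export
update_expected_reward <- function(expected_reward, reward, alpha = 0.15) {
  stopifnot(reward %in% c(0, 1), alpha >= 0, alpha <= 1)
  alpha * reward + (1 - alpha) * expected_reward
}

#' Corticostriatal weight increments (dopamine-gated)
#'
#' Three-factor rule applied once per trial with end-of-trial rates:
#' for each channel m,
#' `dw_d1[m] = gain * lambda_d1 * SNc * PFC * D1_m - d * w_d1[m]` and
#' `dw_d2[m] = -gain * lambda_d2 * SNc * PFC * D2_m - d * w_d2[m]`.
#' A positive dopamine signal potentiates inputs to D1 neurons; a
#' negative one (reward omission) potentiates inputs to D2 neurons.
#' Selectivity comes from the postsynaptic rate: the channel whose PMC
#' won the trial has the more active striatal neurons and receives the
#' larger update.
#'
#' @param snc Dopamine signal from [compute_rpe()].
#' @param end_state End-of-trial activity state.
#' @param weights Current plastic weight vector.
#' @param rates A [plasticity_rates()] object.
#' @return Named increments for the four corticostriatal weights.
#' @export
corticostriatal_deltas <- function(snc, end_state, weights,
                                   rates = plasticity_rates()) {
  s <- as_bg_state(end_state)
  g <- rates$update_gain
  pfc <- s[["PFC"]]
  d <- rates$decay_d
  out <- c(
    w_pfc_d1_1 = g * rates$lambda_d1 * snc * pfc * s[["D1_1"]] -
      d * weights[["w_pfc_d1_1"]],
    w_pfc_d1_2 = g * rates$lambda_d1 * snc * pfc * s[["D1_2"]] -
      d * weights[["w_pfc_d1_2"]],
    w_pfc_d2_1 = -g * rates$lambda_d2 * snc * pfc * s[["D2_1"]] -
      d * weights[["w_pfc_d2_1"]],
    w_pfc_d2_2 = -g * rates$lambda_d2 * snc * pfc * s[["D2_2"]] -
      d * weights[["w_pfc_d2_2"]]
  )
  if (any(!is.finite(out))) stop("non-finite plasticity increment")
  out
}

#' Cortico-cortical weight increments (Hebbian)
#'
#' Reward-independent Hebbian rule applied once per trial with
#' end-of-trial rates:
#' `dw_cm[m] = gain_cm * lambda_cm * PFC * PMC_m - d_cm * w_cm[m]`.
#' Cortical weights therefore track the running frequency of each
#' choice, bounded above by `gain_cm * lambda_cm / d_cm`.
#'
#' @inheritParams corticostriatal_deltas
#' @return Named increments for the two PFC-to-PMC weights.
#' @export
cortical_deltas <- function(end_state, weights,
                            rates = plasticity_rates()) {
  s <- as_bg_state(end_state)
  g <- rates$update_gain_cm
  out <- c(
    w_pfc_pmc_1 = g * rates$lambda_cm * s[["PFC"]] * s[["PMC_1"]] -
      rates$decay_cm * weights[["w_pfc_pmc_1"]],
    w_pfc_pmc_2 = g * rates$lambda_cm * s[["PFC"]] * s[["PMC_2"]] -
      rates$decay_cm * weights[["w_pfc_pmc_2"]]
  )
  if (any(!is.finite(out))) stop("non-finite plasticity increment")
  out
}

#' Apply weight increments with a non-negativity clamp
#'
#' @param weights Current plastic weight vector.
#' @param deltas Named increments (any subset of the six weights).
#' @return The updated weight vector, clamped at 0 from below.
#' @export
apply_updates <- function(weights, deltas) {
  if (any(!is.finite(deltas))) stop("non-finite plasticity increment")
  w <- weights
  w[names(deltas)] <- w[names(deltas)] + deltas
  pmax(w, 0)
}
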