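# The 13-unit two-channel loop: response function, synaptic inputs,
# Euler stepping and within-trial integration.

#' Names of the 13 model units
#'
#' One PFC unit plus, per action channel m in {1, 2}: D1 and D2 medium
#' spiny neurons, GPe, STN, GPi (lumped with SNr) and PMC (lumped with
#' thalamus).
#' @return Character vector of length 13.
#' @export
bg_unit_names <- function() {
  c("PFC",
    "D1_1", "D1_2", "D2_1", "D2_2",
    "GPe_1", "GPe_2", "STN_1", "STN_2",
    "GPi_1", "GPi_2", "PMC_1", "PMC_2")
}

#' Normalized firing-rate response function
#'
#' Rectified hyperbolic tangent: 0 for inputs at or below zero,
#' `tanh(I)` above. Maps any synaptic input into a normalized rate in
#' `[0, 1)`; continuous and monotone non-decreasing.
#'
#' @param I Numeric vector of synaptic inputs (finite).
#' @return Numeric vector of normalized rates.
#' @export
#' @examples
#' response_function(c(-2, 0, 0.5))
response_function <- function(I) {
  if (!is.numeric(I) || any(!is.finite(I)))
    stop("synaptic input must be finite numeric")
  ifelse(I > 0, tanh(I), 0)
}

#' Construct / initialize the plastic weight vector
#'
#' The six trial-varying synaptic weights: PFC to D1, PFC to D2 and PFC
#' to PMC, per channel. `plastic_weights()` builds one from explicit
#' values; `init_plastic_weights()` draws the session-start state:
#' corticostriatal weights uniform on `[0, init_weight_max]` (default
#' `[0, 0.001]`), cortical weights exactly 0.
#'
#' @param d1,d2,pmc Length-2 numeric vectors (channel 1, channel 2) of
#'   non-negative weights.
#' @return Named numeric vector of length 6 with names
#'   `w_pfc_d1_1, w_pfc_d1_2, w_pfc_d2_1, w_pfc_d2_2,
#'    w_pfc_pmc_1, w_pfc_pmc_2`.
#' @export
plastic_weights <- function(d1 = c(0, 0), d2 = c(0, 0), pmc = c(0, 0)) {
  w <- c(d1, d2, pmc)
  if (length(w) != 6 || any(!is.finite(w)) || any(w < 0))
    stop("plastic weights must be six finite non-negative values")
  names(w) <- plastic_weight_names()
  w
}

plastic_weight_names <- function() {
  c("w_pfc_d1_1", "w_pfc_d1_2", "w_pfc_d2_1", "w_pfc_d2_2",
    "w_pfc_pmc_1", "w_pfc_pmc_2")
}

#' @rdname plastic_weights
#' @param params A [bg_params()] object (supplies `init_weight_max`).
#' @export
init_plastic_weights <- function(params = healthy_parameters()) {
  m <- params$plasticity$init_weight_max
  plastic_weights(d1 = stats::runif(2, 0, m),
                  d2 = stats::runif(2, 0, m),
                  pmc = c(0, 0))
}

#' Random initial activity state
#'
#' Each of the 13 units starts a trial at an independent uniform
#' activity on `[0, init_max]` (default `[0, 1]`), emulating an
#' uncontrolled pre-trial network state. The wide default makes early
#' zero-weight choices random; small values start trials near rest so
#' that weak synaptic biases dominate the competition.
#'
#' @param params A [bg_params()] object, or a number giving the upper
#'   bound directly.
#' @return Named numeric vector of length 13.
#' @export
random_initial_state <- function(params = healthy_parameters()) {
  m <- if (is.numeric(params)) params else params$init_max
  stats::setNames(stats::runif(13, 0, m), bg_unit_names())
}

as_bg_state <- function(state) {
  if (length(state) != 13 || any(!is.finite(state)))
    stop("state must be 13 finite activities")
  if (is.null(names(state))) names(state) <- bg_unit_names()
  state[bg_unit_names()]
}

# Fixed-order parameter vector consumed by the compiled integrator.
bg_par_vector <- function(params) {
  c(params$input_pfc, params$w_PMC_D1, params$w_PMC_D2, params$dr_GPe,
    params$w_D2_GPe, params$dr_STN, params$w_GPe_STN, params$dr_GPi,
    params$w_D1_GPi, params$w_STN_GPi, params$dr_PMC, params$w_GPi_PMC,
    params$w_PMC_PMC, params$w_STN_GPe, params$w_HD,
    params$tau_STN, params$tau_GPe, params$tau_default, params$dt)
}

noise_bounds <- function(params, noise = TRUE) {
  if (!noise || params$noise_amplitude == 0) return(c(0, 0))
  a <- params$noise_amplitude
  if (isTRUE(params$noise_symmetric)) c(-a / 2, a / 2) else c(0, a)
}

#' Synaptic input to every unit
#'
#' Evaluates the per-unit input formulas of the loop: PFC receives only
#' its tonic stimulus drive; striatal neurons sum cortical (PFC, plastic)
#' and premotor (static) excitation; GPe, STN and GPi combine their tonic
#' drives with pathway-specific excitation and inhibition (including the
#' hyperdirect PMC-to-STN projection); PMC combines its drive, the
#' plastic PFC input, inhibition from GPi and reciprocal inhibition from
#' the other channel's PMC.
#'
#' @param state Named activity vector (see [bg_unit_names()]).
#' @param params A [bg_params()] object.
#' @param weights Plastic weight vector (see [plastic_weights()]).
#' @return Named numeric vector of 13 synaptic inputs.
#' @export
synaptic_inputs <- function(state, params, weights) {
  s <- as_bg_state(state)
  p <- params
  w <- weights
  I <- numeric(13)
  names(I) <- bg_unit_names()
  I["PFC"] <- p$input_pfc
  for (m in 1:2) {
    n <- 3 - m
    pmc <- s[paste0("PMC_", m)]
    I[paste0("D1_", m)] <- w[paste0("w_pfc_d1_", m)] * s["PFC"] +
      p$w_PMC_D1 * pmc
    I[paste0("D2_", m)] <- w[paste0("w_pfc_d2_", m)] * s["PFC"] +
      p$w_PMC_D2 * pmc
    I[paste0("GPe_", m)] <- p$dr_GPe - p$w_D2_GPe * s[paste0("D2_", m)] +
      p$w_STN_GPe * s[paste0("STN_", m)]
    I[paste0("STN_", m)] <- p$dr_STN - p$w_GPe_STN * s[paste0("GPe_", m)] +
      p$w_HD * pmc
    I[paste0("GPi_", m)] <- p$dr_GPi - p$w_D1_GPi * s[paste0("D1_", m)] +
      p$w_STN_GPi * s[paste0("STN_", m)]
    I[paste0("PMC_", m)] <- p$dr_PMC +
      w[paste0("w_pfc_pmc_", m)] * s["PFC"] -
      p$w_GPi_PMC * s[paste0("GPi_", m)] -
      p$w_PMC_PMC * s[paste0("PMC_", n)]
  }
  I
}

#' One forward-Euler step of the loop
#'
#' Updates every unit by `A <- A + (dt / tau) * (sigma(I) - A + N)`,
#' with the unit-specific time constant (STN 12.8 ms, GPe 20 ms,
#' 15 ms elsewhere) and `N` drawn i.i.d. per unit from the configured
#' uniform noise. Pure-R reference implementation; session-scale work
#' goes through the compiled integrator in [integrate_trial()].
#'
#' @inheritParams synaptic_inputs
#' @param noise Logical; draw the noise forcing this step?
#' @return The next activity state (named numeric, length 13).
#' @export
step_state <- function(state, params, weights, noise = TRUE) {
  s <- as_bg_state(state)
  I <- synaptic_inputs(s, params, weights)
  tau <- rep(params$tau_default, 13)
  names(tau) <- bg_unit_names()
  tau[c("STN_1", "STN_2")] <- params$tau_STN
  tau[c("GPe_1", "GPe_2")] <- params$tau_GPe
  nb <- noise_bounds(params, noise)
  N <- if (nb[2] > nb[1]) stats::runif(13, nb[1], nb[2]) else rep(0, 13)
  s + params$dt / tau * (response_function(I) - s + N)
}

#' Integrate one 750 ms trial
#'
#' Runs the forward-Euler integration for `trial_duration / dt` steps
#' and returns the end-of-trial state. With `record_trace = TRUE` the
#' full trajectory (including the initial state) is attached as a tibble
#' with a `t_ms` column, retrievable via [trial_trace()].
#'
#' @param params A [bg_params()] object.
#' @param weights Plastic weight vector; defaults to all zero.
#' @param init Initial activity state; defaults to a fresh
#'   [random_initial_state()] draw.
#' @param noise Logical; apply the uniform noise forcing?
#' @param record_trace Logical; keep the within-trial trajectory?
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference;
#'   identical results for the same RNG state).
#' @return Named end-of-trial state; with `record_trace`, the trace
#'   tibble is attached as attribute `"trace"`.
#' @export
#' @examples
#' set.seed(1)
#' s <- integrate_trial(healthy_parameters(), noise = FALSE,
#'                      init = rep(0.5, 13))
#' s[c("PMC_1", "PMC_2")]
integrate_trial <- function(params, weights = plastic_weights(),
                            init = NULL, noise = TRUE,
                            record_trace = FALSE,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  init <- if (is.null(init)) random_initial_state(params)
          else as_bg_state(init)
  n_steps <- as.integer(round(params$trial_duration / params$dt))
  nb <- noise_bounds(params, noise)
  if (engine == "cpp") {
    out <- bg_integrate_cpp(unname(init), bg_par_vector(params),
                            unname(weights[plastic_weight_names()]),
                            n_steps, nb[1], nb[2], record_trace)
    colnames(out) <- bg_unit_names()
    final <- stats::setNames(out[nrow(out), ], bg_unit_names())
  } else {
    trace <- if (record_trace)
      matrix(NA_real_, n_steps + 1, 13,
             dimnames = list(NULL, bg_unit_names()))
    s <- init
    if (record_trace) trace[1, ] <- s
    for (k in seq_len(n_steps)) {
      s <- step_state(s, params, weights, noise = nb[2] > nb[1])
      if (record_trace) trace[k + 1, ] <- s
    }
    out <- if (record_trace) trace else matrix(s, 1)
    final <- stats::setNames(s, bg_unit_names())
  }
  if (record_trace) {
    tr <- tibble::as_tibble(as.data.frame(out))
    tr <- dplyr::mutate(tr, t_ms = seq(0, by = params$dt,
                                       length.out = nrow(tr)),
                        .before = 1)
    attr(final, "trace") <- tr
  }
  final
}

#' Extract the within-trial trace recorded by [integrate_trial()]
#'
#' @param state Result of `integrate_trial(..., record_trace = TRUE)`.
#' @return Tibble with columns `t_ms` plus the 13 unit names.
#' @export
trial_trace <- function(state) {
  tr <- attr(state, "trace")
  if (is.null(tr)) stop("no trace recorded; use record_trace = TRUE")
  tr
}

#' Write a within-trial trace to CSV
#'
#' @param state Result of `integrate_trial(..., record_trace = TRUE)`
#'   or a trace tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(state, path) {
  tr <- if (is.data.frame(state)) state else trial_trace(state)
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' Read out the selected action from an end-of-trial state
#'
#' Action m is called selected when its premotor activity exceeds the
#' other channel's by more than the selection threshold (default 0.1,
#' the noise amplitude). If neither does, no action is selected.
#'
#' @param end_state Named end-of-trial activity state.
#' @param threshold Required premotor rate difference.
#' @return `1L`, `2L`, or `NA_integer_` for no selection.
#' @export
#' @examples
#' s <- stats::setNames(rep(0, 13), bg_unit_names())
#' s["PMC_1"] <- 0.8; s["PMC_2"] <- 0.3
#' select_action(s)
select_action <- function(end_state, threshold = 0.1) {
  s <- as_bg_state(end_state)
  d <- s[["PMC_1"]] - s[["PMC_2"]]
  if (d > threshold) 1L else if (-d > threshold) 2L else NA_integer_
}
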