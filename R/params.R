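# Parameter sets for the three calibrated basal-ganglia states.

#' Construct a basal-ganglia loop parameter set
#'
#' Builds the full static parameterization of the two-channel
#' cortico-basal-ganglia-thalamo-cortical rate model: synaptic weights,
#' tonic drives, unit time constants, noise settings, the dopamine output
#' gain and the integration settings. Defaults are the calibrated healthy
#' state; pass overrides by name to derive other states.
#'
#' Signs are encoded in the synaptic-input formulas (see
#' [synaptic_inputs()]), so all weights and drives are configured as
#' non-negative magnitudes.
#'
#' @param ... Named overrides of any parameter field. The `plasticity`
#'   field may be given as a named list overriding a subset of the
#'   plasticity settings (see [plasticity_rates()]).
#' @param condition Label for the parameter state
#'   (`"healthy"`, `"parkinsonian"`, `"huntington"`).
#'
#' @return An object of class `bg_params`: a named list with fields
#' \describe{
#'   \item{input_pfc}{tonic drive to PFC encoding the conditioning stimulus}
#'   \item{w_PMC_D1, w_PMC_D2}{static premotor-to-striatal weights}
#'   \item{dr_GPe, dr_STN, dr_GPi, dr_PMC}{tonic drives}
#'   \item{w_D2_GPe, w_GPe_STN, w_STN_GPe, w_D1_GPi, w_STN_GPi,
#'     w_GPi_PMC, w_PMC_PMC, w_HD}{static pathway weights
#'     (`w_PMC_PMC` is the reciprocal premotor inhibition, `w_HD` the
#'     hyperdirect cortex-to-STN projection)}
#'   \item{tau_STN, tau_GPe, tau_default}{unit time constants (ms)}
#'   \item{noise_amplitude}{amplitude of the uniform noise forcing}
#'   \item{noise_symmetric}{if `TRUE`, noise is uniform on
#'     `[-amplitude/2, amplitude/2]` instead of `[0, amplitude]`}
#'   \item{init_max}{upper bound of the uniform per-unit initial
#'     activity drawn at each trial start (default 1: any normalized
#'     rate is a possible pre-trial state, which is what makes early
#'     choices random; smaller values start trials near rest and let
#'     weak synaptic biases dominate the competition)}
#'   \item{da_gain}{multiplicative dopamine output factor (1 healthy,
#'     0.3 mild Parkinsonian)}
#'   \item{dt, trial_duration}{integration step and trial length (ms)}
#'   \item{selection_threshold}{premotor rate difference required to call
#'     an action selected}
#'   \item{plasticity}{learning-rule settings, see [plasticity_rates()]}
#' }
#' @seealso [healthy_parameters()], [parkinsonian_parameters()],
#'   [huntington_parameters()], [apply_treatment()]
#' @export
#' @examples
#' p <- bg_params()
#' p$w_D1_GPi
#' bg_params(dt = 0.5)$dt
bg_params <- function(..., condition = "healthy") {
  p <- list(
    input_pfc  = 3.0,
    w_PMC_D1   = 2.0,
    w_PMC_D2   = 2.0,
    dr_GPe     = 1.6,
    w_D2_GPe   = 2.0,
    dr_STN     = 0.8,
    w_GPe_STN  = 1.0,
    dr_GPi     = 0.2,
    w_D1_GPi   = 1.4,
    w_STN_GPi  = 1.6,
    dr_PMC     = 1.3,
    w_GPi_PMC  = 1.8,
    w_PMC_PMC  = 1.6,
    w_STN_GPe  = 0.4,
    w_HD       = 0.3,
    tau_STN    = 12.8,
    tau_GPe    = 20,
    tau_default = 15,
    noise_amplitude = 0.1,
    noise_symmetric = FALSE,
    init_max = 1.0,
    da_gain    = 1.0,
    dt         = 1,
    trial_duration = 750,
    selection_threshold = 0.1,
    plasticity = plasticity_rates(),
    condition  = condition
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    if (!is.null(dots$plasticity)) {
      dots$plasticity <- utils::modifyList(p$plasticity, dots$plasticity)
      class(dots$plasticity) <- "bg_plasticity_rates"
    }
    p[names(dots)] <- dots
  }
  validate_bg_params(structure(p, class = "bg_params"))
}

#' Plasticity rate settings
#'
#' Learning-rule constants shared by the session runner: the
#' reward-expectation update rate, the dopamine-gated corticostriatal
#' learning rates (`lambda_d1`, `lambda_d2 = lambda_d1 / 2`, reflecting
#' the roughly two-fold weaker plasticity of synapses on D2 relative to
#' D1 medium spiny neurons), the Hebbian cortical rate `lambda_cm`,
#' per-trial decay constants, and per-trial update gains.
#'
#' `update_gain` scales the dopamine-gated increments: the learning
#' rate constants are on a per-integration-step scale, and the default
#' gain of 750 corresponds to accumulating the rule over every 1 ms
#' step of the 750 ms trial, applied once at trial end. This puts the
#' corticostriatal weights on the order-one scale at which the striatal
#' pathways steer the premotor competition. The Hebbian rule keeps
#' `update_gain_cm = 1` so cortical weights stay on the small scale
#' (a few hundredths) that permits reversal learning.
#'
#' @param alpha Expected-reward update rate.
#' @param lambda_d1,lambda_d2 Corticostriatal learning rates for synapses
#'   onto D1 and D2 medium spiny neurons.
#' @param lambda_cm Hebbian learning rate for PFC-to-PMC synapses.
#' @param decay_d,decay_cm Per-trial multiplicative decay of the
#'   corticostriatal and cortical plastic weights.
#' @param update_gain,update_gain_cm Per-trial gains applied to the
#'   corticostriatal and Hebbian increments (decay is not scaled).
#' @param init_weight_max Upper bound of the uniform distribution used to
#'   initialize corticostriatal weights at session start.
#' @return A `bg_plasticity_rates` list.
#' @export
plasticity_rates <- function(alpha = 0.15,
                             lambda_d1 = 5e-4,
                             lambda_d2 = lambda_d1 / 2,
                             lambda_cm = 5e-4,
                             decay_d = 0.02,
                             decay_cm = 0.01,
                             update_gain = 750,
                             update_gain_cm = 1,
                             init_weight_max = 0.001) {
  r <- list(alpha = alpha, lambda_d1 = lambda_d1, lambda_d2 = lambda_d2,
            lambda_cm = lambda_cm, decay_d = decay_d, decay_cm = decay_cm,
            update_gain = update_gain, update_gain_cm = update_gain_cm,
            init_weight_max = init_weight_max)
  stopifnot(all(vapply(r, is.numeric, logical(1))),
            all(unlist(r) >= 0), alpha <= 1)
  structure(r, class = "bg_plasticity_rates")
}

validate_bg_params <- function(p) {
  weight_fields <- c("input_pfc", "w_PMC_D1", "w_PMC_D2", "dr_GPe",
                     "w_D2_GPe", "dr_STN", "w_GPe_STN", "dr_GPi",
                     "w_D1_GPi", "w_STN_GPi", "dr_PMC", "w_GPi_PMC",
                     "w_PMC_PMC", "w_STN_GPe", "w_HD")
  vals <- unlist(p[weight_fields])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all weights and drives must be finite and >= 0 ",
         "(signs live in the input formulas, not the values)")
  taus <- unlist(p[c("tau_STN", "tau_GPe", "tau_default")])
  if (any(taus <= 0)) stop("time constants must be positive")
  if (p$dt <= 0) stop("dt must be positive")
  if (p$dt > min(taus) / 4)
    stop("dt must not exceed min(tau)/4 for a stable Euler step")
  if (p$da_gain < 0 || p$da_gain > 1) stop("da_gain must be in [0, 1]")
  if (p$noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  if (p$init_max < 0 || p$init_max > 1)
    stop("init_max must be in [0, 1]")
  if (p$trial_duration <= 0 ||
      abs(p$trial_duration / p$dt - round(p$trial_duration / p$dt)) > 1e-9)
    stop("trial_duration must be a positive multiple of dt")
  p
}

#' @export
print.bg_params <- function(x, ...) {
  cat("<bg_params> condition:", x$condition, "\n")
  num <- vapply(x[setdiff(names(x), c("plasticity", "condition",
                                      "noise_symmetric"))],
                identity, numeric(1))
  print(num)
  cat("plasticity:\n")
  print(vapply(unclass(x$plasticity), identity, numeric(1)))
  invisible(x)
}

#' Calibrated healthy parameter state
#'
#' The reference parameterization under which the model acquires a
#' rewarded choice within tens of trials, relearns after reversal, and
#' whose within-trial dynamics settle to a steady state well before the
#' end of a 750 ms trial.
#'
#' @return A [bg_params()] object.
#' @export
healthy_parameters <- function() bg_params(condition = "healthy")

#' Mild Parkinsonian parameter state
#'
#' Derived from the healthy state by suppressing dopamine output by 70%
#' (`da_gain = 0.3`) and shifting the striatal excitation balance toward
#' the indirect pathway: weakened premotor drive to D1 and strengthened
#' drive to D2 medium spiny neurons, together with the documented changes
#' in pallido-subthalamic coupling and output-nucleus drive. The
#' strengthened indirect-pathway negative feedback makes the loop
#' oscillate within trials at roughly a 150 ms period (theta band).
#'
#' @return A [bg_params()] object.
#' @export
parkinsonian_parameters <- function() {
  bg_params(
    w_PMC_D1  = 1.25,
    w_PMC_D2  = 2.75,
    w_D2_GPe  = 2.4,
    w_GPe_STN = 1.2,
    dr_STN    = 1.0,
    dr_GPi    = 0.25,
    w_D1_GPi  = 1.1,
    w_STN_GPi = 2.0,
    w_STN_GPe = 0.5,
    da_gain   = 0.3,
    condition = "parkinsonian"
  )
}

#' Grade 2 Huntington's disease parameter state
#'
#' Derived from the healthy state by weakening the indirect-pathway
#' D2-to-GPe connection by 75% and the direct-pathway D1-to-GPi
#' connection by about 35%, and reducing cortical inputs (PFC drive and
#' premotor-to-striatal weights) to reflect cortical degeneration.
#' Dopamine output is unaffected.
#'
#' @return A [bg_params()] object.
#' @export
huntington_parameters <- function() {
  bg_params(
    input_pfc = 0.8,
    w_PMC_D1  = 1.5,
    w_PMC_D2  = 1.5,
    w_D1_GPi  = 0.9,
    w_D2_GPe  = 0.5,
    condition = "huntington"
  )
}

#' Resolve a condition name to its parameter set
#'
#' @param condition `"healthy"`, `"parkinsonian"` (alias `"pd"`) or
#'   `"huntington"` (alias `"hd"`), or an existing [bg_params()] object
#'   which is returned unchanged.
#' @return A [bg_params()] object.
#' @export
condition_parameters <- function(condition) {
  if (inherits(condition, "bg_params")) return(condition)
  switch(match.arg(tolower(condition),
                   c("healthy", "parkinsonian", "pd", "huntington", "hd")),
         healthy = healthy_parameters(),
         parkinsonian = ,
         pd = parkinsonian_parameters(),
         huntington = ,
         hd = huntington_parameters())
}

#' Ablate the basal-ganglia output to premotor cortex
#'
#' Models a GPi lesion (or, functionally, deep-brain stimulation) by
#' removing the inhibitory projection from the output nuclei to premotor
#' cortex: `w_GPi_PMC` is set to 0. The rest of the loop keeps running;
#' it is simply disconnected from the premotor competition.
#'
#' @param params A [bg_params()] object.
#' @return A copy of `params` with `w_GPi_PMC = 0`. Idempotent.
#' @export
#' @examples
#' apply_treatment(healthy_parameters())$w_GPi_PMC
apply_treatment <- function(params) {
  stopifnot(inherits(params, "bg_params"))
  params$w_GPi_PMC <- 0
  params
}

#' Differences of a parameter set from the healthy state
#'
#' @param params A [bg_params()] object.
#' @return A tibble with one row per differing numeric field:
#'   `parameter`, `healthy`, `value`.
#' @export
condition_diff <- function(params) {
  stopifnot(inherits(params, "bg_params"))
  h <- healthy_parameters()
  fields <- names(h)[vapply(h, function(x) is.numeric(x) &&
                              length(x) == 1, logical(1))]
  diff <- fields[vapply(fields, function(f)
    !isTRUE(all.equal(h[[f]], params[[f]])), logical(1))]
  tibble::tibble(
    parameter = diff,
    healthy = vapply(diff, function(f) h[[f]], numeric(1)),
    value = vapply(diff, function(f) params[[f]], numeric(1))
  )
}

#' Write / read a parameter configuration file
#'
#' Flat JSON serialization of a [bg_params()] object; keys are the field
#' names (e.g. `w_D2_GPe`, `dr_STN`) with the plasticity settings nested
#' under `plasticity`.
#'
#' @param params A [bg_params()] object.
#' @param path File path.
#' @return `write_bg_config()` returns `path` invisibly;
#'   `read_bg_config()` returns a validated [bg_params()] object.
#' @export
write_bg_config <- function(params, path) {
  stopifnot(inherits(params, "bg_params"))
  x <- unclass(params)
  x$plasticity <- unclass(x$plasticity)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bg_config
#' @export
read_bg_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cond <- x$condition %||% "healthy"
  x$condition <- NULL
  num <- function(v) if (is.numeric(v)) as.numeric(v) else v
  x <- lapply(x, num)
  if (!is.null(x$plasticity))
    x$plasticity <- lapply(as.list(x$plasticity), num)
  do.call(bg_params, c(x, list(condition = cond)))
}
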