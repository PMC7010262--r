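# Shared fixtures: all built in code at test time.

zero_state <- function() {
  stats::setNames(rep(0, 13), bg_unit_names())
}

# a state with the named units overridden
state_with <- function(...) {
  s <- zero_state()
  vals <- list(...)
  s[names(vals)] <- unlist(vals)
  s
}

# noise-free relaxation to (near) fixed point
relax <- function(params, weights = plastic_weights(), init = rep(0.2, 13),
                  steps = 5000) {
  s <- stats::setNames(init, bg_unit_names())
  p <- params
  p$trial_duration <- steps * p$dt
  integrate_trial(p, weights, init = s, noise = FALSE)
}

# swap the two channels of a state vector or weight vector
swap_channels <- function(x) {
  nm <- names(x)
  swapped <- sub("_1$", "_TMP", nm)
  swapped <- sub("_2$", "_1", swapped)
  swapped <- sub("_TMP$", "_2", swapped)
  out <- x
  names(out) <- swapped
  out[nm]
}
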