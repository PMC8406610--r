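# shared fixtures: recordings built in code, plus independent oracles

default_cfg <- pushup_config()

# recording with an exactly constant feet force: quiet hold, cosine-shaped
# hands unloading to zero, feet pinned at `feet_const`
make_constant_feet_recording <- function(hands_static = 454,
                                         feet_const = 235,
                                         fs = 1000) {
  tt <- seq(0, 2.1, by = 1 / fs)
  hands <- ifelse(tt < 0.8, hands_static,
                  ifelse(tt < 1.8,
                         hands_static * (1 + cos(pi * (tt - 0.8))) / 2,
                         0))
  pushup_recording(force_trace(hands, fs, "hands"),
                   force_trace(rep(feet_const, length(tt)), fs, "feet"))
}

# baseline object built directly (for phase-detection unit tests)
make_baseline <- function(hands_static, feet_static = 235,
                          gravity = 9.81) {
  bw <- hands_static + feet_static
  structure(list(body_weight = bw, hands_static = hands_static,
                 feet_static = feet_static, body_mass = bw / gravity,
                 window = c(0, 0.5)),
            class = "pushup_baseline")
}

# brute-force first-crossing scan: the independent oracle for detect_phase
scan_phase_oracle <- function(x, hands_static, threshold) {
  start <- NA_integer_
  for (i in seq_along(x)) {
    if (x[i] < hands_static - threshold) { start <- i; break }
  }
  if (is.na(start)) return(list(start = NA, end = NA))
  end <- NA_integer_
  for (i in seq(start + 1, length(x))) {
    if (x[i] < threshold) { end <- i; break }
  }
  list(start = start, end = end)
}

# simulator parameters whose feet force stays at or below its static value
# throughout the phase (deep dip, no end rise, deep takeoff tail)
dominance_params <- function(body_mass = 70.2, push_peak_accel = 4.3,
                             seed = NULL) {
  sim_params(body_mass = body_mass,
             push_peak_accel = push_peak_accel,
             feet_dip_depth = 0.12,
             feet_end_share = 0.34 - 0.12,
             tail_drop_g = 0.99,
             noise_sd_N = 0,
             seed = seed)
}
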