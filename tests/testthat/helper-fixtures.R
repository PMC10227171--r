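# Deterministic, noise-free observer: pursuit gain 1, no latencies except
# the detection latency, no misses/false alarms/drift, unbiased TTC press.
noiseless_params <- function(...) {
  base <- list(
    pursuit_gain = 1, pursuit_latency = 0,
    detection_latency_sd = 0, miss_rate = 0, false_alarm_rate = 0,
    landing_noise_sd = 0, fixation_noise_sd = 0, pursuit_noise_sd = 0,
    measurement_noise_sd = 0, vertical_noise_sd = 0,
    ttc_response_sd = 0, invalid_trial_rate = 0
  )
  do.call(oculomotor_params, utils::modifyList(base, list(...)))
}

# Reference perturbation trial: slow-down to 3 deg/s, late occlusion.
ref_timeline <- function(speed = 3, occlusion = 1.0, ...) {
  build_timeline(trial_design(speed = speed, occlusion = occlusion, ...))
}

# Synthetic gaze holding still then jumping: a hand-built saccade-free ramp.
ramp_gaze <- function(rate = 4, dur = 2, fs = 200) {
  t <- seq(0, dur, by = 1 / fs)
  tibble::tibble(t = t, x = rate * t, y = 0)
}
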