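# Shared fixtures: small synthetic sessions built in code.

small_session <- function(seed = 3, n_neurons = 60, duration = 240, ...) {
  simulate_session(synth_config(n_neurons = n_neurons, duration = duration,
                                seed = seed, ...))
}

# a stepped-gain baseline-only session: 3 min at gain 1, then alternating
# 60-s blocks of gain `low` and 1
stepped_gain_session <- function(seed = 7, n_neurons = 80, low = 0.6,
                                 duration = 360, frame_rate = 30) {
  nf <- duration * frame_rate
  gain <- rep(1, nf)
  gain[(180 * frame_rate + 1):(240 * frame_rate)] <- low
  if (duration >= 360)
    gain[(300 * frame_rate + 1):(360 * frame_rate)] <- low
  cfg <- synth_config(n_neurons = n_neurons, duration = duration,
                      gain_profile = gain, seed = seed,
                      frame_rate = frame_rate)
  proto <- build_protocol(cfg)
  hd <- simulate_trajectory(cfg, proto$n_frames)
  out <- generate_population(cfg, hd, true_gain = gain,
                             cue_angle = proto$cue_angle,
                             epochs = proto$epochs)
  out$gain <- gain
  out$baseline <- seq_len(180 * frame_rate)
  out
}

# synthetic reset trajectories: exponential approach to `shift` degrees
# with time constant tau_s, plus angular noise
make_reset_family <- function(n, tau_s, shift = 90, frames = 1450,
                              frame_rate = 30, noise_sd = 3, seed = 1) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    tt <- (seq_len(frames) - 1) / frame_rate
    shift * (1 - exp(-tt / tau_s)) + stats::rnorm(frames, 0, noise_sd)
  }, numeric(frames)))
}
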