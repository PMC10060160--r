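# Ring-attractor model of the head-direction system with network gain,
# Hebbian association to stable allocentric cues, and asymmetric
# vestibular recalibration.
#
# Rate dynamics (threshold-linear continuous attractor):
#
#   tau dr/dt = -r + g_mod * relu(W_eff r_n + b) + I_cue + I_env
#
# with r_n the rates normalized to unit total (so the recurrent drive sets
# the bump *shape* while g_mod sets its amplitude: total steady-state rate
# scales linearly with gain, and external cue input competes against a
# weaker bump when gain is low - which is what makes low gain speed up
# resets). W_eff = cosine excitation/global-inhibition kernel plus a
# velocity-scaled derivative (asymmetric) kernel that translates the bump
# at the commanded angular velocity, scaled by sign-specific vestibular
# gains. The cue reaches the ring through a fixed Gaussian projection; a
# second, weak "environment" pathway from stable allocentric cues is
# plastic (Hebbian growth with decay) and underlies baseline attraction in
# darkness and its experience dependence.

relu <- function(x) pmax(x, 0)

#' Construct a ring-attractor model state
#'
#' Builds the recurrent kernel, the cue and environment projections, and
#' numerically calibrates the velocity pathway so that a commanded angular
#' velocity of v deg/s moves the bump at v deg/s (gains at 1).
#'
#' @param n number of ring units (preferred directions uniform on 360
#'   degrees).
#' @param tau rate time constant, s.
#' @param j1 cosine recurrent excitation strength.
#' @param b uniform drive offset (negative = global inhibition threshold).
#' @param cue_amp peak cue input (rate units).
#' @param cue_kappa von Mises concentration of the cue input bump.
#' @param env_amp peak input from stable environment cues (weak).
#' @param env_kappa concentration of the environment input.
#' @param hebb_lr Hebbian learning rate of the environment projection
#'   (1/s).
#' @param hebb_decay weight decay rate (1/s).
#' @param recal_eta vestibular recalibration rate (1/s per degree of
#'   low-passed visual error).
#' @param recal_tau time constant (s) of the low-passed cue-minus-internal
#'   error driving recalibration.
#' @param noise_sd s.d. of additive per-unit input noise injected at every
#'   step (rate units; 0 = deterministic dynamics). Draws come from the R
#'   RNG, so callers seed repeats with `set.seed()`.
#' @param seed integer seed (initial bump phase jitter and noise draws go
#'   through the state's own stream counter).
#' @return object of class `ring_state` with fields `rates`, `W_vis`
#'   (fixed cue projection), `W_env` (plastic), `g_mod`, `v_gain_cw`,
#'   `v_gain_ccw`, `cue_pos` (deg or `NA` for off), `head_av` (deg/s),
#'   `err_lp`, calibration constants.
#' @export
ring_state <- function(n = 72, tau = 0.1, j1 = 2.0, b = -0.35,
                       cue_amp = 0.05, cue_kappa = 1.5,
                       env_amp = 0.012, env_kappa = 1.5,
                       hebb_lr = 0.6, hebb_decay = 0.012,
                       recal_eta = 5e-4, recal_tau = 2,
                       noise_sd = 0, seed = 1L) {
  pd <- seq(0, 360 - 360 / n, by = 360 / n) # unit preferred directions
  pd <- wrap_angle(pd)
  th <- pd * pi / 180
  # applied to sum-normalized rates, so no 1/n factor
  W <- j1 * outer(th, th, function(a, b) cos(a - b))
  Wd <- j1 * outer(th, th, function(a, b) sin(a - b)) # derivative kernel
  gauss_proj <- function(kappa) {
    P <- outer(th, th, function(a, b) exp(kappa * (cos(a - b) - 1)))
    # normalize so the ring response (P %*% pre)/n to a cue bump peaks at 1
    resp <- (P %*% exp(kappa * (cos(th) - 1)))[, 1L] / n
    P / max(resp)
  }
  state <- structure(
    list(
      n = n, pd = pd, tau = tau, W = W, Wd = Wd, b = b,
      W_vis = gauss_proj(cue_kappa), W_env = gauss_proj(env_kappa),
      W_env0 = NULL,
      cue_amp = cue_amp, cue_kappa = cue_kappa,
      env_amp = env_amp, env_kappa = env_kappa,
      hebb_lr = hebb_lr, hebb_decay = hebb_decay,
      recal_eta = recal_eta, recal_tau = recal_tau,
      g_mod = 1, v_gain_cw = 1, v_gain_ccw = 1,
      noise_sd = noise_sd,
      cue_pos = NA_real_, head_av = 0, err_lp = 0,
      learn = FALSE, recalibrate = FALSE,
      v_coef = 1 / 360, # provisional; calibrated below
      rates = NULL, seed = as.integer(seed)
    ),
    class = "ring_state"
  )
  state$W_env0 <- state$W_env
  state <- ring_init_bump(state, at = 0)
  state$v_coef <- calibrate_velocity(state)
  state
}

# set the rates to the steady bump at a given angle
ring_init_bump <- function(state, at = 0) {
  prof <- relu(cos((state$pd - at) * pi / 180) - 0.3)
  state$rates <- prof / sum(prof)
  for (i in 1:400) state <- ring_step(state, 0.01, inputs_off = TRUE)
  state
}

# cue/env input bump over the ring channels
channel_bump <- function(pd, pos, kappa) {
  exp(kappa * (cos((pd - pos) * pi / 180) - 1))
}

#' Advance the ring model by one time step
#'
#' Euler step of the rate dynamics. The velocity drive is
#' `head_av` scaled by `v_gain_ccw` (positive velocities) or `v_gain_cw`
#' (negative); the cue input is active when `cue_pos` is not `NA`;
#' Hebbian plasticity of the environment projection runs when
#' `state$learn` is `TRUE`; vestibular recalibration integrates the
#' low-passed cue-minus-internal error when `state$recalibrate` is `TRUE`
#' and the cue is on.
#'
#' @param state a `ring_state`.
#' @param dt time step, s (> 0).
#' @param inputs_off internal flag used during initialization.
#' @return updated `ring_state`.
#' @export
ring_step <- function(state, dt, inputs_off = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  r <- state$rates
  tot <- sum(r)
  r_n <- if (tot > 1e-12) r / tot else r
  v_eff <- if (state$head_av >= 0) state$v_gain_ccw * state$head_av
           else state$v_gain_cw * state$head_av
  gamma <- state$v_coef * v_eff
  drive <- (state$W %*% r_n + gamma * (state$Wd %*% r_n))[, 1L] + state$b
  I <- 0
  cue_on <- !inputs_off && !is.na(state$cue_pos)
  if (cue_on) {
    pre_c <- channel_bump(state$pd, state$cue_pos, state$cue_kappa)
    I <- I + state$cue_amp * (state$W_vis %*% pre_c)[, 1L] / state$n
  }
  if (!inputs_off) {
    pre_e <- channel_bump(state$pd, 0, state$env_kappa)
    I <- I + state$env_amp * (state$W_env %*% pre_e)[, 1L] / state$n
  }
  if (!inputs_off && state$noise_sd > 0)
    I <- I + stats::rnorm(state$n, 0, state$noise_sd)
  r_new <- r + dt / state$tau * (-r + state$g_mod * relu(drive) + I)
  if (any(!is.finite(r_new)) || max(r_new) > 1e6)
    stop("ring dynamics blew up (rates -> Inf); reduce dt or inputs")
  state$rates <- r_new
  if (isTRUE(state$learn) && !inputs_off) {
    pre_e <- channel_bump(state$pd, 0, state$env_kappa)
    state$W_env <- hebbian_update(state$W_env, pre_e,
                                  r_new / max(sum(r_new), 1e-12),
                                  lr = state$hebb_lr * dt,
                                  decay = state$hebb_decay * dt)
  }
  if (isTRUE(state$recalibrate) && cue_on) {
    err <- ang_diff(bump_position(state), state$cue_pos)
    state$err_lp <- state$err_lp +
      dt / state$recal_tau * (err - state$err_lp)
    d <- state$recal_eta * state$err_lp * dt
    state$v_gain_ccw <- min(max(state$v_gain_ccw + d, 0.1), 5)
    state$v_gain_cw <- min(max(state$v_gain_cw - d, 0.1), 5)
  }
  state
}

# empirical bump speed for the commanded-velocity calibration
calibrate_velocity <- function(state) {
  s <- state
  s$head_av <- 30
  s$v_coef <- 1 / 360
  p0 <- bump_position(s)
  steps <- 200; dt <- 0.01
  for (i in seq_len(steps)) s <- ring_step(s, dt, inputs_off = TRUE)
  moved <- ang_diff(p0, bump_position(s))
  speed <- moved / (steps * dt)
  if (!is.finite(speed) || abs(speed) < 1e-6)
    stop("velocity calibration failed: bump did not move")
  state$v_coef * 30 / speed
}

#' Population-vector position of the activity bump
#'
#' @param state a `ring_state` (or a plain rate vector with preferred
#'   directions attached via `pd`).
#' @param pd preferred directions if `state` is a rate vector.
#' @return bump angle in degrees.
#' @export
bump_position <- function(state, pd = NULL) {
  r <- if (inherits(state, "ring_state")) state$rates else state
  if (is.null(pd)) pd <- state$pd
  th <- pd * pi / 180
  wrap_angle(atan2(sum(r * sin(th)), sum(r * cos(th))) * 180 / pi)
}

#' Is the ring activity profile unimodal?
#'
#' Checks that the mean resultant of the rate distribution over preferred
#' directions is high (a dispersed or two-bump profile has low resultant).
#'
#' @param state a `ring_state`.
#' @param threshold minimum resultant length (default 0.35).
#' @return logical.
#' @export
ring_unimodal <- function(state, threshold = 0.35) {
  r <- state$rates
  th <- state$pd * pi / 180
  tot <- sum(r)
  if (tot <= 0) return(FALSE)
  R <- sqrt(sum(r * sin(th))^2 + sum(r * cos(th))^2) / tot
  R > threshold
}

#' Hebbian update of an association matrix
#'
#' `W <- W + lr * (post outer pre) - decay * W`, clipped at zero.
#' Under sustained co-activation of a (pre, post) pair the weight
#' converges to the fixed point `lr * pre * post / decay`; with `lr = 0`
#' weights decay exponentially with half-life `ln(2) / decay` steps.
#'
#' @param W_vis association matrix (post x pre).
#' @param pre presynaptic activity vector.
#' @param post postsynaptic activity vector.
#' @param lr learning-rate increment (>= 0).
#' @param decay decay increment (>= 0).
#' @return updated non-negative matrix.
#' @export
hebbian_update <- function(W_vis, pre, post, lr, decay) {
  if (lr < 0 || decay < 0) stop("lr and decay must be >= 0")
  pmax(W_vis + lr * outer(post, pre) - decay * W_vis, 0)
}

#' Simulate a cue-shift reset
#'
#' Stabilizes the bump with the cue at 0, then displays the cue
#' `cue_shift` degrees away while holding the network gain at
#' `gain_profile` (scalar, or one value per step), and records the bump
#' trajectory. Lower imposed gain yields faster resets.
#'
#' @param state a `ring_state` (bump stabilized; [ring_state()] does
#'   this).
#' @param cue_shift cue displacement in degrees (default 90).
#' @param gain_profile post-cue gain (scalar or per-step vector).
#' @param duration_s simulated time after cue display, s.
#' @param dt integration step, s.
#' @return list: `time` (s), `position` (bump angle trajectory, deg),
#'   `time_to_half` (s to cover half the shift, `NA` if never),
#'   `unimodal` (fraction of steps passing the unimodality check).
#' @export
simulate_reset <- function(state, cue_shift = 90, gain_profile = 1,
                           duration_s = 30, dt = 0.01) {
  n_steps <- round(duration_s / dt)
  gain <- rep_len(gain_profile, n_steps)
  state$cue_pos <- wrap_angle(cue_shift)
  pos <- numeric(n_steps)
  uni <- logical(n_steps)
  for (i in seq_len(n_steps)) {
    state$g_mod <- gain[i]
    state <- ring_step(state, dt)
    pos[i] <- bump_position(state)
    uni[i] <- ring_unimodal(state)
  }
  shift_signed <- wrap_angle(cue_shift)
  covered <- abs(ang_diff(0, pos)) # distance travelled from start (at 0)
  hit <- which(covered >= abs(shift_signed) / 2)
  list(
    time = seq_len(n_steps) * dt, position = pos,
    time_to_half = if (length(hit)) hit[1L] * dt else NA_real_,
    unimodal = mean(uni), state = state
  )
}

#' Pre-train the baseline environment association
#'
#' Runs the model at baseline (cue and bump at 0) with Hebbian learning
#' enabled so the environment projection anchors the baseline reference
#' frame.
#'
#' @param state a `ring_state`.
#' @param duration_s baseline exposure, s.
#' @param dt integration step, s.
#' @return updated `ring_state`.
#' @export
ring_baseline_train <- function(state, duration_s = 120, dt = 0.01) {
  state$cue_pos <- 0
  state$g_mod <- 1
  state$learn <- TRUE
  for (i in seq_len(round(duration_s / dt))) state <- ring_step(state, dt)
  state$learn <- FALSE
  state
}

#' Simulate a timed exposure to a shifted cue, then darkness
#'
#' After baseline pre-training, the cue jumps 90 degrees for `exposure_s`
#' seconds (plasticity on), then turns off; the bump then drifts under
#' the learned environment-association landscape. Short exposures leave
#' the baseline association dominant (strong reversion); long exposures
#' build a competing association at the reset orientation (weak
#' reversion).
#'
#' @param state a baseline-trained `ring_state` (see
#'   [ring_baseline_train()]).
#' @param exposure_s cue exposure duration, s (the experimental contrasts
#'   are 20 and 120).
#' @param cue_shift shift in degrees (default 90).
#' @param darkness_s darkness duration after cue-off, s.
#' @param plasticity enable Hebbian learning during the exposure.
#' @param dt integration step, s.
#' @param reversion_window_s initial darkness window over which the mean
#'   reversion speed is measured, s (default 30).
#' @return list: `dark_time`, `dark_position` (deg), `reversion_speed`
#'   (deg/s toward baseline, positive = reverting), `exposure_end_pos`.
#' @export
simulate_exposure <- function(state, exposure_s, cue_shift = 90,
                              darkness_s = 60, plasticity = TRUE,
                              dt = 0.01, reversion_window_s = 30) {
  state$cue_pos <- wrap_angle(cue_shift)
  state$learn <- isTRUE(plasticity)
  n1 <- round(exposure_s / dt)
  for (i in seq_len(n1)) state <- ring_step(state, dt)
  p_end <- bump_position(state)
  state$cue_pos <- NA_real_
  state$learn <- isTRUE(plasticity)
  n2 <- round(darkness_s / dt)
  pos <- numeric(n2)
  for (i in seq_len(n2)) {
    state <- ring_step(state, dt)
    pos[i] <- bump_position(state)
  }
  win <- seq_len(min(n2, round(reversion_window_s / dt)))
  # distance from baseline (0) at start vs end of the window
  d0 <- abs(ang_diff(0, if (length(pos)) pos[1L] else p_end))
  d1 <- abs(ang_diff(0, pos[win[length(win)]]))
  list(
    dark_time = seq_len(n2) * dt, dark_position = pos,
    reversion_speed = (d0 - d1) / (win[length(win)] * dt),
    exposure_end_pos = p_end, state = state
  )
}

#' Simulate a continuous cue-rotation session
#'
#' The cue rotates at `speed` deg/s for `duration_s` while the simulated
#' head angular velocity is symmetric noise; with recalibration enabled,
#' the low-passed cue-minus-internal error asymmetrically adjusts the
#' vestibular gains. After cue-off the residual asymmetry keeps the bump
#' rotating in the same direction, decaying as it approaches the baseline
#' attractor.
#'
#' @param state a baseline-trained `ring_state`.
#' @param speed cue rotation speed, deg/s (1.5 or 3.0).
#' @param duration_s rotation duration, s (protocol value 420).
#' @param darkness_s post-rotation darkness, s.
#' @param recalibrate enable the recalibration circuit.
#' @param av_sd s.d. of the head-angular-velocity noise, deg/s.
#' @param dt integration step, s.
#' @param seed integer seed for the velocity noise.
#' @return list: `rot_position`, `dark_position` (deg), `post_drift_speed`
#'   (mean signed bump speed in the first 30 s of darkness, deg/s),
#'   `v_gain_ccw`, `v_gain_cw`.
#' @export
simulate_rotation <- function(state, speed = 3.0, duration_s = 420,
                              darkness_s = 120, recalibrate = TRUE,
                              av_sd = 30, dt = 0.01, seed = 1L) {
  set.seed(seed)
  state$recalibrate <- isTRUE(recalibrate)
  state$learn <- TRUE
  n1 <- round(duration_s / dt)
  n2 <- round(darkness_s / dt)
  av <- stats::rnorm(n1 + n2, 0, av_sd)
  rot_pos <- numeric(n1)
  cue <- 0
  for (i in seq_len(n1)) {
    cue <- cue + speed * dt
    state$cue_pos <- wrap_angle(cue)
    state$head_av <- av[i]
    state <- ring_step(state, dt)
    rot_pos[i] <- bump_position(state)
  }
  state$cue_pos <- NA_real_
  state$recalibrate <- FALSE
  dark_pos <- numeric(n2)
  for (i in seq_len(n2)) {
    state$head_av <- av[n1 + i]
    state <- ring_step(state, dt)
    dark_pos[i] <- bump_position(state)
  }
  w <- seq_len(min(n2, round(30 / dt)))
  unwrapped <- unwrap_angle(dark_pos[w])
  post_speed <- (unwrapped[length(w)] - unwrapped[1L]) / ((length(w) - 1L) * dt)
  list(rot_position = rot_pos, dark_position = dark_pos,
       post_drift_speed = post_speed,
       v_gain_ccw = state$v_gain_ccw, v_gain_cw = state$v_gain_cw,
       state = state)
}

#' Convert a simulated rate time series into a population recording
#'
#' Lets the full analysis stack (tuning, decoding, gain, drift) run on
#' model output.
#'
#' @param rates_matrix units x steps matrix of ring rates.
#' @param pd preferred directions of the units, degrees.
#' @param measured_hd simulated head direction per step (default all 0).
#' @param frame_rate sampling rate of the steps, Hz.
#' @return a `population_recording`.
#' @export
ring_recording <- function(rates_matrix, pd, measured_hd = NULL,
                           frame_rate = 100) {
  if (is.null(measured_hd)) measured_hd <- rep(0, ncol(rates_matrix))
  population_recording(pmax(rates_matrix, 0), measured_hd,
                       frame_rate = frame_rate)
}
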