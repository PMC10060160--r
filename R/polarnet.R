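# Supervised polar embedding of population activity.
#
# A feedforward network with three parallel branches maps the N-dim
# activity vector of each frame onto a 2D polar state space. Branches B1
# and B2 (three hidden layers each) output z1 and z2; the middle branch Bm
# (two hidden layers) outputs a positive scalar g. The training target is
# (g z1, g z2) ~ (cos theta, sin theta) under mean squared error, theta the
# measured head direction. At convergence z1 ~ cos(theta)/g and
# z2 ~ sin(theta)/g, so the decoded angle is atan2(z2, z1) and the latent
# radius is R = 1/g: an untrained dimension free to absorb global activity
# fluctuations (network gain). Forward, backward and the Adam optimizer are
# implemented directly with matrix operations.

# --- single branch: tanh hidden layers, linear scalar output ---------------

init_branch <- function(n_input, hidden) {
  sizes <- c(n_input, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    list(
      W = matrix(stats::rnorm(fan_out * fan_in, 0, sqrt(2 / (fan_in + fan_out))),
                 nrow = fan_out),
      b = matrix(0, nrow = fan_out, ncol = 1L)
    )
  })
}

act_fun <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0), df = function(a) (a > 0) * 1),
    tanh = list(f = tanh, df = function(a) 1 - a^2),
    stop("unknown activation: ", name)
  )
}

branch_forward <- function(layers, X, activation) {
  af <- act_fun(activation)
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- layers[[l]]$W %*% acts[[l]] + as.numeric(layers[[l]]$b)
    acts[[l + 1L]] <- if (l < nl) af$f(Z) else Z
  }
  acts
}

branch_backward <- function(layers, acts, dout, activation) {
  af <- act_fun(activation)
  grads <- vector("list", length(layers))
  delta <- dout # gradient wrt linear output
  for (l in rev(seq_along(layers))) {
    grads[[l]] <- list(W = delta %*% t(acts[[l]]),
                       b = matrix(rowSums(delta), ncol = 1L))
    if (l > 1L) {
      delta <- (t(layers[[l]]$W) %*% delta) * af$df(acts[[l]])
    }
  }
  grads
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Build an untrained polar-embedding network
#'
#' @param n_input number of input neurons (>= 1).
#' @param hidden_xy hidden-layer widths of branches B1 and B2 (default
#'   `c(64, 32, 16)`).
#' @param hidden_m hidden-layer widths of the middle branch (default
#'   `c(32, 16)`).
#' @param g_floor additive floor on g (softplus output), keeping the
#'   radius `1/g` well defined.
#' @param activation hidden-layer nonlinearity, `"relu"` (default) or
#'   `"tanh"`. Rectified-linear hidden units extrapolate global activity
#'   scalings approximately linearly, which is what lets the radius track
#'   gain levels never seen during baseline training.
#' @param center subtract the per-neuron training mean from the inputs.
#'   Off by default: inputs are only scaled by the training s.d., so a
#'   global gain change stays a multiplicative transformation of the
#'   input space.
#' @param seed integer seed for the weight initialization.
#' @return object of class `polar_net`. Parameter count:
#'   `sum over consecutive layer pairs of (in*out + out)` across the three
#'   branches, with layer sizes `n_input, hidden..., 1`.
#' @export
build_network <- function(n_input, hidden_xy = c(64, 32, 16),
                          hidden_m = c(32, 16), g_floor = 1e-3,
                          activation = c("relu", "tanh"),
                          center = FALSE, seed = 1L) {
  if (n_input < 1) stop("n_input must be >= 1")
  activation <- match.arg(activation)
  set.seed(seed)
  structure(
    list(
      b1 = init_branch(n_input, hidden_xy),
      b2 = init_branch(n_input, hidden_xy),
      bm = init_branch(n_input, hidden_m),
      n_input = as.integer(n_input), hidden_xy = hidden_xy,
      hidden_m = hidden_m, g_floor = g_floor,
      activation = activation, center = center,
      x_mean = rep(0, n_input), x_sd = rep(1, n_input), trained = FALSE
    ),
    class = "polar_net"
  )
}

#' Number of trainable parameters of a polar network
#'
#' @param model a `polar_net`.
#' @export
n_parameters <- function(model) {
  count <- function(layers) sum(vapply(layers, function(l)
    length(l$W) + length(l$b), numeric(1)))
  count(model$b1) + count(model$b2) + count(model$bm)
}

net_forward <- function(model, X) {
  a1 <- branch_forward(model$b1, X, model$activation)
  a2 <- branch_forward(model$b2, X, model$activation)
  am <- branch_forward(model$bm, X, model$activation)
  z1 <- as.numeric(a1[[length(a1)]])
  z2 <- as.numeric(a2[[length(a2)]])
  graw <- as.numeric(am[[length(am)]])
  g <- softplus(graw) + model$g_floor
  list(a1 = a1, a2 = a2, am = am, z1 = z1, z2 = z2, graw = graw, g = g)
}

adam_state <- function(layers) {
  lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0
  ))
}

adam_update <- function(layers, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      m <- state[[l]][[paste0("m", p)]] <- beta1 * state[[l]][[paste0("m", p)]] + (1 - beta1) * g
      v <- state[[l]][[paste0("v", p)]] <- beta2 * state[[l]][[paste0("v", p)]] + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

#' Train the polar-embedding network on baseline data
#'
#' Full-batch Adam on the mean squared error between `(g z1, g z2)` and
#' `(cos theta, sin theta)`. Inputs are z-scored per neuron (statistics
#' stored in the model). A validation tail is held out for early stopping.
#' Deterministic under a fixed seed.
#'
#' @param model a `polar_net`.
#' @param activity neurons x frames matrix (baseline frames only;
#'   deconvolved activity by default, raw traces work too).
#' @param measured_hd degrees per frame.
#' @param epochs maximum training epochs (default 300).
#' @param lr Adam learning rate (default 2e-3).
#' @param val_frac fraction of frames (tail) held out for validation.
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed (weight init is re-drawn from it).
#' @param verbose print loss every 50 epochs.
#' @return trained `polar_net` with `loss_curve`, `val_curve`,
#'   `final_loss`, `epochs_run` fields.
#' @export
train_polarnet <- function(model, activity, measured_hd, epochs = 300,
                           lr = 2e-3, val_frac = 0.2, patience = 30,
                           seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "polar_net"))
  T <- ncol(activity)
  if (length(measured_hd) != T) stop("activity / measured_hd length mismatch")
  if (circ_sd(measured_hd) < 1)
    warning("head-direction labels are nearly constant: embedding is ",
            "unidentifiable on this training set")
  set.seed(seed)
  model$b1 <- init_branch(model$n_input, model$hidden_xy)
  model$b2 <- init_branch(model$n_input, model$hidden_xy)
  model$bm <- init_branch(model$n_input, model$hidden_m)
  model$x_mean <- if (isTRUE(model$center)) rowMeans(activity)
                  else rep(0, model$n_input)
  model$x_sd <- apply(activity, 1L, stats::sd)
  model$x_sd[model$x_sd == 0] <- 1
  X <- (activity - model$x_mean) / model$x_sd
  th <- measured_hd * pi / 180
  Yc <- cos(th); Ys <- sin(th)
  n_val <- max(1L, round(val_frac * T))
  val <- (T - n_val + 1L):T
  tr <- setdiff(seq_len(T), val)
  Xt <- X[, tr, drop = FALSE]; Xv <- X[, val, drop = FALSE]
  B <- length(tr)
  st1 <- adam_state(model$b1); st2 <- adam_state(model$b2)
  stm <- adam_state(model$bm)
  loss_curve <- val_curve <- numeric(0)
  best_val <- Inf; best <- model; wait <- 0L
  mse <- function(fw, idx) {
    mean((Yc[idx] - fw$g * fw$z1)^2 + (Ys[idx] - fw$g * fw$z2)^2)
  }
  for (ep in seq_len(epochs)) {
    fw <- net_forward(model, Xt)
    e1 <- fw$g * fw$z1 - Yc[tr]
    e2 <- fw$g * fw$z2 - Ys[tr]
    loss <- mean(e1^2 + e2^2)
    if (!is.finite(loss)) stop("training diverged: loss is not finite at epoch ", ep)
    scale <- 2 / B
    dz1 <- matrix(scale * e1 * fw$g, nrow = 1L)
    dz2 <- matrix(scale * e2 * fw$g, nrow = 1L)
    dg <- scale * (e1 * fw$z1 + e2 * fw$z2)
    dgraw <- matrix(dg * stats::plogis(fw$graw), nrow = 1L)
    g1 <- branch_backward(model$b1, fw$a1, dz1, model$activation)
    g2 <- branch_backward(model$b2, fw$a2, dz2, model$activation)
    gm <- branch_backward(model$bm, fw$am, dgraw, model$activation)
    up <- adam_update(model$b1, g1, st1, lr, ep); model$b1 <- up$layers; st1 <- up$state
    up <- adam_update(model$b2, g2, st2, lr, ep); model$b2 <- up$layers; st2 <- up$state
    up <- adam_update(model$bm, gm, stm, lr, ep); model$bm <- up$layers; stm <- up$state
    fv <- net_forward(model, Xv)
    vloss <- mse(fv, val)
    loss_curve <- c(loss_curve, loss); val_curve <- c(val_curve, vloss)
    if (verbose && ep %% 50 == 0)
      message(sprintf("epoch %d: train %.4f, val %.4f", ep, loss, vloss))
    if (vloss < best_val - 1e-6) {
      best_val <- vloss; best <- model; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best$trained <- TRUE
  best$loss_curve <- loss_curve
  best$val_curve <- val_curve
  best$final_loss <- loss_curve[length(loss_curve)]
  best$epochs_run <- length(loss_curve)
  best$seed <- seed
  best
}

#' Embed activity into the 2D polar state space
#'
#' @param model a trained `polar_net`.
#' @param activity neurons x frames matrix.
#' @return object of class `polar_embedding`: `theta_hat` (deg,
#'   `atan2(z2, z1)`), `radius_hat` (`1/g`), `z1`, `z2`, `g`.
#' @export
polar_embed <- function(model, activity) {
  stopifnot(inherits(model, "polar_net"))
  if (!isTRUE(model$trained)) warning("embedding with an untrained network")
  X <- (activity - model$x_mean) / model$x_sd
  fw <- net_forward(model, X)
  radius <- ifelse(fw$g > 0, 1 / fw$g, NA_real_)
  structure(
    list(theta_hat = wrap_angle(atan2(fw$z2, fw$z1) * 180 / pi),
         radius_hat = radius, z1 = fw$z1, z2 = fw$z2, g = fw$g),
    class = "polar_embedding"
  )
}

#' Circular correlation between two angular series
#'
#' Fisher-Lee circular correlation coefficient, used to compare the
#' embedded angle with the measured head direction.
#'
#' @param a,b angles in degrees.
#' @export
circ_correlation <- function(a, b) {
  ar <- a * pi / 180; br <- b * pi / 180
  am <- atan2(mean(sin(ar)), mean(cos(ar)))
  bm <- atan2(mean(sin(br)), mean(cos(br)))
  sa <- sin(ar - am); sb <- sin(br - bm)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}
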