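# hdring

Population-level analysis and modelling of the mammalian head-direction
(HD) system during cue-driven reorientation and drift.

The HD network — the brain's internal compass — is classically described
as a one-dimensional ring attractor: at any moment the population encodes
a single circular variable, the internal head direction. Large calcium-
imaging recordings from the anterodorsal thalamus show that this picture
is incomplete: under cue conflict and darkness, population activity also
varies along a second, radial dimension — a global multiplicative
**network gain** — that predicts how fast the network re-anchors to a
displaced visual cue, stores a "memory trace" of vanished landmarks, and
reflects experience-dependent recalibration of vestibular integration.

`hdring` implements that analysis stack end to end, for anyone who wants
to apply it to their own (neurons × frames) deconvolved-activity
recordings or to study it on synthetic ground truth:

- **`synthgen`** — synthetic sessions with known ground truth: von Mises
  tuning tiling 360°, zero-inflated-gamma (ZIG) emission noise, a global
  gain signal, bounded-random-walk head trajectories and the three cue
  protocols (2-min 90° shifts, 20-s ±90° flashes, continuous 1.5/3.0 °/s
  rotation).
- **`tuning`** — occupancy-normalized 1°-bin tuning curves (50° circular
  smoothing), preferred firing directions, HD scores
  `r = cor(activity, exp(-angdiff(PFD, θ)² / 2σ²))` with σ = 17°, and an
  iterative shuffle-calibrated classification threshold (1,000 circular
  shifts, 95th percentile).
- **`decoder`** — Bayesian maximum-likelihood decoding of the internal HD
  from all recorded cells under per-bin ZIG emission models, with 5-frame
  likelihood smoothing.
- **`popstate`** — closed-form MLE of the network gain,
  `α̂_t = Σᵢ r_{i,t} f_i(θ_t) / Σᵢ f_i(θ_t)²` with `f_i` the baseline
  tuning curve evaluated at the decoded direction θ_t, normalized so the
  baseline mean is 1; activity-bump reconstruction
  `A(θ,t) = Σᵢ f_i(θ) r_i(t) / Σᵢ f_i(θ)`.
- **`driftreset`** — the offset `angdiff(θ_decoded, θ_measured)`, sliding
  20-frame regression drift speeds, reset-event extraction, fast/slow
  classification by city-block k-means on the first 1,450 post-cue
  frames, darkness drift statistics, clockwise-session reflection and
  cue-rotation inclusion windows.
- **`maps`** — gain tuning curves over internal HD and 2D gain /
  drift-speed heat maps over (angular head velocity × internal HD) with
  rank-sum pixel comparison.
- **`vectorfield`** — drift vector fields in (drift angle × drift speed)
  space, central symmetrization and streamline simulation of the stable
  regime.
- **`polarnet`** — a three-branch feedforward network trained on baseline
  data to map activity onto a 2D polar state space; the untrained middle
  branch yields a latent radius `R̂ = 1/g` that tracks network gain.
- **`ringmodel`** — a ring-attractor rate model with multiplicative gain,
  Hebbian association to stable allocentric cues and asymmetric
  vestibular recalibration, reproducing gain-controlled reset speed,
  exposure-dependent baseline reversion and persistent post-rotation
  drift.
- **`pipeline`** — one-call orchestration with per-stage artifacts,
  a plain-text session container, and full determinism from a master
  seed.

## Worked example

Simulate a 5-min baseline session (80 cells, 90% HD-tuned, ZIG noise),
identify HD cells, decode the internal direction on held-out frames, and
estimate the network gain:

```r
library(hdring)

cfg  <- synth_config(n_neurons = 80, duration = 300, seed = 42)
sess <- simulate_session(cfg)
rec  <- sess$recording
rec
#> <population_recording> 80 neurons x 9000 frames @ 30 Hz (5.0 min), epochs: baseline

scores <- score_neurons(rec)
thr    <- shuffle_threshold(rec, scores = list(scores), n_shuffles = 200,
                            seed = 42)
ts     <- classify_hd_cells(rec, thr$r_thresh, scores = scores)
ts
#> <tuning_curve_set> 80 neurons, 72 HD cells (90.0%), r_thresh = 0.080

T     <- ncol(rec$activity)
train <- seq_len(round(0.8 * T)); test <- setdiff(seq_len(T), train)
em    <- fit_emission(rec, frames = train)
dec   <- decode_session(rec, em, frames = test)
decode_mae(dec$map_hd, rec$measured_hd[test])
#> held-out decoding MAE: 0.94 deg

dec_all <- decode_session(rec, em)
gt  <- gain_trace(rec, ts, dec_all, baseline_frames = seq_len(T))
off <- compute_offset(rec$measured_hd, dec_all$map_hd)
#> gain trace: mean 1.000, sd 0.098
#> offset: median |offset| 0.47 deg, drift speed sd 1.57 deg/s
```

The classifier recovers the configured 90% HD fraction exactly; held-out
decoding errs by under a degree on this clean synthetic session (real
recordings carry behavioural and biological variability on top of
emission noise); the normalized gain sits at 1 with ~0.1 frame-to-frame
dispersion; and the measured-minus-decoded offset is centred on zero with
a quiet drift speed — the signature of a stable, cue-anchored network.

Protocol sessions run the same way through one call:

```r
res <- run_pipeline(preset_cue_shift(seed = 1))
res$summary   # HD counts, decoder MAE, reset-event table sizes, gain stats
```

The ring-attractor model is exercised directly:

```r
st <- ring_state(seed = 1)
fast <- simulate_reset(st, cue_shift = 90, gain_profile = 0.6)
slow <- simulate_reset(st, cue_shift = 90, gain_profile = 1.0)
c(fast$time_to_half, slow$time_to_half)  # lower gain => faster reset
```

See `vignettes/hd-network-dynamics.Rmd` for the methods account: model
assumptions, parameter choices, numerical conventions and limitations.

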