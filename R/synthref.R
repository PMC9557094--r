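# Synthetic-reference generation: sled pulses at stated delta-v values,
# a surrogate T1 base response, and volunteer-like reference channel sets
# (truth runs with seeded smooth noise, or analytic waveforms), so the
# whole evaluation and calibration machinery is testable without any
# external dataset. The emulated test structure is a rigid seat, 20 deg
# seatback, no headrest, at delta-v presets 5.8 / 8.1 / 10.0 km/h.

#' Sled pulse specification
#'
#' @param delta_v Velocity change in km/h (presets 5.8, 8.1, 10.0).
#' @param duration Pulse duration in ms (default 100, a standard
#'   low-severity sled pulse length).
#' @param shape `"haversine"` (default) or `"trapezoid"` (ramp fractions
#'   0.25/0.5/0.25).
#' @param dt Sample interval in ms.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(delta_v = 5.8, duration = 100,
                       shape = c("haversine", "trapezoid"), dt = 0.5) {
  stopifnot(delta_v > 0, duration > 0, dt > 0, duration / dt >= 4)
  structure(list(delta_v = delta_v, duration = duration,
                 shape = match.arg(shape), dt = dt),
            class = "pulse_spec")
}

#' Generate a sled acceleration pulse
#'
#' Returns an acceleration channel whose trapezoidal time integral equals
#' the specified delta-v exactly (the waveform is normalized after
#' sampling). The haversine `a(t) = A (1 - cos(2 pi t / T)) / 2` has peak
#' `A = 2 dv / T`.
#'
#' @param spec A [pulse_spec()].
#' @return A [ts_channel()] named `"sled-ax"` in mm/ms^2, starting at
#'   t = 0.
#' @export
make_pulse <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  dv <- spec$delta_v / 3.6            # km/h -> mm/ms (= m/s)
  T <- spec$duration
  t <- seq(0, T, by = spec$dt)
  a <- switch(spec$shape,
    haversine = (2 * dv / T) * (1 - cos(2 * pi * t / T)) / 2,
    trapezoid = {
      r <- 0.25 * T
      ap <- dv / (T - r)              # plateau level for 25/50/25 ramps
      ifelse(t < r, ap * t / r,
             ifelse(t <= T - r, ap, ap * (T - t) / r))
    })
  # normalize so the trapezoidal integral is exactly dv
  n <- length(a)
  s <- sum((a[-1] + a[-n]) / 2 * spec$dt)
  a <- a * dv / s
  ts_channel("sled-ax", "mm/ms^2", 0, spec$dt, a)
}

#' Surrogate T1 kinematics from a sled pulse
#'
#' The T1 x-velocity follows the sled velocity through a second-order lag
#' with unit static gain (the seat/torso path low-passes and delays the
#' base input), so the T1 final velocity equals the sled delta-v. Small
#' coupled z and pitch (ry) components are tied to the T1 x-acceleration
#' through configurable gains. Motion is zero for t < 0.
#'
#' @param pulse Sled acceleration channel from [make_pulse()] (mm/ms^2).
#' @param omega Natural frequency of the lag, rad/ms (default 0.15, i.e.
#'   about 24 Hz).
#' @param zeta Damping ratio of the lag (default 0.8).
#' @param gain_z Vertical coupling, mm per mm/ms^2 of T1 x-acceleration
#'   (default -30: slight downward motion under the seatback load).
#' @param gain_ry Pitch coupling, rad per mm/ms^2 (default -1.2: torso
#'   pitches slightly rearward while accelerating).
#' @param t_pre Time before impact onset to include (ms, default 150).
#' @param t_post Time after the pulse support to append (ms, default 350).
#' @return A [kinematics_set()] with channels `T1-x`, `T1-z` (mm),
#'   `T1-ry` (rad) and `T1-ax` (mm/ms^2).
#' @export
emulate_t1 <- function(pulse, omega = 0.15, zeta = 0.8,
                       gain_z = -30, gain_ry = -1.2,
                       t_pre = 150, t_post = 350) {
  stopifnot(inherits(pulse, "ts_channel"), omega > 0, zeta > 0)
  dt <- pulse$dt
  t <- seq(-t_pre, pulse$t0 + (length(pulse$values) - 1) * dt + t_post,
           by = dt)
  a_sled <- stats::approx(channel_times(pulse), pulse$values, t,
                          yleft = 0, yright = 0)$y
  v_sled <- c(0, cumsum((a_sled[-1] + a_sled[-length(a_sled)]) / 2 * dt))
  # v1'' + 2 zeta omega v1' + omega^2 v1 = omega^2 v_sled, RK4
  n <- length(t)
  v1 <- numeric(n); w <- 0
  deriv <- function(v, w, vs) c(w, omega^2 * (vs - v) - 2 * zeta * omega * w)
  for (i in seq_len(n - 1)) {
    vs0 <- v_sled[i]; vs1 <- v_sled[i + 1]; vsm <- (vs0 + vs1) / 2
    k1 <- deriv(v1[i], w, vs0)
    k2 <- deriv(v1[i] + dt / 2 * k1[1], w + dt / 2 * k1[2], vsm)
    k3 <- deriv(v1[i] + dt / 2 * k2[1], w + dt / 2 * k2[2], vsm)
    k4 <- deriv(v1[i] + dt * k3[1], w + dt * k3[2], vs1)
    v1[i + 1] <- v1[i] + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    w <- w + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  }
  x1 <- c(0, cumsum((v1[-1] + v1[-n]) / 2 * dt))
  a1 <- numeric(n)
  a1[2:(n - 1)] <- (v1[3:n] - v1[1:(n - 2)]) / (2 * dt)
  a1[n] <- (v1[n] - v1[n - 1]) / dt
  kinematics_set(list(
    ts_channel("T1-x", "mm", t[1], dt, x1),
    ts_channel("T1-z", "mm", t[1], dt, gain_z * a1),
    ts_channel("T1-ry", "rad", t[1], dt, gain_ry * a1),
    ts_channel("T1-ax", "mm/ms^2", t[1], dt, a1)),
    meta = list(delta_v = NA, source = "emulate_t1"), align = FALSE)
}

#' Reference generation recipe
#'
#' @param mode `"truth_run"` (simulate the model with known truth
#'   parameters and add seeded smooth noise) or `"analytic"`
#'   (parameterized extension-then-rebound waveforms; a non-validated
#'   placeholder for real volunteer channels).
#' @param truth Named list of truth parameters (`kpa`, `kda`, `tnda`,
#'   `pde`) injected into the model for `truth_run` mode. Defaults to the
#'   female row of [reference_optimized_params()].
#' @param noise_amp Noise amplitude as a fraction of each channel's peak
#'   absolute value (default 0; a warning is issued at or above the
#'   corridor inner fraction 0.05, where ratings saturate).
#' @param noise_window Moving-average smoothing window for the noise, ms
#'   (default 10).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return An object of class `reference_recipe`.
#' @export
reference_recipe <- function(mode = c("truth_run", "analytic"),
                             truth = NULL, noise_amp = 0,
                             noise_window = 10, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(truth)) {
    p <- reference_optimized_params()["female", ]
    truth <- list(kpa = p$kpa, kda = p$kda, tnda = p$tnda, pde = p$pde)
  }
  stopifnot(noise_amp >= 0, noise_window > 0)
  if (noise_amp >= 0.05)
    warning("noise amplitude ", noise_amp, " is at or above the corridor ",
            "inner fraction; ratings against this reference will be ",
            "near-saturated", call. = FALSE)
  structure(list(mode = mode, truth = truth, noise_amp = noise_amp,
                 noise_window = noise_window, seed = as.integer(seed)),
            class = "reference_recipe")
}

# Seeded smooth noise: Gaussian, moving-average smoothed, rescaled so its
# peak equals amp * peak|x|.
.smooth_noise <- function(n, dt, amp_abs, window_ms, rng) {
  e <- rng(n)
  w <- max(1L, round(window_ms / dt))
  e <- stats::filter(e, rep(1 / w, w), sides = 2)
  e[is.na(e)] <- 0
  e <- as.numeric(e)
  m <- max(abs(e))
  if (m > 0) e <- e * amp_abs / m
  e
}

#' Generate a volunteer-like reference kinematics set
#'
#' In `truth_run` mode the scenario is simulated with the recipe's truth
#' parameters and seeded smooth noise is added to every rating channel;
#' in `analytic` mode parameterized extension-then-rebound waveforms are
#' generated for all ten rating channels (placeholders, not validated
#' against any measured data). The output is rateable.
#'
#' @param recipe A [reference_recipe()].
#' @param model A `neck_model` (required for `truth_run` mode).
#' @param scenario A [scenario_config()] (required for `truth_run` mode).
#' @return A [kinematics_set()] containing the ten rating channels (plus,
#'   in truth-run mode, the acceleration and T1 channels of the
#'   simulation output).
#' @export
make_reference <- function(recipe, model = NULL, scenario = NULL) {
  stopifnot(inherits(recipe, "reference_recipe"))
  if (recipe$mode == "truth_run") {
    if (is.null(model) || is.null(scenario))
      stop("truth_run mode requires a model and a scenario", call. = FALSE)
    model <- set_model_params(model, recipe$truth)
    res <- run_scenario(model, scenario)
    set <- res$kinematics
    if (recipe$noise_amp > 0) {
      set.seed(recipe$seed)
      for (nm in rating_channel_names()) {
        ch <- set$channels[[nm]]
        pk <- max(abs(ch$values))
        ch$values <- ch$values +
          .smooth_noise(length(ch$values), ch$dt, recipe$noise_amp * pk,
                        recipe$noise_window, stats::rnorm)
        set$channels[[nm]] <- ch
      }
    }
    set$meta$source <- "truth_run"
    set$meta$truth <- recipe$truth
    set
  } else {
    # Analytic extension-then-rebound waveforms: a damped raised-cosine
    # onset peaking near 150 ms with a slower rebound. Amplitudes taper
    # from head to C7. Not validated against measured volunteer data.
    dt <- 1; t <- seq(0, 500, by = dt)
    wave <- function(A, t_pk, t_reb) {
      up <- A * (t / t_pk)^2 * exp(2 * (1 - t / t_pk))   # peak A at t_pk
      up * exp(-pmax(0, t - t_pk) / t_reb)
    }
    amps_ry <- seq(24, 6, length.out = 7)                # deg, C1..C7
    chans <- c(
      list(ts_channel("HCG-x", "mm", 0, dt, wave(-120, 160, 150)),
           ts_channel("HCG-z", "mm", 0, dt, wave(-35, 170, 150)),
           ts_channel("HCG-ry", "deg", 0, dt, wave(40, 160, 150))),
      lapply(1:7, function(k)
        ts_channel(paste0("C", k, "-ry"), "deg", 0, dt,
                   wave(amps_ry[k], 150 + 5 * k, 150))))
    kinematics_set(chans, meta = list(source = "analytic"), align = FALSE)
  }
}
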