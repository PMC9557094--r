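# Sagittal-plane multibody head-neck model: head + C1..C7 above a
# kinematically driven T1, joined by penalty bushings (the reduced
# surrogate of FE intervertebral compliance), with Hill-type line
# muscles in flexor/extensor groups. x is forward, z is up, ry about y
# with positive ry = extension (rearward pitch). Units mm-ms-kg-kN-rad.
#
# Segment masses, inertias, bushing stiffnesses and muscle geometry are
# documented surrogates on anthropometric orders of magnitude, not
# values taken from any specific FE model; everything is overridable.

.segment_height <- 18   # mm, joint-to-joint spacing of the cervical column

.default_model_params <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  opt <- reference_optimized_params()[sex, ]
  list(
    head_mass = if (sex == "female") 3.7 else 4.4,          # kg
    head_inertia = if (sex == "female") 18000 else 23500,   # kg mm^2
    head_com = c(20, 30),      # head COM forward/up of the C0-C1 joint, mm
    vert_mass = if (sex == "female") 0.25 else 0.30,        # kg
    vert_inertia = if (sex == "female") 150 else 190,       # kg mm^2
    joint_kt = 1.0,            # kN/mm
    joint_ct = 0.05,           # kN/(mm/ms)
    joint_kr = 70,             # kN mm/rad
    joint_cr = 2,              # kN mm/(rad/ms)
    muscle_arm = 25,           # segmental element offset from the column, mm
    long_arm_ext = 45,         # long extensor offset, mm
    long_arm_flex = 32,        # long flexor offset, mm
    pcsa_long_ext = 2000,      # mm^2 (aggregated posterior group)
    pcsa_long_flex = 1000,     # mm^2 (aggregated anterior group)
    pcsa_segmental = 300,      # mm^2 per level and side
    sigma_max = 7e-4,          # kN/mm^2
    fl_width = 0.5, fv_shape = 0.25, fv_ecc_plateau = 1.4, v_max = 0.01,
    k_passive = 5e-5, c_passive = 6,
    pde_coeff = opt$pde,       # kN ms/mm^2, sex-specific identified value
    cco_level = 0.02,
    kpa = opt$kpa, kda = opt$kda, tnda = opt$tnda,
    routing = "reciprocal"
  )
}

#' Build a head-neck model
#'
#' Deterministic assembly of the 8-body chain (C7 up to the head) above
#' the T1 base. Female and male builds share the topology and differ
#' only in parameter values (head mass/inertia, segment properties, and
#' the sex-specific identified controller/damping parameters).
#'
#' @param sex `"female"` or `"male"`.
#' @param overrides Named list of parameter overrides (see
#'   [model_parameter_names()]); unknown names are an error.
#' @return An object of class `neck_model`.
#' @export
build_model <- function(sex = c("female", "male"), overrides = list()) {
  sex <- match.arg(sex)
  p <- .default_model_params(sex)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown))
    stop("unknown model parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(overrides)] <- overrides

  h <- .segment_height
  seg_names <- c(paste0("C", 7:1), "head")
  nb <- 8L
  mass <- c(rep(p$vert_mass, 7), p$head_mass)
  inertia <- c(rep(p$vert_inertia, 7), p$head_inertia)

  # reference world pose (T1 frame at the origin, all angles 0)
  joint_z <- h * (0:7)                       # joint j at z = 18(j-1)
  com <- matrix(0, nb, 2)
  com[1:7, 2] <- joint_z[1:7] + h / 2
  com[8, ] <- c(p$head_com[1], joint_z[8] + p$head_com[2])
  q0 <- cbind(com, 0)

  # bushing anchors in local (COM-relative) frames
  anchor_p <- matrix(0, nb, 2)               # on parent (j-1; T1 for j=1)
  anchor_c <- matrix(0, nb, 2)               # on child j
  anchor_p[1, ] <- c(0, 0)                   # T1 frame: joint 1 at origin
  for (j in 2:8) anchor_p[j, ] <- c(0, joint_z[j]) - com[j - 1, ]
  for (j in 1:8) anchor_c[j, ] <- c(0, joint_z[j]) - com[j, ]

  # muscles: world endpoints at reference, converted to local anchors.
  # body index convention: 1..7 = C7..C1, 8 = head, 0 = T1.
  world <- function(b, pt) if (b == 0) pt else pt - com[b, ]
  mus <- list()
  add_mus <- function(ba, pa, bb, pb, pcsa, group) {
    mus[[length(mus) + 1]] <<- list(
      body = c(ba, bb), a = world(ba, pa), b = world(bb, pb),
      pcsa = pcsa, l0 = sqrt(sum((pb - pa)^2)), group = group)
  }
  head_top <- com[8, ] + c(0, 12)
  add_mus(8, c(-p$long_arm_ext, head_top[2]), 0, c(-p$long_arm_ext, -5),
          p$pcsa_long_ext, "extensor")
  add_mus(8, c(p$long_arm_flex, head_top[2]), 0, c(p$long_arm_flex, -5),
          p$pcsa_long_flex, "flexor")
  for (j in 1:8) {
    zj <- joint_z[j]
    for (side in c(-1, 1)) {
      xoff <- side * p$muscle_arm
      add_mus(j - 1, c(xoff, zj - h / 2), j, c(xoff, zj + h / 2),
              p$pcsa_segmental,
              if (side < 0) "extensor" else "flexor")
    }
  }

  structure(list(
    sex = sex,
    params = p,
    segments = data.frame(name = seg_names, mass = mass, inertia = inertia),
    joints = data.frame(kt = rep(p$joint_kt, nb), ct = rep(p$joint_ct, nb),
                        kr = rep(p$joint_kr, nb), cr = rep(p$joint_cr, nb),
                        neutral = rep(0, nb)),
    anchor_p = anchor_p, anchor_c = anchor_c, q0 = q0,
    muscles = mus,
    curve = list(sigma_max = p$sigma_max, fl_width = p$fl_width,
                 fv_shape = p$fv_shape, fv_ecc_plateau = p$fv_ecc_plateau,
                 v_max = p$v_max, k_passive = p$k_passive,
                 c_passive = p$c_passive),
    pde_coeff = p$pde_coeff, cco_level = p$cco_level,
    controller = controller_params(kpa = p$kpa, kda = p$kda, tnda = p$tnda,
                                   routing = p$routing)),
    class = "neck_model")
}

#' Names of overridable model parameters
#' @return Character vector accepted by `build_model(overrides = ...)`.
#' @export
model_parameter_names <- function() names(.default_model_params("female"))

#' @export
print.neck_model <- function(x, ...) {
  cat(sprintf("<neck_model> %s: 8 segments (%s), %d muscles\n", x$sex,
              paste(rev(x$segments$name), collapse = " "),
              length(x$muscles)))
  cat(sprintf("  head mass %.2f kg, pde %.4f kN.ms/mm^2, cco %.2f, ",
              x$segments$mass[8], x$pde_coeff, x$cco_level))
  cat(sprintf("kpa %.4g, kda %.4g, tnda %.4g ms\n",
              x$controller$kpa, x$controller$kda, x$controller$tnda))
  invisible(x)
}

#' Inject identified parameters into a model
#'
#' @param model A [build_model()] result.
#' @param params Named list with any of `kpa`, `kda`, `tnda` (controller),
#'   `pde` (parallel damping coefficient) and `cco` (co-contraction level).
#' @return The updated model.
#' @export
set_model_params <- function(model, params) {
  stopifnot(inherits(model, "neck_model"))
  known <- c("kpa", "kda", "tnda", "pde", "cco")
  unknown <- setdiff(names(params), known)
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in intersect(c("kpa", "kda", "tnda"), names(params)))
    model$controller[[nm]] <- params[[nm]]
  if ("pde" %in% names(params)) model$pde_coeff <- params$pde
  if ("cco" %in% names(params)) model$cco_level <- params$cco
  model
}

#' Scenario configuration
#'
#' @param toggles Named list `cco`/`pde`/`apf` of logicals: the feature
#'   switches of the configuration matrix. `cco` selects the baseline
#'   co-contraction level (model value vs 0), `pde` the parallel damping
#'   coefficient (model value vs 0), `apf` the reflex controller.
#' @param t1 A [kinematics_set()] holding prescribed `T1-x`, `T1-z`,
#'   `T1-ry` channels covering the full span, or `NULL` to derive T1
#'   motion from `pulse` via [emulate_t1()].
#' @param pulse A [pulse_spec()] used when `t1` is `NULL`.
#' @param settle_ms Quasi-static gravity settling duration (default 150;
#'   occupies t in \[-settle_ms, 0)).
#' @param term_ms Termination time including settling (default 450, i.e.
#'   300 ms of event).
#' @param dt Integration step, ms (default 0.05).
#' @param out_dt Output sampling interval, ms (default 1).
#' @param gravity Gravitational acceleration, mm/ms^2.
#' @param drift_threshold Settling drift flag threshold, deg over the
#'   final 50 ms.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(toggles = list(cco = TRUE, pde = TRUE, apf = TRUE),
                            t1 = NULL, pulse = pulse_spec(5.8),
                            settle_ms = 150, term_ms = 450,
                            dt = 0.05, out_dt = 1,
                            gravity = 9.81e-3, drift_threshold = 0.5) {
  stopifnot(term_ms >= settle_ms, dt > 0, out_dt >= dt)
  for (nm in c("cco", "pde", "apf"))
    if (!is.logical(toggles[[nm]]) || length(toggles[[nm]]) != 1L)
      stop("toggles must contain single logicals cco, pde, apf",
           call. = FALSE)
  if (abs(out_dt / dt - round(out_dt / dt)) > 1e-9)
    stop("out_dt must be an integer multiple of dt", call. = FALSE)
  structure(list(toggles = toggles[c("cco", "pde", "apf")], t1 = t1,
                 pulse = pulse, settle_ms = settle_ms, term_ms = term_ms,
                 dt = dt, out_dt = out_dt, gravity = gravity,
                 drift_threshold = drift_threshold),
            class = "scenario_config")
}

# Interpolate the prescribed T1 channels onto the step grid and build the
# (nsteps+1) x 6 matrix (x, z, th, vx, vz, w) the core expects.
.t1_matrix <- function(t1set, tg, dt) {
  need <- c("T1-x", "T1-z", "T1-ry")
  miss <- setdiff(need, names(t1set$channels))
  if (length(miss))
    stop("T1 input lacks channels: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cov0 <- vapply(t1set$channels[need], `[[`, 0, "t0")
  cov1 <- vapply(t1set$channels[need], function(c)
    c$t0 + (length(c$values) - 1) * c$dt, 0)
  if (max(cov0) > tg[1] + 1e-9 || min(cov1) < tg[length(tg)] - 1e-9)
    stop(sprintf("T1 channels cover [%g, %g] ms but the scenario needs [%g, %g] ms",
                 max(cov0), min(cov1), tg[1], tg[length(tg)]), call. = FALSE)
  grab <- function(nm, unit) {
    ch <- convert_channel(t1set$channels[[nm]], unit)
    t_in <- channel_times(ch)
    # natural spline keeps the derived velocity and acceleration smooth
    # (linear interpolation would put jumps at every input sample)
    y <- stats::spline(t_in, ch$values, xout = pmin(pmax(tg, t_in[1]),
                                                    t_in[length(t_in)]),
                       method = "natural")$y
    y
  }
  x <- grab("T1-x", "mm"); z <- grab("T1-z", "mm"); th <- grab("T1-ry", "rad")
  n <- length(tg)
  fd <- function(y) {
    d <- numeric(n)
    d[1] <- (y[2] - y[1]) / dt; d[n] <- (y[n] - y[n - 1]) / dt
    if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
    d
  }
  cbind(x, z, th, fd(x), fd(z), fd(th))
}

#' Run a loading scenario
#'
#' Fixed-step integration over gravity settling plus the impact event,
#' emitting all rating channels at the output interval. Displacement
#' channels are reported relative to the settled state at t = 0; head
#' and T1 x-accelerations are reported in m/s^2.
#'
#' @param model A [build_model()] result.
#' @param scenario A [scenario_config()].
#' @return An object of class `simulation_result` with fields
#'   `kinematics` (a rateable [kinematics_set()]), `states` (full state
#'   trajectory matrix), `activations`, `muscle_forces`,
#'   `settle_report` and `config`.
#' @export
run_scenario <- function(model, scenario) {
  stopifnot(inherits(model, "neck_model"), inherits(scenario, "scenario_config"))
  tg0 <- -scenario$settle_ms
  tg1 <- scenario$term_ms - scenario$settle_ms
  dt <- scenario$dt
  nsteps <- round((tg1 - tg0) / dt)
  out_every <- round(scenario$out_dt / dt)
  nsteps <- (nsteps %/% out_every) * out_every
  tg <- tg0 + (0:nsteps) * dt

  t1set <- scenario$t1
  if (is.null(t1set)) t1set <- emulate_t1(make_pulse(scenario$pulse))
  t1m <- .t1_matrix(t1set, tg, dt)

  tog <- scenario$toggles
  curve <- c(model$curve,
             list(pde_coeff = if (tog$pde) model$pde_coeff else 0,
                  cco_level = if (tog$cco) model$cco_level else 0))
  ctrl <- list(enabled = tog$apf && isTRUE(model$controller$enabled),
               kpa = model$controller$kpa, kda = model$controller$kda,
               tnda = model$controller$tnda,
               routing = if (model$controller$routing == "agonist_only") 1L else 0L)

  mus <- model$muscles
  nm <- length(mus)
  mus_body <- matrix(0L, max(nm, 1), 2)
  mus_a <- matrix(0, max(nm, 1), 2); mus_b <- matrix(0, max(nm, 1), 2)
  mus_pcsa <- numeric(max(nm, 1)); mus_l0 <- rep(1, max(nm, 1))
  mus_group <- integer(max(nm, 1))
  for (k in seq_len(nm)) {
    mus_body[k, ] <- mus[[k]]$body - 1L      # 0-based, -1 = T1
    mus_a[k, ] <- mus[[k]]$a; mus_b[k, ] <- mus[[k]]$b
    mus_pcsa[k] <- mus[[k]]$pcsa; mus_l0[k] <- mus[[k]]$l0
    mus_group[k] <- if (mus[[k]]$group == "flexor") 0L else 1L
  }
  if (nm == 0) { mus_body <- mus_body[0, , drop = FALSE]
    mus_a <- mus_a[0, , drop = FALSE]; mus_b <- mus_b[0, , drop = FALSE]
    mus_pcsa <- numeric(0); mus_l0 <- numeric(0); mus_group <- integer(0) }

  res <- simulate_chain_cpp(
    mass = model$segments$mass, inertia = model$segments$inertia,
    q0 = model$q0, v0 = matrix(0, 8, 3),
    anchor_p = model$anchor_p, anchor_c = model$anchor_c,
    kt = model$joints$kt, ct = model$joints$ct,
    kr = model$joints$kr, cr = model$joints$cr,
    neutral = model$joints$neutral,
    mus_body = mus_body, mus_a = mus_a, mus_b = mus_b,
    mus_pcsa = mus_pcsa, mus_l0 = mus_l0, mus_group = mus_group,
    curve = curve, ctrl = ctrl,
    timing = list(t_start = tg0, t_end = tg0 + nsteps * dt, dt = dt,
                  out_every = out_every),
    gravity = scenario$gravity,
    settle = list(grav_ramp = min(50, scenario$settle_ms),
                  damp_until = tg0 + 2 * scenario$settle_ms / 3,
                  damp_factor = 5),
    t1 = t1m)
  if (!res$ok)
    stop(sprintf("integrator diverged at t = %.3f ms (segment %s): non-finite state",
                 res$bad_t,
                 model$segments$name[res$bad_body]), call. = FALSE)

  t_out <- res$t
  i0 <- which.min(abs(t_out))
  if (abs(t_out[i0]) > 1e-9 && tg1 > 0)
    stop("output grid does not contain t = 0", call. = FALSE)
  S <- res$state
  bcol <- function(b, c) S[, (b - 1) * 6 + c]
  rel <- function(v) v - v[i0]
  r2d <- 180 / pi
  chans <- list(
    ts_channel("HCG-x", "mm", t_out[1], scenario$out_dt, rel(bcol(8, 1))),
    ts_channel("HCG-z", "mm", t_out[1], scenario$out_dt, rel(bcol(8, 2))),
    ts_channel("HCG-ry", "deg", t_out[1], scenario$out_dt,
               rel(bcol(8, 3)) * r2d))
  for (k in 1:7)   # C1 is body 7, ..., C7 is body 1
    chans[[length(chans) + 1]] <-
      ts_channel(paste0("C", k, "-ry"), "deg", t_out[1], scenario$out_dt,
                 rel(bcol(8 - k, 3)) * r2d)
  # prescribed T1, echoed from the input at the output samples
  keep <- seq(1, nsteps + 1, by = out_every)
  chans <- c(chans, list(
    ts_channel("T1-x", "mm", t_out[1], scenario$out_dt, rel(t1m[keep, 1])),
    ts_channel("T1-z", "mm", t_out[1], scenario$out_dt, rel(t1m[keep, 2])),
    ts_channel("T1-ry", "deg", t_out[1], scenario$out_dt,
               rel(t1m[keep, 3]) * r2d),
    ts_channel("HCG-ax", "m/s^2", t_out[1], scenario$out_dt,
               res$head_ax * 1000)))
  # T1 x-acceleration from the fine-grid prescribed velocity
  t1ax <- numeric(nsteps + 1)
  vx <- t1m[, 4]
  t1ax[1] <- (vx[2] - vx[1]) / dt
  t1ax[nsteps + 1] <- (vx[nsteps + 1] - vx[nsteps]) / dt
  if (nsteps > 1)
    t1ax[2:nsteps] <- (vx[3:(nsteps + 1)] - vx[1:(nsteps - 1)]) / (2 * dt)
  chans[[length(chans) + 1]] <-
    ts_channel("T1-ax", "m/s^2", t_out[1], scenario$out_dt, t1ax[keep] * 1000)

  kin <- kinematics_set(chans, meta = list(
    sex = model$sex, toggles = tog,
    delta_v = if (!is.null(scenario$pulse)) scenario$pulse$delta_v else NA),
    align = FALSE)

  head_th <- bcol(8, 3) * r2d
  wsettle <- t_out >= -50 & t_out <= 0
  drift <- if (tg0 < -1 && sum(wsettle) > 1)
    max(abs(head_th[wsettle] - head_th[i0])) else 0
  settle_report <- list(theta_ref = res$theta_ref, drift_deg_final50 = drift,
                        threshold = scenario$drift_threshold,
                        unsettled = drift > scenario$drift_threshold)

  structure(list(kinematics = kin,
                 states = cbind(t = t_out, S),
                 t1_states = cbind(t = t_out, res$t1),
                 segment_names = model$segments$name,
                 activations = data.frame(t = t_out, u = res$u,
                                          flexor = res$a_flex,
                                          extensor = res$a_ext),
                 muscle_forces = res$f_muscle,
                 settle_report = settle_report,
                 config = list(toggles = tog, dt = dt,
                               out_dt = scenario$out_dt,
                               settle_ms = scenario$settle_ms,
                               term_ms = scenario$term_ms,
                               gravity = scenario$gravity,
                               filtering = "none")),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d channels, t = %g..%g ms%s\n",
              length(x$kinematics$channels), x$states[1, "t"],
              x$states[nrow(x$states), "t"],
              if (x$settle_report$unsettled) " [UNSETTLED]" else ""))
  invisible(x)
}

#' Quasi-static gravity settling
#'
#' Runs the settling phase only (ramped gravity with temporarily raised
#' joint damping, then hold) with zero base motion, and reports the head
#' angle drift over the final 50 ms. Drift above the threshold flags the
#' state as unsettled; the run still returns.
#'
#' @param model A [build_model()] result.
#' @param settle_ms Settling duration, ms.
#' @param cco Apply the model's baseline co-contraction during settling.
#' @param gravity Gravitational acceleration, mm/ms^2.
#' @param dt Integration step, ms.
#' @return A list with `report` (drift metrics), `state` (final body
#'   states at t = 0) and `result` (the full [run_scenario()] output).
#' @export
settle_gravity <- function(model, settle_ms = 150, cco = TRUE,
                           gravity = 9.81e-3, dt = 0.05) {
  n <- round(settle_ms + 10)
  zero <- kinematics_set(list(
    ts_channel("T1-x", "mm", -settle_ms, 1, numeric(n + 1)),
    ts_channel("T1-z", "mm", -settle_ms, 1, numeric(n + 1)),
    ts_channel("T1-ry", "rad", -settle_ms, 1, numeric(n + 1))),
    align = FALSE)
  sc <- scenario_config(toggles = list(cco = cco, pde = TRUE, apf = FALSE),
                        t1 = zero, settle_ms = settle_ms,
                        term_ms = settle_ms, dt = dt, gravity = gravity)
  res <- run_scenario(model, sc)
  n_out <- nrow(res$states)
  list(report = res$settle_report,
       state = res$states[n_out, ],
       result = res)
}

#' Injury-criteria input channels
#'
#' Extracts the standard whiplash injury-criteria inputs from a
#' simulation result: the NIC time history
#' `NIC(t) = 0.2 a_rel(t) + v_rel(t)^2` with
#' `a_rel = a_x(T1) - a_x(head)` in m/s^2 and `v_rel` its time integral
#' from impact onset, the head and T1 x-acceleration channels, and the
#' C1-C7 rotational velocities obtained by [differentiate()].
#'
#' @param result A [run_scenario()] result (or any [kinematics_set()]
#'   with the needed channels).
#' @return A list with `nic` (a [ts_channel()] in m^2/s^2), `nic_max`,
#'   `head_ax`, `t1_ax` and `cervical_velocity` (list of channels named
#'   `C1-ryv` ... `C7-ryv`, deg/ms).
#' @export
compute_injury_channels <- function(result) {
  set <- if (inherits(result, "simulation_result")) result$kinematics else result
  need <- c("HCG-ax", "T1-ax", paste0("C", 1:7, "-ry"))
  miss <- setdiff(need, names(set$channels))
  if (length(miss))
    stop("missing channels: ", paste(miss, collapse = ", "), call. = FALSE)
  ha <- set$channels[["HCG-ax"]]; ta <- set$channels[["T1-ax"]]
  keep <- channel_times(ha) >= 0
  crop <- function(ch) {
    t <- channel_times(ch)
    ts_channel(ch$name, ch$unit, 0, ch$dt, ch$values[t >= -1e-9])
  }
  ha <- crop(convert_channel(ha, "m/s^2"))
  ta <- crop(convert_channel(ta, "m/s^2"))
  arel <- ts_channel("a-rel", "m/s^2", 0, ha$dt, ta$values - ha$values)
  vrel <- integrate_channel(arel, initial = 0)   # mm/ms == m/s numerically
  nic <- ts_channel("NIC", "m^2/s^2", 0, ha$dt,
                    0.2 * arel$values + vrel$values^2)
  cerv <- lapply(1:7, function(k) {
    d <- differentiate(set$channels[[paste0("C", k, "-ry")]])
    d$name <- paste0("C", k, "-ryv")
    d
  })
  names(cerv) <- paste0("C", 1:7, "-ryv")
  list(nic = nic, nic_max = max(nic$values), head_ax = ha, t1_ax = ta,
       cervical_velocity = cerv)
}

#' Cervical oscillation index
#'
#' Counts the sign changes of the rotational velocity of a vertebral
#' channel (default C5-ry) over an evaluation window, beyond the first
#' two (a single extension-rebound motion produces up to two); residual
#' counts indicate oscillation. Used to quantify the suppression of
#' cervical oscillations by the parallel damping element.
#'
#' @param result A [run_scenario()] result or [kinematics_set()].
#' @param channel Displacement channel to analyze.
#' @param t_a,t_b Window in ms.
#' @return Integer oscillation index (>= 0).
#' @export
oscillation_index <- function(result, channel = "C5-ry", t_a = 0, t_b = 300) {
  set <- if (inherits(result, "simulation_result")) result$kinematics else result
  ch <- set$channels[[channel]]
  if (is.null(ch)) stop("missing channel: ", channel, call. = FALSE)
  v <- differentiate(ch)
  t <- channel_times(v)
  y <- v$values[t >= t_a & t <= t_b]
  tol <- 1e-4 * max(abs(y))
  s <- sign(y)
  s[abs(y) < tol] <- 0
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  changes <- sum(diff(s) != 0)
  max(0L, changes - 2L)
}
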