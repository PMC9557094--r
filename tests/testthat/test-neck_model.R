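test_that("model assembly is deterministic and override-faithful", {
  m1 <- build_model("female")
  m2 <- build_model("female")
  expect_identical(m1, m2)
  m3 <- build_model("female", overrides = list(joint_kr = 55))
  expect_equal(m3$joints$kr, rep(55, 8))
  expect_identical(m3$joints$kt, m1$joints$kt)
  expect_identical(m3$segments, m1$segments)
  expect_error(build_model("female", overrides = list(flux_capacitor = 1)),
               "unknown model parameters")
  # sexes share topology but differ in head mass and damping coefficient
  mf <- build_model("female"); mm <- build_model("male")
  expect_identical(mf$segments$name, mm$segments$name)
  expect_length(mm$muscles, length(mf$muscles))
  expect_gt(mm$segments$mass[8], mf$segments$mass[8])
  expect_equal(mf$pde_coeff, 0.0303)
  expect_equal(mm$pde_coeff, 0.0192)
})

test_that("gravity settling: equilibrium, drift flagging, degenerate cases", {
  # zero gravity, no co-contraction: nothing moves
  s0 <- settle_gravity(build_model("female"), settle_ms = 50, cco = FALSE,
                       gravity = 0)
  expect_equal(s0$report$drift_deg_final50, 0, tolerance = 1e-9)
  expect_false(s0$report$unsettled)
  st <- s0$result$states
  expect_lt(max(abs(st[nrow(st), -1] - st[1, -1])), 1e-9)
  # default settling converges below the drift threshold
  s1 <- settle_gravity(build_model("female"))
  expect_lt(s1$report$drift_deg_final50, 0.5)
  expect_false(s1$report$unsettled)
  expect_false(is.na(s1$report$theta_ref))
  # no restoring torque at all: the head falls and the run is flagged
  floppy <- build_model("female",
                        overrides = list(joint_kr = 0, joint_cr = 0))
  s2 <- settle_gravity(floppy, cco = FALSE)
  expect_true(s2$report$unsettled)
})

test_that("equilibrium run with no input stays still; T1 is reproduced exactly", {
  m <- build_model("female", overrides = list(
    pcsa_long_ext = 0, pcsa_long_flex = 0, pcsa_segmental = 0))
  n <- 500
  zero <- kinematics_set(list(
    ts_channel("T1-x", "mm", -20, 1, numeric(n)),
    ts_channel("T1-z", "mm", -20, 1, numeric(n)),
    ts_channel("T1-ry", "rad", -20, 1, numeric(n))), align = FALSE)
  sc <- scenario_config(toggles = list(cco = FALSE, pde = FALSE, apf = FALSE),
                        t1 = zero, settle_ms = 20, term_ms = 120,
                        gravity = 0)
  res <- run_scenario(m, sc)
  for (nm in c("HCG-x", "HCG-z", "HCG-ry", "C4-ry"))
    expect_equal(max(abs(res$kinematics$channels[[nm]]$values)), 0,
                 tolerance = 1e-12)
  # prescribed-motion fidelity on a moving base
  t1in <- fx_static_t1()
  sc2 <- scenario_config(t1 = t1in, settle_ms = 10, term_ms = 310)
  res2 <- run_scenario(build_model("female"), sc2)
  tout <- channel_times(res2$kinematics$channels[["T1-x"]])
  want <- approx(channel_times(t1in$channels[["T1-x"]]),
                 t1in$channels[["T1-x"]]$values, tout)$y
  got <- res2$kinematics$channels[["T1-x"]]$values
  expect_lt(max(abs(got - (want - want[tout == 0]))), 1e-9)
})

test_that("undamped muscle-free chain conserves energy in free vibration", {
  m <- build_model("female", overrides = list(
    joint_ct = 0, joint_cr = 0,
    pcsa_long_ext = 0, pcsa_long_flex = 0, pcsa_segmental = 0))
  sc <- scenario_config(toggles = list(cco = FALSE, pde = FALSE, apf = FALSE),
                        t1 = fx_static_t1(amp = 15), settle_ms = 0,
                        term_ms = 280, gravity = 0, dt = 0.05)
  res <- run_scenario(m, sc)
  E <- oracle_energy(res, m, gravity = 0)
  t <- res$states[, "t"]
  # after t = 100 ms the base is at rest: free vibration. Energy drift
  # over the following 100 ms stays below 0.5% of the stored energy.
  win <- t >= 120 & t <= 220
  E0 <- E[which(win)[1]]
  expect_gt(E0, 0)
  expect_lt(max(abs(E[win] - E0)) / E0, 0.005)
})

test_that("halving the integration step leaves rating channels unchanged to 0.1%", {
  m <- set_model_params(build_model("female"), fx_truth())
  r1 <- run_scenario(m, scenario_config(dt = 0.05))
  r2 <- run_scenario(m, scenario_config(dt = 0.025))
  for (nm in c("HCG-x", "HCG-ry", "C5-ry")) {
    a <- r1$kinematics$channels[[nm]]$values
    b <- r2$kinematics$channels[[nm]]$values
    rms <- sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
    expect_lt(rms, 0.001)
  }
})

test_that("toggles act only after settling when co-contraction is equal", {
  m <- set_model_params(build_model("female"), fx_truth())
  sc_off <- scenario_config(toggles = list(cco = FALSE, pde = TRUE, apf = FALSE))
  sc_on <- scenario_config(toggles = list(cco = FALSE, pde = TRUE, apf = TRUE))
  a <- run_scenario(m, sc_off)$kinematics$channels[["HCG-ry"]]
  b <- run_scenario(m, sc_on)$kinematics$channels[["HCG-ry"]]
  t <- channel_times(a)
  pre <- t <= 0
  expect_equal(a$values[pre], b$values[pre], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$values[!pre], b$values[!pre])))
})

test_that("simulated velocities are consistent with differentiated displacements", {
  res <- fx_active_run()
  ch <- res$kinematics$channels[["C5-ry"]]
  d <- differentiate(ch)
  # body 3 is C5 (order is C7..C1 then head); compare against the
  # integrator's own angular velocity in deg/ms
  w <- res$states[, 1 + 2 * 6 + 6] * 180 / pi
  interior <- 2:(length(w) - 1)
  expect_lt(max(abs(d$values[interior] - w[interior])),
            0.02 * max(abs(w)))
})

test_that("injury channels: NIC closed forms and quadrature oracle", {
  dt <- 0.5
  t <- seq(0, 300, by = dt)
  mk <- function(head_ax, t1_ax) {
    chans <- c(lapply(paste0("C", 1:7, "-ry"), function(nm)
      ts_channel(nm, "deg", 0, dt, sin(t / 50))),
      list(ts_channel("HCG-ax", "m/s^2", 0, dt, head_ax),
           ts_channel("T1-ax", "m/s^2", 0, dt, t1_ax)))
    kinematics_set(chans, align = FALSE)
  }
  # identical head and T1 motion: NIC identically zero
  ic <- compute_injury_channels(mk(sin(t / 30), sin(t / 30)))
  expect_equal(max(abs(ic$nic$values)), 0)
  # constant relative acceleration 1 m/s^2 from rest: NIC = 0.2 + t_s^2
  ic2 <- compute_injury_channels(mk(numeric(length(t)), rep(1, length(t))))
  ts <- t / 1000
  expect_equal(ic2$nic$values, 0.2 + ts^2, tolerance = 1e-9)
  # unit haversine relative acceleration: peak against quadrature oracle
  T <- 100
  hav <- function(tms) ifelse(tms < T, (1 - cos(2 * pi * tms / T)) / 2, 0)
  ic3 <- compute_injury_channels(mk(numeric(length(t)), hav(t)))
  expect_equal(ic3$nic_max, oracle_nic_peak(hav, 300), tolerance = 1e-4)
  expect_error(compute_injury_channels(
    kinematics_set(list(ts_channel("HCG-ax", "m/s^2", 0, 1, 1:10)),
                   align = FALSE)), "missing channels")
  # cervical velocities come out in deg/ms with one channel per level
  res <- fx_active_run()
  ic4 <- compute_injury_channels(res)
  expect_length(ic4$cervical_velocity, 7)
  expect_equal(ic4$cervical_velocity[["C3-ryv"]]$unit, "deg/ms")
  expect_gt(ic4$nic_max, 0)
})

test_that("cervical oscillation index is monotone non-increasing in the damping coefficient", {
  m <- build_model("female")
  idx <- vapply(c(0, 0.01, 0.03, 0.05), function(p) {
    res <- run_scenario(set_model_params(m, c(fx_truth()[c("kpa", "kda", "tnda")],
                                              pde = p)),
                        scenario_config())
    as.numeric(oscillation_index(res))
  }, 0)
  expect_true(all(diff(idx) <= 0))
  expect_gt(idx[1], idx[4] - 1e-9)  # damping visibly suppresses oscillation
})

test_that("integrator failure is reported with time and segment", {
  m <- build_model("female", overrides = list(joint_kt = 1e5))
  expect_error(run_scenario(m, scenario_config(dt = 0.5)),
               "diverged at t")
})
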