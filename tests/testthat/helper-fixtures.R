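# Shared fixtures, built once per test run and cached. All expensive
# simulation products (truth reference, recovery run) live here so
# several test files can assert against the same computation.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fx_model <- function() fx_cached("model", function() build_model("female"))

fx_truth <- function() {
  p <- reference_optimized_params()["female", ]
  list(kpa = p$kpa, kda = p$kda, tnda = p$tnda, pde = p$pde)
}

fx_scenario <- function() scenario_config()

fx_reference <- function() fx_cached("reference", function()
  make_reference(reference_recipe("truth_run", truth = fx_truth()),
                 fx_model(), fx_scenario()))

fx_active_run <- function() fx_cached("active_run", function()
  run_scenario(set_model_params(fx_model(), fx_truth()), fx_scenario()))

# the parameter-recovery experiment (budget 300, seeded); reused by the
# recovery and bounds-fidelity acceptance checks
fx_recovery <- function() fx_cached("recovery", function()
  calibrate(optimization_spec(seed = 2026L), fx_model(), fx_reference(),
            fx_scenario()))

# a smooth displacement-driven T1 input that comes to rest (for
# conservation checks: after t = 100 ms the base is static)
fx_static_t1 <- function(amp = 30, T = 100, t0 = -10, t1 = 350, dt = 0.5) {
  t <- seq(t0, t1, by = dt)
  # one full raised-cosine cycle: returns to rest (x = 0, v = 0) at t = T
  x <- ifelse(t < 0 | t > T, 0, amp * (1 - cos(2 * pi * t / T)) / 2)
  kinematics_set(list(
    ts_channel("T1-x", "mm", t0, dt, x),
    ts_channel("T1-z", "mm", t0, dt, numeric(length(t))),
    ts_channel("T1-ry", "rad", t0, dt, numeric(length(t)))),
    align = FALSE)
}
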