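# Independent oracles used by the tests: total mechanical energy
# recomputed from the state trajectory (not from the integrator's
# internals), and a brute-force quadrature for the NIC integral.

# Total mechanical energy of a simulation result at each output sample:
# kinetic + gravitational potential + elastic energy stored in the
# penalty bushings. Assumes the model's muscles exert no force (pcsa 0).
oracle_energy <- function(res, model, gravity = 0) {
  S <- res$states
  T1 <- res$t1_states
  n <- nrow(S)
  nb <- 8
  E <- numeric(n)
  for (i in seq_len(n)) {
    ke <- 0; pe <- 0
    for (b in seq_len(nb)) {
      vx <- S[i, 1 + (b - 1) * 6 + 4]; vz <- S[i, 1 + (b - 1) * 6 + 5]
      w <- S[i, 1 + (b - 1) * 6 + 6]
      ke <- ke + 0.5 * model$segments$mass[b] * (vx^2 + vz^2) +
        0.5 * model$segments$inertia[b] * w^2
      pe <- pe + model$segments$mass[b] * gravity * S[i, 1 + (b - 1) * 6 + 2]
    }
    for (j in seq_len(nb)) {
      if (j == 1) {
        px <- T1[i, 2]; pz <- T1[i, 3]; pth <- T1[i, 4]
      } else {
        px <- S[i, 1 + (j - 2) * 6 + 1]; pz <- S[i, 1 + (j - 2) * 6 + 2]
        pth <- S[i, 1 + (j - 2) * 6 + 3]
      }
      cx <- S[i, 1 + (j - 1) * 6 + 1]; cz <- S[i, 1 + (j - 1) * 6 + 2]
      cth <- S[i, 1 + (j - 1) * 6 + 3]
      rot <- function(th, v) c(cos(th) * v[1] - sin(th) * v[2],
                               sin(th) * v[1] + cos(th) * v[2])
      ap <- c(px, pz) + rot(pth, model$anchor_p[j, ])
      ac <- c(cx, cz) + rot(cth, model$anchor_c[j, ])
      d <- ac - ap
      pe <- pe + 0.5 * model$joints$kt[j] * sum(d^2) +
        0.5 * model$joints$kr[j] * (cth - pth - model$joints$neutral[j])^2
    }
    E[i] <- ke + pe
  }
  E
}

# Brute-force NIC oracle for a given relative-acceleration waveform
# a_rel(t) in m/s^2 sampled at dt (ms): v_rel by fine Riemann quadrature,
# NIC(t) = 0.2 a_rel + v_rel^2, independent of the package's channel
# arithmetic.
oracle_nic_peak <- function(a_fun, t_end_ms, n = 200001) {
  t <- seq(0, t_end_ms / 1000, length.out = n)      # seconds
  a <- a_fun(t * 1000)
  dt <- t[2] - t[1]
  v <- cumsum(c(0, (a[-1] + a[-n]) / 2 * dt))[seq_len(n)]
  max(0.2 * a + v^2)
}
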