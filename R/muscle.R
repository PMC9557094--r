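# Hill-type line muscle: active contractile stress scaled by force-length
# and force-velocity curves, an exponential passive toe, and the parallel
# damping element (PDE). No serial elastic element is modelled: the line
# element carries contractile + parallel passive + parallel damping stress
# only, and is floored at zero (muscle cannot push).

#' Muscle parameter set
#'
#' @param name Identifier.
#' @param pcsa Physiological cross-sectional area, mm^2.
#' @param l0 Optimal (reference) length, mm.
#' @param sigma_max Peak isometric stress, kN/mm^2. Default 5e-4
#'   (0.5 MPa, a conventional skeletal-muscle value).
#' @param fl_width Half-width of the quadratic force-length bell
#'   (dimensionless, default 0.5).
#' @param fv_shape Concentric curvature constant of the Hill hyperbola
#'   (dimensionless, default 0.25).
#' @param fv_ecc_plateau Eccentric plateau multiplier (>= 1, default 1.4).
#' @param v_max Maximum shortening velocity in optimal lengths per ms
#'   (default 0.01, i.e. 10 l0/s).
#' @param pde_coeff Parallel damping coefficient, kN*ms/mm^2. Acts on the
#'   normalized strain rate so that `pcsa * pde_coeff * (dl/dt)/l0` is a
#'   force in kN. Typical identified range 0.01-0.05.
#' @param cco_level Baseline co-contraction activation in \[0, 1\].
#' @param k_passive,c_passive Passive toe-curve scale (kN/mm^2) and
#'   exponential rate: `sigma_p = k_passive * (exp(c_passive*(lambda-1)) - 1)`
#'   for lambda > 1, zero otherwise.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(name = "muscle", pcsa = 100, l0 = 100,
                          sigma_max = 5e-4, fl_width = 0.5,
                          fv_shape = 0.25, fv_ecc_plateau = 1.4,
                          v_max = 0.01, pde_coeff = 0.02, cco_level = 0,
                          k_passive = 5e-5, c_passive = 6) {
  stopifnot(pcsa > 0, l0 > 0, sigma_max > 0, fl_width > 0,
            fv_shape > 0, fv_ecc_plateau >= 1, v_max > 0,
            pde_coeff >= 0, cco_level >= 0, cco_level <= 1,
            k_passive >= 0, c_passive > 0)
  structure(list(name = name, pcsa = pcsa, l0 = l0, sigma_max = sigma_max,
                 fl_width = fl_width, fv_shape = fv_shape,
                 fv_ecc_plateau = fv_ecc_plateau, v_max = v_max,
                 pde_coeff = pde_coeff, cco_level = cco_level,
                 k_passive = k_passive, c_passive = c_passive),
            class = "muscle_params")
}

#' Force-length scaling factor
#'
#' Quadratic bell: `max(0, 1 - ((lambda - 1)/fl_width)^2)`; equals 1 at
#' optimal length and vanishes outside `[1 - fl_width, 1 + fl_width]`.
#'
#' @param lambda Length ratio l/l0 (> 0). Vectorized.
#' @param fl_width Bell half-width.
#' @return Factor in \[0, 1\].
#' @export
force_length <- function(lambda, fl_width = 0.5) {
  stopifnot(all(lambda > 0), fl_width > 0)
  pmax(0, 1 - ((lambda - 1) / fl_width)^2)
}

#' Force-velocity scaling factor
#'
#' Classic Hill hyperbola for shortening (`v_norm` in \[-1, 0\]):
#' `(1 + v_norm) / (1 - v_norm/fv_shape)`, giving 1 at isometric and 0 at
#' maximal shortening. For lengthening a smooth saturating rise to
#' `fv_ecc_plateau`, slope-matched to the concentric branch at zero so the
#' curve is C1-continuous and monotone non-decreasing.
#'
#' @param v_norm Normalized velocity `(dl/dt) / (l0 * v_max)`; positive =
#'   elongation. Vectorized.
#' @param fv_shape Concentric curvature constant.
#' @param fv_ecc_plateau Eccentric plateau (>= 1).
#' @return Factor >= 0.
#' @export
force_velocity <- function(v_norm, fv_shape = 0.25, fv_ecc_plateau = 1.4) {
  stopifnot(fv_shape > 0, fv_ecc_plateau >= 1)
  slope0 <- 1 + 1 / fv_shape                 # concentric slope at v = 0
  out <- numeric(length(v_norm))
  con <- v_norm <= 0
  vc <- pmax(v_norm[con], -1)
  out[con] <- (1 + vc) / (1 - vc / fv_shape)
  if (any(!con)) {
    ve <- v_norm[!con]
    if (fv_ecc_plateau > 1) {
      d <- (fv_ecc_plateau - 1) / slope0     # slope match at v = 0+
      out[!con] <- fv_ecc_plateau - (fv_ecc_plateau - 1) * exp(-ve / d)
    } else out[!con] <- 1
  }
  out
}

#' Parallel damping element stress
#'
#' Linear viscous stress `sigma_d = pde_coeff * strain_rate`, odd in the
#' strain rate and zero at rest. With the strain rate normalized by l0,
#' the coefficient carries the unit kN*ms/mm^2.
#'
#' @param pde_coeff Damping coefficient, kN*ms/mm^2.
#' @param strain_rate `(dl/dt)/l0`, 1/ms. Vectorized.
#' @return Stress in kN/mm^2.
#' @export
pde_stress <- function(pde_coeff, strain_rate) pde_coeff * strain_rate

#' Passive elastic stress
#'
#' Exponential toe curve, zero at and below optimal length.
#'
#' @param lambda Length ratio l/l0. Vectorized.
#' @param k_passive Scale, kN/mm^2.
#' @param c_passive Exponential rate.
#' @return Stress in kN/mm^2.
#' @export
passive_stress <- function(lambda, k_passive = 5e-5, c_passive = 6) {
  ifelse(lambda > 1, k_passive * (expm1(c_passive * (lambda - 1))), 0)
}

#' Muscle state
#'
#' @param length Current length, mm.
#' @param velocity Lengthening velocity dl/dt, mm/ms (positive = elongation).
#' @param activation Activation in \[0, 1\] (clamped).
#' @return An object of class `muscle_state`.
#' @export
muscle_state <- function(length, velocity = 0, activation = 0) {
  stopifnot(length > 0, is.finite(velocity))
  structure(list(length = length, velocity = velocity,
                 activation = min(1, max(0, activation))),
            class = "muscle_state")
}

#' Total muscle force
#'
#' `F = pcsa * (a * sigma_max * f_l * f_v + sigma_passive + sigma_pde)`,
#' floored at zero: the line element transmits tension only.
#'
#' @param state A [muscle_state()].
#' @param params A [muscle_params()].
#' @return Tensile force in kN (>= 0).
#' @export
total_muscle_force <- function(state, params) {
  stopifnot(inherits(state, "muscle_state"), inherits(params, "muscle_params"))
  lam <- state$length / params$l0
  v_norm <- state$velocity / (params$l0 * params$v_max)
  sig <- state$activation * params$sigma_max *
    force_length(lam, params$fl_width) *
    force_velocity(v_norm, params$fv_shape, params$fv_ecc_plateau) +
    passive_stress(lam, params$k_passive, params$c_passive) +
    pde_stress(params$pde_coeff, state$velocity / params$l0)
  max(0, params$pcsa * sig)
}
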