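# Delayed PD reflex controller on head orientation ("angular-positioned
# feedback"): a surrogate for the vestibulocollic reflex. The control
# error is the head sagittal angle relative to the settled reference
# posture, measured in the ground frame; the command is delayed by the
# neural transmission and processing time and routed to flexor/extensor
# groups about the co-contraction baseline.

#' Reflex controller parameters
#'
#' @param kpa Proportional gain, %contraction per rad.
#' @param kda Derivative gain, %contraction per (rad/ms).
#' @param tnda Neural transmission and processing delay, ms.
#' @param theta_ref Reference head angle, rad. Captured at the end of
#'   gravity settling (t = 0); `NA` until captured.
#' @param enabled Controller toggle.
#' @param routing `"reciprocal"` (command adds to the agonist and
#'   subtracts from the antagonist about the co-contraction baseline) or
#'   `"agonist_only"`.
#' @return An object of class `controller_params`.
#' @export
controller_params <- function(kpa = 6, kda = 5, tnda = 20,
                              theta_ref = NA_real_, enabled = TRUE,
                              routing = c("reciprocal", "agonist_only")) {
  stopifnot(kpa >= 0, kda >= 0, tnda >= 0)
  routing <- match.arg(routing)
  structure(list(kpa = kpa, kda = kda, tnda = tnda, theta_ref = theta_ref,
                 enabled = enabled, routing = routing),
            class = "controller_params")
}

#' Head-orientation error signal
#'
#' `e = theta_head - theta_ref` in the ground frame; positive error means
#' rearward (extension) rotation beyond the settled posture.
#'
#' @param theta_head Current head angle, rad.
#' @param theta_ref Reference angle captured at end of settling, rad.
#' @return Error in rad.
#' @export
error_signal <- function(theta_head, theta_ref) {
  if (any(is.na(theta_ref)))
    stop("theta_ref not captured: settling must complete before the ",
         "controller can evaluate its error", call. = FALSE)
  theta_head - theta_ref
}

#' Create a delay buffer for the controller error history
#'
#' Records `(t, e)` samples on a fixed grid from the controller start
#' time; queries before the start return the neutral value 0. The error
#' rate is obtained by the same central-difference operator as
#' [differentiate()], applied to the buffered error.
#'
#' @param t_start Controller start time, ms (end of settling).
#' @param dt Buffer sample interval, ms.
#' @param horizon Buffer length, ms (must cover the delay).
#' @return An object of class `delay_buffer`.
#' @export
delay_buffer <- function(t_start = 0, dt = 0.05, horizon = 600) {
  stopifnot(dt > 0, horizon > 0)
  structure(list(t_start = t_start, dt = dt,
                 e = numeric(ceiling(horizon / dt) + 1L), n = 0L),
            class = "delay_buffer")
}

#' Append an error sample to a delay buffer
#'
#' Samples must be pushed in order at the buffer's grid times
#' `t_start + k*dt`.
#'
#' @param buffer A [delay_buffer()].
#' @param e Error value at the next grid time.
#' @return The updated buffer.
#' @export
buffer_push <- function(buffer, e) {
  buffer$n <- buffer$n + 1L
  if (buffer$n > length(buffer$e)) buffer$e <- c(buffer$e, numeric(1024L))
  buffer$e[buffer$n] <- e
  buffer
}

# Query e and de/dt at time tq (ms); 0 before controller start.
.buffer_query <- function(buffer, tq) {
  if (buffer$n < 1L || tq < buffer$t_start) return(c(e = 0, de = 0))
  idx <- (tq - buffer$t_start) / buffer$dt   # 0-based fractional index
  i0 <- floor(idx)
  frac <- idx - i0
  get_e <- function(i) {                     # 0-based, clamped to history
    i <- min(max(i, 0), buffer$n - 1L)
    buffer$e[i + 1L]
  }
  e <- (1 - frac) * get_e(i0) + frac * get_e(i0 + 1)
  # central-difference rate at the two bracketing grid points, interpolated
  rate_at <- function(i) {
    if (i <= 0) (get_e(1) - get_e(0)) / buffer$dt
    else if (i >= buffer$n - 1L) (get_e(buffer$n - 1L) - get_e(buffer$n - 2L)) / buffer$dt
    else (get_e(i + 1) - get_e(i - 1)) / (2 * buffer$dt)
  }
  de <- (1 - frac) * rate_at(i0) + frac * rate_at(i0 + 1)
  c(e = e, de = de)
}

#' Delayed PD command
#'
#' `u(t) = kpa * e(t - tnda) + kda * de/dt(t - tnda)`, in percent
#' contraction. Queries earlier than the controller start evaluate to the
#' neutral error 0, so the command is identically zero for
#' `t < t_start + tnda`.
#'
#' @param buffer A [delay_buffer()] populated up to time `t`.
#' @param params A [controller_params()].
#' @param t Current time, ms.
#' @return Command `u` in percent contraction.
#' @export
pd_command <- function(buffer, params, t) {
  if (!params$enabled) return(0)
  q <- .buffer_query(buffer, t - params$tnda)
  params$kpa * q[["e"]] + params$kda * q[["de"]]
}

#' Route a PD command to muscle-group activations
#'
#' Positive command (head extending beyond reference) activates the
#' flexors, which resist extension. With reciprocal routing the
#' antagonist is de-activated symmetrically about the co-contraction
#' baseline; with `agonist_only` routing the antagonist stays at the
#' baseline. All outputs are clamped to \[0, 1\].
#'
#' @param u Command in percent contraction.
#' @param cco_level Baseline co-contraction activation.
#' @param group `"flexor"` or `"extensor"`.
#' @param enabled If `FALSE` the group receives the baseline only.
#' @param routing `"reciprocal"` or `"agonist_only"`.
#' @return Activation in \[0, 1\].
#' @export
route_activation <- function(u, cco_level, group = c("flexor", "extensor"),
                             enabled = TRUE,
                             routing = c("reciprocal", "agonist_only")) {
  group <- match.arg(group)
  routing <- match.arg(routing)
  if (!enabled) return(min(1, max(0, cco_level)))
  s <- if (group == "flexor") u / 100 else -u / 100
  if (routing == "agonist_only") s <- max(s, 0)
  min(1, max(0, cco_level + s))
}
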