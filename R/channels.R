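# Time-series channel model and crash-signal utilities.
#
# Internal unit system is mm-ms-kg, so forces come out in kN and the
# parallel damping coefficient carries its conventional unit kN*ms/mm^2.
# Channels declare their own I/O unit; conversions go through a small
# registry of dimension groups.

.unit_registry <- list(
  length  = c("mm" = 1, "m" = 1000),
  angle   = c("rad" = 1, "deg" = pi / 180),
  linvel  = c("mm/ms" = 1, "m/s" = 1, "km/h" = 1 / 3.6),
  angvel  = c("rad/ms" = 1, "deg/ms" = pi / 180),
  accel   = c("mm/ms^2" = 1, "m/s^2" = 1e-3, "g" = 9.80665e-3),
  nic     = c("m^2/s^2" = 1)
)

.unit_group <- function(unit) {
  for (g in names(.unit_registry)) {
    if (unit %in% names(.unit_registry[[g]])) return(g)
  }
  stop("unknown unit '", unit, "'; registered units: ",
       paste(unlist(lapply(.unit_registry, names)), collapse = ", "),
       call. = FALSE)
}

#' Registered channel units
#'
#' @return Character vector of all unit strings the channel model accepts.
#' @export
channel_units <- function() unname(unlist(lapply(.unit_registry, names)))

#' Create a uniformly sampled time-series channel
#'
#' The basic data container for all kinematic signals: one named,
#' unit-tagged signal on a uniform time grid (milliseconds).
#'
#' @param name Channel identifier, e.g. `"HCG-x"`, `"C3-ry"`, `"T1-ax"`.
#' @param unit Unit string; must be one of [channel_units()].
#' @param t0 Start time in ms. The convention throughout the package is
#'   that t = 0 is impact onset and gravity settling occupies negative time.
#' @param dt Sample interval in ms (uniform, > 0).
#' @param values Numeric vector of samples (finite, length >= 2).
#' @return An object of class `ts_channel`.
#' @export
ts_channel <- function(name, unit, t0, dt, values) {
  values <- as.numeric(values)
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single string", call. = FALSE)
  .unit_group(unit)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (ms)", call. = FALSE)
  if (length(values) < 2L)
    stop("channel '", name, "' needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("channel '", name, "' contains non-finite samples", call. = FALSE)
  structure(list(name = name, unit = unit, t0 = as.numeric(t0),
                 dt = dt, values = values),
            class = "ts_channel")
}

#' @export
print.ts_channel <- function(x, ...) {
  cat(sprintf("<ts_channel> %s [%s]: %d samples, t = %g..%g ms, dt = %g ms\n",
              x$name, x$unit, length(x$values), x$t0,
              x$t0 + (length(x$values) - 1) * x$dt, x$dt))
  invisible(x)
}

#' Sample times of a channel
#'
#' @param ch A [ts_channel()].
#' @return Numeric vector of sample times in ms.
#' @export
channel_times <- function(ch) ch$t0 + (seq_along(ch$values) - 1L) * ch$dt

#' Convert a channel to another unit in the same dimension group
#'
#' Conversions are exact scale factors and round-trip to within 1e-12
#' relative error.
#'
#' @param ch A [ts_channel()].
#' @param to Target unit string.
#' @return The converted channel.
#' @export
convert_channel <- function(ch, to) {
  g_from <- .unit_group(ch$unit)
  g_to <- .unit_group(to)
  if (g_from != g_to)
    stop("cannot convert '", ch$unit, "' to '", to,
         "': incompatible dimensions", call. = FALSE)
  f <- .unit_registry[[g_from]][[ch$unit]] / .unit_registry[[g_to]][[to]]
  ts_channel(ch$name, to, ch$t0, ch$dt, ch$values * f)
}

#' Resample a channel onto a new uniform grid
#'
#' Linear interpolation onto a uniform grid spanning the original support;
#' the original endpoints are grid points whenever the span is an integer
#' multiple of `dt_new`.
#'
#' @param ch A [ts_channel()].
#' @param dt_new New sample interval in ms.
#' @return The resampled channel.
#' @export
resample <- function(ch, dt_new) {
  stopifnot(inherits(ch, "ts_channel"))
  if (!is.numeric(dt_new) || length(dt_new) != 1L || dt_new <= 0)
    stop("'dt_new' must be a single positive number (ms)", call. = FALSE)
  span <- (length(ch$values) - 1L) * ch$dt
  n_steps <- span / dt_new
  n_steps <- if (abs(n_steps - round(n_steps)) < 1e-9) round(n_steps) else floor(n_steps)
  if (n_steps < 1L) stop("dt_new larger than channel support", call. = FALSE)
  t_new <- ch$t0 + (0:n_steps) * dt_new
  y <- stats::approx(channel_times(ch), ch$values, xout = t_new, rule = 2)$y
  ts_channel(ch$name, ch$unit, ch$t0, dt_new, y)
}

.diff_unit <- c("mm" = "mm/ms", "deg" = "deg/ms", "rad" = "rad/ms",
                "mm/ms" = "mm/ms^2", "m" = "mm/ms", "m/s" = "mm/ms^2",
                "km/h" = "mm/ms^2")
.int_unit <- c("mm/ms^2" = "mm/ms", "m/s^2" = "mm/ms", "g" = "mm/ms",
               "mm/ms" = "mm", "m/s" = "mm", "km/h" = "mm",
               "deg/ms" = "deg", "rad/ms" = "rad")

#' Differentiate a channel in time
#'
#' Central differences on interior samples, one-sided at the ends. The
#' unit is transformed accordingly (deg -> deg/ms, mm -> mm/ms, ...).
#'
#' @param ch A [ts_channel()] with at least 3 samples.
#' @return The derivative channel, named `"d(<name>)"`.
#' @export
differentiate <- function(ch) {
  stopifnot(inherits(ch, "ts_channel"))
  if (length(ch$values) < 3L)
    stop("differentiate needs at least 3 samples", call. = FALSE)
  if (!ch$unit %in% names(.diff_unit))
    stop("no derivative unit registered for '", ch$unit, "'", call. = FALSE)
  u_new <- .diff_unit[[ch$unit]]
  y <- ch$values * .unit_registry[[.unit_group(ch$unit)]][[ch$unit]]
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / ch$dt
  d[n] <- (y[n] - y[n - 1]) / ch$dt
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * ch$dt)
  ch2 <- ts_channel(paste0("d(", ch$name, ")"),
                    names(.unit_registry[[.unit_group(u_new)]])[1],
                    ch$t0, ch$dt, d)
  convert_channel(ch2, u_new)
}

#' Cumulative time integral of a channel
#'
#' Trapezoidal cumulative integration with a stated initial value; the
#' unit is transformed (mm/ms^2 -> mm/ms, deg/ms -> deg, ...).
#'
#' @param ch A [ts_channel()].
#' @param initial Value of the integral at the first sample.
#' @return The integral channel, named `"int(<name>)"`.
#' @export
integrate_channel <- function(ch, initial = 0) {
  stopifnot(inherits(ch, "ts_channel"))
  if (!ch$unit %in% names(.int_unit))
    stop("no integral unit registered for '", ch$unit, "'", call. = FALSE)
  u_new <- .int_unit[[ch$unit]]
  y <- ch$values * .unit_registry[[.unit_group(ch$unit)]][[ch$unit]]
  n <- length(y)
  s <- c(0, cumsum((y[-1] + y[-n]) / 2 * ch$dt)) + initial
  ch2 <- ts_channel(paste0("int(", ch$name, ")"),
                    names(.unit_registry[[.unit_group(u_new)]])[1],
                    ch$t0, ch$dt, s)
  convert_channel(ch2, u_new)
}

#' SAE J211 channel-class low-pass filter
#'
#' Phaseless (two-pass, forward and backward) second-order Butterworth
#' low-pass with the standard J211 channel-frequency-class coefficients.
#' DC gain is exactly 1 by construction. The signal is mirror-padded at
#' both ends before filtering to suppress edge transients.
#'
#' @param ch A [ts_channel()].
#' @param cfc_class Channel frequency class: 60, 180, or 1000.
#' @return The filtered channel.
#' @export
cfc_filter <- function(ch, cfc_class = c(60, 180, 1000)) {
  stopifnot(inherits(ch, "ts_channel"))
  cfc_class <- match.arg(as.character(cfc_class[1]), c("60", "180", "1000"))
  cfc <- as.numeric(cfc_class)
  fs <- 1000 / ch$dt                       # Hz
  if (fs < 10 * cfc)
    stop("sampling rate ", fs, " Hz too low for CFC ", cfc,
         " (need >= ", 10 * cfc, " Hz)", call. = FALSE)
  T <- ch$dt / 1000                        # s
  wd <- 2 * pi * cfc * 2.0775
  wa <- tan(wd * T / 2)
  denom <- 1 + sqrt(2) * wa + wa^2
  a0 <- wa^2 / denom
  a1 <- 2 * a0
  a2 <- a0
  b1 <- -2 * (wa^2 - 1) / denom
  b2 <- (-1 + sqrt(2) * wa - wa^2) / denom

  one_pass <- function(x) {
    n <- length(x)
    y <- numeric(n)
    y[1] <- x[1]; y[2] <- x[2]
    for (i in 3:n)
      y[i] <- a0 * x[i] + a1 * x[i - 1] + a2 * x[i - 2] +
        b1 * y[i - 1] + b2 * y[i - 2]
    y
  }
  n <- length(ch$values)
  npad <- min(n - 1L, max(10L, ceiling(10000 / (cfc * ch$dt))))
  x <- ch$values
  # mirror about the end values (odd reflection preserves constants and trends)
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(head_pad, x, tail_pad)
  yp <- rev(one_pass(rev(one_pass(xp))))
  ts_channel(ch$name, ch$unit, ch$t0, ch$dt, yp[(npad + 1):(npad + n)])
}

# ---------------------------------------------------------------------------
# KinematicsSet: the channel bundle used for rating

#' Names of the channels required for head-neck rating
#' @return Character vector of the ten displacement rating channels.
#' @export
rating_channel_names <- function() {
  c("HCG-x", "HCG-z", "HCG-ry", paste0("C", 1:7, "-ry"))
}

#' Bundle channels into a kinematics set
#'
#' A named collection of channels sharing a time base, plus scenario
#' metadata (delta-v, subject sex label, configuration name).
#'
#' @param channels List of [ts_channel()] objects (names taken from the
#'   channels themselves).
#' @param meta Named list of scenario metadata.
#' @param align If `TRUE` (default) all channels are resampled onto the
#'   coarsest common grid over the intersection of supports.
#' @return An object of class `kinematics_set`.
#' @export
kinematics_set <- function(channels, meta = list(), align = TRUE) {
  stopifnot(is.list(channels), all(vapply(channels, inherits, TRUE, "ts_channel")))
  names(channels) <- vapply(channels, `[[`, "", "name")
  if (align && length(channels) > 1L) {
    dt <- max(vapply(channels, `[[`, 0, "dt"))
    t0 <- max(vapply(channels, `[[`, 0, "t0"))
    tend <- min(vapply(channels, function(c)
      c$t0 + (length(c$values) - 1) * c$dt, 0))
    if (tend - t0 < dt) stop("channels have no common support", call. = FALSE)
    n <- floor((tend - t0) / dt + 1e-9)
    tg <- t0 + (0:n) * dt
    channels <- lapply(channels, function(c) {
      y <- stats::approx(channel_times(c), c$values, xout = tg, rule = 2)$y
      ts_channel(c$name, c$unit, t0, dt, y)
    })
  }
  structure(list(channels = channels, meta = meta), class = "kinematics_set")
}

#' @export
print.kinematics_set <- function(x, ...) {
  cat(sprintf("<kinematics_set> %d channels%s\n", length(x$channels),
              if (is_rateable(x)) " (rateable)" else ""))
  for (ch in x$channels)
    cat(sprintf("  %-10s [%s]  n=%d dt=%g\n", ch$name, ch$unit,
                length(ch$values), ch$dt))
  invisible(x)
}

#' Can a kinematics set be rated with the head-neck scheme?
#'
#' @param set A [kinematics_set()].
#' @return `TRUE` if all ten rating channels are present.
#' @export
is_rateable <- function(set) {
  all(rating_channel_names() %in% names(set$channels))
}

#' Channels missing for head-neck rating
#' @param set A [kinematics_set()].
#' @return Character vector of absent required channel names.
#' @export
missing_rating_channels <- function(set) {
  setdiff(rating_channel_names(), names(set$channels))
}

# ---------------------------------------------------------------------------
# CSV I/O. Format: first column "time [ms]", then one column per channel
# with header "name [unit]". Locale-independent (period decimal, comma sep).

.parse_header <- function(h) {
  m <- regmatches(h, regexec("^(.+) \\[(.+)\\]$", h))[[1]]
  if (length(m) != 3L)
    stop("malformed column header '", h, "'; expected \"name [unit]\"",
         call. = FALSE)
  list(name = m[2], unit = m[3])
}

#' Read a kinematics set from CSV
#'
#' @param path CSV file with a `"time [ms]"` column and one column per
#'   channel, headers formatted `"name [unit]"`.
#' @param meta Optional metadata list attached to the returned set.
#' @return A [kinematics_set()].
#' @export
read_channels <- function(path, meta = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("need a time column plus at least one channel",
                          call. = FALSE)
  heads <- lapply(names(df), .parse_header)
  if (heads[[1]]$name != "time" || heads[[1]]$unit != "ms")
    stop("first column must be \"time [ms]\", got \"", names(df)[1], "\"",
         call. = FALSE)
  t <- df[[1]]
  if (length(t) < 2L) stop("too few rows", call. = FALSE)
  dts <- diff(t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * max(dt, 1)))
    stop("time column is not uniformly sampled", call. = FALSE)
  chans <- lapply(seq_along(df)[-1], function(j) {
    ts_channel(heads[[j]]$name, heads[[j]]$unit, t[1], dt, df[[j]])
  })
  kinematics_set(chans, meta = meta, align = FALSE)
}

#' Write a kinematics set to CSV
#'
#' Channels must share `t0` and `dt`. Round-trips through
#' [read_channels()] to within 1e-9.
#'
#' @param set A [kinematics_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channels <- function(set, path) {
  stopifnot(inherits(set, "kinematics_set"))
  chs <- set$channels
  t0 <- vapply(chs, `[[`, 0, "t0"); dt <- vapply(chs, `[[`, 0, "dt")
  ns <- vapply(chs, function(c) length(c$values), 0L)
  if (length(unique(round(t0, 9))) > 1L || length(unique(round(dt, 12))) > 1L ||
      length(unique(ns)) > 1L)
    stop("channels must share t0, dt and length; call kinematics_set(align = TRUE)",
         call. = FALSE)
  df <- data.frame(time = channel_times(chs[[1]]))
  names(df) <- "time [ms]"
  for (ch in chs) df[[paste0(ch$name, " [", ch$unit, "]")]] <- ch$values
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
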