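# CORA-style objective rating: a corridor score (deviation relative to
# reference-derived inner/outer corridors) and a cross-correlation score
# (shape, size, phase), combined by fixed weights, plus the hierarchical
# aggregation schemes used to summarize whole evaluations.

#' CORA rating settings
#'
#' @param inner_frac Inner corridor half-width as a fraction of the
#'   reference peak (default 0.05).
#' @param outer_frac Outer corridor half-width fraction (default 0.50).
#' @param weight_corridor,weight_correlation Top-level weights (default
#'   0.5 / 0.5; normalized to sum 1).
#' @param weight_shape,weight_size,weight_phase Sub-weights of the
#'   correlation method (defaults 0.5 / 0.25 / 0.25; normalized).
#' @param max_phase_shift_frac Maximum admissible phase shift as a
#'   fraction of the evaluation interval (default 0.20).
#' @param t_a,t_b Evaluation interval in ms (default 0 to 300, the event
#'   window after impact onset).
#' @return An object of class `cora_settings`.
#' @export
cora_settings <- function(inner_frac = 0.05, outer_frac = 0.50,
                          weight_corridor = 0.5, weight_correlation = 0.5,
                          weight_shape = 0.5, weight_size = 0.25,
                          weight_phase = 0.25,
                          max_phase_shift_frac = 0.20,
                          t_a = 0, t_b = 300) {
  stopifnot(inner_frac > 0, inner_frac <= 1, outer_frac > 0, outer_frac <= 1,
            inner_frac < outer_frac,
            weight_corridor >= 0, weight_correlation >= 0,
            weight_corridor + weight_correlation > 0,
            weight_shape >= 0, weight_size >= 0, weight_phase >= 0,
            weight_shape + weight_size + weight_phase > 0,
            max_phase_shift_frac > 0, max_phase_shift_frac <= 1,
            t_b > t_a)
  wtot <- weight_corridor + weight_correlation
  wsub <- weight_shape + weight_size + weight_phase
  structure(list(inner_frac = inner_frac, outer_frac = outer_frac,
                 weight_corridor = weight_corridor / wtot,
                 weight_correlation = weight_correlation / wtot,
                 weight_shape = weight_shape / wsub,
                 weight_size = weight_size / wsub,
                 weight_phase = weight_phase / wsub,
                 max_phase_shift_frac = max_phase_shift_frac,
                 t_a = t_a, t_b = t_b),
            class = "cora_settings")
}

# Align a reference/test channel pair onto a common grid over the
# evaluation interval. Accepts ts_channel objects or plain numeric
# vectors of equal length (taken as already aligned over [t_a, t_b]).
.align_pair <- function(ref, test, settings) {
  if (is.numeric(ref) && is.numeric(test)) {
    if (length(ref) != length(test))
      stop("numeric ref/test must have equal length", call. = FALSE)
    return(list(ref = as.numeric(ref), test = as.numeric(test)))
  }
  stopifnot(inherits(ref, "ts_channel"), inherits(test, "ts_channel"))
  dt <- max(ref$dt, test$dt)
  t0 <- max(settings$t_a, ref$t0, test$t0)
  tend <- min(settings$t_b,
              ref$t0 + (length(ref$values) - 1) * ref$dt,
              test$t0 + (length(test$values) - 1) * test$dt)
  if (tend - t0 <= dt)
    stop("channels '", ref$name, "' have no overlap with the evaluation ",
         "interval [", settings$t_a, ", ", settings$t_b, "] ms", call. = FALSE)
  tg <- seq(t0, tend, by = dt)
  list(ref = stats::approx(channel_times(ref), ref$values, tg, rule = 2)$y,
       test = stats::approx(channel_times(test), test$values, tg, rule = 2)$y)
}

#' Corridor rating
#'
#' Per-sample score: 1 inside the inner corridor, 0 outside the outer
#' corridor, linear in between; corridor half-widths are
#' `inner_frac * Y` and `outer_frac * Y` with `Y = max |ref|` over the
#' evaluation interval. The channel score is the mean over samples.
#'
#' @param ref,test Reference and test channels ([ts_channel()] or aligned
#'   numeric vectors).
#' @param settings A [cora_settings()].
#' @return Score in \[0, 1\].
#' @export
corridor_rating <- function(ref, test, settings = cora_settings()) {
  p <- .align_pair(ref, test, settings)
  Y <- max(abs(p$ref))
  if (Y == 0)
    stop("reference is identically zero on the evaluation interval; ",
         "corridor undefined (widen the interval or skip the channel)",
         call. = FALSE)
  d_in <- settings$inner_frac * Y
  d_out <- settings$outer_frac * Y
  dev <- abs(p$test - p$ref)
  s <- ifelse(dev <= d_in, 1,
              ifelse(dev >= d_out, 0, (d_out - dev) / (d_out - d_in)))
  mean(s)
}

#' Cross-correlation rating (shape, size, phase)
#'
#' The test signal is shifted over an admissible window (up to
#' `max_phase_shift_frac` of the interval); the shift maximizing the
#' normalized cross-correlation defines the phase score (1 at zero shift,
#' 0 at the maximum shift, linear). Shape is the normalized
#' cross-correlation at the best shift, floored at 0; size is the ratio
#' of the squared-signal integrals (smaller over larger) after shifting.
#'
#' @inheritParams corridor_rating
#' @return Named vector `c(shape, size, phase)`, each in \[0, 1\].
#' @export
correlation_rating <- function(ref, test, settings = cora_settings()) {
  p <- .align_pair(ref, test, settings)
  n <- length(p$ref)
  if (max(abs(p$ref)) == 0)
    stop("reference is identically zero on the evaluation interval",
         call. = FALSE)
  M <- max(1L, round(settings$max_phase_shift_frac * n))
  rho <- function(m) {
    # positive m: test delayed by m samples relative to ref
    i_ref <- if (m >= 0) seq_len(n - m) else seq(1 - m, n)
    i_test <- i_ref + m
    r <- p$ref[i_ref]; s <- p$test[i_test]
    den <- sqrt(sum(r^2) * sum(s^2))
    if (den == 0) 0 else sum(r * s) / den
  }
  shifts <- (-M):M
  cors <- vapply(shifts, rho, 0)
  best <- which.max(cors)
  m_star <- shifts[best]
  # parabolic sub-sample refinement of the correlation peak keeps the
  # phase and shape scores continuous in small signal changes
  m_hat <- m_star
  rho_hat <- cors[best]
  if (best > 1 && best < length(cors)) {
    y1 <- cors[best - 1]; y2 <- cors[best]; y3 <- cors[best + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      d <- 0.5 * (y1 - y3) / denom
      if (abs(d) <= 0.5) {
        m_hat <- m_star + d
        rho_hat <- y2 - 0.25 * (y1 - y3) * d
      }
    }
  }
  phase <- max(0, 1 - abs(m_hat) / M)
  shape <- min(1, max(0, rho_hat))
  i_ref <- if (m_star >= 0) seq_len(n - m_star) else seq(1 - m_star, n)
  i_test <- i_ref + m_star
  sr <- sum(p$ref[i_ref]^2); st <- sum(p$test[i_test]^2)
  size <- if (max(sr, st) == 0) 1 else min(sr, st) / max(sr, st)
  c(shape = shape, size = size, phase = phase)
}

#' Combined CORA score for one channel pair
#'
#' `combined = w_corridor * corridor +
#'  w_correlation * (w_shape*shape + w_size*size + w_phase*phase)`.
#'
#' @inheritParams corridor_rating
#' @param name Channel name recorded in the result.
#' @return An object of class `cora_score` with fields `channel`,
#'   `corridor`, `shape`, `size`, `phase`, `combined`.
#' @export
cora_score <- function(ref, test, settings = cora_settings(), name = NULL) {
  if (is.null(name))
    name <- if (inherits(ref, "ts_channel")) ref$name else "channel"
  corr <- corridor_rating(ref, test, settings)
  cc <- correlation_rating(ref, test, settings)
  combined <- settings$weight_corridor * corr +
    settings$weight_correlation *
    (settings$weight_shape * cc[["shape"]] +
       settings$weight_size * cc[["size"]] +
       settings$weight_phase * cc[["phase"]])
  structure(list(channel = name, corridor = corr, shape = cc[["shape"]],
                 size = cc[["size"]], phase = cc[["phase"]],
                 combined = combined),
            class = "cora_score")
}

#' @export
print.cora_score <- function(x, ...) {
  cat(sprintf("<cora_score> %s: combined %.3f (corridor %.3f, shape %.3f, size %.3f, phase %.3f)\n",
              x$channel, x$combined, x$corridor, x$shape, x$size, x$phase))
  invisible(x)
}

#' Rate all shared rating channels of two kinematics sets
#'
#' @param ref,test [kinematics_set()] objects.
#' @param settings A [cora_settings()].
#' @param channels Channel names to rate (default: the ten head-neck
#'   rating channels).
#' @return Named numeric vector of combined scores.
#' @export
rate_channels <- function(ref, test, settings = cora_settings(),
                          channels = rating_channel_names()) {
  miss_r <- setdiff(channels, names(ref$channels))
  miss_t <- setdiff(channels, names(test$channels))
  if (length(miss_r) || length(miss_t))
    stop("missing channels - reference: ",
         paste(miss_r, collapse = ", "), "; test: ",
         paste(miss_t, collapse = ", "), call. = FALSE)
  vapply(channels, function(nm)
    cora_score(ref$channels[[nm]], test$channels[[nm]], settings)$combined,
    0)
}

#' Round half away from zero
#'
#' The rounding convention used when reporting scores to 3 decimals.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Hierarchical score aggregation
#'
#' Aggregates per-channel combined scores into group averages and a total
#' average, following one of three schemes:
#' \describe{
#'   \item{head_neck}{head group = mean(HCG-x, HCG-z, HCG-ry); cervical
#'     group = mean(C1-ry ... C7-ry); total = mean of the two groups.}
#'   \item{injury_input}{three-severity composite: cervical group =
#'     mean(`C1-ryv@5.8` ... `C7-ryv@5.8`); 5.8 km/h average =
#'     mean(`HCG-ax@5.8`, cervical group); total = mean(5.8 km/h average,
#'     `HCG-ax@8.1`, `HCG-ax@10.0`).}
#'   \item{full_body}{cervical group = mean(`C1-ryv` ... `C7-ryv`);
#'     total = mean(`HCG-ax`, cervical group, `T1-ax`).}
#' }
#' Group means are computed at full precision; [round_half_away()] to 3
#' decimals is applied only when printing.
#'
#' @param per_channel Named numeric vector of per-channel combined scores.
#' @param scheme Aggregation scheme.
#' @return An object of class `score_table` with fields `scheme`,
#'   `channels`, `groups` (named numeric) and `total`.
#' @export
aggregate_scores <- function(per_channel,
                             scheme = c("head_neck", "injury_input",
                                        "full_body")) {
  scheme <- match.arg(scheme)
  need <- switch(scheme,
    head_neck = rating_channel_names(),
    injury_input = c("HCG-ax@5.8", paste0("C", 1:7, "-ryv@5.8"),
                     "HCG-ax@8.1", "HCG-ax@10.0"),
    full_body = c("HCG-ax", paste0("C", 1:7, "-ryv"), "T1-ax"))
  miss <- setdiff(need, names(per_channel))
  if (length(miss))
    stop("scheme '", scheme, "' requires missing channels: ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- per_channel[need]
  if (scheme == "head_neck") {
    groups <- c("Average HCG" = mean(x[1:3]),
                "Average Cervical Spine" = mean(x[4:10]))
    total <- mean(groups)
  } else if (scheme == "injury_input") {
    cerv <- mean(x[paste0("C", 1:7, "-ryv@5.8")])
    avg58 <- mean(c(x[["HCG-ax@5.8"]], cerv))
    groups <- c("Average Cervical Spine (5.8 km/h)" = cerv,
                "Average (5.8 km/h)" = avg58)
    total <- mean(c(avg58, x[["HCG-ax@8.1"]], x[["HCG-ax@10.0"]]))
  } else {
    cerv <- mean(x[paste0("C", 1:7, "-ryv")])
    groups <- c("Average Cervical Spine" = cerv)
    total <- mean(c(x[["HCG-ax"]], cerv, x[["T1-ax"]]))
  }
  structure(list(scheme = scheme, channels = x, groups = groups,
                 total = total),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> scheme: %s\n", x$scheme))
  for (nm in names(x$channels))
    cat(sprintf("  %-28s %.3f\n", nm, round_half_away(x$channels[[nm]])))
  for (nm in names(x$groups))
    cat(sprintf("  %-28s %.3f\n", nm, round_half_away(x$groups[[nm]])))
  cat(sprintf("  %-28s %.3f\n", "Total Average", round_half_away(x$total)))
  invisible(x)
}
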