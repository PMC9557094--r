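test_that("unit conversions round-trip within 1e-12", {
  for (pair in list(c("mm", "m"), c("deg", "rad"), c("mm/ms", "km/h"),
                    c("m/s^2", "g"), c("mm/ms^2", "m/s^2"))) {
    ch <- ts_channel("x", pair[1], 0, 1, c(1.234, -5.678, 0.1))
    back <- convert_channel(convert_channel(ch, pair[2]), pair[1])
    expect_equal(back$values, ch$values, tolerance = 1e-12)
  }
  ch <- ts_channel("x", "mm", 0, 1, 1:3)
  expect_error(convert_channel(ch, "deg"), "incompatible")
  expect_error(ts_channel("x", "furlong", 0, 1, 1:3), "unknown unit")
})

test_that("channel construction enforces its invariants", {
  expect_error(ts_channel("x", "mm", 0, -1, 1:3), "positive")
  expect_error(ts_channel("x", "mm", 0, 1, 5), "at least 2")
  expect_error(ts_channel("x", "mm", 0, 1, c(1, NA, 3)), "non-finite")
})

test_that("resample interpolates linearly and preserves endpoints", {
  const <- ts_channel("c", "mm", 0, 1, rep(5, 11))
  expect_equal(resample(const, 0.3)$values,
               rep(5, length(resample(const, 0.3)$values)))
  ch <- ts_channel("r", "mm", 0, 1, 2 * (0:10))
  expect_identical(resample(ch, 1)$values, ch$values)
  half <- resample(ch, 0.5)
  expect_equal(half$values, 2 * seq(0, 10, by = 0.5))
  expect_equal(half$values[length(half$values)], 20)  # endpoint preserved
  expect_error(resample(ch, 100), "support")
})

test_that("differentiate: constants, ramps, and the sine oracle", {
  expect_equal(differentiate(ts_channel("c", "mm", 0, 1, rep(3, 9)))$values,
               rep(0, 9))
  d <- differentiate(ts_channel("r", "deg", 0, 0.5, 4 * seq(0, 5, by = 0.5)))
  expect_equal(d$unit, "deg/ms")
  expect_equal(d$values[2:10], rep(4, 9))          # interior exact
  # sin(w t) -> w cos(w t) to O(dt^2) at dt = 0.1 ms
  w <- 0.05
  t <- seq(0, 200, by = 0.1)
  d <- differentiate(ts_channel("s", "rad", 0, 0.1, sin(w * t)))
  interior <- 2:(length(t) - 1)
  expect_equal(d$values[interior], w * cos(w * t[interior]),
               tolerance = 1e-3)
  expect_error(differentiate(ts_channel("n", "m^2/s^2", 0, 1, 1:5)),
               "no derivative unit")
})

test_that("integrate_channel: closed forms and the round-trip property", {
  z <- integrate_channel(ts_channel("z", "mm/ms", 0, 1, rep(0, 11)))
  expect_equal(z$values, rep(0, 11))
  a <- integrate_channel(ts_channel("a", "mm/ms^2", 0, 0.5,
                                    rep(2, 21)), initial = 0)
  expect_equal(a$values[21], 2 * 10)               # a*T
  expect_equal(a$unit, "mm/ms")
  # differentiate(integrate(x)) reproduces a smooth x on the interior
  t <- seq(0, 250, by = 0.1)
  x <- (1 - cos(2 * pi * t / 250)) / 2
  ch <- ts_channel("h", "mm/ms", 0, 0.1, x)
  rt <- differentiate(integrate_channel(ch))
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(rt$values[interior] - x[interior])), 1e-6)
})

test_that("CFC filter: DC fidelity, attenuation, Nyquist guard", {
  const <- ts_channel("c", "m/s^2", 0, 1, rep(3.3, 200))
  f1 <- cfc_filter(const, 60)
  expect_equal(f1$values, rep(3.3, 200), tolerance = 1e-9)
  # repeated filtering of a constant stays the constant (DC idempotence)
  f3 <- cfc_filter(cfc_filter(f1, 60), 60)
  expect_equal(f3$values, rep(3.3, 200), tolerance = 1e-9)
  zero <- cfc_filter(ts_channel("z", "g", 0, 0.5, rep(0, 100)), 180)
  expect_equal(zero$values, rep(0, 100))
  # 1 kHz sine through CFC60 (cutoff ~100 Hz): analytic two-pass
  # Butterworth gain 1/(1+(f/fc)^4) predicts attenuation far beyond 20x
  t <- seq(0, 200, by = 0.1)
  hf <- ts_channel("s", "m/s^2", 0, 0.1, sin(2 * pi * 1.0 * t))  # 1 kHz
  out <- cfc_filter(hf, 60)
  mid <- t > 50 & t < 150
  expect_lt(max(abs(out$values[mid])), 1 / 20)
  expect_error(cfc_filter(ts_channel("x", "g", 0, 1, rep(1, 50)), 1000),
               "too low")
})

test_that("channel CSV round-trips losslessly and rejects bad input", {
  set <- kinematics_set(list(
    ts_channel("C3-ry", "deg", -10, 0.5, sin(seq(0, 3, length.out = 41))),
    ts_channel("HCG-x", "mm", -10, 0.5, cumsum(runif(41)))),
    meta = list(), align = FALSE)
  path <- tempfile(fileext = ".csv")
  write_channels(set, path)
  back <- read_channels(path)
  expect_equal(names(back$channels), c("C3-ry", "HCG-x"))
  expect_equal(back$channels[["C3-ry"]]$unit, "deg")
  expect_equal(back$channels[["C3-ry"]]$t0, -10)
  expect_equal(back$channels[["C3-ry"]]$values, set$channels[["C3-ry"]]$values,
               tolerance = 1e-9)
  expect_equal(back$channels[["HCG-x"]]$values, set$channels[["HCG-x"]]$values,
               tolerance = 1e-9)
  # missing time column
  bad <- tempfile(fileext = ".csv")
  writeLines(c("\"C3-ry [deg]\",\"HCG-x [mm]\"", "1,2", "3,4"), bad)
  expect_error(read_channels(bad), "time")
  # malformed header
  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("\"time [ms]\",\"C3-ry\"", "0,1", "1,2"), bad2)
  expect_error(read_channels(bad2), "malformed|unknown")
  # unknown unit
  bad3 <- tempfile(fileext = ".csv")
  writeLines(c("\"time [ms]\",\"C3-ry [cubit]\"", "0,1", "1,2"), bad3)
  expect_error(read_channels(bad3), "unknown unit")
})

test_that("kinematics sets align channels and report rateability", {
  chans <- c(lapply(rating_channel_names(), function(nm)
    ts_channel(nm, if (grepl("ry", nm)) "deg" else "mm", 0, 1, sin(0:100))))
  set <- kinematics_set(chans, align = FALSE)
  expect_true(is_rateable(set))
  expect_length(missing_rating_channels(set), 0)
  part <- kinematics_set(chans[1:4], align = FALSE)
  expect_false(is_rateable(part))
  expect_true("C7-ry" %in% missing_rating_channels(part))
  # alignment onto the coarsest common grid
  mix <- kinematics_set(list(
    ts_channel("a", "mm", 0, 1, 0:100),
    ts_channel("b", "mm", -5, 2, seq(0, 210, by = 2))), align = TRUE)
  expect_equal(mix$channels[["a"]]$dt, mix$channels[["b"]]$dt)
  expect_equal(mix$channels[["a"]]$t0, mix$channels[["b"]]$t0)
})
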