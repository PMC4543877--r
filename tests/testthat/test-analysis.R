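test_that("identical traces give a unit peak at zero lag in every window", {
  set.seed(61)
  x <- sin(2 * pi * 1.5 * (0:999) / 50) + rnorm(1000, 0, 0.2)
  cg <- sliding_crosscorr(x, x)
  i0 <- which(cg$lags == 0)
  expect_true(all(abs(cg$matrix[i0, ] - 1) < 1e-12))
  expect_equal(which.max(cg$mean), i0)
  expect_true(all(cg$matrix >= -1 & cg$matrix <= 1, na.rm = TRUE))
  expect_length(cg$mean, length(cg$lags))
})

test_that("an imposed harmonic phase shift is recovered from the correlogram peak", {
  fs <- 50; f <- 1.5625
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  delta <- 20 * pi / 180
  x <- sin(2 * pi * f * t - delta)     # x lags: y leads by 20 deg
  y <- sin(2 * pi * f * t)
  cg <- sliding_crosscorr(x, y, fs = fs)
  ph <- peak_phase(cg, f)
  expect_equal(as.numeric(ph), 20, tolerance = 2)
  ## lag = -delta / (360 f): about -35.6 ms, refined below the 20 ms grid
  expect_equal(attr(ph, "lag"), -20 / (360 * f), tolerance = 2e-3)
  ## sign symmetry: swapping the two traces flips the sign
  ph2 <- peak_phase(sliding_crosscorr(y, x, fs = fs), f)
  expect_equal(as.numeric(ph2), -20, tolerance = 2)
  ## zero shift: zero phase
  ph0 <- peak_phase(sliding_crosscorr(x, x, fs = fs), f)
  expect_equal(as.numeric(ph0), 0, tolerance = 0.5)
})

test_that("phase recovery holds across the -90..90 degree range", {
  fs <- 50; f <- 1.5625
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  for (shift in c(-90, -45, -10, 10, 45, 90)) {
    y <- sin(2 * pi * f * t + shift * pi / 180)
    x <- sin(2 * pi * f * t)
    ph <- peak_phase(sliding_crosscorr(x, y, fs = fs), f)
    expect_equal(as.numeric(ph), shift, tolerance = 2)
  }
})

test_that("uncorrelated noise leaves no structure in the mean correlogram", {
  set.seed(62)
  x <- rnorm(3000); y <- rnorm(3000)
  cg <- sliding_crosscorr(x, y)
  expect_lt(max(abs(cg$mean)), 0.1)
})

test_that("swapping the inputs mirrors the lag axis of the correlogram matrix", {
  set.seed(63)
  x <- as.numeric(stats::filter(rnorm(800), rep(0.2, 5), sides = 1)); x[is.na(x)] <- 0
  y <- as.numeric(stats::filter(rnorm(800), rep(0.2, 5), sides = 1)); y[is.na(y)] <- 0
  cxy <- sliding_crosscorr(x, y)
  cyx <- sliding_crosscorr(y, x)
  nl <- length(cxy$lags)
  ## corr_xy(l, centre t) = corr_yx(-l, centre t + l) for interior centres
  for (j in c(10, 51, 70)) {
    l <- round(cxy$lags[j] * cxy$fs)
    cols <- seq_len(ncol(cxy$matrix))
    shifted <- cols + l
    ok <- shifted >= 1 & shifted <= ncol(cyx$matrix)
    expect_equal(cxy$matrix[j, cols[ok]],
                 cyx$matrix[nl + 1L - j, shifted[ok]], tolerance = 1e-10)
  }
})

test_that("degenerate correlogram inputs are handled as specified", {
  expect_error(sliding_crosscorr(1:10, 1:10), "shorter")
  expect_error(sliding_crosscorr(1:300, 1:299), "equal length")
  ## a zero-variance stretch produces NA coefficients, excluded from the mean
  x <- c(rep(0, 250), sin(2 * pi * 1.5 * (0:349) / 50))
  y <- sin(2 * pi * 1.5 * (0:599) / 50)
  cg <- sliding_crosscorr(x, y)
  expect_true(anyNA(cg$matrix))
  expect_false(anyNA(cg$mean))
})

test_that("circular statistics match their closed forms", {
  expect_equal(circular_variance(rep(1.3, 50)), 0)
  expect_equal(circular_variance(c(0, pi / 2, pi, 3 * pi / 2)), 1)
  expect_error(circular_variance(numeric(0)), "empty")
  ## wrapped normal: 1 - R = 1 - exp(-sigma^2 / 2), Monte-Carlo oracle
  set.seed(64)
  sigma <- 10 * pi / 180
  ph <- rnorm(1e4, 0, sigma)
  expect_lt(abs(circular_variance(ph) - (1 - exp(-sigma^2 / 2))), 1e-3)
  ## invariance under global rotation
  expect_equal(circular_variance(ph + 2.345), circular_variance(ph),
               tolerance = 1e-12)
  expect_equal(circular_mean(c(-0.1, 0.1)), 0, tolerance = 1e-12)
})

test_that("working range uses interpolated 5th/95th percentiles", {
  wr <- working_range(seq(0, 100, length.out = 10001))
  expect_equal(wr$lower, 5, tolerance = 0.02)
  expect_equal(wr$upper, 95, tolerance = 0.02)
  expect_equal(wr$width, 90, tolerance = 0.04)
  expect_error(working_range(c(1, NA)), "finite")
})

test_that("the amplitude spectrum localizes an exact-bin component", {
  t <- (0:(50 * 5.12 * 4 - 1)) / 50
  sp <- amplitude_spectrum(7 + 5 * sin(2 * pi * 1.5625 * t), fs = 50)
  expect_equal(sp$n[which.max(sp$magnitude)], 8)
  expect_equal(max(sp$magnitude), 5, tolerance = 1e-9)
  expect_equal(dominant_frequency(5 * sin(2 * pi * 1.5625 * t)), 1.5625)
})

test_that("the trajectory shape ratio separates lines, circles and Lissajous figures", {
  u <- seq(0, 2 * pi, length.out = 501)[-501]
  line <- cbind(1, u, 2 * u)
  expect_lt(trajectory_shape(line)$ratio, 1e-8)
  circle <- cbind(1, cos(u), sin(u))       # in the plane orthogonal to x
  expect_equal(trajectory_shape(circle)$ratio, 1, tolerance = 1e-9)
  ## Lissajous pair mapped through the kinematics: ratio grows from 0 with
  ## the phase difference under sine-only drive
  ch <- antenna_chain()
  ratio_at <- function(shift) {
    tt <- seq(0, 12, by = 0.02)
    hs <- -60 + 39 * sin(2 * pi * 1.5 * tt)
    sp <- 22 + 31 * sin(2 * pi * 1.5 * tt + shift * pi / 180)
    tips <- t(vapply(seq_along(tt), function(k)
      forward_kinematics(c(hs_left = hs[k], sp_left = sp[k]), ch)$tip_left,
      numeric(3)))
    trajectory_shape(tips)$ratio
  }
  r <- vapply(c(2, 20, 60), ratio_at, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_gt(r[1], 0); expect_lt(r[3], 1)
  ## at 2 deg the residual width is the kinematic arc curvature only
  expect_lt(r[1], 0.15)
  expect_error(trajectory_shape(line[1:50, ]), "100")
  expect_error(trajectory_shape(matrix(1, 200, 3), center = c(0, 0, 0)),
               "degenerate|identical")
})

test_that("trace-based demodulation recovers an imposed lead", {
  fs <- 50
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- -60 + 39 * sin(2 * pi * 1.5625 * t)
  y <- 22 + 31 * sin(2 * pi * 1.5625 * t + 20 * pi / 180)
  d <- phase_difference_trace(x, y, fs = fs)
  expect_equal(circular_mean(d) * 180 / pi, 20, tolerance = 1)
  expect_lt(circular_variance(d), 0.01)
})
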