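test_that("hopf derivatives reproduce the closed-form fixed points and hand values", {
  p <- osc_params(v = 1.45, mu = 39, C = -60, gamma = 20)
  ## r = mu is the radial fixed point
  d <- hopf_derivatives(list(r = 39, theta = 0.3, c = -60), p)
  expect_equal(unname(d["dr"]), 0)
  expect_equal(unname(d["dc"]), 0)
  ## direct substitution: gamma*(mu^2 - r^2)*r at r = 1
  d1 <- hopf_derivatives(list(r = 1, theta = 0, c = 0), p)
  expect_equal(unname(d1["dr"]), 20 * (39^2 - 1) * 1)
  ## a neighbour sitting exactly at the bias contributes nothing
  nb <- data.frame(phase = 1.0 + pi / 9, weight = 20, bias = pi / 9)
  d2 <- hopf_derivatives(list(r = 39, theta = 1.0, c = -60), p, nb)
  expect_equal(unname(d2["dtheta"]), 2 * pi * 1.45, tolerance = 1e-12)
  ## non-finite state is flagged as a blow-up
  expect_error(hopf_derivatives(list(r = NaN, theta = 0, c = 0), p),
               "blow-up")
  expect_error(hopf_derivatives(list(r = 1, theta = 0, c = 0), p,
                                data.frame(phase = 0, weight = -1, bias = 0)),
               "weights")
})

test_that("an uncoupled oscillator advances its phase at 2*pi*v per unit time", {
  net <- single_osc_network(v = 1, mu = 10)
  st <- step_rk2(list(r = 10, theta = 0, c = 0), net)
  expect_equal(st$theta, 2 * pi * 0.005, tolerance = 1e-12)
  expect_equal(st$r, 10, tolerance = 1e-12)
})

test_that("a symmetric pair locks at its phase bias (analytic fixed point)", {
  net <- pair_network(w = 20, phi = pi / 9)
  res <- simulate_network(net, duration = 10, seed = 4)
  th <- res$theta[nrow(res$theta), ]
  expect_equal(unname(wrap_pi(th[2] - th[1])), pi / 9, tolerance = 1e-6)
  ## opposite bias locks at the opposite difference
  net2 <- pair_network(w = 20, phi = -pi / 3)
  res2 <- simulate_network(net2, duration = 10, seed = 4)
  th2 <- res2$theta[nrow(res2$theta), ]
  expect_equal(unname(wrap_pi(th2[2] - th2[1])), -pi / 3, tolerance = 1e-6)
})

test_that("steady phase differences compose along the chain when frequencies are equal", {
  net <- default_network(stochastic = FALSE, equal_frequencies = TRUE)
  res <- simulate_network(net, duration = 25, transient = 5, seed = 2)
  th <- res$theta[res$time > 15, ]
  bias <- c(0, cumsum(net$edges$phi))   # expected theta_i - theta_1
  for (i in 1:5) for (j in 1:5) {
    expected <- wrap_pi(bias[i] - bias[j])
    got <- circular_mean(th[, i] - th[, j])
    expect_equal(wrap_pi(got - expected), 0, tolerance = 2e-3)
  }
})

test_that("all oscillators entrain to one common frequency (noise off)", {
  net <- default_network(stochastic = FALSE)
  res <- simulate_network(net, duration = 25, transient = 5, seed = 3)
  sel <- res$time > 10
  span <- sum(sel) * res$dt
  f <- apply(res$theta[sel, ], 2, function(th) diff(range(th))) / (2 * pi * span)
  expect_lt(diff(range(f)), 1e-4)
  ## the compromise frequency lies between the neck and antennal rates
  expect_gt(mean(f), 1.25)
  expect_lt(mean(f), 1.45)
})

test_that("radius converges to the amplitude target within 1% after the transient", {
  net <- default_network(stochastic = FALSE)
  res <- simulate_network(net, duration = 2, transient = 0, seed = 1)
  mu <- vapply(net$oscillators, `[[`, numeric(1), "mu")
  late <- res$r[res$time > 1, ]
  for (i in 1:5)
    expect_true(all(abs(late[, i] - mu[i]) < 0.01 * mu[i]))
})

test_that("amplitude resampling has the configured spread, truncation and reproducibility", {
  p <- osc_params(v = 1.45, mu = 39, C = -60, gamma = 20, U = 8, L_sd = 9)
  set.seed(42)
  ups <- replicate(2000, resample_amplitudes(list(), p, "upper")$amp_upper)
  los <- replicate(2000, resample_amplitudes(list(), p, "lower")$amp_lower)
  expect_equal(mean(ups), 39, tolerance = 0.02)
  expect_equal(sd(ups), 8, tolerance = 0.1)
  expect_equal(sd(los), 9, tolerance = 0.1)
  ## truncation at zero
  p0 <- osc_params(v = 1, mu = 1, C = 0, gamma = 20, U = 10)
  set.seed(1)
  draws <- replicate(500, resample_amplitudes(list(), p0, "upper")$amp_upper)
  expect_true(all(draws >= 0))
  expect_gt(mean(draws == 0), 0)   # the truncation actually binds here
  ## U = L = 0 is the deterministic limit
  pd <- osc_params(v = 1, mu = 5, C = 0, gamma = 20)
  expect_equal(resample_amplitudes(list(), pd)$amp_upper, 5)
  expect_equal(resample_amplitudes(list(), pd)$amp_lower, 5)
  ## fixed seed, identical sequence
  set.seed(7); s1 <- replicate(10, resample_amplitudes(list(), p, "upper")$amp_upper)
  set.seed(7); s2 <- replicate(10, resample_amplitudes(list(), p, "upper")$amp_upper)
  expect_identical(s1, s2)
})

test_that("identical seeds give bit-identical trajectories", {
  net <- default_network()
  r1 <- simulate_network(net, duration = 5, seed = 99)
  r2 <- simulate_network(net, duration = 5, seed = 99)
  expect_identical(r1$theta, r2$theta)
  expect_identical(r1$x, r2$x)
  r3 <- simulate_network(net, duration = 5, seed = 100)
  expect_false(identical(r1$theta, r3$theta))
})

test_that("the drive signal combines offset, radius and pattern as specified", {
  p <- osc_params(v = 1.45, mu = 39, C = -60, gamma = 20)
  zero_pat <- fourier_pattern(numeric(8), numeric(8))   # F identically 0
  expect_equal(drive_signal(list(r = 39, theta = 1.2, c = -60), zero_pat, p),
               -60)
  sine <- fourier_pattern(numeric(8), c(numeric(7), 1))  # F = sin(theta)
  expect_equal(drive_signal(list(r = 39, theta = pi / 2, c = -60), sine, p),
               -21, tolerance = 1e-9)
  ## pure sine, noise off: the drive spans 2*mu over a cycle
  th <- seq(0, 2 * pi, length.out = 2001)
  x <- vapply(th, function(t)
    drive_signal(list(r = 39, theta = t, c = -60), sine, p), numeric(1))
  expect_equal(max(x) - min(x), 2 * 39, tolerance = 1e-6)
  ## unnormalized patterns are rejected
  raw <- fit_fourier(sin(2 * pi * 1.5625 * (0:255) / 50), normalize = FALSE)
  expect_error(drive_signal(list(r = 1, theta = 0, c = 0), raw, p),
               "normalized")
})

test_that("the raw radial mode blows up at the standard step and the guard catches it", {
  net <- make_network(list(osc_params(1.45, 39, -60, 20)))
  expect_error(step_rk2(list(r = 1, theta = 0, c = 0), net,
                        radial_mode = "raw"),
               "blow-up")
  ## with a sufficiently small step the raw mode is fine
  st <- list(r = 1, theta = 0, c = -60)
  for (k in 1:2000) st <- step_rk2(st, net, dt = 1e-5, radial_mode = "raw")
  expect_equal(st$r, 39, tolerance = 1e-6)
})

test_that("the radial fixed point of the literal equation is the amplitude target", {
  p <- osc_params(v = 1.45, mu = 39, C = -60, gamma = 20)
  fp <- hopf_fixed_point(p, r0 = 1)
  expect_equal(fp$r, 39, tolerance = 1e-9)
  fp2 <- hopf_fixed_point(p, r0 = 300)   # from far above
  expect_equal(fp2$r, 39, tolerance = 1e-9)
})

test_that("oscillator parameter invariants are enforced", {
  expect_error(osc_params(1, 39, 0, gamma = 0), "positive")
  expect_error(osc_params(1, -1, 0), "non-negative")
  expect_error(osc_params(1, 39, 0, U = -1), "non-negative")
})

test_that("the rhythm-layer CSV export has the documented layout", {
  res <- simulate_network(default_network(), duration = 2, seed = 30)
  path <- tempfile(fileext = ".csv")
  write_network_csv(res, path)
  df <- utils::read.csv(path)
  expect_equal(names(df)[1], "time_s")
  expect_true(all(c("r_HS_left", "theta_wrapped_HS_left", "c_HS_left",
                    "x_HS_left") %in% names(df)))
  expect_equal(nrow(df), length(res$time))
  expect_true(all(abs(df$theta_wrapped_neck) <= pi + 1e-12))
  expect_equal(df$x_SP_left, unname(res$x[, "SP_left"]), tolerance = 1e-9)
  unlink(path)
})
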