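t_grid <- function(fs = 50, T = 5.12) (0:(fs * T - 1)) / fs

test_that("the standard window puts an exact-bin sine entirely into one harmonic", {
  t <- t_grid()
  expect_length(t, 256)                      # 5.12 s at 50 Hz
  p <- fit_fourier(sin(2 * pi * 1.5625 * t))
  expect_equal(p$b[8], 1, tolerance = 1e-9)  # 1.5625 Hz = bin 8 = 8/5.12
  expect_lt(max(abs(p$a)), 1e-9)
  expect_lt(max(abs(p$b[-8])), 1e-9)
  expect_equal(p$n_dom, 8L)
  expect_equal(p$f1, 1 / 5.12)
  ## independent oracle: projection integrals on the sample grid
  b8 <- 2 * mean(sin(2 * pi * 1.5625 * t) * sin(2 * pi * 8 * t / 5.12))
  expect_equal(p$b[8], b8, tolerance = 1e-12)
  ## a constant trace is pure DC
  pc <- fit_fourier(rep(10, 256))
  expect_equal(pc$a0, 10)
  expect_lt(max(sqrt(pc$a^2 + pc$b^2)), 1e-12)
})

test_that("fit_fourier rejects short, non-finite and ill-posed inputs", {
  expect_error(fit_fourier(numeric(100)), "window")
  x <- sin(t_grid()); x[3] <- NA
  expect_error(fit_fourier(x), "non-finite")
  expect_error(fit_fourier(sin(t_grid()), L = 200), "Nyquist")
})

test_that("pattern evaluation follows the Psi = theta/n_dom convention", {
  sine8 <- fourier_pattern(numeric(8), c(numeric(7), 1))
  th <- seq(-10, 10, length.out = 101)
  ## dominant harmonic completes one period per oscillator cycle
  expect_equal(evaluate(sine8, th), sin(th), tolerance = 1e-12)
  ## sine-only pattern vanishes at theta = 0
  expect_equal(evaluate(sine8, 0), 0)
  ## periodicity over the full pattern period (n_dom oscillator cycles)
  set.seed(5)
  p <- fourier_pattern(rnorm(16, 0, 0.2), c(rnorm(7, 0, 0.2), 1, rnorm(8, 0, 0.2)))
  expect_equal(evaluate(p, th), evaluate(p, th + 2 * pi * p$n_dom),
               tolerance = 1e-12)
})

test_that("normalization gives unit peak magnitude over one pattern period", {
  set.seed(11)
  for (k in 1:5) {
    a <- rnorm(16, 0, 0.3); b <- rnorm(16, 0, 0.3)
    b[8] <- 1.5                       # keep the dominant at n = 8
    p <- fourier_pattern(a, b)
    ## independent check: coarse scan for the peak cell, then optimize()
    ## inside it (the scan alone undershoots a smooth peak)
    psi <- seq(0, 2 * pi, length.out = 20001)
    F <- abs(evaluate(p, psi * p$n_dom))
    i <- which.max(F)
    opt <- stats::optimize(
      function(ps) -abs(evaluate(p, ps * p$n_dom)),
      lower = psi[max(1, i - 1)], upper = psi[min(length(psi), i + 1)],
      tol = 1e-13)
    expect_equal(-opt$objective, 1, tolerance = 1e-9)
    expect_lte(max(F), 1 + 1e-9)
  }
})

test_that("reconstruction is lossless within the retained band and matches the truncation oracle beyond it", {
  t <- t_grid()
  set.seed(21)
  ## band-limited input: exact round trip
  a <- rnorm(16); b <- rnorm(16)
  x <- 3 + colSums(a * sin(outer(1:16, 2 * pi * t / 5.12)) +
                   b * cos(outer(1:16, 2 * pi * t / 5.12)))
  p <- fit_fourier(x)
  expect_lt(reconstruction_rmse(x, reconstruct(p)), 1e-9)
  ## white noise: residual equals the discarded high-harmonic content,
  ## via an independent FFT-truncation oracle
  xn <- rnorm(256)
  pn <- fit_fourier(xn)
  rec <- reconstruct(pn)
  z <- fft(xn)
  keep <- c(1:17, 256:(256 - 15))      # DC + harmonics 1..16 (and conjugates)
  z[setdiff(seq_len(256), keep)] <- 0
  oracle <- Re(fft(z, inverse = TRUE)) / 256
  expect_equal(rec, oracle, tolerance = 1e-10)
  expect_equal(reconstruction_rmse(xn, rec),
               sqrt(mean((xn - oracle)^2)), tolerance = 1e-10)
  ## Parseval/orthogonality: residual power + retained power = total power
  expect_equal(mean(xn^2), mean(rec^2) + mean((xn - rec)^2),
               tolerance = 1e-10)
  expect_error(reconstruction_rmse(xn, rec[-1]), "mismatch")
})

test_that("triangular and augmented test waveforms have the documented structure", {
  tri <- make_triangular()
  ## classic triangle-series weights at odd multiples of the dominant
  expect_equal(tri$b[24] / tri$b[8], -1 / 9)
  expect_equal(tri$b[40] / tri$b[8], 1 / 25)
  expect_equal(tri$b[56] / tri$b[8], -1 / 49)
  expect_true(all(tri$a == 0))
  th <- seq(0, 2 * pi * 8, length.out = 4001)
  ## odd symmetry of the sine-only waveform
  expect_equal(evaluate(tri, th), -evaluate(tri, -th), tolerance = 1e-12)
  ## in oscillator phase the stack sits on odd multiples of theta, so
  ## half-wave antisymmetry F(theta + pi) = -F(theta) holds for any phases
  aug <- make_augmented_triangular()
  expect_equal(evaluate(aug, th + pi), -evaluate(aug, th), tolerance = 1e-9)
  ## ...but the added cosines skew the flanks: the triangle is mirror
  ## symmetric about its peak, the augmented waveform is not
  mirror_err <- function(p) {
    F <- evaluate(p, th)
    th0 <- th[which.max(F)]
    u <- seq(0, 2 * pi, length.out = 801)
    max(abs(evaluate(p, th0 + u) - evaluate(p, th0 - u)))
  }
  expect_lt(mirror_err(tri), 1e-9)
  expect_gt(mirror_err(aug), 0.1)
})

test_that("phase alignment is a pure time shift that zeroes the dominant phase", {
  set.seed(31)
  a <- rnorm(16, 0, 0.2); b <- rnorm(16, 0, 0.2)
  a[8] <- 0.8; b[8] <- 0.6
  p <- fourier_pattern(a, b)
  al <- align_phase(p)
  expect_equal(al$a[8], 0, tolerance = 1e-12)
  expect_gt(al$b[8], 0)
  delta <- atan2(p$a[8], p$b[8]) / p$n_dom
  th <- seq(0, 2 * pi * 8, length.out = 1001)
  expect_equal(evaluate(al, th), evaluate(p, th - p$n_dom * delta),
               tolerance = 1e-9)
})

test_that("variant sampling: identity for Mc/Mm, calibrated spread for Mmsd", {
  base <- fourier_pattern(numeric(16), c(numeric(7), 10, 2, numeric(7)))
  expect_identical(sample_variant(pattern_variant("Mc", base)), base)
  expect_identical(sample_variant(pattern_variant("Mm", base)), base)
  expect_error(pattern_variant("Mmsd", base), "SDs")
  ## all-zero SDs reduce Mmsd to the mean pattern
  v0 <- pattern_variant("Mmsd", base, sds = numeric(16))
  s0 <- sample_variant(v0)
  expect_equal(s0$a, base$a, tolerance = 1e-12)
  expect_equal(s0$b, base$b, tolerance = 1e-12)
  ## per-component magnitude SD matches the configured value within 10%
  sds <- c(numeric(7), 1, 0.4, numeric(7))
  v <- pattern_variant("Mmsd", base, sds = sds)
  set.seed(8)
  draws <- replicate(1000, {
    s <- sample_variant(v); sqrt(s$a^2 + s$b^2)
  })
  expect_equal(sd(draws[8, ]), 1, tolerance = 0.1)
  expect_equal(sd(draws[9, ]), 0.4, tolerance = 0.1)
  ## phases are preserved (only magnitudes move)
  s <- sample_variant(v)
  expect_equal(atan2(s$a[9], s$b[9]), atan2(base$a[9], base$b[9]),
               tolerance = 1e-12)
})

test_that("coefficient CSV files round-trip a fitted pattern", {
  tr <- generate_trial(synthetic_trial_spec(duration = 12), seed = 41)
  p <- fit_fourier(tr$data$hs, L = 16)
  path <- tempfile(fileext = ".csv")
  write_coefficients_csv(p, path)
  q <- read_coefficients_csv(path)
  expect_equal(q$a, p$a, tolerance = 1e-9)
  expect_equal(q$b, p$b, tolerance = 1e-9)
  expect_equal(q$a0, p$a0, tolerance = 1e-9)
  expect_equal(q$n_dom, p$n_dom)
  expect_equal(q$M, p$M, tolerance = 1e-9)
  ## malformed files are rejected
  writeLines("n,a_n\n1,2", path)
  expect_error(read_coefficients_csv(path), "columns")
  writeLines("n,a_n,b_n\n0,1,0.5", path)
  expect_error(read_coefficients_csv(path), "b_0")
  unlink(path)
})
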