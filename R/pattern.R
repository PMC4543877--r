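#' Truncated Fourier pattern
#'
#' A pattern-formation network: the first `L` Fourier coefficients of a
#' joint-angle waveform over an analysis window of length `T` seconds
#' (fundamental `f1 = 1/T`), plus a scaling factor `M` that normalizes the
#' peak magnitude of the pattern function to 1 so that the oscillator
#' amplitude `mu` is the half-range of the drive in degrees.
#'
#' The pattern is evaluated as a function of oscillator phase theta through
#' the pattern phase `Psi = theta / n_dom`, where `n_dom` is the dominant
#' harmonic index (`argmax_n |z_n|`, `z_n = a_n + i b_n`): the dominant
#' component then completes exactly one period per oscillator cycle and the
#' full pattern repeats every `n_dom` cycles, matching the length of the
#' analysis window at the natural cycle frequency.
#'
#' The DC term is fitted (`a0`) and used for reconstruction, but excluded
#' from the normalized pattern function: the mean joint angle is carried
#' exclusively by the oscillator offset state.
#'
#' @param a,b cosine and sine coefficient vectors for harmonics `1..L`
#'   (degrees before normalization). `b0` is identically zero and not
#'   stored.
#' @param a0 DC coefficient (mean of the fitted window, degrees).
#' @param T analysis window length (s). Default 5.12.
#' @param n_dom dominant harmonic index; computed from the coefficients if
#'   `NULL`.
#' @param normalize logical; apply peak normalization (required before the
#'   pattern can drive an oscillator).
#' @return Object of class `fourier_pattern` with fields `a`, `b`, `a0`,
#'   `L`, `T`, `f1`, `n_dom`, `M`, `normalized`.
#' @export
fourier_pattern <- function(a, b, a0 = 0, T = 5.12, n_dom = NULL,
                            normalize = TRUE) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  if (any(!is.finite(c(a, b, a0)))) stop("non-finite coefficients", call. = FALSE)
  L <- length(a)
  mag <- sqrt(a^2 + b^2)
  if (all(mag == 0)) {
    n_dom <- n_dom %||% 1L
    p <- structure(list(a = a, b = b, a0 = a0, L = L, T = T, f1 = 1 / T,
                        n_dom = as.integer(n_dom), M = 1, normalized = TRUE),
                   class = "fourier_pattern")
    return(p)
  }
  n_dom <- as.integer(n_dom %||% which.max(mag))
  p <- structure(list(a = a, b = b, a0 = a0, L = L, T = T, f1 = 1 / T,
                      n_dom = n_dom, M = 1, normalized = FALSE),
                 class = "fourier_pattern")
  if (normalize) p <- normalize_pattern(p)
  p
}

#' @export
print.fourier_pattern <- function(x, ...) {
  cat(sprintf(
    "Fourier pattern: L = %d, T = %g s (f1 = %.4f Hz), dominant n = %d (%.4f Hz), M = %.4g%s\n",
    x$L, x$T, x$f1, x$n_dom, x$n_dom * x$f1, x$M,
    if (x$normalized) ", normalized" else ""))
  invisible(x)
}

## Peak of |sum a_n cos(n psi) + b_n sin(n psi)| over one pattern period:
## every near-maximal local maximum of a fine grid is polished by Newton
## iteration on F'(psi) = 0 (trig polynomials are smooth, so a handful of
## steps reaches machine precision), and the best polished value wins.
pattern_peak <- function(a, b) {
  n <- seq_along(a)
  f0 <- function(p) sum(a * cos(n * p) + b * sin(n * p))
  f1 <- function(p) sum(-n * a * sin(n * p) + n * b * cos(n * p))
  f2 <- function(p) sum(-n^2 * a * cos(n * p) - n^2 * b * sin(n * p))
  m <- 16384L
  grid <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  arg <- outer(grid, n)
  vals <- abs(drop(cos(arg) %*% a + sin(arg) %*% b))
  nxt <- c(vals[-1], vals[1]); prv <- c(vals[m], vals[-m])
  cand <- which(vals >= prv & vals >= nxt & vals >= 0.99 * max(vals))
  h <- 2 * pi / m
  best <- max(vals)
  for (i in cand) {
    p <- grid[i]
    for (it in 1:12) {
      d2 <- f2(p)
      if (d2 == 0) break
      step <- f1(p) / d2
      if (!is.finite(step) || abs(step) > h) break
      p <- p - step
      if (abs(step) < 1e-15) break
    }
    best <- max(best, abs(f0(p)))
  }
  best
}

normalize_pattern <- function(pattern) {
  peak <- pattern_peak(pattern$a, pattern$b)
  if (peak == 0) stop("cannot normalize an all-zero pattern", call. = FALSE)
  pattern$M <- 1 / peak
  pattern$normalized <- TRUE
  pattern
}

#' Evaluate a pattern at oscillator phase theta
#'
#' `F(theta) = M * sum_n [a_n cos(n Psi) + b_n sin(n Psi)]` with pattern
#' phase `Psi = theta / n_dom`. Periodic in theta with period
#' `2 * pi * n_dom`. For a normalized pattern the result lies in `[-1, 1]`.
#'
#' @param pattern a [fourier_pattern()].
#' @param theta oscillator phase (radians; vectorized).
#' @return Numeric vector of pattern values (dimensionless).
#' @export
evaluate <- function(pattern, theta) {
  psi <- theta / pattern$n_dom
  n <- seq_len(pattern$L)
  if (length(psi) == 1L)
    return(pattern$M * sum(pattern$a * cos(n * psi) + pattern$b * sin(n * psi)))
  arg <- outer(psi, n)
  drop(pattern$M * (cos(arg) %*% pattern$a + sin(arg) %*% pattern$b))
}

#' Fit a Fourier pattern to a sampled joint-angle trace
#'
#' Takes the first `fs * T` samples of the trace (default 256 samples: a
#' 5.12 s window at 50 Hz), computes the FFT, and keeps the DC term plus
#' the first `L` harmonics. `a_n = 2 Re(z_n)/N`, `b_n = -2 Im(z_n)/N`, so a
#' window equal to `sin(2 pi n t / T)` yields `b_n = 1`. The spectral bin
#' spacing is `1/T` Hz; with the default window the dominant antennal
#' component near 1.56 Hz falls exactly in bin 8.
#'
#' @param series numeric vector, joint angle (degrees) sampled at `fs`.
#' @param fs sampling rate (Hz). Default 50.
#' @param T window length (s); `fs * T` must be a whole number of samples.
#' @param L number of harmonics retained. Default 16.
#' @param normalize passed to [fourier_pattern()].
#' @return A [fourier_pattern()] (normalized by default; the raw
#'   coefficients are retained for [reconstruct()]).
#' @export
fit_fourier <- function(series, fs = 50, T = 5.12, L = 16, normalize = TRUE) {
  N <- fs * T
  if (abs(N - round(N)) > 1e-9)
    stop("fs * T must be an integer number of samples", call. = FALSE)
  N <- as.integer(round(N))
  if (length(series) < N)
    stop(sprintf("series shorter than the %d-sample analysis window", N),
         call. = FALSE)
  if (L >= N / 2) stop("L must be below the Nyquist index", call. = FALSE)
  x <- as.numeric(series[seq_len(N)])
  if (any(!is.finite(x))) stop("non-finite samples in series", call. = FALSE)
  z <- stats::fft(x) / N
  a0 <- Re(z[1L])
  n <- seq_len(L)
  a <- 2 * Re(z[n + 1L])
  b <- -2 * Im(z[n + 1L])
  fourier_pattern(a, b, a0 = a0, T = T, normalize = normalize)
}

#' Reconstruct the analysis window from a fitted pattern
#'
#' Inverse evaluation of the raw (unnormalized) coefficients on the uniform
#' sample grid of the fitting window: `a0 + sum_n a_n cos(2 pi n t / T) +
#' b_n sin(2 pi n t / T)`.
#'
#' @param pattern a [fourier_pattern()] from [fit_fourier()].
#' @param fs sampling rate (Hz).
#' @param T window length (s); defaults to the pattern's window.
#' @return Numeric vector of length `fs * T` (degrees).
#' @export
reconstruct <- function(pattern, fs = 50, T = pattern$T) {
  N <- as.integer(round(fs * T))
  t <- (seq_len(N) - 1L) / fs
  n <- seq_len(pattern$L)
  arg <- outer(2 * pi * t / T, n)
  drop(pattern$a0 + cos(arg) %*% pattern$a + sin(arg) %*% pattern$b)
}

#' Root-mean-squared reconstruction error
#'
#' @param original,reconstructed equal-length numeric vectors (degrees).
#' @return RMSE in degrees.
#' @export
reconstruction_rmse <- function(original, reconstructed) {
  if (length(original) != length(reconstructed))
    stop("length mismatch between original and reconstruction", call. = FALSE)
  sqrt(mean((original - reconstructed)^2))
}

#' Align a pattern's phase spectrum to a zero-phase dominant sine
#'
#' Applies the pure time shift that turns the dominant harmonic into
#' `sin(n_dom * Psi)` (zero cosine part, positive sine part). Every other
#' harmonic is rotated proportionally to its index, so the waveform shape
#' is unchanged; only the time origin moves. Fitted patterns are aligned
#' before driving the oscillators so that the inter-joint phase lead is
#' carried once, by the oscillator phase bias, and not a second time by the
#' absolute phases of the fitting window.
#'
#' @param pattern a [fourier_pattern()].
#' @return The aligned pattern (same class, renormalized scaling retained).
#' @export
align_phase <- function(pattern) {
  nd <- pattern$n_dom
  R <- sqrt(pattern$a^2 + pattern$b^2)
  if (R[nd] == 0) return(pattern)
  psi <- atan2(pattern$a, pattern$b)   # a cos + b sin = R sin(n Psi + psi)
  delta <- psi[nd] / nd
  n <- seq_along(R)
  psi_new <- psi - n * delta
  pattern$a <- R * sin(psi_new)
  pattern$b <- R * cos(psi_new)
  pattern
}

#' Triangular and augmented-triangular test patterns
#'
#' `make_triangular()` builds the symmetric triangle-wave pattern from the
#' first `n_components` odd harmonics of the dominant frequency: sine terms
#' at `n = (2k+1) * n_dom` with weights `(-1)^k / (2k+1)^2` (weight 1 for
#' the fundamental, -1/9 for the third harmonic, ...), cosines all zero, so
#' the waveform has a single phase in its phase spectrum and odd symmetry
#' `F(-Psi) = -F(Psi)`.
#'
#' `make_augmented_triangular()` duplicates the same magnitudes into the
#' cosine terms, giving the waveform a second phase in its phase spectrum.
#' Because all components sit on odd harmonics, the half-wave antisymmetry
#' `F(Psi + pi) = -F(Psi)` is retained for any phase choice; what the added
#' cosines break is the time-reversal symmetry: the triangular waveform is
#' an even function about each of its peaks, while the augmented waveform
#' is skewed, with rising and falling flanks of different shape.
#'
#' @param n_components number of odd harmonics (>= 1). Default 4.
#' @param n_dom dominant harmonic index of the hosting window. Default 8.
#' @param T analysis window (s).
#' @return A normalized [fourier_pattern()].
#' @export
make_triangular <- function(n_components = 4, n_dom = 8, T = 5.12) {
  stopifnot(n_components >= 1)
  k <- seq_len(n_components) - 1L
  idx <- (2L * k + 1L) * n_dom
  L <- max(idx)
  a <- numeric(L); b <- numeric(L)
  b[idx] <- (-1)^k / (2 * k + 1)^2
  fourier_pattern(a, b, T = T, n_dom = n_dom)
}

#' @rdname make_triangular
#' @export
make_augmented_triangular <- function(n_components = 4, n_dom = 8, T = 5.12) {
  p <- make_triangular(n_components, n_dom, T)
  k <- seq_len(n_components) - 1L
  idx <- (2L * k + 1L) * n_dom
  raw_b <- (-1)^k / (2 * k + 1)^2
  a <- numeric(p$L); b <- numeric(p$L)
  b[idx] <- raw_b
  a[idx] <- raw_b
  fourier_pattern(a, b, T = p$T, n_dom = n_dom)
}

#' Read / write Fourier coefficient files
#'
#' CSV exchange format for pattern coefficients: columns `n` (harmonic
#' index, 0 for the DC term), `a_n` and `b_n` (degrees, unnormalized;
#' `b_0` is identically zero and must be 0 if present). Reading returns a
#' normalized [fourier_pattern()].
#'
#' @param pattern a [fourier_pattern()] (for writing).
#' @param path CSV file.
#' @param T analysis window length (s) to attach on reading.
#' @return `read_coefficients_csv()`: a [fourier_pattern()];
#'   `write_coefficients_csv()`: the path, invisibly.
#' @export
write_coefficients_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "fourier_pattern"))
  df <- data.frame(n = 0:pattern$L,
                   a_n = c(pattern$a0, pattern$a),
                   b_n = c(0, pattern$b))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients_csv
#' @export
read_coefficients_csv <- function(path, T = 5.12) {
  df <- utils::read.csv(path)
  need <- c("n", "a_n", "b_n")
  if (!all(need %in% names(df)))
    stop("coefficient file needs columns n, a_n, b_n", call. = FALSE)
  df <- df[order(df$n), ]
  if (!identical(as.integer(df$n), seq.int(min(df$n), max(df$n))) ||
      min(df$n) > 1L)
    stop("harmonic indices must be consecutive from 0 or 1", call. = FALSE)
  a0 <- 0
  if (df$n[1] == 0L) {
    if (df$b_n[1] != 0) stop("b_0 must be zero", call. = FALSE)
    a0 <- df$a_n[1]
    df <- df[-1, ]
  }
  fourier_pattern(df$a_n, df$b_n, a0 = a0, T = T)
}

#' Pattern variant: single-trial, population-mean, or mean-plus-SD
#'
#' Describes one of the three pattern-formation networks compared in the
#' experiments: `Mc` (the representative single-trial spectrum), `Mm` (the
#' population-mean amplitude spectrum with the representative trial's phase
#' spectrum) and `Mmsd` (as `Mm`, but with each component magnitude
#' perturbed by a zero-mean normal draw with the population standard
#' deviation, truncated at zero; phases preserved; renormalized).
#'
#' @param kind `"Mc"`, `"Mm"` or `"Mmsd"`.
#' @param base a [fourier_pattern()]: the fixed pattern for `Mc`/`Mm`, the
#'   mean pattern for `Mmsd`.
#' @param sds per-harmonic magnitude standard deviations (length `base$L`);
#'   required for `Mmsd`.
#' @param redraw when the magnitudes are resampled during a simulation:
#'   `"cycle"` (each completed oscillator cycle; default) or `"trial"`
#'   (once at trial start).
#' @return Object of class `pattern_variant`.
#' @export
pattern_variant <- function(kind = c("Mc", "Mm", "Mmsd"), base, sds = NULL,
                            redraw = c("cycle", "trial")) {
  kind <- match.arg(kind)
  redraw <- match.arg(redraw)
  stopifnot(inherits(base, "fourier_pattern"))
  if (kind == "Mmsd") {
    if (is.null(sds))
      stop("Mmsd requires per-component magnitude SDs", call. = FALSE)
    if (length(sds) != base$L)
      stop("sds must have one entry per harmonic of the base pattern",
           call. = FALSE)
    if (any(sds < 0)) stop("sds must be non-negative", call. = FALSE)
  }
  structure(list(kind = kind, base = base, sds = sds, redraw = redraw),
            class = "pattern_variant")
}

#' Draw a pattern realization from a variant
#'
#' `Mc` and `Mm` return the base pattern unchanged; `Mmsd` perturbs each
#' harmonic magnitude by `Normal(0, sd_n)`, truncates at zero, preserves
#' the phase of each component, and renormalizes to unit peak. Uses the
#' current RNG stream, so draws are reproducible under `set.seed()`.
#'
#' @param variant a [pattern_variant()].
#' @return A normalized [fourier_pattern()].
#' @export
sample_variant <- function(variant) {
  stopifnot(inherits(variant, "pattern_variant"))
  if (variant$kind != "Mmsd") return(variant$base)
  base <- variant$base
  R <- sqrt(base$a^2 + base$b^2)
  psi <- atan2(base$a, base$b)
  R_new <- pmax(0, R + stats::rnorm(base$L, 0, variant$sds))
  fourier_pattern(R_new * sin(psi), R_new * cos(psi), a0 = base$a0,
                  T = base$T, n_dom = base$n_dom)
}
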