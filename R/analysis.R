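#' Sliding cross-correlogram of two joint-angle traces
#'
#' For every window centre, computes the Pearson correlation between `x`
#' within a `+/- half_window` window and `y` shifted by each lag on the
#' `+/- half_window` lag grid (one-sample spacing). The mean correlogram is
#' the per-lag average over windows. Windows whose lag-shifted counterpart
#' would leave the trace are dropped rather than zero-padded; windows with
#' zero variance yield `NA` coefficients that are excluded from the mean.
#'
#' Sign convention: a correlation band at negative lag means the second
#' trace (`y`) leads the first (`x`), so with `x` = HS and `y` = SP the
#' natural SP lead appears at negative lag.
#'
#' @param x,y equal-length numeric traces, uniformly sampled at `fs`.
#' @param fs sampling rate (Hz). Default 50.
#' @param half_window half window / maximum lag (s). Default 1.
#' @param stride window-centre stride in samples. Default 1 (every sample).
#' @return Object of class `correlogram`: `lags` (s), `centers` (s),
#'   `matrix` (lags x windows), `mean` (per-lag mean).
#' @export
sliding_crosscorr <- function(x, y, fs = 50, half_window = 1, stride = 1L) {
  if (length(x) != length(y))
    stop("traces must have equal length", call. = FALSE)
  n <- length(x)
  h <- as.integer(round(half_window * fs))
  if (h < 1) stop("half_window too small for the sampling rate", call. = FALSE)
  wlen <- 2L * h + 1L
  if (n < wlen + 2L * h)
    stop("trace shorter than one fully lag-covered window", call. = FALSE)
  lags <- seq(-h, h)
  centers <- seq(1L + 2L * h, n - 2L * h, by = as.integer(stride))
  nw <- length(centers)
  ## windowed sums via cumulative sums; window at centre t covers t-h..t+h
  csy <- cumsum(c(0, y)); csyy <- cumsum(c(0, y^2))
  csx <- cumsum(c(0, x)); csxx <- cumsum(c(0, x^2))
  sx <- csx[centers + h + 1L] - csx[centers - h]
  sxx <- csxx[centers + h + 1L] - csxx[centers - h]
  vx <- sxx - sx^2 / wlen
  out <- matrix(NA_real_, length(lags), nw)
  for (j in seq_along(lags)) {
    l <- lags[j]
    sy <- csy[centers + h + l + 1L] - csy[centers - h + l]
    syy <- csyy[centers + h + l + 1L] - csyy[centers - h + l]
    u1 <- max(1L, 1L - l)
    u2 <- min(n, n - l)
    p <- x[u1:u2] * y[(u1 + l):(u2 + l)]     # p at u = x[u] * y[u+l]
    csp <- cumsum(c(0, p))
    off <- u1 - 1L                           # p index = u - off
    sxy <- csp[centers + h - off + 1L] - csp[centers - h - off]
    vy <- syy - sy^2 / wlen
    cv <- sxy - sx * sy / wlen
    ## zero-variance windows are undefined: NA, excluded from the mean
    ok <- vx > 1e-10 * pmax(sxx, 1) & vy > 1e-10 * pmax(syy, 1)
    r <- ifelse(ok, cv / sqrt(pmax(vx * vy, .Machine$double.xmin)), NA_real_)
    out[j, ] <- pmin(pmax(r, -1), 1)
  }
  structure(list(lags = lags / fs, centers = (centers - 1L) / fs,
                 matrix = out, mean = rowMeans(out, na.rm = TRUE), fs = fs),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  i <- which.max(x$mean)
  cat(sprintf(
    "Sliding cross-correlogram: %d lags (+/- %.2f s), %d windows; mean peak r = %.3f at lag %.3f s\n",
    length(x$lags), max(x$lags), ncol(x$matrix), x$mean[i], x$lags[i]))
  invisible(x)
}

#' Phase lead from the mean correlogram peak
#'
#' Locates the maximum of the mean correlogram within half a period of the
#' dominant frequency around zero lag, refines the peak position with a
#' parabolic fit through the three points around the maximum, and converts
#' lag to phase: `phase = -360 * f_dom * lag`. A positive result means the
#' second trace of [sliding_crosscorr()] leads.
#'
#' @param correlogram a [sliding_crosscorr()] result.
#' @param f_dom dominant frequency (Hz) used for the lag-to-phase
#'   conversion.
#' @return Phase lead in degrees, with attributes `lag` (s) and
#'   `peak_correlation`.
#' @export
peak_phase <- function(correlogram, f_dom) {
  stopifnot(inherits(correlogram, "correlogram"), f_dom > 0)
  lags <- correlogram$lags
  m <- correlogram$mean
  win <- which(abs(lags) <= 1 / (2 * f_dom))
  if (length(win) < 3)
    stop("lag grid too coarse for the requested dominant frequency",
         call. = FALSE)
  i <- win[which.max(m[win])]
  if (i == win[1] || i == win[length(win)] || !is.finite(m[i]))
    stop("no interior correlogram peak within half a dominant period",
         call. = FALSE)
  ## parabolic sub-sample refinement
  y1 <- m[i - 1L]; y2 <- m[i]; y3 <- m[i + 1L]
  denom <- y1 - 2 * y2 + y3
  frac <- if (abs(denom) > .Machine$double.eps) 0.5 * (y1 - y3) / denom else 0
  frac <- min(max(frac, -0.5), 0.5)
  dlag <- lags[2] - lags[1]
  lag_peak <- lags[i] + frac * dlag
  structure(-360 * f_dom * lag_peak, lag = lag_peak,
            peak_correlation = y2 - 0.25 * (y1 - y3) * frac)
}

#' Circular statistics of a phase sample
#'
#' `circular_variance(phases)` returns `1 - R`, where `R` is the length of
#' the mean resultant vector of the unit phasors; 0 means perfectly
#' concentrated phases, 1 a uniform spread. `circular_mean(phases)` is the
#' direction of the resultant (radians in `(-pi, pi]`).
#'
#' @param phases numeric vector of phases (radians; wrapping is immaterial).
#' @return Scalar in `[0, 1]` (variance) or radians (mean).
#' @export
circular_variance <- function(phases) {
  if (length(phases) < 1L) stop("empty phase sample", call. = FALSE)
  1 - Mod(mean(exp(1i * phases)))
}

#' @rdname circular_variance
#' @export
circular_mean <- function(phases) {
  if (length(phases) < 1L) stop("empty phase sample", call. = FALSE)
  Arg(mean(exp(1i * phases)))
}

#' Working range of a joint-angle trace
#'
#' The 5th-to-95th percentile span (linear interpolation between order
#' statistics), the convention used for box-whisker summaries of antennal
#' joint angles.
#'
#' @param angles numeric vector (degrees).
#' @return List with `lower`, `upper` (degrees) and `width`.
#' @export
working_range <- function(angles) {
  if (!length(angles) || any(!is.finite(angles)))
    stop("angles must be finite and non-empty", call. = FALSE)
  q <- stats::quantile(angles, c(0.05, 0.95), names = FALSE, type = 7)
  list(lower = q[1], upper = q[2], width = q[2] - q[1])
}

#' Amplitude spectrum on the standard analysis window
#'
#' Fits the Fourier coefficients on every complete, non-overlapping
#' `T`-second window of the trace and averages the per-harmonic magnitudes
#' `|z_n| = sqrt(a_n^2 + b_n^2)` (unnormalized, degrees). Component `n`
#' corresponds to `n/T` Hz.
#'
#' @param trace numeric vector (degrees) sampled at `fs`.
#' @param fs sampling rate (Hz).
#' @param T window length (s). Default 5.12.
#' @param L highest harmonic reported. Default 20.
#' @return Data frame with columns `n`, `freq` (Hz), `magnitude` (deg).
#' @export
amplitude_spectrum <- function(trace, fs = 50, T = 5.12, L = 20) {
  N <- as.integer(round(fs * T))
  nw <- length(trace) %/% N
  if (nw < 1) stop("trace shorter than one analysis window", call. = FALSE)
  mags <- matrix(0, nw, L)
  for (w in seq_len(nw)) {
    p <- fit_fourier(trace[((w - 1L) * N + 1L):(w * N)], fs = fs, T = T,
                     L = L, normalize = FALSE)
    mags[w, ] <- sqrt(p$a^2 + p$b^2)
  }
  data.frame(n = seq_len(L), freq = seq_len(L) / T,
             magnitude = colMeans(mags))
}

#' Dominant spectral frequency of a trace
#'
#' The frequency of the largest non-DC component of the averaged amplitude
#' spectrum on the standard window.
#'
#' @inheritParams amplitude_spectrum
#' @return Frequency in Hz (a multiple of `1/T`).
#' @export
dominant_frequency <- function(trace, fs = 50, T = 5.12, L = 20) {
  sp <- amplitude_spectrum(trace, fs = fs, T = T, L = L)
  sp$freq[which.max(sp$magnitude)]
}

#' Shape ratio of an antennal tip trajectory
#'
#' Projects the tip points onto the plane orthogonal to the mean antennal
#' direction (the unit vector from `center` to the centroid of the points)
#' and eigen-decomposes the 2-D covariance of the projected cloud. The
#' ratio of minor to major axis lengths (square root of the eigenvalue
#' ratio) is 0 for collinear points and approaches 1 for a circular cloud.
#'
#' @param points n x 3 matrix of tip positions (m); n >= 100.
#' @param center origin of the mean antennal direction; default the head
#'   centre at the external-frame origin.
#' @return List with `ratio` in `[0, 1]`, `orientation` (radians of the
#'   major axis in the projection plane) and `axes` (major/minor SDs, m).
#' @export
trajectory_shape <- function(points, center = c(0, 0, 0)) {
  points <- as.matrix(points)
  if (nrow(points) < 100) stop("need at least 100 points", call. = FALSE)
  centroid <- colMeans(points)
  d <- centroid - center
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("degenerate geometry: centroid at the center", call. = FALSE)
  d <- d / nd
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  proj <- cbind(points %*% e1, points %*% e2)
  cv <- stats::cov(proj)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] <= 0)
    stop("degenerate trajectory: all points identical", call. = FALSE)
  list(ratio = sqrt(max(eg$values[2], 0) / eg$values[1]),
       orientation = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       axes = sqrt(pmax(eg$values, 0)))
}

#' Instantaneous phase difference from two traces
#'
#' Fallback for external recordings where the oscillator phases are not
#' available: demodulates each trace at its dominant frequency (complex
#' mixing followed by a one-period moving average) and returns the
#' per-sample phase difference `arg(z_y) - arg(z_x)` (radians), so a
#' positive value means `y` leads.
#'
#' @param x,y equal-length traces (degrees) at `fs`.
#' @param fs sampling rate (Hz).
#' @param f_dom demodulation frequency (Hz); defaults to the dominant
#'   spectral frequency of `x`.
#' @return Numeric vector of wrapped phase differences (radians), shorter
#'   than the input by one averaging period.
#' @export
phase_difference_trace <- function(x, y, fs = 50, f_dom = NULL) {
  if (length(x) != length(y)) stop("traces must have equal length", call. = FALSE)
  if (is.null(f_dom)) f_dom <- dominant_frequency(x, fs = fs)
  n <- length(x)
  t <- (seq_len(n) - 1L) / fs
  mix <- exp(-2i * pi * f_dom * t)
  w <- max(3L, as.integer(round(fs / f_dom)))
  ## one-period moving average; stats::filter is real-valued, so the two
  ## quadrature components are smoothed separately
  smooth <- function(z) {
    complex(real = as.numeric(stats::filter(Re(z), rep(1 / w, w), sides = 2)),
            imaginary = as.numeric(stats::filter(Im(z), rep(1 / w, w),
                                                 sides = 2)))
  }
  zx <- smooth((x - mean(x)) * mix)
  zy <- smooth((y - mean(y)) * mix)
  keep <- which(!is.na(zx) & !is.na(zy))
  as.numeric(Arg(zy[keep] * Conj(zx[keep])))
}
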