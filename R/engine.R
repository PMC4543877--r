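## Fixed-step RK2 simulation engine shared by simulate_network() and
## simulate_trial(). The stochastic draws (amplitude bounds, intrinsic
## frequency, Mmsd pattern coefficients) are held constant between events:
## the upper bound is redrawn at each upward zero-crossing of the pattern
## output F, the lower bound at each downward crossing, and frequency and
## Mmsd coefficients once per completed oscillator cycle.

extract_net_params <- function(network) {
  g <- function(f) vapply(network$oscillators, `[[`, numeric(1), f)
  list(v = g("v"), mu = g("mu"), C = g("C"), gamma = g("gamma"),
       gamma_c = g("gamma_c"), U = g("U"), L_sd = g("L_sd"), v_sd = g("v_sd"))
}

## Aligned initial phases: theta_1 = 0, then cumulative pair biases.
aligned_phases <- function(network) {
  th <- numeric(length(network$oscillators))
  e <- network$edges
  for (k in seq_len(nrow(e))) th[e$b[k]] <- th[e$a[k]] + e$phi[k]
  th
}

sine_pattern <- function(n_dom = 8, T = 5.12) {
  b <- numeric(n_dom); b[n_dom] <- 1
  fourier_pattern(numeric(n_dom), b, T = T, n_dom = n_dom)
}

cpg_engine <- function(network, patterns = NULL, duration = 60,
                       transient = 0, seed = NULL,
                       servo = NULL, init = c("random", "aligned"),
                       radial_mode = "normalized") {
  init <- match.arg(init)
  stopifnot(inherits(network, "cpg_network"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  n_osc <- length(network$oscillators)
  if (is.null(patterns)) patterns <- replicate(n_osc, sine_pattern(),
                                               simplify = FALSE)
  if (length(patterns) != n_osc)
    stop("need one pattern (or variant) per oscillator", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  par <- extract_net_params(network)
  ea <- edge_arrays(network$edges)
  Tg <- matrix(0, n_osc, length(ea$w))
  for (k in seq_along(ea$w)) Tg[ea$tgt[k], k] <- 1
  dt <- network$dt
  n_steps <- as.integer(round((duration + transient) / dt))
  keep_from <- as.integer(round(transient / dt)) + 1L

  ## current pattern realisations (Mmsd redraws per cycle)
  is_variant <- vapply(patterns, inherits, logical(1), "pattern_variant")
  pat <- lapply(patterns, function(p)
    if (inherits(p, "pattern_variant")) sample_variant(p) else p)
  for (p in pat) if (!isTRUE(p$normalized))
    stop("patterns must be normalized before driving the network",
         call. = FALSE)

  rho <- rep(0.5, n_osc)
  theta <- if (init == "random") stats::runif(n_osc, 0, 2 * pi) else
    aligned_phases(network)
  cc <- par$C
  v_cur <- stats::rnorm(n_osc, par$v, par$v_sd)
  amp_u <- pmax(0, stats::rnorm(n_osc, par$mu, par$U))
  amp_l <- pmax(0, stats::rnorm(n_osc, par$mu, par$L_sd))
  cyc_next <- theta + 2 * pi
  f_cur <- vapply(seq_len(n_osc), function(i) evaluate(pat[[i]], theta[i]),
                  numeric(1))
  x <- cc + rho * ifelse(f_cur >= 0, amp_u, amp_l) * f_cur
  angle <- if (!is.null(servo)) cc else NULL

  n_keep <- n_steps - keep_from + 1L
  rec_r <- matrix(NA_real_, n_keep, n_osc)
  rec_theta <- matrix(NA_real_, n_keep, n_osc)
  rec_c <- matrix(NA_real_, n_keep, n_osc)
  rec_x <- matrix(NA_real_, n_keep, n_osc)
  rec_angle <- if (!is.null(servo)) matrix(NA_real_, n_keep, n_osc) else NULL

  gam <- par$gamma; gam_c <- par$gamma_c; mu <- par$mu; C <- par$C
  two_pi <- 2 * pi
  row <- 0L
  for (s in seq_len(n_steps)) {
    ## midpoint RK2 on (rho, theta, c); draws frozen within the step
    om <- two_pi * v_cur
    pull <- ea$w * sin(theta[ea$src] - theta[ea$tgt] - ea$bias)
    k1_rho <- gam * (1 - rho^2) * rho
    k1_th <- om + drop(Tg %*% pull)
    k1_c <- gam_c * (C - cc)
    rho2 <- rho + 0.5 * dt * k1_rho
    th2 <- theta + 0.5 * dt * k1_th
    c2 <- cc + 0.5 * dt * k1_c
    pull2 <- ea$w * sin(th2[ea$src] - th2[ea$tgt] - ea$bias)
    rho <- rho + dt * (gam * (1 - rho2^2) * rho2)
    theta <- theta + dt * (om + drop(Tg %*% pull2))
    cc <- cc + dt * (gam_c * (C - c2))
    if (any(!is.finite(rho)) || any(abs(rho) > 10))
      stop("radial state exceeded 10x its target amplitude: integration ",
           "blow-up (dt too large for the given gains)", call. = FALSE)

    ## cycle events: frequency redraw, Mmsd coefficient redraw
    done <- which(theta >= cyc_next)
    for (i in done) {
      if (par$v_sd[i] > 0) v_cur[i] <- stats::rnorm(1, par$v[i], par$v_sd[i])
      if (is_variant[i] && patterns[[i]]$kind == "Mmsd" &&
          patterns[[i]]$redraw == "cycle")
        pat[[i]] <- sample_variant(patterns[[i]])
      cyc_next[i] <- cyc_next[i] + two_pi
    }

    ## pattern output and amplitude-bound events at its zero crossings
    f_new <- vapply(seq_len(n_osc), function(i) evaluate(pat[[i]], theta[i]),
                    numeric(1))
    up <- which(f_cur <= 0 & f_new > 0)
    for (i in up) if (par$U[i] > 0)
      amp_u[i] <- max(0, stats::rnorm(1, mu[i], par$U[i]))
    down <- which(f_cur >= 0 & f_new < 0)
    for (i in down) if (par$L_sd[i] > 0)
      amp_l[i] <- max(0, stats::rnorm(1, mu[i], par$L_sd[i]))
    f_cur <- f_new

    x <- cc + rho * ifelse(f_cur >= 0, amp_u, amp_l) * f_cur
    if (!is.null(servo))
      angle <- servo_step(angle, x, servo, dt)

    if (s >= keep_from) {
      row <- row + 1L
      rec_r[row, ] <- mu * rho
      rec_theta[row, ] <- theta
      rec_c[row, ] <- cc
      rec_x[row, ] <- x
      if (!is.null(servo)) rec_angle[row, ] <- angle
    }
  }
  nm <- vapply(network$oscillators, `[[`, character(1), "name")
  colnames(rec_r) <- colnames(rec_theta) <- colnames(rec_c) <-
    colnames(rec_x) <- nm
  if (!is.null(rec_angle)) colnames(rec_angle) <- nm
  list(time = (seq_len(n_keep)) * dt, dt = dt,
       r = rec_r, theta = rec_theta, c = rec_c, x = rec_x,
       angle = rec_angle, names = nm)
}

#' Simulate the rhythm-generating network
#'
#' Integrates the coupled Hopf network with the fixed-step midpoint method
#' at the network's `dt` (default 5 ms) and returns the full-rate state
#' trajectory: radius, unwrapped phase, offset and drive signal per
#' oscillator. Stochastic amplitude bounds are redrawn at the zero
#' crossings of each oscillator's pattern output, and intrinsic frequencies
#' once per completed cycle.
#'
#' @param network a [default_network()]-style `cpg_network`.
#' @param duration retained simulation length (s).
#' @param transient initial stretch (s) that is simulated but discarded.
#' @param seed integer seed controlling every stochastic draw (and the
#'   random initial phases).
#' @param patterns optional list of one [fourier_pattern()] or
#'   [pattern_variant()] per oscillator; defaults to pure sines.
#' @param init `"random"` initial phases (default) or `"aligned"` (phases
#'   start at the steady bias profile).
#' @return List with `time` (s), matrices `r`, `theta` (unwrapped, rad),
#'   `c`, `x` (degrees) with one column per oscillator, and `dt`.
#' @export
simulate_network <- function(network, duration = 30, transient = 0,
                             seed = NULL, patterns = NULL,
                             init = c("random", "aligned")) {
  res <- cpg_engine(network, patterns, duration, transient, seed,
                    servo = NULL, init = match.arg(init))
  res$angle <- NULL
  res
}

#' Simulate a full tactile-exploration trial
#'
#' Runs the CPG at the integration step (5 ms), tracks the drive signals
#' with rate-limited velocity servos, evaluates the forward kinematics,
#' and returns joint-angle and antennal-tip trajectories resampled to the
#' experimental convention of 50 Hz. The initial `transient` seconds are
#' discarded.
#'
#' @inheritParams simulate_network
#' @param patterns list of 5 patterns/variants (order: left SP, left HS,
#'   neck, right HS, right SP); defaults to [default_patterns()] `"Mc"`.
#' @param chain an [antenna_chain()].
#' @param servo a [servo_config()].
#' @param duration retained trial length (s) after the transient.
#' @param transient discarded settling time (s). Default 5.
#' @param fs_out output sampling rate (Hz); must divide `1/dt`.
#' @return Object of class `antenna_trial`: `time` (s), `angles` and
#'   `targets` (degrees, columns per joint), `tips_left`/`tips_right`
#'   (m, n x 3), `tracking_rmse` (degrees per joint), plus the
#'   configuration used.
#' @export
simulate_trial <- function(network = default_network(), patterns = NULL,
                           chain = antenna_chain(), servo = servo_config(),
                           duration = 60, transient = 5, seed = NULL,
                           fs_out = 50, init = c("random", "aligned")) {
  if (is.null(patterns)) patterns <- default_patterns("Mc")
  step_ratio <- 1 / (network$dt * fs_out)
  if (abs(step_ratio - round(step_ratio)) > 1e-9)
    stop("fs_out must divide the integration rate 1/dt", call. = FALSE)
  res <- cpg_engine(network, patterns, duration, transient, seed,
                    servo = servo, init = match.arg(init))
  pick <- seq(as.integer(round(step_ratio)), length(res$time),
              by = as.integer(round(step_ratio)))
  angles <- res$angle[pick, , drop = FALSE]
  targets <- res$x[pick, , drop = FALSE]
  n <- length(pick)
  tips_l <- matrix(NA_real_, n, 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  tips_r <- tips_l
  for (k in seq_len(n)) {
    a <- unname(angles[k, ])
    fk <- forward_kinematics(
      c(neck = a[3], hs_left = a[2], sp_left = a[1],
        hs_right = a[4], sp_right = a[5]), chain)
    tips_l[k, ] <- fk$tip_left
    tips_r[k, ] <- fk$tip_right
  }
  rmse <- sqrt(colMeans((angles - targets)^2))
  structure(list(time = res$time[pick] - res$time[pick[1]],
                 fs = fs_out, angles = angles, targets = targets,
                 tips_left = tips_l, tips_right = tips_r,
                 tracking_rmse = rmse, network = network, servo = servo,
                 chain = chain, seed = seed, transient = transient),
            class = "antenna_trial")
}

#' Export a rhythm-layer trajectory to CSV
#'
#' Columns: `time_s`, then per oscillator `r_<name>` (degrees),
#' `theta_wrapped_<name>` (radians in `(-pi, pi]`), `c_<name>` and
#' `x_<name>` (degrees).
#'
#' @param result a [simulate_network()] result.
#' @param path output file.
#' @export
write_network_csv <- function(result, path) {
  wrap <- function(th) atan2(sin(th), cos(th))
  df <- data.frame(time_s = result$time)
  for (i in seq_along(result$names)) {
    nm <- result$names[i]
    df[[paste0("r_", nm)]] <- result$r[, i]
    df[[paste0("theta_wrapped_", nm)]] <- wrap(result$theta[, i])
    df[[paste0("c_", nm)]] <- result$c[, i]
    df[[paste0("x_", nm)]] <- result$x[, i]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.antenna_trial <- function(x, ...) {
  cat(sprintf(
    "Antennal exploration trial: %.1f s at %g Hz (%s, %s network)\n",
    utils::tail(x$time, 1), x$fs, x$network$condition,
    if (x$network$stochastic) "stochastic" else "noise-off"))
  cat("Servo tracking RMSE (deg):\n")
  print(round(x$tracking_rmse, 3))
  invisible(x)
}
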