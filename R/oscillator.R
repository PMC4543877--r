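#' Hopf oscillator parameters
#'
#' Bundles the per-joint parameters of one polar-form Hopf oscillator: the
#' intrinsic cycle frequency `v`, the amplitude target `mu` (the radius the
#' limit cycle converges to, in degrees), the offset target `C` (the mean
#' joint angle carried by a separate first-order state), the convergence
#' gains `gamma` (radius) and `gamma_c` (offset), and the stochasticity
#' parameters: `U` and `L_sd` are the standard deviations of the per-cycle
#' draws of the effective upper and lower oscillation bounds, and `v_sd` is
#' the standard deviation of the per-cycle intrinsic-frequency draw.
#'
#' @param v intrinsic frequency (Hz).
#' @param mu amplitude target (degrees, >= 0).
#' @param C offset target (degrees).
#' @param gamma radius convergence gain (1/s, > 0).
#' @param gamma_c offset convergence gain (1/s, > 0); defaults to `gamma`.
#' @param U standard deviation of the upper-bound amplitude draw (degrees).
#' @param L_sd standard deviation of the lower-bound amplitude draw (degrees).
#' @param v_sd standard deviation of the per-cycle frequency draw (Hz).
#' @param name label used in printed output and trajectory columns.
#' @return An object of class `osc_params`.
#' @examples
#' p <- osc_params(v = 1.45, mu = 39, C = -60, gamma = 20, U = 8, L_sd = 9,
#'                 v_sd = 0.05, name = "HS_left")
#' @export
osc_params <- function(v, mu, C, gamma = 20, gamma_c = gamma,
                       U = 0, L_sd = 0, v_sd = 0, name = "osc") {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (gamma <= 0 || gamma_c <= 0)
    stop("gamma and gamma_c must be positive", call. = FALSE)
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  if (U < 0 || L_sd < 0 || v_sd < 0)
    stop("U, L_sd and v_sd must be non-negative", call. = FALSE)
  structure(list(v = v, mu = mu, C = C, gamma = gamma, gamma_c = gamma_c,
                 U = U, L_sd = L_sd, v_sd = v_sd, name = name),
            class = "osc_params")
}

#' @export
print.osc_params <- function(x, ...) {
  cat(sprintf(
    "Hopf oscillator '%s': v = %.3f +/- %.3f Hz, mu = %g deg (U %g / L %g), C = %g deg, gamma = %g, gamma_c = %g\n",
    x$name, x$v, x$v_sd, x$mu, x$U, x$L_sd, x$C, x$gamma, x$gamma_c))
  invisible(x)
}

## Table of default oscillator parameters. Offsets are given for the left
## antenna; the right side uses sign-inverted offsets (bilateral symmetry of
## the skeleton with mirrored hinge axes).
cpg_param_table <- function(condition = c("intact", "ablated")) {
  condition <- match.arg(condition)
  if (condition == "intact") {
    hs <- list(mu = 39, U = 8,  L = 9,  C = -60)
    sp <- list(mu = 31, U = 9,  L = 15, C = 22)
  } else {
    hs <- list(mu = 55, U = 16, L = 12, C = -72)
    sp <- list(mu = 50, U = 13, L = 18, C = 15)
  }
  list(hs = hs, sp = sp,
       neck = list(mu = 6, U = 1, L = 1, C = 0),
       v_ant = 1.45, v_ant_sd = 0.05, v_neck = 1.25, v_neck_sd = 0.02,
       gamma_ant = 20, gamma_neck = 50)
}

#' Default five-oscillator CPG network
#'
#' Builds the standard rhythm-generating network: a chain of five Hopf
#' oscillators ordered left SP, left HS, neck, right HS, right SP, with
#' strong intra-antennal coupling (w = 20) and weak coupling through the
#' neck (w = 1). The phase biases place the SP joints 20 degrees ahead of
#' their HS joints and the two HS joints 180 degrees apart across the neck.
#'
#' Each undirected neighbour pair is stored with a single bias `phi`
#' interpreted as the target steady difference `theta[b] - theta[a]`; the
#' two directed coupling terms carry antisymmetric biases, so the pair has
#' the unique stable lock `theta[b] - theta[a] = phi`.
#'
#' @param condition `"intact"` or `"ablated"`: selects the amplitude/offset
#'   parameter set. The two conditions differ only in `mu` and `C`.
#' @param stochastic logical; `FALSE` zeroes all amplitude and frequency
#'   jitter (deterministic limit).
#' @param dt integration step (s).
#' @param phase_lead SP-vs-HS phase lead in degrees (target steady lead of
#'   each SP oscillator over its HS oscillator). Default 20.
#' @param equal_frequencies logical; if `TRUE` the neck oscillator runs at
#'   the antennal intrinsic frequency (useful for exact bias-composition
#'   checks; the default network keeps the slower neck of the standard
#'   parameter table, which shifts the locked differences across the weak
#'   neck edges while preserving left-right HS anti-phase by symmetry).
#' @return An object of class `cpg_network`: list with `oscillators` (length
#'   5 list of [osc_params()]), `edges` (data frame `a`, `b`, `phi`, `w_ab`,
#'   `w_ba`), `dt`, and bookkeeping fields.
#' @export
default_network <- function(condition = c("intact", "ablated"),
                            stochastic = TRUE, dt = 0.005, phase_lead = 20,
                            equal_frequencies = FALSE) {
  condition <- match.arg(condition)
  tab <- cpg_param_table(condition)
  s <- function(x) if (stochastic) x else 0
  v_neck <- if (equal_frequencies) tab$v_ant else tab$v_neck
  osc <- list(
    osc_params(tab$v_ant, tab$sp$mu,  tab$sp$C,  tab$gamma_ant,
               U = s(tab$sp$U), L_sd = s(tab$sp$L), v_sd = s(tab$v_ant_sd),
               name = "SP_left"),
    osc_params(tab$v_ant, tab$hs$mu,  tab$hs$C,  tab$gamma_ant,
               U = s(tab$hs$U), L_sd = s(tab$hs$L), v_sd = s(tab$v_ant_sd),
               name = "HS_left"),
    osc_params(v_neck, tab$neck$mu, tab$neck$C, tab$gamma_neck,
               U = s(tab$neck$U), L_sd = s(tab$neck$L),
               v_sd = s(tab$v_neck_sd), name = "neck"),
    osc_params(tab$v_ant, tab$hs$mu, -tab$hs$C,  tab$gamma_ant,
               U = s(tab$hs$U), L_sd = s(tab$hs$L), v_sd = s(tab$v_ant_sd),
               name = "HS_right"),
    osc_params(tab$v_ant, tab$sp$mu, -tab$sp$C,  tab$gamma_ant,
               U = s(tab$sp$U), L_sd = s(tab$sp$L), v_sd = s(tab$v_ant_sd),
               name = "SP_right")
  )
  lead <- phase_lead * pi / 180
  ## theta[b] - theta[a] locks to phi: SP leads HS by `lead` on both sides,
  ## HS_left and HS_right end up pi apart (phi23 + phi34 = pi at the default
  ## lead of 20 deg, i.e. -pi/3 + 4*pi/3).
  edges <- data.frame(
    a   = c(1L, 2L, 3L, 4L),
    b   = c(2L, 3L, 4L, 5L),
    phi = c(-lead, -pi / 3, pi - (-pi / 3), lead),
    w_ab = c(20, 1, 1, 20),
    w_ba = c(20, 1, 1, 20)
  )
  structure(list(oscillators = osc, edges = edges, dt = dt,
                 condition = condition, stochastic = stochastic,
                 phase_lead = phase_lead),
            class = "cpg_network")
}

#' @export
print.cpg_network <- function(x, ...) {
  cat(sprintf("CPG network (%s, %s): %d oscillators, dt = %g s\n",
              x$condition, if (x$stochastic) "stochastic" else "noise off",
              length(x$oscillators), x$dt))
  for (o in x$oscillators) print(o)
  cat("Coupling edges (phi = target theta[b] - theta[a], rad):\n")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Time derivatives of one Hopf oscillator
#'
#' Evaluates the polar-form Hopf equations for a single oscillator given its
#' neighbours' phases: `dr/dt = gamma * (mu^2 - r^2) * r`,
#' `dtheta/dt = 2*pi*v + sum_j w_j * sin(theta_j - theta - phi_j)`, and
#' `dc/dt = gamma_c * (C - c)`.
#'
#' @param state list or numeric vector with elements `r`, `theta`, `c`.
#' @param params an [osc_params()] object.
#' @param neighbor_phases optional data frame or list of rows with elements
#'   `phase`, `weight`, `bias` describing incoming coupling terms.
#' @return Numeric vector `c(dr, dtheta, dc)`.
#' @examples
#' p <- osc_params(v = 1.45, mu = 39, C = -60, gamma = 20)
#' hopf_derivatives(list(r = 39, theta = 0, c = -60), p)  # dr = 0 at r = mu
#' @export
hopf_derivatives <- function(state, params, neighbor_phases = NULL) {
  st <- unlist(state[c("r", "theta", "c")])
  if (any(!is.finite(st)))
    stop("non-finite oscillator state: numerical blow-up ",
         "(integration step too large for the given gamma/weights?)",
         call. = FALSE)
  coup <- 0
  if (!is.null(neighbor_phases) && NROW(neighbor_phases) > 0L) {
    nb <- as.data.frame(neighbor_phases)
    if (any(nb$weight < 0)) stop("coupling weights must be >= 0", call. = FALSE)
    coup <- sum(nb$weight * sin(nb$phase - st[["theta"]] - nb$bias))
  }
  c(dr = params$gamma * (params$mu^2 - st[["r"]]^2) * st[["r"]],
    dtheta = 2 * pi * params$v + coup,
    dc = params$gamma_c * (params$C - st[["c"]]))
}

## Directed edge arrays used by the vectorised network derivative. The
## coupling term into the target is w * sin(theta_src - theta_tgt - bias);
## storing -phi on the a->b direction and +phi on b->a makes the pair lock
## at theta_b - theta_a = phi (the documented sign of the stored bias).
edge_arrays <- function(edges) {
  list(src  = c(edges$a, edges$b),
       tgt  = c(edges$b, edges$a),
       w    = c(edges$w_ab, edges$w_ba),
       bias = c(-edges$phi, edges$phi))
}

## Derivatives of the full network state. `rho` is the normalised radius
## r/mu in the default integration mode, or r itself in raw mode. `v_cur`
## are the currently drawn intrinsic frequencies (Hz).
network_derivatives <- function(rho, theta, cc, v_cur, net, ea,
                                radial_mode = "normalized") {
  mu <- vapply(net$oscillators, `[[`, numeric(1), "mu")
  gam <- vapply(net$oscillators, `[[`, numeric(1), "gamma")
  gam_c <- vapply(net$oscillators, `[[`, numeric(1), "gamma_c")
  C <- vapply(net$oscillators, `[[`, numeric(1), "C")
  drho <- if (radial_mode == "normalized") {
    gam * (1 - rho^2) * rho
  } else {
    gam * (mu^2 - rho^2) * rho
  }
  dtheta <- 2 * pi * v_cur
  pull <- ea$w * sin(theta[ea$src] - theta[ea$tgt] - ea$bias)
  for (k in seq_along(pull)) dtheta[ea$tgt[k]] <- dtheta[ea$tgt[k]] + pull[k]
  list(drho = drho, dtheta = dtheta, dc = gam_c * (C - cc))
}

#' One midpoint (RK2) step of the coupled network
#'
#' Advances the full network state by one fixed step of the explicit
#' midpoint method. Deterministic: the stochastic amplitude and frequency
#' draws are held constant within a step and resampled only at cycle events
#' (see [simulate_network()]).
#'
#' @param state list with numeric vectors `r`, `theta`, `c` (one entry per
#'   oscillator) and optionally `v_cur` (current frequency draws; defaults
#'   to the nominal frequencies).
#' @param network a [default_network()]-style `cpg_network`.
#' @param dt step size (s); defaults to `network$dt`.
#' @param radial_mode `"normalized"` (default; integrates r/mu, same fixed
#'   point, relaxation rate 2*gamma) or `"raw"` (literal radial equation;
#'   requires a much smaller `dt` for Table-scale gains).
#' @return Updated state list.
#' @export
step_rk2 <- function(state, network, dt = network$dt,
                     radial_mode = c("normalized", "raw")) {
  radial_mode <- match.arg(radial_mode)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  mu <- vapply(network$oscillators, `[[`, numeric(1), "mu")
  v_cur <- state$v_cur %||% vapply(network$oscillators, `[[`, numeric(1), "v")
  ea <- edge_arrays(network$edges)
  rho <- if (radial_mode == "normalized") {
    ifelse(mu > 0, state$r / mu, 0)
  } else state$r
  if (any(!is.finite(c(rho, state$theta, state$c))))
    stop("non-finite network state: numerical blow-up", call. = FALSE)
  k1 <- network_derivatives(rho, state$theta, state$c, v_cur, network, ea,
                            radial_mode)
  rho2 <- rho + 0.5 * dt * k1$drho
  th2 <- state$theta + 0.5 * dt * k1$dtheta
  c2 <- state$c + 0.5 * dt * k1$dc
  k2 <- network_derivatives(rho2, th2, c2, v_cur, network, ea, radial_mode)
  rho_n <- rho + dt * k2$drho
  guard <- if (radial_mode == "normalized") 10 else 10 * pmax(mu, 1)
  if (any(!is.finite(rho_n)) || any(abs(rho_n) > guard))
    stop("radial state exceeded 10x its target amplitude: ",
         "integration blow-up (reduce dt or use the normalized mode)",
         call. = FALSE)
  r_n <- if (radial_mode == "normalized") mu * rho_n else rho_n
  list(r = r_n, theta = state$theta + dt * k2$dtheta,
       c = state$c + dt * k2$dc, v_cur = v_cur)
}

#' Resample the stochastic amplitude bounds and frequency of one oscillator
#'
#' Draws a new effective upper or lower amplitude bound from
#' `Normal(mu, U)` / `Normal(mu, L_sd)` truncated at zero, and a new
#' intrinsic frequency from `Normal(v, v_sd)`. During a simulation the
#' upper bound is redrawn at each upward zero-crossing of the pattern
#' output, the lower bound at each downward crossing, and the frequency
#' once per completed oscillator cycle; this helper performs the draws and
#' is exposed mainly so the truncation and reproducibility contracts can be
#' tested in isolation.
#'
#' @param state state list with elements `amp_upper`, `amp_lower`, `v_cur`.
#' @param params an [osc_params()] object.
#' @param what character subset of `c("upper", "lower", "frequency")`.
#' @return State list with the requested fields redrawn.
#' @export
resample_amplitudes <- function(state, params,
                                what = c("upper", "lower", "frequency")) {
  what <- match.arg(what, several.ok = TRUE)
  if ("upper" %in% what)
    state$amp_upper <- max(0, stats::rnorm(1, params$mu, params$U))
  if ("lower" %in% what)
    state$amp_lower <- max(0, stats::rnorm(1, params$mu, params$L_sd))
  if ("frequency" %in% what)
    state$v_cur <- stats::rnorm(1, params$v, params$v_sd)
  state
}

#' Drive signal of one oscillator
#'
#' Combines offset, radius and pattern output into the joint-angle command
#' `x = c + r_eff * F(theta)`. The effective radius gates the positive and
#' negative excursions of the pattern independently:
#' `r_eff = r * A_U / mu` while `F >= 0` and `r * A_L / mu` while `F < 0`,
#' where `A_U`, `A_L` are the current stochastic bound draws. The switch
#' happens at `F = 0`, so `x` stays continuous. With stochasticity off
#' (`A_U = A_L = mu`) this reduces to `x = c + r * F(theta)`.
#'
#' @param state list with `r`, `theta`, `c` and optionally `amp_upper`,
#'   `amp_lower` (default `mu`: deterministic limit).
#' @param pattern a normalized [fourier_pattern()].
#' @param params the oscillator's [osc_params()].
#' @return Drive signal x (degrees).
#' @export
drive_signal <- function(state, pattern, params) {
  if (!isTRUE(pattern$normalized))
    stop("pattern must be normalized (scaling M applied) before use as a drive",
         call. = FALSE)
  f <- evaluate(pattern, state$theta)
  au <- state$amp_upper %||% params$mu
  al <- state$amp_lower %||% params$mu
  scale <- if (params$mu > 0) ifelse(f >= 0, au, al) / params$mu else 0
  state$c + state$r * scale * f
}

#' Fixed point of the radial Hopf equation by direct integration
#'
#' Integrates the literal radial equation `dr/dt = gamma * (mu^2 - r^2) * r`
#' with RK2 at a step small enough for the stiff Table-scale gains, until
#' `|dr/dt| < tol`, and returns the asymptotic radius (the limit-cycle
#' amplitude `mu` for any positive start).
#'
#' @param params an [osc_params()] object.
#' @param r0 initial radius (> 0).
#' @param dt integration step cap (s); the step is additionally bounded by
#'   the local stability limit `0.2 / (gamma * (mu^2 + 3 r^2))`, so starts
#'   far above `mu` are integrated safely.
#' @param tol convergence tolerance on `|dr/dt|`.
#' @param max_steps safety cap.
#' @return List with `r` (fixed-point radius), `steps` used, and `t` (time).
#' @export
hopf_fixed_point <- function(params, r0 = 1, dt = 1e-5, tol = 1e-9,
                             max_steps = 1e6) {
  stopifnot(r0 > 0)
  g <- params$gamma; mu <- params$mu
  f <- function(r) g * (mu^2 - r^2) * r
  r <- r0
  t <- 0
  for (i in seq_len(max_steps)) {
    if (abs(f(r)) < tol) return(list(r = r, steps = i - 1L, t = t))
    h <- min(dt, 0.2 / (g * (mu^2 + 3 * r^2)))
    k1 <- f(r)
    r_new <- r + h * f(r + 0.5 * h * k1)
    t <- t + h
    if (!is.finite(r_new) || r_new <= 0)
      stop("radial integration left the positive domain: reduce dt",
           call. = FALSE)
    if (r_new == r)   # stationary at machine precision
      return(list(r = r, steps = i, t = t))
    r <- r_new
  }
  stop("no convergence within max_steps", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
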