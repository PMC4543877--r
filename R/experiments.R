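#' Experiment configuration
#'
#' Bundles the settings of one simulated experiment: the proprioceptor
#' condition (intact or hair-field-ablated, differing only in oscillator
#' amplitude and offset), the pattern variant, trial timing and seeds, the
#' phase leads of the sweep protocol, and an optional output directory for
#' CSV/JSON artifacts.
#'
#' @param condition `"intact"` or `"ablated"`.
#' @param variant `"Mc"`, `"Mm"`, `"Mmsd"`, `"triangular"` or
#'   `"augmented"`.
#' @param duration retained trial length (s). Default 60.
#' @param transient discarded settling time (s). Default 5.
#' @param seeds integer vector, one simulated trial per seed.
#' @param phase_leads degrees, the SP-over-HS leads of the sweep protocol.
#' @param outdir optional directory for artifacts (created if needed).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(condition = c("intact", "ablated"),
                              variant = c("Mc", "Mm", "Mmsd", "triangular",
                                          "augmented"),
                              duration = 60, transient = 5, seeds = 1L,
                              phase_leads = c(-40, -20, 0, 10, 20, 40, 60,
                                              90, 180),
                              outdir = NULL) {
  condition <- match.arg(condition)
  variant <- match.arg(variant)
  if (duration <= 0 || transient < 0) stop("invalid timing", call. = FALSE)
  if (!length(seeds)) stop("need at least one seed", call. = FALSE)
  structure(list(condition = condition, variant = variant,
                 duration = duration, transient = transient,
                 seeds = as.integer(seeds), phase_leads = phase_leads,
                 outdir = outdir),
            class = "experiment_config")
}

#' Parameter differences between the intact and ablated networks
#'
#' The ablated condition is defined as a change of the per-joint amplitude
#' `mu` (and its bound SDs) and offset `C` only; every other oscillator
#' and coupling parameter is identical. This helper diffs two resolved
#' networks field by field and is used to assert that contract.
#'
#' @param net_a,net_b two `cpg_network` objects.
#' @return Character vector of oscillator fields that differ (excluding
#'   names), plus `"edges"` if the coupling differs.
#' @export
network_diff_fields <- function(net_a, net_b) {
  fields <- c("v", "mu", "C", "gamma", "gamma_c", "U", "L_sd", "v_sd")
  differing <- character()
  for (f in fields) {
    va <- vapply(net_a$oscillators, `[[`, numeric(1), f)
    vb <- vapply(net_b$oscillators, `[[`, numeric(1), f)
    if (!isTRUE(all.equal(va, vb))) differing <- c(differing, f)
  }
  if (!isTRUE(all.equal(net_a$edges, net_b$edges)))
    differing <- c(differing, "edges")
  differing
}

## Zero the neck oscillation (amplitude and its jitter); phase coupling and
## offset dynamics are untouched.
quiet_neck <- function(network) {
  i <- which(vapply(network$oscillators, `[[`, character(1), "name") == "neck")
  for (j in i) {
    network$oscillators[[j]]$mu <- 0
    network$oscillators[[j]]$U <- 0
    network$oscillators[[j]]$L_sd <- 0
  }
  network
}

analyze_trial <- function(trial) {
  hs <- trial$angles[, "HS_left"]
  sp <- trial$angles[, "SP_left"]
  cg <- sliding_crosscorr(hs, sp, fs = trial$fs)
  f_dom <- dominant_frequency(hs, fs = trial$fs)
  ph <- tryCatch(peak_phase(cg, f_dom), error = function(e) NA_real_)
  shape <- trajectory_shape(trial$tips_left)
  wr_hs <- working_range(hs)
  wr_sp <- working_range(sp)
  list(correlogram = cg, f_dom = f_dom,
       phase_lead = as.numeric(ph),
       peak_lag = if (is.na(ph)) NA_real_ else attr(ph, "lag"),
       peak_correlation = if (is.na(ph)) NA_real_ else
         attr(ph, "peak_correlation"),
       shape_ratio = shape$ratio,
       hs_range = wr_hs, sp_range = wr_sp,
       tracking_rmse = trial$tracking_rmse)
}

#' Run one experimental condition
#'
#' Simulates one trial per seed with the configured condition and pattern
#' variant, applies the standard analysis suite to the left antenna
#' (working ranges, sliding and mean cross-correlogram of SP vs HS, peak
#' phase at the dominant HS frequency, tip-trajectory shape ratio), and
#' optionally writes trajectory CSVs, correlogram CSVs and a JSON summary.
#'
#' @param config an [experiment_config()].
#' @return Object of class `condition_result`: `summary` data frame (one
#'   row per seed), `analyses` and `trials` lists, and the config.
#' @export
run_condition <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  network <- default_network(config$condition)
  patterns <- default_patterns(config$variant)
  analyses <- list(); trials <- list()
  rows <- vector("list", length(config$seeds))
  for (k in seq_along(config$seeds)) {
    sd <- config$seeds[k]
    trial <- simulate_trial(network, patterns, duration = config$duration,
                            transient = config$transient, seed = sd)
    an <- analyze_trial(trial)
    rows[[k]] <- data.frame(
      seed = sd, condition = config$condition, variant = config$variant,
      phase_lead_deg = an$phase_lead, peak_lag_s = an$peak_lag,
      peak_correlation = an$peak_correlation, f_dom_hz = an$f_dom,
      shape_ratio = an$shape_ratio,
      hs_range_lower = an$hs_range$lower, hs_range_upper = an$hs_range$upper,
      hs_range_width = an$hs_range$width,
      sp_range_lower = an$sp_range$lower, sp_range_upper = an$sp_range$upper,
      sp_range_width = an$sp_range$width,
      hs_tracking_rmse = an$tracking_rmse[["HS_left"]],
      sp_tracking_rmse = an$tracking_rmse[["SP_left"]])
    analyses[[k]] <- an
    trials[[k]] <- trial
  }
  res <- structure(list(summary = do.call(rbind, rows), analyses = analyses,
                        trials = trials, config = config),
                   class = "condition_result")
  if (!is.null(config$outdir)) write_condition_artifacts(res, config$outdir)
  res
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("Condition run: %s / %s, %d trial(s) of %g s\n",
              x$config$condition, x$config$variant, nrow(x$summary),
              x$config$duration))
  print(x$summary[, c("seed", "phase_lead_deg", "peak_correlation",
                      "shape_ratio", "hs_range_width", "sp_range_width")],
        row.names = FALSE)
  invisible(x)
}

#' Sweep the SP-over-HS phase lead
#'
#' Re-runs the configured variant with the intra-antennal phase bias set
#' to each requested lead and tabulates the recovered phase and the
#' tip-trajectory shape ratio, the protocol used to probe how far the
#' natural 20-degree lead can be moved before the elliptical exploration
#' pattern degrades.
#'
#' With the natural (`Mc`/`Mm`/`Mmsd`) variants the sweep keeps the full
#' quasi-rhythmic stochasticity and the moving neck. The pure-waveform
#' variants (`triangular`, `augmented`) probe the phase spectrum in
#' isolation: they run noise-free and with a quiescent neck, so that
#' in-phase and anti-phase drive collapse the tip trajectory to a line as
#' the geometry dictates (a yawing head would smear any line into a band).
#' Both protocol switches can be overridden.
#'
#' @param config an [experiment_config()]; `config$phase_leads` gives the
#'   sweep values (degrees), `config$seeds[1]` the seed.
#' @param stochastic override the per-variant default described above.
#' @param neck_still override the per-variant default described above.
#' @return Object of class `phase_sweep_result` with a `table` data frame
#'   (`phase_lead`, `recovered_phase`, `peak_correlation`, `shape_ratio`).
#' @export
run_phase_sweep <- function(config, stochastic = NULL, neck_still = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  patterns <- default_patterns(config$variant)
  waveform <- config$variant %in% c("triangular", "augmented")
  stochastic <- stochastic %||% !waveform
  neck_still <- neck_still %||% waveform
  sd <- config$seeds[1]
  rows <- vector("list", length(config$phase_leads))
  analyses <- list()
  for (k in seq_along(config$phase_leads)) {
    lead <- config$phase_leads[k]
    network <- default_network(config$condition, phase_lead = lead,
                               stochastic = stochastic)
    if (neck_still) network <- quiet_neck(network)
    trial <- simulate_trial(network, patterns, duration = config$duration,
                            transient = config$transient, seed = sd)
    an <- analyze_trial(trial)
    rows[[k]] <- data.frame(phase_lead = lead,
                            recovered_phase = an$phase_lead,
                            peak_correlation = an$peak_correlation,
                            shape_ratio = an$shape_ratio)
    analyses[[k]] <- an
  }
  res <- structure(list(table = do.call(rbind, rows), analyses = analyses,
                        config = config),
                   class = "phase_sweep_result")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$table,
                     file.path(config$outdir,
                               paste0("phase_sweep_", config$variant, ".csv")),
                     row.names = FALSE)
  }
  res
}

#' @export
print.phase_sweep_result <- function(x, ...) {
  cat(sprintf("Phase-lead sweep (%s / %s):\n",
              x$config$condition, x$config$variant))
  print(x$table, row.names = FALSE)
  invisible(x)
}

write_condition_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  stem <- paste(cfg$condition, cfg$variant, sep = "_")
  utils::write.csv(res$summary, file.path(outdir, paste0(stem, "_summary.csv")),
                   row.names = FALSE)
  for (k in seq_along(res$trials)) {
    trial <- res$trials[[k]]
    tag <- paste0(stem, "_seed", cfg$seeds[k])
    write_trajectory_csv(trial, file.path(outdir, paste0(tag, "_traj.csv")))
    cg <- res$analyses[[k]]$correlogram
    cmat <- as.data.frame(t(cg$matrix))       # rows = windows, cols = lags
    names(cmat) <- sprintf("lag_%.2fs", cg$lags)
    cmat <- cbind(window_center_s = cg$centers, cmat)
    utils::write.csv(cmat, file.path(outdir, paste0(tag, "_correlogram.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(config = unclass(cfg)[setdiff(names(unclass(cfg)), "outdir")],
         summary = res$summary),
    file.path(outdir, paste0(stem, "_summary.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Export a trial trajectory to CSV
#'
#' Columns: `time_s`, the five joint angles and their CPG targets
#' (degrees), and the left/right antennal tip coordinates (m).
#'
#' @param trial an [simulate_trial()] result.
#' @param path output file.
#' @export
write_trajectory_csv <- function(trial, path) {
  df <- data.frame(time_s = trial$time)
  ang <- as.data.frame(trial$angles)
  names(ang) <- paste0("angle_", names(ang), "_deg")
  tgt <- as.data.frame(trial$targets)
  names(tgt) <- paste0("target_", names(tgt), "_deg")
  tips <- cbind(as.data.frame(trial$tips_left),
                as.data.frame(trial$tips_right))
  names(tips) <- c("tip_left_x_m", "tip_left_y_m", "tip_left_z_m",
                   "tip_right_x_m", "tip_right_y_m", "tip_right_z_m")
  utils::write.csv(cbind(df, ang, tgt, tips), path, row.names = FALSE)
  invisible(path)
}
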