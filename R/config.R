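#' Default configuration as a nested list
#'
#' The complete parameter set of the model in one structure: oscillator
#' table (per joint: frequency, amplitude with upper/lower bound SDs,
#' offset, gains), coupling weights and phase biases, integration step,
#' skeletal geometry, and servo settings. [write_default_config()] saves
#' it as a YAML file that can be edited and fed back through
#' [read_config()] / [network_from_config()].
#'
#' @return Nested list.
#' @export
default_config <- function() {
  tab_i <- cpg_param_table("intact")
  tab_a <- cpg_param_table("ablated")
  ch <- antenna_chain()
  sv <- servo_config()
  joint_entry <- function(tab, joint, v, v_sd, gamma) {
    j <- tab[[joint]]
    list(frequency_hz = v, frequency_sd_hz = v_sd, amplitude_deg = j$mu,
         upper_sd_deg = j$U, lower_sd_deg = j$L, offset_deg = j$C,
         gamma = gamma)
  }
  list(
    network = list(
      dt_s = 0.005,
      phase_lead_deg = 20,
      coupling = list(intra_antennal_weight = 20, neck_weight = 1,
                      hs_neck_bias_deg = -60),
      intact = list(
        hs = joint_entry(tab_i, "hs", tab_i$v_ant, tab_i$v_ant_sd, tab_i$gamma_ant),
        sp = joint_entry(tab_i, "sp", tab_i$v_ant, tab_i$v_ant_sd, tab_i$gamma_ant),
        neck = joint_entry(tab_i, "neck", tab_i$v_neck, tab_i$v_neck_sd, tab_i$gamma_neck)),
      ablated = list(
        hs = joint_entry(tab_a, "hs", tab_a$v_ant, tab_a$v_ant_sd, tab_a$gamma_ant),
        sp = joint_entry(tab_a, "sp", tab_a$v_ant, tab_a$v_ant_sd, tab_a$gamma_ant),
        neck = joint_entry(tab_a, "neck", tab_a$v_neck, tab_a$v_neck_sd, tab_a$gamma_neck))
    ),
    skeleton = list(
      hs_pivot_m = ch$left$hs_pivot, hs_axis = ch$left$hs_axis,
      sp_pivot_m = ch$left$sp_pivot, sp_axis = ch$left$sp_axis,
      neck_pivot_m = ch$neck$pivot,
      scape_length_mm = ch$segments$scape_length * 1000,
      pedicel_flagellum_length_mm = ch$segments$pedicel_flagellum_length * 1000,
      head_diameter_mm = ch$segments$head_diameter * 1000,
      masses_mg = as.list(ch$masses_mg)
    ),
    servo = list(gain_per_s = sv$K, max_rate_deg_per_s = sv$max_rate),
    pattern = list(window_s = 5.12, harmonics = 16, dominant_bin = 8)
  )
}

#' Read / write the YAML configuration
#'
#' @param path YAML file.
#' @return `read_config()`: nested list merged over the defaults (user
#'   entries override); `write_default_config()`: the path, invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(default_config(), user)
}

#' @rdname read_config
#' @export
write_default_config <- function(path) {
  yaml::write_yaml(default_config(), path)
  invisible(path)
}

merge_lists <- function(base, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user))
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      merge_lists(base[[nm]], user[[nm]]) else user[[nm]]
  base
}

#' Build a network from a configuration list
#'
#' @param config a [read_config()] / [default_config()] list.
#' @param condition `"intact"` or `"ablated"`.
#' @param stochastic logical.
#' @return A `cpg_network`.
#' @export
network_from_config <- function(config, condition = c("intact", "ablated"),
                                stochastic = TRUE) {
  condition <- match.arg(condition)
  nc <- config$network
  jt <- nc[[condition]]
  s <- function(x) if (stochastic) x else 0
  mk <- function(j, C_sign, name) {
    osc_params(j$frequency_hz, j$amplitude_deg, C_sign * j$offset_deg,
               gamma = j$gamma, U = s(j$upper_sd_deg),
               L_sd = s(j$lower_sd_deg), v_sd = s(j$frequency_sd_hz),
               name = name)
  }
  lead <- nc$phase_lead_deg * pi / 180
  bias23 <- nc$coupling$hs_neck_bias_deg * pi / 180
  w_in <- nc$coupling$intra_antennal_weight
  w_nk <- nc$coupling$neck_weight
  osc <- list(mk(jt$sp, 1, "SP_left"), mk(jt$hs, 1, "HS_left"),
              mk(jt$neck, 1, "neck"), mk(jt$hs, -1, "HS_right"),
              mk(jt$sp, -1, "SP_right"))
  edges <- data.frame(a = c(1L, 2L, 3L, 4L), b = c(2L, 3L, 4L, 5L),
                      phi = c(-lead, bias23, pi - bias23, lead),
                      w_ab = c(w_in, w_nk, w_nk, w_in),
                      w_ba = c(w_in, w_nk, w_nk, w_in))
  structure(list(oscillators = osc, edges = edges, dt = nc$dt_s,
                 condition = condition, stochastic = stochastic,
                 phase_lead = nc$phase_lead_deg),
            class = "cpg_network")
}
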