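#' Head-antenna kinematic chain
#'
#' Builds the skeletal model of the stick-insect head and antennae: a neck
#' yaw hinge with vertical axis, and per antenna a head-scape (HS) and a
#' scape-pedicel (SP) hinge with slanted, non-orthogonal axes. Pivot
#' positions and rotation axes are given in the external frame for the
#' initial posture, in which both antennae are outstretched in the
#' horizontal plane, pointing 10 degrees medially from straight ahead, and
#' the head centre sits at the origin. Left-side values are tabulated; the
#' right side is the mirror image across the sagittal plane y = 0 (pivot
#' and axis y-components negated), so a mirrored posture corresponds to
#' sign-inverted right joint angles.
#'
#' Joint angle zero is the initial posture; positive rotation follows the
#' right-hand rule about the stored axis. Axes and pivots are rigidly
#' attached to their proximal segment and co-rotate with the proximal
#' joints (neck carries both antenna bases; the HS rotation carries the SP
#' axis and pivot).
#'
#' Segment masses are retained as metadata only; the joints are driven as
#' velocity servos and no inertial dynamics are computed.
#'
#' @param medial_angle initial in-plane angle of each antenna relative to
#'   the body axis, degrees medial. Default 10.
#' @return Object of class `antenna_chain`.
#' @export
antenna_chain <- function(medial_angle = 10) {
  unit <- function(v) v / sqrt(sum(v^2))
  mirror <- function(v) v * c(1, -1, 1)
  hs_pivot <- c(0.0174, -0.0083, 0.0100)
  sp_pivot <- c(0.0342, -0.0066, 0.0100)
  hs_axis <- unit(c(-0.1480, 0.8430, 0.5140))
  sp_axis <- unit(c(-0.1530, 0.8690, -0.4690))
  ang <- medial_angle * pi / 180
  structure(list(
    neck = list(pivot = c(-0.015, 0, 0), axis = c(0, 0, 1)),
    left = list(hs_pivot = hs_pivot, hs_axis = hs_axis,
                sp_pivot = sp_pivot, sp_axis = sp_axis,
                distal_dir = c(cos(ang), sin(ang), 0)),
    right = list(hs_pivot = mirror(hs_pivot), hs_axis = mirror(hs_axis),
                 sp_pivot = mirror(sp_pivot), sp_axis = mirror(sp_axis),
                 distal_dir = c(cos(ang), -sin(ang), 0)),
    segments = list(scape_length = 0.017, pedicel_flagellum_length = 0.263,
                    head_diameter = 0.040),
    masses_mg = c(scape = 3.0, pedicel_flagellum = 12.5, head = 200.0)
  ), class = "antenna_chain")
}

## Rodrigues rotation matrix about a unit axis.
rotation_matrix <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  K <- matrix(c(0, -z, y, z, 0, -x, -y, x, 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(axis)
}

#' Forward kinematics of the head-antenna chain
#'
#' Composes the neck, HS and SP rotations (axes and pivots co-rotating
#' with their proximal joints) and returns the antennal tip positions:
#' `tip = SP pivot (transformed) + pedicel-flagellum length along the
#' transformed distal direction`.
#'
#' @param pose named numeric vector or list of joint angles in degrees:
#'   `neck`, `hs_left`, `sp_left`, `hs_right`, `sp_right` (missing entries
#'   default to 0).
#' @param chain an [antenna_chain()].
#' @return List with `tip_left`, `tip_right`, `sp_pivot_left`,
#'   `sp_pivot_right`, `hs_pivot_left`, `hs_pivot_right` (m, external
#'   frame).
#' @examples
#' fk <- forward_kinematics(c(neck = 0, hs_left = 0, sp_left = 0), antenna_chain())
#' fk$tip_left  # ~ (0.2932, 0.0391, 0.0100) m at the initial posture
#' @export
forward_kinematics <- function(pose, chain = antenna_chain()) {
  p <- c(neck = 0, hs_left = 0, sp_left = 0, hs_right = 0, sp_right = 0)
  pose <- unlist(pose)
  if (length(pose)) {
    if (is.null(names(pose)) || any(!nzchar(names(pose))))
      stop("pose must be a named vector of joint angles", call. = FALSE)
    unknown <- setdiff(names(pose), names(p))
    if (length(unknown))
      stop("unknown joint name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(pose)] <- pose
  }
  if (any(!is.finite(p))) stop("non-finite joint angles", call. = FALSE)
  deg <- pi / 180
  Rn <- rotation_matrix(chain$neck$axis, p[["neck"]] * deg)
  pn <- chain$neck$pivot
  side_fk <- function(side, hs_ang, sp_ang) {
    hs_pivot <- pn + drop(Rn %*% (side$hs_pivot - pn))
    hs_axis <- drop(Rn %*% side$hs_axis)
    Rh <- rotation_matrix(hs_axis, hs_ang * deg)
    sp_pivot0 <- pn + drop(Rn %*% (side$sp_pivot - pn))
    sp_pivot <- hs_pivot + drop(Rh %*% (sp_pivot0 - hs_pivot))
    sp_axis <- drop(Rh %*% Rn %*% side$sp_axis)
    Rs <- rotation_matrix(sp_axis, sp_ang * deg)
    dir <- drop(Rs %*% Rh %*% Rn %*% side$distal_dir)
    list(hs_pivot = hs_pivot, sp_pivot = sp_pivot,
         tip = sp_pivot + chain$segments$pedicel_flagellum_length * dir)
  }
  l <- side_fk(chain$left, p[["hs_left"]], p[["sp_left"]])
  r <- side_fk(chain$right, p[["hs_right"]], p[["sp_right"]])
  list(tip_left = l$tip, tip_right = r$tip,
       sp_pivot_left = l$sp_pivot, sp_pivot_right = r$sp_pivot,
       hs_pivot_left = l$hs_pivot, hs_pivot_right = r$hs_pivot)
}

#' Velocity-servo configuration
#'
#' The joints are abstracted as velocity-controlled servo motors: the
#' angular velocity is proportional to the error between the CPG drive
#' (target angle) and the current angle, clamped at a maximum rate that
#' stands in for the motor torque limit. The default gain keeps the
#' tracking RMSE of the standard intact run well below the working range
#' (about 1 degree for the HS joint).
#'
#' @param K proportional gain (1/s, > 0). `K * dt` must stay below 2 for a
#'   stable discrete update at the integration step.
#' @param max_rate angular rate limit (degrees/s).
#' @return Object of class `servo_config`.
#' @export
servo_config <- function(K = 350, max_rate = 2500) {
  if (K <= 0) stop("servo gain K must be positive", call. = FALSE)
  if (max_rate <= 0) stop("max_rate must be positive", call. = FALSE)
  structure(list(K = K, max_rate = max_rate), class = "servo_config")
}

#' One servo update step
#'
#' `velocity = clamp(K * (target - current), +/- max_rate)`;
#' `next = current + velocity * dt`. For a constant target and no
#' clamping the error decays geometrically with factor `1 - K * dt`.
#'
#' @param current,target angles (degrees; vectorized).
#' @param config a [servo_config()].
#' @param dt step (s, > 0).
#' @return Updated angle(s), degrees.
#' @export
servo_step <- function(current, target, config = servo_config(), dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  v <- pmin(pmax(config$K * (target - current), -config$max_rate),
            config$max_rate)
  current + v * dt
}
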