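#' Delta robot geometry
#'
#' Dimensions of the 3-arm delta parallel robot: fixed and moving platform
#' radii, proximal and distal link lengths, and actuated joint limits. The
#' robot is mounted above the arena with arms reaching down; joint angle 0
#' means the proximal link is horizontal and positive angles rotate it
#' upward, so the default limit range [-90, +45] degrees spans mostly-down
#' postures.
#'
#' @param r_fixed Fixed platform radius (m).
#' @param r_moving Moving platform radius (m).
#' @param len_proximal Proximal (actuated) link length (m).
#' @param len_distal Distal (parallelogram) link length (m).
#' @param joint_limit_low,joint_limit_high Actuated joint limits (degrees).
#' @return An object of class `delta_geometry`.
#' @examples
#' geom <- delta_geometry()
#' geom$len_distal
#' @export
delta_geometry <- function(r_fixed = 0.19, r_moving = 0.1,
                           len_proximal = 0.34, len_distal = 0.656,
                           joint_limit_low = -90, joint_limit_high = 45) {
  stopifnot(r_fixed > 0, r_moving > 0, len_proximal > 0, len_distal > 0,
            joint_limit_low < joint_limit_high)
  structure(list(r_fixed = r_fixed, r_moving = r_moving,
                 len_proximal = len_proximal, len_distal = len_distal,
                 joint_limit_low = joint_limit_low,
                 joint_limit_high = joint_limit_high),
            class = "delta_geometry")
}

#' Goniometer geometry
#'
#' The serial rotation stage hanging below the delta robot's moving platform.
#' All three rotation axes intersect at a common point offset `offset_a1`
#' below the platform center; the virtual pivot (the mouse's head) extends a
#' further `pivot_extension_a4` from that point. Rotation order is pitch
#' (about the mouse's lateral axis), then roll, then yaw about the vertical
#' through the pivot, so pure yaw spins the headstage without translating
#' the pivot (the yaw axis carries a slip ring and supports unbounded
#' rotation).
#'
#' @param offset_a1 Platform center to common rotation point (m).
#' @param pivot_extension_a4 Rotation point to virtual pivot (m).
#' @return An object of class `goniometer_geometry`.
#' @export
goniometer_geometry <- function(offset_a1 = 0.1, pivot_extension_a4 = 0.25) {
  stopifnot(offset_a1 > 0, pivot_extension_a4 > 0)
  structure(list(offset_a1 = offset_a1,
                 pivot_extension_a4 = pivot_extension_a4,
                 rotation_order = c("pitch", "roll", "yaw")),
            class = "goniometer_geometry")
}

#' Joint configuration of the full mechanism
#'
#' @param delta_angles Three actuated delta joint angles (rad).
#' @param gonio_angles Three goniometer angles (pitch, roll, yaw; rad). Yaw
#'   is an accumulated angle and may exceed +/- pi.
#' @return An object of class `joint_config`.
#' @export
joint_config <- function(delta_angles = c(0, 0, 0),
                         gonio_angles = c(0, 0, 0)) {
  stopifnot(length(delta_angles) == 3, length(gonio_angles) == 3,
            all(is.finite(delta_angles)), all(is.finite(gonio_angles)))
  structure(list(delta_angles = as.numeric(delta_angles),
                 gonio_angles = as.numeric(gonio_angles)),
            class = "joint_config")
}

#' Read or write a geometry configuration file
#'
#' Flat YAML with keys `r_fixed_m`, `r_moving_m`, `len_proximal_m`,
#' `len_distal_m`, `joint_limit_low_deg`, `joint_limit_high_deg`,
#' `offset_a1_m`, `pivot_extension_a4_m`. The packaged default
#' (`exoskeleton_default.yaml` under `extdata`) holds the as-built
#' dimensions.
#'
#' @param path File path; `read_geometry_config(NULL)` loads the packaged
#'   default.
#' @return A list with elements `delta` (a `delta_geometry`) and `gonio`
#'   (a `goniometer_geometry`).
#' @export
read_geometry_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "exoskeleton_default.yaml",
                        package = "exotwin", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  list(
    delta = delta_geometry(cfg$r_fixed_m, cfg$r_moving_m, cfg$len_proximal_m,
                           cfg$len_distal_m, cfg$joint_limit_low_deg,
                           cfg$joint_limit_high_deg),
    gonio = goniometer_geometry(cfg$offset_a1_m, cfg$pivot_extension_a4_m)
  )
}

#' @rdname read_geometry_config
#' @param delta,gonio Geometry objects to serialize.
#' @export
write_geometry_config <- function(delta, gonio, path) {
  yaml::write_yaml(list(
    r_fixed_m = delta$r_fixed, r_moving_m = delta$r_moving,
    len_proximal_m = delta$len_proximal, len_distal_m = delta$len_distal,
    joint_limit_low_deg = delta$joint_limit_low,
    joint_limit_high_deg = delta$joint_limit_high,
    offset_a1_m = gonio$offset_a1,
    pivot_extension_a4_m = gonio$pivot_extension_a4), path)
  invisible(path)
}

# arm azimuth unit vectors; arm i lies in the vertical plane through u_i
arm_azimuths <- function() {
  phi <- c(0, 2, 4) * pi / 3
  cbind(cos(phi), sin(phi))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
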