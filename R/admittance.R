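#' Admittance controller parameters
#'
#' Virtual mass and damping per mouse-relevant axis (x forward, y lateral,
#' yaw), the force dead-bands that reject sensor noise and slip-ring drift,
#' the forward velocity limit, and the discrete cycle time. The mass and
#' damping defaults are plausible-tuned values in the range the behavioral
#' tuning converged to; the robot's published constants are the dead-bands
#' (25 mN in x and y, 0.3 mN m in yaw), the 16 cm/s forward limit, and the
#' 100 Hz cycle.
#'
#' @param virtual_mass Numeric(3): kg (x), kg (y), kg m^2 (yaw).
#' @param virtual_damping Numeric(3): N s/m (x, y), N m s/rad (yaw).
#' @param deadband Numeric(3): N (x, y), N m (yaw).
#' @param velocity_limit_forward m/s, cap on the commanded forward velocity.
#' @param cycle_time s, controller cycle (10 ms).
#' @param deadband_mode "subtract" (continuous: output is
#'   sign(F) * (|F| - threshold) outside the band) or "passthrough" (raw
#'   force outside the band).
#' @param inner_lag_tau s, time constant of the first-order lag that stands
#'   in for the tuned inner velocity/current loops.
#' @return An object of class `admittance_params`.
#' @export
admittance_params <- function(virtual_mass = c(0.2, 0.2, 0.005),
                              virtual_damping = c(1.5, 1.5, 0.02),
                              deadband = c(0.025, 0.025, 3e-4),
                              velocity_limit_forward = 0.16,
                              cycle_time = 0.01,
                              deadband_mode = c("subtract", "passthrough"),
                              inner_lag_tau = 0.005) {
  stopifnot(all(virtual_mass > 0), all(virtual_damping >= 0),
            all(deadband >= 0), cycle_time > 0, velocity_limit_forward > 0,
            inner_lag_tau >= 0)
  structure(list(virtual_mass = virtual_mass,
                 virtual_damping = virtual_damping,
                 deadband = deadband,
                 velocity_limit_forward = velocity_limit_forward,
                 cycle_time = cycle_time,
                 deadband_mode = match.arg(deadband_mode),
                 inner_lag_tau = inner_lag_tau),
            class = "admittance_params")
}

#' A 6-axis force sensor reading
#'
#' @param force Numeric(3) force (N), sensor frame.
#' @param torque Numeric(3) torque (N m), sensor frame.
#' @param timestamp s.
#' @return An object of class `force_reading`.
#' @export
force_reading <- function(force = c(0, 0, 0), torque = c(0, 0, 0),
                          timestamp = 0) {
  stopifnot(all(is.finite(force)), all(is.finite(torque)))
  structure(list(force = force, torque = torque, timestamp = timestamp),
            class = "force_reading")
}

#' Dead-band on the mouse-relevant force axes
#'
#' Forces inside the closed band (|F| <= threshold) map to zero. Outside,
#' the default subtracts the threshold so the output is continuous at the
#' band edge; `deadband_mode = "passthrough"` reproduces the discontinuous
#' alternative.
#'
#' @param reading A [force_reading()], or numeric(3) of (Fx, Fy, Tz).
#' @param params An [admittance_params()].
#' @return Numeric(3): dead-banded (Fx, Fy, Tz).
#' @export
apply_deadband <- function(reading, params = admittance_params()) {
  f <- if (inherits(reading, "force_reading")) {
    c(reading$force[1:2], reading$torque[3])
  } else as.numeric(reading)
  th <- params$deadband
  out <- numeric(3)
  live <- abs(f) > th
  if (params$deadband_mode == "subtract") {
    out[live] <- sign(f[live]) * (abs(f[live]) - th[live])
  } else {
    out[live] <- f[live]
  }
  out
}

#' Transform a sensor-frame force into the mouse's frame
#'
#' Planar rotation by the negative of the accumulated yaw; the yaw torque is
#' about the (shared) vertical axis and passes through unchanged.
#'
#' @param reading A [force_reading()] or numeric(3) (Fx, Fy, Tz).
#' @param yaw Accumulated yaw angle (rad).
#' @return Numeric(3): (Fx, Fy, Tz) in the mouse frame.
#' @export
force_to_mouse_frame <- function(reading, yaw) {
  f <- if (inherits(reading, "force_reading")) {
    c(reading$force[1:2], reading$torque[3])
  } else as.numeric(reading)
  ca <- cos(-yaw); sa <- sin(-yaw)
  c(ca * f[1] - sa * f[2], sa * f[1] + ca * f[2], f[3])
}

#' Controller state
#'
#' @param pose Numeric named or plain vector (x, y, yaw) -- the planar
#'   mouse-frame-relevant part of the pivot pose.
#' @param velocity Numeric(3) commanded velocity per axis.
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(pose = c(0, 0, 0), velocity = c(0, 0, 0)) {
  structure(list(pose = as.numeric(pose), velocity = as.numeric(velocity),
                 target_pose = as.numeric(pose),
                 target_velocity = as.numeric(velocity)),
            class = "controller_state")
}

#' One discrete admittance step
#'
#' Per axis: target acceleration a = (F - c v) / m, explicit-Euler
#' integration to a target velocity (clipped to the axis limits) and then to
#' a target position -- the "double integration" of the 100 Hz loop.
#'
#' @param force_mouse Numeric(3) dead-banded mouse-frame (Fx, Fy, Tz).
#' @param state A [controller_state()].
#' @param params An [admittance_params()].
#' @param dt Step (s); defaults to the controller cycle time.
#' @param allow_backward If FALSE the commanded forward velocity is clamped
#'   at >= 0 (arena modes with the backwards direction disabled).
#' @param lateral_yaw_enabled If FALSE the y and yaw commands are zeroed
#'   (oval track and goal arms, where a trajectory servo owns those axes).
#' @return Updated `controller_state`; `target_velocity` holds the
#'   commanded velocities.
#' @export
admittance_step <- function(force_mouse, state, params = admittance_params(),
                            dt = params$cycle_time, allow_backward = TRUE,
                            lateral_yaw_enabled = TRUE) {
  stopifnot(dt > 0)
  m <- params$virtual_mass; cc <- params$virtual_damping
  v <- state$target_velocity
  a <- (force_mouse - cc * v) / m
  v <- v + a * dt
  lim <- params$velocity_limit_forward
  v[1] <- min(v[1], lim)
  if (!allow_backward) v[1] <- max(v[1], 0) else v[1] <- max(v[1], -lim)
  if (!lateral_yaw_enabled) v[2:3] <- 0
  state$target_velocity <- v
  state$target_pose <- state$target_pose + v * dt
  state
}

#' Proportional(-integral-derivative) position loop
#'
#' The outer loop that turns target-vs-actual pose error into an
#' operational-space velocity command. Gains default to P-only.
#'
#' @param target_pose,actual_pose Numeric vectors of equal length.
#' @param gains List with `kp`, and optionally `ki`, `kd` and `state` (the
#'   integrator/previous-error memory returned by a previous call).
#' @param dt Step (s).
#' @return Numeric velocity command with attribute `gains` carrying the
#'   updated loop memory.
#' @export
position_loop_step <- function(target_pose, actual_pose, gains = list(kp = 20),
                               dt = 0.01) {
  err <- target_pose - actual_pose
  kp <- gains$kp %||% 0
  ki <- gains$ki %||% 0
  kd <- gains$kd %||% 0
  integ <- gains$state$integ %||% numeric(length(err))
  prev <- gains$state$prev %||% err
  integ <- integ + err * dt
  cmd <- kp * err + ki * integ + kd * (err - prev) / dt
  gains$state <- list(integ = integ, prev = err)
  attr(cmd, "gains") <- gains
  cmd
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-loop simulation of a virtual mouse driving the exoskeleton
#'
#' Composes, at 100 samples/s: virtual-mouse intent, the muscle model
#' turning the intent-vs-actual velocity mismatch into head forces, the
#' force dead-band, the admittance law, arena-mode constraints, and a
#' first-order inner-loop lag from commanded to actual velocity.
#'
#' @param arena An arena from [arena_oval()], [arena_eightmaze()], or
#'   [arena_open()].
#' @param params An [admittance_params()].
#' @param mouse A [virtual_mouse()] handle.
#' @param duration s.
#' @param seed Integer seed; identical seeds give identical logs.
#' @return A session log data.frame (see [write_session_log()] for the
#'   column schema).
#' @export
run_closed_loop <- function(arena, params = admittance_params(),
                            mouse = virtual_mouse(), duration = 60,
                            seed = 1) {
  stopifnot(duration > 0)
  dt <- params$cycle_time
  intent <- generate_intent(duration, mouse$calibration, seed)
  n <- nrow(intent)
  if (n == 0) stop("virtual mouse produced an empty intent series")
  st <- controller_state(pose = arena$start_pose)
  v_act <- c(0, 0, 0)   # actual mouse-frame velocity after inner lag
  alpha <- if (params$inner_lag_tau > 0) dt / (params$inner_lag_tau + dt) else 1
  pose <- arena$start_pose  # global x, y, yaw
  out <- data.frame(t_s = intent$t, x_m = 0, y_m = 0, z_m = arena$z_m,
                    pitch_rad = arena$pitch_rad, roll_rad = 0, yaw_rad = 0,
                    fx_N = 0, fy_N = 0, tz_Nm = 0,
                    vcmd_x = 0, vcmd_y = 0, vcmd_yaw = 0,
                    zone = "", event = "", stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    v_int <- c(intent$vx[k], intent$vy[k], intent$vyaw[k])
    f_raw <- muscle_force(v_int, v_act, mouse$muscle)
    f <- apply_deadband(f_raw, params)
    zone <- arena_zone(arena, pose)
    st <- admittance_step(f, st, params, dt,
                          allow_backward = zone$allow_backward,
                          lateral_yaw_enabled = zone$lateral_yaw_enabled)
    vcmd <- st$target_velocity
    vcmd <- arena_constrain(arena, pose, vcmd, zone, dt)
    v_act <- v_act + alpha * (vcmd - v_act)
    pose <- arena_advance(arena, pose, v_act, dt)
    st$target_velocity <- v_act  # admittance law sees realized velocity
    out$x_m[k] <- pose[1]; out$y_m[k] <- pose[2]; out$yaw_rad[k] <- pose[3]
    out$fx_N[k] <- f[1]; out$fy_N[k] <- f[2]; out$tz_Nm[k] <- f[3]
    out$vcmd_x[k] <- vcmd[1]; out$vcmd_y[k] <- vcmd[2]
    out$vcmd_yaw[k] <- vcmd[3]
    out$zone[k] <- zone$label
  }
  out
}

#' Write or read a session log
#'
#' CSV with header columns `t_s, x_m, y_m, z_m, pitch_rad, roll_rad,
#' yaw_rad, fx_N, fy_N, tz_Nm, vcmd_x, vcmd_y, vcmd_yaw, zone, event`
#' at 100 samples/s, or a compact binary container (RDS) with the identical
#' schema.
#'
#' @param log Session log data.frame.
#' @param path Output path.
#' @param format "csv" or "rds".
#' @return `path`, invisibly (writer); the data.frame (reader).
#' @export
write_session_log <- function(log, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(log, path, row.names = FALSE)
  } else {
    saveRDS(log, path)
  }
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    readRDS(path)
  }
}
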