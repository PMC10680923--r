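#' Arena models
#'
#' `arena_open()` is an unconstrained planar arena used for free-behavior
#' emulation. `arena_oval()` is the linear oval track: two 27 cm straights
#' joined by semicircles of 33 cm outer-wall diameter, with the controlled
#' path held 3 cm inside the outer wall (corner radius 13.5 cm). The mouse
#' owns its forward axis (backwards disabled); a trajectory servo owns the
#' lateral and yaw axes. `arena_eightmaze()` is the figure-8 maze: two
#' circular goal arms of 36 cm outer and 20 cm inner wall diameter (8 cm
#' channel, centerline radius 14 cm), a triangular turning zone where the
#' mouse controls x, y, and yaw within position and yaw limits, and a
#' 1 cm x 3 cm transition zone at the turning-zone entry where lateral and
#' yaw velocities ramp to zero. Turning-zone triangle vertices and
#' door/beam positions are configuration with documented defaults.
#'
#' @param start_pose Numeric(3) global (x, y, yaw) at session start.
#' @param z_m,pitch_rad Constant pivot height and pitch logged with
#'   sessions (pitch default 20 degrees, the fixed posture).
#' @return An arena object (classes `exo_arena` plus a kind class).
#' @export
arena_open <- function(start_pose = c(0, 0, 0), z_m = -0.55,
                       pitch_rad = deg2rad(20)) {
  structure(list(kind = "open", start_pose = start_pose, z_m = z_m,
                 pitch_rad = pitch_rad),
            class = c("exo_arena_open", "exo_arena"))
}

#' @rdname arena_open
#' @param straight_m,outer_diameter_m,wall_offset_m Oval-track outer-wall
#'   dimensions and the controlled path's offset inside the outer wall.
#' @export
arena_oval <- function(straight_m = 0.27, outer_diameter_m = 0.33,
                       wall_offset_m = 0.03, z_m = -0.55,
                       pitch_rad = deg2rad(20)) {
  r <- outer_diameter_m / 2 - wall_offset_m
  h <- straight_m / 2
  segs <- list(
    path_segment_line(c(-h, -r), c(h, -r)),
    path_segment_arc(c(h, 0), r, -pi / 2, pi / 2, ccw = TRUE),
    path_segment_line(c(h, r), c(-h, r)),
    path_segment_arc(c(-h, 0), r, pi / 2, 3 * pi / 2, ccw = TRUE))
  path <- make_path(segs)
  start <- path_point(path, 0)
  structure(list(kind = "oval", path = path, corner_radius_m = r,
                 straight_m = straight_m, wall_height_m = 0.05,
                 start_pose = c(start$xy, start$heading),
                 z_m = z_m, pitch_rad = pitch_rad),
            class = c("exo_arena_oval", "exo_arena"))
}

#' @rdname arena_open
#' @param outer_wall_m,inner_wall_m Goal-arm wall diameters.
#' @param turning_zone_length_m Apex-to-base length of the triangular
#'   turning zone.
#' @param turning_zone_base_m Base width where the zone meets the arms.
#' @param transition_zone_m Numeric(2): width and length of the transition
#'   zone at the turning-zone entry.
#' @export
arena_eightmaze <- function(outer_wall_m = 0.36, inner_wall_m = 0.20,
                            turning_zone_length_m = 0.08,
                            turning_zone_base_m = 0.08,
                            transition_zone_m = c(0.01, 0.03),
                            z_m = -0.55, pitch_rad = deg2rad(20)) {
  channel <- (outer_wall_m - inner_wall_m) / 2
  r_center <- (outer_wall_m + inner_wall_m) / 4  # centerline radius
  apex <- c(0, -turning_zone_length_m / 2)
  base_y <- turning_zone_length_m / 2
  tri <- rbind(apex,
               c(turning_zone_base_m / 2, base_y),
               c(-turning_zone_base_m / 2, base_y))
  # goal-arm circles meeting at the turning-zone top center
  arm_left <- list(center = c(-r_center, base_y), radius = r_center,
                   ccw = FALSE)
  arm_right <- list(center = c(r_center, base_y), radius = r_center,
                    ccw = TRUE)
  # the arms' first few cm run inside the turning zone (the zone IS the
  # overlap); the linearized path skips that stretch
  u <- seq(0, pi * r_center, by = 5e-4)
  pts <- cbind(r_center * cos(-u / r_center) - r_center,
               base_y + r_center * sin(-u / r_center))
  inside <- vapply(seq_along(u), function(i) {
    point_in_convex(pts[i, ], tri, tol = 1e-12)
  }, logical(1))
  arm_cut <- if (any(!inside)) u[which(!inside)[1]] else 0
  structure(list(kind = "eightmaze",
                 outer_wall_m = outer_wall_m, inner_wall_m = inner_wall_m,
                 channel_width_m = channel, arm_radius_m = r_center,
                 turning_zone = tri, turning_zone_entry = apex,
                 transition_zone = list(
                   width_m = transition_zone_m[1],
                   length_m = transition_zone_m[2],
                   y_lo = apex[2] - transition_zone_m[2], y_hi = apex[2]),
                 arm_left = arm_left, arm_right = arm_right,
                 arm_cut_m = arm_cut,
                 start_pose = c(0, apex[2] - transition_zone_m[2] - 0.05,
                                pi / 2),
                 z_m = z_m, pitch_rad = pitch_rad),
            class = c("exo_arena_eightmaze", "exo_arena"))
}

#' Channel width of the 8-maze goal arms
#'
#' Derived from the wall diameters: (outer - inner) / 2.
#' @param arena An [arena_eightmaze()].
#' @return Width (m).
#' @export
channel_width <- function(arena) {
  (arena$outer_wall_m - arena$inner_wall_m) / 2
}

#' Yaw limit inside the turning zone
#'
#' Scales linearly from +/-20 to +/-45 degrees across the first 5 cm of
#' penetration into the zone and stays at +/-45 degrees beyond.
#'
#' @param penetration_m Depth into the turning zone from its entry (m).
#' @param ramp_m Ramp length (m).
#' @return Limit magnitude (rad).
#' @export
turning_zone_yaw_limit <- function(penetration_m, ramp_m = 0.05) {
  d <- pmin(pmax(penetration_m, 0), ramp_m)
  deg2rad(20 + 25 * d / ramp_m)
}

#' Vector path correction onto a circular trajectory
#'
#' The admittance output in a goal arm is a forward velocity tangent to the
#' circular trajectory, which alone would walk the integrated position off
#' the circle. The correction re-terminates the velocity vector so the end
#' position after `dt` lies on the arc.
#'
#' @param position Numeric(2) current position (on or near the arc).
#' @param velocity Numeric(2) proposed planar velocity (m/s).
#' @param arc List with `center` (numeric(2)) and `radius`.
#' @param dt Integration step (s).
#' @return Corrected numeric(2) velocity whose endpoint lies on the arc.
#' @export
path_correct_velocity <- function(position, velocity, arc, dt = 0.01) {
  stopifnot(arc$radius > 0)
  if (all(velocity == 0)) return(c(0, 0))
  q <- position + velocity * dt
  v <- q - arc$center
  d <- sqrt(sum(v^2))
  if (d < .Machine$double.eps) {
    stop("undefined projection: proposed endpoint at the arc center")
  }
  q_on <- arc$center + arc$radius * v / d
  (q_on - position) / dt
}

#' Trajectory servo for the lateral and yaw axes in a goal arm
#'
#' Drives the radial error and the yaw misalignment with the arm tangent
#' toward zero. The yaw error is formed from heading vectors (equivalently,
#' the mouse yaw is rotated by the global arm angle before the error is
#' taken), so the computation is continuous across the +/-pi wrap.
#'
#' @param position Numeric(2) global position.
#' @param yaw Mouse yaw (rad, accumulated).
#' @param arc List with `center`, `radius`, and `ccw` (direction of
#'   travel).
#' @param gains List with `k_y` (1/s) and `k_yaw` (1/s).
#' @return List: `v_lateral` (mouse-frame lateral velocity command, m/s;
#'   positive is leftward), `v_yaw` (rad/s), `radial_error` (m, positive
#'   outward), `yaw_error` (sin of the tangent misalignment).
#' @export
trajectory_servo_y_yaw <- function(position, yaw, arc,
                                   gains = list(k_y = 2, k_yaw = 2)) {
  v <- position - arc$center
  d <- sqrt(sum(v^2))
  e_r <- d - arc$radius
  # tangent heading at the mouse's angular station
  a <- atan2(v[2], v[1])
  heading_t <- if (arc$ccw) a + pi / 2 else a - pi / 2
  # wrap-free error: sine of the angle between heading vectors
  s_err <- sin(yaw) * cos(heading_t) - cos(yaw) * sin(heading_t)
  # for ccw travel the center lies to the left: outward error -> move left
  v_lat <- (if (arc$ccw) 1 else -1) * gains$k_y * e_r
  list(v_lateral = v_lat,
       v_yaw = -gains$k_yaw * s_err,
       radial_error = e_r,
       yaw_error = s_err)
}

# signed area test: is p inside the (convex, ccw or cw) polygon
point_in_convex <- function(p, poly, tol = 1e-12) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1, ]
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cr) <= tol) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

# largest t in [0, 1] with p + t*step inside the convex polygon
clip_step_to_convex <- function(p, step, poly) {
  n <- nrow(poly)
  # polygon orientation
  area <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1, ]
    area <- area + a[1] * b[2] - b[1] * a[2]
  }
  orient <- sign(area)
  tmax <- 1
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1, ]
    nrm <- orient * c(-(b[2] - a[2]), b[1] - a[1])  # inward normal
    denom <- sum(nrm * step)
    num <- sum(nrm * (p - a))
    if (denom < 0) {
      t_hit <- -num / denom
      tmax <- min(tmax, max(0, t_hit))
    }
  }
  tmax
}

#' One controller step inside the turning zone
#'
#' Scales the proposed position step (direction preserved) so the end
#' position cannot cross the zone boundary, and clamps yaw to the ramped
#' limit for the current penetration depth.
#'
#' @param position Numeric(2), must be inside the zone.
#' @param proposed_step Numeric(2) position increment (m).
#' @param yaw Proposed yaw (rad, relative to the zone's forward direction).
#' @param arena An [arena_eightmaze()].
#' @return List: `position` (clamped end position), `yaw` (clamped),
#'   `step_scale` (fraction of the proposed step retained),
#'   `yaw_limit` (rad).
#' @export
turning_zone_step <- function(position, proposed_step, yaw, arena) {
  tri <- arena$turning_zone
  if (!point_in_convex(position, tri, tol = 1e-9)) {
    stop("turning_zone_step called with start position outside the zone")
  }
  scale <- clip_step_to_convex(position, proposed_step, tri)
  endp <- position + scale * proposed_step
  pen <- endp[2] - arena$turning_zone_entry[2]
  lim <- turning_zone_yaw_limit(pen)
  list(position = endp,
       yaw = min(max(yaw, -lim), lim),
       step_scale = scale,
       yaw_limit = lim)
}

#' Transition-zone velocity blend
#'
#' Across the 3 cm transition zone the lateral and yaw velocities ramp
#' linearly to exactly zero (cosine ramp available) so the mouse enters the
#' turning zone moving purely forward. The forward component is untouched.
#'
#' @param velocities Numeric(3) (forward, lateral, yaw).
#' @param progress Fraction of the zone traversed, in [0, 1].
#' @param ramp "linear" or "cosine".
#' @return Numeric(3) blended velocities.
#' @export
transition_zone_blend <- function(velocities, progress,
                                  ramp = c("linear", "cosine")) {
  stopifnot(progress >= 0, progress <= 1)
  ramp <- match.arg(ramp)
  g <- if (ramp == "linear") 1 - progress else (1 + cos(pi * progress)) / 2
  if (progress >= 1) g <- 0
  c(velocities[1], velocities[2] * g, velocities[3] * g)
}

#' Cue timeline for the decision task
#'
#' Left-turn cue: one 5 kHz tone of 4 s. Right-turn cue: four short 5 kHz
#' tones, 0.75 s ON / 0.25 s OFF.
#'
#' @param direction "left" or "right".
#' @return data.frame with `on_s`, `off_s` tone intervals (relative to cue
#'   onset) and a `freq_hz` column.
#' @export
cue_timeline <- function(direction = c("left", "right")) {
  direction <- match.arg(direction)
  if (direction == "left") {
    data.frame(on_s = 0, off_s = 4, freq_hz = 5000)
  } else {
    on <- (0:3) * 1.0
    data.frame(on_s = on, off_s = on + 0.75, freq_hz = 5000)
  }
}

#' Task engine for the 8-maze
#'
#' Bookkeeping of the turn-training and decision modes: door commands, cue
#' activation at the goal-arm end beams, reward (8 uL) on correct and a 3 s
#' air puff on incorrect choices, and trial records. In decision mode the
#' cued direction alternates deterministically left/right.
#'
#' @param mode "turn_training" or "decision".
#' @param first_cue Direction cued on the first trial.
#' @return A `task_engine` object. Feed it beam events with
#'   [task_engine_step()]; collect scored trials from `$trials`.
#' @export
task_engine <- function(mode = c("decision", "turn_training"),
                        first_cue = "left") {
  structure(list(mode = match.arg(mode), cued = first_cue,
                 awaiting = "choice", trials = list(), events = list(),
                 trial_index = 1L, voided = 0L),
            class = "task_engine")
}

other_side <- function(side) if (side == "left") "right" else "left"

#' @rdname task_engine
#' @param engine A `task_engine`.
#' @param beam Beam event: list with `type` ("arm_start" or "arm_end") and
#'   `side` ("left"/"right").
#' @param time Event time (s).
#' @return The updated engine; `$commands` holds the commands emitted by
#'   this step (reward/puff/cue/door markers with durations).
#' @export
task_engine_step <- function(engine, beam, time = 0) {
  cmds <- list()
  emit <- function(cmd) cmds[[length(cmds) + 1L]] <<- cmd
  if (beam$type == "arm_start") {
    if (engine$awaiting != "choice") {
      warning("inconsistent beam sequence: arm_start while awaiting return; trial voided")
      engine$voided <- engine$voided + 1L
      engine$awaiting <- "choice"
    } else {
      chosen <- beam$side
      correct <- identical(chosen, engine$cued)
      if (engine$mode == "decision") {
        if (correct) {
          emit(list(type = "reward", volume_ul = 8, t = time))
        } else {
          emit(list(type = "air_puff", duration_s = 3, t = time))
        }
      } else {
        emit(list(type = "training_door", position = engine$cued, t = time))
      }
      emit(list(type = "door_block", side = other_side(chosen), t = time))
      engine$trials[[engine$trial_index]] <- list(
        trial = engine$trial_index, cued = engine$cued, chosen = chosen,
        correct = correct, t_choice = time)
      engine$trial_index <- engine$trial_index + 1L
      engine$awaiting <- "return"
    }
  } else if (beam$type == "arm_end") {
    if (engine$awaiting != "return") {
      warning("inconsistent beam sequence: arm_end without a choice; ignored")
      engine$voided <- engine$voided + 1L
    } else {
      engine$cued <- other_side(engine$cued)
      emit(list(type = "cue", direction = engine$cued,
                timeline = cue_timeline(engine$cued), t = time))
      emit(list(type = "light", side = engine$cued, t = time))
      engine$awaiting <- "choice"
    }
  } else {
    stop("unknown beam event type: ", beam$type)
  }
  engine$commands <- cmds
  engine
}

#' Trial table of a task engine
#'
#' @param engine A `task_engine` after a session.
#' @return data.frame with columns `trial`, `cued`, `chosen`, `correct`,
#'   `t_choice`.
#' @export
trial_table <- function(engine) {
  if (length(engine$trials) == 0) {
    return(data.frame(trial = integer(0), cued = character(0),
                      chosen = character(0), correct = logical(0),
                      t_choice = numeric(0)))
  }
  do.call(rbind, lapply(engine$trials, function(tr) {
    data.frame(trial = tr$trial, cued = tr$cued, chosen = tr$chosen,
               correct = tr$correct, t_choice = tr$t_choice)
  }))
}

# ---- arena dispatch used by run_closed_loop ------------------------------

arena_zone <- function(arena, pose) UseMethod("arena_zone")

#' @export
arena_zone.exo_arena_open <- function(arena, pose) {
  list(label = "open", allow_backward = TRUE, lateral_yaw_enabled = TRUE)
}

#' @export
arena_zone.exo_arena_oval <- function(arena, pose) {
  list(label = "track", allow_backward = FALSE, lateral_yaw_enabled = FALSE)
}

#' @export
arena_zone.exo_arena_eightmaze <- function(arena, pose) {
  p <- pose[1:2]
  tz <- arena$transition_zone
  if (point_in_convex(p, arena$turning_zone, tol = 1e-9)) {
    list(label = "turning", allow_backward = TRUE,
         lateral_yaw_enabled = TRUE)
  } else if (abs(p[1]) <= tz$width_m / 2 && p[2] >= tz$y_lo &&
             p[2] < tz$y_hi) {
    list(label = "transition", allow_backward = FALSE,
         lateral_yaw_enabled = TRUE)
  } else if (p[2] < tz$y_lo - 1e-9) {
    list(label = "treadmill", allow_backward = FALSE,
         lateral_yaw_enabled = FALSE)
  } else {
    side <- if (p[1] < 0) "arm_left" else "arm_right"
    list(label = side, allow_backward = FALSE, lateral_yaw_enabled = FALSE)
  }
}

arena_constrain <- function(arena, pose, vcmd, zone, dt) {
  UseMethod("arena_constrain")
}

#' @export
arena_constrain.exo_arena_open <- function(arena, pose, vcmd, zone, dt) vcmd

#' @export
arena_constrain.exo_arena_oval <- function(arena, pose, vcmd, zone, dt) vcmd

#' @export
arena_constrain.exo_arena_eightmaze <- function(arena, pose, vcmd, zone,
                                                dt) {
  if (zone$label == "transition") {
    tz <- arena$transition_zone
    prog <- (pose[2] - tz$y_lo) / tz$length_m
    vcmd <- transition_zone_blend(vcmd, min(max(prog, 0), 1))
  }
  vcmd
}

arena_advance <- function(arena, pose, v, dt) UseMethod("arena_advance")

#' @export
arena_advance.exo_arena_open <- function(arena, pose, v, dt) {
  yaw <- pose[3]
  dxy <- c(cos(yaw) * v[1] - sin(yaw) * v[2],
           sin(yaw) * v[1] + cos(yaw) * v[2])
  c(pose[1:2] + dxy * dt, yaw + v[3] * dt)
}

#' @export
arena_advance.exo_arena_oval <- function(arena, pose, v, dt) {
  s <- path_project(arena$path, pose[1:2])
  pt <- path_point(arena$path, s + v[1] * dt)
  c(pt$xy, pt$heading)
}

#' @export
arena_advance.exo_arena_eightmaze <- function(arena, pose, v, dt) {
  zone <- arena_zone(arena, pose)
  if (zone$label == "turning") {
    yaw_rel <- pose[3] - pi / 2  # zone forward direction is +y
    dxy <- c(cos(pose[3]) * v[1] - sin(pose[3]) * v[2],
             sin(pose[3]) * v[1] + cos(pose[3]) * v[2]) * dt
    stepped <- turning_zone_step(pose[1:2], dxy, yaw_rel + v[3] * dt, arena)
    c(stepped$position, pi / 2 + stepped$yaw)
  } else if (zone$label %in% c("transition", "treadmill")) {
    c(pose[1], pose[2] + v[1] * dt, pi / 2)
  } else {
    arc <- if (zone$label == "arm_left") arena$arm_left else arena$arm_right
    vfwd <- path_correct_velocity(
      pose[1:2], v[1] * c(cos(pose[3]), sin(pose[3])), arc, dt)
    p <- pose[1:2] + vfwd * dt
    a <- atan2(p[2] - arc$center[2], p[1] - arc$center[1])
    heading <- if (arc$ccw) a + pi / 2 else a - pi / 2
    c(p, heading)
  }
}
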