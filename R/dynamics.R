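#' Inertial parameters of the exoskeleton
#'
#' Lumped point-mass model: each proximal link is lumped at its midpoint,
#' each distal link is split between the elbow and the platform end
#' (`distal_mass_split` at the platform end), and the platform, goniometer
#' links, and payload ride with the moving platform / rotation chain. The
#' link masses shipped as defaults are documented estimates for the
#' carbon-fiber construction; they drive only feasibility margins, never
#' calibration targets. The headstage payload default covers the 1.0-1.5 kg
#' range of the recording headstages.
#'
#' @param proximal_link_mass,distal_link_mass,platform_mass Link masses (kg).
#' @param goniometer_link_masses Numeric(3), masses of the goniometer stages
#'   including their motors (kg).
#' @param payload_mass Headstage mass at the pivot (kg).
#' @param payload_yaw_inertia Rotational inertia of the payload about the
#'   yaw axis (kg m^2); point masses on the yaw axis contribute none, so
#'   this is the only yaw-axis inertia in the lumped model.
#' @param gravity Gravitational acceleration (m/s^2).
#' @param distal_mass_split Fraction of each distal link's mass lumped at
#'   the platform end; the remainder rides at the elbow.
#' @return An object of class `inertial_params`.
#' @export
inertial_params <- function(proximal_link_mass = 0.25,
                            distal_link_mass = 0.15,
                            platform_mass = 0.8,
                            goniometer_link_masses = c(0.5, 0.5, 0.5),
                            payload_mass = 1.5,
                            payload_yaw_inertia = 0.002,
                            gravity = 9.81,
                            distal_mass_split = 0.5) {
  stopifnot(proximal_link_mass >= 0, distal_link_mass >= 0,
            platform_mass >= 0, all(goniometer_link_masses >= 0),
            payload_mass >= 0, payload_yaw_inertia >= 0,
            distal_mass_split >= 0, distal_mass_split <= 1)
  structure(list(proximal_link_mass = proximal_link_mass,
                 distal_link_mass = distal_link_mass,
                 platform_mass = platform_mass,
                 goniometer_link_masses = goniometer_link_masses,
                 payload_mass = payload_mass,
                 payload_yaw_inertia = payload_yaw_inertia,
                 gravity = gravity,
                 distal_mass_split = distal_mass_split),
            class = "inertial_params")
}

#' Motor specification
#'
#' @param torque_limit Peak torque (N m).
#' @param velocity_limit Peak velocity (deg/s).
#' @param applies_to Joint indices (1:3 delta, 4:6 goniometer).
#' @return An object of class `motor_spec`.
#' @export
motor_spec <- function(torque_limit, velocity_limit, applies_to) {
  stopifnot(torque_limit > 0, velocity_limit > 0)
  structure(list(torque_limit = torque_limit,
                 velocity_limit = velocity_limit,
                 applies_to = as.integer(applies_to)),
            class = "motor_spec")
}

#' Default motor set: harmonic-drive servos of the built robot
#'
#' Delta joints: 30 N m, 576 deg/s. Goniometer joints: 4.8 N m, 360 deg/s.
#' @return List of two [motor_spec()] objects.
#' @export
default_motors <- function() {
  list(delta = motor_spec(30, 576, 1:3),
       gonio = motor_spec(4.8, 360, 4:6))
}

# platform velocity and acceleration from joint rates/accels via the
# loop-closure relation A pdot = B thdot (and its time derivative)
delta_platform_motion <- function(delta_angles, delta_rates, delta_accels,
                                  geom) {
  parts <- delta_jac_parts(delta_angles, geom)
  u <- arm_azimuths()
  ct <- cos(delta_angles); st <- sin(delta_angles)
  B <- diag(parts$Bd, 3)
  pdot <- solve(parts$A, B %*% delta_rates)
  # Adot rows = ddot_i = pdot - tang_i*thdot_i ; Bdot_ii = ddot.tang + d.tangdot
  Adot <- matrix(0, 3, 3); Bdot <- numeric(3)
  for (i in 1:3) {
    tdot <- geom$len_proximal *
      c(-ct[i] * u[i, ], -st[i]) * delta_rates[i]
    ddot <- as.numeric(pdot) - parts$tang[i, ] * delta_rates[i]
    Adot[i, ] <- ddot
    Bdot[i] <- sum(ddot * parts$tang[i, ]) + sum(parts$A[i, ] * tdot)
  }
  pddot <- solve(parts$A, B %*% delta_accels + Bdot * delta_rates -
                   Adot %*% pdot)
  list(p = parts$p, pdot = as.numeric(pdot), pddot = as.numeric(pddot),
       parts = parts)
}

# enumerate every lumped point mass with position, velocity, acceleration,
# and its 3x6 Jacobian; used by inverse dynamics and by the energy oracle
lumped_masses <- function(cfg, rates, accels, inertial,
                          dg, gg) {
  th <- cfg$delta_angles; thd <- rates[1:3]; thdd <- accels[1:3]
  gd <- cfg$gonio_angles; gdd <- rates[4:6]; gddd <- accels[4:6]
  pm <- delta_platform_motion(th, thd, thdd, dg)
  Jd <- solve(pm$parts$A, diag(pm$parts$Bd, 3))
  u <- arm_azimuths()
  lp <- dg$len_proximal
  masses <- list()
  add <- function(m, x, v, a, J) {
    masses[[length(masses) + 1L]] <<- list(m = m, x = x, v = v, a = a, J = J)
  }
  ct <- cos(th); st <- sin(th)
  for (i in 1:3) {
    e <- c(ct[i] * u[i, ], st[i])
    de <- c(-st[i] * u[i, ], ct[i])
    dde <- -e
    for (spec in list(c(inertial$proximal_link_mass, lp / 2),
                      c((1 - inertial$distal_mass_split) *
                          inertial$distal_link_mass, lp))) {
      m <- spec[1]; r <- spec[2]
      if (m <= 0) next
      J <- matrix(0, 3, 6); J[, i] <- r * de
      add(m, c(dg$r_fixed * u[i, ], 0) + r * e,
          r * de * thd[i],
          r * (dde * thd[i]^2 + de * thdd[i]),
          J)
    }
  }
  # platform-riding masses: platform + platform-end distal lumps + the two
  # goniometer stages at/above the common rotation point
  m_plat <- inertial$platform_mass +
    3 * inertial$distal_mass_split * inertial$distal_link_mass +
    inertial$goniometer_link_masses[1] + inertial$goniometer_link_masses[2]
  if (m_plat > 0) {
    J <- matrix(0, 3, 6); J[, 1:3] <- Jd
    add(m_plat, pm$p, pm$pdot, pm$pddot, J)
  }
  # rotating masses on the pivot extension: third goniometer stage at half
  # extension, payload at the pivot
  a4 <- gg$pivot_extension_a4
  R <- gonio_rotation(gd[1], gd[2])
  dRp <- drot_y(gd[1]) %*% rot_x(gd[2])
  dRr <- rot_y(gd[1]) %*% drot_x(gd[2])
  ddRpp <- ddrot_y(gd[1]) %*% rot_x(gd[2])
  ddRrr <- rot_y(gd[1]) %*% ddrot_x(gd[2])
  ddRpr <- drot_y(gd[1]) %*% drot_x(gd[2])
  base <- pm$p - c(0, 0, gg$offset_a1)
  for (spec in list(c(inertial$goniometer_link_masses[3], a4 / 2),
                    c(inertial$payload_mass, a4))) {
    m <- spec[1]; r <- spec[2]
    if (m <= 0) next
    v0 <- c(0, 0, -r)
    Rdd <- ddRpp %*% v0 * gdd[1]^2 + ddRrr %*% v0 * gdd[2]^2 +
      2 * ddRpr %*% v0 * gdd[1] * gdd[2] +
      dRp %*% v0 * gddd[1] + dRr %*% v0 * gddd[2]
    J <- matrix(0, 3, 6)
    J[, 1:3] <- Jd
    J[, 4] <- dRp %*% v0
    J[, 5] <- dRr %*% v0
    add(m, base + as.numeric(R %*% v0),
        pm$pdot + as.numeric(dRp %*% v0 * gdd[1] + dRr %*% v0 * gdd[2]),
        pm$pddot + as.numeric(Rdd),
        J)
  }
  masses
}

#' Inverse dynamics of the coupled delta robot and goniometer
#'
#' Joint torques that realize a given joint-space state of the lumped
#' point-mass model, computed by Jacobian-transpose assembly of every
#' lump's inertial-plus-gravity force. Goniometer lumps carry the platform
#' motion (their accelerations include the platform's), and their forces
#' map back through the delta Jacobian -- the goniometer's reaction appears
#' as an additional wrench on the delta moving platform.
#'
#' @param cfg A [joint_config()].
#' @param rates,accels Numeric(6) joint rates (rad/s) and accelerations
#'   (rad/s^2), delta joints first.
#' @param inertial An [inertial_params()].
#' @param dg,gg Geometry objects.
#' @return Numeric(6) joint torques (N m).
#' @export
inverse_dynamics <- function(cfg, rates = numeric(6), accels = numeric(6),
                             inertial = inertial_params(),
                             dg = delta_geometry(),
                             gg = goniometer_geometry()) {
  stopifnot(length(rates) == 6, length(accels) == 6)
  parts <- delta_jac_parts(cfg$delta_angles, dg)
  # Bd ~ 1e-4 corresponds to ~30 urad from a stretched/folded arm, where
  # torque amplification exceeds 1000x
  if (rcond(parts$A) < 1e-12 || any(abs(parts$Bd) < 1e-4)) {
    stop("singular configuration: delta Jacobian loses rank")
  }
  g_vec <- c(0, 0, -inertial$gravity)
  tau <- numeric(6)
  for (pt in lumped_masses(cfg, rates, accels, inertial, dg, gg)) {
    tau <- tau + pt$m * as.numeric(crossprod(pt$J, pt$a - g_vec))
  }
  tau[6] <- tau[6] + inertial$payload_yaw_inertia * accels[6]
  tau
}

#' Mechanical energy of the lumped model
#'
#' Kinetic plus gravitational potential energy at a joint-space state; the
#' independent side of the energy-balance identity sum(tau * qdot) = dE/dt.
#'
#' @inheritParams inverse_dynamics
#' @return Energy (J), up to an additive constant in the potential.
#' @export
mechanism_energy <- function(cfg, rates, inertial = inertial_params(),
                             dg = delta_geometry(),
                             gg = goniometer_geometry()) {
  e <- 0
  for (pt in lumped_masses(cfg, rates, numeric(6), inertial, dg, gg)) {
    e <- e + 0.5 * pt$m * sum(pt$v^2) + pt$m * inertial$gravity * pt$x[3]
  }
  e + 0.5 * inertial$payload_yaw_inertia * rates[6]^2
}

#' Decompose joint torques into gravitational, velocity, and acceleration
#' components
#'
#' gravitational = ID(q, 0, 0); velocity = ID(q, qd, 0) - gravitational;
#' acceleration = ID(q, qd, qdd) - ID(q, qd, 0). The three components sum
#' to the total identically.
#'
#' @inheritParams inverse_dynamics
#' @return An object of class `torque_breakdown`: list of numeric(6)
#'   `gravitational`, `velocity`, `acceleration`, `total`.
#' @export
decompose_torques <- function(cfg, rates = numeric(6), accels = numeric(6),
                              inertial = inertial_params(),
                              dg = delta_geometry(),
                              gg = goniometer_geometry()) {
  tg <- inverse_dynamics(cfg, numeric(6), numeric(6), inertial, dg, gg)
  tv <- inverse_dynamics(cfg, rates, numeric(6), inertial, dg, gg)
  tt <- inverse_dynamics(cfg, rates, accels, inertial, dg, gg)
  structure(list(gravitational = tg, velocity = tv - tg,
                 acceleration = tt - tv, total = tg + (tv - tg) + (tt - tv)),
            class = "torque_breakdown")
}

#' Motor feasibility of a joint-space trajectory
#'
#' Runs inverse dynamics along a time-ordered, uniformly sampled joint
#' trajectory and checks every sample against the motor torque and velocity
#' limits.
#'
#' @param trajectory data.frame with columns `t_s`, `q1`..`q6`, `qd1`..`qd6`,
#'   `qdd1`..`qdd6` (angles rad, rates rad/s, accelerations rad/s^2).
#' @param inertial An [inertial_params()].
#' @param motors List of [motor_spec()]s (default [default_motors()]).
#' @param dg,gg Geometry objects.
#' @return List of class `feasibility_report`: `peak_torque` and
#'   `peak_rate_deg_s` per joint, `violations` (data.frame of sample index,
#'   joint, kind, value, limit), and `feasible` (TRUE iff no violations).
#' @export
check_feasibility <- function(trajectory, inertial = inertial_params(),
                              motors = default_motors(),
                              dg = delta_geometry(),
                              gg = goniometer_geometry()) {
  if (nrow(trajectory) == 0) stop("empty trajectory")
  qc <- paste0("q", 1:6); qd <- paste0("qd", 1:6); qdd <- paste0("qdd", 1:6)
  stopifnot(all(c("t_s", qc, qd, qdd) %in% names(trajectory)))
  n <- nrow(trajectory)
  tau <- matrix(0, n, 6)
  for (k in seq_len(n)) {
    cfg <- joint_config(as.numeric(trajectory[k, qc[1:3]]),
                        as.numeric(trajectory[k, qc[4:6]]))
    tau[k, ] <- inverse_dynamics(cfg, as.numeric(trajectory[k, qd]),
                                 as.numeric(trajectory[k, qdd]),
                                 inertial, dg, gg)
  }
  rates_deg <- abs(as.matrix(trajectory[, qd])) * 180 / pi
  tlim <- vlim <- numeric(6)
  for (m in motors) {
    tlim[m$applies_to] <- m$torque_limit
    vlim[m$applies_to] <- m$velocity_limit
  }
  viol <- list()
  for (j in 1:6) {
    bad_t <- which(abs(tau[, j]) > tlim[j])
    bad_v <- which(rates_deg[, j] > vlim[j])
    if (length(bad_t)) {
      viol[[length(viol) + 1L]] <- data.frame(
        sample = bad_t, joint = j, kind = "torque",
        value = abs(tau[bad_t, j]), limit = tlim[j])
    }
    if (length(bad_v)) {
      viol[[length(viol) + 1L]] <- data.frame(
        sample = bad_v, joint = j, kind = "velocity",
        value = rates_deg[bad_v, j], limit = vlim[j])
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(sample = integer(0), joint = integer(0),
               kind = character(0), value = numeric(0), limit = numeric(0))
  structure(list(peak_torque = apply(abs(tau), 2, max),
                 peak_rate_deg_s = apply(rates_deg, 2, max),
                 violations = viol,
                 feasible = nrow(viol) == 0),
            class = "feasibility_report")
}

#' Read an inertial/motor configuration file
#'
#' Same flat YAML dialect as the geometry file. The packaged default
#' (`inertial_default.yaml`) holds the documented link-mass estimates.
#'
#' @param path File path, or NULL for the packaged default.
#' @return An [inertial_params()].
#' @export
read_inertial_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "inertial_default.yaml",
                        package = "exotwin", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  inertial_params(cfg$proximal_link_mass_kg, cfg$distal_link_mass_kg,
                  cfg$platform_mass_kg,
                  c(cfg$gonio_link1_mass_kg, cfg$gonio_link2_mass_kg,
                    cfg$gonio_link3_mass_kg),
                  cfg$payload_mass_kg, cfg$payload_yaw_inertia_kgm2,
                  cfg$gravity_m_s2, cfg$distal_mass_split)
}
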