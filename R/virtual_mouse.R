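#' Calibration of the virtual mouse's locomotor intent
#'
#' Free mouse locomotion is bout structured: rest intervals alternate with
#' movement bouts whose velocity-acceleration profiles trace arching loops,
#' the acceleration peaking while velocity is still rising (at roughly
#' 50-75% of the bout's peak velocity). The generator emulates this with
#' skewed half-sine velocity pulses: v(t) = V sin^p(pi t / T). With the
#' default skew exponent p = 3 the acceleration peak falls at ~54% of V;
#' p = 1 is the plain half-sine (elliptical loop, peak acceleration
#' pi V / T at bout onset).
#'
#' Bout peak velocities V and peak accelerations A are drawn log-normally;
#' the log-means are solved in closed form so that the expected mean of the
#' top 20% of peaks equals the calibration targets (13 cm/s and 35 cm/s^2,
#' the values observed in freely behaving mice). Bout duration follows from
#' T = g_p * pi * V / A, coupling fast bouts to short durations.
#'
#' @param top20_velocity_target m/s, target mean of the top 20% of velocity
#'   peaks.
#' @param top20_accel_target m/s^2, same for acceleration peaks.
#' @param sigma_v,sigma_a Log-sd of the peak-velocity and peak-acceleration
#'   distributions.
#' @param rest_mean_s Mean of the exponential rest-interval duration.
#' @param rest_min_s Floor on rest intervals (keeps bouts separable).
#' @param bout_min_s,bout_max_s Clamp on bout durations.
#' @param skew Skew exponent p (>= 1); 1 disables the asymmetry.
#' @param turn_prob Probability that a rest interval carries a heading-turn
#'   bout.
#' @param yaw_peak_median_rad_s,yaw_sigma Median and log-sd of yaw-bout peak
#'   angular velocity.
#' @param yaw_bout_s Duration of yaw bouts.
#' @return An object of class `intent_calibration`.
#' @export
intent_calibration <- function(top20_velocity_target = 0.13,
                               top20_accel_target = 0.35,
                               sigma_v = 0.5, sigma_a = 0.5,
                               rest_mean_s = 1.5, rest_min_s = 0.4,
                               bout_min_s = 0.15, bout_max_s = 6,
                               skew = 3,
                               turn_prob = 0.5,
                               yaw_peak_median_rad_s = 1.5,
                               yaw_sigma = 0.4, yaw_bout_s = 0.6) {
  stopifnot(top20_velocity_target > 0, top20_accel_target > 0,
            sigma_v > 0, sigma_a > 0, skew >= 1, rest_mean_s > 0)
  structure(list(top20_velocity_target = top20_velocity_target,
                 top20_accel_target = top20_accel_target,
                 mu_v = lognormal_mu_for_top_mean(top20_velocity_target,
                                                  sigma_v, 0.2),
                 mu_a = lognormal_mu_for_top_mean(top20_accel_target,
                                                  sigma_a, 0.2),
                 sigma_v = sigma_v, sigma_a = sigma_a,
                 rest_mean_s = rest_mean_s, rest_min_s = rest_min_s,
                 bout_min_s = bout_min_s, bout_max_s = bout_max_s,
                 skew = skew, turn_prob = turn_prob,
                 yaw_peak_median_rad_s = yaw_peak_median_rad_s,
                 yaw_sigma = yaw_sigma, yaw_bout_s = yaw_bout_s),
            class = "intent_calibration")
}

# log-mean mu such that the expected mean of the top `fraction` of a
# lognormal(mu, sigma) equals `target`:
# E[X | X > q_{1-f}] = exp(mu + sigma^2/2) * pnorm(sigma - z_{1-f}) / f
lognormal_mu_for_top_mean <- function(target, sigma, fraction) {
  z <- stats::qnorm(1 - fraction)
  log(target * fraction / stats::pnorm(sigma - z)) - sigma^2 / 2
}

# peak acceleration factor of v(t) = V sin^p(pi t / T):
# max |dv/dt| = (pi V / T) * g_p
skew_accel_factor <- function(p) {
  if (p <= 1) return(1)
  xs <- atan(sqrt(p - 1))
  p * sin(xs)^(p - 1) * cos(xs)
}

# fraction of bout peak velocity at which the acceleration peaks
skew_accel_velocity_fraction <- function(p) {
  if (p <= 1) return(0)
  sin(atan(sqrt(p - 1)))^p
}

#' Muscle model of the virtual mouse
#'
#' Converts the mismatch between intended and realized velocity into head
#' forces: F = clip(gain * (v_intent - v_actual), +/- saturation), per
#' axis. Saturations are set so that closed-loop peak forces land in the
#' sub-Newton range mice exert through the headpost. The default gain
#' represents a trained animal: against the tuned virtual damping of
#' 1.5 N s/m it leaves only a ~4% steady-state velocity tracking error,
#' so closed-loop locomotion statistics match the free intent.
#'
#' @param gain_linear N per (m/s), x and y axes.
#' @param saturation_linear N.
#' @param gain_yaw N m per (rad/s).
#' @param saturation_yaw N m.
#' @return An object of class `muscle_model`.
#' @export
muscle_model <- function(gain_linear = 40, saturation_linear = 0.25,
                         gain_yaw = 0.05, saturation_yaw = 0.02) {
  stopifnot(gain_linear > 0, gain_yaw > 0, saturation_linear > 0,
            saturation_yaw > 0)
  structure(list(gain_linear = gain_linear,
                 saturation_linear = saturation_linear,
                 gain_yaw = gain_yaw, saturation_yaw = saturation_yaw),
            class = "muscle_model")
}

#' Head force from a velocity mismatch
#'
#' @param v_intent,v_actual Numeric(3) mouse-frame velocities (x m/s,
#'   y m/s, yaw rad/s).
#' @param muscle A [muscle_model()].
#' @return Numeric(3): (Fx N, Fy N, Tz N m).
#' @export
muscle_force <- function(v_intent, v_actual, muscle = muscle_model()) {
  err <- v_intent - v_actual
  f <- c(muscle$gain_linear * err[1:2], muscle$gain_yaw * err[3])
  sat <- c(rep(muscle$saturation_linear, 2), muscle$saturation_yaw)
  pmin(pmax(f, -sat), sat)
}

#' Virtual mouse handle
#'
#' @param calibration An [intent_calibration()].
#' @param muscle A [muscle_model()].
#' @return List used by [run_closed_loop()].
#' @export
virtual_mouse <- function(calibration = intent_calibration(),
                          muscle = muscle_model()) {
  structure(list(calibration = calibration, muscle = muscle),
            class = "virtual_mouse")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate intended velocity time series
#'
#' Bout-structured locomotor intent at 100 samples/s: forward half-sine
#' (skewed) velocity bouts separated by rests; heading-turn bouts (yaw
#' half-sines, randomly signed) during a fraction of the rests; lateral
#' intent zero (the mouse moves along its heading). Reproducible under a
#' fixed seed.
#'
#' @param duration s; 0 yields an empty series.
#' @param calib An [intent_calibration()].
#' @param seed Integer seed.
#' @param fs Samples per second.
#' @return data.frame with `t`, `vx`, `vy`, `vyaw` (mouse frame).
#' @export
generate_intent <- function(duration, calib = intent_calibration(), seed = 1,
                            fs = 100) {
  stopifnot(duration >= 0)
  n <- floor(duration * fs)
  t <- seq_len(n) / fs
  out <- data.frame(t = t, vx = numeric(n), vy = numeric(n),
                    vyaw = numeric(n))
  if (n == 0) return(out)
  with_seed(seed, {
    cur <- 0
    while (cur < duration) {
      rest <- calib$rest_min_s + stats::rexp(1, 1 / calib$rest_mean_s)
      if (stats::runif(1) < calib$turn_prob && rest > calib$yaw_bout_s) {
        w_peak <- stats::rlnorm(1, log(calib$yaw_peak_median_rad_s),
                                calib$yaw_sigma) *
          sample(c(-1, 1), 1)
        t0 <- cur + (rest - calib$yaw_bout_s) / 2
        idx <- which(t > t0 & t < t0 + calib$yaw_bout_s)
        if (length(idx)) {
          out$vyaw[idx] <- w_peak *
            sin(pi * (t[idx] - t0) / calib$yaw_bout_s)
        }
      }
      cur <- cur + rest
      V <- stats::rlnorm(1, calib$mu_v, calib$sigma_v)
      A <- stats::rlnorm(1, calib$mu_a, calib$sigma_a)
      Tb <- skew_accel_factor(calib$skew) * pi * V / A
      Tb <- min(max(Tb, calib$bout_min_s), calib$bout_max_s)
      idx <- which(t > cur & t < cur + Tb)
      if (length(idx)) {
        out$vx[idx] <- V * sin(pi * (t[idx] - cur) / Tb)^calib$skew
      }
      cur <- cur + Tb
    }
  })
  out
}

#' Single velocity bout (deterministic)
#'
#' @param V Peak velocity (m/s).
#' @param T_s Bout duration (s).
#' @param skew Skew exponent (1 = plain half-sine).
#' @param fs Samples per second.
#' @return data.frame with `t` and `v`.
#' @export
intent_bout <- function(V, T_s, skew = 1, fs = 100) {
  t <- seq(0, T_s, by = 1 / fs)
  data.frame(t = t, v = V * sin(pi * t / T_s)^skew)
}

#' Free-behavior session of the virtual mouse
#'
#' Open-loop "freely behaving" emulation (intent = realized motion): global
#' positions are integrated from the intent along the current heading.
#' Head-force columns are zero -- a freely behaving mouse exerts no force
#' on a headpost. Output follows the session-log schema.
#'
#' @inheritParams generate_intent
#' @return Session log data.frame (see [write_session_log()]).
#' @export
free_session <- function(duration, calib = intent_calibration(), seed = 1,
                         fs = 100) {
  intent <- generate_intent(duration, calib, seed, fs)
  n <- nrow(intent)
  dtv <- 1 / fs
  yaw <- cumsum(intent$vyaw) * dtv
  x <- cumsum(intent$vx * cos(yaw)) * dtv
  y <- cumsum(intent$vx * sin(yaw)) * dtv
  data.frame(t_s = intent$t, x_m = x, y_m = y, z_m = 0,
             pitch_rad = 0, roll_rad = 0, yaw_rad = yaw,
             fx_N = 0, fy_N = 0, tz_Nm = 0,
             vcmd_x = intent$vx, vcmd_y = intent$vy,
             vcmd_yaw = intent$vyaw,
             zone = "open", event = "", stringsAsFactors = FALSE)
}
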