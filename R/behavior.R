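#' Kinematic filter specification
#'
#' The robot's position logs are differentiated and then denoised with a
#' 13-point median filter followed by a 5-point mean filter; paw tracks in
#' the gait pipeline use a 5-point median. Windows shrink at the series
#' boundaries rather than padding.
#'
#' @param median_window,mean_window,gait_median_window Odd window lengths
#'   (samples).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(median_window = 13, mean_window = 5,
                        gait_median_window = 5) {
  stopifnot(median_window >= 1, median_window %% 2 == 1,
            mean_window >= 1, mean_window %% 2 == 1,
            gait_median_window >= 1, gait_median_window %% 2 == 1)
  structure(list(median_window = median_window, mean_window = mean_window,
                 gait_median_window = gait_median_window),
            class = "filter_spec")
}

# centered running mean with shrinking windows at the edges
mean_filter <- function(x, k) {
  if (k <= 1) return(x)
  half <- (k - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1, i - half); hi <- pmin(n, i + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

median_then_mean <- function(x, filt) {
  if (filt$median_window > 1 && length(x) >= filt$median_window) {
    x <- as.numeric(stats::runmed(x, filt$median_window,
                                  endrule = "median"))
  }
  mean_filter(x, filt$mean_window)
}

# central finite differences (one-sided at the ends)
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n < 2) return(d)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Filtered velocity and acceleration from positions
#'
#' Finite differences of position, then the median filter, then the mean
#' filter, in that order; acceleration is the finite difference of the raw
#' velocity, filtered the same way.
#'
#' @param positions Numeric vector of positions (m), uniformly sampled.
#' @param dt Sample interval (s).
#' @param filt A [filter_spec()].
#' @return data.frame with `velocity` and `acceleration`.
#' @export
kinematics_from_positions <- function(positions, dt = 0.01,
                                      filt = filter_spec()) {
  if (length(positions) < filt$median_window) {
    stop("position series shorter than the median filter window")
  }
  v_raw <- central_diff(positions, dt)
  a_raw <- central_diff(v_raw, dt)
  data.frame(velocity = median_then_mean(v_raw, filt),
             acceleration = median_then_mean(a_raw, filt))
}

#' Mouse-frame kinematics of a session log
#'
#' Rotates the global planar velocity into the mouse's frame by the logged
#' yaw, then applies the standard filter cascade. The forward axis is the
#' mouse's x.
#'
#' @param log Session log data.frame (columns `t_s`, `x_m`, `y_m`,
#'   `yaw_rad`).
#' @param filt A [filter_spec()].
#' @return data.frame with filtered `v_forward`, `a_forward`, `v_lateral`.
#' @export
session_kinematics <- function(log, filt = filter_spec()) {
  dt <- stats::median(diff(log$t_s))
  vx_g <- central_diff(log$x_m, dt)
  vy_g <- central_diff(log$y_m, dt)
  yaw <- log$yaw_rad
  v_fwd_raw <- cos(yaw) * vx_g + sin(yaw) * vy_g
  v_lat_raw <- -sin(yaw) * vx_g + cos(yaw) * vy_g
  a_fwd_raw <- central_diff(v_fwd_raw, dt)
  data.frame(v_forward = median_then_mean(v_fwd_raw, filt),
             a_forward = median_then_mean(a_fwd_raw, filt),
             v_lateral = median_then_mean(v_lat_raw, filt))
}

#' Positive peaks of a kinematic series
#'
#' Velocity, acceleration, and force are continuous series; to keep samples
#' independent only the positive local maxima enter the statistics.
#'
#' @param series Numeric vector.
#' @return Object of class `peak_set`: numeric amplitudes with attribute
#'   `index`.
#' @export
peak_stats <- function(series) {
  if (length(series) == 0) stop("empty series")
  n <- length(series)
  if (n < 3) {
    idx <- integer(0)
  } else {
    i <- 2:(n - 1)
    idx <- i[series[i] > series[i - 1] & series[i] > series[i + 1] &
               series[i] > 0]
  }
  structure(series[idx], index = idx, class = "peak_set")
}

#' Mean of the top fraction of peaks
#'
#' @param peaks Numeric peak amplitudes (e.g. a [peak_stats()] result).
#' @param fraction Fraction in (0, 1]; the ceiling of `fraction * n`
#'   largest peaks are averaged.
#' @return Mean amplitude.
#' @export
top_fraction_mean <- function(peaks, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  x <- as.numeric(peaks)
  if (length(x) == 0) stop("no peaks to average")
  k <- ceiling(fraction * length(x))
  mean(sort(x, decreasing = TRUE)[seq_len(k)])
}

#' Resample peaks for cross-condition comparison
#'
#' Peak sets are resampled to a common size (default 100, without
#' replacement) before distributional comparisons, so denser sampling of
#' one condition does not exaggerate differences. Sets at or below the
#' target size are returned whole.
#'
#' @param peaks Numeric amplitudes.
#' @param n Target size.
#' @param seed Seed for the subsample.
#' @return Numeric amplitudes of length `min(n, length(peaks))`.
#' @export
resample_peaks <- function(peaks, n = 100, seed = 1) {
  x <- as.numeric(peaks)
  if (length(x) <= n) return(x)
  with_seed(seed, sample(x, n, replace = FALSE))
}

#' Fit the admittance plane F = m a + c v
#'
#' Least squares without intercept on force-velocity-acceleration samples;
#' the plane the controller renders in the v-a-F space. With no
#' acceleration variation the damping-only variant c = <F,v>/<v,v> is
#' returned and the mass flagged indeterminate.
#'
#' @param force,velocity,acceleration Numeric vectors of equal length.
#' @return List: `m`, `c`, `residual` (vector), `m_indeterminate`.
#' @export
fit_admittance_plane <- function(force, velocity, acceleration) {
  stopifnot(length(force) == length(velocity),
            length(force) == length(acceleration))
  if (length(force) < 2) stop("need at least 2 samples")
  X <- cbind(a = acceleration, v = velocity)
  if (all(abs(acceleration) < 1e-15)) {
    cc <- sum(force * velocity) / sum(velocity^2)
    return(list(m = NA_real_, c = cc, residual = force - cc * velocity,
                m_indeterminate = TRUE))
  }
  qx <- qr(X)
  if (qx$rank < 2) stop("rank-deficient regressors: v and a are collinear")
  beta <- qr.coef(qx, force)
  list(m = unname(beta["a"]), c = unname(beta["v"]),
       residual = unname(force - X %*% beta),
       m_indeterminate = FALSE)
}

#' Score a turn from its path through the turning zone
#'
#' A turn is incorrect when the global x-y path deviates by more than 1 cm
#' (strictly) from the midline in the direction contralateral to the turn.
#' The midline is the entry axis: deviations are measured laterally from
#' the path's entry point, so the score is invariant to rigid translation.
#' The maze frame has the entry pointing +y and the left arm toward -x.
#'
#' @param path Two-column matrix/data.frame of x, y samples through the
#'   zone.
#' @param direction "left" or "right".
#' @param threshold_m Contralateral deviation threshold (m).
#' @param exited Set FALSE when the path never exits the zone.
#' @return "correct", "incorrect", or "undecided".
#' @export
score_turn <- function(path, direction = c("left", "right"),
                       threshold_m = 0.01, exited = TRUE) {
  direction <- match.arg(direction)
  if (!exited) return("undecided")
  path <- as.matrix(path)
  stopifnot(ncol(path) >= 2, nrow(path) >= 2)
  lateral <- path[, 1] - path[1, 1]
  contra <- if (direction == "left") max(lateral) else max(-lateral)
  if (contra > threshold_m) "incorrect" else "correct"
}

#' Tortuosity of a path
#'
#' Arc-chord ratio: traversed path length divided by the straight-line
#' entry-to-exit distance. 1 for a straight path, pi/2 for a semicircle.
#'
#' @param path Two-column matrix/data.frame of x, y samples.
#' @return Ratio >= 1 (up to discretization).
#' @export
tortuosity <- function(path) {
  path <- as.matrix(path)
  stopifnot(nrow(path) >= 2)
  seg <- diff(path)
  arc <- sum(sqrt(rowSums(seg^2)))
  chord <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  if (chord < .Machine$double.eps) stop("zero chord: entry equals exit")
  arc / chord
}

#' Extract steps from a paw track
#'
#' Stance phases are intervals where the median-filtered paw speed stays at
#' or below the stationarity threshold for a minimum run of samples (a
#' literal 0 cm/s never survives tracking noise); a step is the swing
#' between consecutive stances. Step length is the displacement between
#' stance centroids; cadence the inverse of the onset-to-onset interval.
#' Records violating the exclusion criteria (length < 1 cm or > 10 cm,
#' swing duration < 0.05 s) are dropped and counted.
#'
#' @param paw Two-column matrix/data.frame of paw x, y (m).
#' @param t_s Time stamps (s).
#' @param body_velocity Body velocity series (m/s), synchronized.
#' @param filt A [filter_spec()] (the gait median window is used).
#' @param stationary_speed Threshold (m/s) below which the paw counts as
#'   stationary.
#' @param min_stance_samples Minimum consecutive samples in stance.
#' @return data.frame (one row per retained step): `paw_step`, `length_cm`,
#'   `duration_s`, `cadence_hz`, `body_velocity_cm_s`; attribute
#'   `n_excluded` counts dropped records, `diagnostic` explains an empty
#'   result.
#' @export
gait_steps <- function(paw, t_s, body_velocity = NULL,
                       filt = filter_spec(), stationary_speed = 0.005,
                       min_stance_samples = 3) {
  paw <- as.matrix(paw)
  n <- nrow(paw)
  stopifnot(length(t_s) == n)
  dt <- stats::median(diff(t_s))
  vx <- central_diff(paw[, 1], dt)
  vy <- central_diff(paw[, 2], dt)
  speed <- sqrt(vx^2 + vy^2)
  k <- filt$gait_median_window
  if (n >= k && k > 1) {
    speed <- as.numeric(stats::runmed(speed, k, endrule = "median"))
  }
  stat <- speed <= stationary_speed
  r <- rle(stat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_stance_samples
  if (!any(keep)) {
    out <- empty_steps()
    attr(out, "diagnostic") <- "no stance phases detected"
    return(out)
  }
  s_start <- starts[keep]; s_end <- ends[keep]
  m <- length(s_start)
  if (m < 2) {
    out <- empty_steps()
    attr(out, "diagnostic") <- "fewer than two stances; no steps"
    return(out)
  }
  centroid <- t(vapply(seq_len(m), function(i) {
    colMeans(paw[s_start[i]:s_end[i], , drop = FALSE])
  }, numeric(2)))
  rows <- lapply(seq_len(m - 1), function(i) {
    len_cm <- 100 * sqrt(sum((centroid[i + 1, ] - centroid[i, ])^2))
    dur <- t_s[s_start[i + 1]] - t_s[s_end[i]]
    cad <- 1 / (t_s[s_start[i + 1]] - t_s[s_start[i]])
    bv <- if (is.null(body_velocity)) NA_real_ else {
      100 * mean(body_velocity[s_end[i]:s_start[i + 1]])
    }
    data.frame(paw_step = i, length_cm = len_cm, duration_s = dur,
               cadence_hz = cad, body_velocity_cm_s = bv)
  })
  steps <- do.call(rbind, rows)
  ok <- steps$length_cm >= 1 & steps$length_cm <= 10 &
    steps$duration_s >= 0.05
  out <- steps[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!ok)
  out
}

empty_steps <- function() {
  data.frame(paw_step = integer(0), length_cm = numeric(0),
             duration_s = numeric(0), cadence_hz = numeric(0),
             body_velocity_cm_s = numeric(0))
}

#' Clopper-Pearson exact binomial interval
#'
#' Success-rate point estimate and exact confidence interval from beta
#' quantiles, as used for turning-proficiency and decision-task
#' performance.
#'
#' @param successes,trials Counts.
#' @param alpha Two-sided miscoverage (0.05 for a 95% interval).
#' @return Numeric: `estimate`, `lower`, `upper`.
#' @export
clopper_pearson <- function(successes, trials, alpha = 0.05) {
  stopifnot(trials >= 1, successes >= 0, successes <= trials,
            alpha > 0, alpha < 1)
  x <- successes; n <- trials
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(estimate = x / n, lower = lower, upper = upper)
}

#' Peak report of a session (controller tuning summary)
#'
#' Mouse-frame forward velocity/acceleration peaks, their top-20% means,
#' and the admittance-plane fit of the logged forces.
#'
#' @param log Session log data.frame.
#' @param filt A [filter_spec()].
#' @return List: `top20_velocity_cm_s`, `top20_accel_cm_s2`, `n_vel_peaks`,
#'   `n_acc_peaks`, `plane_m`, `plane_c`.
#' @export
session_peak_report <- function(log, filt = filter_spec()) {
  kin <- session_kinematics(log, filt)
  vp <- peak_stats(kin$v_forward)
  ap <- peak_stats(kin$a_forward)
  fit <- tryCatch(
    fit_admittance_plane(log$fx_N, kin$v_forward, kin$a_forward),
    error = function(e) list(m = NA_real_, c = NA_real_))
  list(top20_velocity_cm_s = 100 * top_fraction_mean(vp, 0.2),
       top20_accel_cm_s2 = 100 * top_fraction_mean(ap, 0.2),
       n_vel_peaks = length(vp), n_acc_peaks = length(ap),
       plane_m = fit$m, plane_c = fit$c)
}
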