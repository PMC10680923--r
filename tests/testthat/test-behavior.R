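# Filtered kinematics, peak statistics, admittance-plane fit, turn scoring,
# tortuosity, gait extraction, Clopper-Pearson intervals

test_that("a linear position ramp gives constant velocity and zero
           acceleration away from the edges", {
  pos <- seq(0, 1, by = 0.001)
  kin <- kinematics_from_positions(pos, dt = 0.01)
  mid <- 50:950
  expect_equal(kin$velocity[mid], rep(0.1, length(mid)), tolerance = 1e-9)
  expect_equal(kin$acceleration[mid], rep(0, length(mid)),
               tolerance = 1e-9)
})

test_that("a single-sample glitch is suppressed by the 13-point median", {
  pos <- seq(0, 1, by = 0.001)
  pos[500] <- pos[500] + 0.05  # 5 cm tracking glitch
  kin <- kinematics_from_positions(pos, dt = 0.01)
  # raw central difference would spike to 0.05/0.02 = 2.5 m/s
  expect_lt(max(abs(kin$velocity - 0.1)), 0.01)
})

test_that("sine-wave velocity amplitude matches the analytic gain of the
           filter cascade", {
  f0 <- 0.5; dt <- 0.01; A <- 0.1
  t <- seq(0, 20, by = dt)
  pos <- A * sin(2 * pi * f0 * t)
  kin <- kinematics_from_positions(pos, dt = dt)
  w <- 2 * pi * f0
  gain_diff <- sin(w * dt) / (w * dt)            # central difference
  gain_med <- cos(3 * w * dt)                    # 13-pt median at a peak
  gain_mean <- (1 + 2 * cos(w * dt) + 2 * cos(2 * w * dt)) / 5
  expected <- A * w * gain_diff * gain_med * gain_mean
  measured <- max(kin$velocity[100:1900])
  expect_equal(measured, expected, tolerance = 0.005)
})

test_that("too-short series are rejected", {
  expect_error(kinematics_from_positions(1:5, 0.01), "shorter")
})

test_that("peak extraction keeps positive local maxima only", {
  expect_length(peak_stats(1:50), 0)              # monotone: no peaks
  s <- c(0, 1, 0, 2, 0, -3, -1, -4, 3, 0)
  p <- peak_stats(s)
  expect_equal(sort(as.numeric(p)), c(1, 2, 3))   # -1 is a negative maximum
  expect_error(peak_stats(numeric(0)), "empty")
})

test_that("top_fraction_mean averages the ceil(f n) largest peaks", {
  expect_equal(top_fraction_mean(c(1, 2, 3, 4, 5), 0.2), 5)
  expect_equal(top_fraction_mean(c(1, 2, 3, 4, 5), 0.4), 4.5)
  expect_equal(top_fraction_mean(c(1, 2, 3, 4, 5, 6), 0.2), 5.5)  # ceil
  expect_equal(top_fraction_mean(7, 1), 7)
  expect_error(top_fraction_mean(numeric(0), 0.2), "no peaks")
})

test_that("peak resampling subsamples only above the target size, with a
           seed", {
  expect_equal(resample_peaks(1:50, 100), 1:50)
  big <- rnorm(500)
  a <- resample_peaks(big, 100, seed = 2)
  b <- resample_peaks(big, 100, seed = 2)
  expect_identical(a, b)
  expect_length(a, 100)
  expect_true(all(a %in% big))
  expect_false(any(duplicated(a)))  # without replacement
})

test_that("admittance-plane fit recovers known mass and damping exactly on
           noiseless data", {
  set.seed(17)
  v <- rnorm(200); a <- rnorm(200)
  f <- 0.5 * a + 2 * v
  fit <- fit_admittance_plane(f, v, a)
  expect_equal(fit$m, 0.5, tolerance = 1e-10)
  expect_equal(fit$c, 2, tolerance = 1e-10)
  expect_lt(max(abs(fit$residual)), 1e-10)
  # residual orthogonal to both regressors
  expect_lt(abs(sum(fit$residual * v)), 1e-8)
  expect_lt(abs(sum(fit$residual * a)), 1e-8)
})

test_that("admittance-plane fit is unbiased under force noise", {
  set.seed(23)
  v <- rnorm(100); a <- rnorm(100)
  ms <- cs <- numeric(1000)
  for (r in 1:1000) {
    f <- 0.5 * a + 2 * v + rnorm(100, sd = 0.3)
    fit <- fit_admittance_plane(f, v, a)
    ms[r] <- fit$m; cs[r] <- fit$c
  }
  expect_lt(abs(mean(ms) - 0.5), 3 * stats::sd(ms) / sqrt(1000))
  expect_lt(abs(mean(cs) - 2), 3 * stats::sd(cs) / sqrt(1000))
})

test_that("degenerate admittance data are handled: v-only variant and
           collinearity error", {
  v <- rnorm(50)
  f <- 2 * v
  fit <- fit_admittance_plane(f, v, rep(0, 50))
  expect_true(fit$m_indeterminate)
  expect_equal(fit$c, 2, tolerance = 1e-10)
  expect_error(fit_admittance_plane(f, v, 3 * v), "collinear")
})

test_that("turn scoring applies the strict 1 cm contralateral rule", {
  y <- seq(0, 0.1, length.out = 50)
  straight <- cbind(rep(0, 50), y)
  expect_equal(score_turn(straight, "left"), "correct")
  expect_equal(score_turn(straight, "right"), "correct")
  # left turn with a 1.2 cm rightward (contralateral, +x) excursion
  wob <- cbind(0.012 * sin(pi * seq(0, 1, length.out = 50)), y)
  expect_equal(score_turn(wob, "left"), "incorrect")
  expect_equal(score_turn(wob, "right"), "correct")
  # exactly 1.0 cm is still correct (strictly "more than")
  edge <- cbind(0.010 * sin(pi * seq(0, 1, length.out = 50)), y)
  expect_equal(score_turn(edge, "left"), "correct")
  expect_equal(score_turn(straight, "left", exited = FALSE), "undecided")
})

test_that("turn scoring is invariant to rigid translation", {
  y <- seq(0, 0.1, length.out = 50)
  path <- cbind(0.012 * sin(pi * seq(0, 1, length.out = 50)), y)
  shifted <- sweep(path, 2, c(1.3, -2.1), "+")
  expect_equal(score_turn(path, "left"), score_turn(shifted, "left"))
  expect_equal(score_turn(path, "right"), score_turn(shifted, "right"))
})

test_that("tortuosity: straight 1, semicircle pi/2, rigid-motion invariant,
           discretization robust", {
  y <- seq(0, 1, length.out = 100)
  expect_equal(tortuosity(cbind(0 * y, y)), 1, tolerance = 1e-9)
  th <- seq(0, pi, length.out = 2000)
  semi <- cbind(cos(th), sin(th))
  expect_equal(tortuosity(semi), pi / 2, tolerance = 1e-4)
  # rotation + translation invariance
  R <- matrix(c(cos(0.7), sin(0.7), -sin(0.7), cos(0.7)), 2, 2)
  moved <- semi %*% t(R) + matrix(c(5, -3), 2000, 2, byrow = TRUE)
  expect_equal(tortuosity(moved), tortuosity(semi), tolerance = 1e-9)
  # resampling the interior more densely barely changes the value
  th2 <- seq(0, pi, length.out = 7777)^1.1 / pi^0.1
  semi2 <- cbind(cos(th2), sin(th2))
  expect_lt(abs(tortuosity(semi2) - tortuosity(semi)), 1e-3)
  expect_error(tortuosity(rbind(c(0, 0), c(0, 0))), "chord")
})

# synthetic gait: square-wave stance/swing with known stride and cadence
make_gait <- function(stride_m = 0.05, cadence_hz = 3, n_steps = 20,
                      fs = 200, stance_frac = 0.4) {
  period <- 1 / cadence_hz
  t <- seq(0, n_steps * period, by = 1 / fs)
  x <- numeric(length(t))
  for (k in seq_along(t)) {
    ph <- (t[k] %% period) / period
    base <- floor(t[k] / period) * stride_m
    x[k] <- if (ph < stance_frac) base else {
      base + stride_m * (ph - stance_frac) / (1 - stance_frac)
    }
  }
  list(t = t, paw = cbind(x, 0 * x))
}

test_that("gait extraction recovers generator ground truth", {
  g <- make_gait(stride_m = 0.05, cadence_hz = 3)
  steps <- gait_steps(g$paw, g$t)
  expect_gt(nrow(steps), 10)
  expect_equal(mean(steps$length_cm), 5, tolerance = 0.1 / 5)
  expect_equal(mean(steps$cadence_hz), 3, tolerance = 0.05 / 3)
})

test_that("micro-steps and twitches are excluded by the published
           criteria", {
  g <- make_gait(stride_m = 0.005, cadence_hz = 3)   # 0.5 cm micro-steps
  steps <- gait_steps(g$paw, g$t)
  expect_equal(nrow(steps), 0)
  expect_gt(attr(steps, "n_excluded"), 0)
  # 0.04 s swings (duration < 0.05 s) are dropped even at valid length;
  # sampled finely so boundary blur from differentiation stays below the
  # threshold margin
  g2 <- make_gait(stride_m = 0.05, cadence_hz = 3, stance_frac = 0.88,
                  fs = 1000)
  steps2 <- gait_steps(g2$paw, g2$t)
  expect_equal(nrow(steps2), 0)
})

test_that("gait exclusions are idempotent", {
  g <- make_gait()
  s1 <- gait_steps(g$paw, g$t)
  keep <- s1$length_cm >= 1 & s1$length_cm <= 10 & s1$duration_s >= 0.05
  expect_true(all(keep))
})

test_that("no stances yields an empty list with a diagnostic", {
  t <- seq(0, 2, by = 0.005)
  paw <- cbind(0.2 * t, 0 * t)  # constant 20 cm/s, never stationary
  steps <- gait_steps(paw, t)
  expect_equal(nrow(steps), 0)
  expect_match(attr(steps, "diagnostic"), "stance")
})

test_that("Clopper-Pearson matches an independent binomial-tail inversion
           to 1e-10", {
  # oracle: invert the binomial tail probabilities directly
  cp_oracle <- function(x, n, alpha) {
    lo <- if (x == 0) 0 else {
      stats::uniroot(function(p) stats::pbinom(x - 1, n, p,
                                               lower.tail = FALSE) -
                       alpha / 2,
                     c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    }
    hi <- if (x == n) 1 else {
      stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                     c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    }
    c(lo, hi)
  }
  for (case in list(c(35, 40), c(1, 10), c(10, 10), c(0, 25), c(57, 60))) {
    x <- case[1]; n <- case[2]
    got <- clopper_pearson(x, n, 0.05)
    want <- cp_oracle(x, n, 0.05)
    expect_equal(unname(got["lower"]), want[1], tolerance = 1e-10)
    expect_equal(unname(got["upper"]), want[2], tolerance = 1e-10)
    expect_equal(unname(got["estimate"]), x / n)
  }
  expect_equal(unname(clopper_pearson(0, 20)["lower"]), 0)
  expect_equal(unname(clopper_pearson(20, 20)["upper"]), 1)
  expect_error(clopper_pearson(5, 4), "successes")
})
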