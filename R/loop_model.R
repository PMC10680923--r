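#' Frequency-domain model of the force-feedback loop
#'
#' The admittance controller renders a virtual admittance
#' Y_virtual(s) = 1 / (m s + c). Sensor sampling, the discrete cycle, and
#' the inner velocity loop degrade what the mouse actually feels -- the
#' apparent admittance -- at higher frequencies. The loop is aggregated as
#' Y_app = Y_virtual * D(s) with D(s) the product of a pure delay (half the
#' cycle time as the zero-order-hold equivalent, plus one full cycle of
#' computation latency, plus the sensor delay) and a first-order inner-loop
#' lag.
#'
#' @param virtual_mass kg (plausible-tuned default).
#' @param virtual_damping N s/m (plausible-tuned default).
#' @param cycle_time s, controller cycle (default 10 ms).
#' @param sensor_delay s, force-sensor signal delay.
#' @param inner_loop_lag s, first-order lag time constant of the inner
#'   velocity/current loops.
#' @param freq_grid_hz Positive ascending frequency grid (Hz).
#' @return An object of class `loop_model`.
#' @export
loop_model <- function(virtual_mass = 0.2, virtual_damping = 1.5,
                       cycle_time = 0.01, sensor_delay = 0.01,
                       inner_loop_lag = 0.005,
                       freq_grid_hz = 10^seq(-2, 3, length.out = 600)) {
  stopifnot(virtual_mass > 0, virtual_damping >= 0, cycle_time >= 0,
            sensor_delay >= 0, inner_loop_lag >= 0,
            all(freq_grid_hz > 0), !is.unsorted(freq_grid_hz))
  structure(list(virtual_mass = virtual_mass,
                 virtual_damping = virtual_damping,
                 cycle_time = cycle_time, sensor_delay = sensor_delay,
                 inner_loop_lag = inner_loop_lag,
                 freq_grid_hz = freq_grid_hz),
            class = "loop_model")
}

loop_total_delay <- function(model) 1.5 * model$cycle_time + model$sensor_delay

# complex degradation factor D(j 2 pi f)
loop_degradation <- function(model, f_hz) {
  w <- 2 * pi * f_hz
  exp(-1i * w * loop_total_delay(model)) /
    (1 + 1i * w * model$inner_loop_lag)
}

#' Apparent admittance of the closed loop
#'
#' @param model A [loop_model()].
#' @param f_hz Frequencies to evaluate (defaults to the model grid).
#' @return data.frame with `freq_hz`, complex `Y_virtual` and `Y_app`, and
#'   `mag_ratio` / `phase_ratio_rad` of Y_app / Y_virtual.
#' @export
apparent_admittance <- function(model, f_hz = model$freq_grid_hz) {
  w <- 2 * pi * f_hz
  Yv <- 1 / (model$virtual_mass * 1i * w + model$virtual_damping)
  D <- loop_degradation(model, f_hz)
  data.frame(freq_hz = f_hz, Y_virtual = Yv, Y_app = Yv * D,
             mag_ratio = Mod(D), phase_ratio_rad = Arg(D))
}

#' Bandwidth of the apparent admittance
#'
#' The lowest frequency at which the apparent admittance deviates from the
#' virtual admittance by 3 dB, measured on the complex error:
#' |Y_app/Y_virtual - 1| reaching the -3 dB level (1/sqrt(2)). With no
#' delay this crossing is exactly the inner-loop corner frequency; for a
#' pure delay it is inversely proportional to the delay. The alternative
#' -45 degree phase criterion is available via `criterion`.
#'
#' @param model A [loop_model()].
#' @param criterion "error_3db" (default) or "phase_45deg".
#' @param tol_hz Bisection refinement tolerance.
#' @return Bandwidth (Hz) with attribute `no_crossing` = TRUE (and the
#'   upper grid bound returned) when the criterion is never met on the
#'   grid.
#' @export
loop_bandwidth <- function(model, criterion = c("error_3db", "phase_45deg"),
                           tol_hz = 1e-3) {
  criterion <- match.arg(criterion)
  dev <- function(f) {
    D <- loop_degradation(model, f)
    if (criterion == "error_3db") Mod(D - 1) - 1 / sqrt(2)
    else -Arg(D) - pi / 4
  }
  grid <- model$freq_grid_hz
  vals <- dev(grid)
  hit <- which(vals >= 0)
  if (length(hit) == 0) {
    out <- grid[length(grid)]
    attr(out, "no_crossing") <- TRUE
    return(out)
  }
  k <- hit[1]
  if (k == 1) {
    out <- grid[1]
    attr(out, "no_crossing") <- FALSE
    return(out)
  }
  lo <- grid[k - 1]; hi <- grid[k]
  while (hi - lo > tol_hz) {
    mid <- (lo + hi) / 2
    if (dev(mid) >= 0) hi <- mid else lo <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "no_crossing") <- FALSE
  out
}

#' Bandwidth sweep over a loop parameter
#'
#' @param model A [loop_model()].
#' @param param One of "cycle_time", "sensor_delay", "inner_loop_lag".
#' @param values Parameter values (s).
#' @return data.frame with `value` and `bandwidth_hz`.
#' @export
bandwidth_sweep <- function(model, param = "cycle_time", values) {
  stopifnot(param %in% c("cycle_time", "sensor_delay", "inner_loop_lag"))
  bw <- vapply(values, function(v) {
    m <- model
    m[[param]] <- v
    as.numeric(loop_bandwidth(m))
  }, numeric(1))
  data.frame(value = values, bandwidth_hz = bw)
}
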