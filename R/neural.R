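#' Fluorescence imaging session container
#'
#' @param F_cell,F_neu time x cell matrices of cell and neuropil
#'   fluorescence.
#' @param sample_rate Samples per second (imaging default 15).
#' @param morphology Optional data.frame with per-cell `soma_px`,
#'   `aspect_ratio`, `diameter_um`.
#' @return An object of class `fluor_session`.
#' @export
fluor_session <- function(F_cell, F_neu, sample_rate = 15,
                          morphology = NULL) {
  F_cell <- as.matrix(F_cell); F_neu <- as.matrix(F_neu)
  stopifnot(all(dim(F_cell) == dim(F_neu)), sample_rate > 0)
  structure(list(F_cell = F_cell, F_neu = F_neu,
                 sample_rate = sample_rate, morphology = morphology),
            class = "fluor_session")
}

#' Electrophysiology session container
#'
#' @param spike_times List (one numeric vector of spike times per cell, s).
#' @param duration Session duration (s).
#' @param voltages Optional time x channel raw voltage matrix (for
#'   preprocessing).
#' @param in_brain_mask Logical per channel, channels inside the brain
#'   (common-mode reference set).
#' @param sample_rate Voltage acquisition rate (20000 or 30000 S/s).
#' @return An object of class `ephys_session`.
#' @export
ephys_session <- function(spike_times, duration, voltages = NULL,
                          in_brain_mask = NULL, sample_rate = 20000) {
  stopifnot(sample_rate > 0, duration > 0)
  if (!is.null(voltages)) {
    voltages <- as.matrix(voltages)
    if (is.null(in_brain_mask)) in_brain_mask <- rep(TRUE, ncol(voltages))
    stopifnot(length(in_brain_mask) == ncol(voltages), any(in_brain_mask))
  }
  bad <- vapply(spike_times, function(st) any(st < 0 | st > duration),
                logical(1))
  if (any(bad)) stop("spike times outside the session")
  structure(list(spike_times = spike_times, duration = duration,
                 voltages = voltages, in_brain_mask = in_brain_mask,
                 sample_rate = sample_rate),
            class = "ephys_session")
}

# zero-phase Butterworth; signal::butter(n, W) has overall order 2n for a
# band-pass, so n = order/2 there
butter_filtfilt <- function(x, type, order, cutoff_hz, fs) {
  w <- cutoff_hz / (fs / 2)
  n <- if (type == "pass") order / 2 else order
  flt <- signal::butter(n, w, type = type)
  # center first: DC is outside the passband anyway, and removing it keeps
  # the zero-phase edge transients small
  mu <- mean(x)
  signal::filtfilt(flt, x - mu) + if (type == "low") mu else 0
}

#' Calcium dF/F with neuropil subtraction
#'
#' The neuropil-corrected trace F_cell - 0.7 F_neu is band-pass filtered
#' (4th-order Butterworth, 0.05-5 Hz, zero phase) to form the numerator;
#' the denominator is the mean of the raw corrected trace (the band-pass
#' removes DC, so the literal filtered mean would be degenerate). Output is
#' in percent.
#'
#' @param session A [fluor_session()].
#' @param neuropil_coef Neuropil subtraction coefficient (0.7).
#' @param band_hz Passband (Hz).
#' @param denominator "raw_mean" (default) or "filtered_mean" (the literal
#'   alternative).
#' @return time x cell matrix of dF/F (%), with attribute `invalid_cells`
#'   flagging non-positive denominators (their columns are NA).
#' @export
compute_dff <- function(session, neuropil_coef = 0.7, band_hz = c(0.05, 5),
                        denominator = c("raw_mean", "filtered_mean")) {
  denominator <- match.arg(denominator)
  fs <- session$sample_rate
  stopifnot(fs > 10)
  corrected <- session$F_cell - neuropil_coef * session$F_neu
  filtered <- apply(corrected, 2, butter_filtfilt, type = "pass",
                    order = 4, cutoff_hz = band_hz, fs = fs)
  denom <- if (denominator == "raw_mean") colMeans(corrected) else
    colMeans(filtered)
  invalid <- denom <= 0
  out <- 100 * sweep(filtered, 2, denom, "/")
  out[, invalid] <- NA_real_
  attr(out, "invalid_cells") <- which(invalid)
  out
}

#' Cell inclusion filter
#'
#' A cell is kept iff all five criteria hold on its dF/F signal and soma
#' morphology: 3 sd < maximum; sd < 50%; maximum between 20% and 500%;
#' soma between 20 and 400 pixels; aspect ratio between 0.7 and 1.4
#' ("between" is inclusive at the boundaries).
#'
#' @param dff time x cell dF/F matrix (%).
#' @param morphology data.frame with `soma_px` and `aspect_ratio`.
#' @param max_range,sd_limit,soma_px_range,aspect_range Criterion bounds.
#' @return Logical inclusion mask with attribute `per_criterion` (named
#'   pass counts).
#' @export
filter_cells <- function(dff, morphology, max_range = c(20, 500),
                         sd_limit = 50, soma_px_range = c(20, 400),
                         aspect_range = c(0.7, 1.4)) {
  stopifnot(nrow(morphology) == ncol(dff))
  sds <- apply(dff, 2, stats::sd)
  maxs <- apply(dff, 2, max)
  c1 <- 3 * sds < maxs
  c2 <- sds < sd_limit
  c3 <- maxs >= max_range[1] & maxs <= max_range[2]
  c4 <- morphology$soma_px >= soma_px_range[1] &
    morphology$soma_px <= soma_px_range[2]
  c5 <- morphology$aspect_ratio >= aspect_range[1] &
    morphology$aspect_ratio <= aspect_range[2]
  keep <- c1 & c2 & c3 & c4 & c5
  keep[is.na(keep)] <- FALSE
  attr(keep, "per_criterion") <- c(sd_vs_max = sum(c1, na.rm = TRUE),
                                   sd_limit = sum(c2, na.rm = TRUE),
                                   max_range = sum(c3, na.rm = TRUE),
                                   soma_px = sum(c4, na.rm = TRUE),
                                   aspect = sum(c5, na.rm = TRUE))
  keep
}

#' Electrophysiology preprocessing
#'
#' Common-mode subtraction (mean of the in-brain channels removed from all
#' channels), 4th-order 250 Hz high-pass on the cleaned voltages, and spike
#' rates: counts summed in a 50 ms window advanced in 20 ms increments
#' (resampling to exactly 50 S/s), smoothed with a Gaussian pulse of 260 ms
#' width and 20 ms standard deviation, then z-scored per cell. Cells with
#' zero rate variance are flagged and their z-scored column retained as
#' zeros.
#'
#' @param session An [ephys_session()].
#' @param highpass_hz High-pass cutoff.
#' @return List: `voltages_clean` (NULL when no voltages supplied),
#'   `rates` (time x cell z-scored smoothed rates at 50 S/s),
#'   `rate_times_s`, `counts` (raw windowed counts), `flat_cells`.
#' @export
preprocess_ephys <- function(session, highpass_hz = 250) {
  vc <- NULL
  if (!is.null(session$voltages)) {
    cm <- rowMeans(session$voltages[, session$in_brain_mask, drop = FALSE])
    vc <- session$voltages - cm
    vc <- apply(vc, 2, butter_filtfilt, type = "high", order = 4,
                cutoff_hz = highpass_hz, fs = session$sample_rate)
  }
  step <- 0.02; win <- 0.05
  starts <- seq(0, session$duration - win, by = step)
  counts <- vapply(session$spike_times, function(st) {
    vapply(starts, function(s) sum(st >= s & st < s + win), numeric(1))
  }, numeric(length(starts)))
  counts <- matrix(counts, nrow = length(starts))
  # Gaussian pulse: 260 ms width = 13 samples at 50 S/s, sd 20 ms = 1 sample
  kt <- seq(-6, 6)
  kern <- exp(-kt^2 / 2); kern <- kern / sum(kern)
  sm <- apply(counts, 2, function(x) {
    as.numeric(stats::filter(c(rep(x[1], 6), x, rep(x[length(x)], 6)),
                             kern, sides = 2))[7:(length(x) + 6)]
  })
  sds <- apply(sm, 2, stats::sd)
  flat <- which(sds == 0 | is.na(sds))
  z <- sm
  for (j in seq_len(ncol(sm))) {
    if (j %in% flat) z[, j] <- 0 else z[, j] <- (sm[, j] - mean(sm[, j])) / sds[j]
  }
  list(voltages_clean = vc, rates = z,
       rate_times_s = starts + win / 2, counts = counts,
       flat_cells = flat)
}

#' Linearized maze coordinate
#'
#' Arc length along the canonical 8-maze loop: turning zone entry to its
#' top (apex to base), then the left goal arm's full circle, then the right
#' arm's. Samples outside the maze (treadmill, transition) map to NA.
#'
#' @param arena An [arena_eightmaze()].
#' @param xy Two-column matrix of global positions.
#' @param offpath_tol Maximum distance (m) from a goal-arm centerline for a
#'   sample to count as on that arm (half the channel width by default).
#' @return Numeric arc length (m) per row, NA off-maze; attribute
#'   `path_length` gives the total loop length.
#' @export
linearize_position <- function(arena, xy,
                               offpath_tol = arena$channel_width_m / 2) {
  xy <- as.matrix(xy)
  tz_len <- arena$turning_zone[2, 2] - arena$turning_zone_entry[2]
  r <- arena$arm_radius_m
  cut <- arena$arm_cut_m
  span <- 2 * pi * r - cut  # linearized length of one arm
  L <- tz_len + 2 * span
  out <- rep(NA_real_, nrow(xy))
  for (i in seq_len(nrow(xy))) {
    p <- xy[i, ]
    dl <- abs(sqrt(sum((p - arena$arm_left$center)^2)) - r)
    dr <- abs(sqrt(sum((p - arena$arm_right$center)^2)) - r)
    if (point_in_convex(p, arena$turning_zone, tol = 1e-9)) {
      out[i] <- min(max(p[2] - arena$turning_zone_entry[2], 0), tz_len)
    } else if (dl <= offpath_tol && dl <= dr) {
      v <- p - arena$arm_left$center
      a <- atan2(v[2], v[1])
      u <- ((0 - a) %% (2 * pi)) * r  # cw from (0, base_y)
      out[i] <- tz_len + min(max(u - cut, 0), span)
    } else if (dr <= offpath_tol) {
      v <- p - arena$arm_right$center
      a <- atan2(v[2], v[1])
      u <- ((a - pi) %% (2 * pi)) * r
      out[i] <- tz_len + span + min(max(u - cut, 0), span)
    }
  }
  attr(out, "path_length") <- L
  out
}

#' Point on the canonical linearized loop
#'
#' Inverse of [linearize_position()] on the loop centerline.
#'
#' @param arena An [arena_eightmaze()].
#' @param s Arc length (m).
#' @return Two-column matrix of global x, y.
#' @export
linearized_point <- function(arena, s) {
  tz_len <- arena$turning_zone[2, 2] - arena$turning_zone_entry[2]
  r <- arena$arm_radius_m
  cut <- arena$arm_cut_m
  span <- 2 * pi * r - cut
  L <- tz_len + 2 * span
  s <- s %% L
  t(vapply(s, function(si) {
    if (si <= tz_len) {
      c(0, arena$turning_zone_entry[2] + si)
    } else if (si <= tz_len + span) {
      a <- -(si - tz_len + cut) / r  # cw
      arena$arm_left$center + r * c(cos(a), sin(a))
    } else {
      a <- pi + (si - tz_len - span + cut) / r  # ccw from angle pi
      arena$arm_right$center + r * c(cos(a), sin(a))
    }
  }, numeric(2)))
}

#' Build the predictor matrix
#'
#' Binary location block (half-open arc-length bins along the linearized
#' path, exactly one column set per in-maze sample), diagonalized event
#' blocks (each onset expanded into causal lagged indicator columns so the
#' regression learns a temporal response kernel), and z-scored continuous
#' covariates.
#'
#' @param s Linearized position per sample (m; NA off-maze), e.g. from
#'   [linearize_position()].
#' @param path_length Total path length (m); taken from the `s` attribute
#'   when present.
#' @param bin_length Location bin length (m): 0.02 (82-bin imaging
#'   reference) or 0.01 (196-bin ephys reference).
#' @param n_bins Override for the derived bin count (reference configs).
#' @param events Named list of integer onset sample indices per event type
#'   (auditory cues, reward dispensing).
#' @param event_lags Number of causal lag columns per event (default spans
#'   0-1 s at the activity sample rate).
#' @param sample_rate Activity sample rate (sets the default lag span).
#' @param covariates Optional matrix/data.frame of continuous covariates
#'   (velocity, acceleration, force per axis), z-scored into the matrix.
#' @return Matrix X (time x predictor) with attributes `blocks` (column
#'   index list), `n_offpath`, `bin_length`.
#' @export
build_predictors <- function(s, path_length = attr(s, "path_length"),
                             bin_length = 0.02, n_bins = NULL,
                             events = list(), event_lags = NULL,
                             sample_rate = 15, covariates = NULL) {
  stopifnot(bin_length > 0, !is.null(path_length))
  n <- length(s)
  if (is.null(n_bins)) n_bins <- ceiling(path_length / bin_length)
  bin <- ifelse(is.na(s), NA_integer_,
                pmin(floor(s / bin_length), n_bins - 1) + 1L)
  loc <- matrix(0, n, n_bins,
                dimnames = list(NULL, paste0("loc", seq_len(n_bins))))
  ok <- !is.na(bin)
  loc[cbind(which(ok), bin[ok])] <- 1
  blocks <- list(location = seq_len(n_bins))
  X <- loc
  if (is.null(event_lags)) event_lags <- max(1L, round(sample_rate))
  for (nm in names(events)) {
    E <- matrix(0, n, event_lags,
                dimnames = list(NULL, paste0(nm, "_lag", seq_len(event_lags) - 1)))
    for (on in events[[nm]]) {
      lag_idx <- on + seq_len(event_lags) - 1L
      keep <- lag_idx <= n & lag_idx >= 1
      E[cbind(lag_idx[keep], which(keep))] <- 1
    }
    blocks[[nm]] <- ncol(X) + seq_len(event_lags)
    X <- cbind(X, E)
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    cvz <- apply(cv, 2, function(x) {
      sdx <- stats::sd(x)
      if (sdx == 0) rep(0, length(x)) else (x - mean(x)) / sdx
    })
    if (is.null(colnames(cvz))) {
      colnames(cvz) <- paste0("cov", seq_len(ncol(cvz)))
    }
    blocks$covariates <- ncol(X) + seq_len(ncol(cvz))
    X <- cbind(X, cvz)
  }
  attr(X, "blocks") <- blocks
  attr(X, "n_offpath") <- sum(!ok)
  attr(X, "bin_length") <- bin_length
  X
}

#' Spatial-encoding kernel by pseudoinverse regression
#'
#' Solves Y = X K for the kernel of Beta weights with the Moore-Penrose
#' pseudoinverse (minimum-norm when X is rank deficient). Activity rows
#' where the mouse is stationary are zeroed before the regression; kernel
#' rows whose predictor column fires fewer than `min_instances` times are
#' zeroed to avoid over-fitting sparse events.
#'
#' @param Y time x cell activity matrix.
#' @param X time x predictor matrix.
#' @param stationary_mask Logical per sample.
#' @param min_instances Minimum nonzero samples per predictor column.
#' @return predictor x cell kernel matrix with attribute `zeroed_rows`.
#' @export
kernel_pinv <- function(Y, X, stationary_mask = NULL, min_instances = 5) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  if (!is.null(stationary_mask)) {
    stopifnot(length(stationary_mask) == nrow(Y))
    if (all(stationary_mask)) stop("all-stationary session: nothing to fit")
    Y[stationary_mask, ] <- 0
  }
  K <- MASS::ginv(X) %*% Y
  sparse <- which(colSums(X != 0) < min_instances)
  K[sparse, ] <- 0
  rownames(K) <- colnames(X)
  attr(K, "zeroed_rows") <- sparse
  K
}

#' Spatial-encoding kernel by reduced rank regression
#'
#' Least squares subject to rank(K) <= rank: the OLS solution followed by
#' projection onto the leading right singular vectors of the fitted
#' activity. Used when predictors co-occur (location plus diagonalized
#' events plus covariates); the residual norm is non-increasing in rank and
#' the full-rank solution equals OLS.
#'
#' @inheritParams kernel_pinv
#' @param rank Rank constraint, 1..min(ncol(X), ncol(Y)).
#' @return predictor x cell kernel matrix.
#' @export
kernel_rrr <- function(Y, X, rank, stationary_mask = NULL,
                       min_instances = 5) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  rmax <- min(ncol(X), ncol(Y))
  if (rank < 1 || rank > rmax) {
    stop(sprintf("rank must be in 1..%d", rmax))
  }
  if (!is.null(stationary_mask)) {
    if (all(stationary_mask)) stop("all-stationary session: nothing to fit")
    Y[stationary_mask, ] <- 0
  }
  B <- MASS::ginv(X) %*% Y
  fit <- X %*% B
  sv <- svd(fit, nu = 0, nv = rank)
  V <- sv$v[, seq_len(rank), drop = FALSE]
  K <- B %*% V %*% t(V)
  sparse <- which(colSums(X != 0) < min_instances)
  K[sparse, ] <- 0
  rownames(K) <- colnames(X)
  attr(K, "zeroed_rows") <- sparse
  K
}

#' Cross-validated rank selection for reduced rank regression
#'
#' Splits the samples into contiguous folds and picks the rank minimizing
#' held-out squared error.
#'
#' @inheritParams kernel_rrr
#' @param ranks Candidate ranks.
#' @param folds Number of contiguous folds.
#' @return Selected rank with attribute `cv_error` (per candidate).
#' @export
select_rank_cv <- function(Y, X, ranks = NULL, folds = 5) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (is.null(ranks)) ranks <- seq_len(min(ncol(X), ncol(Y)))
  fold_id <- cut(seq_len(n), folds, labels = FALSE)
  err <- sapply(ranks, function(r) {
    sum(sapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      K <- kernel_rrr(Y[tr, , drop = FALSE], X[tr, , drop = FALSE], r,
                      min_instances = 1)
      sum((Y[!tr, , drop = FALSE] - X[!tr, , drop = FALSE] %*% K)^2)
    }))
  })
  out <- ranks[which.min(err)]
  attr(out, "cv_error") <- stats::setNames(err, ranks)
  out
}

#' Normalize and sort a kernel
#'
#' Each cell (column) is scaled by its largest-magnitude Beta weight so the
#' maximum is exactly 1, then columns are arranged by the location onset of
#' their maximum (stable sort; all-zero cells last), or by cortical depth.
#'
#' @param K predictor x cell kernel.
#' @param order "onset_of_max" or "depth".
#' @param depth_table Numeric depth per cell (required for "depth").
#' @return Normalized, column-sorted kernel with attribute `permutation`.
#' @export
normalize_sort <- function(K, order = c("onset_of_max", "depth"),
                           depth_table = NULL) {
  order <- match.arg(order)
  K <- as.matrix(K)
  nz <- logical(ncol(K))
  Kn <- K
  for (j in seq_len(ncol(K))) {
    col <- K[, j]
    if (all(col == 0)) next
    nz[j] <- TRUE
    Kn[, j] <- col / col[which.max(abs(col))]
  }
  key <- if (order == "onset_of_max") {
    vapply(seq_len(ncol(Kn)), function(j) {
      if (!nz[j]) Inf else which.max(Kn[, j])
    }, numeric(1))
  } else {
    stopifnot(!is.null(depth_table), length(depth_table) == ncol(K))
    ifelse(nz, depth_table, Inf)
  }
  perm <- order(key)
  out <- Kn[, perm, drop = FALSE]
  attr(out, "permutation") <- perm
  out
}

#' Synthetic place-tuned neural session
#'
#' Place cells with Gaussian tuning over the linearized 8-maze path drive
#' Poisson spiking from a behavior session; for imaging, spikes are
#' convolved with an exponential calcium kernel and measured with white
#' noise plus a shared neuropil background. Ground truth (tuning table and
#' binned kernel) is returned for recovery tests. This is a synthetic
#' stand-in for recorded sessions; it emulates place tuning and measurement
#' noise, not the full diversity of real neural data.
#'
#' @param arena An [arena_eightmaze()].
#' @param n_cells Number of cells.
#' @param behavior Session log covering the maze (e.g.
#'   [maze_traversal_log()]).
#' @param seed Integer seed.
#' @param modality "imaging" (15 S/s fluorescence) or "ephys" (spike
#'   times).
#' @param peak_rate_hz Range from which per-cell peak rates are drawn.
#' @param tuning_width_m Gaussian tuning width (m).
#' @param noise_sd Fluorescence white-noise sd (imaging; 0 = noiseless).
#' @param neuropil_amp Amplitude of the shared neuropil background.
#' @param baseline Fluorescence baseline (a.u.).
#' @param calcium_tau_s Calcium decay time constant.
#' @param bin_length Bin length for the ground-truth kernel.
#' @return List: `session` ([fluor_session()] or [ephys_session()]),
#'   `rates` (time x cell expected rates), `spikes` (time x cell counts),
#'   `s` (linearized position), `K_true` (bin x cell ground-truth kernel),
#'   `cells` (tuning table).
#' @export
synth_neural_session <- function(arena, n_cells, behavior, seed = 1,
                                 modality = c("imaging", "ephys"),
                                 peak_rate_hz = c(2, 10),
                                 tuning_width_m = 0.05, noise_sd = 0,
                                 neuropil_amp = 20, baseline = 100,
                                 calcium_tau_s = 0.4, bin_length = 0.02) {
  modality <- match.arg(modality)
  s_full <- linearize_position(arena, cbind(behavior$x_m, behavior$y_m))
  if (all(is.na(s_full))) stop("behavior never enters the maze")
  L <- attr(s_full, "path_length")
  dt_log <- stats::median(diff(behavior$t_s))
  fs <- if (modality == "imaging") 15 else 50
  # resample behavior to the activity rate
  t_act <- seq(behavior$t_s[1], behavior$t_s[length(behavior$t_s)],
               by = 1 / fs)
  idx <- pmin(length(s_full),
              pmax(1, round((t_act - behavior$t_s[1]) / dt_log) + 1))
  s <- s_full[idx]
  attr(s, "path_length") <- L
  with_seed(seed, {
    cells <- data.frame(
      cell = seq_len(n_cells),
      center = stats::runif(n_cells, 0, L),
      width = tuning_width_m,
      peak_rate = stats::runif(n_cells, peak_rate_hz[1], peak_rate_hz[2]))
    rate <- matrix(0, length(s), n_cells)
    for (j in seq_len(n_cells)) {
      d <- abs(s - cells$center[j])
      d <- pmin(d, L - d)  # tuning wraps around the loop
      r <- cells$peak_rate[j] * exp(-d^2 / (2 * cells$width[j]^2))
      r[is.na(r)] <- 0
      rate[, j] <- r
    }
    spikes <- matrix(stats::rpois(length(rate), rate / fs), nrow(rate))
    n_bins <- ceiling(L / bin_length)
    centers <- (seq_len(n_bins) - 0.5) * bin_length
    K_true <- vapply(seq_len(n_cells), function(j) {
      d <- abs(centers - cells$center[j])
      d <- pmin(d, L - d)
      cells$peak_rate[j] * exp(-d^2 / (2 * cells$width[j]^2))
    }, numeric(n_bins))
    if (modality == "imaging") {
      kern_t <- seq(0, 5 * calcium_tau_s, by = 1 / fs)
      kern <- exp(-kern_t / calcium_tau_s)
      ca <- apply(spikes, 2, function(x) {
        y <- stats::convolve(x, rev(kern), type = "open")
        y[seq_along(x)]
      })
      neuropil <- neuropil_amp *
        (1 + as.numeric(stats::filter(stats::rnorm(nrow(ca)), 0.95,
                                      method = "recursive"))) / 10
      F_cell <- baseline + 20 * ca + 0.7 * neuropil +
        if (noise_sd > 0) matrix(stats::rnorm(length(ca), 0, noise_sd),
                                 nrow(ca)) else 0
      F_neu <- matrix(neuropil, nrow(ca), n_cells) +
        if (noise_sd > 0) matrix(stats::rnorm(length(ca), 0, noise_sd / 2),
                                 nrow(ca)) else 0
      morph <- data.frame(soma_px = rep(100, n_cells),
                          aspect_ratio = rep(1.1, n_cells),
                          diameter_um = rep(38, n_cells))
      session <- fluor_session(F_cell, F_neu, sample_rate = fs,
                               morphology = morph)
    } else {
      st <- lapply(seq_len(n_cells), function(j) {
        hits <- which(spikes[, j] > 0)
        sort(unlist(lapply(hits, function(i) {
          t_act[i] + stats::runif(spikes[i, j], 0, 1 / fs)
        })))
      })
      dur <- t_act[length(t_act)] + 1 / fs
      st <- lapply(st, function(x) pmin(x, dur))
      session <- ephys_session(st, duration = dur)
    }
    list(session = session, rates = rate, spikes = spikes, s = s,
         t_act = t_act, K_true = K_true, cells = cells)
  })
}

#' Scripted maze traversal
#'
#' Deterministic behavior log that walks the canonical linearized loop at
#' constant speed (with optional stationary pauses), guaranteeing coverage
#' of every location bin for encoding-recovery experiments.
#'
#' @param arena An [arena_eightmaze()].
#' @param n_laps Number of full loops.
#' @param speed m/s.
#' @param pause_s Stationary pause after each lap.
#' @param fs Samples per second.
#' @return Session log data.frame.
#' @export
maze_traversal_log <- function(arena, n_laps = 3, speed = 0.1, pause_s = 0,
                               fs = 100) {
  tz_len <- arena$turning_zone[2, 2] - arena$turning_zone_entry[2]
  L <- tz_len + 2 * (2 * pi * arena$arm_radius_m - arena$arm_cut_m)
  s <- c()
  for (k in seq_len(n_laps)) {
    s <- c(s, seq(0, L, by = speed / fs))
    if (pause_s > 0) s <- c(s, rep(L, round(pause_s * fs)))
  }
  xy <- linearized_point(arena, pmin(s, L - 1e-9))
  n <- length(s)
  data.frame(t_s = seq_len(n) / fs, x_m = xy[, 1], y_m = xy[, 2],
             z_m = arena$z_m, pitch_rad = arena$pitch_rad, roll_rad = 0,
             yaw_rad = 0, fx_N = 0, fy_N = 0, tz_Nm = 0,
             vcmd_x = speed, vcmd_y = 0, vcmd_yaw = 0,
             zone = "maze", event = "", stringsAsFactors = FALSE)
}
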