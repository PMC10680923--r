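# Calcium dF/F, cell QC, ephys preprocessing, predictor matrices, kernel
# regressions, and the synthetic place-tuned session generator

test_that("dF/F removes DC and recovers in-band transient amplitudes
           within 5%", {
  fs <- 15; n <- 1500; B <- 100; A <- 60
  t <- seq_len(n) / fs
  # indicator-like transient (50 ms rise, 0.4 s decay), in-band at 15 S/s
  g <- ifelse(t < 40, 0, (1 - exp(-(t - 40) / 0.05)) * exp(-(t - 40) / 0.4))
  Fc <- matrix(B + A * g / max(g), n, 1)
  sess <- fluor_session(Fc, matrix(0, n, 1), sample_rate = fs)
  dff <- compute_dff(sess)
  expect_equal(max(dff), 100 * A / B, tolerance = 0.05)
  # constant trace: band-pass removes DC entirely
  flat <- fluor_session(matrix(B, n, 1), matrix(0, n, 1), sample_rate = fs)
  expect_lt(max(abs(compute_dff(flat))), 1e-6)
})

test_that("the neuropil coefficient is exactly 0.7", {
  fs <- 15; n <- 600
  set.seed(41)
  Fc <- matrix(100 + rnorm(n), n, 1)
  Fn0 <- matrix(10, n, 1)
  delta <- matrix(0, n, 1); delta[300, 1] <- 5
  d0 <- compute_dff(fluor_session(Fc, Fn0, fs))
  d1 <- compute_dff(fluor_session(Fc, Fn0 + delta, fs))
  # numerator change is -0.7 * delta (scaled by the unchanged-mean denom)
  denom <- mean(Fc - 0.7 * (Fn0 + delta))
  num_change <- (d1[300] - d0[300]) / 100 * denom
  # compare against filtering the -0.7 delta through the same band-pass
  filt_delta <- exotwin:::butter_filtfilt(-0.7 * delta[, 1], "pass", 4,
                                          c(0.05, 5), fs)
  expect_equal(num_change, filt_delta[300] *
                 mean(Fc - 0.7 * Fn0) / denom, tolerance = 0.02)
})

test_that("non-positive dF/F denominators flag the cell invalid", {
  fs <- 15; n <- 300
  Fc <- matrix(c(rep(1, n), rep(100, n)), n, 2)
  Fn <- matrix(c(rep(10, n), rep(10, n)), n, 2)  # cell 1: 1 - 7 < 0
  dff <- compute_dff(fluor_session(Fc, Fn, fs))
  expect_equal(attr(dff, "invalid_cells"), 1L)
  expect_true(all(is.na(dff[, 1])))
  expect_false(anyNA(dff[, 2]))
})

test_that("cell filter applies all five criteria with inclusive bounds", {
  # columns engineered per criterion; sd of a two-point burst is small
  n <- 400
  mk <- function(maxv, base = 0) {
    x <- rep(base, n); x[200] <- maxv; x
  }
  dff <- cbind(mk(600), mk(10), mk(80), mk(80), mk(80))
  morph <- data.frame(soma_px = c(100, 100, 10, 100, 100),
                      aspect_ratio = c(1.1, 1.1, 1.1, 2.0, 1.1))
  keep <- filter_cells(dff, morph)
  expect_equal(as.logical(keep), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # boundary somas are inclusive
  dff2 <- cbind(mk(80), mk(80))
  morph2 <- data.frame(soma_px = c(20, 400), aspect_ratio = c(0.7, 1.4))
  expect_equal(as.logical(filter_cells(dff2, morph2)), c(TRUE, TRUE))
})

test_that("common-mode interference on in-brain channels is removed", {
  fs <- 20000
  t <- seq(0, 0.5, by = 1 / fs)[-1]
  hum <- 50 * sin(2 * pi * 60 * t)
  set.seed(3)
  v <- matrix(rnorm(length(t) * 4, sd = 1e-3), ncol = 4) + hum
  sess <- ephys_session(list(c(0.1)), duration = 0.5, voltages = v,
                        in_brain_mask = rep(TRUE, 4), sample_rate = fs)
  out <- preprocess_ephys(sess)
  # the shared 60 Hz is annihilated far below its input amplitude
  amp <- max(abs(out$voltages_clean))
  expect_lt(amp / 50, 1e-10 + 1e-3)
})

test_that("spike rates resample at exactly 50 S/s and match a Poisson
           oracle", {
  set.seed(8)
  lam <- 6
  st <- list(sort(stats::runif(round(lam * 200), 0, 200)))
  sess <- ephys_session(st, duration = 200)
  out <- preprocess_ephys(sess)
  expect_equal(unique(round(diff(out$rate_times_s), 12)), 0.02)
  expect_equal(mean(out$counts), lam * 0.05,
               tolerance = 3 * sqrt(lam * 0.05 / length(out$counts)) /
                 (lam * 0.05))
  # z-scored output: mean 0, sd 1
  expect_equal(mean(out$rates), 0, tolerance = 1e-10)
  expect_equal(stats::sd(out$rates), 1, tolerance = 1e-3)
})

test_that("silent cells are flagged and retained as zeros", {
  sess <- ephys_session(list(numeric(0), sort(runif(100, 0, 50))),
                        duration = 50)
  out <- preprocess_ephys(sess)
  expect_true(1 %in% out$flat_cells)
  expect_true(all(out$rates[, 1] == 0))
})

test_that("location rows are one-hot for in-maze samples and the block has
           full rank once all bins are visited", {
  maze <- arena_eightmaze()
  beh <- maze_traversal_log(maze, n_laps = 2, speed = 0.1)
  s <- linearize_position(maze, cbind(beh$x_m, beh$y_m))
  X <- build_predictors(s, bin_length = 0.02, sample_rate = 100)
  loc <- X[, attr(X, "blocks")$location]
  expect_true(all(rowSums(loc) %in% c(0, 1)))
  expect_equal(sum(rowSums(loc) == 1), sum(!is.na(s)))
  expect_equal(qr(loc)$rank, ncol(loc))
  expect_equal(attr(X, "n_offpath"), sum(is.na(s)))
})

test_that("diagonalized events expand onsets into causal lag columns", {
  s <- rep(NA_real_, 50); attr(s, "path_length") <- 1
  X <- build_predictors(s, bin_length = 0.5,
                        events = list(cue = c(10)), event_lags = 5)
  cue_cols <- X[, attr(X, "blocks")$cue]
  expect_equal(dim(cue_cols), c(50, 5))
  for (l in 1:5) {
    expect_equal(sum(cue_cols[, l]), 1)
    expect_equal(which(cue_cols[, l] == 1), 10 + l - 1)
  }
})

test_that("continuous covariates are z-scored into the matrix", {
  s <- rep(0.1, 30); attr(s, "path_length") <- 1
  cov <- cbind(vel = 1:30, frc = rep(2, 30))
  X <- build_predictors(s, bin_length = 0.5, covariates = cov)
  cz <- X[, attr(X, "blocks")$covariates]
  expect_equal(mean(cz[, 1]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(cz[, 1]), 1, tolerance = 1e-12)
  expect_equal(cz[, 2], rep(0, 30))  # zero-variance covariate stays zero
})

test_that("kernel_pinv exactly recovers a known kernel from noiseless
           data", {
  set.seed(12)
  n <- 300; bins <- 10; cells <- 4
  bin_id <- sample(bins, n, replace = TRUE)
  X <- matrix(0, n, bins); X[cbind(1:n, bin_id)] <- 1
  K_true <- matrix(runif(bins * cells), bins, cells)
  Y <- X %*% K_true
  K <- kernel_pinv(Y, X)
  expect_lt(max(abs(K - K_true)), 1e-8)
})

test_that("kernel_pinv equals per-bin mean activity for one-hot
           predictors", {
  set.seed(14)
  n <- 500; bins <- 8; cells <- 3
  bin_id <- sample(bins, n, replace = TRUE)
  X <- matrix(0, n, bins); X[cbind(1:n, bin_id)] <- 1
  Y <- matrix(rnorm(n * cells), n, cells)
  K <- kernel_pinv(Y, X)
  oracle <- t(vapply(1:bins, function(b) colMeans(Y[bin_id == b, ,
                                                    drop = FALSE]),
                     numeric(cells)))
  expect_equal(matrix(K, bins), matrix(oracle, bins), tolerance = 1e-10)
})

test_that("a cell firing only in one bin yields a single nonzero kernel
           row", {
  n <- 60; bins <- 3
  bin_id <- rep(1:3, each = 20)
  X <- matrix(0, n, bins); X[cbind(1:n, bin_id)] <- 1
  Y <- matrix(0, n, 1); Y[bin_id == 2, 1] <- 5
  K <- kernel_pinv(Y, X)
  expect_equal(as.numeric(K), c(0, 5, 0), tolerance = 1e-10)
})

test_that("sparse predictor columns (under 5 instances) are zeroed", {
  n <- 100
  X <- cbind(rep(1, n), c(rep(1, 4), rep(0, n - 4)))
  Y <- matrix(rnorm(n), n, 1)
  K <- kernel_pinv(Y, X)
  expect_equal(attr(K, "zeroed_rows"), 2L)
  expect_equal(K[2, 1], 0)
  # 5 instances survive
  X5 <- cbind(rep(1, n), c(rep(1, 5), rep(0, n - 5)))
  expect_length(attr(kernel_pinv(Y, X5), "zeroed_rows"), 0)
})

test_that("stationary samples are zeroed before the fit and an
           all-stationary session errors", {
  set.seed(15)
  n <- 200; bins <- 4
  bin_id <- sample(bins, n, replace = TRUE)
  X <- matrix(0, n, bins); X[cbind(1:n, bin_id)] <- 1
  Y <- matrix(rnorm(n, mean = 5), n, 1)
  mask <- rep(c(TRUE, FALSE), n / 2)
  K <- kernel_pinv(Y, X, stationary_mask = mask)
  Y2 <- Y; Y2[mask, ] <- 0
  expect_equal(K, kernel_pinv(Y2, X))
  expect_error(kernel_pinv(Y, X, stationary_mask = rep(TRUE, n)),
               "stationary")
})

test_that("reduced rank regression: full rank equals OLS, rank-1 recovery,
           monotone residual", {
  set.seed(18)
  n <- 400; p <- 12; q <- 6
  X <- matrix(rnorm(n * p), n, p)
  K1 <- outer(rnorm(p), rnorm(q))  # rank-1 truth
  Y <- X %*% K1
  expect_lt(max(abs(kernel_rrr(Y, X, 1, min_instances = 1) - K1)), 1e-6)
  Yn <- Y + matrix(rnorm(n * q, sd = 0.5), n, q)
  K_ols <- kernel_pinv(Yn, X, min_instances = 1)
  expect_lt(max(abs(kernel_rrr(Yn, X, min(p, q), min_instances = 1) -
                      K_ols)), 1e-8)
  res <- vapply(1:q, function(r) {
    sum((Yn - X %*% kernel_rrr(Yn, X, r, min_instances = 1))^2)
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-8))
  expect_error(kernel_rrr(Yn, X, 0), "rank")
  expect_error(kernel_rrr(Yn, X, 50), "rank")
})

test_that("cross-validated rank selection finds a low-rank structure", {
  set.seed(19)
  n <- 300; p <- 8; q <- 5
  X <- matrix(rnorm(n * p), n, p)
  K2 <- outer(rnorm(p), rnorm(q)) + outer(rnorm(p), rnorm(q))
  Y <- X %*% K2 + matrix(rnorm(n * q, sd = 0.3), n, q)
  r <- select_rank_cv(Y, X, folds = 3)
  expect_lte(as.numeric(r), 4)
  expect_gte(as.numeric(r), 2)
})

test_that("normalize_sort scales maxima to 1, sorts stably, and is
           permutation invariant", {
  K <- cbind(c(0, 2, 1), c(3, 0, 0), c(0, 0, 0), c(0, 1, 4))
  out <- normalize_sort(K)
  expect_equal(max(out[, 1]), 1)
  # sorted by onset of maximum; all-zero cell last
  onsets <- apply(out, 2, which.max)
  expect_equal(attr(out, "permutation"), c(2L, 1L, 4L, 3L))
  perm_in <- K[, c(3, 1, 4, 2)]
  out2 <- normalize_sort(perm_in)
  expect_equal(matrix(out2, nrow(out2)), matrix(out, nrow(out)))
  # depth ordering
  outd <- normalize_sort(K, order = "depth",
                         depth_table = c(0.3, 0.1, 0.2, 0.05))
  expect_equal(attr(outd, "permutation"), c(4L, 2L, 1L, 3L))
})

test_that("zero-noise synthetic sessions are recovered almost perfectly by
           kernel_pinv", {
  maze <- arena_eightmaze()
  beh <- maze_traversal_log(maze, n_laps = 6, speed = 0.1)
  syn <- synth_neural_session(maze, n_cells = 50, behavior = beh, seed = 5)
  X <- build_predictors(syn$s, bin_length = 0.02, sample_rate = 15)
  K <- kernel_pinv(syn$rates, X)  # expected rates: no measurement noise
  pk_true <- apply(syn$K_true, 2, which.max)
  pk_est <- apply(K[seq_len(nrow(syn$K_true)), ], 2, which.max)
  expect_gte(mean(abs(pk_est - pk_true) <= 1), 0.95)
})

test_that("a zero-peak-rate cell has an all-zero kernel column", {
  maze <- arena_eightmaze()
  beh <- maze_traversal_log(maze, n_laps = 2, speed = 0.1)
  syn <- synth_neural_session(maze, n_cells = 3, behavior = beh, seed = 6,
                              peak_rate_hz = c(0, 0))
  X <- build_predictors(syn$s, bin_length = 0.02, sample_rate = 15)
  K <- kernel_pinv(syn$spikes, X)
  expect_true(all(K == 0))
})

test_that("synthetic sessions are seed-deterministic across modalities", {
  maze <- arena_eightmaze()
  beh <- maze_traversal_log(maze, n_laps = 1, speed = 0.12)
  a <- synth_neural_session(maze, 5, beh, seed = 9)
  b <- synth_neural_session(maze, 5, beh, seed = 9)
  expect_identical(a$session$F_cell, b$session$F_cell)
  e1 <- synth_neural_session(maze, 5, beh, seed = 9, modality = "ephys")
  e2 <- synth_neural_session(maze, 5, beh, seed = 9, modality = "ephys")
  expect_identical(e1$session$spike_times, e2$session$spike_times)
  expect_error(
    synth_neural_session(maze, 5,
                         within(beh, {x_m <- x_m + 10}), seed = 1),
    "never enters")
})

test_that("place-field recovery degrades gracefully with rate noise", {
  # noise enters the inferred rates the kernel consumes (spike inference
  # is upstream); three levels from clean to rate-sized
  maze <- arena_eightmaze()
  beh <- maze_traversal_log(maze, n_laps = 8, speed = 0.1)
  syn <- synth_neural_session(maze, n_cells = 30, behavior = beh,
                              seed = 30, peak_rate_hz = c(8, 15))
  X <- build_predictors(syn$s, bin_length = 0.02, sample_rate = 15)
  pk_true <- apply(syn$K_true, 2, which.max)
  set.seed(77)
  recovery <- vapply(c(0, 0.5, 3), function(ns) {
    Y <- syn$rates + matrix(rnorm(length(syn$rates), 0, ns),
                            nrow(syn$rates))
    K <- kernel_pinv(Y, X)
    pk_est <- apply(K[seq_len(nrow(syn$K_true)), ], 2, which.max)
    mean(abs(pk_est - pk_true) <= 1)
  }, numeric(1))
  expect_gte(recovery[1], 0.95)
  expect_gte(recovery[2], 0.7)
  expect_true(all(diff(recovery) <= 0.05))  # non-improving with noise
})

test_that("the composed imaging pipeline yields a diagonally dominant
           sorted kernel", {
  maze <- arena_eightmaze()
  beh <- maze_traversal_log(maze, n_laps = 8, speed = 0.1)
  syn <- synth_neural_session(maze, n_cells = 60, behavior = beh,
                              seed = 44, noise_sd = 2,
                              peak_rate_hz = c(8, 15))
  dff <- compute_dff(syn$session)
  keep <- filter_cells(dff, syn$session$morphology,
                       max_range = c(0, Inf), sd_limit = Inf)
  X <- build_predictors(syn$s, bin_length = 0.02, sample_rate = 15)
  K <- kernel_pinv(dff[, keep, drop = FALSE], X)
  Kn <- normalize_sort(K[seq_len(ceiling(attr(syn$s, "path_length") /
                                           0.02)), ])
  # mass concentrates near the sorted diagonal
  n_bins <- nrow(Kn); n_cells <- ncol(Kn)
  frac <- vapply(seq_len(n_cells), function(j) {
    peak <- which.max(Kn[, j])
    expected_band <- abs(seq_len(n_bins) - peak) <= 3
    sum(pmax(Kn[expected_band, j], 0)) / max(sum(pmax(Kn[, j], 0)), 1e-12)
  }, numeric(1))
  expect_gt(mean(frac > 0.6), 0.6)
})

test_that("neural sessions and kernels round-trip through the text
           formats", {
  maze <- arena_eightmaze()
  beh <- maze_traversal_log(maze, n_laps = 1, speed = 0.15)
  syn <- synth_neural_session(maze, 4, beh, seed = 2, noise_sd = 1)
  csv <- tempfile(fileext = ".csv")
  write_fluor_session(syn$session, csv)
  back <- read_fluor_session(csv)
  expect_equal(back$F_cell, syn$session$F_cell, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$sample_rate, 15)
  expect_equal(back$morphology$soma_px, syn$session$morphology$soma_px)
  eph <- synth_neural_session(maze, 4, beh, seed = 2, modality = "ephys")
  spk <- tempfile(fileext = ".csv")
  write_spike_csv(eph$session, spk)
  back_e <- read_spike_csv(spk)
  expect_equal(back_e$spike_times, eph$session$spike_times,
               tolerance = 1e-10)
  K <- matrix(rnorm(12), 4, 3)
  kf <- tempfile(fileext = ".csv")
  write_kernel_csv(K, kf)
  expect_equal(read_kernel_csv(kf), K, tolerance = 1e-12)
})
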