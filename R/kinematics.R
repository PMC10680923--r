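#' Inverse kinematics of the delta robot
#'
#' Geometric (loop-closure) solution: for each arm the platform attachment
#' point is pulled back by the moving-platform radius, leaving a two-link
#' planar problem in the arm's vertical plane plus an out-of-plane offset.
#' Of the two elbow branches the knuckles-out solution (elbow radially
#' outboard of the platform) is selected, which is the branch physical
#' delta robots are assembled in.
#'
#' @param position Platform center position, numeric(3), meters, in the base
#'   frame (origin at the fixed platform center, z up).
#' @param geom A [delta_geometry()].
#' @return Numeric(3) joint angles (rad) with attribute `within_limits`, a
#'   logical(3) flagging angles inside the actuated joint limits. Angles
#'   outside the limits are flagged, never clamped.
#' @seealso [delta_fk()]
#' @export
delta_ik <- function(position, geom = delta_geometry()) {
  stopifnot(length(position) == 3, all(is.finite(position)))
  u <- arm_azimuths()
  lp <- geom$len_proximal; ld <- geom$len_distal
  th <- numeric(3)
  for (i in 1:3) {
    ui <- c(u[i, ], 0)
    wi <- c(-u[i, 2], u[i, 1], 0)
    q <- position + geom$r_moving * ui - geom$r_fixed * ui
    a <- sum(q * ui); b <- q[3]; cc <- sum(q * wi)
    e <- (sum(q^2) + lp^2 - ld^2) / (2 * lp)
    rho <- sqrt(a^2 + b^2)
    if (rho < .Machine$double.eps || abs(e) > rho) {
      stop(sprintf("position out of workspace: arm %d cannot close its loop", i))
    }
    phi0 <- atan2(b, a)
    alpha <- acos(pmin(1, pmax(-1, e / rho)))
    cand <- c(phi0 + alpha, phi0 - alpha)
    cand <- atan2(sin(cand), cos(cand))  # wrap to (-pi, pi]
    # knuckles-out: elbow as far outboard (radially) as possible
    pick <- if (cos(cand[1]) > cos(cand[2])) 1L else if
            (cos(cand[2]) > cos(cand[1])) 2L else which.min(cand)
    th[i] <- cand[pick]
  }
  lo <- deg2rad(geom$joint_limit_low); hi <- deg2rad(geom$joint_limit_high)
  attr(th, "within_limits") <- th >= lo & th <= hi
  th
}

# sphere centers for forward kinematics: platform center must lie at
# distance len_distal from each knee pulled back by the moving radius
delta_sphere_centers <- function(delta_angles, geom) {
  u <- arm_azimuths()
  r <- geom$r_fixed - geom$r_moving
  ct <- cos(delta_angles); st <- sin(delta_angles)
  t(vapply(1:3, function(i) {
    c((r + geom$len_proximal * ct[i]) * u[i, ],
      geom$len_proximal * st[i])
  }, numeric(3)))
}

# three-sphere intersection, equal radii; returns both points (rows) or NULL
trilaterate <- function(centers, radius) {
  p1 <- centers[1, ]; p2 <- centers[2, ]; p3 <- centers[3, ]
  ex <- p2 - p1; d <- sqrt(sum(ex^2)); ex <- ex / d
  t3 <- p3 - p1
  i <- sum(ex * t3)
  ey <- t3 - i * ex; j <- sqrt(sum(ey^2)); ey <- ey / j
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  x <- d / 2
  y <- (i^2 + j^2 - 2 * i * x) / (2 * j)
  h2 <- radius^2 - x^2 - y^2
  if (h2 < 0) return(NULL)
  base <- p1 + x * ex + y * ey
  h <- sqrt(h2)
  rbind(base + h * ez, base - h * ez)
}

#' Forward kinematics of the delta robot
#'
#' Intersects the three spheres of distal-link reach (one per arm) and takes
#' the lower-z intersection, the branch in which the platform hangs below
#' the arms.
#'
#' @param delta_angles Numeric(3) actuated joint angles (rad).
#' @param geom A [delta_geometry()].
#' @return Platform center position, numeric(3) (m).
#' @export
delta_fk <- function(delta_angles, geom = delta_geometry()) {
  stopifnot(length(delta_angles) == 3, all(is.finite(delta_angles)))
  pts <- trilaterate(delta_sphere_centers(delta_angles, geom),
                     geom$len_distal)
  if (is.null(pts)) {
    stop("invalid configuration: distal-link spheres do not intersect")
  }
  pts[which.min(pts[, 3]), ]
}

# rotation matrices about fixed axes
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
drot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(0, 0, 0, 0, -sa, ca, 0, -ca, -sa), 3, 3)
}
drot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(-sa, 0, -ca, 0, 0, 0, ca, 0, -sa), 3, 3)
}
ddrot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(0, 0, 0, 0, -ca, -sa, 0, sa, -ca), 3, 3)
}
ddrot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(-ca, 0, sa, 0, 0, 0, -sa, 0, -ca), 3, 3)
}

# orientation of the pivot extension: pitch about y, then roll about x
gonio_rotation <- function(pitch, roll) rot_y(pitch) %*% rot_x(roll)

#' Pose of the virtual pivot point
#'
#' Composes delta forward kinematics with the goniometer chain. The pivot
#' sits `offset_a1` below the platform center at the common rotation point,
#' then `pivot_extension_a4` along the (pitched and rolled) downward axis.
#' Yaw is the final axis, aligned with the pivot extension, so it changes
#' orientation only.
#'
#' @param cfg A [joint_config()].
#' @param dg A [delta_geometry()].
#' @param gg A [goniometer_geometry()].
#' @return An object of class `pivot_pose`: list with `position`
#'   (numeric(3), m) and `orientation` (pitch, roll, yaw; rad, yaw
#'   accumulated/unbounded).
#' @export
pivot_pose <- function(cfg, dg = delta_geometry(), gg = goniometer_geometry()) {
  p <- delta_fk(cfg$delta_angles, dg)
  ang <- cfg$gonio_angles
  rotpt <- p - c(0, 0, gg$offset_a1)
  v <- gonio_rotation(ang[1], ang[2]) %*% c(0, 0, -gg$pivot_extension_a4)
  structure(list(position = as.numeric(rotpt + v),
                 orientation = c(pitch = ang[1], roll = ang[2], yaw = ang[3])),
            class = "pivot_pose")
}

# delta velocity relationship A %*% pdot = B %*% thetadot, with A rows the
# distal-link vectors and B the diagonal of their projections on the knee
# tangents (the vector method)
delta_jac_parts <- function(delta_angles, geom) {
  u <- arm_azimuths()
  p <- delta_fk(delta_angles, geom)
  ct <- cos(delta_angles); st <- sin(delta_angles)
  A <- matrix(0, 3, 3); Bd <- numeric(3)
  K <- matrix(0, 3, 3); tang <- matrix(0, 3, 3)
  for (i in 1:3) {
    ui <- c(u[i, ], 0)
    K[i, ] <- geom$r_fixed * ui + geom$len_proximal * c(ct[i] * u[i, ], st[i])
    att <- p + geom$r_moving * ui
    d <- att - K[i, ]
    tang[i, ] <- geom$len_proximal * c(-st[i] * u[i, ], ct[i])
    A[i, ] <- d
    Bd[i] <- sum(d * tang[i, ])
  }
  list(A = A, Bd = Bd, p = p, K = K, tang = tang)
}

#' Jacobian of the pivot pose
#'
#' 6x6 matrix mapping joint rates (three delta, three goniometer) to the
#' pivot pose rates (x, y, z, pitch, roll, yaw). The delta sub-block comes
#' from the vector method (distal-link loop closure); the goniometer
#' position columns from differentiating the rotation chain. Configurations
#' whose condition number exceeds `cond_threshold` are flagged singular
#' (the matrix is still returned, via a pseudoinverse solve if needed).
#'
#' @inheritParams pivot_pose
#' @param cond_threshold Condition number above which the configuration is
#'   flagged singular.
#' @return 6x6 matrix with attribute `singular` (logical).
#' @export
jacobian <- function(cfg, dg = delta_geometry(), gg = goniometer_geometry(),
                     cond_threshold = 1e6) {
  parts <- delta_jac_parts(cfg$delta_angles, dg)
  B <- diag(parts$Bd, 3)
  Jd <- tryCatch(solve(parts$A, B), error = function(e) NULL)
  sing <- FALSE
  if (is.null(Jd)) {
    Jd <- MASS::ginv(parts$A) %*% B
    sing <- TRUE
  }
  ang <- cfg$gonio_angles
  a4v <- c(0, 0, -gg$pivot_extension_a4)
  dpitch <- (drot_y(ang[1]) %*% rot_x(ang[2])) %*% a4v
  droll <- (rot_y(ang[1]) %*% drot_x(ang[2])) %*% a4v
  J <- matrix(0, 6, 6)
  J[1:3, 1:3] <- Jd
  J[1:3, 4] <- dpitch
  J[1:3, 5] <- droll
  J[4:6, 4:6] <- diag(3)
  if (!sing) sing <- kappa(J, exact = TRUE) > cond_threshold
  attr(J, "singular") <- sing
  J
}

#' Reachable workspace of the delta robot
#'
#' Sweeps the three actuated joints over their limit range on a regular
#' grid, evaluates forward kinematics (vectorized, in chunks), bins the
#' reachable platform positions into z slices, and reports per slice the
#' side of the largest axis-aligned square centered on the robot axis whose
#' every occupancy cell is reached.
#'
#' @param dg A [delta_geometry()].
#' @param grid_resolution Joint grid step (rad).
#' @param z_slice Thickness of z slices (m).
#' @param cell Occupancy cell size in x-y (m).
#' @param chunk Number of joint triples per vectorized chunk.
#' @return A list of class `exo_workspace`: `slices` (data.frame with
#'   `z_lo`, `z_hi`, `n_points`, `square_side_m`), `max_square_side_m`,
#'   `best_z_m`, and `empty` (TRUE when no grid point is reachable; a
#'   degenerate geometry yields an explicit empty report, not an error).
#' @export
workspace_extent <- function(dg = delta_geometry(),
                             grid_resolution = deg2rad(0.5),
                             z_slice = 0.02, cell = 0.01, chunk = 2e6) {
  stopifnot(grid_resolution > 0)
  lo <- deg2rad(dg$joint_limit_low); hi <- deg2rad(dg$joint_limit_high)
  th <- seq(lo, hi, by = grid_resolution)
  if (length(th) < 1 || th[length(th)] < hi) th <- c(th, hi)
  n <- length(th)
  u <- arm_azimuths()
  r <- dg$r_fixed - dg$r_moving
  # per-arm sphere centers depend on one angle each
  cx <- lapply(1:3, function(i) (r + dg$len_proximal * cos(th)) * u[i, 1])
  cy <- lapply(1:3, function(i) (r + dg$len_proximal * cos(th)) * u[i, 2])
  cz <- dg$len_proximal * sin(th)
  total <- as.double(n)^3
  per_i <- n * n  # triples per outer index
  outer_per_chunk <- max(1L, as.integer(chunk / per_i))
  idx23 <- expand.grid(j = seq_len(n), k = seq_len(n))
  occ <- new.env(parent = emptyenv())  # z-slice id -> set of xy cell ids
  counts <- new.env(parent = emptyenv())
  i_start <- 1L
  while (i_start <= n) {
    i_end <- min(n, i_start + outer_per_chunk - 1L)
    ii <- rep(i_start:i_end, each = per_i)
    jj <- rep(idx23$j, times = i_end - i_start + 1L)
    kk <- rep(idx23$k, times = i_end - i_start + 1L)
    p <- trilaterate_vec(
      cbind(cx[[1]][ii], cy[[1]][ii], cz[ii]),
      cbind(cx[[2]][jj], cy[[2]][jj], cz[jj]),
      cbind(cx[[3]][kk], cy[[3]][kk], cz[kk]),
      dg$len_distal)
    ok <- !is.na(p[, 3])
    if (any(ok)) {
      x <- p[ok, 1]; y <- p[ok, 2]; z <- p[ok, 3]
      zi <- floor(z / z_slice)
      xi <- floor(x / cell); yi <- floor(y / cell)
      for (zz in unique(zi)) {
        key <- as.character(zz)
        sel <- zi == zz
        cells <- unique((xi[sel] + 1e6) * 4e6 + (yi[sel] + 1e6))
        occ[[key]] <- unique(c(occ[[key]], cells))
        counts[[key]] <- sum(counts[[key]], sum(sel))
      }
    }
    i_start <- i_end + 1L
  }
  keys <- ls(occ)
  if (length(keys) == 0) {
    return(structure(list(slices = data.frame(z_lo = numeric(0),
                                              z_hi = numeric(0),
                                              n_points = integer(0),
                                              square_side_m = numeric(0)),
                          max_square_side_m = 0, best_z_m = NA_real_,
                          empty = TRUE),
                     class = "exo_workspace"))
  }
  slices <- do.call(rbind, lapply(keys, function(key) {
    zz <- as.numeric(key)
    cells <- occ[[key]]
    xi <- floor(cells / 4e6) - 1e6
    yi <- (cells %% 4e6) - 1e6
    side <- centered_square_side(xi, yi, cell)
    data.frame(z_lo = zz * z_slice, z_hi = (zz + 1) * z_slice,
               n_points = counts[[key]], square_side_m = side)
  }))
  slices <- slices[order(slices$z_lo), ]
  rownames(slices) <- NULL
  best <- which.max(slices$square_side_m)
  structure(list(slices = slices,
                 max_square_side_m = slices$square_side_m[best],
                 best_z_m = (slices$z_lo[best] + slices$z_hi[best]) / 2,
                 empty = FALSE),
            class = "exo_workspace")
}

# vectorized three-sphere intersection; rows of c1/c2/c3 are sphere centers;
# returns lower-z intersection point per row, NA when spheres miss
trilaterate_vec <- function(c1, c2, c3, radius) {
  ex <- c2 - c1
  d <- sqrt(rowSums(ex^2)); ex <- ex / d
  t3 <- c3 - c1
  i <- rowSums(ex * t3)
  ey <- t3 - i * ex
  j <- sqrt(rowSums(ey^2)); ey <- ey / j
  ez <- cbind(ex[, 2] * ey[, 3] - ex[, 3] * ey[, 2],
              ex[, 3] * ey[, 1] - ex[, 1] * ey[, 3],
              ex[, 1] * ey[, 2] - ex[, 2] * ey[, 1])
  x <- d / 2
  y <- (i^2 + j^2 - 2 * i * x) / (2 * j)
  h2 <- radius^2 - x^2 - y^2
  h <- sqrt(ifelse(h2 < 0, NA_real_, h2))
  base <- c1 + x * ex + y * ey
  # lower-z branch: ez z-component sign decides which root is lower
  s <- ifelse(ez[, 3] > 0, -1, 1)
  base + (s * h) * ez
}

# side of the largest square centered on the origin fully covered by
# occupied cells (cell indices are floor(x/cell))
centered_square_side <- function(xi, yi, cell) {
  kmax <- min(max(xi) + 1, max(yi) + 1, -min(xi), -min(yi))
  if (!is.finite(kmax) || kmax < 1) return(0)
  have <- paste(xi, yi)
  for (k in 1:kmax) {
    ring <- expand.grid(x = (-k):(k - 1), y = (-k):(k - 1))
    ring <- ring[pmax(ring$x + 1, ring$y + 1, -ring$x, -ring$y) == k, ]
    if (!all(paste(ring$x, ring$y) %in% have)) return(2 * (k - 1) * cell)
  }
  2 * kmax * cell
}

#' @export
print.exo_workspace <- function(x, ...) {
  if (x$empty) {
    cat("delta workspace: empty (no reachable grid point)\n")
  } else {
    cat(sprintf(
      "delta workspace: %d z slices; largest centered square %.1f cm at z = %.2f m\n",
      nrow(x$slices), 100 * x$max_square_side_m, x$best_z_m))
  }
  invisible(x)
}
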