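# Piecewise centerline paths (line segments and circular arcs) with
# arc-length parameterization. Used by the oval track and the 8-maze goal
# arms.

path_segment_line <- function(p0, p1) {
  L <- sqrt(sum((p1 - p0)^2))
  list(type = "line", p0 = p0, p1 = p1, length = L)
}

# ccw: TRUE if the arc is traversed counterclockwise from a0
path_segment_arc <- function(center, radius, a0, a1, ccw = TRUE) {
  sweep <- if (ccw) (a1 - a0) %% (2 * pi) else (a0 - a1) %% (2 * pi)
  if (sweep == 0) sweep <- 2 * pi
  list(type = "arc", center = center, radius = radius, a0 = a0,
       ccw = ccw, sweep = sweep, length = radius * sweep)
}

make_path <- function(segments, closed = TRUE) {
  lens <- vapply(segments, `[[`, numeric(1), "length")
  list(segments = segments, cum = c(0, cumsum(lens)),
       length = sum(lens), closed = closed)
}

# point and tangent heading at arc length s (wrapped if closed)
path_point <- function(path, s) {
  if (path$closed) s <- s %% path$length else s <- min(max(s, 0), path$length)
  k <- findInterval(s, path$cum, rightmost.closed = TRUE)
  k <- min(max(k, 1L), length(path$segments))
  seg <- path$segments[[k]]
  ds <- s - path$cum[k]
  if (seg$type == "line") {
    dir <- (seg$p1 - seg$p0) / seg$length
    list(xy = seg$p0 + ds * dir, heading = atan2(dir[2], dir[1]))
  } else {
    a <- if (seg$ccw) seg$a0 + ds / seg$radius else seg$a0 - ds / seg$radius
    xy <- seg$center + seg$radius * c(cos(a), sin(a))
    heading <- if (seg$ccw) a + pi / 2 else a - pi / 2
    list(xy = xy, heading = atan2(sin(heading), cos(heading)))
  }
}

# arc length of the closest point on the path to p
path_project <- function(path, p) {
  best_s <- 0; best_d <- Inf
  for (k in seq_along(path$segments)) {
    seg <- path$segments[[k]]
    if (seg$type == "line") {
      dir <- (seg$p1 - seg$p0) / seg$length
      t <- sum((p - seg$p0) * dir)
      t <- min(max(t, 0), seg$length)
      q <- seg$p0 + t * dir
      d <- sum((p - q)^2)
      if (d < best_d) { best_d <- d; best_s <- path$cum[k] + t }
    } else {
      v <- p - seg$center
      a <- atan2(v[2], v[1])
      da <- if (seg$ccw) (a - seg$a0) %% (2 * pi) else (seg$a0 - a) %% (2 * pi)
      ds <- min(da * seg$radius, seg$length)
      q <- path_point(make_path(list(seg), closed = FALSE), ds)$xy
      d <- sum((p - q)^2)
      if (d < best_d) { best_d <- d; best_s <- path$cum[k] + ds }
      # also consider the segment endpoints (angle outside the sweep)
      for (send in c(0, seg$length)) {
        q <- path_point(make_path(list(seg), closed = FALSE), send)$xy
        d <- sum((p - q)^2)
        if (d < best_d) { best_d <- d; best_s <- path$cum[k] + send }
      }
    }
  }
  best_s
}
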