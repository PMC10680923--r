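# Shared fixtures: default geometries and a sampler of in-workspace
# platform positions (rejection sampling through inverse kinematics).

default_dg <- delta_geometry()
default_gg <- goniometer_geometry()

sample_workspace_positions <- function(n, seed = 42, dg = default_dg) {
  set.seed(seed)
  out <- matrix(NA_real_, n, 3)
  got <- 0
  while (got < n) {
    p <- c(runif(1, -0.4, 0.4), runif(1, -0.4, 0.4), runif(1, -0.7, -0.35))
    th <- tryCatch(delta_ik(p, dg), error = function(e) NULL)
    if (is.null(th) || !all(attr(th, "within_limits"))) next
    got <- got + 1
    out[got, ] <- p
  }
  out
}

# random valid joint configurations (delta within limits, gonio moderate)
sample_configs <- function(n, seed = 7, dg = default_dg) {
  pos <- sample_workspace_positions(n, seed, dg)
  set.seed(seed + 1)
  lapply(seq_len(n), function(i) {
    joint_config(delta_ik(pos[i, ], dg),
                 c(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5),
                   runif(1, -pi, pi)))
  })
}
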