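# In-code fixtures shared across the test files.

kp_names <- c("K1", "K2", "K3", "K4")

# Build a bout from four n x 2 coordinate matrices (or length-2 points).
make_bout <- function(k1, k2, k3, k4, likelihood = 1, fps = 25,
                      bout_id = "test") {
  pts <- lapply(list(k1, k2, k3, k4), rbind)
  n <- max(vapply(pts, nrow, 1L))
  fr <- data.frame(frame_index = seq_len(n) - 1L)
  lik <- matrix(likelihood, n, 4L)
  for (j in 1:4) {
    p <- pts[[j]]
    if (nrow(p) == 1L) p <- p[rep(1L, n), , drop = FALSE]
    fr[[paste0(kp_names[j], "_x")]] <- p[, 1]
    fr[[paste0(kp_names[j], "_y")]] <- p[, 2]
    fr[[paste0(kp_names[j], "_likelihood")]] <- lik[, j]
  }
  trajectory_bout(bout_id, fps, fr)
}

# Straight-backed cow template: all four keypoints collinear per frame,
# translated forward each frame.
make_collinear_bout <- function(n = 10, fps = 25) {
  x0 <- 3 * (seq_len(n) - 1)
  make_bout(cbind(x0 + 1200, 500), cbind(x0 + 800, 500),
            cbind(x0 + 400, 500), cbind(x0, 500), fps = fps)
}

# Independent angle oracle: dot product of the two vertex-to-endpoint
# vectors via atan2 (numerically unrelated to the law-of-cosines path).
angle_oracle <- function(vertex, end1, end2) {
  u <- end1 - vertex
  v <- end2 - vertex
  atan2(abs(u[1] * v[2] - u[2] * v[1]), sum(u * v)) * 180 / pi
}

# Random non-degenerate triangle: resample until well conditioned.
random_triangle <- function() {
  repeat {
    p <- matrix(runif(6, -100, 100), 3, 2)
    d <- as.matrix(dist(p))
    area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    if (min(d[upper.tri(d)]) > 1 && area > 1) return(p)
  }
}

# Build an angle series with a prescribed fraction of alpha (and beta)
# samples inside the given reference intervals.
series_with_fraction <- function(frac_alpha, frac_beta, n = 200,
                                 ref = reference_model(), seed = 1) {
  set.seed(seed)
  n_in_a <- round(frac_alpha * n)
  n_in_b <- round(frac_beta * n)
  alpha <- c(runif(n_in_a, ref$alpha_low, ref$alpha_high),
             runif(n - n_in_a, ref$alpha_low - 20, ref$alpha_low - 10))
  beta <- c(runif(n_in_b, ref$beta_low, ref$beta_high),
            runif(n - n_in_b, ref$beta_low - 20, ref$beta_low - 10))
  angle_series("frac", 25, seq_len(n) - 1L, sample(alpha), sample(beta))
}
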