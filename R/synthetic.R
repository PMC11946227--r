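# Synthetic gait generator. Angle dynamics are prescribed directly (a
# grade-dependent sinusoid with jitter, clipped to the grade's characteristic
# interval) and then realised as keypoint positions by inverting the
# feature-triangle geometry with a bisection solver, so the generated bout
# reproduces the target angle series exactly (to the solver tolerance)
# before noise is added. This makes the generator the ground-truth oracle
# for the whole downstream pipeline.

# Per-grade sinusoid half-range defaults (degrees). Rule, fixed a priori:
# h = 0.9 * min(mean - low, high - m) of the grade's characteristic
# interval, EXCEPT where the resulting stationary overlap against the
# normal reference lands within 0.05 of a score-band edge (grade-1 beta,
# grade-3 alpha); there h is solved from the arcsine stationary law
# C = 1/2 + asin((mean - ref_low)/h)/pi for a band-centre target
# (C* = 0.85 and 0.45 respectively). Derivation in the methods vignette.
SIM_HALF_RANGE <- list(
  alpha = c(7.7329, 6.8141, 8.0791, 2.2859),
  beta = c(1.8881, 1.4607, 4.0601, 6.9598))

#' Configuration for the synthetic gait generator
#'
#' Collects every knob of the generator. Angle parameters default to the
#' grade's characteristic statistics ([cow_grade_reference()]): the mean is
#' the grade mean, the clip interval is the grade's variation interval, and
#' the sinusoid half-ranges are the package's calibrated per-grade defaults
#' (narrower than the pooled interval; see the methods vignette).
#'
#' @param grade Lameness grade 0..3 the bout should emulate (default 0).
#' @param duration_s Bout duration in seconds (default 6, a typical
#'   traversal of the observation area).
#' @param fps Frames per second (default 25).
#' @param alpha_mean,beta_mean Angle means in degrees.
#' @param alpha_half_range,beta_half_range Sinusoid half-amplitudes in
#'   degrees.
#' @param alpha_interval,beta_interval Length-2 clip intervals in degrees;
#'   synthesized angles never leave them.
#' @param stride_freq Stride frequency in Hz (default 1.2).
#' @param angle_jitter_sd Per-frame Gaussian jitter added to the sinusoid,
#'   in degrees (default 0.05).
#' @param noise_sd Gaussian pixel noise added to every keypoint coordinate
#'   after geometric realisation (default 0.5 px).
#' @param dropout_rate Per-frame probability that a frame is a tracking
#'   dropout: likelihood 0.1 and grossly perturbed coordinates
#'   (default 0.05).
#' @param artifact `"none"` (default) or `"railing_lick"`: a contiguous 10%
#'   of frames where the head keypoint K1 is displaced upward/forward, the
#'   failure mode of a cow licking a railing while walking.
#' @param walk_speed Horizontal advance in pixels per frame (default 3;
#'   the cow walks left to right, head leading).
#' @param baseline_y Image y of the K1--K4 baseline in pixels (default
#'   1400; image origin is top-left, so the back arches upward = smaller y).
#' @param spacing Pixels between successive keypoint anchors; the K1--K4
#'   base is `3 * spacing` long (default 400).
#' @param seed Integer seed; identical configs give identical bouts.
#' @return A `gait_sim_config` list.
#' @export
gait_sim_config <- function(grade = 0, duration_s = 6, fps = 25,
                            alpha_mean = NULL, alpha_half_range = NULL,
                            beta_mean = NULL, beta_half_range = NULL,
                            alpha_interval = NULL, beta_interval = NULL,
                            stride_freq = 1.2, angle_jitter_sd = 0.05,
                            noise_sd = 0.5, dropout_rate = 0.05,
                            artifact = c("none", "railing_lick"),
                            walk_speed = 3, baseline_y = 1400,
                            spacing = 400, seed = 1L) {
  artifact <- match.arg(artifact)
  if (!grade %in% 0:3)
    cg_stop("grade must be in {0, 1, 2, 3}", "cowgait_domain_error")
  if (duration_s <= 0 || fps <= 0 || stride_freq <= 0 || spacing <= 0)
    cg_stop("duration_s, fps, stride_freq and spacing must be positive",
            "cowgait_domain_error")
  if (dropout_rate < 0 || dropout_rate > 1)
    cg_stop("dropout_rate must be in [0, 1]", "cowgait_domain_error")
  ref <- cow_grade_reference()
  ra <- ref[ref$grade == grade & ref$angle == "alpha", ]
  rb <- ref[ref$grade == grade & ref$angle == "beta", ]
  if (is.null(alpha_mean)) alpha_mean <- ra$mean
  if (is.null(beta_mean)) beta_mean <- rb$mean
  if (is.null(alpha_half_range))
    alpha_half_range <- SIM_HALF_RANGE$alpha[grade + 1L]
  if (is.null(beta_half_range))
    beta_half_range <- SIM_HALF_RANGE$beta[grade + 1L]
  if (is.null(alpha_interval))
    alpha_interval <- c(ra$interval_low, ra$interval_high)
  if (is.null(beta_interval))
    beta_interval <- c(rb$interval_low, rb$interval_high)
  for (m in list(c(alpha_mean, alpha_half_range),
                 c(beta_mean, beta_half_range))) {
    if (m[1] - m[2] <= 0 || m[1] + m[2] >= 180)
      cg_stop("mean +/- half_range must stay within (0, 180) degrees",
              "cowgait_domain_error")
  }
  structure(list(grade = as.integer(grade), duration_s = duration_s,
                 fps = fps, alpha_mean = alpha_mean,
                 alpha_half_range = alpha_half_range, beta_mean = beta_mean,
                 beta_half_range = beta_half_range,
                 alpha_interval = alpha_interval,
                 beta_interval = beta_interval, stride_freq = stride_freq,
                 angle_jitter_sd = angle_jitter_sd, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, artifact = artifact,
                 walk_speed = walk_speed, baseline_y = baseline_y,
                 spacing = spacing, seed = as.integer(seed)),
            class = "gait_sim_config")
}

#' Synthesize a target angle series
#'
#' Generates `alpha(t) = mean + half_range * sin(2 pi f t + phi) + jitter`,
#' clipped to the configured interval, with an independent random phase for
#' beta. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [gait_sim_config()].
#' @return An [angle_series()] of `duration_s * fps` frames.
#' @export
synthesize_angle_series <- function(cfg) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fps)
  tt <- (seq_len(n) - 1L) / cfg$fps
  phi <- stats::runif(2L, 0, 2 * pi)
  clip <- function(v, iv) pmin(iv[2], pmax(iv[1], v))
  jit <- function() if (cfg$angle_jitter_sd > 0)
    stats::rnorm(n, 0, cfg$angle_jitter_sd) else numeric(n)
  alpha <- clip(cfg$alpha_mean + cfg$alpha_half_range *
                  sin(2 * pi * cfg$stride_freq * tt + phi[1]) + jit(),
                cfg$alpha_interval)
  beta <- clip(cfg$beta_mean + cfg$beta_half_range *
                 sin(2 * pi * cfg$stride_freq * tt + phi[2]) + jit(),
               cfg$beta_interval)
  angle_series(sprintf("sim_g%d_s%d", cfg$grade, cfg$seed), cfg$fps,
               seq_len(n) - 1L, alpha, beta)
}

# Height of a vertex above its base such that the vertex angle equals
# `target_deg`. The vertex sits at perpendicular height h over a point
# splitting the base into segments dx1 and dx2; the angle decreases
# monotonically from 180 (h = 0) to 0 (h -> Inf), so bisection converges
# unconditionally. Vectorised over frames; tolerance in degrees.
solve_vertex_height <- function(target_deg, dx1, dx2, tol = 1e-9) {
  if (any(target_deg >= 180 | target_deg <= 0))
    cg_stop("target angle must lie strictly inside (0, 180) degrees",
            "cowgait_generation_error")
  n <- length(target_deg)
  dx1 <- rep_len(dx1, n); dx2 <- rep_len(dx2, n)
  ang <- function(h) {
    cosv <- (h^2 - dx1 * dx2) / (sqrt(dx1^2 + h^2) * sqrt(dx2^2 + h^2))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }
  lo <- numeric(n)
  hi <- dx1 + dx2
  for (i in 1:64) {
    grow <- ang(hi) > target_deg
    if (!any(grow)) break
    hi[grow] <- hi[grow] * 2
  }
  if (any(ang(hi) > target_deg))
    cg_stop("vertex height solve failed to bracket the target angle",
            "cowgait_generation_error")
  for (i in 1:120) {
    mid <- (lo + hi) / 2
    too_high <- ang(mid) > target_deg  # angle too large -> raise vertex
    lo[too_high] <- mid[too_high]
    hi[!too_high] <- mid[!too_high]
    if (max(hi - lo) < 1e-13 * max(1, max(hi))) break
  }
  h <- (lo + hi) / 2
  if (max(abs(ang(h) - target_deg)) > tol)
    cg_stop("vertex height solve did not reach tolerance",
            "cowgait_generation_error")
  h
}

#' Realise an angle series as keypoint positions
#'
#' Inverts the feature-triangle geometry: per frame, K1 (head) and K4
#' (tail) are placed on a horizontal baseline advancing left to right by
#' `walk_speed`, separated by `3 * spacing`; K2 is raised above the K1--K4
#' base at one third of the base from K1 until the vertex angle at K2
#' equals `alpha(t)` (bisection, tolerance 1e-9 degrees); K3 is then raised
#' above the midpoint of the K2--K4 base until the angle at K3 equals
#' `beta(t)`. Gaussian coordinate noise (`noise_sd`) is added after
#' solving; dropout frames get likelihood 0.1 and grossly perturbed
#' coordinates; the `railing_lick` artifact displaces K1 upward/forward
#' over a contiguous 10% of frames.
#'
#' With `noise_sd = 0` and no dropout/artifact,
#' `compute_angle_series(realize_keypoints(s, cfg))` reproduces `s` within
#' the solver tolerance.
#'
#' @param series An [angle_series()] with all angles strictly inside
#'   (0, 180).
#' @param cfg A [gait_sim_config()].
#' @return A [trajectory_bout()].
#' @export
realize_keypoints <- function(series, cfg) {
  stopifnot(inherits(series, "angle_series"),
            inherits(cfg, "gait_sim_config"))
  fr <- series$frames
  n <- nrow(fr)
  if (any(is.na(fr$alpha)) || any(is.na(fr$beta)))
    cg_stop("angle series contains missing values; cannot realise geometry",
            "cowgait_generation_error")
  s <- cfg$spacing
  y0 <- cfg$baseline_y
  x_tail <- 200 + cfg$walk_speed * (seq_len(n) - 1L)
  k4 <- cbind(x_tail, rep(y0, n))
  k1 <- cbind(x_tail + 3 * s, rep(y0, n))
  # K2: vertex over the horizontal K1-K4 base, one third from the head end
  h2 <- solve_vertex_height(fr$alpha, dx1 = s, dx2 = 2 * s)
  k2 <- cbind(k1[, 1] - s, y0 - h2)
  # K3: vertex over the midpoint of the (tilted) K2-K4 base
  v <- k4 - k2
  len <- sqrt(rowSums(v^2))
  h3 <- solve_vertex_height(fr$beta, dx1 = len / 2, dx2 = len / 2)
  nrm <- cbind(v[, 2], -v[, 1]) / len  # unit normal
  flip <- nrm[, 2] > 0                 # choose the upward (smaller-y) side
  nrm[flip, ] <- -nrm[flip, ]
  k3 <- k2 + v / 2 + nrm * h3
  set.seed((cfg$seed %% 2147483646L) + 1L)
  lik <- matrix(1, n, 4L)
  coords <- list(K1 = k1, K2 = k2, K3 = k3, K4 = k4)
  if (cfg$artifact == "railing_lick" && n >= 10L) {
    start <- floor(0.4 * n) + 1L
    sel <- start:min(n, start + ceiling(0.1 * n) - 1L)
    coords$K1[sel, 1] <- coords$K1[sel, 1] + 0.3 * s  # forward
    coords$K1[sel, 2] <- coords$K1[sel, 2] - 0.8 * s  # upward (licking)
  }
  drop_mask <- if (cfg$dropout_rate > 0)
    stats::rbinom(n, 1L, cfg$dropout_rate) == 1L else rep(FALSE, n)
  for (j in 1:4) {
    if (cfg$noise_sd > 0)
      coords[[j]] <- coords[[j]] + matrix(stats::rnorm(2L * n, 0,
                                                       cfg$noise_sd), n, 2L)
    if (any(drop_mask)) {
      nd <- sum(drop_mask)
      coords[[j]][drop_mask, ] <- coords[[j]][drop_mask, ] +
        matrix(stats::rnorm(2L * nd, 0, 50), nd, 2L)
      lik[drop_mask, j] <- 0.1
    }
  }
  frames <- data.frame(frame_index = fr$frame_index)
  for (j in seq_along(KEYPOINTS)) {
    kp <- KEYPOINTS[j]
    frames[[paste0(kp, "_x")]] <- coords[[j]][, 1]
    frames[[paste0(kp, "_y")]] <- coords[[j]][, 2]
    frames[[paste0(kp, "_likelihood")]] <- lik[, j]
  }
  trajectory_bout(series$bout_id, cfg$fps, frames)
}

#' Simulate a labelled cohort of walking bouts
#'
#' Generates `n_per_grade` bouts for each grade 0..3 with the grade-default
#' angle parameters plus per-cow jitter: stride frequency `N(stride_freq,
#' freq_jitter_sd)`, a common multiplicative amplitude factor
#' `N(1, amp_jitter_sd)` on both half-ranges, and optionally additive mean
#' jitter (`mean_jitter_sd`, default 0 -- under this scoring model a shifted
#' angle mean changes the bout's true grade, so mean jitter is label noise;
#' see the methods vignette). Angles always remain clipped to the grade's
#' characteristic interval. Fully reproducible from `base_seed`.
#'
#' @param n_per_grade Number of bouts per grade (>= 1).
#' @param base_seed Integer seed for the whole cohort.
#' @param overrides Named list of [gait_sim_config()] arguments applied to
#'   every bout (e.g. `list(noise_sd = 0, dropout_rate = 0)`).
#' @param freq_jitter_sd Per-cow stride-frequency jitter in Hz
#'   (default 0.1).
#' @param amp_jitter_sd Per-cow multiplicative amplitude jitter
#'   (default 0.05).
#' @param mean_jitter_sd Per-cow additive jitter on the angle means in
#'   degrees (default 0).
#' @return A list with elements `bouts` (list of [trajectory_bout()]),
#'   `labels` (data frame `bout_id`, `grade`) and `configs` (the per-bout
#'   [gait_sim_config()]s).
#' @export
simulate_cohort <- function(n_per_grade, base_seed = 1L,
                            overrides = list(), freq_jitter_sd = 0.1,
                            amp_jitter_sd = 0.05, mean_jitter_sd = 0) {
  if (n_per_grade < 1)
    cg_stop("n_per_grade must be >= 1", "cowgait_domain_error")
  bouts <- list()
  configs <- list()
  labels <- data.frame(bout_id = character(0), grade = integer(0))
  for (g in 0:3) {
    for (i in seq_len(n_per_grade)) {
      cow_seed <- (base_seed + 7919L * g + i) %% 2147483647L
      set.seed(cow_seed)
      freq <- max(0.4, stats::rnorm(1L, 1.2, freq_jitter_sd))
      amp_mult <- max(0.5, stats::rnorm(1L, 1, amp_jitter_sd))
      dmean <- if (mean_jitter_sd > 0)
        stats::rnorm(2L, 0, mean_jitter_sd) else c(0, 0)
      args <- list(grade = g, stride_freq = freq,
                   seed = (cow_seed + 500009L) %% 2147483647L)
      args[names(overrides)] <- overrides
      cfg <- do.call(gait_sim_config, args)
      if (!"alpha_half_range" %in% names(overrides))
        cfg$alpha_half_range <- cfg$alpha_half_range * amp_mult
      if (!"beta_half_range" %in% names(overrides))
        cfg$beta_half_range <- cfg$beta_half_range * amp_mult
      cfg$alpha_mean <- cfg$alpha_mean + dmean[1]
      cfg$beta_mean <- cfg$beta_mean + dmean[2]
      series <- synthesize_angle_series(cfg)
      id <- sprintf("g%d_c%03d", g, i)
      series$bout_id <- id
      bout <- realize_keypoints(series, cfg)
      bouts[[id]] <- bout
      configs[[id]] <- cfg
      labels <- rbind(labels, data.frame(bout_id = id, grade = g))
    }
  }
  list(bouts = bouts, labels = labels, configs = configs)
}
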