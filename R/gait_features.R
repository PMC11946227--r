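# Trajectory cleaning and the feature-triangle angle series.
#
# Two triangles are read off the cow's silhouette each frame:
#   alpha: vertex K2 (back near neck), base endpoints K1 (mouth) and K4 (tail)
#   beta:  vertex K3 (mid-back),       base endpoints K2 and K4
# The vertex angle is computed with the law of cosines, so it is invariant to
# translation, rotation, reflection and uniform scaling of the image -- the
# distance between cow and camera does not matter.

#' Interpolate low-confidence frames of a trajectory
#'
#' Frames where a keypoint's likelihood falls below `likelihood_threshold`
#' (or whose coordinates are missing) have that keypoint's coordinates
#' replaced by linear interpolation in time, but only across runs of at most
#' `max_gap` consecutive bad frames bracketed by good frames. Longer runs,
#' and leading/trailing runs (which would require extrapolation), remain
#' flagged-missing. Interpolated frames get likelihood equal to the
#' threshold; unfilled bad frames keep their likelihood with `NA`
#' coordinates.
#'
#' @param bout A [trajectory_bout()].
#' @param likelihood_threshold Minimum acceptable likelihood (default 0.6).
#' @param max_gap Longest run of consecutive bad frames to bridge
#'   (default 12, about half a second at 25 fps).
#' @return A cleaned [trajectory_bout()].
#' @export
clean_trajectory <- function(bout, likelihood_threshold = 0.6, max_gap = 12) {
  stopifnot(inherits(bout, "trajectory_bout"))
  if (likelihood_threshold < 0 || likelihood_threshold > 1)
    cg_stop("likelihood_threshold must be in [0, 1]", "cowgait_domain_error")
  fr <- bout$frames
  n <- nrow(fr)
  if (n == 0L) return(bout)
  t_ax <- fr$frame_index
  for (kp in KEYPOINTS) {
    xc <- paste0(kp, "_x"); yc <- paste0(kp, "_y")
    lc <- paste0(kp, "_likelihood")
    bad <- fr[[lc]] < likelihood_threshold |
           !is.finite(fr[[xc]]) | !is.finite(fr[[yc]])
    if (!any(bad)) next
    fr[[xc]][bad] <- NA_real_
    fr[[yc]][bad] <- NA_real_
    if (all(bad)) next
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    good_idx <- which(!bad)
    for (r in which(runs$values)) {
      s <- starts[r]; e <- ends[r]
      interior <- s > 1L && e < n
      if (!interior || runs$lengths[r] > max_gap) next
      sel <- s:e
      fr[[xc]][sel] <- stats::approx(t_ax[good_idx], fr[[xc]][good_idx],
                                     xout = t_ax[sel])$y
      fr[[yc]][sel] <- stats::approx(t_ax[good_idx], fr[[yc]][good_idx],
                                     xout = t_ax[sel])$y
      fr[[lc]][sel] <- likelihood_threshold
    }
  }
  trajectory_bout(bout$bout_id, bout$fps, fr)
}

#' Euclidean distance between two keypoints
#'
#' @param a,b Numeric length-2 vectors `c(x, y)` or two-column matrices
#'   (rowwise points), in pixels.
#' @return Distance(s) in pixels; `NA` where either point has a missing
#'   coordinate.
#' @export
#' @examples
#' keypoint_distance(c(0, 0), c(3, 4))  # 5
keypoint_distance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  unname(sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2))
}

# Law-of-cosines vertex angle, vectorised over rows. b, c are the
# vertex-to-endpoint sides, a the base; the cosine is clamped to [-1, 1]
# before acos. Degenerate triangles (a vertex-to-endpoint side of length 0)
# give NA.
vertex_angle_xy <- function(vx, vy, x1, y1, x2, y2) {
  b <- sqrt((vx - x1)^2 + (vy - y1)^2)
  cc <- sqrt((vx - x2)^2 + (vy - y2)^2)
  a <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  cosv <- (b^2 + cc^2 - a^2) / (2 * b * cc)
  cosv <- pmin(1, pmax(-1, cosv))
  ang <- acos(cosv) * 180 / pi
  ang[!is.na(b) & !is.na(cc) & (b == 0 | cc == 0)] <- NA_real_
  ang
}

#' Vertex angle of a feature triangle
#'
#' Angle at `vertex` in the triangle (`end1`, `vertex`, `end2`), in degrees,
#' computed with the law of cosines (cosine clamped to `[-1, 1]`). The result
#' lies in `(0, 180]` and is invariant under translation, rotation,
#' reflection and uniform scaling of all three points.
#'
#' @param vertex,end1,end2 Numeric length-2 vectors `c(x, y)` or two-column
#'   matrices (rowwise points), in pixels.
#' @return Angle(s) in degrees; `NA` for degenerate triangles (a
#'   vertex-to-endpoint distance of zero) or missing coordinates.
#' @export
#' @examples
#' vertex_angle(c(0, 1), c(0, 0), c(1, 1))  # 90
#' vertex_angle(c(1, 0), c(0, 0), c(2, 0))  # 180 (collinear)
vertex_angle <- function(vertex, end1, end2) {
  v <- rbind(vertex); e1 <- rbind(end1); e2 <- rbind(end2)
  unname(vertex_angle_xy(v[, 1], v[, 2], e1[, 1], e1[, 2], e2[, 1],
                         e2[, 2]))
}

#' Construct an angle series
#'
#' @param bout_id Character bout identifier.
#' @param fps Frames per second.
#' @param frame_index Integer frame indices (strictly increasing).
#' @param alpha,beta Per-frame angles in degrees (`NA` allowed); each present
#'   value must lie in `(0, 180]`.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(bout_id, fps, frame_index, alpha, beta) {
  if (length(alpha) != length(beta) ||
      length(alpha) != length(frame_index))
    cg_stop("frame_index, alpha and beta must have equal length",
            "cowgait_domain_error")
  for (nm in c("alpha", "beta")) {
    v <- get(nm)
    if (any(!is.na(v) & (v <= 0 | v > 180)))
      cg_stop(paste0(nm, " values must lie in (0, 180]"),
              "cowgait_domain_error")
  }
  structure(list(bout_id = bout_id, fps = fps,
                 frames = data.frame(frame_index = frame_index,
                                     alpha = as.numeric(alpha),
                                     beta = as.numeric(beta))),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf(
    "<angle_series '%s': %d frames @ %g fps; alpha valid %d, beta valid %d>\n",
    x$bout_id, nrow(x$frames), x$fps,
    sum(!is.na(x$frames$alpha)), sum(!is.na(x$frames$beta))))
  invisible(x)
}

#' @export
as.data.frame.angle_series <- function(x, ...) x$frames

#' Compute the feature-triangle angle series of a bout
#'
#' For each frame, `alpha` is the vertex angle at K2 of triangle
#' (K1, K2, K4) and `beta` the vertex angle at K3 of triangle (K2, K3, K4).
#' A frame where any keypoint required by an angle is missing yields `NA`
#' for that angle (K1 affects only alpha; K3 only beta).
#'
#' @param bout A [trajectory_bout()], typically after [clean_trajectory()].
#' @return An [angle_series()].
#' @export
compute_angle_series <- function(bout) {
  stopifnot(inherits(bout, "trajectory_bout"))
  fr <- bout$frames
  alpha <- vertex_angle_xy(fr$K2_x, fr$K2_y, fr$K1_x, fr$K1_y,
                           fr$K4_x, fr$K4_y)
  beta <- vertex_angle_xy(fr$K3_x, fr$K3_y, fr$K2_x, fr$K2_y,
                          fr$K4_x, fr$K4_y)
  angle_series(bout$bout_id, bout$fps, fr$frame_index, alpha, beta)
}

#' Summarise an angle series into per-bout interval statistics
#'
#' For each angle the variation interval (min/max of present values, or a
#' symmetric percentile interval), the arithmetic mean, the amplitude
#' (defined as interval width, `interval_high - interval_low`) and the
#' number of valid frames.
#'
#' @param series An [angle_series()].
#' @param interval_method `"minmax"` (default) or `"percentile"`.
#' @param percentile_tail Tail mass in percent for the percentile method:
#'   the interval is the (`tail`, `100 - tail`) percentile pair (default
#'   2.5). Ignored for `"minmax"`.
#' @param min_frames Minimum number of valid frames per angle below which an
#'   insufficient-data error is raised (default 50, about two seconds at
#'   25 fps).
#' @return A `gait_summary` data frame with one row per angle and columns
#'   `angle`, `interval_low`, `interval_high`, `mean`, `amplitude`,
#'   `n_valid_frames`.
#' @export
summarize_angles <- function(series, interval_method = c("minmax",
                                                         "percentile"),
                             percentile_tail = 2.5, min_frames = 50) {
  stopifnot(inherits(series, "angle_series"))
  interval_method <- match.arg(interval_method)
  if (interval_method == "percentile" &&
      (percentile_tail < 0 || percentile_tail >= 50))
    cg_stop("percentile_tail must be in [0, 50)", "cowgait_domain_error")
  rows <- lapply(c("alpha", "beta"), function(nm) {
    v <- series$frames[[nm]]
    v <- v[!is.na(v)]
    if (length(v) < min_frames)
      cg_stop(sprintf(
        "insufficient data for angle %s in bout '%s': %d valid frames (< %d)",
        nm, series$bout_id, length(v), min_frames),
        "cowgait_insufficient_data")
    iv <- if (interval_method == "minmax") range(v) else
      unname(stats::quantile(v, c(percentile_tail, 100 - percentile_tail) /
                                  100))
    data.frame(angle = nm, interval_low = iv[1], interval_high = iv[2],
               mean = mean(v), amplitude = iv[2] - iv[1],
               n_valid_frames = length(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "interval_method") <- interval_method
  attr(out, "bout_id") <- series$bout_id
  class(out) <- c("gait_summary", "data.frame")
  out
}

#' Write an angle series to CSV
#'
#' Columns `frame_index,alpha,beta`, one row per frame, suitable for
#' plotting the angle traces.
#'
#' @param series An [angle_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_angle_series <- function(series, path) {
  stopifnot(inherits(series, "angle_series"))
  utils::write.csv(series$frames, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Plot the angle traces of a bout
#'
#' @param x An [angle_series()].
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.angle_series <- function(x, ...) {
  tt <- x$frames$frame_index / x$fps
  graphics::matplot(tt, cbind(x$frames$alpha, x$frames$beta), type = "l",
                    lty = 1, col = c("#D55E00", "#0072B2"),
                    xlab = "time (s)", ylab = "angle (degrees)",
                    main = x$bout_id, ...)
  graphics::legend("bottomleft", legend = c(expression(alpha),
                                            expression(beta)),
                   col = c("#D55E00", "#0072B2"), lty = 1, bty = "n")
  invisible(x)
}
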