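# Core container: one walking bout of one cow, as a per-frame table of
# keypoint coordinates (pixels, image convention: origin top-left, y grows
# downward) and tracking likelihoods. Missing detections are kept in place
# (NA coordinates, likelihood 0) so frame indexing stays aligned with video
# time; interpolation is an explicit downstream step.

kp_columns <- function() {
  as.vector(t(outer(KEYPOINTS, c("x", "y", "likelihood"), paste, sep = "_")))
}

#' Construct a keypoint trajectory bout
#'
#' A `trajectory_bout` holds the per-frame positions and tracking likelihoods
#' of the four gait keypoints (K1 mouth, K2 back-near-neck, K3 mid-back, K4
#' near-tail) for one continuous walking bout of a single cow.
#'
#' @param bout_id Character scalar identifying the bout.
#' @param fps Frames per second of the source video (positive; default 25).
#' @param frames Data frame with column `frame_index` (strictly increasing
#'   non-negative integers) and, for each keypoint `K1`..`K4`, columns
#'   `<kp>_x`, `<kp>_y` (pixels; `NA` marks a missing detection) and
#'   `<kp>_likelihood` (in `[0, 1]`).
#'
#' @return An object of class `trajectory_bout`.
#' @seealso [read_dlc_table()], [clean_trajectory()], [compute_angle_series()]
#' @export
#' @examples
#' fr <- data.frame(frame_index = 0:1,
#'   K1_x = c(0, 1), K1_y = 0, K1_likelihood = 1,
#'   K2_x = c(1, 2), K2_y = -1, K2_likelihood = 1,
#'   K3_x = c(2, 3), K3_y = -1, K3_likelihood = 1,
#'   K4_x = c(3, 4), K4_y = 0, K4_likelihood = 1)
#' trajectory_bout("demo", 25, fr)
trajectory_bout <- function(bout_id, fps = 25, frames) {
  stopifnot(is.character(bout_id), length(bout_id) == 1L)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    cg_stop("fps must be a single positive number", "cowgait_domain_error")
  if (!is.data.frame(frames))
    cg_stop("frames must be a data frame", "cowgait_domain_error")
  needed <- c("frame_index", kp_columns())
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols))
    cg_stop(paste0("frames is missing columns: ",
                   paste(missing_cols, collapse = ", ")),
            "cowgait_format_error")
  frames <- frames[needed]
  frames[] <- lapply(frames, as.numeric)
  fi <- frames$frame_index
  if (nrow(frames)) {
    if (any(!is.finite(fi)) || any(fi < 0) || any(fi != round(fi)))
      cg_stop("frame_index must be non-negative integers",
              "cowgait_domain_error")
    if (nrow(frames) > 1L && any(diff(fi) <= 0))
      cg_stop("frame_index must be strictly increasing",
              "cowgait_domain_error")
    for (kp in KEYPOINTS) {
      lik <- frames[[paste0(kp, "_likelihood")]]
      lik[is.na(lik)] <- 0
      if (any(lik < 0 | lik > 1))
        cg_stop(paste0(kp, " likelihood outside [0, 1]"),
                "cowgait_domain_error")
      frames[[paste0(kp, "_likelihood")]] <- as.numeric(lik)
      for (ax in c("_x", "_y")) {
        v <- as.numeric(frames[[paste0(kp, ax)]])
        v[!is.finite(v)] <- NA_real_  # flagged missing
        frames[[paste0(kp, ax)]] <- v
      }
    }
  }
  rownames(frames) <- NULL
  structure(list(bout_id = bout_id, fps = fps, frames = frames),
            class = "trajectory_bout")
}

#' @export
print.trajectory_bout <- function(x, ...) {
  n <- nrow(x$frames)
  valid <- if (n) {
    sapply(KEYPOINTS, function(kp)
      sum(stats::complete.cases(x$frames[paste0(kp, c("_x", "_y"))])))
  } else rep(0L, 4)
  cat(sprintf("<trajectory_bout '%s': %d frames @ %g fps>\n",
              x$bout_id, n, x$fps))
  cat("  valid frames per keypoint: ",
      paste(sprintf("%s=%d", KEYPOINTS, valid), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory_bout <- function(x, ...) x$frames

#' Number of frames in a bout
#' @param bout A [trajectory_bout()].
#' @return Integer frame count.
#' @export
n_frames <- function(bout) {
  stopifnot(inherits(bout, "trajectory_bout"))
  nrow(bout$frames)
}

#' Extract one keypoint's coordinates
#'
#' @param bout A [trajectory_bout()].
#' @param keypoint One of `"K1"`, `"K2"`, `"K3"`, `"K4"`.
#' @return A numeric matrix with columns `x`, `y` (one row per frame; `NA`
#'   where the detection is missing).
#' @export
keypoint_coords <- function(bout, keypoint) {
  stopifnot(inherits(bout, "trajectory_bout"))
  keypoint <- match.arg(keypoint, KEYPOINTS)
  m <- cbind(x = bout$frames[[paste0(keypoint, "_x")]],
             y = bout$frames[[paste0(keypoint, "_y")]])
  m
}
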