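# The banded scoring model. Each angle's overlap coefficient C (how much of
# the bout's angle distribution lies within the normal-cow reference
# interval) is mapped through four score bands to an initial score 0-3; the
# two initial scores are averaged and decimals rounded UP to give the final
# lameness score, which maps onto the four-level clinical grading scale.

#' Overlap coefficient of a bout's angle against a reference interval
#'
#' `sample_fraction` counts the fraction of the bout's present per-frame
#' angle values lying inside `[ref_low, ref_high]` (frame-weighted, robust
#' to single outlier frames). `interval_overlap` instead intersects the
#' bout's variation interval with the reference interval and divides by the
#' bout interval's width (0 if disjoint, 1 if the bout interval is contained
#' in the reference).
#'
#' @param series An [angle_series()].
#' @param ref_low,ref_high Reference interval endpoints in degrees.
#' @param angle `"alpha"` or `"beta"`.
#' @param method `"sample_fraction"` (default) or `"interval_overlap"`.
#' @param summary Optional [summarize_angles()] result supplying the bout's
#'   variation interval for `interval_overlap`; computed (min/max) when
#'   absent.
#' @return A single number in `[0, 1]`.
#' @export
overlap_coefficient <- function(series, ref_low, ref_high,
                                angle = c("alpha", "beta"),
                                method = c("sample_fraction",
                                           "interval_overlap"),
                                summary = NULL) {
  stopifnot(inherits(series, "angle_series"))
  angle <- match.arg(angle)
  method <- match.arg(method)
  if (!(ref_low < ref_high))
    cg_stop("reference interval must satisfy low < high",
            "cowgait_domain_error")
  v <- series$frames[[angle]]
  v <- v[!is.na(v)]
  if (!length(v))
    cg_stop(sprintf("no valid %s frames in bout '%s'", angle,
                    series$bout_id), "cowgait_insufficient_data")
  if (method == "sample_fraction") {
    cc <- mean(v >= ref_low & v <= ref_high)
  } else {
    if (!is.null(summary)) {
      row <- summary[summary$angle == angle, ]
      lo <- row$interval_low; hi <- row$interval_high
    } else {
      lo <- min(v); hi <- max(v)
    }
    if (hi == lo) {
      cc <- as.numeric(lo >= ref_low && lo <= ref_high)
    } else {
      cc <- max(0, min(hi, ref_high) - max(lo, ref_low)) / (hi - lo)
    }
  }
  min(1, max(0, cc))
}

# Band mapping shared by both angles: edges are the three interior cut
# points, highest first; a coefficient equal to an edge takes the better
# (lower) score.
band_score <- function(coefficient, edges) {
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      is.na(coefficient) || coefficient < 0 || coefficient > 1)
    cg_stop("overlap coefficient must be a single number in [0, 1]",
            "cowgait_domain_error")
  as.integer(sum(coefficient < edges))
}

#' Initial score for angle alpha
#'
#' Maps the alpha overlap coefficient through the alpha score bands
#' (defaults `[0.75, 1]` -> 0, `[0.50, 0.75)` -> 1, `[0.25, 0.50)` -> 2,
#' `[0, 0.25)` -> 3).
#'
#' @param c_alpha Overlap coefficient in `[0, 1]`.
#' @param edges Three strictly decreasing interior band edges (default
#'   `c(0.75, 0.50, 0.25)`).
#' @return Integer score 0..3.
#' @export
#' @examples
#' score_alpha(0.80)  # 0
#' score_alpha(0.60)  # 1
score_alpha <- function(c_alpha, edges = c(0.75, 0.50, 0.25)) {
  band_score(c_alpha, edges)
}

#' Initial score for angle beta
#'
#' Maps the beta overlap coefficient through the beta score bands (defaults
#' `[0.90, 1]` -> 0, `[0.80, 0.90)` -> 1, `[0.70, 0.80)` -> 2,
#' `[0, 0.70)` -> 3).
#'
#' @param c_beta Overlap coefficient in `[0, 1]`.
#' @param edges Three strictly decreasing interior band edges (default
#'   `c(0.90, 0.80, 0.70)`).
#' @return Integer score 0..3.
#' @export
#' @examples
#' score_beta(0.95)  # 0
#' score_beta(0.65)  # 3
score_beta <- function(c_beta, edges = c(0.90, 0.80, 0.70)) {
  band_score(c_beta, edges)
}

#' Grade label for a lameness score
#' @param score Integer score(s) in 0..3.
#' @return `"normal"`, `"mild"`, `"moderate"` or `"severe"`.
#' @export
score_grade_label <- function(score) {
  if (any(!score %in% 0:3))
    cg_stop("score must be in {0, 1, 2, 3}", "cowgait_domain_error")
  GRADE_LABELS[score + 1L]
}

#' Combine the two initial angle scores into the final lameness score
#'
#' The final score is the mean of the two initial scores with decimals
#' rounded up to the nearest whole number:
#' `S = ceiling((s_alpha + s_beta) / 2)`.
#'
#' @param s_alpha,s_beta Integer initial scores in 0..3.
#' @return A `lameness_score` list with elements `s_alpha`, `s_beta`,
#'   `s_final` and `grade_label`.
#' @export
#' @examples
#' final_score(2, 1)  # s_final 2 (ceiling of 1.5), "moderate"
final_score <- function(s_alpha, s_beta) {
  if (length(s_alpha) != 1L || length(s_beta) != 1L ||
      !s_alpha %in% 0:3 || !s_beta %in% 0:3)
    cg_stop("initial scores must be single values in {0, 1, 2, 3}",
            "cowgait_domain_error")
  s <- as.integer(ceiling((s_alpha + s_beta) / 2))
  structure(list(s_alpha = as.integer(s_alpha), s_beta = as.integer(s_beta),
                 s_final = s, grade_label = score_grade_label(s)),
            class = "lameness_score")
}

#' @export
print.lameness_score <- function(x, ...) {
  cat(sprintf("<lameness_score: S_alpha=%d S_beta=%d -> S=%d (%s)>\n",
              x$s_alpha, x$s_beta, x$s_final, x$grade_label))
  invisible(x)
}

#' Score one walking bout end to end
#'
#' Deterministic composition of the pipeline: optional cleaning, angle
#' computation, interval summary, overlap coefficients against the reference
#' model, band scores and the final grade. All intermediates are returned
#' for auditability -- a suspicious final score should always be traced back
#' to the angle behind it.
#'
#' @param bout A [trajectory_bout()].
#' @param ref A [reference_model()] (defaults to the study-herd normal
#'   intervals and standard bands).
#' @param clean Whether to run [clean_trajectory()] first (default `TRUE`).
#' @param likelihood_threshold,max_gap Cleaning options, see
#'   [clean_trajectory()].
#' @param interval_method,percentile_tail,min_frames Summary options, see
#'   [summarize_angles()].
#' @return A `lameness_result` list with elements `bout_id`, `c_alpha`,
#'   `c_beta`, `s_alpha`, `s_beta`, `s_final`, `grade_label`,
#'   `n_valid_alpha`, `n_valid_beta`, `overlap_method`, `summary` (the
#'   [summarize_angles()] table) and `series` (the [angle_series()]).
#' @export
score_bout <- function(bout, ref = reference_model(), clean = TRUE,
                       likelihood_threshold = 0.6, max_gap = 12,
                       interval_method = c("minmax", "percentile"),
                       percentile_tail = 2.5, min_frames = 50) {
  stopifnot(inherits(bout, "trajectory_bout"),
            inherits(ref, "reference_model"))
  interval_method <- match.arg(interval_method)
  if (clean)
    bout <- clean_trajectory(bout, likelihood_threshold, max_gap)
  series <- compute_angle_series(bout)
  smry <- summarize_angles(series, interval_method, percentile_tail,
                           min_frames)
  c_alpha <- overlap_coefficient(series, ref$alpha_low, ref$alpha_high,
                                 "alpha", ref$overlap_method, summary = smry)
  c_beta <- overlap_coefficient(series, ref$beta_low, ref$beta_high,
                                "beta", ref$overlap_method, summary = smry)
  s_a <- band_score(c_alpha, ref$alpha_band_edges)
  s_b <- band_score(c_beta, ref$beta_band_edges)
  fs <- final_score(s_a, s_b)
  structure(list(bout_id = bout$bout_id,
                 c_alpha = c_alpha, c_beta = c_beta,
                 s_alpha = fs$s_alpha, s_beta = fs$s_beta,
                 s_final = fs$s_final, grade_label = fs$grade_label,
                 n_valid_alpha =
                   smry$n_valid_frames[smry$angle == "alpha"],
                 n_valid_beta = smry$n_valid_frames[smry$angle == "beta"],
                 overlap_method = ref$overlap_method,
                 summary = smry, series = series),
            class = "lameness_result")
}

#' @export
print.lameness_result <- function(x, ...) {
  cat(sprintf("<lameness_result '%s'>\n", x$bout_id))
  cat(sprintf("  C_alpha=%.3f C_beta=%.3f (%s)\n", x$c_alpha, x$c_beta,
              x$overlap_method))
  cat(sprintf("  S_alpha=%d S_beta=%d -> S=%d (%s)\n", x$s_alpha, x$s_beta,
              x$s_final, x$grade_label))
  cat(sprintf("  valid frames: alpha %d, beta %d\n", x$n_valid_alpha,
              x$n_valid_beta))
  invisible(x)
}

#' @export
as.data.frame.lameness_result <- function(x, ...) {
  data.frame(bout_id = x$bout_id, c_alpha = x$c_alpha, c_beta = x$c_beta,
             s_alpha = x$s_alpha, s_beta = x$s_beta, s_final = x$s_final,
             grade_label = x$grade_label,
             n_valid_frames = min(x$n_valid_alpha, x$n_valid_beta),
             stringsAsFactors = FALSE)
}

#' Combine scoring results into a report table
#'
#' @param results A list of `lameness_result` objects from [score_bout()].
#' @return Data frame with one row per bout: `bout_id`, `c_alpha`, `c_beta`,
#'   `s_alpha`, `s_beta`, `s_final`, `grade_label`, `n_valid_frames`.
#' @export
score_report <- function(results) {
  if (inherits(results, "lameness_result")) results <- list(results)
  do.call(rbind, lapply(results, as.data.frame))
}
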