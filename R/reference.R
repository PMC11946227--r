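# Reference data: the per-grade characteristic-angle statistics of the study
# herd (45 cows), and the reference model (normal-cow intervals + score
# bands) that the scorer compares bouts against.

#' Characteristic angle statistics per lameness grade
#'
#' Pooled per-grade statistics of the feature angles alpha and beta from the
#' study herd: the variation interval endpoints, the mean, the amplitude
#' recomputed as interval width (`high - low`), and the amplitude figure as
#' printed in the original report. The two differ only for the severe-grade
#' beta row, where the printed amplitude (17.96) does not match its own
#' interval endpoints (179.95 - 162.99 = 16.96); the width is taken as
#' authoritative.
#'
#' These values seed both the default [reference_model()] (the grade-0 rows)
#' and the per-grade defaults of the synthetic generator.
#'
#' @return Data frame with columns `grade` (0..3), `label`, `angle`
#'   (`"alpha"`/`"beta"`), `interval_low`, `interval_high`, `mean`,
#'   `amplitude` (computed width) and `printed_amplitude`.
#' @export
cow_grade_reference <- function() {
  ref <- data.frame(
    grade = rep(0:3, times = 2L),
    label = rep(GRADE_LABELS, times = 2L),
    angle = rep(c("alpha", "beta"), each = 4L),
    interval_low = c(146.26, 141.44, 138.75, 133.34,
                     175.29, 173.53, 170.48, 162.99),
    interval_high = c(164.87, 156.99, 158.33, 156.27,
                      179.99, 179.93, 179.95, 179.95),
    mean = c(156.2779, 149.0112, 149.3532, 145.9024,
             177.8921, 176.5915, 175.4388, 172.2169),
    printed_amplitude = c(18.61, 15.55, 19.58, 22.93,
                          4.70, 6.40, 9.47, 17.96),
    stringsAsFactors = FALSE)
  ref$amplitude <- ref$interval_high - ref$interval_low
  ref[c("grade", "label", "angle", "interval_low", "interval_high",
        "mean", "amplitude", "printed_amplitude")]
}

#' Normal-cow reference model for lameness scoring
#'
#' Bundles the normal-cow variation intervals for alpha and beta, the score
#' band edges for each angle, and the overlap method. Defaults are the
#' study-herd grade-0 intervals ([cow_grade_reference()]); override them for
#' per-herd calibration.
#'
#' Band edges are the three interior cut points of the four score bands over
#' the overlap coefficient, highest first. The default alpha bands are
#' `[0.75, 1]` -> 0, `[0.50, 0.75)` -> 1, `[0.25, 0.50)` -> 2,
#' `[0, 0.25)` -> 3; the beta bands `[0.90, 1]` -> 0, `[0.80, 0.90)` -> 1,
#' `[0.70, 0.80)` -> 2, `[0, 0.70)` -> 3. At a shared edge the better
#' (lower) score wins.
#'
#' @param alpha_low,alpha_high Normal reference interval for alpha
#'   (degrees).
#' @param beta_low,beta_high Normal reference interval for beta (degrees).
#' @param alpha_band_edges,beta_band_edges Three strictly decreasing interior
#'   band edges in (0, 1).
#' @param overlap_method `"sample_fraction"` (default: fraction of the
#'   bout's per-frame angle values inside the reference interval) or
#'   `"interval_overlap"` (overlap of the bout's variation interval with the
#'   reference interval, as a fraction of the bout interval).
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(alpha_low = 146.26, alpha_high = 164.87,
                            beta_low = 175.29, beta_high = 179.99,
                            alpha_band_edges = c(0.75, 0.50, 0.25),
                            beta_band_edges = c(0.90, 0.80, 0.70),
                            overlap_method = c("sample_fraction",
                                               "interval_overlap")) {
  overlap_method <- match.arg(overlap_method)
  if (!(alpha_low < alpha_high) || !(beta_low < beta_high))
    cg_stop("reference intervals must satisfy low < high",
            "cowgait_domain_error")
  check_edges <- function(e, nm) {
    if (length(e) != 3L || any(!is.finite(e)) || any(e <= 0) ||
        any(e >= 1) || any(diff(e) >= 0))
      cg_stop(paste0(nm,
        " must be three strictly decreasing values in (0, 1)"),
        "cowgait_domain_error")
  }
  check_edges(alpha_band_edges, "alpha_band_edges")
  check_edges(beta_band_edges, "beta_band_edges")
  structure(list(alpha_low = alpha_low, alpha_high = alpha_high,
                 beta_low = beta_low, beta_high = beta_high,
                 alpha_band_edges = alpha_band_edges,
                 beta_band_edges = beta_band_edges,
                 overlap_method = overlap_method),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat("<reference_model>\n")
  cat(sprintf("  alpha reference: [%.2f, %.2f] deg; band edges %s\n",
              x$alpha_low, x$alpha_high,
              paste(x$alpha_band_edges, collapse = " / ")))
  cat(sprintf("  beta  reference: [%.2f, %.2f] deg; band edges %s\n",
              x$beta_low, x$beta_high,
              paste(x$beta_band_edges, collapse = " / ")))
  cat("  overlap method:", x$overlap_method, "\n")
  invisible(x)
}

#' Read a run configuration file
#'
#' Parses a YAML configuration holding the reference model and the cleaning
#' and summary options, validating against the documented schema. All keys
#' are optional; absent keys take package defaults. Schema:
#'
#' ```yaml
#' reference:
#'   alpha: {low: 146.26, high: 164.87}
#'   beta:  {low: 175.29, high: 179.99}
#'   alpha_band_edges: [0.75, 0.50, 0.25]
#'   beta_band_edges:  [0.90, 0.80, 0.70]
#'   overlap_method: sample_fraction   # or interval_overlap
#' cleaning:
#'   likelihood_threshold: 0.6
#'   max_gap: 12
#' summary:
#'   interval_method: minmax           # or percentile
#'   percentile_tail: 2.5
#'   min_frames: 50
#' fps: 25
#' ```
#'
#' @param path Path to the YAML file.
#' @return A list with elements `reference` (a [reference_model()]),
#'   `cleaning`, `summary` and `fps`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    cg_stop(paste0("config file does not exist: ", path), "cowgait_io_error")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("reference", "cleaning", "summary", "fps")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    cg_stop(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
            "cowgait_config_error")
  ref_args <- list()
  r <- cfg$reference
  if (!is.null(r$alpha)) {
    ref_args$alpha_low <- r$alpha$low; ref_args$alpha_high <- r$alpha$high
  }
  if (!is.null(r$beta)) {
    ref_args$beta_low <- r$beta$low; ref_args$beta_high <- r$beta$high
  }
  if (!is.null(r$alpha_band_edges))
    ref_args$alpha_band_edges <- as.numeric(r$alpha_band_edges)
  if (!is.null(r$beta_band_edges))
    ref_args$beta_band_edges <- as.numeric(r$beta_band_edges)
  if (!is.null(r$overlap_method)) ref_args$overlap_method <- r$overlap_method
  reference <- tryCatch(do.call(reference_model, ref_args),
                        error = function(e)
    cg_stop(paste0("invalid reference config: ", conditionMessage(e)),
            "cowgait_config_error"))
  cleaning <- list(likelihood_threshold = 0.6, max_gap = 12)
  cleaning[names(cfg$cleaning)] <- cfg$cleaning
  if (cleaning$likelihood_threshold < 0 || cleaning$likelihood_threshold > 1)
    cg_stop("cleaning: likelihood_threshold must be in [0, 1]",
            "cowgait_config_error")
  summary_opts <- list(interval_method = "minmax", percentile_tail = 2.5,
                       min_frames = 50)
  summary_opts[names(cfg$summary)] <- cfg$summary
  if (!summary_opts$interval_method %in% c("minmax", "percentile"))
    cg_stop("summary: interval_method must be 'minmax' or 'percentile'",
            "cowgait_config_error")
  fps <- if (is.null(cfg$fps)) 25 else cfg$fps
  if (!is.numeric(fps) || fps <= 0)
    cg_stop("fps must be a positive number", "cowgait_config_error")
  list(reference = reference, cleaning = cleaning, summary = summary_opts,
       fps = fps)
}
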