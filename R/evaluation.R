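# Evaluation: keypoint localisation error (mean Euclidean distance to
# ground truth, per bodypart and global) and grade-classification accuracy
# (confusion matrix, per-grade and overall accuracy).

#' Keypoint localisation error between a predicted and a truth bout
#'
#' For frames present in both bouts, computes per keypoint the mean
#' Euclidean distance between predicted and true positions (pairwise
#' complete per keypoint: a frame missing that keypoint in either bout is
#' skipped for that keypoint only). The global mean is the unweighted mean
#' of the four per-keypoint means -- a two-stage average, not a pooled mean
#' over all points, so each bodypart contributes equally even when their
#' valid-frame counts differ.
#'
#' @param pred,truth [trajectory_bout()]s aligned on `frame_index`.
#' @return A `keypoint_error_report` list with `per_keypoint_mean_px`
#'   (named numeric), `global_mean_px`, `n_points` (total point pairs
#'   compared) and `per_keypoint_n`.
#' @export
keypoint_error <- function(pred, truth) {
  stopifnot(inherits(pred, "trajectory_bout"),
            inherits(truth, "trajectory_bout"))
  common <- intersect(pred$frames$frame_index, truth$frames$frame_index)
  if (!length(common))
    cg_stop("no overlapping frames between prediction and truth",
            "cowgait_insufficient_data")
  pf <- pred$frames[match(common, pred$frames$frame_index), ]
  tf <- truth$frames[match(common, truth$frames$frame_index), ]
  per_kp <- numeric(length(KEYPOINTS))
  per_n <- integer(length(KEYPOINTS))
  names(per_kp) <- names(per_n) <- KEYPOINTS
  for (kp in KEYPOINTS) {
    d <- sqrt((pf[[paste0(kp, "_x")]] - tf[[paste0(kp, "_x")]])^2 +
              (pf[[paste0(kp, "_y")]] - tf[[paste0(kp, "_y")]])^2)
    d <- d[!is.na(d)]
    if (!length(d))
      cg_stop(paste0("no comparable frames for keypoint ", kp),
              "cowgait_insufficient_data")
    per_kp[kp] <- mean(d)
    per_n[kp] <- length(d)
  }
  structure(list(per_keypoint_mean_px = per_kp,
                 global_mean_px = mean(per_kp),
                 n_points = sum(per_n), per_keypoint_n = per_n),
            class = "keypoint_error_report")
}

#' @export
print.keypoint_error_report <- function(x, ...) {
  cat("<keypoint_error_report>\n")
  for (kp in names(x$per_keypoint_mean_px))
    cat(sprintf("  %s: %.4f px (n=%d)\n", kp, x$per_keypoint_mean_px[kp],
                x$per_keypoint_n[kp]))
  cat(sprintf("  global mean: %.4f px over %d point pairs\n",
              x$global_mean_px, x$n_points))
  invisible(x)
}

#' Grade-classification accuracy report
#'
#' Builds the 4x4 confusion matrix (true grade in rows, predicted grade in
#' columns), per-grade accuracy (diagonal over row total) and overall
#' accuracy (trace over total).
#'
#' @param predictions Data frame with columns `bout_id` and `grade`
#'   (predicted, 0..3); a list of `lameness_result`s or a [score_report()]
#'   is also accepted (its `s_final` is used).
#' @param labels Ground-truth data frame `bout_id`, `grade` (e.g. from
#'   [read_labels()]); every prediction must have a matching label.
#' @return An `accuracy_report` list with `confusion` (4x4 matrix),
#'   `per_grade_accuracy` (named numeric, `NA` for grades with no bouts),
#'   `overall_accuracy` and `n`.
#' @export
grade_accuracy <- function(predictions, labels) {
  if (is.list(predictions) && !is.data.frame(predictions) &&
      all(vapply(predictions, inherits, TRUE, "lameness_result")))
    predictions <- score_report(predictions)
  if (is.data.frame(predictions) && "s_final" %in% names(predictions) &&
      !"grade" %in% names(predictions))
    predictions$grade <- predictions$s_final
  stopifnot(all(c("bout_id", "grade") %in% names(predictions)),
            all(c("bout_id", "grade") %in% names(labels)))
  m <- match(predictions$bout_id, labels$bout_id)
  if (anyNA(m))
    cg_stop(paste0("predictions without a matching label: ",
                   paste(predictions$bout_id[is.na(m)], collapse = ", ")),
            "cowgait_validation_error")
  truth <- factor(labels$grade[m], levels = 0:3)
  predicted <- factor(predictions$grade, levels = 0:3)
  if (anyNA(predicted) || anyNA(truth))
    cg_stop("grades must be in {0, 1, 2, 3}", "cowgait_domain_error")
  confusion <- table(truth = truth, predicted = predicted)
  confusion <- unclass(confusion)
  row_tot <- rowSums(confusion)
  per_grade <- ifelse(row_tot > 0, diag(confusion) / row_tot, NA_real_)
  names(per_grade) <- 0:3
  structure(list(confusion = confusion,
                 per_grade_accuracy = per_grade,
                 overall_accuracy = sum(diag(confusion)) / sum(confusion),
                 n = sum(confusion)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  print(x$confusion)
  pg <- ifelse(is.na(x$per_grade_accuracy), "--",
               sprintf("%.1f%%", 100 * x$per_grade_accuracy))
  cat("  per-grade accuracy: ",
      paste(sprintf("%s=%s", names(x$per_grade_accuracy), pg),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  overall accuracy: %.2f%% (n=%d)\n",
              100 * x$overall_accuracy, x$n))
  invisible(x)
}
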