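# Readers/writers for the two table dialects the pipeline consumes:
# the pose-tracker CSV (three header rows: scorer / bodyparts / coords, one
# leading index column, x/y/likelihood triplets per bodypart) and a plain
# long format (frame,keypoint,x,y,likelihood). Plus the two-column grade
# label CSV used for accuracy evaluation.

#' Read a keypoint trajectory table
#'
#' Reads a pose-tracker style CSV into a [trajectory_bout()]. The default
#' dialect has three header rows (`scorer`, `bodyparts`, `coords`), a leading
#' frame-index column, and an `x`/`y`/`likelihood` column triplet per
#' bodypart. `format = "long"` instead expects a header row with columns
#' `frame,keypoint,x,y,likelihood`.
#'
#' Empty or non-finite coordinate cells become flagged-missing (`NA`
#' coordinates, likelihood 0); rows are never dropped, so frame indexing
#' stays aligned with video time. Bodyparts other than `K1`..`K4` are
#' ignored; all four must be present.
#'
#' @param path Path to the CSV file.
#' @param fps Frames per second of the source video (the CSV dialect does not
#'   carry it; default 25).
#' @param format `"dlc"` (three-header-row dialect, default) or `"long"`.
#' @param bout_id Bout identifier; defaults to the file name without
#'   extension.
#' @return A [trajectory_bout()], one frame per table row, in row order.
#' @export
read_dlc_table <- function(path, fps = 25, format = c("dlc", "long"),
                           bout_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    cg_stop(paste0("input file does not exist: ", path), "cowgait_io_error")
  if (is.null(bout_id))
    bout_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "long") return(read_long_table(path, fps, bout_id))

  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 3L)
    cg_stop("malformed header: fewer than three header rows",
            "cowgait_format_error")
  labels <- c("scorer", "bodyparts", "coords")
  for (i in 1:3) {
    if (tolower(raw[i, 1]) != labels[i])
      cg_stop(sprintf(
        "malformed header: row %d column 1 is '%s', expected '%s'",
        i, raw[i, 1], labels[i]), "cowgait_format_error")
  }
  bodyparts <- as.character(raw[2, -1])
  coords <- tolower(as.character(raw[3, -1]))
  bad <- which(!coords %in% c("x", "y", "likelihood"))
  if (length(bad))
    cg_stop(sprintf(
      "malformed header: column %d ('%s' / '%s') has coords field '%s'",
      bad[1] + 1L, bodyparts[bad[1]], coords[bad[1]], coords[bad[1]]),
      "cowgait_format_error")
  absent <- setdiff(KEYPOINTS, unique(bodyparts))
  if (length(absent))
    cg_stop(paste0("missing keypoint columns: ",
                   paste(absent, collapse = ", ")), "cowgait_format_error")

  dat <- raw[-(1:3), , drop = FALSE]
  n <- nrow(dat)
  frames <- data.frame(frame_index =
    if (n) as.numeric(dat[, 1]) else numeric(0))
  for (kp in KEYPOINTS) {
    for (field in c("x", "y", "likelihood")) {
      j <- which(bodyparts == kp & coords == field)
      if (!length(j))
        cg_stop(sprintf("bodypart '%s' lacks a '%s' column", kp, field),
                "cowgait_format_error")
      v <- if (n) suppressWarnings(as.numeric(dat[, j[1] + 1L]))
           else numeric(0)
      frames[[paste(kp, field, sep = "_")]] <- v
    }
    miss <- !is.finite(frames[[paste0(kp, "_x")]]) |
            !is.finite(frames[[paste0(kp, "_y")]])
    lik <- frames[[paste0(kp, "_likelihood")]]
    lik[is.na(lik)] <- 0
    lik[miss] <- 0
    frames[[paste0(kp, "_likelihood")]] <- lik
  }
  trajectory_bout(bout_id, fps, frames)
}

read_long_table <- function(path, fps, bout_id) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame", "keypoint", "x", "y", "likelihood")
  missing_cols <- setdiff(needed, names(dat))
  if (length(missing_cols))
    cg_stop(paste0("long-format table missing columns: ",
                   paste(missing_cols, collapse = ", ")),
            "cowgait_format_error")
  absent <- setdiff(KEYPOINTS, unique(dat$keypoint))
  if (length(absent))
    cg_stop(paste0("missing keypoint columns: ",
                   paste(absent, collapse = ", ")), "cowgait_format_error")
  idx <- sort(unique(dat$frame))
  frames <- data.frame(frame_index = idx)
  for (kp in KEYPOINTS) {
    sub <- dat[dat$keypoint == kp, ]
    m <- match(idx, sub$frame)
    for (field in c("x", "y", "likelihood"))
      frames[[paste(kp, field, sep = "_")]] <- as.numeric(sub[[field]][m])
    lik <- frames[[paste0(kp, "_likelihood")]]
    lik[is.na(lik)] <- 0
    miss <- !is.finite(frames[[paste0(kp, "_x")]]) |
            !is.finite(frames[[paste0(kp, "_y")]])
    lik[miss] <- 0
    frames[[paste0(kp, "_likelihood")]] <- lik
  }
  trajectory_bout(bout_id, fps, frames)
}

num_chr <- function(v) {
  out <- sprintf("%.17g", v)  # shortest exact round-trip is not available in
  out[is.na(v)] <- ""         # base R; 17 significant digits is lossless
  out
}

#' Write a keypoint trajectory table
#'
#' Serialises a bout in a dialect readable by [read_dlc_table()]. Numeric
#' values are written with 17 significant digits so a write/read round trip
#' is value-identical; missing coordinates become empty cells.
#'
#' @param bout A [trajectory_bout()].
#' @param path Output file path.
#' @param format `"dlc"` (default) or `"long"`.
#' @param scorer Value for the first header row (dlc format only).
#' @return `path`, invisibly.
#' @export
write_dlc_table <- function(bout, path, format = c("dlc", "long"),
                            scorer = "cowgait") {
  stopifnot(inherits(bout, "trajectory_bout"))
  format <- match.arg(format)
  fr <- bout$frames
  con <- tryCatch(file(path, "w"), error = function(e)
    cg_stop(paste0("cannot open for writing: ", path), "cowgait_io_error"))
  on.exit(close(con))
  if (format == "dlc") {
    writeLines(c(
      paste(c("scorer", rep(scorer, 12L)), collapse = ","),
      paste(c("bodyparts", rep(KEYPOINTS, each = 3L)), collapse = ","),
      paste(c("coords", rep(c("x", "y", "likelihood"), 4L)), collapse = ",")
    ), con)
    if (nrow(fr)) {
      body <- cbind(sprintf("%d", as.integer(fr$frame_index)),
                    do.call(cbind, lapply(kp_columns(),
                                          function(cl) num_chr(fr[[cl]]))))
      writeLines(apply(body, 1L, paste, collapse = ","), con)
    }
  } else {
    writeLines("frame,keypoint,x,y,likelihood", con)
    if (nrow(fr)) {
      for (kp in KEYPOINTS) {
        rows <- paste(sprintf("%d", as.integer(fr$frame_index)), kp,
                      num_chr(fr[[paste0(kp, "_x")]]),
                      num_chr(fr[[paste0(kp, "_y")]]),
                      num_chr(fr[[paste0(kp, "_likelihood")]]), sep = ",")
        writeLines(rows, con)
      }
    }
  }
  invisible(path)
}

#' Read grade labels
#'
#' Reads a CSV with header `bout_id,grade` into a validated data frame of
#' ground-truth lameness grades (0 normal, 1 mild, 2 moderate, 3 severe).
#'
#' @param path Path to the label CSV.
#' @return Data frame with columns `bout_id` (character) and `grade`
#'   (integer in 0..3).
#' @export
read_labels <- function(path) {
  if (!file.exists(path))
    cg_stop(paste0("label file does not exist: ", path), "cowgait_io_error")
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("bout_id", "grade"), names(dat))
  if (length(missing_cols))
    cg_stop(paste0("label file missing columns: ",
                   paste(missing_cols, collapse = ", ")),
            "cowgait_format_error")
  g <- suppressWarnings(as.numeric(dat$grade))
  bad <- which(is.na(g) | g != round(g) | g < 0 | g > 3)
  if (length(bad))
    cg_stop(sprintf("invalid grade '%s' at row %d (must be 0, 1, 2 or 3)",
                    dat$grade[bad[1]], bad[1]), "cowgait_validation_error")
  data.frame(bout_id = as.character(dat$bout_id), grade = as.integer(g),
             stringsAsFactors = FALSE)
}

#' Write grade labels
#' @param labels Data frame with columns `bout_id`, `grade`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("bout_id", "grade") %in% names(labels)))
  utils::write.csv(labels[c("bout_id", "grade")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
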