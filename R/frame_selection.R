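# Representative-frame selection for labelling: frames are summarised as
# small intensity descriptors and clustered with k-means; the frame nearest
# each centroid is kept, removing near-duplicate frames far better than
# uniform subsampling of a video.

#' Build a frame descriptor from a grayscale image
#'
#' Resizes the image to `side x side` by exact area averaging (each target
#' cell is the area-weighted mean of the source pixels it covers), flattens
#' it row-wise and normalises intensities to zero mean and unit variance.
#' Constant images (zero variance) give the zero vector.
#'
#' @param image Numeric matrix of grayscale intensities (any range).
#' @param side Target side length (default 32).
#' @return Numeric descriptor vector of length `side^2`.
#' @export
descriptor_from_image <- function(image, side = 32) {
  image <- as.matrix(image)
  if (!length(image) || !is.numeric(image))
    cg_stop("image must be a non-empty numeric matrix",
            "cowgait_domain_error")
  if (side < 1 || side != round(side))
    cg_stop("side must be a positive integer", "cowgait_domain_error")
  small <- area_resize(image, side, side)
  v <- as.vector(t(small))
  s <- stats::sd(v)
  if (is.na(s) || s == 0) return(numeric(length(v)))
  (v - mean(v)) / s
}

# Exact area-average resampling via fractional-overlap weight matrices:
# out = Wr %*% img %*% t(Wc), rows of Wr/Wc normalised to sum 1.
area_resize <- function(img, out_r, out_c) {
  wmat <- function(n_out, n_in) {
    w <- matrix(0, n_out, n_in)
    scale <- n_in / n_out
    for (j in seq_len(n_out)) {
      a <- (j - 1) * scale
      b <- j * scale
      i0 <- floor(a) + 1
      i1 <- ceiling(b)
      for (i in i0:min(i1, n_in))
        w[j, i] <- min(b, i) - max(a, i - 1)
    }
    w / rowSums(w)
  }
  wmat(out_r, nrow(img)) %*% img %*% t(wmat(out_c, ncol(img)))
}

#' Select representative frames by k-means clustering
#'
#' Clusters the frame descriptors into `k` groups (Lloyd k-means, at most
#' 300 iterations, deterministic seeded initialisation on the descriptors
#' sorted by frame index) and returns, per cluster, the index of the frame
#' whose descriptor is nearest the centroid (ties broken toward the lowest
#' frame index). Output is sorted by frame index; identical inputs and seed
#' give identical output regardless of input row order.
#'
#' @param descriptors Numeric matrix, one row per frame; or a data frame
#'   whose numeric columns are the descriptor.
#' @param k Number of representatives, `1 <= k <= nrow(descriptors)`.
#' @param seed Integer seed for the initial centroid draw.
#' @param frame_index Optional integer frame indices (default
#'   `0:(n - 1)` in input row order).
#' @return Sorted integer vector of `k` selected frame indices.
#' @export
select_representatives <- function(descriptors, k, seed = 1L,
                                   frame_index = NULL) {
  x <- as.matrix(descriptors)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  if (length(frame_index) != n)
    cg_stop("frame_index length must match the number of descriptors",
            "cowgait_domain_error")
  if (anyDuplicated(frame_index))
    cg_stop("frame_index values must be unique", "cowgait_domain_error")
  if (k < 1 || k != round(k) || k > n)
    cg_stop(sprintf("k must be an integer in [1, %d]", n),
            "cowgait_domain_error")
  ord <- order(frame_index)
  x <- x[ord, , drop = FALSE]
  frame_index <- frame_index[ord]
  if (k == n) return(frame_index)

  set.seed(seed)
  uniq <- !duplicated(x)
  pool <- which(uniq)
  if (length(pool) <= k) {
    init_rows <- c(pool, sample(setdiff(seq_len(n), pool),
                                k - length(pool)))
  } else {
    init_rows <- sample(pool, k)
  }
  km <- tryCatch(
    suppressWarnings(stats::kmeans(x, centers = x[init_rows, , drop = FALSE],
                                   iter.max = 300L, algorithm = "Lloyd")),
    error = function(e)  # Lloyd can abandon a cluster on degenerate data
      suppressWarnings(stats::kmeans(x, centers = x[init_rows, , drop = FALSE],
                                     iter.max = 300L)))
  picked <- integer(0)
  for (cl in seq_len(k)) {
    members <- which(km$cluster == cl)
    if (!length(members)) next
    d2 <- rowSums((x[members, , drop = FALSE] -
                     matrix(km$centers[cl, ], length(members),
                            ncol(x), byrow = TRUE))^2)
    best <- members[d2 == min(d2)]
    picked <- c(picked, best[which.min(frame_index[best])])
  }
  # backfill if any cluster came back empty, keeping k unique selections
  if (length(picked) < k) {
    rest <- setdiff(seq_len(n), picked)
    picked <- c(picked, rest[seq_len(k - length(picked))])
  }
  sort(frame_index[picked])
}
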