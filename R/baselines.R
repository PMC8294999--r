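#' Otsu thresholding (maximum between-class variance)
#'
#' Builds a 256-bin histogram of the \[0, 1\] intensity range and picks the
#' threshold maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}; ties go to the lowest
#' qualifying threshold. The mask is \eqn{\{P > t\}}.
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @param roi Optional logical/0-1 matrix restricting the histogram and mask
#'   to a region of interest; pixels outside it never enter the mask.
#' @return A list: `mask` (integer 0/1 matrix) and `threshold`.
#' @export
otsu_segment <- function(image, roi = NULL) {
  assert_image(image)
  if (any(image < 0 | image > 1)) {
    abort("`image` must be rescaled to [0, 1] before Otsu thresholding.",
          class = "hotspotseg_input_error")
  }
  vals <- if (is.null(roi)) as.vector(image) else image[roi > 0]
  if (length(unique(vals)) < 2L) {
    abort("Otsu thresholding needs at least two distinct intensity levels.",
          class = "hotspotseg_degenerate_error")
  }
  # 256 equal bins on [0,1]; bin k covers ((k-1)/256, k/256]
  bin <- pmin(pmax(ceiling(vals * 256), 1L), 256L)
  h <- tabulate(bin, nbins = 256L)
  p <- h / sum(h)
  mids <- (seq_len(256L) - 0.5) / 256
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_T <- mu0[256L]
  # candidate cuts after bin k = threshold at k/256, k = 1..255
  w0k <- w0[1:255]; mu0k <- mu0[1:255]
  valid <- w0k > 0 & w0k < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_T * w0k[valid] - mu0k[valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  k <- which.max(sigma_b)  # lowest qualifying threshold on ties
  threshold <- k / 256
  mask <- (image > threshold)
  if (!is.null(roi)) mask <- mask & (roi > 0)
  list(mask = matrix(as.integer(mask), nrow(image), ncol(image)),
       threshold = threshold)
}

#' Seeded region growing
#'
#' Grows each seed breadth-first (row-major queue order): a neighbouring
#' pixel joins the region when its intensity lies within `tau` of the current
#' region mean (classic, `reference = "running"`) or of the seed's own value
#' (`reference = "frozen"`). The result is the union over seeds.
#'
#' @param image Numeric matrix.
#' @param seeds Two-column matrix or data frame of (row, col) seed positions.
#' @param tau Intensity tolerance (>= 0).
#' @param connectivity Pixel neighbourhood, 4 or 8.
#' @param reference `"running"` (classic region mean) or `"frozen"` (seed
#'   value; monotone in `tau`).
#' @return Integer 0/1 mask matrix.
#' @export
region_grow <- function(image, seeds, tau = 0.15, connectivity = 4L,
                        reference = c("running", "frozen")) {
  assert_image(image)
  reference <- match.arg(reference)
  check_scalar(tau, "tau", lower = 0)
  if (!connectivity %in% c(4L, 8L)) {
    abort("`connectivity` must be 4 or 8.", class = "hotspotseg_spec_error")
  }
  seeds <- as.matrix(seeds)
  if (ncol(seeds) != 2L || nrow(seeds) < 1L) {
    abort("`seeds` must be a non-empty (row, col) matrix.",
          class = "hotspotseg_input_error")
  }
  if (any(seeds[, 1] < 1 | seeds[, 1] > nrow(image) |
          seeds[, 2] < 1 | seeds[, 2] > ncol(image))) {
    abort("seed position out of image bounds.",
          class = "hotspotseg_input_error")
  }
  mask <- matrix(0L, nrow(image), ncol(image))
  for (s in seq_len(nrow(seeds))) {
    m <- region_grow_cpp(image, as.integer(seeds[s, 1]) - 1L,
                         as.integer(seeds[s, 2]) - 1L, tau,
                         as.integer(connectivity),
                         reference == "frozen")
    mask <- pmax(mask, m)
  }
  matrix(as.integer(mask), nrow(image), ncol(image))
}

#' Seed points from a probability map
#'
#' Local maxima of the hot-spot probability map above `rho`, used to give the
#' baseline segmenters the same detection input as the level-set route. A
#' pixel is a seed when it strictly exceeds `rho` and is no smaller than any
#' neighbour in its `(2k+1)` square neighbourhood; plateau runs keep their
#' first row-major pixel.
#'
#' When `image` is supplied each peak is snapped to the brightest image pixel
#' within `k` pixels: the probability map is piecewise constant over window
#' plateaus, so its maxima can sit on the dim rim of a lesion, and a growth
#' seed must lie on the bright structure it is meant to grow.
#'
#' @param prob_map Numeric matrix in \[0, 1\].
#' @param rho Detection threshold.
#' @param k Neighbourhood radius in pixels.
#' @param image Optional intensity image for seed snapping.
#' @return Integer matrix of (row, col) seeds (possibly zero rows).
#' @export
probmap_seeds <- function(prob_map, rho = 0.5, k = 3L, image = NULL) {
  assert_image(prob_map, "prob_map")
  H <- nrow(prob_map); W <- ncol(prob_map)
  cand <- which(prob_map > rho, arr.ind = TRUE)
  if (!nrow(cand)) return(matrix(integer(0), 0, 2))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - k):min(H, r + k)
    cc <- max(1, c - k):min(W, c + k)
    keep[i] <- prob_map[r, c] >= max(prob_map[rr, cc])
  }
  peaks <- cand[keep, , drop = FALSE]
  if (!is.null(image)) {
    assert_same_dim(prob_map, image, c("prob_map", "image"))
    for (i in seq_len(nrow(peaks))) {
      rr <- max(1, peaks[i, 1] - k):min(H, peaks[i, 1] + k)
      cc <- max(1, peaks[i, 2] - k):min(W, peaks[i, 2] + k)
      sub <- image[rr, cc, drop = FALSE]
      b <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      peaks[i, ] <- c(rr[b[1]], cc[b[2]])
    }
    peaks <- unique(peaks)
  }
  if (nrow(peaks) <= 1L) return(peaks)
  # collapse plateau clusters: keep first row-major peak within k Chebyshev
  ord <- order(peaks[, 2], peaks[, 1])
  peaks <- peaks[ord, , drop = FALSE]
  kept <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(peaks))) {
    if (nrow(kept) == 0L ||
        all(pmax(abs(kept[, 1] - peaks[i, 1]),
                 abs(kept[, 2] - peaks[i, 2])) > k)) {
      kept <- rbind(kept, peaks[i, , drop = FALSE])
    }
  }
  kept
}

#' Region of interest around probability-map support
#'
#' Bounding box of \eqn{\{P > \rho\}} dilated by `pad` pixels, as a 0/1
#' matrix. Localizes the Otsu histogram so a small lesion is not swamped by
#' the whole-spine intensity distribution; pass `NULL` as `roi` to
#' [otsu_segment()] for the whole-image variant.
#'
#' @param prob_map Numeric matrix in \[0, 1\].
#' @param rho Detection threshold.
#' @param pad Dilation margin in pixels (default 10).
#' @return Integer 0/1 matrix, or all-ones when the map has no support.
#' @export
probmap_roi <- function(prob_map, rho = 0.5, pad = 10L) {
  assert_image(prob_map, "prob_map")
  idx <- which(prob_map > rho, arr.ind = TRUE)
  roi <- matrix(0L, nrow(prob_map), ncol(prob_map))
  if (!nrow(idx)) return(roi + 1L)
  rr <- max(1, min(idx[, 1]) - pad):min(nrow(prob_map), max(idx[, 1]) + pad)
  cc <- max(1, min(idx[, 2]) - pad):min(ncol(prob_map), max(idx[, 2]) + pad)
  roi[rr, cc] <- 1L
  roi
}
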