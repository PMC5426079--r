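#' Segmenter parameters
#'
#' The two control parameters of the region-merging predicate plus the pixel
#' connectivity.  When driven by the optimizer, `k` ranges over
#' \[100, 4000\] and `alpha` over \[0.001, 4\]; any positive values are
#' accepted in direct use.
#'
#' @param k positive scale parameter; larger `k` raises the merge threshold
#'   so regions merge more easily.
#' @param alpha positive parameter; larger `alpha` lowers the threshold so
#'   regions merge less easily.
#' @param connectivity 4 or 8 pixel neighbourhood.
#' @return an object of class `rgb_params`.
#' @export
rgb_params <- function(k, alpha, connectivity = 4) {
  if (!is.numeric(k) || k <= 0 || !is.numeric(alpha) || alpha <= 0)
    stop("k and alpha must be positive", call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(k = k, alpha = alpha,
                 connectivity = as.integer(connectivity)),
            class = "rgb_params")
}

#' Region statistics
#'
#' Size, mean and population standard deviation of a pixel region, carried
#' with running sum and sum of squares so that two regions merge in O(1).
#' The population (not sample) deviation keeps sigma well defined (zero)
#' for single-pixel regions.
#'
#' @param pixels numeric vector of member intensities, or `NULL` when
#'   `sum`/`sumsq`/`size` are given directly.
#' @param size,sum,sumsq precomputed accumulators.
#' @return an object of class `region_stats` with fields `size`, `mean`,
#'   `stdev`, `sum`, `sumsq`.
#' @export
region_stats <- function(pixels = NULL, size = NULL, sum = NULL,
                         sumsq = NULL) {
  if (!is.null(pixels)) {
    size <- length(pixels)
    sum <- base::sum(pixels)
    sumsq <- base::sum(pixels^2)
  }
  stopifnot(size >= 1)
  m <- sum / size
  v <- max(sumsq / size - m^2, 0)
  structure(list(size = size, mean = m, stdev = sqrt(v), sum = sum,
                 sumsq = sumsq),
            class = "region_stats")
}

#' Merge two region statistics in O(1)
#'
#' @param s1,s2 [region_stats()] objects.
#' @return the merged [region_stats()].
#' @export
merge_stats <- function(s1, s2) {
  region_stats(size = s1$size + s2$size, sum = s1$sum + s2$sum,
               sumsq = s1$sumsq + s2$sumsq)
}

#' Merge threshold tau
#'
#' `tau(C) = (k / |C|) * (1 + beta / alpha)` with `beta = mu(C) / sigma(C)`,
#' and `beta = 0` when `sigma(C) = 0` (singleton or uniform region), which
#' reduces tau to the size threshold `k / |C|`.
#'
#' @param stats a [region_stats()].
#' @param params an [rgb_params()].
#' @return the threshold value, always positive.
#' @export
tau <- function(stats, params) {
  beta <- if (stats$stdev > 0) stats$mean / stats$stdev else 0
  (params$k / stats$size) * (1 + beta / params$alpha)
}

#' Pairwise region comparison predicate
#'
#' Merging is allowed iff the inter-region difference
#' `Dif = |mu(C1) - mu(C2)|` does not exceed the minimum internal tolerance
#' `MInt = min(sigma(C1) + tau(C1), sigma(C2) + tau(C2))`.  Symmetric in its
#' two arguments.
#'
#' @param s1,s2 [region_stats()] of the two regions.
#' @param params an [rgb_params()].
#' @return `TRUE` when the boundary between the regions may be eliminated.
#' @export
merge_predicate <- function(s1, s2, params) {
  dif <- abs(s1$mean - s2$mean)
  mint <- min(s1$stdev + tau(s1, params), s2$stdev + tau(s2, params))
  dif <= mint
}

#' Build the pixel adjacency graph
#'
#' One vertex per pixel; edges join spatially neighbouring pixels with
#' weight equal to the absolute intensity difference.  Edges are emitted in
#' construction order: pixels scanned row-major, and per pixel the
#' right-edge before the down-edge (8-connectivity appends down-right then
#' down-left).  Pixel indices are 1-based column-major (R convention).
#'
#' @param img grayscale matrix.
#' @param connectivity 4 or 8.
#' @return data frame with columns `a`, `b` (pixel indices) and `weight`.
#' @export
build_graph <- function(img, connectivity = 4) {
  assert_gray_image(img)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  idx <- function(r, c) (c - 1L) * h + r # 1-based, column-major
  a <- integer(0); b <- integer(0)
  steps <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) steps <- c(steps, list(c(1L, 1L), c(1L, -1L)))
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      for (s in steps) {
        rr <- r + s[1]; cc <- c + s[2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
          a <- c(a, idx(r, c)); b <- c(b, idx(rr, cc))
        }
      }
    }
  }
  data.frame(a = a, b = b, weight = abs(img[a] - img[b]))
}

#' MST region-merging segmentation
#'
#' Sorts the pixel-graph edges in non-descending weight order (stable, ties
#' broken by construction order), traverses them once, and merges the two
#' regions joined by an edge whenever [merge_predicate()] holds for their
#' current statistics.  Deterministic for fixed input.
#'
#' @param img grayscale matrix (the preprocessed TCI).
#' @param params an [rgb_params()].
#' @return an object of class `region_partition`: list with `labels`
#'   (integer matrix, labels `1..n` in order of first appearance), `stats`
#'   (data frame: `label`, `size`, `mean`, `stdev`) and `params`.
#' @export
segment <- function(img, params) {
  assert_gray_image(img)
  res <- cpp_segment(img, params$k, params$alpha, params$connectivity)
  m <- res$sum / res$size
  v <- pmax(res$sumsq / res$size - m^2, 0)
  structure(list(labels = res$labels,
                 stats = data.frame(label = seq_along(res$size),
                                    size = res$size, mean = m,
                                    stdev = sqrt(v)),
                 params = params),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region partition: %dx%d pixels, %d regions (k=%g, alpha=%g)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$stats), x$params$k,
              x$params$alpha))
  invisible(x)
}

#' Region owning a pixel
#'
#' @param partition a [segment()] result.
#' @param pixel `c(row, col)`, 1-based.
#' @return the integer region label.
#' @export
region_containing <- function(partition, pixel) {
  lb <- partition$labels
  if (pixel[1] < 1 || pixel[1] > nrow(lb) || pixel[2] < 1 ||
      pixel[2] > ncol(lb))
    stop("pixel outside image", call. = FALSE)
  lb[pixel[1], pixel[2]]
}

#' Export a partition
#'
#' Writes the label map as a 16-bit plain PGM and the per-region statistics
#' as CSV.
#'
#' @param partition a [segment()] result.
#' @param label_path destination for the label image (`.pgm`).
#' @param stats_path destination for the statistics CSV.
#' @return invisibly, the two paths.
#' @export
export_partition <- function(partition, label_path, stats_path) {
  write_image(partition$labels, label_path, maxval = 65535L)
  write.csv(partition$stats, stats_path, row.names = FALSE)
  invisible(c(label_path, stats_path))
}
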