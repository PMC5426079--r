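#' Preprocessing configuration
#'
#' Parameters of the three enhancement stages applied to the cropped
#' tumor-centered image (TCI).  The source publication leaves these values
#' unstated; the defaults are conventional choices for 8-bit medical images
#' and every one is adjustable.
#'
#' @param bilateral_diameter pixel diameter of the bilateral-filter window.
#' @param bilateral_sigma_color range (intensity) sigma of the bilateral
#'   filter, in gray levels.
#' @param bilateral_sigma_space spatial sigma of the bilateral filter,
#'   in pixels.
#' @param meanshift_spatial_radius spatial window radius of mean shift,
#'   in pixels.
#' @param meanshift_range_radius intensity window radius of mean shift,
#'   in gray levels.
#' @param meanshift_pyramid_levels number of coarse pyramid levels used to
#'   seed the mean-shift modes (0 = single scale).
#' @param enabled logical; `FALSE` turns the enhancement stages off so the
#'   pipeline reduces to the crop.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(bilateral_diameter = 9,
                              bilateral_sigma_color = 75,
                              bilateral_sigma_space = 75,
                              meanshift_spatial_radius = 10,
                              meanshift_range_radius = 20,
                              meanshift_pyramid_levels = 2,
                              enabled = TRUE) {
  stopifnot(bilateral_diameter > 0, bilateral_sigma_color > 0,
            bilateral_sigma_space > 0, meanshift_spatial_radius > 0,
            meanshift_range_radius > 0, meanshift_pyramid_levels >= 0)
  structure(list(bilateral_diameter = as.integer(bilateral_diameter),
                 bilateral_sigma_color = bilateral_sigma_color,
                 bilateral_sigma_space = bilateral_sigma_space,
                 meanshift_spatial_radius =
                   as.integer(meanshift_spatial_radius),
                 meanshift_range_radius = meanshift_range_radius,
                 meanshift_pyramid_levels =
                   as.integer(meanshift_pyramid_levels),
                 enabled = isTRUE(enabled)),
            class = "preprocess_config")
}

#' Rectangular region of interest
#'
#' Two diagonal corner points, 0-based, half-open `[x0, x1) x [y0, y1)`.
#' Corners may be given in any diagonal order; they are normalized so that
#' `x1 > x0` and `y1 > y0`.
#'
#' @param x0,y0,x1,y1 corner coordinates in pixels.
#' @return an object of class `roi_rect`.
#' @export
roi_rect <- function(x0, y0, x1, y1) {
  r <- list(x0 = min(x0, x1), y0 = min(y0, y1),
            x1 = max(x0, x1), y1 = max(y0, y1))
  if (r$x1 <= r$x0 || r$y1 <= r$y0)
    stop("invalid ROI: zero area", call. = FALSE)
  structure(r, class = "roi_rect")
}

#' Crop the tumor-centered image
#'
#' Extracts the rectangular ROI from the full frame.  The result is the TCI
#' every downstream stage consumes; the lesion is assumed to be fully
#' contained and roughly centered in it.
#'
#' @param image grayscale matrix.
#' @param roi an [roi_rect()].
#' @return the cropped matrix of shape `(y1 - y0) x (x1 - x0)`.
#' @export
crop_tci <- function(image, roi) {
  assert_gray_image(image, "image")
  if (!inherits(roi, "roi_rect")) roi <- do.call(roi_rect, as.list(roi))
  if (roi$x0 < 0 || roi$y0 < 0 || roi$x1 > ncol(image) ||
      roi$y1 > nrow(image))
    stop("invalid ROI: outside image bounds", call. = FALSE)
  image[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1, drop = FALSE]
}

#' Bilateral filter (speckle reduction)
#'
#' Edge-preserving smoothing with Gaussian spatial and range kernels; the
#' first enhancement stage.  Output is rounded back to the integer gray
#' grid.
#'
#' @param img grayscale matrix.
#' @param cfg a [preprocess_config()].
#' @return filtered matrix, same shape.
#' @export
bilateral_filter <- function(img, cfg = preprocess_config()) {
  assert_gray_image(img)
  out <- cpp_bilateral(img, cfg$bilateral_diameter,
                       cfg$bilateral_sigma_color, cfg$bilateral_sigma_space)
  round(clamp255(out))
}

#' Global histogram equalization
#'
#' Classical CDF remapping of the 256-level histogram: level `v` maps to
#' `round((cdf(v) - cdf_min) / (N - cdf_min) * 255)`.  The mapping is
#' monotone non-decreasing, so pixel rank order is preserved.  A constant
#' image is returned unchanged.
#'
#' @param img grayscale matrix (integer levels).
#' @return equalized matrix, same shape.
#' @export
equalize_histogram <- function(img) {
  assert_gray_image(img)
  lut <- equalization_lut(img)
  matrix(lut[round(img) + 1L], nrow = nrow(img))
}

# the 256-entry lookup table induced by the CDF mapping (exposed for tests)
equalization_lut <- function(img) {
  h <- tabulate(round(img) + 1L, nbins = 256L)
  cdf <- cumsum(h)
  n <- length(img)
  cdf_min <- cdf[which(h > 0)[1]]
  if (n == cdf_min) return(0:255) # single occupied bin: identity
  round((pmax(cdf - cdf_min, 0)) / (n - cdf_min) * 255)
}

#' Pyramid mean shift filtering
#'
#' Flattens the image towards its local modes in the joint spatial-range
#' domain, improving region homogeneity.  With `meanshift_pyramid_levels`
#' greater than 0 the mode search is seeded coarse-to-fine: the image is
#' Gaussian-blurred and 2x downsampled per level, filtered at the coarsest
#' scale, and the upsampled result initializes the range coordinate of the
#' next finer pass.  Converged modes are snapped to the nearest intensity
#' value present in the input, so the output never has more distinct levels
#' than the input.
#'
#' @param img grayscale matrix.
#' @param cfg a [preprocess_config()].
#' @return filtered matrix, same shape.
#' @export
pyramid_mean_shift <- function(img, cfg = preprocess_config()) {
  assert_gray_image(img)
  levels <- cfg$meanshift_pyramid_levels
  sp <- cfg$meanshift_spatial_radius
  sr <- cfg$meanshift_range_radius
  pyr <- list(img)
  if (levels > 0) {
    for (l in seq_len(levels)) {
      prev <- pyr[[l]]
      if (min(dim(prev)) < 8) { levels <- l - 1L; break }
      pyr[[l + 1L]] <- downsample2(cpp_gaussian_blur(prev, 1))
    }
  }
  init <- pyr[[levels + 1L]]
  for (l in seq(levels + 1L, 1L)) {
    cur <- pyr[[l]]
    if (!all(dim(init) == dim(cur))) init <- upsample_to(init, dim(cur))
    init <- cpp_meanshift(cur, init, max(1L, as.integer(sp / 2^(l - 1))),
                          sr, 5L)
  }
  snap_to_levels(init, img)
}

downsample2 <- function(img) {
  h <- nrow(img) %/% 2L
  w <- ncol(img) %/% 2L
  sub <- img[seq_len(2L * h), seq_len(2L * w), drop = FALSE]
  0.25 * (sub[seq(1, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE] +
          sub[seq(2, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE] +
          sub[seq(1, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE] +
          sub[seq(2, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE])
}

upsample_to <- function(img, d) {
  ri <- pmin(nrow(img), pmax(1L, ceiling(seq_len(d[1]) / d[1] * nrow(img))))
  ci <- pmin(ncol(img), pmax(1L, ceiling(seq_len(d[2]) / d[2] * ncol(img))))
  img[ri, ci, drop = FALSE]
}

# snap each filtered value to the nearest gray level present in the source
snap_to_levels <- function(filtered, source) {
  lv <- sort(unique(as.vector(source)))
  if (length(lv) == 1L) return(matrix(lv, nrow(source), ncol(source)))
  idx <- findInterval(filtered, lv, all.inside = TRUE)
  lower <- lv[idx]
  upper <- lv[pmin(idx + 1L, length(lv))]
  snapped <- ifelse(filtered - lower <= upper - filtered, lower, upper)
  matrix(snapped, nrow = nrow(source))
}

#' Full preprocessing chain
#'
#' Crop, then bilateral filter, histogram equalization and pyramid mean
#' shift, in exactly that order.  With `cfg$enabled = FALSE` only the crop
#' is applied.
#'
#' @inheritParams crop_tci
#' @param cfg a [preprocess_config()].
#' @return the preprocessed TCI.
#' @export
preprocess_pipeline <- function(image, roi, cfg = preprocess_config()) {
  tci <- crop_tci(image, roi)
  if (!cfg$enabled) return(tci)
  if (nrow(tci) < 8 || ncol(tci) < 8)
    stop("TCI must be at least 8x8 for segmentation", call. = FALSE)
  tci |>
    bilateral_filter(cfg) |>
    equalize_histogram() |>
    pyramid_mean_shift(cfg)
}
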