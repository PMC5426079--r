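#' Volume fractions of a segmentation against truth
#'
#' With `A_m` the truth foreground, `A_n` the segmented foreground:
#' `TPVF = |A_m & A_n| / |A_m| * 100`,
#' `FPVF = (|A_n| - |A_m & A_n|) / |A_m| * 100`,
#' `FNVF = (|A_m| - |A_m & A_n|) / |A_m| * 100`.
#' `TPVF + FNVF = 100` identically; FPVF may exceed 100 for gross
#' over-coverage and is not capped.
#'
#' @param truth,seg 0/1 matrices of equal shape; `truth` non-empty.
#' @return named numeric vector `c(tpvf, fpvf, fnvf)`, in percent.
#' @export
volume_fractions <- function(truth, seg) {
  stopifnot(all(dim(truth) == dim(seg)))
  am <- sum(truth == 1)
  if (am == 0) stop("empty truth mask: volume fractions undefined",
                    call. = FALSE)
  an <- sum(seg == 1)
  ov <- sum(truth == 1 & seg == 1)
  tpvf <- ov / am * 100
  # (|A_m| - ov)/|A_m| = 1 - ov/|A_m| algebraically; computing it as the
  # complement keeps TPVF + FNVF = 100 exact in floating point
  c(tpvf = tpvf, fpvf = (an - ov) / am * 100, fnvf = 100 - tpvf)
}

#' Center of the true tumor region
#'
#' Centroid of the truth foreground, rounded to the nearest pixel.  If the
#' rounded centroid falls on background (non-convex truth), the nearest
#' foreground pixel is used instead, with a warning.
#'
#' @param truth 0/1 matrix, non-empty.
#' @return integer `c(row, col)`, 1-based.
#' @export
region_center <- function(truth) {
  fg <- which(truth == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty truth mask has no center", call. = FALSE)
  ctr <- floor(colMeans(fg) + 0.5) # translation-equivariant rounding
  if (truth[ctr[1], ctr[2]] != 1) {
    warning("centroid falls on background; using nearest foreground pixel",
            call. = FALSE)
    d2 <- (fg[, 1] - ctr[1])^2 + (fg[, 2] - ctr[2])^2
    ctr <- fg[which.min(d2), ]
  }
  stats::setNames(as.integer(ctr), c("row", "col"))
}

#' Radial boundary crossings
#'
#' For each of `n_rays` rays from `center` at angles `2 pi i / n_rays`
#' (i = 0..n_rays-1; x = cos, y = sin, y pointing down the rows), the
#' radius of the outermost foreground-to-background transition.  The mask
#' is sampled bilinearly along the ray at 0.25-px steps (outside the image
#' counts as background) and the last downward crossing of the 0.5 level
#' is localized by linear interpolation between the bracketing samples.
#' A ray starting on background (center outside the mask) can get radius 0,
#' with a warning.
#'
#' @param mask 0/1 matrix.
#' @param center `c(row, col)`, 1-based.
#' @param n_rays number of rays (published setting: 180).
#' @return numeric vector of `n_rays` radii in pixels.
#' @export
radial_crossings <- function(mask, center, n_rays = 180) {
  h <- nrow(mask); w <- ncol(mask)
  if (mask[center[1], center[2]] != 1)
    warning("ray origin on background: zero radii possible", call. = FALSE)
  step <- 0.25
  rs <- seq(0, sqrt(h^2 + w^2), by = step)
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  radii <- numeric(n_rays)
  for (i in seq_len(n_rays)) {
    v <- bilinear_sample(mask, center[1] + rs * sin(theta[i]),
                         center[2] + rs * cos(theta[i]))
    n <- length(v)
    trans <- which(v[-n] >= 0.5 & v[-1] < 0.5)
    if (length(trans)) {
      j <- max(trans)
      radii[i] <- rs[j] + step * (v[j] - 0.5) / (v[j] - v[j + 1])
    } else radii[i] <- 0
  }
  radii
}

# bilinear interpolation of a matrix at fractional (row, col) positions;
# positions outside the grid read as 0
bilinear_sample <- function(m, y, x) {
  h <- nrow(m); w <- ncol(m)
  at <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    out <- numeric(length(r))
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  at(y0, x0) * (1 - fy) * (1 - fx) + at(y0 + 1, x0) * fy * (1 - fx) +
    at(y0, x0 + 1) * (1 - fy) * fx + at(y0 + 1, x0 + 1) * fy * fx
}

#' Averaged radial error (ARE)
#'
#' `ARE = 100/n * sum_i |C_s(i) - C_r(i)| / |C_r(i) - C_o|`, where `C_o` is
#' the center of the truth region and `C_s(i)`, `C_r(i)` are the outermost
#' crossings of ray `i` with the segmented and true boundaries.  Both
#' contours are probed along rays from the truth center.  Rays with zero
#' truth radius are skipped (with a warning) and `n` reduced accordingly.
#'
#' @param truth,seg 0/1 matrices of equal shape, both non-empty.
#' @param n_rays number of rays (default 180).
#' @return the averaged radial error, in percent.
#' @export
averaged_radial_error <- function(truth, seg, n_rays = 180) {
  stopifnot(all(dim(truth) == dim(seg)))
  if (!any(seg == 1)) stop("empty segmentation mask", call. = FALSE)
  ctr <- region_center(truth)
  cr <- radial_crossings(truth, ctr, n_rays)
  cs <- suppressWarnings(radial_crossings(seg, ctr, n_rays))
  ok <- cr > 0
  if (!all(ok))
    warning(sum(!ok), " ray(s) with zero truth radius skipped",
            call. = FALSE)
  if (!any(ok)) stop("all rays degenerate: ARE undefined", call. = FALSE)
  mean(abs(cs[ok] - cr[ok]) / cr[ok]) * 100
}

#' Full metrics report
#'
#' @param truth,seg 0/1 matrices of equal shape.
#' @param n_rays number of rays for the radial error.
#' @return list with `are`, `tpvf`, `fpvf`, `fnvf` (percent) and `n_rays`,
#'   class `metrics_report`.
#' @export
metrics_report <- function(truth, seg, n_rays = 180) {
  vf <- volume_fractions(truth, seg)
  are <- averaged_radial_error(truth, seg, n_rays)
  structure(list(are = are, tpvf = unname(vf["tpvf"]),
                 fpvf = unname(vf["fpvf"]), fnvf = unname(vf["fnvf"]),
                 n_rays = n_rays),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ARE %.2f%%  TPVF %.2f%%  FPVF %.2f%%  FNVF %.2f%%  (%d rays)\n",
              x$are, x$tpvf, x$fpvf, x$fnvf, x$n_rays))
  invisible(x)
}
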