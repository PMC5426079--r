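#' Synthetic ultrasound phantom specification
#'
#' A stated imaging world for testing: a darker, roughly elliptical
#' (optionally lobulated) lesion centered in a brighter background,
#' corrupted by multiplicative speckle, Gaussian blur, smooth intensity
#' inhomogeneity and (optionally) a posterior acoustic shadow band.
#' Everything is deterministic given the spec (including its seed).
#'
#' @param height,width frame size in pixels.
#' @param lesion_shape `"ellipse"` or `"lobulated"` (5-lobed radius
#'   modulation, echoing the lobulated outline of malignant lesions).
#' @param center_jitter maximum lesion-center displacement from the frame
#'   center, pixels (the actual offset is drawn deterministically from the
#'   seed).
#' @param semi_axes `c(a, b)` ellipse semi-axes in pixels.
#' @param lobe_amplitude radius modulation fraction for the lobulated
#'   shape.
#' @param rotation ellipse rotation, radians.
#' @param background_mean,lesion_mean intensity levels; the lesion is
#'   darker (`background_mean > lesion_mean`).
#' @param speckle_sigma scale of the multiplicative mean-1 speckle
#'   (squared-Rayleigh style heavy tail: `1 + sigma * (Exp(1) - 1)`).
#' @param blur_sigma Gaussian point-spread sigma, pixels.
#' @param inhomogeneity_amplitude amplitude of the additive low-frequency
#'   intensity field, gray levels.
#' @param shadow add a posterior dark band below the lesion.
#' @param seed RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64,
                         lesion_shape = c("ellipse", "lobulated"),
                         center_jitter = 0, semi_axes = c(12, 9),
                         lobe_amplitude = 0.15, rotation = 0,
                         background_mean = 170, lesion_mean = 90,
                         speckle_sigma = 0.1, blur_sigma = 1,
                         inhomogeneity_amplitude = 10, shadow = FALSE,
                         seed = 1L) {
  lesion_shape <- match.arg(lesion_shape)
  if (background_mean <= lesion_mean)
    stop("lesion must be darker than the background", call. = FALSE)
  offset <- c(0, 0)
  if (center_jitter > 0) {
    u <- ((seed * c(0.6180339887, 0.7548776662)) %% 1) * 2 - 1 # low-discrepancy
    offset <- round(u * center_jitter)
  }
  spec <- structure(list(height = as.integer(height),
                         width = as.integer(width),
                         lesion_shape = lesion_shape,
                         center_jitter = center_jitter,
                         center = c(height %/% 2 + 1, width %/% 2 + 1) +
                           offset,
                         semi_axes = semi_axes,
                         lobe_amplitude = lobe_amplitude,
                         rotation = rotation,
                         background_mean = background_mean,
                         lesion_mean = lesion_mean,
                         speckle_sigma = speckle_sigma,
                         blur_sigma = blur_sigma,
                         inhomogeneity_amplitude = inhomogeneity_amplitude,
                         shadow = isTRUE(shadow), seed = as.integer(seed)),
                    class = "phantom_spec")
  m <- lesion_mask(spec)
  fg <- which(m == 1, arr.ind = TRUE)
  if (min(fg[, 1], spec$height - fg[, 1] + 1, fg[, 2],
          spec$width - fg[, 2] + 1) <= 4)
    stop("lesion does not fit inside the frame with a 4-pixel margin",
         call. = FALSE)
  if (m[height %/% 2 + 1, width %/% 2 + 1] != 1)
    stop("jittered lesion no longer contains the frame center",
         call. = FALSE)
  spec
}

#' Ground-truth lesion mask of a phantom
#'
#' Ellipse: pixels satisfying the rotated-ellipse inequality.  Lobulated:
#' the ellipse radius is modulated as
#' `r(theta) = r0(theta) * (1 + lobe_amplitude * sin(5 theta + phi))` with
#' a seed-derived phase `phi`; amplitude 0 reduces exactly to the ellipse.
#'
#' @param spec a [phantom_spec()].
#' @return 0/1 integer matrix.
#' @export
lesion_mask <- function(spec) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  dy <- matrix(seq_len(spec$height) - spec$center[1], spec$height,
               spec$width)
  dx <- matrix(rep(seq_len(spec$width) - spec$center[2],
                   each = spec$height), spec$height, spec$width)
  u <- dx * cos(spec$rotation) + dy * sin(spec$rotation)
  v <- -dx * sin(spec$rotation) + dy * cos(spec$rotation)
  q <- sqrt((u / a)^2 + (v / b)^2)
  if (spec$lesion_shape == "lobulated" && spec$lobe_amplitude > 0) {
    phi <- (spec$seed * 0.6180339887) %% 1 * 2 * pi
    s <- 1 + spec$lobe_amplitude * sin(5 * atan2(v, u) + phi)
    (q <= s) + 0L
  } else {
    (q <= 1) + 0L
  }
}

#' Render a phantom image with its truth mask
#'
#' `image = clip(blur((base + inhomogeneity + shadow) * speckle))`, where
#' `base` is the two-level lesion/background image, the inhomogeneity is a
#' single low-frequency sinusoidal field of the stated amplitude with
#' seed-drawn orientation and phase, the optional shadow is a dark band
#' below the lesion, and the speckle is i.i.d. multiplicative mean-1 noise.
#' Output is rounded to the integer gray grid.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (matrix) and `truth` (0/1 matrix).
#' @export
render_phantom <- function(spec) {
  mask <- lesion_mask(spec)
  h <- spec$height; w <- spec$width
  base <- ifelse(mask == 1, spec$lesion_mean, spec$background_mean)
  set.seed(spec$seed)
  if (spec$inhomogeneity_amplitude > 0) {
    ang <- runif(1, 0, 2 * pi)
    phase <- runif(1, 0, 2 * pi)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(rep(seq_len(w), each = h), h, w)
    field <- sin(2 * pi * (cos(ang) * xx + sin(ang) * yy) / max(h, w) +
                   phase)
    base <- base + spec$inhomogeneity_amplitude * field
  } else {
    runif(2) # keep the RNG stream aligned across configurations
  }
  if (spec$shadow) {
    bottom <- max(which(rowSums(mask) > 0))
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(rep(seq_len(w), each = h), h, w)
    lateral <- exp(-((xx - spec$center[2]) / (0.9 * spec$semi_axes[1]))^2)
    onset <- 1 / (1 + exp(-(yy - bottom - 2)))
    base <- base - 35 * lateral * onset
  }
  if (spec$speckle_sigma > 0) {
    speckle <- 1 + spec$speckle_sigma * (rexp(h * w) - 1)
    base <- base * matrix(speckle, h, w)
  }
  img <- cpp_gaussian_blur(base, spec$blur_sigma)
  list(image = round(clamp255(img)), truth = mask)
}

#' Deterministic phantom batches by difficulty
#'
#' Difficulty scales the stated world: easy = contrast 80, speckle 0.1,
#' ellipse; medium = contrast 50, speckle 0.2, mild lobulation; hard =
#' contrast 30, speckle 0.3, lobulated with posterior shadow.  Geometry
#' (semi-axes, rotation, center jitter) is varied per item by the seeded
#' RNG; identical calls return identical suites.
#'
#' @param n number of phantoms.
#' @param difficulty `"easy"`, `"medium"` or `"hard"`.
#' @param seed RNG seed for the batch.
#' @param height,width frame size.  The default 128 px frame with lesion
#'   semi-axes of 16-28 px approximates the pixel scale of a clinical TCI;
#'   much smaller frames inflate the relative radial error, because the
#'   preprocessing chain absorbs the blurred lesion rim (a roughly
#'   fixed-width band) into the lesion.
#' @return list of `n` elements, each with `image`, `truth`, `spec`.
#' @export
phantom_suite <- function(n, difficulty = c("easy", "medium", "hard"),
                          seed = 1L, height = 128, width = 128) {
  difficulty <- match.arg(difficulty)
  stopifnot(n >= 1)
  par <- switch(difficulty,
    easy = list(contrast = 80, speckle = 0.1, shape = "ellipse",
                lobe = 0, shadow = FALSE),
    medium = list(contrast = 50, speckle = 0.2, shape = "lobulated",
                  lobe = 0.08, shadow = FALSE),
    hard = list(contrast = 30, speckle = 0.3, shape = "lobulated",
                lobe = 0.15, shadow = TRUE))
  set.seed(seed)
  out <- vector("list", n)
  scale <- min(height, width) / 128
  for (i in seq_len(n)) {
    a <- runif(1, 20, 28) * scale
    b <- runif(1, 16, 22) * scale
    rot <- runif(1, 0, pi)
    item_seed <- sample.int(2^30, 1)
    spec <- phantom_spec(height = height, width = width,
                         lesion_shape = par$shape, center_jitter = 3 * scale,
                         semi_axes = c(a, b), lobe_amplitude = par$lobe,
                         rotation = rot, background_mean = 170,
                         lesion_mean = 170 - par$contrast,
                         speckle_sigma = par$speckle,
                         shadow = par$shadow, seed = item_seed)
    out[[i]] <- c(render_phantom(spec), list(spec = spec))
  }
  out
}
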