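# 5x5 "elliptical" structuring element: the discrete disk of radius 2,
# cells with dx^2 + dy^2 <= 4 (13 active cells).  Fixed for
# reproducibility.
morph_kernel_5x5 <- function() {
  d <- expand.grid(dy = -2:2, dx = -2:2)
  matrix(as.integer(d$dx^2 + d$dy^2 <= 4), 5, 5)
}

# binary erosion/dilation by an arbitrary structuring element via
# shift-and-combine; outside the image counts as background
morph_shift <- function(mask, dy, dx) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dy):min(h, h + dy)
  cs <- max(1, 1 + dx):min(w, w + dx)
  out[rs, cs] <- mask[rs - dy, cs - dx, drop = FALSE]
  out
}

binary_erode <- function(mask, kernel = morph_kernel_5x5()) {
  off <- which(kernel == 1, arr.ind = TRUE) -
    matrix(rep((dim(kernel) + 1) %/% 2, each = sum(kernel)), ncol = 2)
  acc <- matrix(1L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    acc <- acc & morph_shift(mask, -off[i, 1], -off[i, 2])
  acc + 0L
}

binary_dilate <- function(mask, kernel = morph_kernel_5x5()) {
  off <- which(kernel == 1, arr.ind = TRUE) -
    matrix(rep((dim(kernel) + 1) %/% 2, each = sum(kernel)), ncol = 2)
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    acc <- acc | morph_shift(mask, off[i, 1], off[i, 2])
  acc + 0L
}

#' Binary tumor mask from a partition
#'
#' The mask is 1 exactly on reference-region pixels.
#'
#' @param partition a [segment()] result.
#' @param ref an [extract_reference_region()] result.
#' @return 0/1 integer matrix.
#' @export
to_binary <- function(partition, ref) {
  (partition$labels == ref$label) + 0L
}

#' Morphological opening then closing
#'
#' Opening (erode then dilate) removes spicules, closing (dilate then
#' erode) fills holes; both use the fixed 5x5 elliptical (13-cell discrete
#' disk) structuring element.
#'
#' @param mask 0/1 matrix.
#' @return refined 0/1 matrix.
#' @export
morph_open_close <- function(mask) {
  k <- morph_kernel_5x5()
  opened <- binary_dilate(binary_erode(mask, k), k)
  binary_erode(binary_dilate(opened, k), k)
}

# 4-connected components by flood fill (iterative queue)
connected_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  fg <- which(mask == 1)
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% h + 1L
      c <- (q - 1L) %/% h + 1L
      for (nb in c(if (r > 1) q - 1L, if (r < h) q + 1L,
                   if (c > 1) q - h, if (c < w) q + h)) {
        if (mask[nb] == 1L && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

#' Keep the central (or largest) foreground component
#'
#' Guard against morphology splitting the mask: keep the component
#' containing the image center; if the center is background, keep the
#' largest component.  An empty mask passes through with a warning.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix with a single component (or empty).
#' @export
largest_central_component <- function(mask) {
  if (!any(mask == 1)) {
    warning("empty mask", call. = FALSE)
    return(mask)
  }
  lab <- connected_components(mask)
  ctr <- lab[nrow(mask) %/% 2L + 1L, ncol(mask) %/% 2L + 1L]
  keep <- if (ctr > 0) ctr else which.max(tabulate(lab[lab > 0]))
  (lab == keep) + 0L
}

#' Trace the outer contour of a mask
#'
#' Moore boundary tracing of the foreground's outer boundary, returning a
#' closed, ordered pixel chain (consecutive points 8-adjacent).  The mask
#' is expected to hold a single 4-connected component.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return integer matrix with columns `row`, `col` (1-based), ordered.
#' @export
extract_contour <- function(mask) {
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask has no contour", call. = FALSE)
  # start: topmost, then leftmost foreground pixel
  start <- fg[order(fg[, 1], fg[, 2]), , drop = FALSE][1, ]
  if (nrow(fg) == 1) {
    out <- matrix(start, ncol = 2)
    colnames(out) <- c("row", "col")
    return(out)
  }
  h <- nrow(mask); w <- ncol(mask)
  inside <- function(p) p[1] >= 1 && p[1] <= h && p[2] >= 1 && p[2] <= w
  isfg <- function(p) inside(p) && mask[p[1], p[2]] == 1
  # clockwise Moore neighbourhood starting from "west"
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  contour <- matrix(start, ncol = 2)
  prev_dir <- 1L # came from the west (above-left of start is background)
  cur <- start
  repeat {
    found <- FALSE
    # scan clockwise starting just after the backtrack direction
    for (s in seq_len(8)) {
      d <- (prev_dir - 1L + s - 1L) %% 8L + 1L
      cand <- cur + nb[d, ]
      if (isfg(cand)) {
        # backtrack for next step: direction pointing back to cur,
        # advanced by one clockwise
        prev_dir <- (d + 4L - 1L + 1L) %% 8L + 1L
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel (cannot happen with nrow(fg) > 1)
    if (all(cur == start)) break
    contour <- rbind(contour, cur)
  }
  colnames(contour) <- c("row", "col")
  contour
}

#' Full postprocessing chain
#'
#' Binary conversion, opening/closing, central-component guard, contour
#' extraction.
#'
#' @param partition a [segment()] result.
#' @param ref an [extract_reference_region()] result.
#' @param keep_central apply [largest_central_component()] (default TRUE).
#' @return list with `mask` (0/1 matrix) and `contour` (coordinate
#'   matrix, or `NULL` when the mask came out empty).
#' @export
postprocess_mask <- function(partition, ref, keep_central = TRUE) {
  mask <- morph_open_close(to_binary(partition, ref))
  if (keep_central) mask <- suppressWarnings(largest_central_component(mask))
  contour <- if (any(mask == 1)) extract_contour(mask) else NULL
  list(mask = mask, contour = contour)
}
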