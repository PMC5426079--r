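#' Objective weights
#'
#' Non-negative weights of the three fitness terms: between-class variance
#' `V_B`, within-class variance `V_W` and average boundary gradient `G_A`.
#' Defaults are the published operating point a = 0.3, b = 0.3, c = 0.4.
#'
#' @param a,b,c term weights, `a + b + c > 0`.
#' @return an object of class `objective_weights`.
#' @export
objective_weights <- function(a = 0.3, b = 0.3, c = 0.4) {
  if (any(c(a, b, c) < 0) || a + b + c <= 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "objective_weights")
}

#' Reference region of a partition
#'
#' The candidate tumor region: the subregion containing the central pixel
#' of the TCI, `(floor(H/2), floor(W/2))` 0-based.  The lesion is assumed
#' centered in the TCI, so this region is the expected tumor when the
#' segmenter parameters are well chosen.
#'
#' @param partition a [segment()] result.
#' @return list with `label`, `mask` (0/1 matrix) and `stats`
#'   ([region_stats()] of the region), class `reference_region`.
#' @export
extract_reference_region <- function(partition) {
  lb <- partition$labels
  ctr <- c(nrow(lb) %/% 2L + 1L, ncol(lb) %/% 2L + 1L) # 0-based floor(H/2)
  lab <- lb[ctr[1], ctr[2]]
  row <- partition$stats[lab, ]
  structure(list(label = lab, mask = (lb == lab) + 0L,
                 stats = region_stats(size = row$size,
                                      sum = row$size * row$mean,
                                      sumsq = row$size *
                                        (row$stdev^2 + row$mean^2))),
            class = "reference_region")
}

#' Regions adjacent to the reference region
#'
#' Labels of regions owning at least one pixel 4-adjacent to a
#' reference-region pixel; never includes the reference region itself.
#'
#' @param partition a [segment()] result.
#' @param ref an [extract_reference_region()] result.
#' @return integer vector of labels (possibly empty).
#' @export
adjacent_regions <- function(partition, ref) {
  lb <- partition$labels
  h <- nrow(lb); w <- ncol(lb)
  m <- ref$mask == 1
  # shifted comparisons: for each direction collect the neighbour labels of
  # reference pixels
  labs <- integer(0)
  if (h > 1) {
    labs <- c(labs, lb[-1, , drop = FALSE][m[-h, , drop = FALSE]]) # below
    labs <- c(labs, lb[-h, , drop = FALSE][m[-1, , drop = FALSE]]) # above
  }
  if (w > 1) {
    labs <- c(labs, lb[, -1, drop = FALSE][m[, -w, drop = FALSE]]) # right
    labs <- c(labs, lb[, -w, drop = FALSE][m[, -1, drop = FALSE]]) # left
  }
  sort(unique(labs[labs != ref$label]))
}

#' Between-class variance V_B
#'
#' `V_B = sum_i P(C_i) * (mu(C_i) - mu(C_Ref))^2` over the regions adjacent
#' to the reference region, with `P(C_i) = |C_i| / |TCI|`.  Maximizing it
#' drives the reference region's neighbours to contrast with it, countering
#' oversegmentation.
#'
#' @param partition a [segment()] result.
#' @param ref an [extract_reference_region()] result.
#' @param tci_size total pixel count of the TCI (defaults to the label-map
#'   size).
#' @return non-negative scalar.
#' @export
between_class_variance <- function(partition, ref,
                                   tci_size = length(partition$labels)) {
  adj <- adjacent_regions(partition, ref)
  if (length(adj) == 0) return(0)
  st <- partition$stats[adj, ]
  sum(st$size / tci_size * (st$mean - ref$stats$mean)^2)
}

#' Within-class variance V_W
#'
#' `V_W = arctan(var(C_Ref)) / P(C_Ref)` where `var` is the population
#' variance of the reference-region intensities and
#' `P(C_Ref) = |C_Ref| / |TCI|`.  The arctan compresses the variance to the
#' scale of the area fraction, and dividing by `P` penalizes small reference
#' regions so that minimizing `V_W` does not collapse the region
#' (oversegmentation guard).  The multiplier form `arctan(var) * P` is
#' available for sensitivity checks.
#'
#' @param img the (preprocessed) TCI matrix.
#' @param ref an [extract_reference_region()] result.
#' @param tci_size total TCI pixel count.
#' @param p_form `"divide"` (default) or `"multiply"`.
#' @return non-negative scalar.
#' @export
within_class_variance <- function(img, ref, tci_size = length(img),
                                  p_form = c("divide", "multiply")) {
  p_form <- match.arg(p_form)
  px <- img[ref$mask == 1]
  v <- mean((px - mean(px))^2)
  p <- length(px) / tci_size
  if (p_form == "divide") atan(v) / p else atan(v) * p
}

#' Inner boundary of the reference region
#'
#' Member pixels with at least one 4-neighbour outside the region; the
#' image border counts as outside.
#'
#' @param ref an [extract_reference_region()] result.
#' @return integer matrix with columns `row`, `col` (1-based), in
#'   column-major scan order.
#' @export
boundary_pixels <- function(ref) {
  m <- ref$mask == 1
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- m
  inner <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  b <- which(m & !inner, arr.ind = TRUE)
  colnames(b) <- c("row", "col")
  b
}

#' Average boundary gradient G_A
#'
#' Mean Sobel gradient magnitude over the inner boundary pixels of the
#' reference region, computed on the preprocessed TCI with replicate border
#' padding.  Maximizing it pulls the candidate contour towards strong
#' edges.
#'
#' @param img the (preprocessed) TCI matrix.
#' @param ref an [extract_reference_region()] result.
#' @param sobel optional precomputed gradient-magnitude matrix (one Sobel
#'   pass per image suffices for all candidates).
#' @return non-negative scalar.
#' @export
average_gradient <- function(img, ref, sobel = NULL) {
  if (is.null(sobel)) sobel <- cpp_sobel(img)
  b <- boundary_pixels(ref)
  mean(sobel[b])
}

#' Swarm normalization factors
#'
#' Arithmetic means of `V_B`, `V_W` and `G_A` over the term triples of the
#' uniformly initialized swarm, computed once per image before the first
#' optimizer iteration.  A zero mean (degenerate image) is replaced by 1
#' with a warning so later divisions are always defined.
#'
#' @param term_samples matrix or data frame with one row per initial
#'   particle and columns `v_b`, `v_w`, `g_a`.
#' @return list with `f_b`, `f_w`, `f_a`, class `normalization_factors`.
#' @export
normalization_factors <- function(term_samples) {
  ts <- as.data.frame(term_samples)
  stopifnot(nrow(ts) >= 1)
  f <- c(f_b = mean(ts$v_b), f_w = mean(ts$v_w), f_a = mean(ts$g_a))
  if (any(f == 0)) {
    warning("zero-mean objective term(s): ",
            paste(names(f)[f == 0], collapse = ", "),
            " set to 1 (degenerate image)", call. = FALSE)
    f[f == 0] <- 1
  }
  structure(as.list(f), class = "normalization_factors")
}

#' Combined fitness F_O
#'
#' `F_O = a * V_B / f_B - b * V_W / f_W + c * G_A / f_A`; larger is better
#' and the swarm maximizes it.  With weights `(1, 0, 0)` and unit factors
#' this reduces to the single-objective between-class-variance fitness.
#'
#' @param v_b,v_w,g_a raw term values.
#' @param factors a [normalization_factors()] result.
#' @param weights an [objective_weights()].
#' @return scalar fitness.
#' @export
combined_objective <- function(v_b, v_w, g_a, factors,
                               weights = objective_weights()) {
  weights$a * v_b / factors$f_b - weights$b * v_w / factors$f_w +
    weights$c * g_a / factors$f_a
}

#' Evaluate one (k, alpha) candidate
#'
#' Segments the image, extracts the reference region and computes the three
#' objective terms; when normalization factors are supplied the combined
#' fitness is attached, otherwise `f_o` is `NA` (pre-normalization pass).
#'
#' @param img the preprocessed TCI matrix.
#' @param params an [rgb_params()].
#' @param factors a [normalization_factors()] result, or `NULL`.
#' @param weights an [objective_weights()].
#' @param sobel optional precomputed Sobel magnitude matrix.
#' @param p_form passed to [within_class_variance()].
#' @return list with `v_b`, `v_w`, `g_a`, `f_o`, class
#'   `objective_breakdown`.
#' @export
evaluate_candidate <- function(img, params, factors = NULL,
                               weights = objective_weights(),
                               sobel = NULL, p_form = "divide") {
  part <- segment(img, params)
  ref <- extract_reference_region(part)
  v_b <- between_class_variance(part, ref)
  v_w <- within_class_variance(img, ref, p_form = p_form)
  g_a <- average_gradient(img, ref, sobel)
  f_o <- if (is.null(factors)) NA_real_ else
    combined_objective(v_b, v_w, g_a, factors, weights)
  structure(list(v_b = v_b, v_w = v_w, g_a = g_a, f_o = f_o),
            class = "objective_breakdown")
}
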