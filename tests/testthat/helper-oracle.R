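# Independent brute-force references used by the unit and acceptance tests.
# These recompute everything from raw pixels at every step and share no code
# with the package's incremental implementations.

# Naive MST region-merging segmenter: edges built in construction order
# (row-major scan, right-edge before down-edge), sorted non-descending with
# ties broken by construction index, and every merge decision recomputed
# from the raw pixel multisets of the two regions.
oracle_segment <- function(img, k, alpha) {
  h <- nrow(img); w <- ncol(img)
  idx <- function(r, c) (c - 1L) * h + r
  a <- integer(0); b <- integer(0)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (c < w) { a <- c(a, idx(r, c)); b <- c(b, idx(r, c + 1L)) }
      if (r < h) { a <- c(a, idx(r, c)); b <- c(b, idx(r + 1L, c)) }
    }
  }
  wts <- abs(img[a] - img[b])
  ord <- order(wts, seq_along(wts)) # explicit stable tie-break
  labels <- seq_len(h * w)
  for (e in ord) {
    la <- labels[a[e]]; lb <- labels[b[e]]
    if (la == lb) next
    p1 <- img[labels == la]; p2 <- img[labels == lb]
    mu1 <- mean(p1); mu2 <- mean(p2)
    sd1 <- sqrt(mean((p1 - mu1)^2)); sd2 <- sqrt(mean((p2 - mu2)^2))
    tau1 <- (k / length(p1)) *
      (1 + (if (sd1 > 0) mu1 / sd1 else 0) / alpha)
    tau2 <- (k / length(p2)) *
      (1 + (if (sd2 > 0) mu2 / sd2 else 0) / alpha)
    if (abs(mu1 - mu2) <= min(sd1 + tau1, sd2 + tau2))
      labels[labels == lb] <- la
  }
  # compact by first appearance in column-major order
  first <- match(labels, unique(labels))
  matrix(first, h, w)
}

# Brute-force binary morphology by direct structuring-element scans.
bf_dilate <- function(mask, kernel) {
  h <- nrow(mask); w <- ncol(mask)
  kh <- (nrow(kernel) - 1L) / 2L; kw <- (ncol(kernel) - 1L) / 2L
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    hit <- FALSE
    for (dr in -kh:kh) for (dc in -kw:kw) {
      if (kernel[dr + kh + 1L, dc + kw + 1L] == 1 &&
          r + dr >= 1 && r + dr <= h && c + dc >= 1 && c + dc <= w &&
          mask[r + dr, c + dc] == 1) hit <- TRUE
    }
    out[r, c] <- as.integer(hit)
  }
  out
}

bf_erode <- function(mask, kernel) {
  h <- nrow(mask); w <- ncol(mask)
  kh <- (nrow(kernel) - 1L) / 2L; kw <- (ncol(kernel) - 1L) / 2L
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    all_in <- TRUE
    for (dr in -kh:kh) for (dc in -kw:kw) {
      if (kernel[dr + kh + 1L, dc + kw + 1L] == 1) {
        inside <- r + dr >= 1 && r + dr <= h && c + dc >= 1 && c + dc <= w
        if (!inside || mask[r + dr, c + dc] != 1) all_in <- FALSE
      }
    }
    out[r, c] <- as.integer(all_in)
  }
  out
}

# filled disk mask: pixels whose center lies within radius r0 of `center`
disk_mask <- function(h, w, center, r0) {
  dy <- matrix(seq_len(h) - center[1], h, w)
  dx <- matrix(rep(seq_len(w) - center[2], each = h), h, w)
  (dy^2 + dx^2 <= r0^2) + 0L
}

# reference-region object for a hand-constructed mask (bypasses segment())
make_ref <- function(mask, img, label = 1L) {
  structure(list(label = label, mask = mask,
                 stats = region_stats(img[mask == 1])),
            class = "reference_region")
}
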