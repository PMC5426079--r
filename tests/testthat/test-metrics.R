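test_that("volume fractions match their definitions", {
  truth <- disk_mask(41, 41, c(21, 21), 10)
  expect_equal(unname(volume_fractions(truth, truth)), c(100, 0, 0))

  # disjoint masks
  a <- matrix(0L, 20, 20); a[2:5, 2:5] <- 1L      # 16 px
  b <- matrix(0L, 20, 20); b[12:19, 12:19] <- 1L  # 64 px
  expect_equal(unname(volume_fractions(a, b)), c(0, 400, 100))

  # |A_m| = 100, overlap 80, |A_n| = 100
  am <- matrix(0L, 30, 30); am[1:10, 1:10] <- 1L
  an <- matrix(0L, 30, 30); an[1:10, 3:12] <- 1L
  expect_equal(unname(volume_fractions(am, an)), c(80, 20, 20))

  expect_error(volume_fractions(matrix(0L, 5, 5), a[1:5, 1:5]), "empty")
})

test_that("TPVF + FNVF is an exact identity and matches brute force", {
  set.seed(17)
  for (i in 1:100) {
    t <- matrix(rbinom(100, 1, runif(1, 0.2, 0.8)), 10, 10)
    if (!any(t == 1)) t[5, 5] <- 1L
    s <- matrix(rbinom(100, 1, runif(1, 0.2, 0.8)), 10, 10)
    vf <- volume_fractions(t, s)
    expect_identical(vf[["tpvf"]] + vf[["fnvf"]], 100)
    # brute-force set-intersection count
    ov <- 0
    for (q in 1:100) if (t[q] == 1 && s[q] == 1) ov <- ov + 1
    expect_equal(vf[["tpvf"]], ov / sum(t) * 100)
  }
})

test_that("region_center is the rounded centroid with foreground fallback", {
  px <- matrix(0L, 9, 9); px[3, 7] <- 1L
  expect_equal(unname(region_center(px)), c(3, 7))

  rect <- matrix(0L, 30, 30); rect[3:7, 11:21] <- 1L # rows 2-6, cols 10-20 0-based
  expect_equal(unname(region_center(rect)), c(5, 16)) # (4, 15) 0-based

  ring <- disk_mask(41, 41, c(21, 21), 15) - disk_mask(41, 41, c(21, 21), 8)
  expect_warning(ctr <- region_center(ring), "background")
  expect_equal(ring[ctr[1], ctr[2]], 1)
})

test_that("radial crossings recover simple geometry", {
  d <- disk_mask(61, 61, c(31, 31), 10)
  r <- radial_crossings(d, c(31, 31), 180)
  # rasterized disk extends up to half a pixel beyond its nominal radius
  expect_true(all(abs(r - 10) <= 0.5 + 1e-9))

  sq <- matrix(0L, 61, 61); sq[21:41, 21:41] <- 1L # half-width 10
  r4 <- radial_crossings(sq, c(31, 31), 8)
  expect_true(all(abs(r4[c(1, 3, 5, 7)] - 10) <= 0.55))       # axis rays
  expect_true(all(abs(r4[c(2, 4, 6, 8)] - 10 * sqrt(2)) <= 0.8)) # diagonals

  # plus shape, 4 rays -> the four arm lengths
  plus <- matrix(0L, 41, 41)
  plus[21, 9:35] <- 1L  # left arm 12, right arm 14
  plus[5:31, 21] <- 1L  # up arm 16, down arm 10
  r_arm <- radial_crossings(plus, c(21, 21), 4)
  expect_true(all(abs(r_arm - c(14, 10, 12, 16)) <= 0.5 + 1e-9))
})

test_that("averaged radial error behaves as a normalized contour distance", {
  d10 <- disk_mask(61, 61, c(31, 31), 10)
  d12 <- disk_mask(61, 61, c(31, 31), 12)
  d8 <- disk_mask(61, 61, c(31, 31), 8)
  expect_equal(averaged_radial_error(d10, d10), 0)
  # 2 px of radial error on a radius-10 disk, +/- discretization
  expect_lt(abs(averaged_radial_error(d10, d12) - 20), 2)
  expect_lt(abs(averaged_radial_error(d10, d8) - 20), 2)

  # translation invariance of all four metrics
  sh <- function(m, dy, dx) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  expect_equal(averaged_radial_error(sh(d10, 3, 5), sh(d12, 3, 5)),
               averaged_radial_error(d10, d12))
  expect_equal(volume_fractions(sh(d10, 3, 5), sh(d12, 3, 5)),
               volume_fractions(d10, d12))
})

test_that("metrics_report bundles the four criteria", {
  d10 <- disk_mask(61, 61, c(31, 31), 10)
  d12 <- disk_mask(61, 61, c(31, 31), 12)
  rep <- metrics_report(d10, d12)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$tpvf, 100)
  expect_equal(rep$tpvf + rep$fnvf, 100)
  expect_gt(rep$fpvf, 0)
  expect_output(print(rep), "ARE")
})
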