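test_that("build_graph emits the 4-connectivity edge set with |dI| weights", {
  expect_equal(nrow(build_graph(matrix(0, 2, 2))), 4)

  g3 <- build_graph(matrix(100, 3, 3))
  expect_equal(nrow(g3), 12)
  expect_true(all(g3$weight == 0))

  g <- build_graph(matrix(c(10, 20, 5), 1, 3))
  expect_setequal(g$weight, c(10, 15))

  # 8-connectivity adds the diagonals
  expect_equal(nrow(build_graph(matrix(0, 3, 3), connectivity = 8)), 20)
  expect_error(build_graph(matrix(0, 3, 3), connectivity = 6), "connectivity")
})

test_that("tau follows the threshold formula with the sigma=0 convention", {
  s <- region_stats(size = 100, sum = 100 * 120, sumsq = 100 * (10^2 + 120^2))
  expect_equal(tau(s, rgb_params(1000, 1)), 130)

  uniform <- region_stats(rep(80, 50))
  expect_equal(tau(uniform, rgb_params(500, 0.123)), 10)

  # alpha -> Inf approaches k/|C| monotonically from above
  taus <- vapply(c(0.5, 1, 2, 4, 8, 1e6), function(a) tau(s, rgb_params(1000, a)), 0)
  expect_true(all(diff(taus) < 0))
  expect_gt(taus[length(taus)], 1000 / 100 - 1e-6)
})

test_that("merge predicate compares Dif against MInt symmetrically", {
  p <- rgb_params(100, 4)
  s1 <- region_stats(size = 100, sum = 100 * 100, sumsq = 100 * (5^2 + 100^2))
  s2 <- region_stats(size = 100, sum = 100 * 200, sumsq = 100 * (5^2 + 200^2))
  # tau1 = 1 * (1 + 20/4) = 6, MInt = min(11, ...), Dif = 100 -> no merge
  expect_false(merge_predicate(s1, s2, p))
  expect_identical(merge_predicate(s1, s2, p), merge_predicate(s2, s1, p))

  expect_true(merge_predicate(s1, s1, rgb_params(1, 1000))) # Dif = 0
})

test_that("incremental merged stats equal recomputation from raw pixels", {
  set.seed(99)
  for (i in 1:20) {
    p1 <- runif(sample(1:40, 1), 0, 255)
    p2 <- runif(sample(1:40, 1), 0, 255)
    m <- merge_stats(region_stats(p1), region_stats(p2))
    ref <- region_stats(c(p1, p2))
    expect_equal(m$size, ref$size)
    expect_equal(m$mean, ref$mean, tolerance = 1e-9)
    expect_equal(m$stdev, ref$stdev, tolerance = 1e-9)
  }
})

test_that("segment handles the canonical instances", {
  expect_equal(nrow(segment(matrix(128, 8, 8), rgb_params(100, 1))$stats), 1)

  halves <- cbind(matrix(50, 8, 4), matrix(200, 8, 4))
  part <- segment(halves, rgb_params(100, 1))
  expect_equal(nrow(part$stats), 2)
  expect_equal(length(unique(as.vector(part$labels[, 1:4]))), 1)
  expect_equal(length(unique(as.vector(part$labels[, 5:8]))), 1)
  expect_setequal(part$stats$mean, c(50, 200))

  # piecewise-constant image: a maximal constant component is never split
  blocks <- rbind(cbind(matrix(10, 4, 4), matrix(240, 4, 4)),
                  cbind(matrix(120, 4, 4), matrix(10, 4, 4)))
  for (k in c(100, 1000, 4000)) {
    pt <- segment(blocks, rgb_params(k, 2))
    expect_equal(length(unique(as.vector(pt$labels[1:4, 1:4]))), 1)
    expect_equal(length(unique(as.vector(pt$labels[5:8, 5:8]))), 1)
  }
})

test_that("segment matches the brute-force oracle on seeded random images", {
  set.seed(123)
  for (i in 1:10) {
    h <- sample(4:10, 1); w <- sample(4:10, 1)
    img <- matrix(sample(0:255, h * w, TRUE), h, w)
    k <- runif(1, 100, 4000); alpha <- runif(1, 0.001, 4)
    expect_identical(segment(img, rgb_params(k, alpha))$labels,
                     oracle_segment(img, k, alpha),
                     label = sprintf("seeded image %d (k=%.1f, alpha=%.3f)",
                                     i, k, alpha))
  }
})

test_that("region count is non-increasing in k on a fixed noisy image", {
  set.seed(21)
  img <- matrix(pmin(pmax(round(128 + rnorm(256, 0, 40)), 0), 255), 16, 16)
  counts <- vapply(c(100, 500, 1000, 2000, 4000),
                   function(k) nrow(segment(img, rgb_params(k, 1))$stats), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("region_containing resolves pixels and bounds", {
  halves <- cbind(matrix(50, 8, 4), matrix(200, 8, 4))
  part <- segment(halves, rgb_params(100, 1))
  left <- region_containing(part, c(1, 1))
  expect_equal(part$stats$mean[left], 50)
  # centre pixel under the floor convention: (4,4) 0-based = row 5, col 5
  ctr <- region_containing(part, c(5, 5))
  expect_equal(part$stats$mean[ctr], 200)
  expect_error(region_containing(part, c(9, 1)), "outside")
})

test_that("partitions export as 16-bit label PGM plus stats CSV", {
  part <- segment(cbind(matrix(50, 8, 4), matrix(200, 8, 4)),
                  rgb_params(100, 1))
  lp <- tempfile(fileext = ".pgm"); sp <- tempfile(fileext = ".csv")
  export_partition(part, lp, sp)
  expect_identical(read_image(lp), part$labels)
  st <- read.csv(sp)
  expect_equal(st$size, part$stats$size)
  unlink(c(lp, sp))
})
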