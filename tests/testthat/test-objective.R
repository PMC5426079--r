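# two-region instance used throughout: left half 100, right half 150;
# k = 10 keeps the halves separate (singleton tau = 10 < Dif = 50)
two_region_img <- function() cbind(matrix(100, 10, 5), matrix(150, 10, 5))

test_that("reference region is the one owning the central pixel", {
  one <- segment(matrix(40, 8, 8), rgb_params(100, 1))
  expect_equal(extract_reference_region(one)$label, 1)

  part <- segment(two_region_img(), rgb_params(10, 1))
  ref <- extract_reference_region(part)
  # centre (5,5) 0-based = row 6, col 6 -> right half
  expect_equal(ref$stats$mean, 150)
  expect_equal(ref$stats$size, 50)
})

test_that("adjacent_regions finds exactly the 4-adjacent neighbours", {
  one <- segment(matrix(40, 8, 8), rgb_params(100, 1))
  expect_length(adjacent_regions(one, extract_reference_region(one)), 0)

  # three vertical stripes; middle stripe is the reference
  img <- cbind(matrix(0, 9, 3), matrix(120, 9, 3), matrix(250, 9, 3))
  part <- segment(img, rgb_params(10, 1))
  ref <- extract_reference_region(part)
  expect_equal(ref$stats$mean, 120)
  adj <- adjacent_regions(part, ref)
  expect_setequal(part$stats$mean[adj], c(0, 250))

  # concentric: ring around core -> ring only
  core <- matrix(200, 11, 11)
  core[4:8, 4:8] <- 50
  pc <- segment(core, rgb_params(10, 1))
  rc <- extract_reference_region(pc)
  expect_equal(rc$stats$mean, 50)
  expect_length(adjacent_regions(pc, rc), 1)
})

test_that("between-class variance matches the hand-computed instance", {
  part <- segment(two_region_img(), rgb_params(10, 1))
  ref <- extract_reference_region(part) # mean 150, neighbour mean 100
  # single adjacent region: P = 50/100, contrast 50 -> 0.5 * 2500 = 1250
  expect_equal(between_class_variance(part, ref), 1250)

  # doubling the contrast quadruples V_B
  img2 <- cbind(matrix(100, 10, 5), matrix(200, 10, 5))
  part2 <- segment(img2, rgb_params(10, 1))
  expect_equal(between_class_variance(part2, extract_reference_region(part2)),
               4 * 1250)

  # neighbours sharing the reference mean give V_B = 0 (constant image)
  one <- segment(matrix(90, 8, 8), rgb_params(100, 1))
  expect_equal(between_class_variance(one, extract_reference_region(one)), 0)
})

test_that("within-class variance follows the arctan-over-P form", {
  img <- matrix(128, 10, 10)
  mask <- matrix(0L, 10, 10); mask[5, 5:6] <- 1L
  img[5, 5] <- 90; img[5, 6] <- 110
  ref <- make_ref(mask, img)
  # variance 100 over 2 pixels, P = 0.02 -> atan(100)/0.02
  expect_equal(within_class_variance(img, ref, tci_size = 100),
               atan(100) / 0.02, tolerance = 1e-12)
  expect_equal(atan(100) / 0.02, 78.04, tolerance = 1e-4)

  # growing the region to the whole TCI rescales by 1/P
  expect_equal(within_class_variance(img, ref, tci_size = 2), atan(100))

  # uniform reference region -> 0 under both forms
  flat_ref <- make_ref(matrix(1L, 4, 4), matrix(7, 4, 4))
  expect_equal(within_class_variance(matrix(7, 4, 4), flat_ref), 0)
  expect_equal(within_class_variance(matrix(7, 4, 4), flat_ref,
                                     p_form = "multiply"), 0)
})

test_that("boundary_pixels returns the inner 4-boundary", {
  m1 <- matrix(0L, 7, 7); m1[4, 4] <- 1L
  expect_equal(boundary_pixels(make_ref(m1, matrix(0, 7, 7))),
               matrix(c(4L, 4L), 1, dimnames = list(NULL, c("row", "col"))))

  sq <- matrix(0L, 8, 8); sq[3:6, 3:6] <- 1L
  b <- boundary_pixels(make_ref(sq, matrix(0, 8, 8)))
  expect_equal(nrow(b), 12) # 16 cells minus 4 interior
  expect_true(all(sq[b] == 1))

  # full-image region: the border counts as outside
  full <- make_ref(matrix(1L, 5, 6), matrix(0, 5, 6))
  bf <- boundary_pixels(full)
  expect_equal(nrow(bf), 2 * 5 + 2 * 6 - 4)
})

test_that("average gradient is the Sobel energy along the boundary", {
  flat_ref <- make_ref(matrix(1L, 6, 6), matrix(55, 6, 6))
  expect_equal(average_gradient(matrix(55, 6, 6), flat_ref), 0)

  # ideal vertical 0/255 step; reference = the last dark column, whose
  # boundary is the full column sitting on the step: every pixel sees
  # gx = 4 * 255
  step <- cbind(matrix(0, 8, 4), matrix(255, 8, 4))
  colmask <- matrix(0L, 8, 8); colmask[, 4] <- 1L
  ref <- make_ref(colmask, step)
  expect_equal(average_gradient(step, ref), 1020)

  # linearity: scaling intensities scales G_A
  expect_equal(average_gradient(step * 0.4, ref), 0.4 * 1020)
})

test_that("normalization factors are swarm means with a zero guard", {
  f <- normalization_factors(data.frame(v_b = c(2, 4), v_w = c(4, 8),
                                        g_a = c(6, 10)))
  expect_equal(c(f$f_b, f$f_w, f$f_a), c(3, 6, 8))

  same <- normalization_factors(data.frame(v_b = 5, v_w = 7, g_a = 9))
  expect_equal(c(same$f_b, same$f_w, same$f_a), c(5, 7, 9))

  expect_warning(
    z <- normalization_factors(data.frame(v_b = c(0, 0), v_w = c(1, 3),
                                          g_a = c(0, 0))),
    "zero-mean")
  expect_equal(c(z$f_b, z$f_w, z$f_a), c(1, 2, 1))
})

test_that("combined objective is the weighted normalized sum", {
  unit <- normalization_factors(data.frame(v_b = 1, v_w = 1, g_a = 1))
  expect_equal(combined_objective(2, 1, 1, unit), 0.7)
  expect_equal(combined_objective(0, 0, 0, unit), 0)
  # (1,0,0) degenerates to the between-class-variance-only objective
  w100 <- objective_weights(1, 0, 0)
  for (v in c(0.3, 2, 117))
    expect_equal(combined_objective(v, runif(1), runif(1), unit, w100), v)
})

test_that("evaluate_candidate composes the terms deterministically", {
  const <- evaluate_candidate(matrix(99, 16, 16), rgb_params(100, 1))
  expect_equal(c(const$v_b, const$v_w, const$g_a), c(0, 0, 0))
  expect_true(is.na(const$f_o)) # pre-normalization pass leaves f_o unset

  b <- evaluate_candidate(two_region_img(), rgb_params(10, 1))
  expect_equal(b$v_b, 1250)
  expect_equal(b$v_w, 0) # both halves constant

  b2 <- evaluate_candidate(two_region_img(), rgb_params(10, 1))
  expect_identical(b, b2)

  # with factors, f_o matches the explicit combination
  unit <- normalization_factors(data.frame(v_b = 1, v_w = 1, g_a = 1))
  b3 <- evaluate_candidate(two_region_img(), rgb_params(10, 1), unit)
  expect_equal(b3$f_o, combined_objective(b3$v_b, b3$v_w, b3$g_a, unit))
})
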