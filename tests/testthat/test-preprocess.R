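test_that("crop_tci extracts the stated sub-rectangle", {
  img <- matrix(0, 100, 100)
  # shape is (y1 - y0) x (x1 - x0)
  expect_equal(dim(crop_tci(img, roi_rect(10, 10, 60, 50))), c(40, 50))

  full <- matrix(runif(25, 0, 255), 5, 5)
  expect_identical(crop_tci(full, roi_rect(0, 0, 5, 5)), full)

  ramp <- outer(0:4, 0:4, function(r, c) 10 * r + c)
  sub <- crop_tci(ramp, roi_rect(1, 1, 4, 4))
  expect_equal(dim(sub), c(3, 3))
  expect_equal(sub[1, 1], 11)
  expect_equal(sub[3, 3], 33)

  # corners in any diagonal order are normalized
  expect_identical(crop_tci(ramp, roi_rect(4, 4, 1, 1)), sub)
})

test_that("crop_tci rejects degenerate or out-of-bounds ROIs", {
  img <- matrix(0, 10, 10)
  expect_error(roi_rect(2, 2, 2, 5), "zero area")
  expect_error(crop_tci(img, roi_rect(5, 5, 12, 8)), "bounds")
})

test_that("bilateral filter preserves constants and edges, reduces noise", {
  cfg <- preprocess_config()
  flat <- matrix(128, 16, 16)
  expect_equal(bilateral_filter(flat, cfg), flat)

  step <- cbind(matrix(0, 16, 8), matrix(255, 16, 8))
  out <- bilateral_filter(step, cfg)
  # edge position unchanged: halves stay on their own side of 128; each
  # half stays essentially flat (up to one gray level of quantization)
  expect_true(all(out[, 1:8] < 128) && all(out[, 9:16] > 128))
  expect_lte(sd(as.vector(out[, 1:8])), 1)
  expect_lte(sd(as.vector(out[, 9:16])), 1)

  set.seed(42)
  noisy <- matrix(pmin(pmax(100 + rnorm(64 * 64, 0, 10), 0), 255), 64, 64)
  expect_lt(var(as.vector(bilateral_filter(noisy, cfg))),
            var(as.vector(noisy)))
})

test_that("histogram equalization is monotone and contrast-expanding", {
  flat <- matrix(77, 8, 8)
  expect_equal(equalize_histogram(flat), flat)

  two <- matrix(c(0, 0, 1, 1), 2, 2)
  eq <- equalize_histogram(two)
  expect_length(unique(as.vector(eq)), 2)
  expect_true(eq[1, 2] > eq[1, 1]) # order of the two levels preserved

  # induced lookup table is monotone non-decreasing for any input
  set.seed(7)
  img <- matrix(sample(90:110, 256, TRUE), 16, 16)
  lut <- moorgb:::equalization_lut(img)
  expect_true(all(diff(lut) >= 0))
  # low-contrast input expands towards the full range
  out <- equalize_histogram(img)
  expect_gt(diff(range(out)), diff(range(img)))
})

test_that("mean shift flattens noise but keeps strong steps", {
  cfg <- preprocess_config()
  flat <- matrix(60, 16, 16)
  expect_equal(pyramid_mean_shift(flat, cfg), flat)

  step <- cbind(matrix(50, 16, 8), matrix(200, 16, 8)) # gap > range radius
  out <- pyramid_mean_shift(step, cfg)
  expect_identical(out, step)

  set.seed(11)
  noisy <- matrix(pmin(pmax(round(100 + rnorm(64 * 64, 0, 10)), 0), 255),
                  64, 64)
  smoothed <- pyramid_mean_shift(noisy, cfg)
  expect_lt(sd(as.vector(smoothed)), sd(as.vector(noisy)))
  # piecewise flattening never invents new intensity levels
  expect_lte(length(unique(as.vector(smoothed))),
             length(unique(as.vector(noisy))))
})

test_that("preprocess_pipeline composes the stages in order", {
  flat <- matrix(90, 32, 32)
  expect_equal(preprocess_pipeline(flat, roi_rect(0, 0, 32, 32)),
               matrix(90, 32, 32))

  # disabled config reduces to the crop
  ramp <- matrix(rep(seq(0, 255, length.out = 20), each = 20), 20, 20)
  cfg_off <- preprocess_config(enabled = FALSE)
  expect_identical(preprocess_pipeline(ramp, roi_rect(2, 3, 18, 15), cfg_off),
                   crop_tci(ramp, roi_rect(2, 3, 18, 15)))

  # on a phantom, the lesion interior (eroded truth, excluding the blurred
  # rim that equalization stretches) comes out more homogeneous than raw
  ph <- render_phantom(phantom_spec(seed = 5))
  roi <- roi_rect(0, 0, 64, 64)
  tci <- preprocess_pipeline(ph$image, roi)
  inside <- moorgb:::binary_erode(ph$truth) == 1
  expect_lt(sd(tci[inside]), sd(ph$image[inside]))

  # stages also preserve shape and range end to end
  expect_equal(dim(tci), c(64, 64))
  expect_true(all(tci >= 0 & tci <= 255))
})
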