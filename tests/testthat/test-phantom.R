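test_that("high-field phantoms are deterministic, seed-sensitive, zero-background", {
  h1 <- make_high_field_subject("s1", 4, 64, "A", 7)
  h2 <- make_high_field_subject("s1", 4, 64, "A", 7)
  expect_identical(h1$slices, h2$slices)
  expect_equal(length(h1$slices), 4)
  expect_equal(dim(h1$slices[[1]]), c(64, 64))

  h3 <- make_high_field_subject("s1", 4, 64, "A", 8)
  expect_true(any(h1$slices[[1]] != h3$slices[[1]]))

  one <- make_high_field_subject("s1", 1, 32, "A", 7)
  # outside the head ellipse the background is exactly zero
  expect_true(any(one$slices[[1]] == 0))
  expect_true(all(one$slices[[1]] >= 0 & one$slices[[1]] <= 1))

  expect_error(make_high_field_subject("s1", 0, 64, "A", 7), "n_slices")
  expect_error(make_high_field_subject("s1", 4, 16, "A", 7), "size_px")
})

test_that("neutral degradation is the exact identity (except the field tag)", {
  h <- make_high_field_subject("s1", 3, 64, "B", 11)
  low <- degrade_to_low_field(h, degradation_params())
  expect_identical(low$slices, h$slices)
  expect_equal(low$field_strength, "low")
  expect_equal(low$vendor, "B")
})

test_that("pure additive noise gives the expected mean absolute deviation", {
  h <- make_high_field_subject("s1", 4, 64, "A", 7)
  low <- degrade_to_low_field(h, degradation_params(noise_sigma = 0.05, seed = 3))
  mad <- mean(abs(unlist(low$slices) - unlist(h$slices)))
  # E|N(0, sigma)| = sigma * sqrt(2/pi) ~ 0.0399 at sigma = 0.05
  expect_gt(mad, 0.03)
  expect_lt(mad, 0.06)
  expect_error(degradation_params(noise_sigma = -1), "noise_sigma")
  expect_error(degradation_params(blur_fwhm_px = -1), "blur_fwhm")
})

test_that("pure misalignment is recovered by brute-force shift search", {
  h <- make_high_field_subject("s1", 2, 64, "A", 7)
  low <- degrade_to_low_field(h, degradation_params(
    misalign = rigid_transform2d(3, -2, 0)))
  best <- c(NA, NA); bv <- Inf
  for (dx in -5:5) for (dy in -5:5) {
    w <- warp_rigid(h$slices[[1]], rigid_transform2d(dx, dy, 0))
    v <- mean((w - low$slices[[1]])^2)
    if (v < bv) { bv <- v; best <- c(dx, dy) }
  }
  expect_equal(best, c(3, -2))
})

test_that("repeat scans share deterministic components but not noise", {
  h <- make_high_field_subject("s1", 3, 64, "C", 5)
  p <- degradation_params(noise_sigma = 0.03, blur_fwhm_px = 1, bias_amplitude = 0.1,
                          seed = 9)
  low <- degrade_to_low_field(h, p)

  r1 <- make_repeat_scan(low, repeat_seed = 101)
  expect_equal(r1$repeat_index, 1L)
  expect_true(any(unlist(r1$slices) != unlist(low$slices)))
  expect_identical(make_repeat_scan(low, repeat_seed = 101)$slices, r1$slices)
  expect_error(make_repeat_scan(low, repeat_seed = 9), "independent")

  p0 <- degradation_params(noise_sigma = 0, blur_fwhm_px = 1, bias_amplitude = 0.1,
                           seed = 9)
  low0 <- degrade_to_low_field(h, p0)
  expect_identical(make_repeat_scan(low0, repeat_seed = 55)$slices, low0$slices)
})

test_that("averaging repeat scans converges at the 1/sqrt(k) rate", {
  h <- make_high_field_subject("s1", 1, 64, "A", 21)
  p <- degradation_params(noise_sigma = 0.05, blur_fwhm_px = 1, seed = 2)
  p0 <- degradation_params(noise_sigma = 0, blur_fwhm_px = 1, seed = 2)
  v <- degrade_to_low_field(h, p0)$slices[[1]]
  # magnitude reconstruction: repeats fluctuate around the folded-normal mean
  sigma <- 0.05 * diff(range(unlist(h$slices)))
  target <- sigma * sqrt(2 / pi) * exp(-v^2 / (2 * sigma^2)) +
    v * (1 - 2 * stats::pnorm(-v / sigma))
  low <- degrade_to_low_field(h, p)
  reps <- lapply(1:16, function(i) make_repeat_scan(low, repeat_seed = 1000 + i)$slices[[1]])
  mad_k <- function(k) mean(abs(Reduce(`+`, reps[1:k]) / k - target))
  m1 <- mad_k(1); m4 <- mad_k(4); m16 <- mad_k(16)
  expect_gt(m1, m4)
  expect_gt(m4, m16)
  # ~1/sqrt(k): 16 repeats should cut the deviation by ~4 (loosely)
  expect_lt(m16, m1 / 2.5)
})

test_that("vendor gain rescales intensities without reordering tissue means", {
  h <- make_high_field_subject("s1", 1, 64, "A", 3)
  img <- h$slices[[1]]
  tiers <- cut(img, breaks = c(-Inf, 0.01, 0.4, 0.7, Inf))
  lowg <- degrade_to_low_field(h, degradation_params(vendor_gain = 1.4))
  means_orig <- tapply(img, tiers, mean)
  means_gain <- tapply(lowg$slices[[1]], tiers, mean)
  expect_equal(order(means_orig), order(means_gain))
  expect_equal(max(lowg$slices[[1]]), 1.4 * max(img), tolerance = 1e-12)
})

test_that("cohorts respect counts, same-vendor pairing and determinism", {
  defs <- degradation_params(noise_sigma = 0.03, blur_fwhm_px = 1.5,
                             bias_amplitude = 0.1, contrast_scale = 0.85)
  co <- make_cohort(c(A = 2, B = 1, C = 1), defs, seed = 3,
                    n_slices = 2, size_px = 64)
  expect_length(co, 4)
  expect_equal(sapply(co, function(s) s$high$vendor), c("A", "A", "B", "C"))
  for (s in co) {
    expect_equal(s$high$vendor, s$low$vendor)
    expect_equal(length(s$high$slices), length(s$low$slices))
  }
  co2 <- make_cohort(c(A = 2, B = 1, C = 1), defs, seed = 3,
                     n_slices = 2, size_px = 64)
  expect_identical(lapply(co, function(s) s$low$slices),
                   lapply(co2, function(s) s$low$slices))
  expect_error(make_cohort(c(), defs, 1), "non-empty")
})
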