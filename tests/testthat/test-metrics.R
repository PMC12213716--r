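test_that("quantization rounds half away from zero and clips", {
  expect_equal(quantize(matrix(0, 2, 2)), matrix(0L, 2, 2))
  expect_equal(quantize(matrix(0.5, 1, 1))[1, 1], 128L)
  expect_equal(quantize(matrix(1.2, 1, 1))[1, 1], 255L)
  expect_equal(quantize(matrix(-0.3, 1, 1))[1, 1], 0L)
  expect_error(quantize(matrix(NaN, 1, 1)), "finite")
})

test_that("PSNR matches its closed form in both variants", {
  r <- matrix(0L, 10, 10)
  pair1 <- quantized_pair(r, r + 1L)  # MSE exactly 1
  expect_equal(psnr(pair1, "standard"), 10 * log10(255^2), tolerance = 1e-3)
  expect_equal(psnr(pair1, "standard"), 48.1308, tolerance = 1e-3)
  # the printed-formula variant coincides with standard iff MSE = 1
  expect_equal(psnr(pair1, "as_printed"), 48.1308, tolerance = 1e-3)
  pair4 <- quantized_pair(r, r + 2L)  # MSE = 4
  expect_equal(psnr(pair4, "standard"), 10 * log10(255^2 / 4))
  expect_equal(psnr(pair4, "as_printed"), 20 * log10(255 / 4))
  expect_false(isTRUE(all.equal(psnr(pair4, "standard"), psnr(pair4, "as_printed"))))
  expect_identical(psnr(quantized_pair(r, r)), Inf)
})

test_that("PSNR strictly decreases as noise variance grows", {
  ref <- make_high_field_subject("p", 1, 64, "A", 3)$slices[[1]]
  set.seed(5)
  vals <- sapply(c(0.01, 0.02, 0.04, 0.08, 0.16), function(s)
    psnr(quantized_pair(ref, pmin(pmax(ref + matrix(rnorm(length(ref), 0, s),
                                                    nrow(ref)), 0), 1))))
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM is 1 for identical and degenerate-constant images", {
  img <- seeded_image(1, 32)
  expect_equal(ssim(quantized_pair(img, img)), 1)
  cst <- matrix(128L, 32, 32)
  expect_equal(ssim(quantized_pair(cst, cst)), 1)
  expect_error(ssim(quantized_pair(img, img), window = 10), "odd")
  expect_error(ssim(quantized_pair(img, img), window = 41), "larger")
})

test_that("SSIM equals the naive sliding-window oracle", {
  for (seed in 1:3) {
    p <- seeded_pair(seed, 32)
    qp <- quantized_pair(p$ref, p$cand)
    expect_equal(ssim(qp), naive_ssim(qp$reference, qp$candidate),
                 tolerance = 1e-7)
  }
  # correlated pair (more realistic structure)
  ref <- make_high_field_subject("s", 1, 32, "A", 2)$slices[[1]]
  set.seed(7)
  cand <- pmin(pmax(ref + matrix(rnorm(1024, 0, 0.05), 32), 0), 1)
  qp <- quantized_pair(ref, cand)
  expect_equal(ssim(qp), naive_ssim(qp$reference, qp$candidate), tolerance = 1e-7)
  # symmetry at unit exponents
  expect_equal(ssim(qp), ssim(quantized_pair(cand, ref)), tolerance = 1e-12)
})

test_that("perceptual distance is zero at identity, symmetric, noise-monotone", {
  ref <- make_high_field_subject("pc", 1, 64, "B", 5)$slices[[1]]
  expect_equal(perceptual_distance(quantized_pair(ref, ref)), 0)
  set.seed(9)
  light <- pmin(pmax(ref + matrix(rnorm(4096, 0, 0.02), 64), 0), 1)
  heavy <- pmin(pmax(ref + matrix(rnorm(4096, 0, 0.2), 64), 0), 1)
  dl <- perceptual_distance(quantized_pair(ref, light))
  dh <- perceptual_distance(quantized_pair(ref, heavy))
  expect_gt(dh, dl)
  expect_equal(perceptual_distance(quantized_pair(ref, heavy)),
               perceptual_distance(quantized_pair(heavy, ref)), tolerance = 1e-9)
})

test_that("IDP reproduces the hand-worked 2x2 case exactly", {
  qp <- quantized_pair(matrix(100L, 2, 2), matrix(c(100L, 100L, 90L, 50L), 2, 2))
  expect_equal(idp(qp, 0)$idp, 0.5)
  expect_equal(idp(qp, 0.10)$idp, 0.25)  # the exactly-10% pixel fails strict >
  expect_equal(idp(qp, 0.50)$idp, 0.0)
  expect_equal(idp(qp, 0)$n_qualifying, 2L)
  expect_equal(idp(qp, 0)$n_pixels, 4L)
})

test_that("IDP zero policies behave as documented", {
  qp <- quantized_pair(matrix(c(0L, 0L, 100L, 100L), 2, 2),
                       matrix(c(0L, 50L, 100L, 120L), 2, 2))
  r <- idp(qp, 0.5, "flag_nonzero")
  expect_equal(r$n_qualifying, 1L)  # only the hallucinated background pixel
  expect_equal(r$n_pixels, 4L)
  rm <- idp(qp, 0.5, "mask")
  expect_equal(rm$n_pixels, 2L)
  expect_equal(rm$n_qualifying, 0L)
  ident <- quantized_pair(matrix(0L, 2, 2), matrix(0L, 2, 2))
  expect_equal(idp(ident, 0)$idp, 0)
  expect_error(idp(qp, -0.1), "psi")
})

test_that("IDP matches the naive per-pixel oracle on seeded pairs", {
  for (seed in 1:5) {
    p <- seeded_pair(seed + 50, 32)
    qp <- quantized_pair(p$ref, p$cand)
    for (psi in c(0, 0.1, 0.25, 0.5))
      expect_equal(idp(qp, psi)$idp, naive_idp(qp$reference, qp$candidate, psi))
  }
})

test_that("the IDP sweep uses the six default thresholds and is monotone", {
  expect_equal(default_psi_sweep(), c(0, 0.10, 0.20, 0.25, 0.50, 0.75))
  img <- seeded_image(3, 32)
  expect_equal(sapply(idp_sweep(quantized_pair(img, img)), `[[`, "idp"),
               rep(0, 6))
  for (seed in 1:10) {
    p <- seeded_pair(seed + 200, 24)
    vals <- sapply(idp_sweep(quantized_pair(p$ref, p$cand)), `[[`, "idp")
    expect_true(all(diff(vals) <= 0))
  }
  expect_error(idp_sweep(quantized_pair(img, img), c(0.5, 0.1)), "ascending")
})

test_that("IDP is invariant under simultaneous pixel permutation", {
  p <- seeded_pair(77, 16)
  qp <- quantized_pair(p$ref, p$cand)
  set.seed(8)
  perm <- sample(256)
  qp2 <- quantized_pair(matrix(qp$reference[perm], 16) / 255,
                        matrix(qp$candidate[perm], 16) / 255)
  for (psi in c(0, 0.2, 0.5))
    expect_equal(idp(qp, psi)$idp, idp(qp2, psi)$idp)
})

test_that("difference overlay agrees with IDP at psi = 0 and is symmetric", {
  p <- seeded_pair(31, 16)
  ov <- difference_overlay(p$ref, p$cand)
  expect_equal(ov$count, idp(quantized_pair(p$ref, p$cand), 0)$n_qualifying)
  ov2 <- difference_overlay(p$cand, p$ref)
  expect_identical(ov$overlay, ov2$overlay)
  same <- difference_overlay(p$ref, p$ref)
  expect_equal(same$count, 0)
  expect_false(any(same$overlay))
})
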