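# Full-reference image quality metrics. All metrics operate on 8-bit
# quantized pairs: the IDP definition counts gray-level differences and the
# PSNR peak is 255, so quantization is part of the metric layer, not the
# phantom layer (phantoms are float in [0, 1]).

#' Quantize a float image to 8-bit gray levels
#'
#' `round(255 * clip(img, 0, 1))` with round-half-away-from-zero (so 0.5 maps
#' to 128, not the IEC banker's rounding of base `round`).
#'
#' @param img Numeric matrix with finite values (nominally in `[0, 1]`).
#' @return Integer matrix in `[0, 255]`.
#' @export
quantize <- function(img) {
  if (any(is.na(img)) || any(!is.finite(img))) stopf("quantize: non-finite values")
  v <- pmin(pmax(img, 0), 1)
  q <- floor(255 * v + 0.5)
  storage.mode(q) <- "integer"
  q
}

#' Bundle two quantized images for metric computation
#'
#' @param reference,candidate Numeric matrices in `[0, 1]` (quantized here) or
#'   integer matrices already in `[0, 255]`.
#' @return A list of class `quantized_pair` with integer `reference`,
#'   `candidate`, and `max_f = 255`.
#' @export
quantized_pair <- function(reference, candidate) {
  as_q <- function(m) if (is.integer(m)) m else quantize(m)
  r <- as_q(reference); c <- as_q(candidate)
  if (!identical(dim(r), dim(c))) stopf("reference and candidate dimensions differ")
  if (any(r < 0 | r > 255) || any(c < 0 | c > 255))
    stopf("quantized values must lie in [0, 255]")
  structure(list(reference = r, candidate = c, max_f = 255L),
            class = "quantized_pair")
}

#' Peak signal-to-noise ratio
#'
#' Two variants are provided because the field's canonical definition and a
#' common shorthand of it disagree: `standard` is
#' `10 * log10(max_f^2 / MSE)`; `as_printed` is `20 * log10(max_f / MSE)`,
#' i.e. the shorthand applied literally (the two coincide only at MSE = 1).
#' Identical images return `Inf`.
#'
#' @param pair A [quantized_pair()].
#' @param variant `"standard"` or `"as_printed"`.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(pair, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  mse <- mean((as.numeric(pair$reference) - as.numeric(pair$candidate))^2)
  if (mse == 0) return(Inf)
  switch(variant,
         standard = 10 * log10(pair$max_f^2 / mse),
         as_printed = 20 * log10(pair$max_f / mse))
}

# 1-D Gaussian window weights, normalized to sum 1
gaussian_window <- function(n, sigma) {
  h <- (n - 1) / 2
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w / sum(w)
}

# valid-mode separable windowed mean: out[i,j] = sum_w g wt over the window
window_means <- function(img, w) {
  n <- length(w)
  Wr <- matrix(0, nrow(img) - n + 1, nrow(img))
  for (i in seq_len(nrow(Wr))) Wr[i, i:(i + n - 1)] <- w
  Wc <- matrix(0, ncol(img) - n + 1, ncol(img))
  for (i in seq_len(nrow(Wc))) Wc[i, i:(i + n - 1)] <- w
  Wr %*% img %*% t(Wc)
}

#' Structural similarity index
#'
#' Mean over local Gaussian-windowed luminance, contrast and structure
#' similarity products,
#' `SSIM = mean( l^alpha * c^beta * s^gamma )`, with the standard stabilizing
#' constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2` at dynamic
#' range `L = 255`. Defaults (11x11 Gaussian window, sigma 1.5, unit
#' exponents) are the canonical reference values; with unit exponents the
#' measure is symmetric in its arguments. Windows are valid-mode (borders
#' without a full window are skipped).
#'
#' @param pair A [quantized_pair()].
#' @param alpha,beta,gamma Component exponents.
#' @param window Odd window size, at most the smaller image dimension.
#' @param window_sigma Gaussian window SD in pixels.
#' @return SSIM value (1 for identical images).
#' @export
ssim <- function(pair, alpha = 1, beta = 1, gamma = 1, window = 11L,
                 window_sigma = 1.5) {
  if (window %% 2 == 0) stopf("window must be odd")
  if (window > min(dim(pair$reference))) stopf("window larger than image")
  x <- as.numeric(pair$reference); dim(x) <- dim(pair$reference)
  y <- as.numeric(pair$candidate); dim(y) <- dim(pair$candidate)
  L <- pair$max_f
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2; C3 <- C2 / 2
  w <- gaussian_window(window, window_sigma)
  mx <- window_means(x, w); my <- window_means(y, w)
  sx2 <- pmax(window_means(x^2, w) - mx^2, 0)
  sy2 <- pmax(window_means(y^2, w) - my^2, 0)
  sxy <- window_means(x * y, w) - mx * my
  sx <- sqrt(sx2); sy <- sqrt(sy2)
  l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
  cc <- (2 * sx * sy + C2) / (sx2 + sy2 + C2)
  ss <- (sxy + C3) / (sx * sy + C3)
  mean(l^alpha * cc^beta * ss^gamma)
}

#' Perceptual feature distance
#'
#' Distance between deep-feature embeddings of the two images: both are run
#' through a fixed-seed convolutional feature extractor, each layer's feature
#' map is unit-normalized along channels at every spatial position, and the
#' mean squared difference is averaged across layers. Zero for identical
#' inputs, symmetric, and larger for perceptually more dissimilar images.
#' The backbone is deterministic and untrained, so absolute values are NOT
#' comparable to published LPIPS numbers; only orderings are meaningful.
#'
#' @param pair A [quantized_pair()].
#' @param backbone A backbone from `build_perceptual_backbone()`; a shared
#'   default is used when omitted.
#' @return Non-negative distance.
#' @export
perceptual_distance <- function(pair, backbone = default_backbone()) {
  xa <- as.numeric(pair$reference) / 255; dim(xa) <- dim(pair$reference)
  xb <- as.numeric(pair$candidate) / 255; dim(xb) <- dim(pair$candidate)
  fa <- backbone_features(backbone, xa)$features
  fb <- backbone_features(backbone, xb)$features
  unit_norm <- function(f) {
    nrm <- sqrt(apply(f^2, c(1, 2), sum)) + 1e-10
    sweep(f, c(1, 2), nrm, "/")
  }
  d <- 0
  for (l in seq_along(fa)) d <- d + mean((unit_norm(fa[[l]]) - unit_norm(fb[[l]]))^2)
  d / length(fa)
}

.fieldbridge_env <- new.env(parent = emptyenv())

default_backbone <- function() {
  if (is.null(.fieldbridge_env$backbone))
    .fieldbridge_env$backbone <- build_perceptual_backbone()
  .fieldbridge_env$backbone
}

#' Intensity Differences in Pixels (IDP)
#'
#' Fraction of pixels whose relative intensity difference from the reference
#' strictly exceeds the threshold `psi`:
#' `Q(i,j) = 1 if |ref(i,j) - cand(i,j)| / ref(i,j) > psi`, and
#' `IDP = sum(Q) / N` over all `N` pixels. The ratio is undefined where the
#' reference is 0; `zero_policy` controls those pixels:
#' \describe{
#'   \item{`flag_nonzero`}{(default) reference 0 and candidate 0 contribute
#'     `Q = 0`; reference 0 and candidate nonzero contribute `Q = 1` at every
#'     threshold (hallucinated signal on empty background is always counted).}
#'   \item{`mask`}{reference-zero pixels are excluded from both the count and
#'     the normalizer `N`.}
#' }
#' At `psi = 0` the metric equals the fraction of pixels with at least one
#' gray level of difference after 8-bit quantization.
#'
#' @param pair A [quantized_pair()].
#' @param psi Relative-difference threshold (fraction, >= 0).
#' @param zero_policy `"flag_nonzero"` or `"mask"`.
#' @return A list of class `idp_result`: `psi`, `idp` (fraction),
#'   `n_pixels`, `n_qualifying`.
#' @export
idp <- function(pair, psi = 0, zero_policy = c("flag_nonzero", "mask")) {
  zero_policy <- match.arg(zero_policy)
  if (!is.numeric(psi) || psi < 0) stopf("psi must be >= 0")
  r <- as.numeric(pair$reference)
  c <- as.numeric(pair$candidate)
  zero_ref <- r == 0
  if (zero_policy == "mask") {
    keep <- !zero_ref
    q <- abs(r[keep] - c[keep]) / r[keep] > psi
    n <- sum(keep)
  } else {
    q <- logical(length(r))
    nz <- !zero_ref
    q[nz] <- abs(r[nz] - c[nz]) / r[nz] > psi
    q[zero_ref] <- c[zero_ref] != 0
    n <- length(r)
  }
  structure(list(psi = psi, idp = sum(q) / n, n_pixels = n,
                 n_qualifying = sum(q)),
            class = "idp_result")
}

#' IDP threshold sweep
#'
#' Computes [idp()] at each threshold of an ascending sweep; the default is
#' the six-threshold sweep psi = 0, 10, 20, 25, 50, 75 percent. Results are
#' non-increasing in psi (the qualifying pixel sets are nested).
#'
#' @param pair A [quantized_pair()].
#' @param thresholds Ascending numeric thresholds (fractions).
#' @param zero_policy Passed to [idp()].
#' @return List of `idp_result`, one per threshold.
#' @export
idp_sweep <- function(pair, thresholds = default_psi_sweep(),
                      zero_policy = c("flag_nonzero", "mask")) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stopf("thresholds must be sorted strictly ascending")
  lapply(thresholds, function(p) idp(pair, p, zero_policy))
}

#' The default psi sweep
#'
#' @return `c(0, 0.10, 0.20, 0.25, 0.50, 0.75)`.
#' @export
default_psi_sweep <- function() c(0, 0.10, 0.20, 0.25, 0.50, 0.75)
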