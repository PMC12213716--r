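# Classical resampling baselines. Both methods are separable: a 1-D weight
# matrix is built per axis from the kernel and applied as out = Wr %*% img %*% t(Wc).
# Coordinate convention: pixel centres at integer coordinates, output grid
# aligned by centre (the half-pixel offset convention), so scale = 1 is the
# exact identity. Borders use edge replication and per-position weight
# renormalization so constants are reproduced exactly.

# Keys' cubic convolution kernel with free parameter a (Catmull-Rom: a = -0.5).
cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

# Lanczos kernel: sinc(x) * sinc(x/a) on |x| < a.
lanczos_kernel <- function(x, a) {
  w <- numeric(length(x))
  nz <- abs(x) < a & x != 0
  px <- pi * x[nz]
  w[nz] <- a * sin(px) * sin(px / a) / (px^2)
  w[x == 0] <- 1
  w
}

# 1-D resampling matrix (n_out x n_in) for a kernel with the given support
# (taps run floor(x) - support + 1 ... floor(x) + support).
resample_matrix <- function(n_in, n_out, kernel, support) {
  W <- matrix(0, n_out, n_in)
  scale <- n_out / n_in
  for (i in seq_len(n_out)) {
    x <- (i - 0.5) / scale + 0.5          # source coordinate, 1-based centres
    j0 <- floor(x)
    taps <- (j0 - support + 1):(j0 + support)
    w <- kernel(x - taps)
    taps <- pmin(pmax(taps, 1L), n_in)    # edge replication
    w <- w / sum(w)                       # partition of unity at every position
    for (t in seq_along(taps)) W[i, taps[t]] <- W[i, taps[t]] + w[t]
  }
  W
}

resample_separable <- function(img, scale, kernel, support) {
  n_out_r <- round(scale * nrow(img))
  n_out_c <- round(scale * ncol(img))
  Wr <- resample_matrix(nrow(img), n_out_r, kernel, support)
  Wc <- resample_matrix(ncol(img), n_out_c, kernel, support)
  Wr %*% img %*% t(Wc)
}

#' Bicubic upsampling
#'
#' Resamples a 2-D grid with cubic convolution: each output pixel is a
#' weighted sum over the surrounding 4x4 source neighbourhood. The kernel is
#' Keys' cubic convolution with `a = -0.5` (Catmull-Rom), the interpolating
#' member of the family, so linear ramps are reproduced exactly.
#'
#' @param img Numeric matrix, at least 4x4.
#' @param scale Positive scale factor; output dimensions are
#'   `round(scale * dim(img))`.
#' @return Numeric matrix.
#' @export
bicubic_upsample <- function(img, scale) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stopf("scale must be a positive scalar")
  if (nrow(img) < 4 || ncol(img) < 4) stopf("bicubic needs at least a 4x4 image")
  if (scale == 1) return(img)
  resample_separable(img, scale, cubic_kernel, 2L)
}

#' Lanczos upsampling
#'
#' Separable Lanczos-windowed-sinc resampling with window size `a`; the tap
#' window at source coordinate x runs `floor(x) - a + 1 ... floor(x) + a`.
#'
#' @param img Numeric matrix, at least `2a x 2a`.
#' @param scale Positive scale factor.
#' @param a Positive integer window size (default 3).
#' @return Numeric matrix of dimensions `round(scale * dim(img))`.
#' @export
lanczos_upsample <- function(img, scale, a = 3L) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stopf("scale must be a positive scalar")
  if (a < 1) stopf("Lanczos window size a must be >= 1")
  a <- as.integer(a)
  if (nrow(img) < 2 * a || ncol(img) < 2 * a)
    stopf("Lanczos-%d needs at least a %dx%d image", a, 2 * a, 2 * a)
  if (scale == 1) return(img)
  resample_separable(img, scale, function(x) lanczos_kernel(x, a), a)
}

#' Nearest-neighbour upsampling
#'
#' Pixel replication by an integer factor; the crudest upsampler, used as the
#' reference point the learned methods must beat.
#'
#' @param img Numeric matrix.
#' @param factor Positive integer replication factor.
#' @return Numeric matrix of `factor * dim(img)`.
#' @export
nearest_upsample <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stopf("factor must be a positive integer")
  img[rep(seq_len(nrow(img)), each = factor), rep(seq_len(ncol(img)), each = factor)]
}

#' Block-mean downsampling
#'
#' Averages non-overlapping `factor x factor` blocks; a simple anti-aliased
#' decimation used to emulate the coarser low-field acquisition matrix.
#'
#' @param img Numeric matrix with dimensions divisible by `factor`.
#' @param factor Positive integer.
#' @return Numeric matrix of `dim(img) / factor`.
#' @export
downsample_block <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stopf("factor must be a positive integer")
  if (factor == 1) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (nr %% factor != 0 || nc %% factor != 0)
    stopf("image dimensions (%d x %d) must be divisible by %d", nr, nc, factor)
  A <- matrix(0, nr / factor, nr)
  for (i in seq_len(nr / factor)) A[i, ((i - 1) * factor + 1):(i * factor)] <- 1 / factor
  B <- matrix(0, nc / factor, nc)
  for (i in seq_len(nc / factor)) B[i, ((i - 1) * factor + 1):(i * factor)] <- 1 / factor
  A %*% img %*% t(B)
}

# Apply an upsampler slice-wise to a stack, preserving tags.
upsample_stack <- function(stack, scale, method = c("nearest", "bicubic", "lanczos"),
                           lanczos_a = 3L) {
  method <- match.arg(method)
  f <- switch(method,
              nearest = function(s) nearest_upsample(s, scale),
              bicubic = function(s) bicubic_upsample(s, scale),
              lanczos = function(s) lanczos_upsample(s, scale, lanczos_a))
  out <- lapply(stack$slices, function(s) pmax(f(s), 0))
  slice_stack(out, stack$subject_id, stack$pixel_spacing_mm / scale,
              stack$field_strength, stack$vendor, stack$repeat_index)
}
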