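# Independent brute-force oracles used to validate the vectorized
# implementations. These are deliberately naive (double loops, direct
# formulas) and share no code with the package internals.

seeded_image <- function(seed, nr, nc = nr) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}

seeded_pair <- function(seed, n) {
  set.seed(seed)
  list(ref = matrix(runif(n * n), n, n),
       cand = matrix(runif(n * n), n, n))
}

cubic_w <- function(x, a = -0.5) {
  ax <- abs(x)
  if (ax <= 1) (a + 2) * ax^3 - (a + 3) * ax^2 + 1
  else if (ax < 2) a * ax^3 - 5 * a * ax^2 + 8 * a * ax - 4 * a
  else 0
}

lanczos_w <- function(x, a) {
  if (x == 0) return(1)
  if (abs(x) >= a) return(0)
  a * sin(pi * x) * sin(pi * x / a) / (pi * x)^2
}

# direct 2-D windowed-sum resampler: product kernel over the full
# neighborhood, weights normalized over the window, indices edge-clamped
naive_resample <- function(img, scale, wfun, support) {
  nr_out <- round(scale * nrow(img)); nc_out <- round(scale * ncol(img))
  out <- matrix(0, nr_out, nc_out)
  for (i in seq_len(nr_out)) {
    y <- (i - 0.5) / scale + 0.5
    for (j in seq_len(nc_out)) {
      x <- (j - 0.5) / scale + 0.5
      acc <- 0; wsum <- 0
      for (dy in (floor(y) - support + 1):(floor(y) + support)) {
        for (dx in (floor(x) - support + 1):(floor(x) + support)) {
          w <- wfun(y - dy) * wfun(x - dx)
          ri <- min(max(dy, 1), nrow(img))
          ci <- min(max(dx, 1), ncol(img))
          acc <- acc + w * img[ri, ci]
          wsum <- wsum + w
        }
      }
      out[i, j] <- acc / wsum
    }
  }
  out
}

naive_bicubic <- function(img, scale) naive_resample(img, scale, cubic_w, 2)
naive_lanczos <- function(img, scale, a = 3)
  naive_resample(img, scale, function(x) lanczos_w(x, a), a)

# sliding-window SSIM with Gaussian weights, one window at a time
naive_ssim <- function(qr, qc, window = 11, sigma = 1.5) {
  h <- (window - 1) / 2
  g1 <- exp(-((-h:h)^2) / (2 * sigma^2)); g1 <- g1 / sum(g1)
  G <- outer(g1, g1)
  L <- 255
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2; C3 <- C2 / 2
  x <- matrix(as.numeric(qr), nrow(qr)); y <- matrix(as.numeric(qc), nrow(qc))
  vals <- c()
  for (i in seq_len(nrow(x) - window + 1)) {
    for (j in seq_len(ncol(x) - window + 1)) {
      wx <- x[i:(i + window - 1), j:(j + window - 1)]
      wy <- y[i:(i + window - 1), j:(j + window - 1)]
      mx <- sum(G * wx); my <- sum(G * wy)
      vx <- max(sum(G * wx^2) - mx^2, 0); vy <- max(sum(G * wy^2) - my^2, 0)
      cxy <- sum(G * wx * wy) - mx * my
      l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
      cc <- (2 * sqrt(vx) * sqrt(vy) + C2) / (vx + vy + C2)
      ss <- (cxy + C3) / (sqrt(vx) * sqrt(vy) + C3)
      vals <- c(vals, l * cc * ss)
    }
  }
  mean(vals)
}

# direct per-pixel IDP (default zero policy)
naive_idp <- function(qr, qc, psi) {
  nq <- 0
  for (i in seq_len(nrow(qr))) for (j in seq_len(ncol(qr))) {
    r <- qr[i, j]; c <- qc[i, j]
    if (r == 0) {
      if (c != 0) nq <- nq + 1
    } else if (abs(r - c) / r > psi) nq <- nq + 1
  }
  nq / length(qr)
}

# quick low-field pair for learned-SR tests: blur + mild noise degradation,
# block-downsampled inputs against full-resolution targets
make_sr_dataset <- function(seed, n_subjects, size = 32, slices = 4,
                            noise = 0.02) {
  pairs <- list(); stacks <- list()
  for (i in seq_len(n_subjects)) {
    h <- make_high_field_subject(sprintf("D%03d", i), slices, size, "A",
                                 seed = derive_seed(seed, i))
    p <- degradation_params(noise_sigma = noise, blur_fwhm_px = 1.2,
                            contrast_scale = 0.9,
                            seed = derive_seed(seed, "deg", i))
    l <- degrade_to_low_field(h, p)
    for (k in seq_len(slices))
      pairs[[length(pairs) + 1]] <- list(low = downsample_block(l$slices[[k]], 2),
                                         high = h$slices[[k]])
    stacks[[i]] <- list(high = h, low = l)
  }
  list(pairs = pairs, stacks = stacks)
}
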