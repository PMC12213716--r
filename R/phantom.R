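#' Slice stack container
#'
#' One subject's image as an ordered list of 2-D intensity slices plus
#' acquisition tags. Intensities are arbitrary non-negative floats; phantoms
#' are generated in `[0, 1]` and 8-bit quantization happens inside the metrics
#' layer, not here.
#'
#' @param slices List of numeric matrices, all the same dimensions.
#' @param subject_id Opaque subject identifier string.
#' @param pixel_spacing_mm Positive length-2 numeric (row, column spacing).
#' @param field_strength `"high"` (3T-like) or `"low"` (1.5T-like).
#' @param vendor Vendor label, one of `"A"`, `"B"`, `"C"` (emulating the three
#'   scanner manufacturers in a same-vendor paired design).
#' @param repeat_index Non-negative integer; 0 = first scan of this subject at
#'   this field strength, 1+ = same-session repeat acquisitions.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, subject_id, pixel_spacing_mm = c(1, 1),
                        field_strength = c("high", "low"),
                        vendor = c("A", "B", "C"), repeat_index = 0L) {
  field_strength <- match.arg(field_strength)
  vendor <- match.arg(vendor)
  if (!is.list(slices) || length(slices) < 1) stopf("slices must be a non-empty list")
  d <- dim(slices[[1]])
  for (s in slices) {
    if (!is.matrix(s) || !identical(dim(s), d))
      stopf("all slices must be matrices with identical dimensions")
    if (any(!is.finite(s)) || any(s < 0))
      stopf("slice intensities must be finite and non-negative")
  }
  if (length(pixel_spacing_mm) != 2 || any(pixel_spacing_mm <= 0))
    stopf("pixel_spacing_mm must be a positive pair")
  if (repeat_index < 0) stopf("repeat_index must be non-negative")
  structure(list(subject_id = as.character(subject_id), slices = slices,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 field_strength = field_strength, vendor = vendor,
                 repeat_index = as.integer(repeat_index)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("slice_stack '%s': %d slice(s) of %dx%d, field=%s, vendor=%s, repeat=%d\n",
              x$subject_id, length(x$slices), d[1], d[2],
              x$field_strength, x$vendor, x$repeat_index))
  invisible(x)
}

n_slices <- function(stack) length(stack$slices)
slice_dim <- function(stack) dim(stack$slices[[1]])

#' Generate a high-field (3T-like) phantom subject
#'
#' Builds a brain-like multi-tissue phantom: nested smooth elliptical regions
#' emulating the CSF / gray-matter / white-matter intensity tiers over a dark
#' (exactly zero) background, with per-subject random ellipse perturbations
#' and radii that shrink smoothly across slices like an axial sweep through a
#' spheroid. Intensities lie in `[0, 1]`. Deterministic given `seed`.
#'
#' @param subject_id Subject identifier.
#' @param n_slices Number of slices (>= 1).
#' @param size_px Slice side length in pixels (>= 32).
#' @param vendor Vendor label `"A"`, `"B"` or `"C"`.
#' @param seed Integer seed; the phantom is a pure function of it.
#' @return A `slice_stack` with `field_strength = "high"`.
#' @export
make_high_field_subject <- function(subject_id, n_slices, size_px,
                                    vendor = c("A", "B", "C"), seed = 1L) {
  vendor <- match.arg(vendor)
  if (n_slices < 1) stopf("n_slices must be >= 1, got %s", n_slices)
  if (size_px < 32) stopf("size_px must be >= 32, got %s", size_px)
  n_slices <- as.integer(n_slices); size_px <- as.integer(size_px)
  with_seed(derive_seed(seed, "phantom", subject_id), {
    # per-subject anatomy: head ellipse + tissue tiers + cortical ripple
    a_head <- stats::runif(1, 0.70, 0.82)   # semi-axes, fraction of half-size
    b_head <- stats::runif(1, 0.82, 0.92)
    cx <- stats::runif(1, -0.04, 0.04)
    cy <- stats::runif(1, -0.04, 0.04)
    tilt <- stats::runif(1, -0.3, 0.3)
    i_csf <- stats::runif(1, 0.22, 0.30)
    i_gm  <- stats::runif(1, 0.50, 0.60)
    i_wm  <- stats::runif(1, 0.80, 0.90)
    ripple_k <- sample(3:6, 1)
    ripple_a <- stats::runif(1, 0.02, 0.05)
    ripple_ph <- stats::runif(1, 0, 2 * pi)
    n_lesions <- sample(2:4, 1)
    les <- data.frame(x = stats::runif(n_lesions, -0.4, 0.4),
                      y = stats::runif(n_lesions, -0.4, 0.4),
                      r = stats::runif(n_lesions, 0.05, 0.12),
                      amp = stats::runif(n_lesions, -0.12, 0.12))

    half <- (size_px - 1) / 2
    xs <- ((seq_len(size_px) - 1) - half) / half
    X <- matrix(rep(xs, each = size_px), size_px, size_px)  # columns -> x
    Y <- matrix(rep(xs, times = size_px), size_px, size_px) # rows -> y
    Xr <- cos(tilt) * (X - cx) + sin(tilt) * (Y - cy)
    Yr <- -sin(tilt) * (X - cx) + cos(tilt) * (Y - cy)
    phi <- atan2(Yr, Xr)

    slices <- vector("list", n_slices)
    for (k in seq_len(n_slices)) {
      # spheroid cut: radii shrink toward the stack ends
      z <- if (n_slices == 1) 0 else (k - (n_slices + 1) / 2) / ((n_slices + 1) / 2)
      shrink <- sqrt(pmax(1 - 0.6 * z^2, 0.2))
      r2 <- (Xr / (a_head * shrink))^2 + (Yr / (b_head * shrink))^2
      r <- sqrt(r2)
      rip <- 1 + ripple_a * cos(ripple_k * phi + ripple_ph)
      img <- matrix(0, size_px, size_px)
      head_mask <- r <= 1
      # soft tier transitions (logistic in normalized radius), hard zero outside
      t_gm <- 0.92 * rip; t_wm <- 0.62 * rip
      w_gm <- 1 / (1 + exp((r - t_gm) / 0.02))   # 1 inside gray boundary
      w_wm <- 1 / (1 + exp((r - t_wm) / 0.03))   # 1 inside white boundary
      img <- i_csf + (i_gm - i_csf) * w_gm + (i_wm - i_gm) * w_wm
      for (j in seq_len(n_lesions)) {
        d2 <- (Xr - les$x[j])^2 + (Yr - les$y[j])^2
        img <- img + les$amp[j] * exp(-d2 / (2 * (les$r[j] * shrink)^2)) * w_wm
      }
      img[!head_mask] <- 0
      slices[[k]] <- pmin(pmax(img, 0), 1)
    }
    slice_stack(slices, subject_id, c(1, 1), "high", vendor, 0L)
  })
}

#' Degradation parameters for the low-field arm
#'
#' The generative parameters turning a high-field phantom into its low-field
#' (1.5T-like) pair: reduced gray-white contrast, smoothing, a smooth
#' multiplicative bias field, additive Gaussian noise, a vendor-specific
#' global gain, and a small in-plane rigid misalignment.
#'
#' @param noise_sigma Additive Gaussian noise SD, as a fraction of the
#'   high-field stack's intensity range (>= 0).
#' @param blur_fwhm_px Gaussian blur FWHM in pixels (>= 0).
#' @param bias_amplitude Peak deviation of the multiplicative bias field from
#'   1 (>= 0).
#' @param contrast_scale Gray-white contrast retention in `(0, 1]`; 1 keeps
#'   the original contrast.
#' @param misalign A `rigid_transform2d` applied to the degraded stack.
#' @param vendor_gain Global intensity gain (> 0).
#' @param seed Integer seed driving the bias-field shape and noise draws.
#' @return An object of class `degradation_params`.
#' @export
degradation_params <- function(noise_sigma = 0, blur_fwhm_px = 0,
                               bias_amplitude = 0, contrast_scale = 1,
                               misalign = rigid_transform2d(), vendor_gain = 1,
                               seed = 1L) {
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (blur_fwhm_px < 0) stopf("blur_fwhm_px must be >= 0")
  if (bias_amplitude < 0) stopf("bias_amplitude must be >= 0")
  if (contrast_scale <= 0 || contrast_scale > 1) stopf("contrast_scale must be in (0, 1]")
  if (vendor_gain <= 0) stopf("vendor_gain must be > 0")
  if (!inherits(misalign, "rigid_transform2d")) stopf("misalign must be a rigid_transform2d")
  structure(list(noise_sigma = noise_sigma, blur_fwhm_px = blur_fwhm_px,
                 bias_amplitude = bias_amplitude, contrast_scale = contrast_scale,
                 misalign = misalign, vendor_gain = vendor_gain,
                 seed = as.integer(seed)),
            class = "degradation_params")
}

# Smooth multiplicative bias field: low-order 2-D polynomial surface scaled to
# the requested peak deviation, then renormalized to mean 1.
bias_field <- function(size, amplitude, seed) {
  if (amplitude == 0) return(matrix(1, size[1], size[2]))
  with_seed(derive_seed(seed, "bias"), {
    cf <- stats::rnorm(5)
    xs <- seq(-1, 1, length.out = size[2])
    ys <- seq(-1, 1, length.out = size[1])
    X <- matrix(rep(xs, each = size[1]), size[1], size[2])
    Y <- matrix(rep(ys, times = size[2]), size[1], size[2])
    f <- cf[1] * X + cf[2] * Y + cf[3] * X * Y +
      cf[4] * (X^2 - 1 / 3) + cf[5] * (Y^2 - 1 / 3)
    f <- f / max(abs(f))
    b <- 1 + amplitude * f
    b / mean(b)
  })
}

#' Degrade a high-field stack into its low-field pair
#'
#' Applies, in order: contrast scaling toward the slice mean, Gaussian blur,
#' a smooth multiplicative bias field, additive Gaussian noise, the vendor
#' gain, and finally rigid resampling by `params$misalign`. The result is
#' tagged `field_strength = "low"` with the same vendor. With every parameter
#' at its neutral value the output is pixel-identical to the input. Negative
#' intensities produced by noise are clipped to zero. Deterministic given
#' `params$seed` (noise stream overridable via `noise_seed` for repeats).
#'
#' @param high A `slice_stack` with `field_strength == "high"`.
#' @param params A `degradation_params`.
#' @param noise_seed Seed for the additive-noise stream only; defaults to
#'   `params$seed`. The bias field always derives from `params$seed`, so two
#'   scans differing only in `noise_seed` share every deterministic component.
#' @return A `slice_stack` with `field_strength = "low"`. The generating
#'   inputs are kept in attributes so repeats can be regenerated.
#' @export
degrade_to_low_field <- function(high, params, noise_seed = params$seed) {
  if (!inherits(high, "slice_stack")) stopf("high must be a slice_stack")
  if (high$field_strength != "high") stopf("input stack must be high-field")
  if (!inherits(params, "degradation_params")) stopf("params must be degradation_params")
  d <- slice_dim(high)
  bias <- bias_field(d, params$bias_amplitude, params$seed)
  rng_all <- range(unlist(lapply(high$slices, range)))
  tissue_range <- max(diff(rng_all), .Machine$double.eps)
  out <- vector("list", n_slices(high))
  for (k in seq_along(out)) {
    img <- high$slices[[k]]
    if (params$contrast_scale < 1) {
      m <- mean(img)
      img <- m + params$contrast_scale * (img - m)
    }
    img <- blur_gaussian(img, params$blur_fwhm_px)
    img <- img * bias
    if (params$noise_sigma > 0) {
      noise <- with_seed(derive_seed(noise_seed, "noise", k),
                         matrix(stats::rnorm(length(img), 0,
                                             params$noise_sigma * tissue_range),
                                d[1], d[2]))
      # magnitude reconstruction: keeps intensities non-negative and gives the
      # Rayleigh-like positive background of real magnitude MRI
      img <- abs(img + noise)
    }
    img <- img * params$vendor_gain
    img <- warp_rigid(img, params$misalign)
    out[[k]] <- pmax(img, 0)
  }
  low <- slice_stack(out, high$subject_id, high$pixel_spacing_mm, "low",
                     high$vendor, 0L)
  attr(low, "source_high") <- high
  attr(low, "params") <- params
  attr(low, "noise_seed") <- noise_seed
  low
}

#' Regenerate a low-field scan with an independent noise realization
#'
#' Emulates a same-session repeat acquisition: the same underlying subject and
#' identical degradation parameters (including the bias field and
#' misalignment), but an independent noise draw. Used for the repeat-scan
#' variability anchor.
#'
#' @param low A low-field `slice_stack` produced by [degrade_to_low_field()].
#' @param params The `degradation_params` used for `low` (defaults to the ones
#'   stored on `low`).
#' @param repeat_seed Seed for the new noise realization; must differ from the
#'   original noise seed so the repeat is independent.
#' @return A `slice_stack` with `repeat_index` incremented.
#' @export
make_repeat_scan <- function(low, params = attr(low, "params"), repeat_seed) {
  if (!inherits(low, "slice_stack") || low$field_strength != "low")
    stopf("low must be a low-field slice_stack")
  high <- attr(low, "source_high")
  if (is.null(high) || is.null(params))
    stopf("low stack does not carry its generating high-field stack/params")
  if (identical(as.integer(repeat_seed), as.integer(attr(low, "noise_seed"))))
    stopf("repeat_seed must differ from the original noise seed (repeats must be independent)")
  rep_scan <- degrade_to_low_field(high, params, noise_seed = repeat_seed)
  rep_scan$repeat_index <- low$repeat_index + 1L
  rep_scan
}

#' Generate a paired synthetic cohort
#'
#' Builds `sum(n_subjects_per_vendor)` high/low pairs. Pairs are always
#' same-vendor (cross-manufacturer pairs are never generated). Per-subject
#' degradation parameters are jittered around the configured defaults:
#' noise/blur/bias/contrast get multiplicative lognormal-ish jitter and each
#' subject draws its own small rigid misalignment.
#'
#' @param n_subjects_per_vendor Named integer vector, e.g. `c(A = 4, B = 2, C = 2)`.
#' @param defaults A `degradation_params` giving the cohort-level defaults.
#' @param seed Integer cohort seed.
#' @param n_slices,size_px Phantom geometry per subject.
#' @param misalign_max_px,misalign_max_deg Half-widths of the uniform
#'   per-subject misalignment draws.
#' @return A list of elements `list(high =, low =, params =)`, one per subject.
#' @export
make_cohort <- function(n_subjects_per_vendor, defaults = degradation_params(),
                        seed = 1L, n_slices = 16L, size_px = 64L,
                        misalign_max_px = 3, misalign_max_deg = 5) {
  if (length(n_subjects_per_vendor) == 0 || is.null(names(n_subjects_per_vendor)))
    stopf("n_subjects_per_vendor must be a non-empty named vector")
  if (!all(names(n_subjects_per_vendor) %in% c("A", "B", "C")))
    stopf("vendor names must be in {A, B, C}")
  if (sum(n_subjects_per_vendor) < 1) stopf("need at least one subject")
  vendor_gains <- c(A = 1.0, B = 1.15, C = 0.9)
  cohort <- list()
  idx <- 0L
  for (v in names(n_subjects_per_vendor)) {
    for (i in seq_len(n_subjects_per_vendor[[v]])) {
      idx <- idx + 1L
      sid <- sprintf("S%03d_%s", idx, v)
      sseed <- derive_seed(seed, "subject", sid)
      high <- make_high_field_subject(sid, n_slices, size_px, v, seed = sseed)
      p <- with_seed(derive_seed(sseed, "params"), {
        jit <- function(x) if (x > 0) x * exp(stats::rnorm(1, 0, 0.15)) else 0
        degradation_params(
          noise_sigma = jit(defaults$noise_sigma),
          blur_fwhm_px = jit(defaults$blur_fwhm_px),
          bias_amplitude = jit(defaults$bias_amplitude),
          contrast_scale = min(1, defaults$contrast_scale *
                                 exp(stats::rnorm(1, 0, 0.05))),
          misalign = rigid_transform2d(
            stats::runif(1, -misalign_max_px, misalign_max_px),
            stats::runif(1, -misalign_max_px, misalign_max_px),
            stats::runif(1, -misalign_max_deg, misalign_max_deg)),
          vendor_gain = defaults$vendor_gain * vendor_gains[[v]],
          seed = derive_seed(sseed, "degrade"))
      })
      low <- degrade_to_low_field(high, p)
      cohort[[idx]] <- list(high = high, low = low, params = p)
    }
  }
  cohort
}
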