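# Rigid intra-subject realignment of a low-field stack onto its high-field
# pair. Same modality, same subject, so the similarity measure is plain mean
# squared error after median scaling; the search is coarse-to-fine over
# (tx, ty, theta) with Nelder-Mead at each pyramid level, and the whole
# procedure restarts from perturbed initializations when the automated
# alignment check fails (the surrogate for iterative visual-inspection loops).

# Median-scale an image so intensity gain differences do not bias the MSE.
# Foreground = pixels above 10% of the maximum: plain positivity is not
# usable on magnitude images, whose background noise is all-positive.
median_scale <- function(img) {
  fg <- img > 0.1 * max(img)
  m <- if (any(fg)) stats::median(img[fg]) else 0
  if (!is.finite(m) || m <= 0) m <- stats::median(abs(img)) + .Machine$double.eps
  img / m
}

pyramid_level <- function(img, factor) {
  if (factor == 1) return(img)
  nr <- nrow(img) - nrow(img) %% factor
  nc <- ncol(img) - ncol(img) %% factor
  downsample_block(img[seq_len(nr), seq_len(nc), drop = FALSE], factor)
}

# Stack-mean MSE in the halfway space: the moving stack is warped by half the
# candidate transform and the reference by the inverse half, so both sides
# incur exactly one resampling. An asymmetric objective (warping only the
# moving image) is biased toward under-rotation, because the second
# interpolation blurs the moving image while the reference stays crisp.
half_transform <- function(par) {
  th_h <- par[3] / 2 * pi / 180
  Rh <- matrix(c(cos(th_h), sin(th_h), -sin(th_h), cos(th_h)), 2, 2)
  t_h <- solve(diag(2) + Rh, c(par[1], par[2]))
  rigid_transform2d(t_h[1], t_h[2], par[3] / 2)
}

registration_objective <- function(par, moving, reference) {
  h <- half_transform(par)
  hi <- invert_transform(h)
  val <- 0
  for (k in seq_along(moving)) {
    w <- warp_rigid(moving[[k]], h)
    r <- warp_rigid(reference[[k]], hi)
    val <- val + mean((w - r)^2)
  }
  val / length(moving)
}

#' Automated alignment check
#'
#' Surrogate for visual inspection: returns `TRUE` iff the normalized
#' cross-correlation (Pearson correlation, hence intensity-scale invariant)
#' between aligned and reference foreground pixels is at least `threshold`
#' on every slice. Foreground = pixels where the reference is positive.
#'
#' @param aligned,reference `slice_stack`s with matched dimensions.
#' @param threshold Correlation threshold in `[0, 1]` (default 0.95).
#' @return Logical scalar.
#' @export
alignment_check <- function(aligned, reference, threshold = 0.95) {
  if (!identical(slice_dim(aligned), slice_dim(reference)) ||
      n_slices(aligned) != n_slices(reference))
    stopf("aligned and reference stacks must have matching dimensions")
  for (k in seq_len(n_slices(reference))) {
    fg <- reference$slices[[k]] > 0
    if (sum(fg) < 3) next
    a <- aligned$slices[[k]][fg]
    r <- reference$slices[[k]][fg]
    if (stats::sd(a) == 0 || stats::sd(r) == 0) {
      if (stats::sd(a) != stats::sd(r)) return(FALSE) else next
    }
    if (stats::cor(a, r) < threshold) return(FALSE)
  }
  TRUE
}

#' Rigid registration of a low-field stack to its high-field reference
#'
#' Minimizes the stack-mean squared intensity difference over an in-plane
#' rigid transform (tx, ty, theta) shared by all slices, using a
#' multi-resolution (coarse-to-fine) Nelder-Mead search on median-scaled
#' intensities. If the post-alignment correlation check fails, the search is
#' restarted from seeded perturbed initializations up to `max_restarts` times
#' and the best result is kept.
#'
#' @param moving,reference `slice_stack`s with equal slice counts and
#'   dimensions; `moving` is resampled into the frame of `reference`.
#' @param max_restarts Maximum number of perturbed-restart attempts (default 3).
#' @param tol Relative convergence tolerance of the optimizer (> 0).
#' @param check_threshold NCC threshold for the automated alignment check.
#' @param seed Seed for restart perturbations.
#' @param smooth_fwhm FWHM (pixels) of the Gaussian smoothing applied to both
#'   stacks before optimization (widens the capture range; 0 disables).
#' @return A list of class `registration_result` with elements `transform`
#'   (the correcting `rigid_transform2d`), `aligned` (the resampled moving
#'   stack), `objective_trace` (best objective after each accepted stage),
#'   `converged`, and `n_restarts`.
#' @export
register_rigid <- function(moving, reference, max_restarts = 3L, tol = 1e-4,
                           check_threshold = 0.95, seed = 1L,
                           smooth_fwhm = 1) {
  if (!identical(slice_dim(moving), slice_dim(reference)) ||
      n_slices(moving) != n_slices(reference))
    stopf("moving and reference stacks must have matching dimensions")
  if (tol <= 0) stopf("tol must be > 0")
  for (s in c(moving$slices, reference$slices))
    if (any(!is.finite(s))) stopf("non-finite intensities in input stacks")

  # optimize on median-scaled, lightly smoothed intensities: smoothing widens
  # the capture range and removes the bias of resampling-induced blur, which
  # otherwise favours slight under-rotation
  mov <- lapply(moving$slices, function(s) blur_gaussian(median_scale(s), smooth_fwhm))
  ref <- lapply(reference$slices, function(s) blur_gaussian(median_scale(s), smooth_fwhm))

  factors <- c(4L, 2L, 1L)
  factors <- factors[min(slice_dim(reference)) / factors >= 16]
  pyramids <- lapply(factors, function(f)
    list(mv = lapply(mov, pyramid_level, factor = f),
         rf = lapply(ref, pyramid_level, factor = f)))

  solve_from <- function(init) {
    par <- init
    trace <- numeric(0)
    for (li in seq_along(factors)) {
      factor <- factors[li]
      par_lvl <- c(par[1] / factor, par[2] / factor, par[3])
      opt <- stats::optim(par_lvl, registration_objective,
                          moving = pyramids[[li]]$mv,
                          reference = pyramids[[li]]$rf,
                          method = "Nelder-Mead",
                          control = list(reltol = tol, maxit = 400,
                                         parscale = c(1, 1, 2)))
      par <- c(opt$par[1] * factor, opt$par[2] * factor, opt$par[3])
      trace <- c(trace, registration_objective(par, mov, ref))
    }
    list(par = par, value = registration_objective(par, mov, ref), trace = trace)
  }

  # exhaustive sweep over a coarse transform grid, ranked at full resolution:
  # rotation MSE landscapes on ring-like anatomy have shallow local minima,
  # so the multi-resolution descent is started from the best few candidates
  cf <- factors[1]
  grid <- expand.grid(tx = cf * (-1:1), ty = cf * (-1:1),
                      th = seq(-10, 10, by = 2))
  grid$obj <- apply(grid, 1, function(g)
    registration_objective(c(g[1], g[2], g[3]), mov, ref))
  grid <- grid[order(grid$obj), ]
  starts <- list(c(0, 0, 0))
  for (th in unique(grid$th)[seq_len(min(3, length(unique(grid$th))))]) {
    g <- grid[grid$th == th, ][1, ]
    starts[[length(starts) + 1]] <- c(g$tx, g$ty, g$th)
  }

  id_obj <- registration_objective(c(0, 0, 0), mov, ref)
  cands <- lapply(starts, solve_from)
  best <- cands[[which.min(vapply(cands, `[[`, 0, "value"))]]
  # full-resolution polish with a tight tolerance
  polish <- stats::optim(best$par, registration_objective, moving = mov,
                         reference = ref, method = "Nelder-Mead",
                         control = list(reltol = min(tol, 1e-8), maxit = 300,
                                        parscale = c(0.5, 0.5, 0.5)))
  if (polish$value < best$value)
    best <- list(par = polish$par, value = polish$value,
                 trace = c(best$trace, polish$value))
  n_restarts <- 0L
  make_aligned <- function(par) {
    tf <- rigid_transform2d(par[1], par[2], par[3])
    slice_stack(lapply(moving$slices, function(s) pmax(warp_rigid(s, tf), 0)),
                moving$subject_id, moving$pixel_spacing_mm, moving$field_strength,
                moving$vendor, moving$repeat_index)
  }
  ok <- alignment_check(make_aligned(best$par), reference, check_threshold)
  while (!ok && n_restarts < max_restarts) {
    n_restarts <- n_restarts + 1L
    init <- with_seed(derive_seed(seed, "restart", n_restarts),
                      c(stats::runif(2, -4, 4), stats::runif(1, -8, 8)))
    cand <- solve_from(init)
    if (cand$value < best$value) best <- cand
    ok <- alignment_check(make_aligned(best$par), reference, check_threshold)
  }
  # never return something worse than not moving at all
  if (best$value > id_obj) best <- list(par = c(0, 0, 0), value = id_obj,
                                        trace = id_obj)
  aligned <- make_aligned(best$par)
  structure(list(transform = rigid_transform2d(best$par[1], best$par[2], best$par[3]),
                 aligned = aligned,
                 objective_trace = cummin(c(id_obj, best$trace)),
                 converged = ok, n_restarts = n_restarts),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: tx=%.3f ty=%.3f theta=%.3f deg, converged=%s, restarts=%d\n",
              x$transform$tx_px, x$transform$ty_px, x$transform$theta_deg,
              x$converged, x$n_restarts))
  invisible(x)
}
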