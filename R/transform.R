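#' In-plane rigid transform
#'
#' A 2-D rigid transform relating a low-field slice to its high-field pair:
#' translation in pixels plus rotation (degrees, counter-clockwise) about the
#' slice centre. Applying the transform to an image moves its content by
#' `(tx_px, ty_px)` after rotating by `theta_deg`; x indexes columns and y
#' indexes rows.
#'
#' @param tx_px,ty_px Translation in pixels (x = columns, y = rows).
#' @param theta_deg Rotation in degrees about the image centre.
#' @return An object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(tx_px = 0, ty_px = 0, theta_deg = 0) {
  for (v in c(tx_px, ty_px, theta_deg))
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stopf("rigid transform parameters must be finite scalars")
  structure(list(tx_px = tx_px, ty_px = ty_px, theta_deg = theta_deg),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("rigid_transform2d: tx=%.3f px, ty=%.3f px, theta=%.3f deg\n",
              x$tx_px, x$ty_px, x$theta_deg))
  invisible(x)
}

is_identity_transform <- function(tf, tol = 0) {
  abs(tf$tx_px) <= tol && abs(tf$ty_px) <= tol && abs(tf$theta_deg) <= tol
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `a` first, then `b`.
#'
#' @param a,b `rigid_transform2d` objects.
#' @return A `rigid_transform2d`.
#' @export
compose_transforms <- function(a, b) {
  tb <- b$theta_deg * pi / 180
  R <- matrix(c(cos(tb), sin(tb), -sin(tb), cos(tb)), 2, 2)
  t_new <- R %*% c(a$tx_px, a$ty_px) + c(b$tx_px, b$ty_px)
  rigid_transform2d(t_new[1], t_new[2], a$theta_deg + b$theta_deg)
}

#' Invert a rigid transform
#'
#' @param tf A `rigid_transform2d`.
#' @return The inverse `rigid_transform2d`: `compose_transforms(tf, invert_transform(tf))`
#'   is the identity.
#' @export
invert_transform <- function(tf) {
  th <- -tf$theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_new <- -R %*% c(tf$tx_px, tf$ty_px)
  rigid_transform2d(t_new[1], t_new[2], -tf$theta_deg)
}

#' Resample a slice under a rigid transform
#'
#' Applies a `rigid_transform2d` to a 2-D intensity grid by inverse mapping
#' with bilinear interpolation; out-of-range source coordinates are clamped to
#' the border (edge replication). Content moves by `(+tx, +ty)` pixels and is
#' rotated `theta_deg` counter-clockwise about the image centre.
#'
#' @param img Numeric matrix.
#' @param tf A `rigid_transform2d`.
#' @return Numeric matrix of the same dimensions.
#' @export
warp_rigid <- function(img, tf) {
  if (!is.matrix(img)) stopf("warp_rigid expects a matrix")
  if (is_identity_transform(tf)) return(img)
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- tf$theta_deg * pi / 180
  # inverse map: source = R(-theta) %*% (dest - centre - t) + centre
  xd <- rep(seq_len(nc), each = nr) - cx - tf$tx_px
  yd <- rep(seq_len(nr), times = nc) - cy - tf$ty_px
  xs <- cos(th) * xd + sin(th) * yd + cx
  ys <- -sin(th) * xd + cos(th) * yd + cy
  bilinear_sample(img, xs, ys)
}

# Bilinear sampling at fractional (x, y) coordinates with border clamping.
bilinear_sample <- function(img, xs, ys) {
  nr <- nrow(img); nc <- ncol(img)
  xs <- pmin(pmax(xs, 1), nc)
  ys <- pmin(pmax(ys, 1), nr)
  x0 <- pmin(floor(xs), nc - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(ys), nr - 1L); y1 <- y0 + 1
  fx <- xs - x0; fy <- ys - y0
  v00 <- img[cbind(y0, x0)]; v01 <- img[cbind(y0, x1)]
  v10 <- img[cbind(y1, x0)]; v11 <- img[cbind(y1, x1)]
  v <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  matrix(v, nr, nc)
}
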