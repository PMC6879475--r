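#' Rigid 2-D transform
#'
#' A rotation about the image center followed by a translation, mapping
#' moving-frame coordinates into the fixed frame:
#' `T(p) = R(theta) (p - c) + c + (dx, dy)`, with `p = (x, y)` in 0-based
#' pixel coordinates and `c` the canvas center `((w-1)/2, (h-1)/2)`.
#' Scale is fixed at 1: session-to-session eye repositioning at this field
#' size is approximately rigid and the optics do not change.
#'
#' @param dx,dy Translation in pixels.
#' @param rotation Rotation in degrees (counter-clockwise in x/y
#'   coordinates).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(dx = 0, dy = 0, rotation = 0) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(rotation))
  structure(list(dx = dx, dy = dy, rotation = rotation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx=%.3f px, dy=%.3f px, rot=%.3f deg\n",
              x$dx, x$dy, x$rotation))
  invisible(x)
}

rot_matrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`
#' (both about the same canvas center).
#'
#' @param second,first `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(second, first) {
  R2 <- rot_matrix(second$rotation)
  t1 <- c(first$dx, first$dy)
  t <- as.numeric(R2 %*% t1) + c(second$dx, second$dy)
  rigid_transform(t[1], t[2], second$rotation + first$rotation)
}

#' Invert a rigid transform
#'
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rinv <- rot_matrix(-transform$rotation)
  t <- -as.numeric(Rinv %*% c(transform$dx, transform$dy))
  rigid_transform(t[1], t[2], -transform$rotation)
}

# Map (x, y) point matrices through a transform (or its inverse).
apply_transform_xy <- function(x, y, transform, height, width, inverse = FALSE) {
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  if (inverse) transform <- invert_transform(transform)
  R <- rot_matrix(transform$rotation)
  xs <- x - cx; ys <- y - cy
  list(x = R[1, 1] * xs + R[1, 2] * ys + cx + transform$dx,
       y = R[2, 1] * xs + R[2, 2] * ys + cy + transform$dy)
}

# Core resampler. Returns list(pixels, valid). method "bilinear" for
# intensity images, "nearest" for binary masks (fractional vessel pixels
# are undefined, so masks are never interpolated).
resample <- function(pixels, transform, method = c("bilinear", "nearest"),
                     fill = 0) {
  method <- match.arg(method)
  h <- nrow(pixels); w <- ncol(pixels)
  xs <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  src <- apply_transform_xy(xs, ys, transform, h, w, inverse = TRUE)
  sx <- src$x; sy <- src$y
  if (method == "nearest") {
    ix <- round(sx); iy <- round(sy)
    valid <- ix >= 0 & ix <= (w - 1) & iy >= 0 & iy <= (h - 1)
    out <- matrix(fill, h, w)
    out[valid] <- pixels[cbind(iy[valid] + 1, ix[valid] + 1)]
    return(list(pixels = out, valid = valid))
  }
  valid <- sx >= 0 & sx <= (w - 1) & sy >= 0 & sy <= (h - 1)
  # clamp the interpolation cell so exact border samples stay valid
  x0c <- pmax(pmin(floor(sx), w - 2), 0)
  y0c <- pmax(pmin(floor(sy), h - 2), 0)
  fxc <- pmin(pmax(sx - x0c, 0), 1)
  fyc <- pmin(pmax(sy - y0c, 0), 1)
  yv <- as.vector(y0c); xv <- as.vector(x0c)
  v00 <- pixels[cbind(yv + 1, xv + 1)]
  v01 <- pixels[cbind(yv + 1, xv + 2)]
  v10 <- pixels[cbind(yv + 2, xv + 1)]
  v11 <- pixels[cbind(yv + 2, xv + 2)]
  fx <- as.vector(fxc); fy <- as.vector(fyc)
  vals <- matrix((1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v01 +
                 (1 - fx) * fy * v10 + fx * fy * v11, h, w)
  out <- matrix(fill, h, w)
  out[valid] <- vals[valid]
  list(pixels = out, valid = valid)
}

#' Warp an image by a rigid transform
#'
#' Resamples a moving image into the fixed frame by bilinear interpolation.
#' Pixels whose source location falls outside the moving canvas are marked
#' invalid in the returned validity mask (never encoded as a sentinel
#' intensity).
#'
#' @param frame An [image_frame] or numeric matrix.
#' @param transform A [rigid_transform] mapping moving to fixed coordinates.
#' @return A list with `frame` (the warped [image_frame] or matrix) and
#'   `valid` (logical matrix of in-canvas pixels).
#' @export
warp <- function(frame, transform) {
  px <- if (inherits(frame, "image_frame")) frame$pixels else frame
  res <- resample(px, transform, method = "bilinear")
  res$pixels <- clamp01(res$pixels)
  out <- if (inherits(frame, "image_frame")) with_pixels(frame, res$pixels) else res$pixels
  list(frame = out, valid = res$valid)
}

#' Warp a binary mask by a rigid transform (nearest neighbour)
#'
#' @param mask Logical matrix.
#' @param transform A [rigid_transform].
#' @return A list with `mask` (warped logical matrix, `FALSE` outside the
#'   source canvas) and `valid` (logical matrix of in-canvas pixels).
#' @export
warp_mask <- function(mask, transform) {
  res <- resample(mask * 1, transform, method = "nearest")
  list(mask = res$pixels > 0.5 & res$valid, valid = res$valid)
}
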