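
# Cross-power spectrum peak: translation t such that fixed(x) ~ moving(x - t),
# i.e. the moving-to-fixed translation, with parabolic subpixel refinement.
phase_correlate <- function(fixed, moving) {
  h <- nrow(fixed); w <- ncol(fixed)
  Ff <- stats::fft(fixed)
  Fm <- stats::fft(moving)
  cross <- Ff * Conj(Fm)
  denom <- Mod(cross)
  denom[denom < .Machine$double.eps] <- .Machine$double.eps
  r <- Re(stats::fft(cross / denom, inverse = TRUE)) / (h * w)
  peak <- which.max(r)
  pr <- ((peak - 1) %% h)
  pc <- ((peak - 1) %/% h)
  # parabolic subpixel fit along each axis (indices wrap)
  sub <- function(cm1, c0, cp1) {
    d <- cm1 - 2 * c0 + cp1
    if (abs(d) < .Machine$double.eps) 0 else 0.5 * (cm1 - cp1) / d
  }
  rm1 <- r[((pr - 1) %% h) + 1, pc + 1]
  rp1 <- r[((pr + 1) %% h) + 1, pc + 1]
  cm1 <- r[pr + 1, ((pc - 1) %% w) + 1]
  cp1 <- r[pr + 1, ((pc + 1) %% w) + 1]
  dy <- pr + sub(rm1, r[pr + 1, pc + 1], rp1)
  dx <- pc + sub(cm1, r[pr + 1, pc + 1], cp1)
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  list(dx = dx, dy = dy, peak = max(r))
}

ncc <- function(a, b, mask) {
  x <- a[mask]; y <- b[mask]
  if (length(x) < 16 || stats::sd(x) == 0 || stats::sd(y) == 0) return(-1)
  stats::cor(x, y)
}

#' Register a follow-up image to its predecessor
#'
#' Two-stage automated rigid registration: a global translation estimate by
#' phase correlation, then a bounded rotation-plus-translation refinement
#' that maximizes normalized correlation on the common overlap region
#' (coarse 0.5 degree grid, then golden-section refinement; translation is
#' re-estimated by phase correlation at every candidate rotation). The
#' transform family is rigid with unit scale. Registration always runs on
#' preprocessed intensity images, never on binary masks, so segmentation
#' error cannot propagate into alignment.
#'
#' @param moving,fixed Preprocessed [image_frame]s on the same canvas.
#' @param max_rotation Rotation search half-range in degrees.
#' @param score_floor Minimum accepted normalized correlation; below it the
#'   registration fails with an error carrying the best score.
#' @return A `registration_result`: `transform` (moving-to-fixed
#'   [rigid_transform]), `common_mask` (pixels valid in both frames after
#'   warping), `score` (normalized correlation on the common region) and
#'   `warped` (the warped moving [image_frame]).
#' @export
register_pair <- function(moving, fixed, max_rotation = 10, score_floor = 0.2) {
  stopifnot(inherits(moving, "image_frame"), inherits(fixed, "image_frame"))
  if (moving$height != fixed$height || moving$width != fixed$width)
    stop_validation("moving and fixed images must share a canvas",
                    "vasctrack_validation_error")
  if (stats::sd(fixed$pixels) < 1e-9 || stats::sd(moving$pixels) < 1e-9)
    stop_validation("degenerate (flat) image cannot be registered",
                    "vasctrack_degenerate_image")
  fpx <- fixed$pixels
  mpx <- moving$pixels
  evaluate <- function(theta) {
    rot <- resample(mpx, rigid_transform(0, 0, theta), method = "bilinear")
    pc <- phase_correlate(fpx, rot$pixels)
    tf <- rigid_transform(pc$dx, pc$dy, theta)
    wr <- resample(mpx, tf, method = "bilinear")
    list(theta = theta, transform = tf,
         score = ncc(fpx, wr$pixels, wr$valid), valid = wr$valid,
         warped = wr$pixels)
  }
  thetas <- seq(-max_rotation, max_rotation, by = 0.5)
  coarse <- lapply(thetas, evaluate)
  scores <- vapply(coarse, function(z) z$score, numeric(1))
  best <- coarse[[which.max(scores)]]
  # golden-section refinement around the best coarse rotation
  lo <- best$theta - 0.5; hi <- best$theta + 0.5
  gr <- (sqrt(5) - 1) / 2
  a <- hi - gr * (hi - lo); b <- lo + gr * (hi - lo)
  fa <- evaluate(a); fb <- evaluate(b)
  for (k in 1:12) {
    if (fa$score > fb$score) {
      hi <- b; b <- a; fb <- fa
      a <- hi - gr * (hi - lo); fa <- evaluate(a)
    } else {
      lo <- a; a <- b; fa <- fb
      b <- lo + gr * (hi - lo); fb <- evaluate(b)
    }
  }
  cand <- list(best, fa, fb)
  best <- cand[[which.max(vapply(cand, function(z) z$score, numeric(1)))]]
  if (best$score < score_floor)
    stop_validation(sprintf(
      "registration failed: best normalized correlation %.3f below floor %.3f",
      best$score, score_floor), "vasctrack_registration_failure")
  structure(list(transform = best$transform,
                 common_mask = best$valid,
                 score = best$score,
                 warped = with_pixels(moving, clamp01(best$warped))),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> dx=%.2f dy=%.2f rot=%.2f deg, score=%.3f, overlap=%d px\n",
    x$transform$dx, x$transform$dy, x$transform$rotation, x$score,
    sum(x$common_mask)))
  invisible(x)
}

#' Magenta-green overlay of a registered pair
#'
#' Renders the fixed frame in magenta (red and blue channels) and the
#' warped moving frame in green; where both are bright the composite tends
#' toward white, so residual misalignment shows as colored fringes.
#'
#' @param fixed An [image_frame].
#' @param moving_warped The moving [image_frame] already warped into the
#'   fixed frame.
#' @return An `height x width x 3` RGB array in `[0, 1]`.
#' @export
overlay_composite <- function(fixed, moving_warped) {
  fp <- if (inherits(fixed, "image_frame")) fixed$pixels else fixed
  mp <- if (inherits(moving_warped, "image_frame")) moving_warped$pixels else moving_warped
  stopifnot(all(dim(fp) == dim(mp)))
  out <- array(0, c(nrow(fp), ncol(fp), 3))
  out[, , 1] <- fp
  out[, , 2] <- mp
  out[, , 3] <- fp
  out
}
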