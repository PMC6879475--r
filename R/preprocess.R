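#' Preprocessing parameters
#'
#' @param median_radius Median filter radius in pixels (0 disables).
#' @param motion_z_threshold Robust z-score (median/MAD of row means) above
#'   which a row is flagged as a motion artefact.
#' @param flatten_radius Background estimation structuring-element radius
#'   in pixels for ICGA flattening (0 disables); must exceed the widest
#'   vessel radius.
#' @param motion_repair,flatten Logical step-enable flags; flattening
#'   applies to ICGA frames only and is off by default (the seeded
#'   segmentation discards unseeded bright background components, which
#'   already neutralizes the smooth fluorescence gradient, while
#'   subtracting an estimated background measurably biases dense frames).
#' @param unsharp_sigma,unsharp_amount Unsharp-mask PSF compensation
#'   applied to ICGA frames after flattening (`amount = 0` disables);
#'   sigma should approximate the modality's excess blur in pixels.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(median_radius = 1L, motion_z_threshold = 3.5,
                              flatten_radius = 9L, motion_repair = TRUE,
                              flatten = FALSE, unsharp_sigma = 1.3,
                              unsharp_amount = 1) {
  stopifnot(median_radius >= 0, motion_z_threshold > 0, flatten_radius >= 0,
            unsharp_sigma >= 0, unsharp_amount >= 0)
  structure(list(median_radius = as.integer(median_radius),
                 motion_z_threshold = motion_z_threshold,
                 flatten_radius = as.integer(flatten_radius),
                 motion_repair = isTRUE(motion_repair),
                 flatten = isTRUE(flatten),
                 unsharp_sigma = unsharp_sigma,
                 unsharp_amount = unsharp_amount),
            class = "preprocess_params")
}

#' Remove horizontal motion-artefact lines
#'
#' OCTA motion artefacts follow the fast-scan axis and show up as
#' abnormally bright whole rows. Rows whose mean intensity has a robust
#' z-score (against the median/MAD of all row means) above the threshold
#' are replaced by the average of the nearest non-flagged rows above and
#' below; every other pixel is left untouched.
#'
#' @param frame An [image_frame].
#' @param z_threshold Robust z-score threshold (> 0).
#' @return The repaired [image_frame].
#' @export
remove_motion_lines <- function(frame, z_threshold = 3.5) {
  px <- frame$pixels
  z <- robust_z(rowMeans(px))
  flagged <- which(z > z_threshold)
  if (length(flagged) == 0) return(frame)
  if (length(flagged) > 0.3 * nrow(px))
    stop_validation(sprintf(
      "%d of %d rows flagged as motion artefacts; image unusable",
      length(flagged), nrow(px)), "vasctrack_artefact_saturation")
  clean <- setdiff(seq_len(nrow(px)), flagged)
  out <- px
  for (r in flagged) {
    above <- clean[clean < r]
    below <- clean[clean > r]
    if (length(above) && length(below)) {
      out[r, ] <- (px[max(above), ] + px[min(below), ]) / 2
    } else if (length(above)) {
      out[r, ] <- px[max(above), ]
    } else {
      out[r, ] <- px[min(below), ]
    }
  }
  with_pixels(frame, out)
}

#' Median-filter denoising
#'
#' @param frame An [image_frame].
#' @param radius Median filter radius in pixels; 0 is the identity.
#' @return The denoised [image_frame].
#' @export
denoise <- function(frame, radius = 1L) {
  stopifnot(radius >= 0)
  if (radius == 0) return(frame)
  out <- ebi_matrix(EBImage::medianFilter(frame$pixels, size = as.integer(radius)))
  with_pixels(frame, clamp01(out))
}

#' Flatten a smooth background field
#'
#' Estimates the background by grayscale morphological opening with a disc
#' larger than any vessel (a rolling-ball estimate: opening removes bright
#' structures smaller than the element, so the estimate cannot absorb the
#' vasculature even where vessels are dense), lightly smooths it,
#' subtracts it, and min-max re-normalizes to `[0, 1]`. Used on ICGA
#' frames, whose additive fluorescence gradient otherwise makes a single
#' global segmentation threshold non-stationary.
#'
#' @param frame An [image_frame].
#' @param kernel_radius Structuring-element radius in pixels (>= 1, larger
#'   than the widest vessel radius).
#' @return The flattened [image_frame].
#' @export
flatten_background <- function(frame, kernel_radius = 9L) {
  stopifnot(kernel_radius >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(kernel_radius) + 1L, "disc")
  bg <- ebi_matrix(EBImage::opening(frame$pixels, brush))
  bg <- gaussian_blur(bg, kernel_radius / 2)
  resid <- frame$pixels - bg
  rng <- range(resid)
  out <- if (diff(rng) < .Machine$double.eps) {
    matrix(0, nrow(resid), ncol(resid))
  } else {
    (resid - rng[1]) / diff(rng)
  }
  with_pixels(frame, out)
}

#' Unsharp-mask sharpening
#'
#' Adds back the difference between the image and its Gaussian-smoothed
#' version, compensating a known excess point-spread blur (used on ICGA
#' frames so vessel support is not widened relative to OCTA).
#'
#' @param frame An [image_frame].
#' @param sigma Gaussian sigma in pixels.
#' @param amount Gain applied to the high-pass residual; 0 is the
#'   identity.
#' @return The sharpened [image_frame], clipped to `[0, 1]`.
#' @export
unsharp_mask <- function(frame, sigma = 1.3, amount = 1) {
  stopifnot(sigma >= 0, amount >= 0)
  if (amount == 0 || sigma == 0) return(frame)
  px <- frame$pixels
  with_pixels(frame, clamp01(px + amount * (px - gaussian_blur(px, sigma))))
}

#' Run the full preprocessing chain on one frame
#'
#' Motion-line repair, then median denoising, then (for ICGA frames)
#' background flattening and unsharp PSF compensation. With all steps
#' disabled the chain is the identity.
#'
#' @param frame An [image_frame].
#' @param params A [preprocess_params].
#' @return The preprocessed [image_frame].
#' @export
preprocess_frame <- function(frame, params = preprocess_params()) {
  out <- frame
  if (params$motion_repair)
    out <- remove_motion_lines(out, params$motion_z_threshold)
  if (params$median_radius > 0)
    out <- denoise(out, params$median_radius)
  if (out$modality == "ICGA") {
    if (params$flatten && params$flatten_radius > 0)
      out <- flatten_background(out, params$flatten_radius)
    if (params$unsharp_amount > 0)
      out <- unsharp_mask(out, params$unsharp_sigma, params$unsharp_amount)
  }
  out
}
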