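#' Modality rendering parameters
#'
#' Noise and point-spread parameters for turning a boolean vessel map into
#' an OCTA-like or ICGA-like en-face angiogram. OCTA frames get
#' multiplicative speckle on bright vessels plus horizontal bright-line
#' motion artefacts (the fast-scan axis); ICGA frames get a wider PSF
#' (Gaussian blur), a smooth additive background fluorescence gradient and
#' lower vessel contrast.
#'
#' @param modality `"OCTA"` or `"ICGA"`.
#' @param vessel_level,background_level Mean intensities of vessel and
#'   background pixels before noise, in `[0, 1]`.
#' @param speckle_sd Multiplicative speckle SD (fraction of local level).
#' @param additive_sd Additive Gaussian noise SD.
#' @param blur_sigma Gaussian PSF sigma in pixels (0 = no blur).
#' @param motion_line_rate Expected number of bright motion-artefact rows
#'   per frame (OCTA; Poisson-distributed count).
#' @param motion_line_gain Intensity added on an artefact row.
#' @param background_gradient Peak-to-peak amplitude of the smooth additive
#'   background field (ICGA fluorescence gradient).
#' @return A `modality_noise` parameter list.
#' @export
modality_noise <- function(modality = c("OCTA", "ICGA"),
                           vessel_level = NULL, background_level = NULL,
                           speckle_sd = NULL, additive_sd = NULL,
                           blur_sigma = NULL, motion_line_rate = NULL,
                           motion_line_gain = NULL, background_gradient = NULL) {
  modality <- match.arg(modality)
  def <- if (modality == "OCTA") {
    list(vessel_level = 0.88, background_level = 0.12, speckle_sd = 0.18,
         additive_sd = 0.04, blur_sigma = 0.6, motion_line_rate = 1.5,
         motion_line_gain = 0.55, background_gradient = 0)
  } else {
    list(vessel_level = 0.75, background_level = 0.22, speckle_sd = 0.06,
         additive_sd = 0.04, blur_sigma = 0.8, motion_line_rate = 0,
         motion_line_gain = 0, background_gradient = 0.25)
  }
  out <- list(modality = modality,
              vessel_level = vessel_level %||% def$vessel_level,
              background_level = background_level %||% def$background_level,
              speckle_sd = speckle_sd %||% def$speckle_sd,
              additive_sd = additive_sd %||% def$additive_sd,
              blur_sigma = blur_sigma %||% def$blur_sigma,
              motion_line_rate = motion_line_rate %||% def$motion_line_rate,
              motion_line_gain = motion_line_gain %||% def$motion_line_gain,
              background_gradient = background_gradient %||% def$background_gradient)
  stopifnot(out$speckle_sd >= 0, out$additive_sd >= 0, out$blur_sigma >= 0,
            out$motion_line_rate >= 0)
  structure(out, class = "modality_noise")
}

#' Noise-free rendering parameters (mask passes through unchanged)
#'
#' @param modality `"OCTA"` or `"ICGA"`.
#' @return A `modality_noise` with unit vessel level and all noise off.
#' @export
noiseless_noise <- function(modality = "OCTA") {
  modality_noise(modality, vessel_level = 1, background_level = 0,
                 speckle_sd = 0, additive_sd = 0, blur_sigma = 0,
                 motion_line_rate = 0, motion_line_gain = 0,
                 background_gradient = 0)
}

gaussian_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  out <- EBImage::imageData(EBImage::gblur(px, sigma = sigma))
  matrix(out, nrow(px), ncol(px))
}

#' Render a vessel mask as a noisy angiogram
#'
#' @param mask Logical vessel map.
#' @param noise A [modality_noise] parameter list.
#' @param meta Optional metadata list passed to [image_frame].
#' @param seed Optional integer seed; when `NULL` the caller's RNG stream
#'   is used.
#' @return An [image_frame] with intensities clipped to `[0, 1]`.
#' @export
render_modality <- function(mask, noise, meta = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  base <- matrix(noise$background_level, h, w)
  base[mask] <- noise$vessel_level
  img <- gaussian_blur(base, noise$blur_sigma)
  if (noise$background_gradient > 0) {
    # smooth diagonal fluorescence gradient with a random orientation
    th <- stats::runif(1, 0, 2 * pi)
    xs <- matrix(rep(seq_len(w) - 1, each = h), nrow = h) / (w - 1) - 0.5
    ys <- matrix(rep(seq_len(h) - 1, times = w), nrow = h) / (h - 1) - 0.5
    img <- img + noise$background_gradient * (cos(th) * xs + sin(th) * ys + 0.5)
  }
  if (noise$speckle_sd > 0)
    img <- img * (1 + noise$speckle_sd * matrix(stats::rnorm(h * w), h, w))
  if (noise$additive_sd > 0)
    img <- img + noise$additive_sd * matrix(stats::rnorm(h * w), h, w)
  if (noise$motion_line_rate > 0) {
    n_lines <- stats::rpois(1, noise$motion_line_rate)
    if (n_lines > 0) {
      rows <- sample.int(h, min(n_lines, h))
      img[rows, ] <- img[rows, ] + noise$motion_line_gain
    }
  }
  meta <- as.list(meta %||% list())
  meta$modality <- meta$modality %||% noise$modality
  do.call(image_frame, c(list(pixels = clamp01(img)), meta))
}

#' Simulate a registration test pair with a known transform
#'
#' Grows a vessel tree, renders the fixed frame from its mask, applies a
#' known rigid transform to the mask and renders the moving frame with
#' independent noise. The pair is what two consecutive sessions of the same
#' eye look like, so `register_pair(moving, fixed)` should recover the
#' inverse of `transform` applied here (i.e. the moving-to-fixed mapping).
#'
#' @param config A [simulation_config].
#' @param transform A [rigid_transform]: the fixed-to-moving pose change.
#' @param seed Integer seed.
#' @param modality Rendered modality.
#' @return List with `fixed`, `moving` ([image_frame]s), `mask` (canonical
#'   vessel map) and `true_transform` (the moving-to-fixed
#'   [rigid_transform] a registration should recover).
#' @export
simulate_registration_pair <- function(config, transform, seed = 1L,
                                       modality = "OCTA") {
  set.seed(seed)
  tree <- grow_tree(config, weeks_of_growth = 2L)
  mask <- rasterize(tree)
  noise <- if (modality == "OCTA") config$octa_noise else config$icga_noise
  fixed <- render_modality(mask, noise)
  moved <- warp_mask(mask, transform)$mask
  moving <- render_modality(moved, noise)
  list(fixed = fixed, moving = moving, mask = mask,
       true_transform = invert_transform(transform))
}
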