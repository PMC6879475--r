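#' Segmentation parameters
#'
#' @param scales Gaussian scales (pixel radii) of the multiscale vesselness
#'   filter, positive and ascending.
#' @param method Threshold method: `"otsu_global"` (Otsu on the ROI
#'   histogram) or `"local_mean"` (local mean plus offset, robust to
#'   residual background gradients).
#' @param window Local-mean window size in pixels (odd, >= 3).
#' @param offset Local-mean threshold offset.
#' @param min_area Minimum connected-component area in pixels
#'   (8-connectivity); smaller components are removed.
#' @param closing_radius Morphological closing radius in pixels (0
#'   disables).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(scales = c(1, 2, 4), method = c("otsu_global", "local_mean"),
                                window = 31L, offset = 0.08, min_area = 20L,
                                closing_radius = 0L) {
  method <- match.arg(method)
  stopifnot(all(scales > 0), !is.unsorted(scales, strictly = TRUE),
            window >= 3, window %% 2 == 1, min_area >= 0, closing_radius >= 0)
  structure(list(scales = scales, method = method, window = as.integer(window),
                 offset = offset, min_area = as.integer(min_area),
                 closing_radius = as.integer(closing_radius)),
            class = "segmentation_params")
}

# Hessian of a Gaussian-smoothed image by central differences.
hessian_fields <- function(px, sigma) {
  g <- gaussian_blur(px, sigma)
  h <- nrow(g); w <- ncol(g)
  shift <- function(m, dr, dc) {
    rs <- pmin(pmax(seq_len(h) + dr, 1), h)
    cs <- pmin(pmax(seq_len(w) + dc, 1), w)
    m[rs, cs, drop = FALSE]
  }
  gxx <- shift(g, 0, 1) - 2 * g + shift(g, 0, -1)
  gyy <- shift(g, 1, 0) - 2 * g + shift(g, -1, 0)
  gxy <- (shift(shift(g, 1, 0), 0, 1) - shift(shift(g, 1, 0), 0, -1) -
          shift(shift(g, -1, 0), 0, 1) + shift(shift(g, -1, 0), 0, -1)) / 4
  list(xx = gxx, yy = gyy, xy = gxy)
}

#' Multiscale Hessian vessel enhancement
#'
#' Line filter for bright curvilinear structures: per scale, the Hessian of
#' the Gaussian-smoothed image is diagonalized in closed form and the
#' response is the rectified negative principal curvature (strong negative
#' second derivative across a bright vessel, near zero along it and inside
#' flat regions, so wide isotropic blobs respond only near their rim, far
#' below an equal-contrast ridge at its centerline). Responses are
#' scale-normalized with `sigma^2`, maximized over scales and min-max
#' normalized to `[0, 1]`.
#'
#' @param frame An [image_frame] (preprocessed) or numeric matrix.
#' @param scales Gaussian scales in pixels.
#' @return Numeric matrix in `[0, 1]`.
#' @export
enhance_vessels <- function(frame, scales = c(1, 2, 4)) {
  px <- if (inherits(frame, "image_frame")) frame$pixels else frame
  best <- matrix(0, nrow(px), ncol(px))
  for (s in scales) {
    hs <- hessian_fields(px, s)
    # sigma^2 normalization keeps responses comparable across scales
    xx <- s^2 * hs$xx; yy <- s^2 * hs$yy; xy <- s^2 * hs$xy
    tr <- xx + yy
    disc <- sqrt(pmax((xx - yy)^2 + 4 * xy^2, 0))
    l2 <- (tr - disc) / 2               # most negative eigenvalue
    best <- pmax(best, pmax(-l2, 0))
  }
  rng <- range(best)
  if (diff(rng) < .Machine$double.eps) return(matrix(0, nrow(px), ncol(px)))
  (best - rng[1]) / diff(rng)
}

# Otsu threshold on the values inside the ROI (256-bin histogram).
otsu_threshold <- function(values, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(values * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5) / n_bins)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  k / n_bins
}

box_mean <- function(px, window) {
  kern <- matrix(1 / (window * window), window, window)
  ebi_matrix(EBImage::filter2(px, kern, boundary = "replicate"))
}

# Threshold a raster within the ROI; ties at the threshold go to
# foreground.
threshold_raster <- function(raster, roi, params) {
  if (params$method == "otsu_global") {
    raster >= otsu_threshold(raster[roi])
  } else {
    raster >= box_mean(raster, params$window) + params$offset
  }
}

#' Binarize a vesselness map within a region of interest
#'
#' Thresholds the vesselness response (threshold computed within the ROI
#' only; ties at the threshold go to foreground), applies morphological
#' closing with a disc element, and removes 8-connected components smaller
#' than the minimum area.
#'
#' @param vesselness Numeric matrix in `[0, 1]`.
#' @param roi Logical ROI matrix (non-empty).
#' @param params A [segmentation_params].
#' @param provenance Optional list recorded with the mask.
#' @return A `binary_vessel_mask`: `mask`, `roi`, `provenance`.
#' @export
binarize <- function(vesselness, roi, params = segmentation_params(),
                     provenance = NULL) {
  stopifnot(is.matrix(vesselness), is.logical(roi),
            all(dim(vesselness) == dim(roi)))
  if (!any(roi))
    stop_validation("empty ROI", "vasctrack_validation_error")
  mask <- threshold_raster(vesselness, roi, params) & roi
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, shape = "disc")
    mask <- ebi_matrix(EBImage::closing(mask * 1, brush)) > 0.5
    mask <- mask & roi
  }
  mask <- drop_small_components(mask, params$min_area)
  structure(list(mask = mask, roi = roi, provenance = provenance,
                 params = params),
            class = "binary_vessel_mask")
}

#' Remove small connected components from a vessel mask
#'
#' 8-connected components with fewer than `min_area` pixels are dropped;
#' `min_area = 0` is the identity and the operation is idempotent.
#'
#' @param vmask A `binary_vessel_mask`.
#' @param min_area Minimum component area in pixels.
#' @return The cleaned `binary_vessel_mask`.
#' @export
clean_mask <- function(vmask, min_area) {
  stopifnot(inherits(vmask, "binary_vessel_mask"), min_area >= 0)
  vmask$mask <- drop_small_components(vmask$mask, as.integer(min_area))
  vmask
}

#' Segment vessels in a preprocessed frame
#'
#' Vesselness-seeded segmentation. A pure tubularity response cannot carry
#' a region threshold on its own once vessels reach the densities seen in
#' suture-induced vascularization (25-35% of the cornea): converging
#' vessels merge into clusters whose interiors are flat, so every
#' curvature-based response vanishes exactly where vessels are thickest.
#' The mask is therefore reconstructed from two thresholded rasters: the
#' multiscale Hessian vesselness map provides high-precision seeds (Otsu
#' within the ROI), the intensity image thresholded by the configured
#' method provides candidate vessel support, and only 8-connected support
#' components containing at least one seed are kept. Blob-like bright
#' structures without a tubular core are discarded with the unseeded
#' components; closing and minimum-area cleanup run last.
#'
#' The default support threshold is global Otsu for both modalities: the
#' reconstruction step discards bright background components that carry no
#' tubular seed, which keeps the global threshold serviceable even under
#' the ICGA fluorescence gradient. `local_mean` remains available for
#' stronger gradients.
#'
#' @param frame A preprocessed [image_frame].
#' @param roi Logical ROI matrix.
#' @param params A [segmentation_params]; when `NULL`, modality defaults
#'   are used.
#' @return A `binary_vessel_mask`.
#' @export
segment_frame <- function(frame, roi, params = NULL) {
  if (is.null(params)) params <- segmentation_params(method = "otsu_global")
  if (!any(roi))
    stop_validation("empty ROI", "vasctrack_validation_error")
  v <- enhance_vessels(frame, params$scales)
  seed_params <- params; seed_params$method <- "otsu_global"
  seeds <- threshold_raster(v, roi, seed_params) & roi
  support <- threshold_raster(frame$pixels, roi, params) & roi
  lab <- label_components_8(support)
  keep <- unique(lab[seeds & support])
  keep <- keep[keep > 0]
  mask <- support & matrix(lab %in% keep, nrow(support), ncol(support))
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, shape = "disc")
    mask <- ebi_matrix(EBImage::closing(mask * 1, brush)) > 0.5
    mask <- mask & roi
  }
  mask <- drop_small_components(mask, params$min_area)
  structure(list(mask = mask, roi = roi,
                 provenance = list(animal_id = frame$animal_id,
                                   modality = frame$modality,
                                   week = frame$week,
                                   replicate = frame$replicate),
                 params = params),
            class = "binary_vessel_mask")
}
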