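#' En-face angiogram image frame
#'
#' An `image_frame` bundles one 2-D grayscale en-face angiogram with its
#' study metadata. Pixel intensities are stored as a numeric matrix in
#' `[0, 1]` (row-major, origin top-left, 0-based coordinates; `x` runs along
#' columns, `y` along rows). Physical pixel size is not modelled: all
#' densities downstream are pixel-fraction percentages.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`, at least 64 x 64.
#' @param modality `"OCTA"` or `"ICGA"`.
#' @param animal_id Animal identifier string.
#' @param eye `"OD"` or `"OS"`.
#' @param week Integer study week (1-based).
#' @param arm Treatment arm: `"saline"`, `"aflibercept"` or `"ranibizumab"`.
#' @param route Delivery route: `"subconjunctival"` or `"topical"`.
#' @param replicate Same-session scan index (>= 1).
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, modality = "OCTA", animal_id = "NA", eye = "OD",
                        week = 1L, arm = "saline", route = "subconjunctival",
                        replicate = 1L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop_validation("image must be at least 64 x 64 pixels", "vasctrack_invalid_image")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop_validation("image contains non-finite intensities", "vasctrack_invalid_image")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop_validation("intensities must lie in [0, 1]", "vasctrack_invalid_image")
  modality <- match.arg(modality, c("OCTA", "ICGA"))
  eye <- match.arg(eye, c("OD", "OS"))
  arm <- match.arg(arm, c("saline", "aflibercept", "ranibizumab"))
  route <- match.arg(route, c("subconjunctival", "topical"))
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         modality = modality, animal_id = as.character(animal_id), eye = eye,
         week = as.integer(week), arm = arm, route = route,
         replicate = as.integer(replicate)),
    class = "image_frame"
  )
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %s %s week %d rep %d (%s/%s), %d x %d px\n",
              x$animal_id, x$modality, x$week, x$replicate, x$arm, x$route,
              x$height, x$width))
  invisible(x)
}

# Replace pixels, keeping metadata; re-validates the range.
with_pixels <- function(frame, pixels) {
  frame$pixels <- pixels
  frame$height <- nrow(pixels)
  frame$width <- ncol(pixels)
  if (anyNA(pixels) || any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1)
    stop_validation("derived image left [0, 1]", "vasctrack_invalid_image")
  frame
}

#' Read an angiogram image
#'
#' Reads a single-channel PNG or TIFF raster, converts RGB inputs by channel
#' averaging (luminance), min-max normalizes intensities to `[0, 1]`, and
#' attaches metadata from a manifest record.
#'
#' @param path Path to a PNG or TIFF file.
#' @param meta A one-row data frame (or named list) with the manifest fields
#'   `animal_id`, `eye`, `modality`, `week`, `arm`, `route`, `replicate`.
#' @return An [image_frame].
#' @export
read_image <- function(path, meta = NULL) {
  if (!file.exists(path))
    stop_validation(paste0("cannot read image file: ", path), "vasctrack_io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_validation("the 'tiff' package is required to read TIFF files",
                        "vasctrack_io_error")
      tiff::readTIFF(path)
    },
    stop_validation(paste0("unsupported image format '", ext, "': ", path),
                    "vasctrack_io_error")
  )
  if (length(dim(raw)) == 3L) raw <- rowMeans(raw, dims = 2L)
  rng <- range(raw)
  if (diff(rng) < .Machine$double.eps)
    stop_validation(paste0("degenerate image (zero intensity variance): ", path),
                    "vasctrack_degenerate_image")
  px <- (raw - rng[1]) / diff(rng)
  meta <- as.list(meta %||% list())
  image_frame(px,
    modality = meta$modality %||% "OCTA",
    animal_id = meta$animal_id %||% "NA",
    eye = meta$eye %||% "OD",
    week = meta$week %||% 1L,
    arm = meta$arm %||% "saline",
    route = meta$route %||% "subconjunctival",
    replicate = meta$replicate %||% 1L)
}

#' Write an angiogram image
#'
#' Writes the `[0, 1]` pixel matrix as an 8-bit grayscale PNG, so a write/read
#' round trip reproduces intensities within 1/255 quantization.
#'
#' @param frame An [image_frame] or a numeric matrix in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(frame, path) {
  px <- if (inherits(frame, "image_frame")) frame$pixels else frame
  png::writePNG(clamp01(px), target = path)
  invisible(path)
}
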