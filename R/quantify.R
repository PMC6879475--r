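#' Vessel density within a region of interest
#'
#' The percentage of ROI pixels classified as vessel:
#' `100 * n_vessel_px / n_roi_px`, from exact integer pixel counts.
#'
#' @param vmask A `binary_vessel_mask` (or a logical matrix).
#' @param roi Logical ROI matrix; defaults to the mask's own ROI.
#' @return A one-row tibble: `vessel_density_pct`, `n_vessel_px`,
#'   `n_roi_px` plus any provenance fields (`animal_id`, `modality`,
#'   `week`, `replicate`).
#' @export
vessel_density <- function(vmask, roi = NULL) {
  m <- if (inherits(vmask, "binary_vessel_mask")) vmask$mask else vmask
  roi <- roi %||% (if (inherits(vmask, "binary_vessel_mask")) vmask$roi else NULL)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(m), ncol(m))
  stopifnot(is.logical(m), is.logical(roi), all(dim(m) == dim(roi)))
  n_roi <- sum(roi)
  if (n_roi == 0)
    stop_validation("empty ROI", "vasctrack_validation_error")
  n_ves <- sum(m & roi)
  prov <- if (inherits(vmask, "binary_vessel_mask")) vmask$provenance else NULL
  out <- tibble::tibble(vessel_density_pct = 100 * n_ves / n_roi,
                        n_vessel_px = n_ves, n_roi_px = n_roi)
  if (!is.null(prov)) out <- dplyr::bind_cols(tibble::as_tibble(prov), out)
  out
}

#' Vessel growth density between consecutive follow-ups
#'
#' The later mask is warped into the earlier frame (nearest neighbour, so
#' it stays boolean) and the computation is restricted to the registered
#' pair's common overlap region intersected with the ROI. Pixels are
#' partitioned into grown (`b & !a`), regressed (`a & !b`), persistent
#' (`a & b`) and empty; the growth density is
#' `100 * (grown - regressed) / common_roi_px`, which equals the vessel
#' density difference of the two masks on the common region exactly.
#'
#' @param mask_a `binary_vessel_mask` of the earlier week (the fixed
#'   frame).
#' @param mask_b `binary_vessel_mask` of the later week (the moving
#'   frame).
#' @param reg A `registration_result` from
#'   `register_pair(moving = later, fixed = earlier)`, or `NULL` when both
#'   masks already share a frame (identity transform, full overlap).
#' @param interval Optional `c(week_a, week_b)` recorded in the output.
#' @return A list with `measurement` (one-row tibble: `growth_density_pct`,
#'   `grown_px`, `regressed_px`, `persistent_px`, `common_roi_px`,
#'   `interval`) and `change_map` (character matrix with labels `empty`,
#'   `grown`, `regressed`, `persistent`; `NA` outside the common ROI).
#' @export
growth_density <- function(mask_a, mask_b, reg = NULL, interval = NULL) {
  a <- if (inherits(mask_a, "binary_vessel_mask")) mask_a$mask else mask_a
  b <- if (inherits(mask_b, "binary_vessel_mask")) mask_b$mask else mask_b
  roi <- if (inherits(mask_a, "binary_vessel_mask")) mask_a$roi
         else matrix(TRUE, nrow(a), ncol(a))
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(reg)) {
    b_w <- b
    common <- matrix(TRUE, nrow(a), ncol(a))
  } else {
    wb <- warp_mask(b, reg$transform)
    b_w <- wb$mask
    common <- reg$common_mask
  }
  common_roi <- common & roi
  n <- sum(common_roi)
  if (n == 0)
    stop_validation("empty common ROI between the registered pair",
                    "vasctrack_registration_failure")
  grown <- sum(b_w & !a & common_roi)
  regressed <- sum(a & !b_w & common_roi)
  persistent <- sum(a & b_w & common_roi)
  change_map <- matrix(NA_character_, nrow(a), ncol(a))
  change_map[common_roi] <- "empty"
  change_map[b_w & !a & common_roi] <- "grown"
  change_map[a & !b_w & common_roi] <- "regressed"
  change_map[a & b_w & common_roi] <- "persistent"
  meas <- tibble::tibble(
    growth_density_pct = 100 * (grown - regressed) / n,
    grown_px = grown, regressed_px = regressed, persistent_px = persistent,
    common_roi_px = n,
    interval = if (is.null(interval)) NA_character_
               else paste(interval, collapse = "-"))
  list(measurement = meas, change_map = change_map)
}

#' Same-session repeatability error
#'
#' Signed vessel density difference between two replicate scans of the
#' same region at the same visit, on their shared ROI. Replicates are
#' acquired in one session and are treated as pre-aligned; no registration
#' is applied.
#'
#' @param mask_r1,mask_r2 `binary_vessel_mask`s of replicates 1 and 2.
#' @param roi Logical ROI; defaults to replicate 1's ROI, which must match
#'   replicate 2's.
#' @return Signed density difference `density(r2) - density(r1)` in
#'   percentage points.
#' @export
repeatability_error <- function(mask_r1, mask_r2, roi = NULL) {
  roi1 <- if (inherits(mask_r1, "binary_vessel_mask")) mask_r1$roi else roi
  roi2 <- if (inherits(mask_r2, "binary_vessel_mask")) mask_r2$roi else roi
  roi <- roi %||% roi1
  if (!is.null(roi1) && !is.null(roi2) && !identical(roi1, roi2))
    stop_validation("replicate ROIs do not match", "vasctrack_validation_error")
  d1 <- vessel_density(mask_r1, roi)$vessel_density_pct
  d2 <- vessel_density(mask_r2, roi)$vessel_density_pct
  d2 - d1
}

#' Render a change map as an RGB overlay
#'
#' Grown pixels in green, regressed in red, persistent in white, on a
#' black background.
#'
#' @param change_map Character label matrix from [growth_density].
#' @return `height x width x 3` RGB array in `[0, 1]`.
#' @export
change_map_rgb <- function(change_map) {
  h <- nrow(change_map); w <- ncol(change_map)
  out <- array(0, c(h, w, 3))
  g <- !is.na(change_map) & change_map == "grown"
  r <- !is.na(change_map) & change_map == "regressed"
  p <- !is.na(change_map) & change_map == "persistent"
  out[, , 1][r] <- 1; out[, , 2][g] <- 1
  out[, , 1][p] <- 1; out[, , 2][p] <- 1; out[, , 3][p] <- 1
  out
}
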