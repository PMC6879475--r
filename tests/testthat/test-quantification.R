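make_vmask <- function(mask, roi = matrix(TRUE, nrow(mask), ncol(mask))) {
  structure(list(mask = mask & roi, roi = roi, provenance = NULL),
            class = "binary_vessel_mask")
}

test_that("vessel density is an exact pixel-count ratio", {
  roi <- matrix(FALSE, 64, 64); roi[1:4, 1:4] <- TRUE
  m <- matrix(FALSE, 64, 64); m[1:2, 1:2] <- TRUE
  d <- vessel_density(make_vmask(m, roi))
  expect_equal(d$vessel_density_pct, 25)
  expect_equal(d$n_vessel_px, 4L)
  expect_equal(d$n_roi_px, 16L)
  full <- vessel_density(make_vmask(matrix(TRUE, 64, 64)))
  expect_equal(full$vessel_density_pct, 100)
  expect_error(vessel_density(make_vmask(m, matrix(FALSE, 64, 64))),
               class = "vasctrack_validation_error")
})

test_that("vessel density equals a brute-force double loop on random masks", {
  set.seed(19)
  for (k in 1:5) {
    m <- matrix(runif(64 * 64) < 0.3, 64, 64)
    roi <- matrix(runif(64 * 64) < 0.8, 64, 64)
    if (!any(roi)) next
    cnt <- 0L; tot <- 0L
    for (r in 1:64) for (c in 1:64) {
      if (roi[r, c]) {
        tot <- tot + 1L
        if (m[r, c]) cnt <- cnt + 1L
      }
    }
    d <- vessel_density(make_vmask(m, roi))
    expect_identical(d$n_vessel_px, cnt)
    expect_identical(d$n_roi_px, tot)
    expect_equal(d$vessel_density_pct, 100 * cnt / tot, tolerance = 1e-12)
  }
})

test_that("growth density: identity pair is zero, pure growth counts exactly", {
  m <- matrix(FALSE, 64, 64); m[10:20, 10:20] <- TRUE
  same <- growth_density(make_vmask(m), make_vmask(m))
  expect_equal(same$measurement$growth_density_pct, 0)
  expect_equal(same$measurement$grown_px, 0L)
  expect_equal(same$measurement$regressed_px, 0L)

  roi <- matrix(FALSE, 64, 64); roi[1:10, 1:10] <- TRUE
  a <- matrix(FALSE, 64, 64)
  b <- matrix(FALSE, 64, 64); b[1:2, 1:5] <- TRUE
  out <- growth_density(make_vmask(a, roi), make_vmask(b, roi))
  expect_equal(out$measurement$growth_density_pct, 10)
  expect_equal(out$measurement$grown_px, 10L)
})

test_that("growth density is antisymmetric and matches set-difference counts", {
  set.seed(23)
  for (k in 1:5) {
    roi <- matrix(runif(64 * 64) < 0.9, 64, 64)
    a <- matrix(runif(64 * 64) < 0.25, 64, 64) & roi
    b <- matrix(runif(64 * 64) < 0.3, 64, 64) & roi
    ab <- growth_density(make_vmask(a, roi), make_vmask(b, roi))
    ba <- growth_density(make_vmask(b, roi), make_vmask(a, roi))
    expect_equal(ab$measurement$growth_density_pct,
                 -ba$measurement$growth_density_pct, tolerance = 1e-12)
    expect_identical(ab$measurement$grown_px, sum(b & !a & roi))
    expect_identical(ab$measurement$regressed_px, sum(a & !b & roi))
    expect_identical(ab$measurement$persistent_px, sum(a & b & roi))
    # partition identity over the common ROI
    n_empty <- sum(!is.na(ab$change_map) & ab$change_map == "empty")
    expect_identical(ab$measurement$grown_px + ab$measurement$regressed_px +
                       ab$measurement$persistent_px + n_empty,
                     ab$measurement$common_roi_px)
    # consistency with the density difference on the common region
    da <- vessel_density(make_vmask(a, roi))$vessel_density_pct
    db <- vessel_density(make_vmask(b, roi))$vessel_density_pct
    expect_equal(ab$measurement$growth_density_pct, db - da, tolerance = 1e-10)
  }
})

test_that("growth density respects the registration's common overlap", {
  cfg <- test_config()
  mask_a <- rasterize(grow_tree(cfg, 1L, seed = 161))
  tf <- rigid_transform(6, -4, 0)
  mask_b_frame <- warp_mask(mask_a, tf)$mask      # same vasculature, new pose
  roi <- test_roi(cfg)
  pp <- preprocess_params()
  fixed <- preprocess_frame(render_modality(mask_a, modality_noise("OCTA"), seed = 162))
  moving <- preprocess_frame(render_modality(mask_b_frame, modality_noise("OCTA"), seed = 163))
  reg <- register_pair(moving, fixed)
  out <- growth_density(make_vmask(mask_a, roi), make_vmask(mask_b_frame, roi),
                        reg, interval = c(1, 2))
  # identical vasculature after alignment: residual signed growth is small
  # and total change (grown + regressed) is far below the unregistered case
  expect_lt(abs(out$measurement$growth_density_pct), 2.5)
  unreg <- growth_density(make_vmask(mask_a, roi), make_vmask(mask_b_frame, roi))
  total <- function(g) g$measurement$grown_px + g$measurement$regressed_px
  expect_lt(total(out), 0.3 * total(unreg))
  expect_equal(out$measurement$interval, "1-2")
})

test_that("repeatability error is a signed density difference on a shared ROI", {
  roi <- matrix(FALSE, 64, 64); roi[1:10, 1:10] <- TRUE
  m1 <- matrix(FALSE, 64, 64); m1[1, 1:5] <- TRUE
  m2 <- m1; m2[2, 1] <- TRUE
  expect_equal(repeatability_error(make_vmask(m1, roi), make_vmask(m1, roi)), 0)
  expect_equal(repeatability_error(make_vmask(m1, roi), make_vmask(m2, roi)), 1)
  expect_equal(repeatability_error(make_vmask(m2, roi), make_vmask(m1, roi)), -1)
  roi2 <- roi; roi2[11, 11] <- TRUE
  expect_error(repeatability_error(make_vmask(m1, roi), make_vmask(m2, roi2)),
               class = "vasctrack_validation_error")
})

test_that("change maps export to RGB with the documented color code", {
  roi <- matrix(TRUE, 64, 64)
  a <- matrix(FALSE, 64, 64); a[1:5, 1:5] <- TRUE
  b <- matrix(FALSE, 64, 64); b[1:5, 4:8] <- TRUE
  out <- growth_density(make_vmask(a, roi), make_vmask(b, roi))
  rgb <- change_map_rgb(out$change_map)
  grown <- out$change_map == "grown" & !is.na(out$change_map)
  regressed <- out$change_map == "regressed" & !is.na(out$change_map)
  persistent <- out$change_map == "persistent" & !is.na(out$change_map)
  expect_true(all(rgb[, , 2][grown] == 1) && all(rgb[, , 1][grown] == 0))
  expect_true(all(rgb[, , 1][regressed] == 1) && all(rgb[, , 2][regressed] == 0))
  expect_true(all(rgb[, , 1][persistent] == 1) && all(rgb[, , 3][persistent] == 1))
})
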