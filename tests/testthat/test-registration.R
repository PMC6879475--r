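test_that("rigid transforms compose and invert consistently", {
  t1 <- rigid_transform(3, -2, 4)
  t2 <- rigid_transform(-1, 5, -2.5)
  comp <- compose_transforms(t2, t1)
  p <- c(10, 20)
  via <- vasctrack:::apply_transform_xy(p[1], p[2], t1, 96, 96)
  via <- vasctrack:::apply_transform_xy(via$x, via$y, t2, 96, 96)
  direct <- vasctrack:::apply_transform_xy(p[1], p[2], comp, 96, 96)
  expect_equal(c(via$x, via$y), c(direct$x, direct$y), tolerance = 1e-10)
  inv <- invert_transform(t1)
  back <- vasctrack:::apply_transform_xy(
    vasctrack:::apply_transform_xy(p[1], p[2], t1, 96, 96)$x,
    vasctrack:::apply_transform_xy(p[1], p[2], t1, 96, 96)$y, inv, 96, 96)
  expect_equal(c(back$x, back$y), p, tolerance = 1e-10)
})

test_that("warp: identity is exact, integer shifts are exact, inverse round-trips", {
  set.seed(7)
  px <- matrix(runif(96 * 96), 96, 96)
  fr <- image_frame(px)
  w_id <- warp(fr, rigid_transform(0, 0, 0))
  expect_equal(w_id$frame$pixels, px, tolerance = 1e-12)
  expect_true(all(w_id$valid))

  tf <- rigid_transform(3, 0, 0)
  w <- warp(fr, tf)
  # fixed-frame pixel (r, c) samples the moving image at x - 3
  expect_equal(w$frame$pixels[, 4:96], px[, 1:93], tolerance = 1e-12)
  expect_false(any(w$valid[, 1:3]))

  # round trip on a smooth field: warp then inverse-warp within tolerance
  smooth <- vasctrack:::gaussian_blur(px, 3)
  sfr <- image_frame(smooth)
  tf2 <- rigid_transform(4.3, -2.7, 3.1)
  fwd <- warp(sfr, tf2)
  back <- warp(fwd$frame, invert_transform(tf2))
  both <- back$valid & fwd$valid
  inner <- both & row(px) > 8 & row(px) < 88 & col(px) > 8 & col(px) < 88
  expect_lt(max(abs(back$frame$pixels[inner] - smooth[inner])), 0.02)
})

test_that("binary masks warp nearest-neighbour and stay boolean", {
  mask <- matrix(FALSE, 96, 96); mask[40:50, 30:60] <- TRUE
  w <- warp_mask(mask, rigid_transform(5, 7, 0))
  expect_type(w$mask, "logical")
  expect_equal(sum(w$mask), sum(mask))
  expect_true(all(w$mask[47:57, 35:65][mask[40:50, 30:60]]))
})

test_that("an image registers to itself as the identity", {
  cfg <- test_config()
  mask <- rasterize(grow_tree(cfg, 2L, seed = 91))
  fr <- preprocess_frame(render_modality(mask, modality_noise("OCTA"), seed = 92))
  reg <- register_pair(fr, fr)
  expect_lte(abs(reg$transform$dx), 0.5)
  expect_lte(abs(reg$transform$dy), 0.5)
  expect_lte(abs(reg$transform$rotation), 0.25)
  expect_gte(reg$score, 0.99)
})

test_that("known translations and rotations are recovered within tolerance", {
  cfg <- test_config()
  pp <- preprocess_params()
  pair <- simulate_registration_pair(cfg, rigid_transform(-7, 4, 0), seed = 101)
  reg <- register_pair(preprocess_frame(pair$moving, pp),
                       preprocess_frame(pair$fixed, pp))
  expect_lt(abs(reg$transform$dx - pair$true_transform$dx), 0.5)
  expect_lt(abs(reg$transform$dy - pair$true_transform$dy), 0.5)

  pair2 <- simulate_registration_pair(cfg, rigid_transform(5, -3, -3), seed = 102)
  reg2 <- register_pair(preprocess_frame(pair2$moving, pp),
                        preprocess_frame(pair2$fixed, pp))
  expect_lt(abs(reg2$transform$dx - pair2$true_transform$dx), 0.5)
  expect_lt(abs(reg2$transform$dy - pair2$true_transform$dy), 0.5)
  expect_lt(abs(reg2$transform$rotation - pair2$true_transform$rotation), 0.5)
})

test_that("degenerate and unregistrable inputs raise classed errors", {
  flat <- flat_frame(0.5, 96)
  expect_error(register_pair(flat, flat), class = "vasctrack_degenerate_image")
  set.seed(14)
  a <- image_frame(matrix(runif(96 * 96), 96, 96))
  b <- image_frame(matrix(runif(96 * 96), 96, 96))
  expect_error(register_pair(a, b, score_floor = 0.9),
               class = "vasctrack_registration_failure")
})

test_that("forward and reverse registrations give near-identical overlap", {
  cfg <- test_config()
  pp <- preprocess_params()
  pair <- simulate_registration_pair(cfg, rigid_transform(6, -5, 2), seed = 111)
  mv <- preprocess_frame(pair$moving, pp)
  fx <- preprocess_frame(pair$fixed, pp)
  fwd <- register_pair(mv, fx)
  rev <- register_pair(fx, mv)
  # map the reverse overlap into the forward frame and compare
  rev_in_fwd <- warp_mask(rev$common_mask, fwd$transform)$mask
  jacc <- sum(fwd$common_mask & rev_in_fwd) / sum(fwd$common_mask | rev_in_fwd)
  expect_gte(jacc, 0.95)
})

test_that("overlay composite uses magenta/green channels as documented", {
  set.seed(15)
  px <- matrix(runif(64 * 64), 64, 64)
  same <- overlay_composite(px, px)
  expect_equal(same[, , 1], same[, , 2])
  expect_equal(same[, , 1], same[, , 3])
  zero <- overlay_composite(px, matrix(0, 64, 64))
  expect_equal(zero[, , 2], matrix(0, 64, 64))
  expect_equal(zero[, , 1], px)
  expect_equal(zero[, , 3], px)
})
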