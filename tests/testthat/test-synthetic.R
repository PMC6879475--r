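test_that("a noise-free single root grows as one straight radial chain", {
  cfg <- test_config(n_roots = 1L, branch_prob = 0, dir_noise_sd = 0)
  tree <- grow_tree(cfg, weeks_of_growth = 1L, seed = 5)
  seg <- tree$segments
  expect_true(is.na(seg$parent[1]))
  expect_equal(seg$parent[-1], seq_len(nrow(seg) - 1))
  # every segment heads toward the limbal center along one line
  lim <- tree$limbus
  r0 <- sqrt((seg$x0 - lim$cx)^2 + (seg$y0 - lim$cy)^2)
  r1 <- sqrt((seg$x1 - lim$cx)^2 + (seg$y1 - lim$cy)^2)
  expect_true(all(r1 < r0))
  # collinearity: cross product of successive directions is ~0
  dx <- seg$x1 - seg$x0; dy <- seg$y1 - seg$y0
  cross <- head(dx, -1) * tail(dy, -1) - head(dy, -1) * tail(dx, -1)
  expect_lt(max(abs(cross)), 1e-8)
})

test_that("growth is deterministic under a fixed seed and extends week by week", {
  cfg <- test_config()
  t_a <- grow_tree(cfg, 2L, seed = 9)
  t_b <- grow_tree(cfg, 2L, seed = 9)
  expect_identical(t_a$segments, t_b$segments)
  t1 <- grow_tree(cfg, 1L, seed = 9)
  expect_equal(t1$segments,
               t_a$segments[seq_len(nrow(t1$segments)), ])
})

test_that("an unreachable target reports the exhausted step budget", {
  cfg <- test_config(step_budget = 3L)
  expect_error(grow_tree(cfg, 2L, seed = 1), "budget",
               class = "vasctrack_simulation_error")
})

test_that("regress_tree prunes distal-first and stays a valid tree", {
  cfg <- test_config()
  tree <- grow_tree(cfg, 2L, seed = 21)
  expect_identical(regress_tree(tree, 0), tree)
  roots_only <- regress_tree(tree, 1)
  expect_true(all(is.na(roots_only$segments$parent)))
  half <- regress_tree(tree, 0.5)
  seg <- half$segments
  ok_parent <- is.na(seg$parent) | (seg$parent >= 1 & seg$parent < seq_len(nrow(seg)))
  expect_true(all(ok_parent))
  # child birth is always after parent birth
  nonroot <- which(!is.na(seg$parent))
  expect_true(all(seg$birth_step[nonroot] > seg$birth_step[seg$parent[nonroot]]))
})

test_that("pruning monotonically reduces rasterized density", {
  cfg <- test_config()
  tree <- grow_tree(cfg, 2L, seed = 33)
  roi <- test_roi(cfg)
  dens <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    sum(rasterize(regress_tree(tree, f), roi = roi))
  }, numeric(1))
  expect_true(all(diff(dens) <= 0))
  expect_lt(dens[3], dens[1])
})

test_that("rasterize matches a brute-force distance-to-segment oracle", {
  cfg <- test_config()
  tree <- structure(list(
    segments = tibble::tibble(x0 = 20, y0 = 30, x1 = 30, y1 = 30,
                              radius = 1, birth_step = 1L,
                              parent = NA_integer_),
    canvas = c(96L, 96L),
    limbus = list(cx = 47.5, cy = 47.5, radius = 60)), class = "vessel_tree")
  roi <- matrix(TRUE, 96, 96)
  got <- rasterize(tree, roi = roi)
  brute <- matrix(FALSE, 96, 96)
  for (r in 1:96) for (c in 1:96) {
    x <- c - 1; y <- r - 1
    t <- min(max((x - 20) / 10, 0), 1)
    d <- sqrt((x - (20 + 10 * t))^2 + (y - 30)^2)
    brute[r, c] <- d <= 1
  }
  expect_identical(got, brute)
})

test_that("rasterize of a union of trees is the union of rasters", {
  cfg <- test_config()
  t1 <- grow_tree(cfg, 1L, seed = 41)
  t2 <- grow_tree(cfg, 1L, seed = 42)
  both <- t1
  both$segments <- dplyr::bind_rows(t1$segments, t2$segments)
  roi <- test_roi(cfg)
  expect_identical(rasterize(both, roi = roi),
                   rasterize(t1, roi = roi) | rasterize(t2, roi = roi))
  empty <- t1; empty$segments <- empty$segments[0, ]
  expect_false(any(rasterize(empty, roi = roi)))
})

test_that("noise-free rendering is the mask cast to {0,1}", {
  cfg <- test_config()
  mask <- rasterize(grow_tree(cfg, 1L, seed = 50))
  fr <- render_modality(mask, noiseless_noise("OCTA"))
  expect_identical(fr$pixels, mask * 1)
})

test_that("rendering is deterministic and keeps vessel/background contrast", {
  cfg <- test_config()
  mask <- rasterize(grow_tree(cfg, 2L, seed = 51))
  for (mod in c("OCTA", "ICGA")) {
    noise <- modality_noise(mod)
    f1 <- render_modality(mask, noise, seed = 77)
    f2 <- render_modality(mask, noise, seed = 77)
    expect_identical(f1$pixels, f2$pixels)
    expect_gt(mean(f1$pixels[mask]), mean(f1$pixels[!mask]))
  }
})

test_that("default-config pre-treatment densities sit in the calibration band", {
  cfg <- simulation_config()
  lim <- list(cx = (cfg$canvas[2] - 1) / 2, cy = (cfg$canvas[1] - 1) / 2)
  radius <- cfg$limbus_radius_frac * (min(cfg$canvas) - 1) / 2
  roi <- disk_mask(cfg$canvas[1], cfg$canvas[2], c(lim$cx, lim$cy), radius)
  dens <- vapply(1:4, function(s) {
    m <- rasterize(grow_tree(cfg, 2L, seed = s))
    100 * sum(m & roi) / sum(roi)
  }, numeric(1))
  expect_true(all(dens >= 20 & dens <= 35))
})

test_that("generate_study produces consistent ground truth and schedules", {
  cfg <- test_config()
  dir <- withr::local_tempdir()
  st <- generate_study(cfg, dir, seed = 71)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_equal(nrow(st$manifest), 6 * 4 * 2 * 2)
  for (an in names(st$truth)) {
    tr <- st$truth[[an]]
    expect_equal(tr$true_growth_pct, diff(tr$true_density_pct), tolerance = 1e-12)
    if (tr$arm == "saline")
      expect_true(all(diff(tr$true_density_pct) > 0))
    if (tr$arm == "ranibizumab")
      expect_gt(tr$true_density_pct[4], tr$true_density_pct[3])
    if (tr$arm == "aflibercept")
      expect_lte(tr$true_density_pct[4], tr$true_density_pct[3])
  }
  # all manifest files exist and are readable
  expect_true(all(file.exists(st$manifest$file_path)))
})

test_that("generate_study is bit-reproducible under a fixed seed", {
  cfg <- test_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_study(cfg, d1, seed = 83)
  s2 <- generate_study(cfg, d2, seed = 83)
  expect_equal(lapply(s1$truth, `[`, c("true_density_pct", "pair_transforms")),
               lapply(s2$truth, `[`, c("true_density_pct", "pair_transforms")))
  f1 <- s1$manifest$file_path[1]
  f2 <- s2$manifest$file_path[1]
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
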