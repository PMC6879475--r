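#' Default simulated study design
#'
#' One animal per arm-by-route cell: two anti-VEGF-like arms and a saline
#' control, each delivered by sub-conjunctival injection or topical
#' instillation, right eyes only.
#'
#' @return A tibble with `animal_id`, `eye`, `arm`, `route`.
#' @export
default_study_design <- function() {
  tidyr::expand_grid(
    arm = c("saline", "aflibercept", "ranibizumab"),
    route = c("subconjunctival", "topical")
  ) |>
    dplyr::mutate(animal_id = sprintf("rabbit%02d", dplyr::row_number()),
                  eye = "OD") |>
    dplyr::select("animal_id", "eye", "arm", "route")
}

# Tree trajectory over four study weeks: two weeks of growth, then the
# arm-specific schedule (prune or regrow) for weeks 3 and 4.
simulate_trajectory <- function(config, arm, route) {
  trees <- vector("list", 4L)
  trees[[1]] <- grow_tree(config, weeks_of_growth = 1L)
  trees[[2]] <- {
    t2 <- trees[[1]]
    target <- row_radius(config, config$growth_extent[2])
    grow_walk(t2, config, target, max(t2$segments$birth_step))
  }
  for (wk in 3:4) {
    action <- config$schedule[[arm]][[route]][[as.character(wk)]]
    trees[[wk]] <- switch(action$type,
      prune = regress_tree(trees[[wk - 1]], action$fraction),
      grow = extend_tree(trees[[wk - 1]], config, action$target),
      stop_validation(paste0("unknown schedule action: ", action$type),
                      "vasctrack_validation_error"))
  }
  trees
}

random_pose <- function(config) {
  s <- config$max_shift_frac * min(config$canvas)
  rigid_transform(dx = stats::runif(1, -s, s), dy = stats::runif(1, -s, s),
                  rotation = stats::runif(1, -config$max_rot_deg, config$max_rot_deg))
}

#' Generate a ground-truthed synthetic longitudinal study
#'
#' Simulates the full four-week study for every animal in `design`: vessel
#' growth to week 2, then the arm-specific treatment response for weeks 3
#' and 4 (sustained regression, rebound regrowth, or continued control
#' growth). Each visit is rendered in both modalities and twice per
#' modality (replicates 1 and 2, identical vasculature and pose,
#' independent rendering noise) for repeatability testing. Between
#' consecutive visits the eye is repositioned by a small random rigid
#' transform; the moving-to-fixed transform of every consecutive pair is
#' recorded in the ground truth, together with per-visit true masks and
#' exact true densities.
#'
#' @param config A [simulation_config].
#' @param out_dir Output directory; images, the manifest CSV and a ground
#'   truth JSON are written beneath it.
#' @param design Study design tibble, see [default_study_design()].
#' @param seed Integer seed; the full output is reproducible bit for bit.
#' @return Invisibly, a list with `manifest` (tibble), `truth` (per-animal
#'   ground truth), `config` and `dir`.
#' @export
generate_study <- function(config = simulation_config(), out_dir,
                           design = default_study_design(), seed = 1L) {
  set.seed(seed)
  img_dir <- file.path(out_dir, "images")
  mask_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config$canvas[1]; w <- config$canvas[2]
  lim <- limbus_geometry(config)
  roi <- disk_mask(h, w, c(lim$cx, lim$cy), lim$radius)
  n_roi <- sum(roi)
  manifest <- list()
  truth <- list()
  for (i in seq_len(nrow(design))) {
    an <- design[i, ]
    trees <- simulate_trajectory(config, an$arm, an$route)
    masks <- lapply(trees, rasterize, canvas = config$canvas, roi = roi)
    dens <- vapply(masks, function(m) 100 * sum(m & roi) / n_roi, numeric(1))
    poses <- vector("list", 4L)
    poses[[1]] <- rigid_transform(0, 0, 0)
    for (v in 2:4) poses[[v]] <- random_pose(config)
    pair_tf <- lapply(1:3, function(t)
      compose_transforms(poses[[t]], invert_transform(poses[[t + 1]])))
    for (v in 1:4) {
      mv <- warp_mask(masks[[v]], poses[[v]])$mask
      mask_path <- file.path(mask_dir, sprintf("%s_w%d_mask.png", an$animal_id, v))
      write_image(mv * 1, mask_path)
      for (modality in c("OCTA", "ICGA")) {
        noise <- if (modality == "OCTA") config$octa_noise else config$icga_noise
        for (rep_ in 1:2) {
          frame <- render_modality(mv, noise, meta = list(
            modality = modality, animal_id = an$animal_id, eye = an$eye,
            week = v, arm = an$arm, route = an$route, replicate = rep_))
          fp <- file.path(img_dir, sprintf("%s_%s_w%d_r%d.png",
                                           an$animal_id, modality, v, rep_))
          write_image(frame, fp)
          manifest[[length(manifest) + 1L]] <- tibble::tibble(
            animal_id = an$animal_id, eye = an$eye, modality = modality,
            week = v, arm = an$arm, route = an$route, replicate = rep_,
            file_path = fp)
        }
      }
    }
    truth[[an$animal_id]] <- list(
      arm = an$arm, route = an$route,
      true_density_pct = dens,
      true_growth_pct = diff(dens),
      poses = lapply(poses, unclass),
      pair_transforms = lapply(pair_tf, unclass),
      mask_files = file.path(mask_dir,
                             sprintf("%s_w%d_mask.png", an$animal_id, 1:4)))
  }
  manifest <- dplyr::bind_rows(manifest) |>
    dplyr::arrange(.data$animal_id, .data$modality, .data$week, .data$replicate)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  jsonlite::write_json(
    list(seed = seed,
         roi = list(center = c(lim$cx, lim$cy), radius = lim$radius),
         animals = truth),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, truth = truth, config = config,
                 dir = out_dir,
                 roi = list(center = c(lim$cx, lim$cy), radius = lim$radius)))
}
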