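#' Pipeline configuration
#'
#' Validated bundle of per-stage parameters for [run_quantify]. The ROI is
#' a disk specified relative to the canvas (the corneal region inside the
#' limbal circle); it is placed on the first visit and then propagated to
#' later visits through the estimated registrations, so the denominator
#' follows the eye as it repositions between sessions.
#'
#' @param preprocess A [preprocess_params].
#' @param seg_octa,seg_icga [segmentation_params] per modality. Both
#'   default to a global Otsu support threshold (the seeded segmentation
#'   discards unseeded gradient components, see [segment_frame]);
#'   `local_mean` remains available for stronger background gradients.
#' @param roi_radius_frac ROI disk radius as a fraction of
#'   `min(canvas) - 1`.
#' @param score_floor Registration acceptance floor (normalized
#'   correlation).
#' @param max_rotation Registration rotation search half-range, degrees.
#' @param register_replicates Force registration of same-session
#'   replicates instead of assuming them pre-aligned.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_params(),
                            seg_octa = segmentation_params(method = "otsu_global"),
                            seg_icga = segmentation_params(method = "otsu_global"),
                            roi_radius_frac = 0.44,
                            score_floor = 0.2,
                            max_rotation = 10,
                            register_replicates = FALSE) {
  stopifnot(inherits(preprocess, "preprocess_params"),
            inherits(seg_octa, "segmentation_params"),
            inherits(seg_icga, "segmentation_params"),
            roi_radius_frac > 0, roi_radius_frac <= 0.5,
            score_floor >= -1, score_floor <= 1, max_rotation > 0)
  structure(list(preprocess = preprocess, seg_octa = seg_octa,
                 seg_icga = seg_icga, roi_radius_frac = roi_radius_frac,
                 score_floor = score_floor, max_rotation = max_rotation,
                 register_replicates = isTRUE(register_replicates)),
            class = "pipeline_config")
}

config_roi_geometry <- function(config, height, width) {
  list(center = c((width - 1) / 2, (height - 1) / 2),
       radius = config$roi_radius_frac * (min(height, width) - 1))
}

#' Quantify a longitudinal study
#'
#' End-to-end realization of the measurement pipeline for every animal and
#' modality in the manifest: preprocess all frames, register each
#' consecutive-week pair (week `t` fixed, week `t + 1` moving), segment
#' vessels within the propagated ROI, and compute the per-visit vessel
#' density, the per-interval vessel growth density on the common overlay
#' region, and the same-session repeatability error for every replicate
#' pair. Registration failures exclude the affected interval from the
#' results with a logged warning; they never abort the run.
#'
#' @param manifest A manifest tibble from [load_manifest] or
#'   [generate_study].
#' @param config A [pipeline_config].
#' @return A list of tibbles: `measurements` (one row per animal x
#'   modality x week with `vessel_density_pct`, and per interval the
#'   `growth_density_pct` assigned to the later week), `repeatability`
#'   (signed replicate differences per visit), `registrations` (per-pair
#'   transform parameters, score and status).
#' @export
run_quantify <- function(manifest, config = pipeline_config()) {
  groups <- manifest |>
    dplyr::distinct(.data$animal_id, .data$modality, .data$arm, .data$route)
  meas <- list(); rep_tab <- list(); reg_tab <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    sub <- manifest |>
      dplyr::filter(.data$animal_id == g$animal_id,
                    .data$modality == g$modality) |>
      dplyr::arrange(.data$week, .data$replicate)
    weeks <- sort(unique(sub$week))
    seg_params <- if (g$modality == "ICGA") config$seg_icga else config$seg_octa
    frames <- list()
    for (i in seq_len(nrow(sub))) {
      rec <- sub[i, ]
      fr <- read_image(rec$file_path, rec)
      frames[[paste(rec$week, rec$replicate)]] <-
        preprocess_frame(fr, config$preprocess)
    }
    first <- frames[[paste(weeks[1], min(sub$replicate))]]
    geom <- config_roi_geometry(config, first$height, first$width)
    # a rigid transform maps a disk to a disk, so the ROI is propagated
    # analytically: move the center through the estimated registrations
    # and redraw, avoiding raster-warp boundary erosion
    centers <- list()
    centers[[as.character(weeks[1])]] <- geom$center
    rois <- list()
    rois[[as.character(weeks[1])]] <-
      disk_mask(first$height, first$width, geom$center, geom$radius)
    regs <- list()
    for (t in seq_len(length(weeks) - 1)) {
      wa <- weeks[t]; wb <- weeks[t + 1]
      fixed <- frames[[paste(wa, 1)]]
      moving <- frames[[paste(wb, 1)]]
      reg <- tryCatch(
        register_pair(moving, fixed, max_rotation = config$max_rotation,
                      score_floor = config$score_floor),
        vasctrack_registration_failure = function(e) e,
        vasctrack_degenerate_image = function(e) e)
      if (inherits(reg, "condition")) {
        warning(sprintf("registration failed for %s %s weeks %d-%d: %s",
                        g$animal_id, g$modality, wa, wb, conditionMessage(reg)),
                call. = FALSE)
        reg_tab[[length(reg_tab) + 1L]] <- tibble::tibble(
          animal_id = g$animal_id, modality = g$modality,
          interval = sprintf("%d-%d", wa, wb), dx = NA_real_, dy = NA_real_,
          rotation = NA_real_, score = NA_real_, status = "failed")
        regs[[as.character(wb)]] <- NULL
        # ROI cannot be propagated past a failed registration; reuse the
        # previous ROI so later visits still get densities.
        centers[[as.character(wb)]] <- centers[[as.character(wa)]]
        rois[[as.character(wb)]] <- rois[[as.character(wa)]]
      } else {
        regs[[as.character(wb)]] <- reg
        ca <- centers[[as.character(wa)]]
        cb <- apply_transform_xy(ca[1], ca[2], reg$transform,
                                 fixed$height, fixed$width, inverse = TRUE)
        centers[[as.character(wb)]] <- c(cb$x, cb$y)
        rois[[as.character(wb)]] <-
          disk_mask(fixed$height, fixed$width, c(cb$x, cb$y), geom$radius)
        reg_tab[[length(reg_tab) + 1L]] <- tibble::tibble(
          animal_id = g$animal_id, modality = g$modality,
          interval = sprintf("%d-%d", wa, wb), dx = reg$transform$dx,
          dy = reg$transform$dy, rotation = reg$transform$rotation,
          score = reg$score, status = "ok")
      }
    }
    masks <- list()
    for (wk in weeks) {
      roi_w <- rois[[as.character(wk)]]
      reps_w <- sort(unique(sub$replicate[sub$week == wk]))
      for (rp in reps_w) {
        masks[[paste(wk, rp)]] <-
          segment_frame(frames[[paste(wk, rp)]], roi_w, seg_params)
      }
      d <- vessel_density(masks[[paste(wk, 1)]])
      meas[[length(meas) + 1L]] <- tibble::tibble(
        animal_id = g$animal_id, modality = g$modality, week = wk,
        arm = g$arm, route = g$route,
        vessel_density_pct = d$vessel_density_pct,
        growth_density_pct = NA_real_, interval = NA_character_)
      if (length(reps_w) >= 2) {
        err <- repeatability_error(masks[[paste(wk, reps_w[1])]],
                                   masks[[paste(wk, reps_w[2])]])
        rep_tab[[length(rep_tab) + 1L]] <- tibble::tibble(
          animal_id = g$animal_id, modality = g$modality, week = wk,
          arm = g$arm, route = g$route, repeatability_error_pct = err)
      }
    }
    for (t in seq_len(length(weeks) - 1)) {
      wb <- weeks[t + 1]
      reg <- regs[[as.character(wb)]]
      if (is.null(reg)) next
      gd <- growth_density(masks[[paste(weeks[t], 1)]],
                           masks[[paste(wb, 1)]], reg,
                           interval = c(weeks[t], wb))
      row <- which(vapply(meas, function(m)
        m$animal_id == g$animal_id && m$modality == g$modality &&
          m$week == wb, logical(1)))
      meas[[row]]$growth_density_pct <- gd$measurement$growth_density_pct
      meas[[row]]$interval <- gd$measurement$interval
    }
  }
  list(measurements = dplyr::bind_rows(meas) |>
         dplyr::arrange(.data$animal_id, .data$modality, .data$week),
       repeatability = dplyr::bind_rows(rep_tab),
       registrations = dplyr::bind_rows(reg_tab))
}

#' Between-modality agreement statistics
#'
#' Matches OCTA and ICGA growth densities of the same animal and interval
#' and computes Bland-Altman agreement, Pearson correlation and the paired
#' t-test, pooled and stratified by treatment arm.
#'
#' @param measurements The `measurements` tibble from [run_quantify].
#' @return A list: `pairs` (matched tibble), `pooled` (list with
#'   `bland_altman`, `correlation`, `paired_t`), `by_arm` (named list of
#'   per-arm `bland_altman` objects, arms with >= 3 pairs).
#' @export
run_compare_modalities <- function(measurements) {
  pairs <- measurements |>
    dplyr::filter(!is.na(.data$growth_density_pct)) |>
    dplyr::select("animal_id", "arm", "route", "interval", "modality",
                  "growth_density_pct") |>
    tidyr::pivot_wider(names_from = "modality",
                       values_from = "growth_density_pct") |>
    dplyr::filter(!is.na(.data$OCTA), !is.na(.data$ICGA))
  if (nrow(pairs) < 3)
    stop_validation(sprintf(
      "need at least 3 matched OCTA/ICGA pairs, got %d", nrow(pairs)),
      "vasctrack_sample_size_error")
  pooled <- list(
    bland_altman = bland_altman(pairs$OCTA, pairs$ICGA),
    correlation = pearson_correlation(pairs$OCTA, pairs$ICGA),
    paired_t = paired_t_test(pairs$OCTA, pairs$ICGA))
  by_arm <- list()
  for (a in unique(pairs$arm)) {
    pa <- pairs[pairs$arm == a, ]
    if (nrow(pa) >= 3)
      by_arm[[a]] <- bland_altman(pa$OCTA, pa$ICGA)
  }
  list(pairs = pairs, pooled = pooled, by_arm = by_arm)
}

#' Vessel density trend plot
#'
#' Density against study week, one line per animal, colored by arm and
#' faceted by route and modality.
#'
#' @param measurements The `measurements` tibble from [run_quantify].
#' @return A ggplot object.
#' @export
plot_trend <- function(measurements) {
  ggplot2::ggplot(measurements,
                  ggplot2::aes(x = .data$week, y = .data$vessel_density_pct,
                               color = .data$arm,
                               group = interaction(.data$animal_id, .data$modality))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$modality), ggplot2::vars(.data$route)) +
    ggplot2::labs(x = "Study week", y = "Vessel density (%)", color = "Arm") +
    ggplot2::theme_minimal()
}

#' Write the analysis report bundle
#'
#' Writes the measurement CSV, a density trend plot, pooled and per-arm
#' Bland-Altman plots, and a machine-readable JSON summary. With an empty
#' measurement table a valid report with explicit empty sections is still
#' written.
#'
#' @param results The list from [run_quantify].
#' @param comparison Optional list from [run_compare_modalities].
#' @param out_dir Output directory.
#' @return Invisibly, the path of the JSON summary.
#' @export
run_report <- function(results, comparison = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meas <- results$measurements
  summary <- list(n_measurements = nrow(meas))
  if (nrow(meas) > 0) {
    write_measurements(meas, file.path(out_dir, "measurements.csv"))
    p <- plot_trend(meas)
    ggplot2::ggsave(file.path(out_dir, "trend.png"), p, width = 7, height = 5,
                    dpi = 120)
    summary$densities_by_week <- meas |>
      dplyr::group_by(.data$arm, .data$route, .data$modality, .data$week) |>
      dplyr::summarise(mean_density_pct = mean(.data$vessel_density_pct),
                       .groups = "drop")
  } else {
    summary$note <- "no data"
  }
  if (!is.null(results$repeatability) && nrow(results$repeatability) > 0)
    summary$repeatability <- group_summary(
      results$repeatability$repeatability_error_pct)
  if (!is.null(comparison)) {
    ggplot2::ggsave(file.path(out_dir, "bland_altman_pooled.png"),
                    autoplot.bland_altman(comparison$pooled$bland_altman),
                    width = 6, height = 5, dpi = 120)
    summary$modality_agreement <- list(
      bland_altman = glance.bland_altman(comparison$pooled$bland_altman),
      correlation = comparison$pooled$correlation,
      paired_t = comparison$pooled$paired_t)
    for (a in names(comparison$by_arm)) {
      ggplot2::ggsave(file.path(out_dir, sprintf("bland_altman_%s.png", a)),
                      autoplot.bland_altman(comparison$by_arm[[a]]),
                      width = 6, height = 5, dpi = 120)
    }
  }
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(json_path)
}
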