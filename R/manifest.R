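manifest_columns <- c("animal_id", "eye", "modality", "week", "arm", "route",
                      "replicate", "file_path")

#' Load a study manifest
#'
#' Reads the manifest that organizes a longitudinal angiography study: one
#' row per acquired image, keyed by `(animal_id, modality, week, replicate)`.
#' Accepts CSV (header `animal_id,eye,modality,week,arm,route,replicate,
#' file_path`) or a JSON array of objects with the same fields. Records are
#' returned sorted by the key; duplicate keys and non-contiguous week
#' sequences are rejected.
#'
#' @param path Path to a `.csv` or `.json` manifest.
#' @return A tibble with the eight manifest columns, sorted by
#'   `(animal_id, modality, week, replicate)`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path))
    stop_validation(paste0("cannot read manifest: ", path), "vasctrack_io_error")
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing) > 0)
    stop_validation(paste0("manifest is missing required column(s): ",
                           paste(missing, collapse = ", ")),
                    "vasctrack_schema_error")
  df <- df |>
    dplyr::mutate(animal_id = as.character(.data$animal_id),
                  week = as.integer(.data$week),
                  replicate = as.integer(.data$replicate)) |>
    dplyr::select(dplyr::all_of(manifest_columns)) |>
    dplyr::arrange(.data$animal_id, .data$modality, .data$week, .data$replicate)
  dup <- df |>
    dplyr::count(.data$animal_id, .data$modality, .data$week, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    key <- dup[1, ]
    stop_validation(sprintf(
      "duplicate manifest key: (%s, %s, week %d, replicate %d)",
      key$animal_id, key$modality, key$week, key$replicate),
      "vasctrack_validation_error")
  }
  bad_weeks <- df |>
    dplyr::distinct(.data$animal_id, .data$modality, .data$week) |>
    dplyr::group_by(.data$animal_id, .data$modality) |>
    dplyr::summarise(contiguous = all(diff(sort(unique(.data$week))) == 1L),
                     .groups = "drop") |>
    dplyr::filter(!.data$contiguous)
  if (nrow(bad_weeks) > 0)
    stop_validation(paste0("weeks are not a contiguous ascending sequence for animal ",
                           bad_weeks$animal_id[1]),
                    "vasctrack_validation_error")
  df
}

#' Write a study manifest
#'
#' @param manifest A manifest tibble as returned by [load_manifest].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest[, manifest_columns], path, progress = FALSE)
  invisible(path)
}

#' Write a measurement table
#'
#' Writes per-visit vessel densities and per-interval growth densities as a
#' CSV with a fixed column order and percentages rounded to three decimals,
#' so a read-back reproduces every value to 3 decimals. Rows carrying an
#' out-of-range density abort before anything is written.
#'
#' @param table A measurement tibble with columns `animal_id`, `modality`,
#'   `week`, `arm`, `route`, `vessel_density_pct`, `growth_density_pct`,
#'   `interval`. `growth_density_pct` and `interval` may be `NA` on
#'   density-only rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  cols <- c("animal_id", "modality", "week", "arm", "route",
            "vessel_density_pct", "growth_density_pct", "interval")
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0)
    stop_validation(paste0("measurement table is missing column(s): ",
                           paste(missing, collapse = ", ")),
                    "vasctrack_schema_error")
  vd <- table$vessel_density_pct
  gd <- table$growth_density_pct
  if (any(!is.na(vd) & (vd < 0 | vd > 100)))
    stop_validation("vessel_density_pct outside [0, 100]", "vasctrack_validation_error")
  if (any(!is.na(gd) & (gd < -100 | gd > 100)))
    stop_validation("growth_density_pct outside [-100, 100]", "vasctrack_validation_error")
  out <- table[, cols]
  out$vessel_density_pct <- sprintf("%.3f", out$vessel_density_pct)
  out$growth_density_pct <- ifelse(is.na(gd), "", sprintf("%.3f", gd))
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read a measurement table written by [write_measurements]
#'
#' @param path CSV path.
#' @return A measurement tibble with numeric percentage columns.
#' @export
read_measurements <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    animal_id = readr::col_character(),
                    modality = readr::col_character(),
                    week = readr::col_integer(),
                    arm = readr::col_character(),
                    route = readr::col_character(),
                    vessel_density_pct = readr::col_double(),
                    growth_density_pct = readr::col_double(),
                    interval = readr::col_character()))
}
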