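#' Run the full endemism-interpolation pipeline
#'
#' Chains range summaries, per-category kernel surfaces, the standardized
#' consensus, isoline extraction and area delimitation in one call.
#'
#' @param occ An occurrence tibble (see [as_occurrences()]).
#' @param scheme A [category_scheme()], default the nine-class preset.
#' @param cell_size_deg Raster cell size in degrees, default 0.1.
#' @param levels Optional ascending isoline ladder, as fractions of the
#'   consensus maximum, default `c(0.05, 0.25, 0.5, 0.75)`.
#' @param level Delimitation threshold as a fraction of the consensus
#'   maximum, default 0.05 (the outer fuzzy boundary).
#' @param weights Optional per-category consensus weights.
#' @param grid Optional [grid_spec()]; default [default_grid()].
#' @param min_species,q Passed to [delimit_areas()].
#' @param sigma_ratio Passed to [influence_value()].
#' @return A `gie_result` list: `ranges`, `surfaces`, `consensus`,
#'   `isolines`, `areas`, `level` (absolute threshold used), `scheme`.
#' @examples
#' set.seed(1)
#' d <- generate_dataset(landscape_spec(n_centers = 2, species_per_center = 8,
#'                                      n_widespread = 0, seed = 7))
#' res <- gie_run(d$occurrences, cell_size_deg = 0.2)
#' glance(res)
#' @export
gie_run <- function(occ, scheme = scheme_preset("nine"), cell_size_deg = 0.1,
                    levels = c(0.05, 0.25, 0.5, 0.75), level = 0.05,
                    weights = NULL, grid = NULL, min_species = 1, q = 1,
                    sigma_ratio = 3) {
  ranges <- build_ranges(occ, scheme)
  grid <- grid %||% default_grid(ranges, cell_size_deg)
  surfaces <- build_all_surfaces(ranges, grid, sigma_ratio)
  consensus <- build_consensus(surfaces, weights)
  kmax <- max(consensus$values)
  iso <- extract_isolines(consensus, sort(levels) * kmax)
  areas <- delimit_areas(consensus, occ, level = level * kmax,
                         min_species = min_species, q = q)
  structure(list(
    ranges = ranges, surfaces = surfaces, consensus = consensus,
    isolines = iso, areas = areas, level = level * kmax, scheme = scheme
  ), class = "gie_result")
}

#' @export
print.gie_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<gie_result: %d species in %d categories; consensus max k = %.3f; ",
    "%d area(s) of endemism at level %.3f>\n"),
    nrow(x$ranges), length(x$surfaces), max(x$consensus$values),
    nrow(x$areas), x$level))
  invisible(x)
}

#' @export
tidy.gie_result <- function(x, ...) area_report(x$areas)

#' @export
glance.gie_result <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$ranges),
    n_categories = length(x$surfaces),
    max_k = max(x$consensus$values),
    level = x$level,
    n_areas = nrow(x$areas),
    max_synendemics = if (nrow(x$areas)) max(x$areas$n_synendemics) else 0L
  )
}

#' @export
autoplot.gie_result <- function(object, ...) {
  autoplot(object$consensus) +
    ggplot2::geom_path(
      data = object$isolines,
      ggplot2::aes(.data$lon, .data$lat,
                   group = interaction(.data$level, .data$ring)),
      colour = "white", linewidth = 0.3, inherit.aes = FALSE
    )
}

#' Write all pipeline outputs to a directory
#'
#' Writes the range summary CSV, per-category and consensus rasters
#' (plain-text ESRI ASCII), isolines and areas (GeoJSON), and the area
#' report (CSV).
#'
#' @param result A [gie_run()] result.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_gie_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ranges(result$ranges, file.path(dir, "ranges.csv"))
  for (nm in names(result$surfaces)) {
    write_surface_ascii(result$surfaces[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  write_surface_ascii(result$consensus, file.path(dir, "consensus.asc"))
  if (nrow(result$isolines) > 0) {
    write_isolines_geojson(result$isolines, file.path(dir, "isolines.geojson"))
  }
  write_areas_geojson(result$areas, file.path(dir, "areas.geojson"))
  readr::write_csv(area_report(result$areas), file.path(dir, "areas.csv"),
                   progress = FALSE)
  invisible(dir)
}
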