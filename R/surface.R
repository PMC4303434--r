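#' Define a raster grid
#'
#' A plain geographic lon/lat lattice. The eastern and northern bounds are
#' snapped outward so the extent is a whole number of cells. Values are held
#' row-major north-to-south (row 1 = northernmost cells).
#'
#' @param lon_min,lon_max,lat_min,lat_max Extent in decimal degrees.
#' @param cell_size_deg Cell size in degrees (> 0), default 0.1.
#' @return An object of class `gie_grid`.
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, cell_size_deg = 0.1) {
  if (!is.finite(cell_size_deg) || cell_size_deg <= 0) {
    abort("cell_size_deg must be > 0")
  }
  if (lon_max <= lon_min || lat_max <= lat_min) abort("Degenerate extent")
  ncol <- ceiling((lon_max - lon_min) / cell_size_deg - 1e-9)
  nrow <- ceiling((lat_max - lat_min) / cell_size_deg - 1e-9)
  structure(list(
    lon_min = lon_min, lon_max = lon_min + ncol * cell_size_deg,
    lat_min = lat_min, lat_max = lat_min + nrow * cell_size_deg,
    cell_size_deg = cell_size_deg, nrow = nrow, ncol = ncol
  ), class = "gie_grid")
}

#' @export
print.gie_grid <- function(x, ...) {
  cat(sprintf("<gie_grid %d x %d cells of %g deg, lon [%g, %g], lat [%g, %g]>\n",
              x$nrow, x$ncol, x$cell_size_deg,
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

# cell-center coordinate vectors; latitudes descend (row 1 is north)
grid_lon_centers <- function(grid) {
  grid$lon_min + (seq_len(grid$ncol) - 0.5) * grid$cell_size_deg
}
grid_lat_centers <- function(grid) {
  grid$lat_max - (seq_len(grid$nrow) - 0.5) * grid$cell_size_deg
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("lon_min", "lat_min", "cell_size_deg")],
                   unclass(b)[c("lon_min", "lat_min", "cell_size_deg")])) &&
    a$nrow == b$nrow && a$ncol == b$ncol
}

# row/col of the half-open cell [west, east) x [south, north) containing a
# point; NA outside the extent. Shared by area attribution and GridMatrix.
# Points exactly on the grid's own outer north/east boundary are kept in
# the outermost cell rather than dropped.
grid_cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$cell_size_deg) + 1
  row <- grid$nrow - floor((lat - grid$lat_min) / grid$cell_size_deg)
  row[lat == grid$lat_max] <- 1
  col[lon == grid$lon_max] <- grid$ncol
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Default grid for a set of ranges
#'
#' Extent covering all centroids, padded by the largest influence radius
#' (converted to degrees at the grid's mid-latitude) plus one cell.
#'
#' @param ranges Output of [build_ranges()].
#' @param cell_size_deg Cell size in degrees.
#' @return A [grid_spec()] object.
#' @export
default_grid <- function(ranges, cell_size_deg = 0.1) {
  r <- max(ranges$radius_km)
  mid_lat <- mean(range(ranges$centroid_lat))
  pad_lat <- r / .KM_PER_DEG + cell_size_deg
  pad_lon <- r / (.KM_PER_DEG * max(cos(mid_lat * pi / 180), 0.1)) + cell_size_deg
  grid_spec(min(ranges$centroid_lon) - pad_lon, max(ranges$centroid_lon) + pad_lon,
            min(ranges$centroid_lat) - pad_lat, max(ranges$centroid_lat) + pad_lat,
            cell_size_deg)
}

#' Gaussian influence of a species at a distance
#'
#' The area of influence decays from 1 at the centroid as a Gaussian with
#' sigma = radius / `sigma_ratio` and is truncated to exactly 0 beyond the
#' radius, so the circular area of influence is literal. With the default
#' `sigma_ratio = 3` the influence at the boundary is exp(-4.5) ~ 0.0111.
#'
#' @param dist_km Distance(s) from the centroid, km, >= 0.
#' @param radius_km Influence radius, km, > 0.
#' @param sigma_ratio Radius-to-sigma ratio, default 3.
#' @return Influence value(s) in `[0, 1]`.
#' @export
influence_value <- function(dist_km, radius_km, sigma_ratio = 3) {
  if (any(!is.finite(radius_km)) || any(radius_km <= 0)) {
    abort("radius_km must be > 0")
  }
  sigma <- radius_km / sigma_ratio
  v <- exp(-dist_km^2 / (2 * sigma^2))
  v[dist_km > radius_km] <- 0
  v
}

new_surface <- function(values, grid, category = NA_integer_, n_species = 0L,
                        class = "gie_surface") {
  structure(list(values = values, grid = grid, category = category,
                 n_species = n_species), class = class)
}

#' @export
print.gie_surface <- function(x, ...) {
  cat(sprintf("<%s: %d x %d cells, category %s, %d species, max k = %.4g>\n",
              class(x)[1], x$grid$nrow, x$grid$ncol,
              paste(x$category, collapse = "+"), sum(x$n_species),
              max(x$values)))
  invisible(x)
}

# add one species' truncated Gaussian field to `values` in place (returns
# the updated matrix); restricted to the bounding box of the truncation
# radius plus one cell diagonal, which is bit-identical to the full scan
# because the kernel is exactly 0 beyond the radius.
add_kernel <- function(values, grid, lon0, lat0, radius_km, sigma_ratio) {
  lat_c <- grid_lat_centers(grid)
  lon_c <- grid_lon_centers(grid)
  pad <- radius_km + sqrt(2) * grid$cell_size_deg * .KM_PER_DEG
  dlat <- pad / .KM_PER_DEG
  rows <- which(abs(lat_c - lat0) <= dlat)
  if (length(rows) == 0) return(values)
  coslat <- max(cos(lat0 * pi / 180), 1e-6)
  cols <- which(abs(lon_c - lon0) <= pad / (.KM_PER_DEG * coslat))
  if (length(cols) == 0) return(values)
  pts <- cbind(rep(lon_c[cols], each = length(rows)),
               rep(lat_c[rows], times = length(cols)))
  d <- geosphere::distHaversine(pts, c(lon0, lat0), r = .EARTH_RADIUS_KM)
  v <- influence_value(d, radius_km, sigma_ratio)
  values[rows, cols] <- values[rows, cols] + matrix(v, nrow = length(rows))
  values
}

#' Rasterize one range-size category
#'
#' Each cell's kernel index k is the sum over the category's species of the
#' truncated Gaussian influence at the great-circle distance between the
#' cell center and the species centroid. The map is linear in species:
#' adding a species adds its field.
#'
#' @param ranges [build_ranges()] rows, all sharing one category.
#' @param grid A [grid_spec()]; default [default_grid()] of the ranges.
#' @param sigma_ratio Radius-to-sigma ratio, see [influence_value()].
#' @return A `gie_surface`: values matrix (north-to-south rows), grid,
#'   category, n_species.
#' @export
rasterize_category <- function(ranges, grid = NULL, sigma_ratio = 3) {
  if (nrow(ranges) > 0 && dplyr::n_distinct(ranges$category) > 1) {
    abort("rasterize_category expects ranges from a single category")
  }
  grid <- grid %||% default_grid(ranges)
  values <- matrix(0, grid$nrow, grid$ncol)
  for (i in seq_len(nrow(ranges))) {
    values <- add_kernel(values, grid, ranges$centroid_lon[i],
                         ranges$centroid_lat[i], ranges$radius_km[i],
                         sigma_ratio)
  }
  cat_idx <- if (nrow(ranges)) ranges$category[1] else NA_integer_
  new_surface(values, grid, cat_idx, nrow(ranges))
}

#' Rasterize every populated category
#'
#' @param ranges Output of [build_ranges()] (all species).
#' @param grid Shared [grid_spec()]; default [default_grid()] of all ranges
#'   (the shared geometry is required by [build_consensus()]).
#' @param sigma_ratio Radius-to-sigma ratio.
#' @return A named list of `gie_surface` (class `gie_surfaces`), one per
#'   non-empty category; empty categories are noted and omitted.
#' @export
build_all_surfaces <- function(ranges, grid = NULL, sigma_ratio = 3) {
  scheme <- attr(ranges, "scheme")
  grid <- grid %||% default_grid(ranges)
  cats <- sort(unique(ranges$category))
  if (!is.null(scheme)) {
    empty <- setdiff(seq_along(scheme$breakpoints_km), cats)
    if (length(empty)) {
      inform(paste0("Categories with no species omitted: ",
                    paste(empty, collapse = ", ")))
    }
  }
  out <- lapply(cats, function(ci) {
    rasterize_category(ranges[ranges$category == ci, , drop = FALSE],
                       grid, sigma_ratio)
  })
  names(out) <- paste0("category_", cats)
  structure(out, class = "gie_surfaces", grid = grid)
}

#' @export
tidy.gie_surface <- function(x, ...) {
  tibble::tibble(
    lon = rep(grid_lon_centers(x$grid), each = x$grid$nrow),
    lat = rep(grid_lat_centers(x$grid), times = x$grid$ncol),
    k = as.vector(x$values)
  )
}

#' Write a surface as a plain-text grid (ESRI ASCII raster)
#'
#' Plain-text `.asc` raster (header + rows north to south), readable by
#' standard GIS software as a WGS84 lon/lat grid.
#'
#' @param surface A `gie_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_ascii <- function(surface, path) {
  g <- surface$grid
  hdr <- c(
    paste("ncols", g$ncol), paste("nrows", g$nrow),
    paste("xllcorner", g$lon_min), paste("yllcorner", g$lat_min),
    paste("cellsize", g$cell_size_deg), "NODATA_value -9999"
  )
  rows <- apply(surface$values, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a plain-text grid written by [write_surface_ascii()]
#'
#' @param path Path to an `.asc` raster.
#' @return A `gie_surface` (category/n_species unknown).
#' @export
read_surface_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], " +")
  val <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                  tolower(vapply(hdr, `[`, "", 1)))
  g <- grid_spec(val[["xllcorner"]],
                 val[["xllcorner"]] + val[["ncols"]] * val[["cellsize"]],
                 val[["yllcorner"]],
                 val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]],
                 val[["cellsize"]])
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), " +")[[1]])
  }))
  new_surface(m, g)
}

#' @export
autoplot.gie_surface <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$k)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "kernel index") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}
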