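#' Min–max standardize a kernel surface
#'
#' Rescales cell values to `[0, 1]` by `(v - min) / (max - min)` so that
#' categories with many species do not dominate the consensus. A constant
#' surface maps to all zeros. Scaling a surface by any positive constant
#' beforehand leaves the standardized output unchanged.
#'
#' @param surface A `gie_surface` (or bare numeric matrix).
#' @return The same type, values in `[0, 1]`.
#' @export
standardize <- function(surface) {
  v <- if (inherits(surface, "gie_surface")) surface$values else surface
  if (any(!is.finite(v))) abort("Surface has non-finite values")
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  if (inherits(surface, "gie_surface")) {
    surface$values <- v
    surface
  } else {
    v
  }
}

#' Assemble the consensus kernel-index map
#'
#' Each category surface is min–max standardized and the consensus is their
#' weighted sum. Unit weights (the default) give every spatial scale equal
#' say; raising the weight on one category emphasizes that scale in the
#' consensus (useful e.g. to prioritize restricted-range species).
#'
#' @param surfaces A `gie_surfaces` list (or plain list of `gie_surface`
#'   sharing one grid geometry).
#' @param weights Optional non-negative per-category multipliers, recycled
#'   names-free in surface order; default all 1.
#' @return A `gie_consensus` surface with `weights` and `categories` fields.
#' @export
build_consensus <- function(surfaces, weights = NULL) {
  if (length(surfaces) == 0) abort("No surfaces to combine")
  grid <- surfaces[[1]]$grid
  ok <- vapply(surfaces, function(s) same_grid(s$grid, grid), TRUE)
  if (!all(ok)) abort("Surfaces do not share one grid geometry")
  weights <- weights %||% rep(1, length(surfaces))
  if (length(weights) != length(surfaces) || any(weights < 0)) {
    abort("weights must be non-negative, one per surface")
  }
  values <- matrix(0, grid$nrow, grid$ncol)
  for (i in seq_along(surfaces)) {
    values <- values + weights[i] * standardize(surfaces[[i]])$values
  }
  out <- new_surface(values, grid,
                     category = vapply(surfaces, function(s) s$category, 1L),
                     n_species = sum(vapply(surfaces, function(s) s$n_species, 1L)),
                     class = c("gie_consensus", "gie_surface"))
  out$weights <- weights
  out
}

# contourLines wants ascending x/y with z[i, j] at (x[i], y[j]); our values
# are (lat desc) x (lon asc), so transpose and flip the latitude axis.
.contour_rings <- function(surface, levels) {
  g <- surface$grid
  z <- t(surface$values)[, g$nrow:1, drop = FALSE]
  cl <- grDevices::contourLines(grid_lon_centers(g), rev(grid_lat_centers(g)),
                                z, levels = levels)
  cl
}

#' Extract isolines of a consensus surface
#'
#' Level curves of the kernel index, computed by marching squares on the
#' raster (with linear sub-cell interpolation between cell centers). Nested
#' isolines express the hierarchy of areas of endemism across spatial
#' scales.
#'
#' @param consensus A `gie_consensus` (any `gie_surface` works).
#' @param levels Ascending positive thresholds, at most the surface maximum.
#' @return A `gie_isolines` tibble: `level`, `ring` (id within level),
#'   `lon`, `lat` vertex coordinates; zero rows when no level is crossed.
#' @export
extract_isolines <- function(consensus, levels) {
  if (length(levels) == 0) abort("levels must be non-empty")
  if (is.unsorted(levels)) abort("levels must be ascending")
  cl <- .contour_rings(consensus, levels)
  out <- purrr::imap(cl, function(cr, i) {
    tibble::tibble(level = cr$level, ring = i, lon = cr$x, lat = cr$y)
  }) |> purrr::list_rbind()
  if (nrow(out) == 0) {
    out <- tibble::tibble(level = numeric(), ring = integer(),
                          lon = numeric(), lat = numeric())
  } else {
    # re-number rings within each level
    out <- out |>
      dplyr::group_by(.data$level) |>
      dplyr::mutate(ring = match(.data$ring, unique(.data$ring))) |>
      dplyr::ungroup()
  }
  class(out) <- c("gie_isolines", class(out))
  out
}

# deterministic connected components (4-connectivity) of cells >= level;
# labels ordered west-to-east (ties: north first). Returns an integer
# matrix, 0 = below level.
label_components <- function(values, level) {
  n <- nrow(values)
  m <- ncol(values)
  mask <- values >= level
  lab <- matrix(0L, n, m)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  vid <- integer(n * m)
  vid[idx] <- seq_along(idx)
  edges <- NULL
  if (n > 1) {
    p <- which(mask[-n, , drop = FALSE] & mask[-1, , drop = FALSE])
    if (length(p)) {
      r <- (p - 1) %% (n - 1) + 1
      cc <- (p - 1) %/% (n - 1) + 1
      lin <- (cc - 1) * n + r
      edges <- rbind(edges, cbind(vid[lin], vid[lin + 1]))
    }
  }
  if (m > 1) {
    p <- which(mask[, -m, drop = FALSE] & mask[, -1, drop = FALSE])
    if (length(p)) {
      r <- (p - 1) %% n + 1
      cc <- (p - 1) %/% n + 1
      lin <- (cc - 1) * n + r
      edges <- rbind(edges, cbind(vid[lin], vid[lin + n]))
    }
  }
  g <- igraph::make_empty_graph(length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  lab[idx] <- memb
  # relabel west-to-east by each component's westmost (then northmost) cell
  ord <- tibble::tibble(
    comp = memb,
    row = (idx - 1) %% n + 1,
    col = (idx - 1) %/% n + 1
  ) |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(col = min(.data$col), row = min(.data$row), .groups = "drop") |>
    dplyr::arrange(.data$col, .data$row)
  relab <- integer(max(memb))
  relab[ord$comp] <- seq_len(nrow(ord))
  lab[idx] <- relab[memb]
  lab
}

# assign each contour ring at `level` to the component whose inside cell
# its vertices hug; returns integer vector, NA if unmatched
.ring_components <- function(rings, lab, grid) {
  n <- nrow(lab)
  vapply(rings, function(ring) {
    hits <- integer(0)
    for (k in seq_along(ring$x)) {
      ci <- grid_cell_index(grid, ring$x[k], ring$y[k])
      if (is.na(ci$row[1])) next
      for (dr in -1:1) for (dc in -1:1) {
        r <- ci$row[1] + dr
        cc <- ci$col[1] + dc
        if (r >= 1 && r <= n && cc >= 1 && cc <= ncol(lab) && lab[r, cc] > 0) {
          hits <- c(hits, lab[r, cc])
        }
      }
    }
    if (length(hits) == 0) NA_integer_ else as.integer(names(which.max(table(hits))))
  }, 1L)
}

#' Delimit areas of endemism at a threshold
#'
#' Connected raster components with consensus kernel index at or above
#' `level` (ties count as inside) become candidate areas. A species supports
#' an area when at least a fraction `q` of its records — by default all of
#' them, the strict synendemic reading — fall in cells of the component.
#' Areas with fewer than `min_species` such species are discarded. Areas
#' touching the grid border are kept but flagged as possibly truncated.
#'
#' @param consensus A `gie_consensus` surface.
#' @param occ The occurrence tibble the surface was built from.
#' @param level Threshold on the consensus; default 0.05 x its maximum (the
#'   outer fuzzy boundary). Nested sets come from calling this at an
#'   ascending ladder of levels, or from [extract_isolines()].
#' @param min_species Minimum synendemic species to keep an area, default 1.
#' @param q Fraction of a species' records that must fall inside, default 1.
#' @return A `gie_areas` tibble ordered west-to-east: `area_id`, `level`,
#'   `n_cells`, `peak_k`, `lon`, `lat` (component center of mass),
#'   `n_synendemics`, `touches_border`, `species` (list-column), `ring`
#'   (list-column of boundary vertex tibbles, possibly empty for sub-cell
#'   components). The component label matrix is attached as attribute
#'   `labels`, the grid as `grid`, the level as `level`.
#' @export
delimit_areas <- function(consensus, occ, level = NULL, min_species = 1, q = 1) {
  grid <- consensus$grid
  level <- level %||% (0.05 * max(consensus$values))
  if (!is.finite(level) || level <= 0) abort("level must be positive")
  lab <- label_components(consensus$values, level)
  k <- max(lab)
  empty <- tibble::tibble(
    area_id = character(), level = numeric(), n_cells = integer(),
    peak_k = numeric(), lon = numeric(), lat = numeric(),
    n_synendemics = integer(), touches_border = logical(),
    species = list(), ring = list()
  )
  if (k == 0) {
    return(structure(empty, class = c("gie_areas", class(empty)),
                     labels = lab, grid = grid, level = level))
  }
  lon_c <- grid_lon_centers(grid)
  lat_c <- grid_lat_centers(grid)

  # species -> component support at fraction q of records
  ci <- grid_cell_index(grid, occ$lon, occ$lat)
  rec_comp <- rep(0L, nrow(occ))
  inside <- !is.na(ci$row)
  rec_comp[inside] <- lab[cbind(ci$row[inside], ci$col[inside])]
  support <- tibble::tibble(species = occ$species, comp = rec_comp) |>
    dplyr::add_count(.data$species, name = "n_rec") |>
    dplyr::filter(.data$comp > 0) |>
    dplyr::count(.data$species, .data$comp, .data$n_rec, name = "n_in") |>
    dplyr::filter(.data$n_in >= q * .data$n_rec)

  rings <- .contour_rings(consensus, level)
  ring_comp <- .ring_components(rings, lab, grid)

  rows <- purrr::map(seq_len(k), function(a) {
    cells <- which(lab == a)
    r <- (cells - 1) %% grid$nrow + 1
    cc <- (cells - 1) %/% grid$nrow + 1
    sp <- sort(support$species[support$comp == a])
    a_rings <- rings[which(!is.na(ring_comp) & ring_comp == a)]
    ring_tbl <- purrr::imap(a_rings, function(rr, i) {
      tibble::tibble(ring = as.integer(i), lon = rr$x, lat = rr$y)
    }) |> purrr::list_rbind()
    if (is.null(ring_tbl)) {
      ring_tbl <- tibble::tibble(ring = integer(), lon = numeric(),
                                 lat = numeric())
    }
    tibble::tibble(
      level = level, n_cells = length(cells),
      peak_k = max(consensus$values[cells]),
      lon = mean(lon_c[cc]), lat = mean(lat_c[r]),
      n_synendemics = length(sp),
      touches_border = any(r == 1 | r == grid$nrow |
                             cc == 1 | cc == grid$ncol),
      species = list(sp), ring = list(ring_tbl)
    )
  }) |> purrr::list_rbind()
  keep <- rows$n_synendemics >= min_species
  relab <- integer(k)
  relab[which(keep)] <- seq_len(sum(keep))
  lab[lab > 0] <- relab[lab[lab > 0]]
  rows <- rows[keep, , drop = FALSE]
  rows <- dplyr::mutate(rows, area_id = sprintf("A%02d", dplyr::row_number()),
                        .before = 1)
  structure(rows, class = c("gie_areas", class(empty)),
            labels = lab, grid = grid, level = level)
}

#' Tabular report of delimited areas
#'
#' One row per area, ordered by (level, west-to-east), species lists sorted
#' and collapsed; ids are stable across reruns on the same inputs.
#'
#' @param areas A `gie_areas` result (or several row-bound via [rbind()]).
#' @return A plain tibble: `area_id`, `level`, `n_cells`, `peak_k`,
#'   `lon`, `lat`, `n_synendemics`, `touches_border`, `species`
#'   (semicolon-separated).
#' @export
area_report <- function(areas) {
  out <- tibble::as_tibble(areas) |>
    dplyr::mutate(species = vapply(.data$species, paste, "", collapse = ";")) |>
    dplyr::select(-"ring") |>
    dplyr::arrange(.data$level, .data$lon)
  out
}

#' @export
tidy.gie_areas <- function(x, ...) area_report(x)

#' @export
glance.gie_consensus <- function(x, ...) {
  tibble::tibble(
    n_categories = length(x$category), n_species = sum(x$n_species),
    max_k = max(x$values), mean_k = mean(x$values)
  )
}

#' @export
autoplot.gie_areas <- function(object, occ = NULL, ...) {
  rings <- tibble::as_tibble(object) |>
    dplyr::select("area_id", "ring") |>
    tidyr::unnest("ring")
  p <- ggplot2::ggplot()
  if (!is.null(occ)) {
    p <- p + ggplot2::geom_point(
      data = occ, ggplot2::aes(.data$lon, .data$lat),
      colour = "grey60", size = 0.4
    )
  }
  if (nrow(rings) > 0) {
    p <- p + ggplot2::geom_path(
      data = rings,
      ggplot2::aes(.data$lon, .data$lat,
                   group = interaction(.data$area_id, .data$ring),
                   colour = .data$area_id)
    )
  }
  p + ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = "Area") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gie_isolines <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$lon, .data$lat,
                               group = interaction(.data$level, .data$ring),
                               colour = factor(.data$level))) +
    ggplot2::geom_path() +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = "Level") +
    ggplot2::theme_minimal()
}

# GeoJSON writers ------------------------------------------------------------

.geojson_feature <- function(coords, properties) {
  list(type = "Feature", properties = properties,
       geometry = list(type = "Polygon", coordinates = coords))
}

.close_ring <- function(lon, lat) {
  if (lon[1] != lon[length(lon)] || lat[1] != lat[length(lat)]) {
    lon <- c(lon, lon[1])
    lat <- c(lat, lat[1])
  }
  lapply(seq_along(lon), function(i) c(lon[i], lat[i]))
}

#' Write delimited areas as GeoJSON
#'
#' Polygon features carrying `area_id`, `level`, `peak_k`, `n_synendemics`
#' and the synendemic species list. Areas whose component is smaller than a
#' raster cell carry no ring and are written as a point-like degenerate
#' polygon around the component center.
#'
#' @param areas A `gie_areas` result.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_areas_geojson <- function(areas, path) {
  half <- attr(areas, "grid")$cell_size_deg / 2
  feats <- purrr::map(seq_len(nrow(areas)), function(i) {
    ring <- areas$ring[[i]]
    coords <- if (nrow(ring) > 0) {
      lapply(split(ring, ring$ring), function(rr) .close_ring(rr$lon, rr$lat))
    } else {
      lon <- areas$lon[i] + c(-half, half, half, -half)
      lat <- areas$lat[i] + c(-half, -half, half, half)
      list(.close_ring(lon, lat))
    }
    .geojson_feature(coords, list(
      area_id = areas$area_id[i], level = areas$level[i],
      peak_k = areas$peak_k[i], n_synendemics = areas$n_synendemics[i],
      species = paste(areas$species[[i]], collapse = ";")
    ))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write isolines as GeoJSON
#'
#' @param isolines A `gie_isolines` tibble.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_isolines_geojson <- function(isolines, path) {
  feats <- isolines |>
    dplyr::group_by(.data$level, .data$ring) |>
    dplyr::group_map(function(g, key) {
      .geojson_feature(list(.close_ring(g$lon, g$lat)),
                       list(level = key$level, ring = key$ring))
    })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
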