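#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km. Vectorized
#' over all four coordinate vectors (recycled). One degree along a meridian
#' is 6371.0088 * pi / 180 = 111.1951 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in km; symmetric; zero iff the points coincide.
#' @examples
#' great_circle_km(0, 0, 0, 1) # 111.195
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM)
}

#' Range-size category schemes
#'
#' A category scheme is a strictly increasing vector of km breakpoints; class
#' 1 covers `[0, b1]` and class i > 1 covers `(b[i-1], b[i]]` (right-closed,
#' so a species exactly on a boundary stays in the smaller class — the larger
#' class's radius would overestimate the range of the more restricted
#' species). The class upper bound is the shared influence radius of every
#' species in the class.
#'
#' @param breakpoints_km Strictly increasing positive km breakpoints; the
#'   last is the largest range the scheme accepts.
#' @param labels Optional class labels; auto-generated when `NULL`.
#' @param name Optional scheme name.
#' @return An object of class `category_scheme`.
#' @seealso [scheme_preset()] for the standard 5/9/18-class schemes.
#' @export
category_scheme <- function(breakpoints_km, labels = NULL, name = "custom") {
  b <- as.numeric(breakpoints_km)
  if (length(b) < 1 || any(!is.finite(b)) || any(b <= 0) ||
      is.unsorted(b, strictly = TRUE)) {
    abort("breakpoints_km must be strictly increasing positive numbers")
  }
  if (is.null(labels)) {
    lo <- c(0, head(b, -1))
    labels <- ifelse(lo == 0, paste0("up to ", b, " km"),
                     paste0(lo, "–", b, " km"))
  }
  if (length(labels) != length(b)) abort("One label per breakpoint required")
  structure(list(breakpoints_km = b, labels = labels, name = name),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme '", x$name, "': ", length(x$breakpoints_km),
      " classes, max ", max(x$breakpoints_km), " km>\n", sep = "")
  invisible(x)
}

#' @describeIn category_scheme Standard presets: `"nine"` (50, 200, 400,
#'   600, 800, 1000, 1500, 2000, 3299 km — the default scheme), `"five"`
#'   (more inclusive) and `"eighteen"` (less inclusive).
#' @param preset One of `"nine"`, `"five"`, `"eighteen"`.
#' @export
scheme_preset <- function(preset = c("nine", "five", "eighteen")) {
  preset <- match.arg(preset)
  b <- switch(preset,
    nine = c(50, 200, 400, 600, 800, 1000, 1500, 2000, 3299),
    five = c(50, 400, 600, 800, 3299),
    eighteen = c(25, 50, 100, 200, 300, 400, 500, 600, 700, 800, 900,
                 1000, 1300, 1600, 1750, 2000, 2500, 3299)
  )
  category_scheme(b, name = preset)
}

#' Assign range-size categories
#'
#' @param max_dist_km Non-negative centroid-to-farthest-record distances.
#' @param scheme A [category_scheme()].
#' @return Integer class indices (1-based).
#' @export
assign_category <- function(max_dist_km, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  d <- as.numeric(max_dist_km)
  if (any(!is.finite(d)) || any(d < 0)) abort("Distances must be finite and >= 0")
  b <- scheme$breakpoints_km
  if (any(d > max(b))) {
    abort(paste0("Distance ", format(max(d)), " km exceeds the scheme's ",
                 "largest bound (", max(b), " km); extend the scheme"))
  }
  idx <- rowSums(outer(d, b, `>`)) + 1L
  as.integer(idx)
}

#' Per-species distribution centroids
#'
#' The centroid of a species distribution is the plain arithmetic mean of
#' the longitudes and latitudes of its records (no geodesic averaging). A
#' warning is emitted for species spanning more than 180 degrees of
#' longitude, where the arithmetic mean is not meaningful.
#'
#' @param occ An occurrence tibble.
#' @return A tibble `species`, `n_records`, `centroid_lon`, `centroid_lat`.
#' @export
compute_centroid <- function(occ) {
  if (nrow(occ) == 0) abort("Empty occurrence table")
  out <- occ |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      centroid_lon = mean(.data$lon),
      centroid_lat = mean(.data$lat),
      lon_span = diff(range(.data$lon)),
      .groups = "drop"
    )
  if (any(out$lon_span > 180)) {
    warn(paste0(sum(out$lon_span > 180), " species span > 180 degrees of ",
                "longitude; arithmetic-mean centroids are unreliable there"))
  }
  out$lon_span <- NULL
  out
}

#' Centroid-to-farthest-record distance
#'
#' @param occ An occurrence tibble.
#' @param centroids Optional precomputed [compute_centroid()] output.
#' @return `centroids` with a `max_dist_km` column: the maximum great-circle
#'   distance from the centroid to any record (0 for singletons).
#' @export
max_range_distance <- function(occ, centroids = NULL) {
  cen <- centroids %||% compute_centroid(occ)
  d <- occ |>
    dplyr::inner_join(cen, by = "species") |>
    dplyr::mutate(dist_km = great_circle_km(.data$lon, .data$lat,
                                            .data$centroid_lon, .data$centroid_lat)) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(max_dist_km = max(.data$dist_km), .groups = "drop")
  dplyr::left_join(cen, d, by = "species")
}

#' Build per-species range summaries
#'
#' Runs the first three interpolation steps for every species: centroid,
#' farthest-record distance, range-size category under `scheme`, and the
#' influence radius (the class upper bound, shared by all species in the
#' class).
#'
#' @param occ An occurrence tibble.
#' @param scheme A [category_scheme()]; default the nine-class preset.
#' @return A tibble with one row per species: `species`, `n_records`,
#'   `centroid_lon`, `centroid_lat`, `max_dist_km`, `category`,
#'   `category_label`, `radius_km`; the scheme is attached as attribute
#'   `scheme`.
#' @export
build_ranges <- function(occ, scheme = scheme_preset("nine")) {
  out <- max_range_distance(occ) |>
    dplyr::mutate(
      category = assign_category(.data$max_dist_km, scheme),
      category_label = scheme$labels[.data$category],
      radius_km = scheme$breakpoints_km[.data$category]
    )
  attr(out, "scheme") <- scheme
  out
}

#' Write range summaries as CSV
#'
#' @param ranges Output of [build_ranges()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranges <- function(ranges, path) {
  readr::write_csv(ranges, path, progress = FALSE)
  invisible(path)
}
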