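# Independent oracles, kept free of the package's own code paths.

# scalar haversine straight from the formula
oracle_haversine <- function(lon1, lat1, lon2, lat2, R = 6371.0088) {
  to <- pi / 180
  a <- sin((lat2 - lat1) * to / 2)^2 +
    cos(lat1 * to) * cos(lat2 * to) * sin((lon2 - lon1) * to / 2)^2
  2 * R * asin(pmin(sqrt(a), 1))
}

# brute-force kernel raster: plain double loop over cells x species
oracle_kernel_raster <- function(grid, lon, lat, radius_km, sigma_ratio = 3) {
  lon_c <- grid$lon_min + (seq_len(grid$ncol) - 0.5) * grid$cell_size_deg
  lat_c <- grid$lat_max - (seq_len(grid$nrow) - 0.5) * grid$cell_size_deg
  vals <- matrix(0, grid$nrow, grid$ncol)
  for (i in seq_len(grid$nrow)) {
    for (j in seq_len(grid$ncol)) {
      k <- 0
      for (s in seq_along(lon)) {
        d <- oracle_haversine(lon_c[j], lat_c[i], lon[s], lat[s])
        if (d <= radius_km[s]) {
          sigma <- radius_km[s] / sigma_ratio
          k <- k + exp(-d^2 / (2 * sigma^2))
        }
      }
      vals[i, j] <- k
    }
  }
  vals
}

# union-find connected components of the graph with edges d <= gap_km
oracle_single_linkage <- function(lon, lat, gap_km) {
  n <- length(lon)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (oracle_haversine(lon[i], lat[i], lon[j], lat[j]) <= gap_km) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# tiny occurrence fixture builder
occ_fixture <- function(species, lon, lat) {
  suppressMessages(as_occurrences(
    tibble::tibble(species = species, lon = lon, lat = lat)
  ))
}

# two well-separated planted clusters of restricted species (fixed layout)
two_cluster_fixture <- function(n_per = 5, seed = 11) {
  set.seed(seed)
  centers <- rbind(c(-50, -10), c(-44, -10)) # ~660 km apart
  rows <- purrr::map(1:2, function(ctr) {
    purrr::map(seq_len(n_per), function(s) {
      n <- 4
      tibble::tibble(
        species = sprintf("c%d_sp%d", ctr, s),
        lon = centers[ctr, 1] + rnorm(n, 0, 0.1),
        lat = centers[ctr, 2] + rnorm(n, 0, 0.1)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  suppressMessages(as_occurrences(rows))
}

KM_PER_DEG <- 6371.0088 * pi / 180
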