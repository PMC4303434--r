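#' Specify a synthetic endemism landscape
#'
#' Describes a landscape with K planted endemic centers — clusters of
#' co-occurring restricted-range species — plus widespread species spanning
#' the whole extent, with a long-tailed record-count profile (many species
#' known from a single record). The defaults emulate a continental spider
#' database profile: 40% singleton species, 45% with 2–15 records, 10%
#' with 16–60, 3% with 61–100 and 2% with more than 100; endemic records
#' scattered within 25 km of their center, which keeps every planted
#' species inside the smallest range-size class of the nine-class scheme
#' (record-to-centroid distance is bounded by twice the scatter radius,
#' i.e. 50 km).
#'
#' @param extent Named list or vector `lon_min, lon_max, lat_min, lat_max`;
#'   default a 20 x 20 degree continental window.
#' @param n_centers Number of planted endemic centers (K), default 5.
#' @param center_positions Optional 2-column matrix/data.frame of explicit
#'   center lon/lat; otherwise drawn with a minimum-separation rule.
#' @param species_per_center Endemic species per center, default 30.
#' @param n_widespread Widespread species spanning the extent, default 15.
#' @param within_center_radius_km Hard scatter radius of endemic records
#'   about their center, km; default 25.
#' @param min_separation_factor Minimum pairwise center separation as a
#'   multiple of `within_center_radius_km` when centers are auto-placed;
#'   default 8 (= 4 x the 50 km class radius at the default scatter).
#' @param singleton_fraction Fraction of species with exactly one record,
#'   default 0.4.
#' @param count_bin_probs Probabilities of the record-count bins
#'   (1, 2–15, 16–60, 61–100, >100); the first entry is
#'   `singleton_fraction`.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(extent = c(lon_min = -60, lon_max = -40,
                                      lat_min = -25, lat_max = -5),
                           n_centers = 5, center_positions = NULL,
                           species_per_center = 30, n_widespread = 15,
                           within_center_radius_km = 25,
                           min_separation_factor = 8,
                           singleton_fraction = 0.4,
                           count_bin_probs = c(singleton_fraction,
                                               0.45, 0.10, 0.03, 0.02),
                           seed = 1L) {
  if (singleton_fraction < 0 || singleton_fraction > 1) {
    abort("singleton_fraction must be in [0, 1]")
  }
  count_bin_probs <- count_bin_probs / sum(count_bin_probs)
  structure(list(
    extent = as.list(extent), n_centers = n_centers,
    center_positions = center_positions,
    species_per_center = species_per_center, n_widespread = n_widespread,
    within_center_radius_km = within_center_radius_km,
    min_separation_factor = min_separation_factor,
    singleton_fraction = singleton_fraction,
    count_bin_probs = count_bin_probs, seed = seed
  ), class = "landscape_spec")
}

# draw a record count from the long-tailed bin profile
.draw_counts <- function(n, probs) {
  bin <- sample.int(5, n, replace = TRUE, prob = probs)
  vapply(bin, function(b) {
    switch(b,
      1L,
      sample(2:15, 1, prob = 0.7^(0:13)),   # geometric-like within 2-15
      sample(16:60, 1),
      sample(61:100, 1),
      sample(101:150, 1)
    )
  }, 1L)
}

# isotropic truncated-Gaussian scatter (sigma = radius/2, hard-truncated at
# the radius) about a center, in km, mapped to degrees at the center
.scatter <- function(n, lon0, lat0, radius_km) {
  sigma <- radius_km / 2
  out <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  while (length(need)) {
    dx <- rnorm(length(need), 0, sigma)
    dy <- rnorm(length(need), 0, sigma)
    ok <- sqrt(dx^2 + dy^2) <= radius_km
    out[need[ok], ] <- cbind(dx[ok], dy[ok])
    need <- need[!ok]
  }
  cbind(lon = lon0 + out[, 1] / (.KM_PER_DEG * cos(lat0 * pi / 180)),
        lat = lat0 + out[, 2] / .KM_PER_DEG)
}

.place_centers <- function(spec) {
  if (!is.null(spec$center_positions)) {
    cp <- as.matrix(spec$center_positions)
    if (nrow(cp) != spec$n_centers) abort("center_positions/n_centers mismatch")
    return(cp)
  }
  ext <- spec$extent
  min_sep <- spec$min_separation_factor * spec$within_center_radius_km
  # keep centers away from the border by the scatter radius
  pad_lat <- spec$within_center_radius_km / .KM_PER_DEG
  mid_lat <- (ext$lat_min + ext$lat_max) / 2
  pad_lon <- pad_lat / cos(mid_lat * pi / 180)
  for (attempt in 1:200) {
    lon <- runif(spec$n_centers, ext$lon_min + pad_lon, ext$lon_max - pad_lon)
    lat <- runif(spec$n_centers, ext$lat_min + pad_lat, ext$lat_max - pad_lat)
    if (spec$n_centers == 1) return(cbind(lon, lat))
    d <- great_circle_km(rep(lon, each = spec$n_centers), rep(lat, each = spec$n_centers),
                         rep(lon, times = spec$n_centers), rep(lat, times = spec$n_centers))
    d <- matrix(d, spec$n_centers)
    diag(d) <- Inf
    if (min(d) >= min_sep) return(cbind(lon, lat))
  }
  abort("Could not place centers with the required separation; enlarge the extent")
}

#' Generate a synthetic occurrence dataset with planted ground truth
#'
#' Endemic species' records are scattered (truncated Gaussian, sigma =
#' radius/2, hard-truncated at the radius) about their planted center;
#' widespread species' records are uniform over the extent; record counts
#' follow the long-tailed profile of the spec (singletons get exactly one
#' record). Identical spec + seed reproduces the table bit-for-bit.
#'
#' @param spec A [landscape_spec()].
#' @return A list: `occurrences` (validated occurrence tibble), `truth`
#'   (tibble `species`, `center` id — `"widespread"` for extent-wide
#'   species — and center coordinates), `centers` (tibble of planted
#'   center positions).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  centers <- .place_centers(spec)
  ext <- spec$extent
  n_end <- spec$n_centers * spec$species_per_center
  n_sp <- n_end + spec$n_widespread
  wide <- max(nchar(n_sp), 3)
  rows <- vector("list", n_sp)
  truth <- vector("list", n_sp)
  idx <- 0
  for (ctr in seq_len(spec$n_centers)) {
    counts <- .draw_counts(spec$species_per_center, spec$count_bin_probs)
    for (s in seq_len(spec$species_per_center)) {
      idx <- idx + 1
      sp_id <- sprintf("end%0*d", wide, idx)
      xy <- .scatter(counts[s], centers[ctr, 1], centers[ctr, 2],
                     spec$within_center_radius_km)
      rows[[idx]] <- tibble::tibble(species = sp_id,
                                    lon = xy[, 1], lat = xy[, 2])
      truth[[idx]] <- tibble::tibble(
        species = sp_id, center = as.character(ctr),
        center_lon = centers[ctr, 1], center_lat = centers[ctr, 2]
      )
    }
  }
  if (spec$n_widespread > 0) {
    for (s in seq_len(spec$n_widespread)) {
      idx <- idx + 1
      sp_id <- sprintf("wid%0*d", wide, idx)
      n_rec <- sample(10:30, 1)
      rows[[idx]] <- tibble::tibble(
        species = sp_id,
        lon = runif(n_rec, ext$lon_min, ext$lon_max),
        lat = runif(n_rec, ext$lat_min, ext$lat_max)
      )
      truth[[idx]] <- tibble::tibble(species = sp_id, center = "widespread",
                                     center_lon = NA_real_, center_lat = NA_real_)
    }
  }
  occ <- suppressMessages(as_occurrences(purrr::list_rbind(rows)))
  list(
    occurrences = occ,
    truth = purrr::list_rbind(truth),
    centers = tibble::tibble(center = as.character(seq_len(spec$n_centers)),
                             lon = centers[, 1], lat = centers[, 2])
  )
}

#' Perturb an occurrence table
#'
#' Jitters coordinates isotropically (Gaussian, sd `jitter_km` in a local
#' km projection) and drops a random fraction of records; supports
#' robustness experiments against sampling noise. Reproducible from `seed`.
#'
#' @param occ An occurrence tibble.
#' @param jitter_km Jitter standard deviation in km, default 0.
#' @param drop_fraction Fraction of records removed at random, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A perturbed occurrence tibble (species losing all their records
#'   disappear from the table).
#' @export
perturb_dataset <- function(occ, jitter_km = 0, drop_fraction = 0, seed = 1L) {
  if (jitter_km < 0) abort("jitter_km must be >= 0")
  if (drop_fraction < 0 || drop_fraction >= 1) abort("drop_fraction in [0, 1)")
  if (jitter_km == 0 && drop_fraction == 0) return(occ)
  set.seed(seed)
  out <- occ
  if (drop_fraction > 0) {
    n_rm <- round(drop_fraction * nrow(out))
    if (n_rm > 0) out <- out[-sample.int(nrow(out), n_rm), , drop = FALSE]
  }
  if (jitter_km > 0) {
    out$lon <- out$lon + rnorm(nrow(out), 0, jitter_km) /
      (.KM_PER_DEG * cos(out$lat * pi / 180))
    out$lat <- out$lat + rnorm(nrow(out), 0, jitter_km) / .KM_PER_DEG
    out$lat <- pmin(pmax(out$lat, -90), 90)
  }
  out
}
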