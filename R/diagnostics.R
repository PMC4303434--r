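#' Centroid stability under rarefaction
#'
#' Quantifies how sensitive each species' distribution centroid is to
#' sampling effort: for each removal fraction, a fraction of the species'
#' records is removed at random (without replacement), the centroid is
#' recomputed, and the great-circle displacement from the original centroid
#' is recorded over `n_reps` randomizations. Per-species removal counts are
#' `round(fraction * n_records)`, floored at 1 for `fraction > 0`; species
#' with a single record are skipped (removing their only record is
#' undefined). A `"global"` mode instead removes the fraction from the
#' pooled table each replicate.
#'
#' @param occ An occurrence tibble.
#' @param fractions Removal fractions in `[0, 1)`, default `c(0.1, 0.2, 0.3)`.
#' @param n_reps Randomizations per fraction, default 100.
#' @param seed Integer seed; same seed gives bit-identical results.
#' @param mode `"per_species"` (default) or `"global"`.
#' @return A tibble: `species`, `n_records`, `removal_fraction`,
#'   `n_removed` (per-species mode), `mean_displacement_km`,
#'   `var_displacement_km2`, `n_replicates`.
#' @export
rarefy_centroids <- function(occ, fractions = c(0.1, 0.2, 0.3), n_reps = 100,
                             seed = 1L, mode = c("per_species", "global")) {
  mode <- match.arg(mode)
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (any(fractions < 0 | fractions >= 1)) abort("fractions must be in [0, 1)")
  cen <- compute_centroid(occ)
  eligible <- cen$species[cen$n_records >= 2]
  if (length(eligible) == 0) abort("No species with >= 2 records")
  set.seed(seed)
  if (mode == "per_species") {
    recs <- split(occ[c("lon", "lat")], occ$species)
    out <- purrr::map(sort(eligible), function(sp) {
      xy <- recs[[sp]]
      n <- nrow(xy)
      c0 <- c(mean(xy$lon), mean(xy$lat))
      purrr::map(fractions, function(f) {
        n_rm <- if (f == 0) 0L else max(1L, round(f * n))
        disp <- vapply(seq_len(n_reps), function(r) {
          keep <- if (n_rm == 0) seq_len(n) else -sample.int(n, n_rm)
          great_circle_km(mean(xy$lon[keep]), mean(xy$lat[keep]), c0[1], c0[2])
        }, 1)
        tibble::tibble(
          species = sp, n_records = n, removal_fraction = f, n_removed = n_rm,
          mean_displacement_km = mean(disp),
          var_displacement_km2 = if (n_reps > 1) var(disp) else 0,
          n_replicates = n_reps
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  } else {
    n_tot <- nrow(occ)
    out <- purrr::map(fractions, function(f) {
      n_rm <- if (f == 0) 0L else max(1L, round(f * n_tot))
      disp <- purrr::map(seq_len(n_reps), function(r) {
        keep <- if (n_rm == 0) seq_len(n_tot) else -sample.int(n_tot, n_rm)
        sub <- occ[keep, , drop = FALSE]
        compute_centroid(sub) |>
          dplyr::inner_join(cen, by = "species", suffix = c("", ".orig")) |>
          dplyr::transmute(
            species = .data$species,
            d = great_circle_km(.data$centroid_lon, .data$centroid_lat,
                                .data$centroid_lon.orig, .data$centroid_lat.orig)
          )
      }) |> purrr::list_rbind()
      disp |>
        dplyr::filter(.data$species %in% eligible) |>
        dplyr::group_by(.data$species) |>
        dplyr::summarise(
          removal_fraction = f,
          mean_displacement_km = mean(.data$d),
          var_displacement_km2 = if (dplyr::n() > 1) var(.data$d) else 0,
          n_replicates = dplyr::n(), .groups = "drop"
        ) |>
        dplyr::left_join(cen[c("species", "n_records")], by = "species") |>
        dplyr::relocate("n_records", .after = "species")
    }) |> purrr::list_rbind()
  }
  out
}

#' Frequency distribution of centroid displacements
#'
#' Bins species by their mean rarefaction displacement and by its variance,
#' per removal fraction. Bins are right-closed, with 0 in the first bin.
#'
#' @param results Output of [rarefy_centroids()].
#' @param bin_km Bin width for the mean displacement, km; default 50.
#' @param bin_km2 Bin width for the variance, km^2; default `bin_km^2`.
#' @return A tibble: `removal_fraction`, `metric` (`"mean"` / `"variance"`),
#'   `bin` (label), `lower`, `upper`, `n_species`. Counts per fraction and
#'   metric sum to the number of species analyzed.
#' @export
displacement_histogram <- function(results, bin_km = 50, bin_km2 = bin_km^2) {
  if (nrow(results) == 0) abort("Empty rarefaction results")
  bin1 <- function(x, w) {
    b <- pmax(ceiling(x / w), 1)
    tibble::tibble(lower = (b - 1) * w, upper = b * w)
  }
  one <- function(x, w, metric) {
    results |>
      dplyr::mutate(bin1(.data[[x]], w)) |>
      dplyr::count(.data$removal_fraction, .data$lower, .data$upper,
                   name = "n_species") |>
      dplyr::mutate(metric = metric,
                    bin = paste0("(", .data$lower, ", ", .data$upper, "]"))
  }
  dplyr::bind_rows(
    one("mean_displacement_km", bin_km, "mean"),
    one("var_displacement_km2", bin_km2, "variance")
  ) |>
    dplyr::select("removal_fraction", "metric", "bin", "lower", "upper",
                  "n_species") |>
    dplyr::arrange(.data$removal_fraction, .data$metric, .data$lower)
}

# local equirectangular projection to km offsets about (lon0, lat0);
# adequate at range scale, avoids CRS machinery
.local_km <- function(lon, lat, lon0, lat0) {
  cbind(x = (lon - lon0) * cos(lat0 * pi / 180) * .KM_PER_DEG,
        y = (lat - lat0) * .KM_PER_DEG)
}

#' Elongation screening of species distributions
#'
#' The circular area of influence over-generalizes species whose records
#' describe an elongated polygon. The elongation index is the square root of
#' the ratio of the largest to the smallest eigenvalue of the 2x2 covariance
#' of the records in a local km projection about the centroid — the aspect
#' ratio of the best-fitting dispersion ellipse (1 = isotropic). Collinear
#' and two-record species have a degenerate minor axis and are capped at
#' `cap` and flagged; species with fewer than 2 records get `NA`.
#'
#' @param occ An occurrence tibble (any number of species).
#' @param threshold Flagging threshold on the index, default 3.
#' @param cap Sentinel value for degenerate (collinear) sets, default 100.
#' @return A tibble: `species`, `n_records`, `elongation`, `degenerate`,
#'   `flagged` (`elongation >= threshold` or degenerate).
#' @export
elongation_index <- function(occ, threshold = 3, cap = 100) {
  if (nrow(occ) == 0) abort("Empty occurrence table")
  occ |>
    dplyr::group_by(.data$species) |>
    dplyr::group_map(function(g, key) {
      n <- nrow(g)
      if (n < 2) {
        return(tibble::tibble(species = key$species, n_records = n,
                              elongation = NA_real_, degenerate = NA,
                              flagged = NA))
      }
      xy <- .local_km(g$lon, g$lat, mean(g$lon), mean(g$lat))
      ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
      degen <- ev[2] <= 1e-12 * max(ev[1], 1e-12)
      e <- if (degen) cap else min(sqrt(ev[1] / ev[2]), cap)
      tibble::tibble(species = key$species, n_records = n, elongation = e,
                     degenerate = degen, flagged = degen | e >= threshold)
    }) |>
    purrr::list_rbind()
}

#' Detect disjoint species distributions
#'
#' Single-linkage clustering of each species' records with merge distance
#' `gap_km`: two records join a cluster when some chain of records links
#' them with successive great-circle gaps at or below `gap_km`. Species
#' whose records form more than one cluster have disjoint distributions; a
#' single circular area of influence then spans empty range, so such
#' species can be split (`split = TRUE`) into one pseudo-species per
#' cluster — each cluster gets its own centroid and range, letting the same
#' species support different areas of endemism.
#'
#' @param occ An occurrence tibble.
#' @param gap_km Linkage threshold in km.
#' @param split If `TRUE`, return the table with species relabelled
#'   `"<species>|<cluster>"` for multi-cluster species, ready for
#'   [build_ranges()]. Default `FALSE`.
#' @return `occ` with an integer `cluster` column (per species); with
#'   `split = TRUE`, also a relabelled `species` column (original kept as
#'   `species_full`).
#' @export
detect_disjoint <- function(occ, gap_km, split = FALSE) {
  if (!is.finite(gap_km) || gap_km <= 0) abort("gap_km must be > 0")
  out <- occ |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(function(g, key) {
      n <- nrow(g)
      if (n == 1) {
        g$cluster <- 1L
        return(g)
      }
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        j <- (i + 1):n
        d[i, j] <- d[j, i] <- great_circle_km(g$lon[i], g$lat[i], g$lon[j], g$lat[j])
      }
      hc <- hclust(as.dist(d), method = "single")
      g$cluster <- as.integer(cutree(hc, h = gap_km))
      g
    }) |>
    dplyr::ungroup()
  if (split) {
    out <- out |>
      dplyr::group_by(.data$species) |>
      dplyr::mutate(
        species_full = .data$species,
        species = if (dplyr::n_distinct(.data$cluster) > 1) {
          paste0(.data$species, "|", .data$cluster)
        } else {
          .data$species
        }
      ) |>
      dplyr::ungroup()
  }
  out
}

#' Pearson correlation between two kernel surfaces
#'
#' `"cellwise"` pairs every raster cell (deterministic). `"sampled"`
#' reproduces the coarse-grid protocol used for cross-method congruence:
#' the shared extent is tiled with `grid_cell_deg` cells, `n_points_per_cell`
#' uniform random points estimate the mean kernel index of each coarse cell
#' on each surface, and the per-cell means are correlated.
#'
#' @param surface_a,surface_b Two `gie_surface`s; cellwise mode requires
#'   identical grid geometry.
#' @param mode `"cellwise"` (default) or `"sampled"`.
#' @param grid_cell_deg Coarse cell size for sampled mode, default 2.
#' @param n_points_per_cell Random points per coarse cell, default 10.
#' @param seed Seed for sampled mode.
#' @return Pearson r in `[-1, 1]` (exactly 1 for identical surfaces).
#' @export
map_correlation <- function(surface_a, surface_b,
                            mode = c("cellwise", "sampled"),
                            grid_cell_deg = 2, n_points_per_cell = 10,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "cellwise") {
    if (!same_grid(surface_a$grid, surface_b$grid)) {
      abort("cellwise mode requires identical grid geometry")
    }
    a <- as.vector(surface_a$values)
    b <- as.vector(surface_b$values)
    if (length(a) < 3) abort("Fewer than 3 pairs")
    if (identical(a, b)) return(1)
    return(cor(a, b))
  }
  ga <- surface_a$grid
  gb <- surface_b$grid
  lon_rng <- c(max(ga$lon_min, gb$lon_min), min(ga$lon_max, gb$lon_max))
  lat_rng <- c(max(ga$lat_min, gb$lat_min), min(ga$lat_max, gb$lat_max))
  if (diff(lon_rng) <= 0 || diff(lat_rng) <= 0) abort("Extents do not overlap")
  coarse <- grid_spec(lon_rng[1], lon_rng[2], lat_rng[1], lat_rng[2],
                      grid_cell_deg)
  sample_cell_mean <- function(s, lon, lat) {
    ci <- grid_cell_index(s$grid, lon, lat)
    v <- rep(NA_real_, length(lon))
    ok <- !is.na(ci$row)
    v[ok] <- s$values[cbind(ci$row[ok], ci$col[ok])]
    v
  }
  set.seed(seed)
  pairs <- purrr::map(seq_len(coarse$nrow * coarse$ncol), function(cell) {
    r <- (cell - 1) %% coarse$nrow + 1
    cc <- (cell - 1) %/% coarse$nrow + 1
    lon <- coarse$lon_min + (cc - 1 + runif(n_points_per_cell)) * grid_cell_deg
    lat <- coarse$lat_max - (r - 1 + runif(n_points_per_cell)) * grid_cell_deg
    tibble::tibble(a = mean(sample_cell_mean(surface_a, lon, lat), na.rm = TRUE),
                   b = mean(sample_cell_mean(surface_b, lon, lat), na.rm = TRUE))
  }) |> purrr::list_rbind() |>
    dplyr::filter(is.finite(.data$a), is.finite(.data$b))
  if (nrow(pairs) < 3) abort("Fewer than 3 pairs")
  if (identical(pairs$a, pairs$b)) return(1)
  cor(pairs$a, pairs$b)
}

#' Compare consensus maps across categorization schemes
#'
#' Runs the full interpolation per scheme on one shared grid and correlates
#' every pair of consensus surfaces. High off-diagonal r means the choice of
#' range-size classes hardly moves the areas of endemism.
#'
#' @param occ An occurrence tibble.
#' @param schemes A named (or unnamed) list of [category_scheme()]s, >= 2.
#' @param cell_size_deg Grid cell size, default 0.1.
#' @param grid Optional shared [grid_spec()]; default sized to the scheme
#'   with the largest radius.
#' @param mode Passed to [map_correlation()], default `"cellwise"`.
#' @return A symmetric correlation matrix with unit diagonal, with the
#'   consensus surfaces attached as attribute `consensus`.
#' @export
compare_schemes <- function(occ, schemes, cell_size_deg = 0.1, grid = NULL,
                            mode = "cellwise") {
  if (length(schemes) < 2) abort("Need at least 2 schemes")
  nm <- names(schemes) %||% paste0("scheme", seq_along(schemes))
  nm[nm == ""] <- paste0("scheme", which(nm == ""))
  all_ranges <- lapply(schemes, function(s) build_ranges(occ, s))
  if (is.null(grid)) {
    widest <- which.max(vapply(all_ranges, function(r) max(r$radius_km), 1))
    grid <- default_grid(all_ranges[[widest]], cell_size_deg)
  }
  cons <- lapply(all_ranges, function(r) {
    build_consensus(build_all_surfaces(r, grid))
  })
  k <- length(cons)
  m <- diag(1, k)
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- map_correlation(cons[[i]], cons[[j]], mode = mode)
    }
  }
  attr(m, "consensus") <- setNames(cons, nm)
  m
}

#' Presence/absence grid matrix
#'
#' Binary species-by-cell incidence over a rectangular lon/lat grid: a
#' species is present in a cell iff at least one record falls in it. Cells
#' are half-open (`[west, east) x [south, north)`), so a record on a shared
#' edge belongs to exactly one cell. This is the input other grid-based
#' endemicity methods (parsimony analysis of endemism, NDM) start from.
#'
#' @param occ An occurrence tibble.
#' @param cell_deg Cell size in degrees, default 2.
#' @param grid Optional [grid_spec()]; default covers all records.
#' @return A `gie_grid_matrix`: integer 0/1 matrix with cells as rows
#'   (`r<row>c<col>` names) and species as columns; attributes `grid` and
#'   `cells` (tibble of cell ids, row/col, center coordinates). Only cells
#'   containing at least one record are kept.
#' @export
build_grid_matrix <- function(occ, cell_deg = 2, grid = NULL) {
  if (!is.finite(cell_deg) || cell_deg <= 0) abort("cell_deg must be > 0")
  grid <- grid %||% grid_spec(min(occ$lon), max(occ$lon) + cell_deg * 1e-6,
                              min(occ$lat), max(occ$lat) + cell_deg * 1e-6,
                              cell_deg)
  ci <- grid_cell_index(grid, occ$lon, occ$lat)
  ok <- !is.na(ci$row)
  inc <- tibble::tibble(
    species = occ$species[ok],
    cell = sprintf("r%02dc%02d", ci$row[ok], ci$col[ok]),
    row = ci$row[ok], col = ci$col[ok]
  ) |> dplyr::distinct()
  cells <- inc |>
    dplyr::distinct(.data$cell, .data$row, .data$col) |>
    dplyr::arrange(.data$row, .data$col) |>
    dplyr::mutate(
      lon = grid$lon_min + (.data$col - 0.5) * grid$cell_size_deg,
      lat = grid$lat_max - (.data$row - 0.5) * grid$cell_size_deg
    )
  species <- sort(unique(occ$species))
  m <- matrix(0L, nrow(cells), length(species),
              dimnames = list(cells$cell, species))
  m[cbind(match(inc$cell, cells$cell), match(inc$species, species))] <- 1L
  structure(m, class = c("gie_grid_matrix", class(m)),
            grid = grid, cells = cells)
}

#' @export
tidy.gie_grid_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    setNames(c("cell", "species", "present")) |>
    dplyr::mutate(present = as.integer(.data$present)) |>
    tibble::as_tibble()
}

#' Write a grid matrix as CSV
#'
#' @param gm A `gie_grid_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_matrix_csv <- function(gm, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(gm)), rownames = "cell")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a grid matrix as a TNT/NEXUS-style block
#'
#' Cells are terminals and species are binary characters, the layout
#' parsimony programs expect. With `root = TRUE` a hypothetical all-absent
#' cell (`ROOT`) is prepended so trees can be rooted on it.
#'
#' @param gm A `gie_grid_matrix`.
#' @param path Output path.
#' @param root Prepend the all-absent hypothetical root row? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_grid_matrix_tnt <- function(gm, path, root = TRUE) {
  m <- unclass(gm)
  taxa <- rownames(m)
  rows <- apply(m, 1, paste, collapse = "")
  if (root) {
    taxa <- c("ROOT", taxa)
    rows <- c(strrep("0", ncol(m)), rows)
  }
  lines <- c(
    "xread",
    "'presence/absence of species over grid cells'",
    paste(ncol(m), length(taxa)),
    paste(formatC(taxa, width = max(nchar(taxa)) + 2, flag = "-"), rows),
    ";"
  )
  writeLines(lines, path)
  invisible(path)
}
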