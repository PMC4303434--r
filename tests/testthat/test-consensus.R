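make_surface <- function(values, grid) {
  s <- rasterize_category(tibble::tibble(
    species = character(), n_records = integer(), centroid_lon = numeric(),
    centroid_lat = numeric(), max_dist_km = numeric(), category = integer(),
    category_label = character(), radius_km = numeric()
  ), grid)
  s$values <- values
  s$n_species <- 1L
  s
}

test_that("min-max standardization follows the formula and its degeneracies", {
  g <- grid_spec(0, 3, 0, 1, 1)
  s <- make_surface(matrix(c(2, 4, 6), 1), g)
  expect_equal(standardize(s)$values, matrix(c(0, 0.5, 1), 1))
  s$values <- matrix(c(3, 3, 3), 1)
  expect_equal(standardize(s)$values, matrix(0, 1, 3))
  # scale invariance
  set.seed(2)
  v <- matrix(runif(12), 3)
  expect_equal(standardize(7 * v), standardize(v))
})

test_that("consensus is the weighted sum of standardized surfaces", {
  g <- grid_spec(0, 4, 0, 3, 1)
  set.seed(4)
  a <- make_surface(matrix(runif(12, 0, 5), 3), g)
  b <- make_surface(matrix(runif(12, 0, 9), 3), g)

  both <- build_consensus(list(a, a))
  expect_equal(both$values, 2 * standardize(a)$values)

  drop_b <- build_consensus(list(a, b), weights = c(1, 0))
  expect_equal(drop_b$values, standardize(a)$values)

  w <- build_consensus(list(a, b), weights = c(1, 2))
  # brute-force cell loop
  want <- matrix(0, 3, 4)
  sa <- standardize(a)$values
  sb <- standardize(b)$values
  for (i in 1:3) for (j in 1:4) want[i, j] <- sa[i, j] + 2 * sb[i, j]
  expect_equal(w$values, want)

  g2 <- grid_spec(0, 4, 0, 3, 0.5)
  expect_error(build_consensus(list(a, make_surface(matrix(0, 6, 8), g2))),
               "grid geometry")
  expect_error(build_consensus(list(a, b), weights = c(1, -1)), "weights")
})

test_that("scaling any raw category surface leaves the consensus unchanged", {
  occ <- two_cluster_fixture()
  r <- build_ranges(occ)
  s <- suppressMessages(build_all_surfaces(r))
  c1 <- build_consensus(s)
  s_scaled <- s
  s_scaled[[1]]$values <- 7 * s_scaled[[1]]$values
  c2 <- build_consensus(s_scaled)
  expect_equal(c1$values, c2$values, tolerance = 1e-12)
})

test_that("isolines of one species approximate the analytic half-max circle", {
  occ <- occ_fixture("s", -45, -10)
  r <- build_ranges(occ) # radius 50 km, sigma = 50/3
  grid <- grid_spec(-46, -44, -11, -9, 0.02)
  cons <- build_consensus(build_all_surfaces(r, grid))
  iso <- extract_isolines(cons, 0.5 * max(cons$values))
  expect_gt(nrow(iso), 0)
  expect_equal(dplyr::n_distinct(iso$ring), 1)
  radii <- great_circle_km(iso$lon, iso$lat, -45, -10)
  analytic <- (50 / 3) * sqrt(2 * log(2))
  cell_km <- 0.02 * KM_PER_DEG
  expect_true(all(abs(radii - analytic) < cell_km))
})

test_that("isoline extraction handles empty and multi-ring cases", {
  occ <- two_cluster_fixture()
  cons <- build_consensus(suppressMessages(build_all_surfaces(
    build_ranges(occ), default_grid(build_ranges(occ), 0.1)
  )))
  above <- extract_isolines(cons, max(cons$values) * 1.5)
  expect_equal(nrow(above), 0)
  low <- extract_isolines(cons, 0.1 * max(cons$values))
  expect_equal(dplyr::n_distinct(paste(low$level, low$ring)), 2)
  expect_error(extract_isolines(cons, numeric()), "non-empty")
  expect_error(extract_isolines(cons, c(2, 1)), "ascending")
})

test_that("two planted clusters are delimited with their full species sets", {
  occ <- two_cluster_fixture(n_per = 5, seed = 11)
  res <- gie_run(occ, cell_size_deg = 0.1)
  areas <- res$areas
  expect_equal(nrow(areas), 2)
  expect_equal(areas$n_synendemics, c(5, 5))
  # west-to-east ordering: cluster 1 is at lon -50, cluster 2 at -44
  expect_true(all(startsWith(areas$species[[1]], "c1_")))
  expect_true(all(startsWith(areas$species[[2]], "c2_")))
  expect_true(all(areas$peak_k > 0))
})

test_that("a species with records in two areas supports neither (totality)", {
  occ <- two_cluster_fixture(n_per = 4, seed = 12)
  straddler <- tibble::tibble(species = "straddler",
                              lon = c(-50, -44), lat = c(-10, -10))
  occ2 <- suppressMessages(as_occurrences(dplyr::bind_rows(occ, straddler)))
  res <- gie_run(occ, cell_size_deg = 0.1)
  areas <- delimit_areas(res$consensus, occ2, level = res$level)
  expect_equal(nrow(areas), 2)
  expect_false("straddler" %in% unlist(areas$species))
  # relaxed attribution assigns it to every area holding >= half its records
  relaxed <- delimit_areas(res$consensus, occ2, level = res$level, q = 0.5)
  expect_true("straddler" %in% unlist(relaxed$species))
})

test_that("a level just below the peak delimits a single area", {
  occ <- occ_fixture(c("a", "a", "b"), c(-45.002, -45.004, -45.003),
                     c(-10.002, -10.001, -10))
  res <- gie_run(occ, cell_size_deg = 0.02, level = 0.95)
  expect_equal(nrow(res$areas), 1)
  expect_equal(res$areas$n_synendemics, 2)
})

test_that("areas nest and synendemic counts never grow with the level", {
  occ <- two_cluster_fixture(n_per = 6, seed = 13)
  r <- build_ranges(occ)
  cons <- build_consensus(suppressMessages(build_all_surfaces(r)))
  kmax <- max(cons$values)
  ladder <- c(0.05, 0.25, 0.5, 0.75) * kmax
  prev_lab <- NULL
  prev_areas <- NULL
  for (lev in ladder) {
    ar <- delimit_areas(cons, occ, level = lev)
    lab <- attr(ar, "labels")
    if (!is.null(prev_lab)) {
      # containment: every cell above the higher level was above the lower
      expect_true(all(prev_lab[lab > 0] > 0))
      # per-area monotonicity: an area's support never exceeds that of the
      # containing lower-level area
      for (i in seq_len(nrow(ar))) {
        cells <- which(lab == i)
        parent <- unique(prev_lab[cells])
        expect_length(parent, 1)
        expect_lte(ar$n_synendemics[i],
                   prev_areas$n_synendemics[parent])
      }
    }
    prev_lab <- lab
    prev_areas <- ar
  }
})

test_that("area reports are deterministic, ordered and complete", {
  empty <- delimit_areas(
    build_consensus(suppressMessages(build_all_surfaces(
      build_ranges(occ_fixture("s", -45, -10))
    ))),
    occ_fixture("s", -45, -10), level = 1e6, min_species = 0
  )
  rep0 <- area_report(empty)
  expect_equal(nrow(rep0), 0)
  expect_true(all(c("area_id", "level", "peak_k", "n_synendemics", "species")
                  %in% names(rep0)))

  occ <- two_cluster_fixture()
  res1 <- gie_run(occ, cell_size_deg = 0.1)
  res2 <- gie_run(occ, cell_size_deg = 0.1)
  expect_identical(area_report(res1$areas), area_report(res2$areas))
  expect_equal(area_report(res1$areas)$area_id, c("A01", "A02"))
  expect_false(is.unsorted(area_report(res1$areas)$lon))
})
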