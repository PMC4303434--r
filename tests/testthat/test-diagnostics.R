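test_that("rarefaction displacement is zero in degenerate settings", {
  # all records at one location (validation would collapse these, so the
  # tibble is built directly)
  occ <- tibble::tibble(species = "a", lon = rep(-45, 5), lat = rep(-10, 5))
  res <- rarefy_centroids(occ, fractions = c(0.1, 0.3), n_reps = 10, seed = 1)
  expect_true(all(res$mean_displacement_km == 0))
  # removal count 0 at fraction 0
  occ2 <- occ_fixture(c("a", "a", "a"), c(-45, -45.2, -45.4), c(-10, -10, -10))
  res0 <- rarefy_centroids(occ2, fractions = 0, n_reps = 5, seed = 1)
  expect_equal(res0$n_removed, 0L)
  expect_true(all(res0$mean_displacement_km == 0))
})

test_that("rarefaction skips singletons, floors removal at one record", {
  occ <- occ_fixture(c("solo", "a", "a", "a", "a"),
                     c(0, -45, -45.1, -45.2, -45.3), c(0, -10, -10, -10, -10))
  res <- rarefy_centroids(occ, fractions = 0.1, n_reps = 5, seed = 2)
  expect_false("solo" %in% res$species)
  expect_equal(res$n_removed, 1L) # round(0.1 * 4) = 0, floored to 1
})

test_that("rarefaction is bit-reproducible from the seed", {
  d <- generate_dataset(landscape_spec(n_centers = 2, species_per_center = 10,
                                       n_widespread = 0, seed = 31))
  a <- rarefy_centroids(d$occurrences, n_reps = 20, seed = 99)
  b <- rarefy_centroids(d$occurrences, n_reps = 20, seed = 99)
  expect_identical(a, b)
  c2 <- rarefy_centroids(d$occurrences, n_reps = 20, seed = 100)
  expect_false(identical(a, c2))
})

test_that("displacement grows with removal fraction on a record-rich ring", {
  # 100 records uniform on a 1-degree ring
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  occ <- occ_fixture(rep("ring", 100), -45 + cos(th), -10 + sin(th))
  res <- rarefy_centroids(occ, fractions = c(0.1, 0.2, 0.3), n_reps = 100,
                          seed = 7)
  m <- res$mean_displacement_km[order(res$removal_fraction)]
  expect_lt(m[1], 0.2 * KM_PER_DEG) # far below the ring radius (~111 km)
  expect_true(all(diff(m) > -1)) # non-decreasing within Monte-Carlo error
})

test_that("global-mode rarefaction runs and is reproducible", {
  d <- generate_dataset(landscape_spec(n_centers = 2, species_per_center = 8,
                                       n_widespread = 0, seed = 5))
  a <- rarefy_centroids(d$occurrences, fractions = 0.2, n_reps = 5, seed = 3,
                        mode = "global")
  b <- rarefy_centroids(d$occurrences, fractions = 0.2, n_reps = 5, seed = 3,
                        mode = "global")
  expect_identical(a, b)
  expect_true(all(a$mean_displacement_km >= 0))
})

test_that("displacement histograms tally species exactly", {
  res <- tibble::tibble(
    species = c("a", "b"), n_records = c(5, 5), removal_fraction = 0.1,
    n_removed = 1L, mean_displacement_km = c(10, 70),
    var_displacement_km2 = c(1, 2), n_replicates = 10L
  )
  h <- displacement_histogram(res, bin_km = 50)
  hm <- h[h$metric == "mean", ]
  expect_equal(hm$n_species, c(1L, 1L))
  expect_equal(hm$lower, c(0, 50))

  # all-zero displacements land in the first bin
  res0 <- dplyr::mutate(res, mean_displacement_km = 0)
  h0 <- displacement_histogram(res0, bin_km = 50)
  expect_equal(h0$n_species[h0$metric == "mean"], 2L)

  # totals always match a direct tally
  set.seed(8)
  resr <- tibble::tibble(
    species = paste0("s", 1:40), n_records = 10, removal_fraction = 0.1,
    n_removed = 1L, mean_displacement_km = runif(40, 0, 400),
    var_displacement_km2 = runif(40, 0, 1000), n_replicates = 10L
  )
  hr <- displacement_histogram(resr, bin_km = 100)
  for (met in c("mean", "variance")) {
    expect_equal(sum(hr$n_species[hr$metric == met]), 40)
  }
  hm <- hr[hr$metric == "mean", ]
  direct <- table(cut(resr$mean_displacement_km, seq(0, 400, 100),
                      include.lowest = TRUE))
  expect_equal(hm$n_species, as.integer(direct[direct > 0]),
               ignore_attr = TRUE)
})

test_that("elongation index is 1 for a square, capped for collinear sets", {
  occ <- occ_fixture(rep("sq", 4), c(-45, -45, -44, -44), c(-10, -9, -10, -9))
  e <- elongation_index(occ)
  expect_equal(e$elongation, 1, tolerance = 0.02) # square is isotropic
  expect_false(e$flagged)

  line <- occ_fixture(rep("ln", 5), seq(-45, -44, length.out = 5), rep(-10, 5))
  e2 <- elongation_index(line)
  expect_equal(e2$elongation, 100)
  expect_true(e2$degenerate)
  expect_true(e2$flagged)

  two <- occ_fixture(rep("tw", 2), c(-45, -44), c(-10, -9))
  e3 <- elongation_index(two)
  expect_true(e3$degenerate)

  solo <- occ_fixture("s", -45, -10)
  expect_true(is.na(elongation_index(solo)$elongation))
})

test_that("elongation recovers the aspect ratio of a 3:1 ellipse", {
  set.seed(17)
  n <- 200
  r <- sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  x <- 3 * r * cos(th) # degrees, equator-ish, so km scale is uniform
  y <- r * sin(th)
  occ <- occ_fixture(rep("el", n), x - 45, y - 1)
  e <- elongation_index(occ)
  expect_equal(e$elongation, 3, tolerance = 0.1)
  expect_true(e$flagged) # threshold default 3
})

test_that("disjunction detection matches a union-find oracle", {
  # two tight clusters 1000 km apart
  occ <- occ_fixture(rep("d", 6),
                     c(-50, -50.1, -50.05, -41, -41.1, -41.05),
                     rep(-10, 6))
  expect_equal(dplyr::n_distinct(detect_disjoint(occ, 200)$cluster), 2)
  expect_equal(dplyr::n_distinct(detect_disjoint(occ, 2000)$cluster), 1)

  for (seed in 1:5) {
    set.seed(seed)
    occ <- occ_fixture(rep("r", 20), runif(20, -55, -40), runif(20, -20, -5))
    gap <- runif(1, 100, 600)
    got <- detect_disjoint(occ, gap)$cluster
    want <- oracle_single_linkage(occ$lon, occ$lat, gap)
    # same partition, label-permutation aside
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
  }
})

test_that("split mode yields per-cluster pseudo-species for range building", {
  occ <- occ_fixture(rep("d", 4), c(-50, -50.1, -41, -41.1), rep(-10, 4))
  sp <- detect_disjoint(occ, 200, split = TRUE)
  expect_setequal(unique(sp$species), c("d|1", "d|2"))
  r <- build_ranges(sp)
  expect_equal(nrow(r), 2)
  expect_true(all(r$radius_km == 50)) # each cluster is restricted again
})

test_that("map correlation honours its exact bounds and identities", {
  occ <- two_cluster_fixture()
  cons <- build_consensus(suppressMessages(build_all_surfaces(build_ranges(occ))))
  expect_identical(map_correlation(cons, cons), 1)
  flipped <- cons
  flipped$values <- max(cons$values) - cons$values
  expect_equal(map_correlation(cons, flipped), -1)
  # independent white noise is uncorrelated
  g <- grid_spec(0, 40, 0, 25, 1)
  set.seed(41)
  rs <- lapply(1:2, function(i) {
    s <- cons
    s$grid <- g
    s$values <- matrix(rnorm(1000), 25)
    s
  })
  expect_lt(abs(map_correlation(rs[[1]], rs[[2]])), 0.1)
  expect_true(abs(map_correlation(rs[[1]], rs[[2]])) <= 1)
})

test_that("sampled-mode correlation reproduces the coarse-cell protocol", {
  occ <- two_cluster_fixture()
  cons <- build_consensus(suppressMessages(build_all_surfaces(build_ranges(occ))))
  r1 <- map_correlation(cons, cons, mode = "sampled", grid_cell_deg = 2,
                        n_points_per_cell = 10, seed = 5)
  expect_equal(r1, 1)
  a <- map_correlation(cons, cons, mode = "sampled", seed = 6)
  b <- map_correlation(cons, cons, mode = "sampled", seed = 6)
  expect_identical(a, b)
})

test_that("scheme comparison is symmetric with unit diagonal", {
  occ <- two_cluster_fixture()
  m <- compare_schemes(occ, list(a = scheme_preset("nine"),
                                 b = scheme_preset("nine")),
                       cell_size_deg = 0.2)
  expect_equal(unname(diag(m)), c(1, 1))
  expect_equal(m[1, 2], 1) # identical schemes, identical consensus
  expect_equal(m, t(m))
})

test_that("grid matrix incidences match hand enumeration", {
  # one species, one record
  gm1 <- build_grid_matrix(occ_fixture("a", -45.5, -10.5), cell_deg = 2)
  expect_equal(sum(gm1), 1)

  # 3 species on a 2x2-degree grid over [0,4) x [0,4):
  #   s1 in the NW and SE cells, s2 in the NW cell twice (one incidence),
  #   s3 exactly on the shared edge lon=2 -> east cell only
  occ <- occ_fixture(
    c("s1", "s1", "s2", "s2", "s3"),
    c(0.5, 3.5, 1.0, 1.2, 2.0),
    c(3.5, 0.5, 3.8, 3.9, 3.0)
  )
  gm <- build_grid_matrix(occ, cell_deg = 2, grid = grid_spec(0, 4, 0, 4, 2))
  m <- unclass(gm)
  expect_equal(sum(m), 4)
  expect_equal(m["r01c01", "s1"], 1L) # NW
  expect_equal(m["r02c02", "s1"], 1L) # SE
  expect_equal(m["r01c01", "s2"], 1L)
  expect_equal(m["r01c02", "s3"], 1L) # east cell of the shared edge

  # a record on a shared horizontal edge belongs to the northern cell
  # (south-inclusive): lat = 2 is the south edge of the top row
  occn <- occ_fixture("n", 1, 2)
  gmn <- build_grid_matrix(occn, cell_deg = 2, grid = grid_spec(0, 4, 0, 4, 2))
  expect_equal(rownames(unclass(gmn)), "r01c01")
})

test_that("grid matrix marginals match direct record tallies", {
  set.seed(9)
  occ <- occ_fixture(sample(paste0("s", 1:6), 40, replace = TRUE),
                     runif(40, -50, -42), runif(40, -15, -8))
  gm <- build_grid_matrix(occ, cell_deg = 2)
  m <- unclass(gm)
  grid <- attr(gm, "grid")
  # oracle: per species, set of cells holding >= 1 record
  for (sp in colnames(m)) {
    sub <- occ[occ$species == sp, ]
    col <- floor((sub$lon - grid$lon_min) / grid$cell_size_deg) + 1
    row <- grid$nrow - floor((sub$lat - grid$lat_min) / grid$cell_size_deg)
    cells <- unique(sprintf("r%02dc%02d", row, col))
    expect_equal(sum(m[, sp]), length(cells))
    expect_setequal(rownames(m)[m[, sp] == 1], cells)
  }
})

test_that("grid matrix writers emit CSV and a rooted TNT block", {
  occ <- occ_fixture(c("s1", "s2"), c(0.5, 2.5), c(0.5, 2.5))
  gm <- build_grid_matrix(occ, cell_deg = 2, grid = grid_spec(0, 4, 0, 4, 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_grid_matrix_csv(gm, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), 2)
  expect_equal(sort(names(back)), sort(c("cell", "s1", "s2")))

  tnt <- withr::local_tempfile(fileext = ".tnt")
  write_grid_matrix_tnt(gm, tnt, root = TRUE)
  lines <- readLines(tnt)
  expect_equal(lines[1], "xread")
  expect_equal(lines[3], "2 3") # 2 characters, 2 cells + ROOT
  expect_match(lines[4], "^ROOT +00$")
  expect_equal(lines[length(lines)], ";")
})
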