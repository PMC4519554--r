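test_that("unit aggregation merges counts, areas and keeps the target", {
  units <- list(
    land_unit("A", unit_square(0, 0), n_samples = 47L),
    land_unit("B", unit_square(1, 0), n_samples = 7L),
    land_unit("C", unit_square(2, 0), n_samples = 6L))
  region <- region_set(units)
  merged <- aggregate_units(region, c(B = "A", C = "A"))
  expect_equal(unit_ids(merged), "A")
  expect_equal(merged$units[["A"]]$n_samples, 60L)
  # area additivity: two unit squares sharing an edge
  r2 <- aggregate_units(region_set(units[1:2]), c(B = "A"))
  expect_equal(polygon_area(r2$units[["A"]]$polygon), 2)
  # identity mapping leaves the region unchanged
  expect_equal(unit_ids(aggregate_units(region, character(0))),
               c("A", "B", "C"))
  # chained and unknown mappings are rejected
  expect_error(aggregate_units(region, c(B = "A", A = "C")), "chained")
  expect_error(aggregate_units(region, c(Z = "A")), "unknown")
})

test_that("Voronoi cells tile the bounding region around their centroids", {
  square <- unit_square(0, 0, 10)
  # one centroid: the whole region
  one <- voronoi_partition(rbind(c(3, 3)), square)
  expect_equal(polygon_area(one[[1]]), 100)
  # two centroids: split by the perpendicular bisector
  two <- voronoi_partition(rbind(c(2, 5), c(8, 5)), square)
  expect_equal(polygon_area(two[[1]]), 50)
  expect_equal(polygon_area(two[[2]]), 50)
  expect_true(point_in_polygon(c(2, 5), two[[1]]))
  expect_true(point_in_polygon(c(8, 5), two[[2]]))
  expect_false(point_in_polygon(c(8, 5), two[[1]])
               && !point_in_polygon(c(8, 5), two[[2]]))
  # 13 centroids: 13 cells, areas sum to the region, nearest-centroid rule
  set.seed(4)
  cents <- cbind(runif(13, 1, 9), runif(13, 1, 9))
  cells <- voronoi_partition(cents, square)
  expect_length(cells, 13)
  expect_equal(sum(vapply(cells, polygon_area, 0)), 100,
               tolerance = 1e-6)
  for (k in seq_len(13)) {
    expect_true(point_in_polygon(cents[k, ], cells[[k]]))
  }
  # probe points belong to the cell of their nearest centroid
  probes <- cbind(runif(25, 0.2, 9.8), runif(25, 0.2, 9.8))
  for (i in seq_len(nrow(probes))) {
    d <- sqrt(colSums((t(cents) - probes[i, ])^2))
    expect_true(point_in_polygon(probes[i, ], cells[[which.min(d)]]))
  }
  expect_error(voronoi_partition(rbind(c(1, 1), c(1, 1)), square),
               "duplicate")
})

test_that("contiguity detects touching units and applies the
           connect/drop thresholds", {
  # two squares sharing an edge
  region <- region_set(list(land_unit("A", unit_square(0, 0)),
                            land_unit("B", unit_square(1, 0))))
  region <- build_contiguity(region)
  expect_equal(region$adjacency$A, "B")
  expect_equal(region$adjacency$B, "A")
  # contiguity is symmetric and reorder-invariant
  region_r <- build_contiguity(region_set(list(
    land_unit("B", unit_square(1, 0)), land_unit("A", unit_square(0, 0)))))
  expect_equal(region_r$adjacency$A, "B")
  # 12 km gap with a 10 km drop threshold: isolate, excluded
  km <- 1000
  far <- region_set(list(
    land_unit("A", unit_square(0, 0, 2 * km)),
    land_unit("B", unit_square(2 * km, 0, 2 * km)),
    land_unit("C", unit_square(16 * km, 0, 2 * km))))
  far <- build_contiguity(far)
  expect_equal(far$isolates, "C")
  w <- binary_weights(far)
  expect_equal(w$ids, c("A", "B"))
  # a 4 km gap is auto-connected to the nearest unit
  near <- region_set(list(
    land_unit("A", unit_square(0, 0, 2 * km)),
    land_unit("B", unit_square(2 * km, 0, 2 * km)),
    land_unit("C", unit_square(8 * km, 0, 2 * km))))
  expect_message(near <- build_contiguity(near), "connected isolate")
  expect_true("C" %in% near$adjacency$B)
})

test_that("the schematic study region yields 12 connected units after
           the published repairs", {
  fx <- augsburg_fixture()
  region <- study_contiguity(fx$region)
  expect_equal(region$isolates, "11")  # the remote north-western unit
  w <- binary_weights(region)
  expect_length(w$ids, 12)
  expect_true("7" %in% region$adjacency[["13"]])
  expect_true("4" %in% region$adjacency[["2"]])
  expect_true("2" %in% region$adjacency[["5"]])
  # the 12 weighted units form one connected component
  reach <- w$ids[1]
  repeat {
    grown <- union(reach,
                   w$ids[colSums(w$W[reach, , drop = FALSE]) > 0])
    if (setequal(grown, reach)) break
    reach <- grown
  }
  expect_setequal(reach, w$ids)
})

test_that("binary weights carry the Cliff-Ord sums", {
  pair <- spatial_weights(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(pair$W, matrix(c(0, 1, 1, 0), 2, 2,
                              dimnames = list(c("1", "2"), c("1", "2"))))
  expect_equal(c(pair$S0, pair$S1, pair$S2), c(2, 4, 8))
  p3 <- path_weights(3)
  expect_equal(c(p3$S0, p3$S1, p3$S2), c(4, 8, 24))
  # brute-force check of the S sums on a random symmetric W
  set.seed(12)
  W <- matrix(rbinom(36, 1, 0.4), 6, 6)
  W <- 1 * ((W + t(W)) > 0)
  diag(W) <- 0
  w <- spatial_weights(W)
  S1 <- 0; S2 <- 0
  for (i in 1:6) {
    S2 <- S2 + (sum(W[i, ]) + sum(W[, i]))^2
    for (j in 1:6) S1 <- S1 + (W[i, j] + W[j, i])^2 / 2
  }
  expect_equal(w$S1, S1)
  expect_equal(w$S2, S2)
  expect_equal(w$S1, 2 * w$S0)  # binary symmetric weights
  # degenerate inputs
  expect_error(spatial_weights(matrix(0, 3, 3)), "no nonzero")
  region <- region_set(list(land_unit("A", unit_square(0, 0)),
                            land_unit("B", unit_square(5, 0))))
  region <- build_contiguity(region, drop_threshold = 1,
                             connect_threshold = 0.5)
  expect_error(binary_weights(region), "fewer than two connected")
})

test_that("GeoJSON and weight-matrix exports round-trip", {
  dir <- withr::local_tempdir()
  fx <- augsburg_fixture()
  gj <- file.path(dir, "region.geojson")
  write_region_geojson(fx$region, gj)
  back <- read_region_geojson(gj)
  expect_equal(unit_ids(back), unit_ids(fx$region))
  a0 <- vapply(fx$region$units, function(u) polygon_area(u$polygon), 0)
  a1 <- vapply(back$units, function(u) polygon_area(u$polygon), 0)
  expect_equal(unname(a1), unname(a0), tolerance = 1e-9)
  w <- binary_weights(study_contiguity(fx$region))
  wcsv <- file.path(dir, "W.csv")
  write_weights_csv(w, wcsv)
  w2 <- read_weights_csv(wcsv)
  expect_equal(w2$W, w$W)
  expect_equal(c(w2$S0, w2$S1, w2$S2), c(w$S0, w$S1, w$S2))
  edges <- adjacency_edges(study_contiguity(fx$region),
                           file.path(dir, "adj.csv"))
  expect_equal(nrow(edges), w$S0 / 2)
})
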