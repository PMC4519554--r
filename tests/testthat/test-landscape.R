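test_that("point layers replicate sub-centroid values", {
  fx <- augsburg_fixture()
  vals <- setNames(rnorm(13, 44, 0.5), unit_ids(fx$region))
  layer <- build_point_layer(fx$region, vals)
  # 12 single centroids + 14 city sub-centroids
  expect_equal(nrow(layer), 26)
  city <- layer[layer$unit_id == "1", ]
  expect_equal(nrow(city), 14)
  expect_equal(unique(city$value), vals[["1"]])
  # flag off: exactly one point per unit
  plain <- build_point_layer(fx$region, vals,
                             replicate_sub_centroids = FALSE)
  expect_equal(nrow(plain), 13)
  # missing value: point omitted with a warning
  expect_warning(part <- build_point_layer(fx$region, vals[-3]),
                 "point omitted")
  expect_false("3" %in% part$unit_id)
})

test_that("spline with tension reproduces constants and interpolates
           exactly at zero smoothing", {
  set.seed(5)
  pts <- data.frame(x = runif(6, 0, 1000), y = runif(6, 0, 1000),
                    value = 7)
  m <- rst_model(pts, tension = 40, smoothing = 0)
  probes <- data.frame(x = runif(20, 0, 1000), y = runif(20, 0, 1000))
  expect_lt(max(abs(predict(m, probes) - 7)), 1e-6)
  pts$value <- rnorm(6, 50, 3)
  m2 <- rst_model(pts, tension = 40, smoothing = 0)
  expect_lt(max(abs(predict(m2, pts[, 1:2]) - pts$value)), 1e-6)
  # surface value converges to the data value near a data point
  eps_path <- vapply(c(50, 5, 0.5, 0.05), function(d) {
    abs(predict(m2, data.frame(x = pts$x[1] + d, y = pts$y[1])) -
          pts$value[1])
  }, 0)
  expect_true(all(diff(eps_path) < 0))
  expect_lt(eps_path[4], 0.05 * diff(range(pts$value)))
  # coincident points with conflicting values need smoothing
  bad <- rbind(pts, pts[1, ])
  bad$value[7] <- bad$value[1] + 5
  expect_error(rst_model(bad, smoothing = 0), "coincident")
  expect_s3_class(rst_model(bad, smoothing = 0.5), "rst_model")
})

test_that("spline solution matches an independent dense solve", {
  # independently coded: build the same saddle system from scratch
  set.seed(9)
  pts <- data.frame(x = runif(5, 0, 2000), y = runif(5, 0, 2000),
                    value = rnorm(5, 44, 1))
  tension <- 25; smoothing <- 0.3
  scale <- max(diff(range(pts$x)), diff(range(pts$y)))
  basis <- function(r) {
    ifelse(r == 0, 0, {
      rho <- (tension / scale * r / 2)^2
      -(log(rho) + pracma::expint_E1(rho) + 0.577215664901532861)
    })
  }
  D <- as.matrix(dist(pts[, 1:2]))
  K <- basis(D) + smoothing * diag(5)
  A <- rbind(cbind(K, 1), c(rep(1, 5), 0))
  sol <- solve(A, c(pts$value, 0))
  probe <- data.frame(x = c(300, 900, 1500), y = c(1700, 200, 1000))
  oracle <- vapply(seq_len(3), function(i) {
    r <- sqrt((pts$x - probe$x[i])^2 + (pts$y - probe$y[i])^2)
    sol[6] + sum(sol[1:5] * basis(r))
  }, 0)
  m <- rst_model(pts, tension = tension, smoothing = smoothing)
  expect_equal(predict(m, probe), oracle, tolerance = 1e-9)
  expect_equal(predict(m, pts[, 1:2]),
               unname(drop(K %*% sol[1:5] + sol[6] -
                             smoothing * sol[1:5])),
               tolerance = 1e-9)
})

test_that("interpolated surfaces honor the grid spec and clip mask", {
  fx <- augsburg_fixture()
  vals <- setNames(seq(43, 45, length.out = 13), unit_ids(fx$region))
  layer <- build_point_layer(fx$region, vals)
  s <- interpolate_rst(layer, region = fx$region, ncols = 40,
                       smoothing = 0)
  expect_s3_class(s, "het_surface")
  expect_equal(s$ncols, 40)
  expect_true(anyNA(s$values))          # cells outside the units
  expect_true(!all(is.na(s$values)))
  # data points sit on the fitted surface (smoothing 0)
  model <- attr(s, "model")
  expect_lt(max(abs(predict(model, layer[, c("x", "y")]) - layer$value)),
            1e-6)
})

test_that("divergence landscapes normalize by the observed range", {
  obs <- surface(rbind(c(45.00, 44.18), c(43.36, 44.00)), c(0, 0), 100)
  prd <- surface(rbind(c(45.00, 43.36), c(43.36, 44.00)), c(0, 0), 100)
  d <- divergence_landscape(obs, prd)
  expect_equal(d$max_rg, 1.64)
  expect_equal(d$surface$values[1, 2], 0.82 / 1.64 * 100)
  # identical surfaces: zero everywhere
  d0 <- divergence_landscape(obs, obs)
  expect_true(all(d0$surface$values == 0))
  # shifting both surfaces by a constant changes nothing
  obs2 <- obs; obs2$values <- obs$values + 10
  prd2 <- prd; prd2$values <- prd$values + 10
  expect_equal(divergence_landscape(obs2, prd2)$surface$values,
               d$surface$values)
  # |a-b| = |b-a| up to the normalizing range
  swapped <- divergence_landscape(prd, obs)
  expect_equal(swapped$surface$values * (max(prd$values) - min(prd$values)),
               d$surface$values * 1.64)
  # nodata propagates; incongruent grids and flat observations error
  obsNA <- obs; obsNA$values[2, 2] <- NA
  dNA <- divergence_landscape(obsNA, prd)
  expect_true(is.na(dNA$surface$values[2, 2]))
  expect_error(divergence_landscape(obs, surface(obs$values, c(0, 0), 50)),
               "congruent")
  flat <- surface(matrix(1, 2, 2), c(0, 0), 100)
  expect_error(divergence_landscape(flat, prd), "max_rg = 0")
})

test_that("surface summaries cover valid cells only", {
  flat <- surface(matrix(3.5, 4, 4), c(0, 0), 10)
  st <- surface_summary(flat)
  expect_equal(unname(st[c("mean", "median", "min", "max")]),
               rep(3.5, 4))
  expect_equal(unname(st["sd"]), 0)
  s <- surface(rbind(c(0, 100), c(0, 100)), c(0, 0), 10)
  expect_equal(unname(surface_summary(s)[c("mean", "median")]), c(50, 50))
  half <- surface(rbind(c(1, NA), c(3, NA)), c(0, 0), 10)
  sth <- surface_summary(half)
  expect_equal(unname(sth["mean"]), 2)
  expect_equal(unname(sth["max"]), 3)
  expect_error(surface_summary(surface(matrix(NA_real_, 2, 2),
                                       c(0, 0), 1)), "nodata")
})

test_that("models rank by mean divergence with sd tie-break", {
  sm <- data.frame(model = c("m1", "m2", "m3", "m4"),
                   mean = c(17.0, 10.0, 13.2, 11.8),
                   sd = c(14.9, 7.6, 8.4, 8.2))
  rk <- rank_models(sm)
  expect_equal(rk$best, "m2")
  expect_equal(rk$ranking$model, c("m2", "m4", "m3", "m1"))
  # tie on the mean: smaller sd wins
  tie <- data.frame(model = c("a", "b"), mean = c(5, 5), sd = c(5, 4))
  expect_equal(rank_models(tie)$best, "b")
  single <- data.frame(model = "only", mean = 1, sd = 1)
  expect_equal(rank_models(single)$best, "only")
})

test_that("ESRI ASCII grids round-trip bit-equivalently", {
  dir <- withr::local_tempdir()
  s <- surface(rbind(c(1.25, NA, 3), c(4, 5, -2.5)), c(100, 200), 50)
  p <- file.path(dir, "s.asc")
  write_ascii_grid(s, p)
  hdr <- readLines(p, n = 6)
  expect_match(hdr[1], "^ncols 3$")
  expect_match(hdr[2], "^nrows 2$")
  expect_match(hdr[6], "^NODATA_value -9999$")
  s2 <- read_ascii_grid(p)
  expect_equal(s2$values, s$values)
  expect_equal(s2$origin, s$origin)
  expect_equal(s2$cell_size, s$cell_size)
  csv <- file.path(dir, "s.csv")
  write_surface_csv(s, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 5)  # nodata dropped
  expect_setequal(tab$value, c(1.25, 3, 4, 5, -2.5))
})
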