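test_that("the cohort fixture reproduces the published counts exactly", {
  fx <- augsburg_fixture()
  expect_length(fx$region$units, 13)
  expect_equal(sum(fx$counts$n_native), 549)
  expect_equal(sum(fx$counts$n_immigrant), 179)
  expect_equal(sum(fx$counts$n_main), 146)
  expect_equal(sum(fx$counts$n_all), 728)
  covar <- compute_covariates(fx$subjects, units = unit_ids(fx$region),
                              rounding = "integer")
  expect_equal(covar$MAIN_IMP,
               c(78, 60, 0, 50, 0, 100, 87, 94, 75, 100, 100, 88, 100))
  expect_equal(covar$N_ALL, fx$counts$n_all)
  # ages and education stay in the survey ranges
  expect_true(all(fx$subjects$age >= 25 & fx$subjects$age <= 74))
  expect_true(all(fx$subjects$education_years >= 8 &
                    fx$subjects$education_years <= 17))
  expect_true(all(fx$subjects$education_level >= 0 &
                    fx$subjects$education_level <= 9))
  # the city unit carries 14 interpolation sub-centroids
  expect_equal(nrow(fx$region$units[["1"]]$sub_centroids), 14)
})

test_that("synthetic studies are reproducible and HWE-consistent", {
  cfg <- simulation_config(n_loci = 60, seed = 11)
  s1 <- suppressMessages(generate_synthetic_study(cfg))
  s2 <- suppressMessages(generate_synthetic_study(cfg))
  expect_identical(s1$genotypes$codes, s2$genotypes$codes)
  expect_identical(s1$subjects, s2$subjects)
  # native H_O approaches 100 * mean(2q(1-q)) at large n
  cfg2 <- simulation_config(layout = "grid", n_units = 4L,
                            sample_sizes = rep(500L, 4), n_loci = 80,
                            delta = 0, immigrant_fraction = rep(0, 4),
                            call_rate = 1, seed = 21)
  s3 <- suppressMessages(generate_synthetic_study(cfg2))
  expected <- 100 * mean(2 * s3$maf_native * (1 - s3$maf_native))
  got <- observed_heterozygosity(s3$genotypes)$value
  expect_lt(abs(got - expected), 0.5)
  # immigrant pool frequencies are shifted toward 0.5
  cfg3 <- simulation_config(n_loci = 30, delta = 0.4, seed = 3)
  s4 <- suppressMessages(generate_synthetic_study(cfg3))
  expect_true(all(abs(s4$maf_immigrant - 0.5) <=
                    abs(s4$maf_native - 0.5) + 1e-12))
})

test_that("an immigrant-fraction gradient induces detectable spatial
           structure in H_O, a flat field does not", {
  n_rej_null <- 0; n_rej_grad <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    base <- list(layout = "grid", n_units = 16L,
                 sample_sizes = rep(60L, 16), n_loci = 120,
                 call_rate = 1)
    null_cfg <- do.call(simulation_config, c(base, list(
      delta = 0, immigrant_fraction = rep(0.2, 16), seed = 1000 + r)))
    grad_cfg <- do.call(simulation_config, c(base, list(
      delta = 1, immigrant_gradient = c(0, 0.8), seed = 2000 + r)))
    for (case in list(list(cfg = null_cfg, which = "null"),
                      list(cfg = grad_cfg, which = "grad"))) {
      st <- suppressMessages(generate_synthetic_study(case$cfg))
      region <- suppressMessages(build_contiguity(st$region))
      w <- binary_weights(region)
      membership <- setNames(st$subjects$unit_id, st$subjects$subject_id)
      ho <- per_unit_heterozygosity(st$genotypes, membership,
                                    units = w$ids)
      p <- moran_permutation_test(setNames(ho$H_O, ho$unit_id), w,
                                  nsim = 199, seed = r)$p_permutation
      if (case$which == "null" && p <= 0.05) n_rej_null <- n_rej_null + 1
      if (case$which == "grad" && p < 0.05) n_rej_grad <- n_rej_grad + 1
    }
  }
  expect_lte(n_rej_null, 6)        # near-nominal false positives
  expect_gte(n_rej_grad, reps / 2) # gradient detected in most runs
})

test_that("simulate_sar_outcome honors its parameters", {
  w <- lattice_weights(4)
  X <- data.frame(x = 1:16)
  # sigma = 0, lambda = 0: exact linear predictor
  y <- simulate_sar_outcome(w, X, beta = c(2, 0.5), lambda = 0, sigma = 0)
  expect_equal(unname(y), 2 + 0.5 * (1:16))
  # lambda = 0 is pure regression noise (no spatial mixing)
  y1 <- simulate_sar_outcome(w, X, beta = c(2, 0.5), lambda = 0,
                             sigma = 1, seed = 4)
  set.seed(4)
  expect_equal(unname(y1), 2 + 0.5 * (1:16) + rnorm(16))
  expect_error(simulate_sar_outcome(w, X, beta = c(2, 0.5), lambda = 0.9),
               "feasible")
  expect_error(simulate_sar_outcome(w, X, beta = 1, lambda = 0),
               "one entry per design column")
})

test_that("study export writes the formats the pipeline reads", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_loci = 25, seed = 8)
  st <- suppressMessages(generate_synthetic_study(cfg))
  write_study(st, dir)
  g <- read_genotypes_csv(file.path(dir, "genotypes.csv"))
  expect_equal(unname(g$codes), unname(st$genotypes$codes))
  r <- read_region_geojson(file.path(dir, "region.geojson"))
  expect_equal(unit_ids(r), unit_ids(st$region))
  s <- read.csv(file.path(dir, "subjects.csv"),
                colClasses = c(unit_id = "character"))
  expect_equal(nrow(s), nrow(st$subjects))
})
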