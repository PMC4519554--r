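# Published per-land-unit sample composition of the Augsburg-region
# cohort (total / natives / immigrants / major immigrant group).
fixture_counts <- data.frame(
  unit_id = as.character(1:13),
  name = c("Augsburg", "Aichach", "Eurasburg", "Friedberg", "Pöttmes",
           "Rehling", "Bobingen", "Königsbrunn", "Langweid",
           "Neusäß", "Altenmünster", "Aystetten",
           "Schwabmünchen"),
  n_all = c(359L, 23L, 9L, 25L, 12L, 13L, 51L, 42L, 34L, 60L, 53L, 31L, 16L),
  n_native = c(258L, 18L, 9L, 21L, 12L, 12L, 36L, 24L, 22L, 52L, 48L, 23L,
               14L),
  n_immigrant = c(101L, 5L, 0L, 4L, 0L, 1L, 15L, 18L, 12L, 8L, 5L, 8L, 2L),
  n_main = c(79L, 3L, 0L, 2L, 0L, 1L, 13L, 17L, 9L, 8L, 5L, 7L, 2L),
  stringsAsFactors = FALSE
)

# schematic square footprints (km) reproducing the study-area topology:
# a central city ringed by suburbs, three near-isolates within 5 km of
# the net, and one remote unit > 10 km from every other.
fixture_squares <- matrix(c(
  24, 18, 30, 24,   # Augsburg (city, 14 postal areas)
  38, 26, 44, 32,   # Aichach (gap to Friedberg/Rehling ~2-3 km)
  36, 18, 42, 24,   # Eurasburg
  30, 18, 36, 24,   # Friedberg
  38, 36, 44, 42,   # Poettmes (gap ~4 km to Aichach)
  30, 24, 36, 30,   # Rehling
  24, 12, 30, 18,   # Bobingen
  30, 12, 36, 18,   # Koenigsbrunn
  24, 24, 30, 30,   # Langweid
  18, 18, 24, 24,   # Neusaess
   0, 34,  5, 39,   # Altenmuenster (> 10 km from all others)
  12, 18, 18, 24,   # Aystetten
  24,  4, 30, 10    # Schwabmuenchen (gap 2 km to Bobingen)
), ncol = 4, byrow = TRUE)

square_ring <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

#' Schematic cohort fixture (13 land units)
#'
#' A counts-exact fixture emulating the Augsburg-region cohort: 13
#' land units on a schematic tiling (synthetic geometry, in meters;
#' only topology and centroids matter to the methods) whose per-unit
#' counts of all subjects, natives, immigrants and the major immigrant
#' group match the published cohort table. The city unit carries 14
#' sub-centroids standing for its postal areas. Ages and education
#' variables are filled deterministically within the survey ranges
#' (25-74 years, 8-17 education years, 0-9 education score);
#' genotypes are not part of this fixture.
#'
#' @return list with \code{region} (a \code{region_set}),
#'   \code{subjects} (data.frame of subject records) and
#'   \code{counts} (the per-unit count table).
#' @export
augsburg_fixture <- function() {
  km <- 1000
  units <- lapply(seq_len(13L), function(i) {
    sq <- fixture_squares[i, ] * km
    sub <- NULL
    if (i == 1L) {
      # 14 postal-area stand-ins on a jittered 4x4 grid, corners dropped
      gx <- seq(sq[1L] + 750, sq[3L] - 750, length.out = 4L)
      gy <- seq(sq[2L] + 750, sq[4L] - 750, length.out = 4L)
      g <- as.matrix(expand.grid(x = gx, y = gy))
      sub <- g[-c(1L, 16L), , drop = FALSE]
    }
    land_unit(unit_id = fixture_counts$unit_id[i],
              name = fixture_counts$name[i],
              polygon = square_ring(sq[1L], sq[2L], sq[3L], sq[4L]),
              sub_centroids = sub,
              n_samples = fixture_counts$n_all[i])
  })
  region <- region_set(units)
  subjects <- fixture_subjects(fixture_counts)
  list(region = region, subjects = subjects, counts = fixture_counts)
}

# deterministic subject records matching a count table
fixture_subjects <- function(counts) {
  ages <- 25:74
  eys <- 8:17
  edus <- 0:9
  rows <- vector("list", nrow(counts))
  sid <- 0L
  for (i in seq_len(nrow(counts))) {
    n <- counts$n_all[i]
    if (n == 0L) next
    nat <- c(rep(TRUE, counts$n_native[i]),
             rep(FALSE, counts$n_immigrant[i]))
    main <- c(rep(FALSE, counts$n_native[i]),
              rep(TRUE, counts$n_main[i]),
              rep(FALSE, counts$n_immigrant[i] - counts$n_main[i]))
    idx <- sid + seq_len(n)
    rows[[i]] <- data.frame(
      subject_id = sprintf("S%04d", idx),
      unit_id = counts$unit_id[i],
      native = nat, main_immigrant = main,
      age = ages[(idx + 7L * i) %% length(ages) + 1L],
      education_years = eys[(idx + 3L * i) %% length(eys) + 1L],
      education_level = edus[(idx + i) %% length(edus) + 1L],
      stringsAsFactors = FALSE)
    sid <- sid + n
  }
  do.call(rbind, rows)
}

#' Simulation configuration
#'
#' Defaults mirror the emulated study: 13 land units with the cohort's
#' per-unit sample sizes and immigrant mixtures, 212 biallelic loci
#' with minor-allele frequencies uniform on [0.10, 0.50], an average
#' call rate of 97.3 percent, immigrant allele frequencies shifted a
#' fraction \code{delta} of the way toward 0.5, and spatially
#' autocorrelated unit-level covariate fields generated by a SAR
#' process with known lambda.
#'
#' @param n_units number of land units (default 13).
#' @param layout \code{"fixture"} (the schematic cohort tiling; 13
#'   units only), \code{"grid"} (square tiling) or \code{"voronoi"}
#'   (jittered random centroids tessellated into Thiessen polygons).
#' @param sample_sizes per-unit subject counts; defaults to the cohort
#'   counts for 13 units, else 30 per unit.
#' @param n_loci number of SNP loci (default 212).
#' @param maf_range native minor-allele-frequency range (default
#'   c(0.10, 0.50)).
#' @param delta fractional shift of immigrant allele frequencies
#'   toward 0.5 (default 0.2; 0 = no genetic contrast).
#' @param immigrant_fraction per-unit immigrant fractions; defaults to
#'   the cohort fractions for the fixture layout, else a west-to-east
#'   gradient over \code{immigrant_gradient}.
#' @param immigrant_gradient range of the gradient used when
#'   \code{immigrant_fraction} is not given (default c(0.05, 0.35)).
#' @param main_immigrant_fraction share of the major group among
#'   immigrants (default 0.82).
#' @param call_rate genotype call rate (default 0.973).
#' @param sar list with \code{lambda} and \code{sigma} controlling the
#'   spatially autocorrelated covariate fields (default lambda 0.15,
#'   sigma 1).
#' @param seed integer seed (default 1).
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_units = 13L,
                              layout = c("fixture", "grid", "voronoi"),
                              sample_sizes = NULL, n_loci = 212L,
                              maf_range = c(0.10, 0.50), delta = 0.2,
                              immigrant_fraction = NULL,
                              immigrant_gradient = c(0.05, 0.35),
                              main_immigrant_fraction = 0.82,
                              call_rate = 0.973,
                              sar = list(lambda = 0.15, sigma = 1),
                              seed = 1L) {
  layout <- match.arg(layout)
  if (layout == "fixture" && n_units != 13L) {
    stop("the fixture layout has exactly 13 units")
  }
  if (is.null(sample_sizes)) {
    sample_sizes <- if (layout == "fixture") fixture_counts$n_all else
      rep(30L, n_units)
  }
  if (length(sample_sizes) != n_units) {
    stop("sample_sizes must have one entry per unit")
  }
  if (maf_range[1L] <= 0 || maf_range[2L] >= 1 ||
      maf_range[1L] > maf_range[2L]) {
    stop("maf_range must be increasing within (0, 1)")
  }
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  if (!is.null(immigrant_fraction) &&
      length(immigrant_fraction) != n_units) {
    stop("immigrant_fraction must have one entry per unit")
  }
  structure(list(n_units = as.integer(n_units), layout = layout,
                 sample_sizes = as.integer(sample_sizes),
                 n_loci = as.integer(n_loci), maf_range = maf_range,
                 delta = delta, immigrant_fraction = immigrant_fraction,
                 immigrant_gradient = immigrant_gradient,
                 main_immigrant_fraction = main_immigrant_fraction,
                 call_rate = call_rate, sar = sar,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

layout_region <- function(config) {
  if (config$layout == "fixture") return(augsburg_fixture()$region)
  n <- config$n_units
  km <- 1000
  k <- ceiling(sqrt(n))
  if (config$layout == "grid") {
    units <- lapply(seq_len(n), function(i) {
      r <- (i - 1L) %/% k
      c0 <- (i - 1L) %% k
      land_unit(unit_id = as.character(i),
                polygon = square_ring(c0 * 6 * km, r * 6 * km,
                                      (c0 + 1) * 6 * km, (r + 1) * 6 * km))
    })
    return(region_set(units))
  }
  # voronoi: jittered grid centroids tessellated inside a square
  side <- 6 * k * km
  gx <- (rep(seq_len(k), k)[seq_len(n)] - 0.5) * 6 * km
  gy <- (rep(seq_len(k), each = k)[seq_len(n)] - 0.5) * 6 * km
  cents <- cbind(gx + stats::runif(n, -2 * km, 2 * km),
                 gy + stats::runif(n, -2 * km, 2 * km))
  bound <- square_ring(0, 0, side, side)
  cells <- voronoi_partition(cents, bound)
  units <- lapply(seq_len(n), function(i) {
    land_unit(unit_id = as.character(i), polygon = cells[[i]],
              centroid = cents[i, ])
  })
  region_set(units)
}

#' Generate a synthetic study (region, subjects, genotypes)
#'
#' Lays out land units, assigns subjects with per-unit native /
#' immigrant composition, and draws genotypes per subject under
#' Hardy-Weinberg proportions from the subject's pool frequencies:
#' natives from minor-allele frequencies uniform on the configured
#' range, immigrants from frequencies shifted \code{delta} of the way
#' toward 0.5 (raising their expected heterozygosity). A spatial
#' gradient in immigrant fraction therefore induces spatial structure
#' in per-unit observed heterozygosity. Fully reproducible from the
#' config seed.
#'
#' @param config a [simulation_config()].
#' @return list with \code{region}, \code{subjects},
#'   \code{genotypes} (a \code{genotype_matrix}), \code{maf_native},
#'   \code{maf_immigrant} and the \code{config}.
#' @export
generate_synthetic_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  region <- layout_region(config)
  n_units <- config$n_units
  frac <- config$immigrant_fraction
  if (is.null(frac)) {
    if (config$layout == "fixture") {
      frac <- fixture_counts$n_immigrant / fixture_counts$n_all
    } else {
      cx <- region_centroids(region)[, 1L]
      rng <- range(cx)
      t <- if (diff(rng) > 0) (cx - rng[1L]) / diff(rng) else rep(0.5, n_units)
      g <- config$immigrant_gradient
      frac <- g[1L] + t * (g[2L] - g[1L])
    }
  }
  ids <- unit_ids(region)
  counts <- data.frame(
    unit_id = ids,
    name = vapply(region$units, function(u) u$name, ""),
    n_all = config$sample_sizes,
    stringsAsFactors = FALSE)
  counts$n_immigrant <- round(frac * counts$n_all)
  counts$n_native <- counts$n_all - counts$n_immigrant
  counts$n_main <- round(config$main_immigrant_fraction * counts$n_immigrant)
  subjects <- fixture_subjects(counts)
  # spatially autocorrelated unit-level covariate fields perturb the
  # deterministic age/education fill so Moran tests see structure
  region2 <- build_contiguity(region)
  if (length(region2$isolates) < n_units - 1L) {
    w <- binary_weights(region2)
    lam <- config$sar$lambda
    field <- simulate_sar_outcome(w, X = NULL, beta = 0,
                                  lambda = lam,
                                  sigma = config$sar$sigma)
    shift <- stats::setNames(rep(0, n_units), ids)
    shift[names(field)] <- field
    subjects$age <- pmin(74, pmax(25, round(
      subjects$age + 5 * shift[subjects$unit_id])))
    subjects$education_years <- pmin(17, pmax(8, round(
      subjects$education_years + shift[subjects$unit_id])))
  }
  rownames(subjects) <- NULL
  # genotype pools
  q_nat <- stats::runif(config$n_loci, config$maf_range[1L],
                        config$maf_range[2L])
  q_img <- q_nat + config$delta * (0.5 - q_nat)
  if (any(q_img <= 0 | q_img >= 1)) stop("infeasible immigrant frequencies")
  n_sub <- nrow(subjects)
  q_mat <- matrix(rep(q_nat, each = n_sub), n_sub, config$n_loci)
  img <- !subjects$native
  if (any(img)) {
    q_mat[img, ] <- matrix(rep(q_img, each = sum(img)), sum(img),
                           config$n_loci)
  }
  codes <- matrix(stats::rbinom(n_sub * config$n_loci, 2L, q_mat),
                  n_sub, config$n_loci)
  if (config$call_rate < 1) {
    drop <- stats::runif(length(codes)) > config$call_rate
    codes[drop] <- NA_integer_
  }
  loci <- data.frame(
    locus_id = sprintf("rs%05d", seq_len(config$n_loci)),
    class = rep(c("intragenic", "intergenic"),
                length.out = config$n_loci),
    maf = q_nat, stringsAsFactors = FALSE)
  geno <- genotype_matrix(codes, subject_ids = subjects$subject_id,
                          loci = loci)
  list(region = region, subjects = subjects, genotypes = geno,
       maf_native = q_nat, maf_immigrant = q_img, config = config)
}

#' Simulate a SAR-error outcome on given weights
#'
#' Draws \eqn{y = X\beta + (I - \lambda W)^{-1} \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2 I)} — the data-generating process
#' matched by [fit_sar_error()].
#'
#' @param w a \code{spatial_weights} object.
#' @param X covariate columns (no intercept; NULL for none).
#' @param beta coefficients, intercept first.
#' @param lambda spatial parameter, inside the feasible interval of W.
#' @param sigma residual standard deviation.
#' @param seed optional integer seed.
#' @return named per-unit outcome vector.
#' @export
simulate_sar_outcome <- function(w, X = NULL, beta = 0, lambda = 0,
                                 sigma = 1, seed = NULL) {
  stopifnot(inherits(w, "spatial_weights"))
  n <- length(w$ids)
  Xm <- build_design(X, n)
  if (length(beta) != ncol(Xm)) {
    stop("beta must have one entry per design column (intercept first)")
  }
  omega <- eigen(w$W, symmetric = TRUE, only.values = TRUE)$values
  if (lambda != 0 &&
      (lambda <= 1 / min(omega) || lambda >= 1 / max(omega))) {
    stop("lambda outside the feasible interval of these weights")
  }
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(n, 0, sigma)
  u <- if (lambda == 0) eps else
    drop(solve(diag(n) - lambda * w$W, eps))
  stats::setNames(drop(Xm %*% beta) + u, w$ids)
}

#' Write a synthetic study to disk
#'
#' Emits the same formats the pipeline reads: \code{genotypes.csv},
#' \code{subjects.csv} and \code{region.geojson}.
#'
#' @param study result of [generate_synthetic_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  codes <- study$genotypes$codes
  gdf <- data.frame(subject_id = rownames(codes), codes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(gdf, file.path(dir, "genotypes.csv"), row.names = FALSE,
                   na = "-1")
  subj <- study$subjects
  if (is.null(subj$birth_land)) {
    # encode the flags as a birth-land column so the subject-CSV
    # reader reconstructs them
    subj$birth_land <- ifelse(subj$native, "DE",
                              ifelse(subj$main_immigrant, "PL", "XX"))
  }
  utils::write.csv(subj, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  write_region_geojson(study$region, file.path(dir, "region.geojson"))
  invisible(dir)
}
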