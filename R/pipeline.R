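#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis. Inputs
#' are either file paths (genotype CSV, subject CSV, region GeoJSON)
#' or, when \code{simulate} is TRUE, a [simulation_config()] driving
#' the synthetic generator. Defaults: contiguity connect threshold
#' 5 km and drop threshold 10 km, 10000 Moran permutations, SAR alpha
#' 0.05 with at most 4 covariates.
#'
#' @param out_dir output directory for the run artifacts.
#' @param simulate generate inputs synthetically (default TRUE when no
#'   paths are given).
#' @param simulation a [simulation_config()] used when simulating.
#' @param genotypes,subjects,region input file paths (CSV, CSV,
#'   GeoJSON) used when not simulating.
#' @param aggregation optional named vector mapping small units into
#'   their aggregation targets.
#' @param connect_pairs optional 2-column matrix/list of unit-id pairs
#'   forced to be contiguity neighbors.
#' @param connect_threshold,drop_threshold,snap_tolerance meters; see
#'   [build_contiguity()].
#' @param nsim Moran permutations (default 10000).
#' @param seed integer seed for every random stage.
#' @param alpha covariate significance threshold (default 0.05).
#' @param max_terms forward-search size cap (default 4).
#' @param response response column for model selection (default
#'   "HO_GER", natives-only heterozygosity).
#' @param candidates candidate covariates for the forward search.
#' @param test_added covariate whose addition to each retained model
#'   is tested (default "MAIN_IMP"; NULL to skip).
#' @param ncols,tension,smoothing interpolation parameters, see
#'   [interpolate_rst()].
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(out_dir,
                            simulate = is.null(genotypes),
                            simulation = simulation_config(),
                            genotypes = NULL, subjects = NULL,
                            region = NULL, aggregation = NULL,
                            connect_pairs = NULL,
                            connect_threshold = 5000,
                            drop_threshold = 10000,
                            snap_tolerance = 1,
                            nsim = 10000, seed = 1L, alpha = 0.05,
                            max_terms = 4L, response = "HO_GER",
                            candidates = c("GER_P", "AGE25_39",
                                           "AGE40_54", "AGE55_74",
                                           "AGE_MEAN", "EY8_11",
                                           "EY_MEAN", "EDU_MEAN"),
                            test_added = "MAIN_IMP",
                            ncols = 200, tension = 40, smoothing = 0.1) {
  if (!simulate) {
    for (p in c(genotypes, subjects, region)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  if (connect_threshold <= 0 || drop_threshold <= 0) {
    stop("contiguity thresholds must be positive")
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 simulation = simulation, genotypes = genotypes,
                 subjects = subjects, region = region,
                 aggregation = aggregation,
                 connect_pairs = connect_pairs,
                 connect_threshold = connect_threshold,
                 drop_threshold = drop_threshold,
                 snap_tolerance = snap_tolerance, nsim = nsim,
                 seed = as.integer(seed), alpha = alpha,
                 max_terms = max_terms, response = response,
                 candidates = candidates, test_added = test_added,
                 ncols = ncols, tension = tension,
                 smoothing = smoothing),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; a nested
#' \code{simulation} map is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    y$simulation <- do.call(simulation_config, y$simulation)
  }
  if (!is.null(y$aggregation)) y$aggregation <- unlist(y$aggregation)
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full genetic-geostatistics pipeline
#'
#' Sequences every stage: input (or simulation), optional unit
#' aggregation, contiguity and binary weights, per-unit covariates
#' and observed heterozygosity (HO_ALL on all subjects, HO_GER on
#' natives), Moran's I tests for every variable, SAR forward model
#' selection on the response, covariate-augmentation testing,
#' observed/predicted landscape interpolation, divergence landscapes
#' and the model ranking. Artifacts (CSV tables, ASCII grids, a JSON
#' manifest) are written to \code{config$out_dir}.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  inputs <- stage("input", {
    if (config$simulate) {
      generate_synthetic_study(config$simulation)
    } else {
      list(region = read_region_geojson(config$region),
           subjects = read_subjects_csv(config$subjects),
           genotypes = read_genotypes_csv(config$genotypes))
    }
  })
  region <- inputs$region
  subjects <- inputs$subjects
  geno <- inputs$genotypes

  if (!is.null(config$aggregation) && length(config$aggregation)) {
    agg <- stage("aggregate", list(
      region = aggregate_units(region, config$aggregation),
      subjects = remap_membership(subjects, config$aggregation)))
    region <- agg$region
    subjects <- agg$subjects
  }

  region <- stage("contiguity", build_contiguity(
    region, connect_pairs = config$connect_pairs,
    connect_threshold = config$connect_threshold,
    drop_threshold = config$drop_threshold,
    snap_tolerance = config$snap_tolerance))
  w <- stage("weights", binary_weights(region))
  write_weights_csv(w, out("weights.csv"))
  adjacency_edges(region, out("adjacency.csv"))

  covar <- stage("covariates", {
    tab <- compute_covariates(subjects, units = unit_ids(region))
    membership <- stats::setNames(subjects$unit_id, subjects$subject_id)
    ho_all <- per_unit_heterozygosity(geno, membership,
                                      units = unit_ids(region))
    ho_ger <- per_unit_heterozygosity(
      geno, membership,
      subject_filter = subjects$subject_id[subjects$native],
      units = unit_ids(region))
    tab$HO_ALL <- ho_all$H_O
    tab$HO_GER <- ho_ger$H_O
    tab
  })
  utils::write.csv(covar, out("covariates.csv"), row.names = FALSE)

  moran <- stage("moran", moran_table(covar, w, nsim = config$nsim,
                                      seed = config$seed))
  utils::write.csv(moran, out("moran.csv"), row.names = FALSE)

  search <- stage("sar", forward_search(
    y = stats::setNames(covar[[config$response]], covar$unit_id)[w$ids],
    data = covar, candidates = config$candidates, w = w,
    alpha = config$alpha, max_terms = config$max_terms))
  models <- retained_models_table(search)
  added <- NULL
  if (!is.null(config$test_added) && length(search$retained)) {
    added <- stage("sar-augment", {
      do.call(rbind, lapply(seq_along(search$retained), function(i) {
        m <- search$retained[[i]]
        ev <- evaluate_added_covariate(
          m$covariates, config$test_added,
          y = stats::setNames(covar[[config$response]],
                              covar$unit_id)[w$ids],
          data = covar, w = w, alpha = config$alpha)
        data.frame(model = paste0("m", i), extra = config$test_added,
                   p_extra = ev$p_extra,
                   delta_loglik = ev$delta_loglik,
                   improves = ev$improves, stringsAsFactors = FALSE)
      }))
    })
    utils::write.csv(added, out("sar_augmentation.csv"), row.names = FALSE)
  }
  utils::write.csv(models, out("sar_models.csv"), row.names = FALSE)

  landscapes <- stage("landscape", {
    vals <- stats::setNames(covar[[config$response]], covar$unit_id)
    layer <- build_point_layer(region, vals)
    observed <- interpolate_rst(layer, region = region,
                                ncols = config$ncols,
                                tension = config$tension,
                                smoothing = config$smoothing)
    write_ascii_grid(observed, out(paste0("observed_",
                                          config$response, ".asc")))
    preds <- lapply(seq_along(search$retained), function(i) {
      fit <- search$retained[[i]]$fit
      pl <- build_point_layer(region, fit$fitted)
      s <- interpolate_rst(pl, region = region, ncols = config$ncols,
                           tension = config$tension,
                           smoothing = config$smoothing)
      write_ascii_grid(s, out(sprintf("predicted_m%d.asc", i)))
      s
    })
    list(observed = observed, predicted = preds)
  })

  summaries <- NULL
  ranking <- NULL
  if (length(landscapes$predicted)) {
    summaries <- stage("divergence", {
      do.call(rbind, lapply(seq_along(landscapes$predicted), function(i) {
        dv <- divergence_landscape(landscapes$observed,
                                   landscapes$predicted[[i]])
        write_ascii_grid(dv$surface, out(sprintf("divergence_m%d.asc", i)))
        st <- surface_summary(dv$surface)
        data.frame(model = paste0("m", i), mean = st[["mean"]],
                   sd = st[["sd"]], median = st[["median"]],
                   min = st[["min"]], max = st[["max"]],
                   max_rg = dv$max_rg, stringsAsFactors = FALSE)
      }))
    })
    utils::write.csv(summaries, out("divergence_summary.csv"),
                     row.names = FALSE)
    ranking <- rank_models(summaries)
  }

  manifest <- list(
    package = "hetscape",
    version = as.character(utils::packageVersion("hetscape")),
    r_version = R.version.string,
    seed = config$seed, nsim = config$nsim, alpha = config$alpha,
    max_terms = config$max_terms, response = config$response,
    candidates = config$candidates,
    contiguity = list(connect_threshold = config$connect_threshold,
                      drop_threshold = config$drop_threshold,
                      snap_tolerance = config$snap_tolerance),
    interpolation = list(ncols = config$ncols, tension = config$tension,
                         smoothing = config$smoothing),
    simulated = config$simulate,
    simulation_seed = if (config$simulate) config$simulation$seed,
    isolates = region$isolates,
    n_units = length(region$units),
    retained_models = nrow(models),
    best_model = if (!is.null(ranking)) ranking$best)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(region = region, subjects = subjects, weights = w,
                 covariates = covar, moran = moran, search = search,
                 models = models, augmentation = added,
                 landscapes = landscapes, summaries = summaries,
                 ranking = ranking, manifest = manifest))
}
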