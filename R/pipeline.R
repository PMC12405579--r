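#' @title Study-scale annotation and end-to-end pipeline
#' @name pipeline
#' @description
#' Orchestrates the full analysis from raw observations to summary
#' tables: cleaning and the n >= 5 filter, range geometry, per-species
#' correlations, group summaries, weighted grand means, stepwise and
#' all-subsets models, marginal effects, and phylogenetic-signal tests.
#' Also provides the spatial-scale annotations (extent, grain, focus).
NULL

#' Classify study extent
#'
#' Categorises the overall span of sampling locations into `Local`
#' (`<= 250` km), `Landscape` (`(250, 500]`), `Regional` (`(500, 1500]`)
#' or `Continental` (`> 1500`). The intervals are contiguous and
#' lower-inclusive at each boundary.
#'
#' @param extent_km nonnegative extent(s) in km.
#' @return character vector of classes.
#' @export
classify_extent <- function(extent_km) {
  if (any(!is.finite(extent_km)) || any(extent_km < 0))
    stopf("extent_km must be nonnegative", class = "abundicentre_invalid_argument")
  cut(extent_km, breaks = c(-Inf, 250, 500, 1500, Inf),
      labels = c("Local", "Landscape", "Regional", "Continental"),
      right = TRUE) |> as.character()
}

#' Bin grain or focus area into small/large
#'
#' Log10 areas up to -3 are `small`; above -3 (up to 3) are `large`.
#' Values outside `[-10, 3]` on the log10 scale trigger an out-of-range
#' warning and are assigned to the nearest bin.
#'
#' @param value_km2 positive area(s) in km².
#' @return character vector `"small"`/`"large"`.
#' @export
bin_grain_focus <- function(value_km2) {
  if (any(!is.finite(value_km2)) || any(value_km2 <= 0))
    stopf("area must be positive", class = "abundicentre_invalid_argument")
  lg <- log10(value_km2)
  if (any(lg < -10 | lg > 3))
    warnf("log10 area outside [-10, 3] for %d value(s); assigned to nearest bin",
          sum(lg < -10 | lg > 3))
  ifelse(lg <= -3, "small", "large")
}

#' Study extent from sampling sites
#'
#' The larger of the latitudinal and longitudinal spans of the bounding
#' box of the sites, each expressed as a great-circle distance (the
#' longitudinal span measured at the box's mid-latitude).
#'
#' @param sites data.frame/matrix with columns `lon`, `lat` (`>= 2`
#'   rows).
#' @return extent in km.
#' @export
study_extent_km <- function(sites) {
  sites <- as.data.frame(sites)
  if (nrow(sites) < 2)
    stopf("study extent needs at least 2 sites",
          class = "abundicentre_invalid_argument")
  validate_lonlat(sites$lon, sites$lat, "site")
  fr <- lon_frame(sites$lon)
  x <- fr$to(sites$lon)
  lon_rng <- fr$from(range(x)); lat_rng <- range(sites$lat)
  lat_mid <- mean(lat_rng); lon_mid <- fr$from(mean(range(x)))
  lat_span <- geodesic_distance_km(c(lon_mid, lat_rng[1]), c(lon_mid, lat_rng[2]))
  lon_span <- geodesic_distance_km(c(lon_rng[1], lat_mid), c(lon_rng[2], lat_mid))
  max(lat_span, lon_span)
}

#' Pipeline configuration
#'
#' Inputs may be in-memory objects (a `synthetic_dataset`'s components)
#' or paths to the plain-text formats written by [write_dataset()].
#'
#' @param observations data.frame (species, lon, lat, abundance) or a CSV
#'   path.
#' @param traits trait data.frame or CSV path.
#' @param ranges named list of `range_polygon`, a GeoJSON path, or `NULL`
#'   to build minimum convex polygons from the observation points.
#' @param tree Newick string/`phylo`/path, or `NULL` to skip the
#'   phylogenetic stage.
#' @param out_dir output directory, or `NULL` for no file output.
#' @param group_col trait column used for group summaries.
#' @param model_terms predictor terms for the model stage; defaults to
#'   the trait columns plus `abs_latitude` and `log10_range_size`.
#' @param alpha significance threshold.
#' @param delta_aic best-set threshold for the dredge stage.
#' @param collinearity_threshold pairwise |r| above which continuous
#'   predictors are flagged.
#' @param min_n per-species minimum observations.
#' @param seed integer seed (the analysis is deterministic; the seed is
#'   recorded in the manifest and seeds any generator invoked upstream).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(observations, traits, ranges = NULL, tree = NULL,
                            out_dir = NULL, group_col = "functional_group",
                            model_terms = NULL, alpha = 0.05, delta_aic = 2,
                            collinearity_threshold = 0.70, min_n = 5,
                            seed = 1) {
  structure(list(observations = observations, traits = traits,
                 ranges = ranges, tree = tree, out_dir = out_dir,
                 group_col = group_col, model_terms = model_terms,
                 alpha = alpha, delta_aic = delta_aic,
                 collinearity_threshold = collinearity_threshold,
                 min_n = min_n, seed = seed),
            class = "pipeline_config")
}

read_if_path <- function(x, reader) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) reader(x) else x
}

#' Run the full abundant-centre analysis
#'
#' Stages: input reading and validation; range summaries (expert polygons
#' or minimum convex polygons from the points); distance to centroid;
#' cleaning and the minimum-sample filter; per-species Spearman/Fisher-Z
#' statistics; group summaries; weighted grand mean; backward stepwise
#' fixed-effect selection; all-subsets two-way-interaction AIC dredge;
#' marginal effects of the retained predictors; and, when a tree is
#' supplied, the PGLS AIC comparison at lambda 0/1/fit plus residual
#' signal tests at the three model complexities. When `out_dir` is set,
#' every table is written as CSV/JSON together with a machine-readable
#' run manifest; reruns with the same inputs and seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with elements `audit`,
#'   `range_summaries`, `correlations`, `group_summary`, `grand_mean`,
#'   `collinearity`, `stepwise`, `dredge`, `marginal_effects`,
#'   `phylo` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  obs <- read_if_path(config$observations, function(p)
    read.csv(p, stringsAsFactors = FALSE))
  traits <- read_if_path(config$traits, function(p)
    read.csv(p, stringsAsFactors = FALSE))
  ranges <- read_if_path(config$ranges, read_ranges_geojson)
  tree <- config$tree
  if (is.character(tree) && length(tree) == 1 && file.exists(tree))
    tree <- ape::read.tree(tree)

  species <- unique(obs$species)
  missing_traits <- setdiff(species, traits$species)
  if (length(missing_traits))
    stopf("[stage traits] species missing from trait table: %s",
          paste(head(missing_traits, 10), collapse = ", "),
          class = "abundicentre_missing_data")

  # stage: range geometry
  summaries <- lapply(setNames(species, species), function(sp) {
    poly <- if (!is.null(ranges)) ranges[[sp]] else NULL
    if (is.null(poly)) {
      pts <- obs[obs$species == sp, c("lon", "lat")]
      poly <- tryCatch(minimum_convex_polygon(pts), error = function(e)
        stopf("[stage geometry] species %s: %s", sp, conditionMessage(e),
              class = "abundicentre_stage_error"))
    }
    range_summary(poly)
  })
  range_table <- data.frame(
    species = species,
    centroid_lon = vapply(summaries, function(s) s$centroid[["lon"]], numeric(1)),
    centroid_lat = vapply(summaries, function(s) s$centroid[["lat"]], numeric(1)),
    range_size_km2 = vapply(summaries, `[[`, numeric(1), "range_size_km2"),
    abs_latitude = vapply(summaries, `[[`, numeric(1), "abs_latitude_deg"),
    stringsAsFactors = FALSE)

  # stage: distances, cleaning, per-species correlations
  obs_parts <- lapply(species, function(sp) {
    distance_to_centroid(obs[obs$species == sp, , drop = FALSE], summaries[[sp]])
  })
  obs_d <- do.call(rbind, obs_parts)
  cleaned <- clean_and_filter(obs_d, min_n = config$min_n)
  if (nrow(cleaned$observations) == 0)
    stopf("[stage cleaning] no observations survive cleaning",
          class = "abundicentre_stage_error")
  correlations <- species_correlations(cleaned$observations)

  # stage: join predictors
  tbl <- merge(correlations, traits, by = "species")
  tbl <- merge(tbl, range_table[, c("species", "range_size_km2", "abs_latitude")],
               by = "species")
  tbl$log10_range_size <- log10(tbl$range_size_km2)
  tbl <- tbl[order(tbl$species), ]
  rownames(tbl) <- NULL

  group_summary <- summarize_groups(correlations,
    setNames(traits[[config$group_col]], traits$species), alpha = config$alpha)

  gm <- grand_mean(tbl)

  # stage: models on standardized continuous predictors
  default_terms <- c(setdiff(names(traits), "species"),
                     "abs_latitude", "log10_range_size")
  model_terms <- config$model_terms %||% default_terms
  constant <- vapply(tbl[model_terms], function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    warnf("dropping constant predictor(s): %s",
          paste(model_terms[constant], collapse = ", "))
    model_terms <- model_terms[!constant]
  }
  cont <- model_terms[vapply(tbl[model_terms], function(x)
    is.numeric(x) && length(unique(x)) > 2, logical(1))]
  colin <- if (length(cont) >= 2)
    collinearity_screen(tbl, cont, config$collinearity_threshold) else NULL
  if (length(cont)) tbl <- standardize_predictors(tbl, cont, weights = tbl$weight)
  step_res <- stepwise_select(tbl, terms = model_terms, alpha = config$alpha)
  dredge_res <- dredge_interactions(tbl, main_terms = model_terms,
                                    delta_aic = config$delta_aic)
  marginals <- if (length(step_res$final_terms)) {
    do.call(rbind, lapply(step_res$final_terms[!grepl(":", step_res$final_terms)],
                          function(p) marginal_effects(step_res$fit, p)))
  }

  # stage: phylogenetic signal
  phylo <- NULL
  if (!is.null(tree)) {
    comparison <- pgls_lambda_comparison(tbl, fisher_z ~ 1, tree,
                                         weights = "weight")
    fits <- list(grand_mean = gm$fit, fixed = step_res$fit,
                 interactions = dredge_res$fit)
    residual_tests <- lapply(fits, residual_signal, tree = tree)
    residual_table <- data.frame(
      model = names(residual_tests),
      lambda = vapply(residual_tests, `[[`, numeric(1), "lambda_hat"),
      lr = vapply(residual_tests, `[[`, numeric(1), "lr_statistic"),
      p_value = vapply(residual_tests, `[[`, numeric(1), "p_value"),
      stringsAsFactors = FALSE)
    phylo <- list(comparison = comparison, residual_table = residual_table,
                  residual_tests = residual_tests)
  }

  report <- structure(list(
    audit = cleaned$audit,
    exclusions = list(records = cleaned$excluded_records,
                      species = cleaned$excluded_species),
    range_summaries = range_table,
    correlations = correlations,
    species_table = tbl,
    group_summary = group_summary,
    grand_mean = gm[c("mean_z", "se", "t", "df", "p", "ci_95", "significant", "n")],
    collinearity = colin,
    stepwise = step_res,
    dredge = dredge_res,
    marginal_effects = marginals,
    phylo = phylo,
    manifest = list(seed = config$seed,
                    min_n = config$min_n, alpha = config$alpha,
                    delta_aic = config$delta_aic,
                    collinearity_threshold = config$collinearity_threshold,
                    n_species_in = length(species),
                    n_species_used = nrow(correlations),
                    package_version = as.character(utils::packageVersion("abundicentre")))),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d species analysed (%s observations used)\n",
              nrow(x$correlations), format(x$audit[["used"]], big.mark = ",")))
  cat(sprintf(" grand mean Z = %.4f [%.4f, %.4f]%s\n", x$grand_mean$mean_z,
              x$grand_mean$ci_95[1], x$grand_mean$ci_95[2],
              if (x$grand_mean$significant) " *" else ""))
  cat(" group summary:\n"); print(x$group_summary)
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(dir, name), row.names = FALSE)
  wcsv(report$correlations, "species_correlations.csv")
  wcsv(report$group_summary, "group_summary.csv")
  wcsv(report$range_summaries, "range_summaries.csv")
  wcsv(report$marginal_effects, "marginal_effects.csv")
  wcsv(report$dredge$candidates, "candidate_models.csv")
  jsonlite::write_json(list(
    grand_mean = report$grand_mean,
    stepwise = list(final_terms = report$stepwise$final_terms,
                    trace = report$stepwise$trace,
                    coefficients = as.data.frame(report$stepwise$fit$coefficients)),
    dredge = list(final_terms = report$dredge$final_terms,
                  n_candidates = nrow(report$dredge$candidates),
                  best_set_size = length(report$dredge$best_set))),
    file.path(dir, "models.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$phylo)) {
    wcsv(report$phylo$comparison, "pgls_lambda_comparison.csv")
    wcsv(report$phylo$residual_table, "residual_signal.csv")
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
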