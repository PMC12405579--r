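#' @title Synthetic abundance/trait/phylogeny data generator
#' @name synthetic-data
#' @description
#' Generates datasets with the statistical structure the analysis assumes:
#' species ranges with centre-peaked, flat or edge-peaked abundance
#' fields, uneven per-species sampling, trait structure that shifts
#' species-level mean Fisher's Z, and lambda-structured Brownian
#' phylogenetic covariance among those means on a simulated Yule tree.
#' Every generator is a pure function of its seed.
NULL

#' Simulate abundance/distance pairs with a target Spearman correlation
#'
#' Draws pairs from a Gaussian copula whose latent Pearson correlation is
#' chosen so the population Spearman correlation equals `target_rs`
#' (`rho = 2 sin(pi * rs / 6)`, exact on the bivariate-normal latent
#' scale). Margins are strictly positive lognormals for both abundance
#' and distance, so no zero handling is needed downstream.
#'
#' @param n_obs number of observations (`>= 5`).
#' @param target_rs population Spearman correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @param meanlog_abundance,sdlog_abundance lognormal abundance margin.
#' @param meanlog_distance,sdlog_distance lognormal distance margin (km).
#' @return data.frame `abundance`, `distance_km`.
#' @export
simulate_copula_species <- function(n_obs, target_rs, seed,
                                    meanlog_abundance = 2, sdlog_abundance = 1,
                                    meanlog_distance = 5, sdlog_distance = 0.7) {
  n_obs <- assert_count(n_obs, "n_obs", min = 1L)
  if (n_obs < 5)
    stopf("n_obs must be >= 5 (got %d): the analysis filters such species anyway",
          n_obs, class = "abundicentre_invalid_argument")
  assert_scalar_number(target_rs, "target_rs")
  if (abs(target_rs) > 1)
    stopf("|target_rs| must be <= 1", class = "abundicentre_invalid_argument")
  rho <- 2 * sin(pi * target_rs / 6)
  with_seed(seed, {
    z1 <- rnorm(n_obs)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_obs)
    data.frame(
      abundance = qlnorm(pnorm(z1), meanlog_abundance, sdlog_abundance),
      distance_km = qlnorm(pnorm(z2), meanlog_distance, sdlog_distance))
  })
}

# destination point: start c(lon,lat) deg, bearing rad, angular distance rad
destination_point <- function(lon, lat, bearing, ang) {
  to_rad <- pi / 180
  phi1 <- lat * to_rad; lam1 <- lon * to_rad
  phi2 <- asin(sin(phi1) * cos(ang) + cos(phi1) * sin(ang) * cos(bearing))
  lam2 <- lam1 + atan2(sin(bearing) * sin(ang) * cos(phi1),
                       cos(ang) - sin(phi1) * sin(phi2))
  cbind(lon = ((lam2 / to_rad + 180) %% 360) - 180, lat = phi2 / to_rad)
}

#' Simulate a species with an explicit spatial abundance gradient
#'
#' Sampling sites are uniform over the spherical cap of radius
#' `range_radius_km` around `centre`; abundance follows
#' `exp(alpha - gradient_strength * d / range_radius_km + eps)` with
#' `eps ~ Normal(0, noise_sd)`, where `d` is the great-circle distance to
#' the centre. Positive `gradient_strength` gives a centre-peaked field
#' (expected Spearman correlation negative), zero a flat field, negative
#' an edge-peaked field.
#'
#' @param range_radius_km positive cap radius in km.
#' @param centre range centre as `c(lon, lat)`.
#' @param n_obs number of sites (`>= 5`).
#' @param gradient_strength log-abundance drop from centre to edge.
#' @param noise_sd lognormal noise SD (`>= 0`).
#' @param seed integer seed.
#' @param alpha log-abundance at the range centre.
#' @return data.frame `lon`, `lat`, `abundance`, `distance_km` (true
#'   distance to the generating centre).
#' @export
simulate_spatial_species <- function(range_radius_km, centre, n_obs,
                                     gradient_strength, noise_sd, seed,
                                     alpha = 2) {
  assert_scalar_number(range_radius_km, "range_radius_km")
  if (range_radius_km <= 0)
    stopf("range_radius_km must be positive",
          class = "abundicentre_invalid_argument")
  n_obs <- assert_count(n_obs, "n_obs", min = 5L)
  if (noise_sd < 0)
    stopf("noise_sd must be >= 0", class = "abundicentre_invalid_argument")
  validate_lonlat(centre[1], centre[2], "range centre")
  theta_max <- range_radius_km / EARTH_RADIUS_KM
  with_seed(seed, {
    # uniform over the cap: cos(theta) uniform on [cos(theta_max), 1]
    cosd <- 1 - runif(n_obs) * (1 - cos(theta_max))
    ang <- acos(pmin(pmax(cosd, -1), 1))
    bearing <- runif(n_obs, 0, 2 * pi)
    pts <- destination_point(centre[1], centre[2], bearing, ang)
    d <- ang * EARTH_RADIUS_KM
    eps <- rnorm(n_obs, 0, noise_sd)
    data.frame(lon = pts[, "lon"], lat = pts[, "lat"],
               abundance = exp(alpha - gradient_strength * d / range_radius_km + eps),
               distance_km = d)
  })
}

#' Simulate an ultrametric Yule phylogeny
#'
#' Pure-birth tree with `n_tips` labelled tips, rescaled to unit
#' root-to-tip depth so lambda and sigma2 are identifiable and comparable
#' across tree sizes. Tips are labelled `sp0001 ...`.
#'
#' @param n_tips number of tips (`>= 2`).
#' @param seed integer seed.
#' @param birth speciation rate of the pure-birth process.
#' @return Newick string.
#' @export
simulate_yule_tree <- function(n_tips, seed, birth = 1) {
  n_tips <- assert_count(n_tips, "n_tips", min = 2L)
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = birth, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%04d", seq_len(n_tips))
  ape::write.tree(tr)
}

#' Simulate a continuous trait under Pagel's lambda Brownian model
#'
#' Draws tip values from a multivariate normal with mean `mean` and
#' covariance `sigma2 * C(lambda_true)`, where `C(lambda)` is the
#' lambda-transformed Brownian covariance of the tree. `lambda_true = 0`
#' gives i.i.d. values with variance `sigma2 * depth`; `lambda_true = 1`
#' full Brownian motion.
#'
#' @param tree an `ape::phylo` or Newick string.
#' @param lambda_true signal strength in `[0, 1]`.
#' @param sigma2 Brownian rate (`> 0`).
#' @param mean trait mean at the root.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_lambda_trait <- function(tree, lambda_true, sigma2, mean, seed) {
  assert_scalar_number(lambda_true, "lambda_true")
  if (lambda_true < 0 || lambda_true > 1)
    stopf("lambda_true must be in [0, 1]", class = "abundicentre_invalid_argument")
  if (sigma2 <= 0)
    stopf("sigma2 must be > 0", class = "abundicentre_invalid_argument")
  tree <- as_phylo(tree)
  C <- lambda_transform(ape::vcv(tree), lambda_true)
  vals <- with_seed(seed,
    MASS::mvrnorm(1, mu = rep(mean, nrow(C)), Sigma = sigma2 * C))
  setNames(as.numeric(vals), rownames(C))
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of [simulate_dataset()]. The
#' defaults describe the study conditions the generator emulates: a
#' plant-like assemblage with a weak abundant-centre tendency
#' (`target_rs = -0.1`), functional-group and height effects shifting the
#' species-level mean Fisher's Z, a modest phylogenetic signal
#' (`lambda_true = 0.2`) with between-species spread `sqrt(0.04) = 0.2`,
#' and per-species sampling effort log-uniform between 5 and 2000
#' observations.
#'
#' @param n_species number of species (= tree tips).
#' @param n_obs_range `c(min, max)` per-species observation counts,
#'   drawn log-uniformly; `min >= 5`.
#' @param gradient_mode `"copula"` (pairs with an exact target Spearman
#'   correlation) or `"spatial"` (explicit abundance surface over the
#'   range).
#' @param target_rs baseline population Spearman correlation (copula
#'   mode).
#' @param gradient_strength baseline centre-to-edge log-abundance drop
#'   (spatial mode; `> 0` means centre-peaked).
#' @param noise_sd lognormal abundance noise (spatial mode).
#' @param trait_effect_sizes named numeric vector of additive shifts on
#'   the species-level mean Fisher's Z: names are either
#'   `"<trait>.<level>"` for categorical levels or `"<trait>"` for
#'   continuous traits (shift per unit).
#' @param tree_tips tips of the simulated phylogeny (defaults to
#'   `n_species`).
#' @param lambda_true phylogenetic signal of the species-level mean Z.
#' @param sigma2_bm Brownian rate of the species-level mean Z.
#' @param seed master integer seed; every downstream draw derives from it.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 80,
                              n_obs_range = c(5, 2000),
                              gradient_mode = c("copula", "spatial"),
                              target_rs = -0.1,
                              gradient_strength = 1,
                              noise_sd = 1,
                              trait_effect_sizes = c("functional_group.tree" = 0.15,
                                                     "log10_height" = -0.04),
                              tree_tips = n_species,
                              lambda_true = 0.2,
                              sigma2_bm = 0.04,
                              seed = 1) {
  gradient_mode <- match.arg(gradient_mode)
  n_species <- assert_count(n_species, "n_species", min = 2L)
  if (length(n_obs_range) != 2 || n_obs_range[1] < 5 ||
      n_obs_range[2] < n_obs_range[1])
    stopf("n_obs_range must be c(min, max) with min >= 5",
          class = "abundicentre_invalid_argument")
  assert_scalar_number(target_rs, "target_rs")
  if (abs(target_rs) > 1)
    stopf("target_rs must be in [-1, 1]", class = "abundicentre_invalid_argument")
  assert_scalar_number(lambda_true, "lambda_true")
  if (lambda_true < 0 || lambda_true > 1)
    stopf("lambda_true must be in [0, 1]", class = "abundicentre_invalid_argument")
  if (sigma2_bm <= 0)
    stopf("sigma2_bm must be > 0", class = "abundicentre_invalid_argument")
  if (noise_sd < 0)
    stopf("noise_sd must be >= 0", class = "abundicentre_invalid_argument")
  structure(list(n_species = n_species, n_obs_range = n_obs_range,
                 gradient_mode = gradient_mode, target_rs = target_rs,
                 gradient_strength = gradient_strength, noise_sd = noise_sd,
                 trait_effect_sizes = trait_effect_sizes,
                 tree_tips = assert_count(tree_tips, "tree_tips", min = 2L),
                 lambda_true = lambda_true, sigma2_bm = sigma2_bm,
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "simulation_config")
}

# trait table emulating the compiled predictors: a plant-like functional
# group (frequencies as in the compiled plant table), a rare invasive
# flag, and a continuous log10 height
simulate_traits <- function(species, seed) {
  with_seed(seed, {
    grp <- sample(c("grass", "herb", "shrub", "tree"), length(species),
                  replace = TRUE, prob = c(65, 386, 29, 120) / 600)
    data.frame(
      species = species,
      functional_group = grp,
      invasive = sample(c(0L, 1L), length(species), replace = TRUE,
                        prob = c(0.96, 0.04)),
      log10_height = round(rnorm(length(species),
                                 mean = ifelse(grp == "tree", 1, -0.3),
                                 sd = 0.4), 6),
      stringsAsFactors = FALSE)
  })
}

trait_shift <- function(traits, effects) {
  shift <- numeric(nrow(traits))
  for (nm in names(effects)) {
    if (grepl(".", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      shift <- shift + effects[[nm]] * (traits[[parts[1]]] == parts[2])
    } else {
      shift <- shift + effects[[nm]] * traits[[nm]]
    }
  }
  shift
}

#' Generate a complete synthetic dataset
#'
#' Builds, from one master seed: an ultrametric Yule tree; a trait table;
#' species-level true mean Fisher's Z values
#' `atanh(target_rs) + trait shifts + phylogenetic deviation` (the
#' deviation drawn under Pagel's lambda Brownian motion); per-species
#' abundance/distance observations realising each species' target
#' correlation (copula mode) or an explicit abundance surface (spatial
#' mode); circular range polygons around each species' true centre; and a
#' truth table recording the generating parameters.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_dataset`: `observations` (species,
#'   lon, lat, abundance), `ranges` (named list of `range_polygon`),
#'   `traits`, `tree` (Newick string), `truth`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- derive_seeds(config$seed, 6 + config$n_species * 2)
  tree <- simulate_yule_tree(config$tree_tips, seeds[1])
  species <- as_phylo(tree)$tip.label[seq_len(config$n_species)]
  traits <- simulate_traits(species, seeds[2])
  phylo_dev <- simulate_lambda_trait(tree, config$lambda_true,
                                     config$sigma2_bm, 0, seeds[3])
  base_z <- atanh(config$target_rs)
  mean_z <- base_z + trait_shift(traits, config$trait_effect_sizes) +
    as.numeric(phylo_dev[species])
  target_rs_sp <- tanh(mean_z)
  lr <- log(config$n_obs_range)
  meta <- with_seed(seeds[4], data.frame(
    species = species,
    n_obs = pmax(5L, as.integer(round(exp(runif(config$n_species, lr[1], lr[2]))))),
    centre_lon = runif(config$n_species, -150, 150),
    centre_lat = runif(config$n_species, -55, 55),
    radius_km = exp(runif(config$n_species, log(300), log(3000))),
    stringsAsFactors = FALSE))
  obs_list <- vector("list", config$n_species)
  ranges <- vector("list", config$n_species)
  names(ranges) <- species
  for (i in seq_len(config$n_species)) {
    ctr <- c(meta$centre_lon[i], meta$centre_lat[i])
    r_km <- meta$radius_km[i]
    if (config$gradient_mode == "copula") {
      pairs <- simulate_copula_species(meta$n_obs[i], target_rs_sp[i],
                                       seed = seeds[6 + i])
      # map the lognormal distance margin into the range: rank-preserving
      # rescale onto (0, radius], so the target Spearman value survives
      d <- r_km * rank(pairs$distance_km) / (meta$n_obs[i] + 1)
      bearing <- with_seed(seeds[6 + config$n_species + i],
                           runif(meta$n_obs[i], 0, 2 * pi))
      pts <- destination_point(ctr[1], ctr[2], bearing, d / EARTH_RADIUS_KM)
      obs_list[[i]] <- data.frame(species = species[i],
                                  lon = pts[, "lon"], lat = pts[, "lat"],
                                  abundance = pairs$abundance,
                                  stringsAsFactors = FALSE)
    } else {
      sp_obs <- simulate_spatial_species(r_km, ctr, meta$n_obs[i],
                                         config$gradient_strength,
                                         config$noise_sd, seed = seeds[6 + i])
      obs_list[[i]] <- data.frame(species = species[i],
                                  lon = sp_obs$lon, lat = sp_obs$lat,
                                  abundance = sp_obs$abundance,
                                  stringsAsFactors = FALSE)
    }
    # circular range polygon centred on the generating centre
    brg <- seq(0, 2 * pi, length.out = 73)[-73]
    ring <- destination_point(ctr[1], ctr[2], brg, r_km / EARTH_RADIUS_KM)
    ranges[[species[i]]] <- new_range_polygon(list(ring), source = "expert_map")
  }
  truth <- data.frame(species = species, mean_z_true = mean_z,
                      target_rs = target_rs_sp,
                      phylo_deviation = as.numeric(phylo_dev[species]),
                      n_obs = meta$n_obs,
                      centre_lon = meta$centre_lon,
                      centre_lat = meta$centre_lat,
                      radius_km = meta$radius_km,
                      stringsAsFactors = FALSE)
  structure(list(observations = do.call(rbind, obs_list),
                 ranges = ranges, traits = traits, tree = tree,
                 truth = truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d species, %d observations, mode=%s, seed=%d\n",
              nrow(x$traits), nrow(x$observations),
              x$config$gradient_mode, x$config$seed))
  invisible(x)
}

#' Validate the internal consistency of a dataset
#'
#' Checks the contracts downstream stages rely on: every species with
#' observations appears in the trait table and the range set, and every
#' tree tip label matches a species id.
#'
#' @param dataset a `synthetic_dataset` or a list with the same fields.
#' @return `TRUE` invisibly; aborts naming the offending species.
#' @export
validate_dataset <- function(dataset) {
  sp <- unique(dataset$observations$species)
  miss_tr <- setdiff(sp, dataset$traits$species)
  if (length(miss_tr))
    stopf("species missing from traits: %s",
          paste(head(miss_tr, 10), collapse = ", "),
          class = "abundicentre_missing_data")
  miss_rg <- setdiff(sp, names(dataset$ranges))
  if (length(miss_rg))
    stopf("species missing from ranges: %s",
          paste(head(miss_rg, 10), collapse = ", "),
          class = "abundicentre_missing_data")
  tips <- as_phylo(dataset$tree)$tip.label
  bad_tips <- setdiff(tips, dataset$traits$species)
  if (length(bad_tips))
    stopf("tree tips without a species id: %s",
          paste(head(bad_tips, 10), collapse = ", "),
          class = "abundicentre_missing_data")
  invisible(TRUE)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `observations.csv`, `traits.csv`, `ranges.geojson`, `tree.nwk`,
#' `truth.csv` and `config.json` into `dir`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(dataset$observations, file.path(dir, "observations.csv"),
            row.names = FALSE)
  write.csv(dataset$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  write_ranges_geojson(dataset$ranges, file.path(dir, "ranges.geojson"))
  writeLines(dataset$tree, file.path(dir, "tree.nwk"))
  write.csv(dataset$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
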