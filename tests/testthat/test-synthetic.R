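test_that("copula generator hits its target Spearman correlation", {
  d0 <- simulate_copula_species(10000, 0, seed = 1)
  expect_lt(abs(spearman_rs(d0$abundance, d0$distance_km)$rs), 0.03)
  rs_hat <- vapply(1:50, function(s)
    spearman_rs(simulate_copula_species(10000, -0.5, seed = s)$abundance,
                simulate_copula_species(10000, -0.5, seed = s)$distance_km)$rs,
    numeric(1))
  expect_lt(abs(mean(rs_hat) + 0.5), 0.03)
  expect_error(simulate_copula_species(4, 0, seed = 1),
               class = "abundicentre_invalid_argument")
  expect_error(simulate_copula_species(10, -1.2, seed = 1),
               class = "abundicentre_invalid_argument")
  expect_true(all(d0$abundance > 0) && all(d0$distance_km > 0))
})

test_that("copula mean correlation sits within Monte-Carlo error across targets", {
  for (target in c(-0.8, -0.3, 0, 0.3)) {
    rs_hat <- vapply(1:100, function(s) {
      d <- simulate_copula_species(500, target, seed = 7000 + s)
      spearman_rs(d$abundance, d$distance_km)$rs
    }, numeric(1))
    mc_se <- sd(rs_hat) / sqrt(length(rs_hat))
    expect_lt(abs(mean(rs_hat) - target), 2 * mc_se + 0.01)
  }
})

test_that("spatial generator produces the expected gradient sign and containment", {
  ctr <- c(10, 45)
  flat <- vapply(1:100, function(s)
    spearman_rs(simulate_spatial_species(1000, ctr, 100, 0, 1, seed = s)$abundance,
                simulate_spatial_species(1000, ctr, 100, 0, 1, seed = s)$distance_km)$rs,
    numeric(1))
  expect_lt(abs(mean(flat)), 0.02)
  steep <- vapply(1:50, function(s) {
    d <- simulate_spatial_species(1000, ctr, 200, 3, 0.1, seed = 200 + s)
    spearman_rs(d$abundance, d$distance_km)$rs
  }, numeric(1))
  expect_lt(mean(steep), -0.8)
  # edge-peaked: positive gradient sign flips the correlation
  edge <- vapply(1:20, function(s) {
    d <- simulate_spatial_species(1000, ctr, 200, -2, 0.3, seed = 300 + s)
    spearman_rs(d$abundance, d$distance_km)$rs
  }, numeric(1))
  expect_gt(mean(edge), 0.5)
  d <- simulate_spatial_species(800, ctr, 500, 1, 0.5, seed = 4)
  expect_true(all(geodesic_distance_km(d[, c("lon", "lat")],
                                       matrix(ctr, 500, 2, byrow = TRUE,
                                              dimnames = list(NULL, c("lon", "lat"))))
                  <= 800 + 1e-6))
  expect_error(simulate_spatial_species(-5, ctr, 10, 1, 1, seed = 1),
               class = "abundicentre_invalid_argument")
})

test_that("Yule trees are binary, ultrametric, unit depth and reproducible", {
  nwk <- simulate_yule_tree(8, seed = 5)
  expect_identical(nwk, simulate_yule_tree(8, seed = 5))
  expect_false(identical(nwk, simulate_yule_tree(8, seed = 6)))
  tr <- ape::read.tree(text = nwk)
  expect_equal(length(tr$tip.label), 8)
  expect_equal(tr$Nnode, 7)
  depths <- ape::node.depth.edgelength(tr)[1:8]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(max(depths), 1, tolerance = 1e-9)
  expect_error(simulate_yule_tree(1, seed = 1),
               class = "abundicentre_invalid_argument")
})

test_that("lambda traits have the prescribed moments at the independence and Brownian ends", {
  tree <- simulate_yule_tree(40, seed = 8)
  # lambda = 0: i.i.d. Normal(mean, sigma2 * depth); depth = 1 after scaling
  vars <- vapply(1:200, function(s)
    var(simulate_lambda_trait(tree, 0, 0.5, 2, seed = s)), numeric(1))
  expect_equal(mean(vars), 0.5, tolerance = 0.05)
  means <- vapply(1:200, function(s)
    mean(simulate_lambda_trait(tree, 0, 0.5, 2, seed = s)), numeric(1))
  expect_equal(mean(means), 2, tolerance = 0.05)
  # lambda = 0: near-zero cross-tip covariance between sibling tips
  tr <- ape::read.tree(text = tree)
  sib <- tr$tip.label[1:2]
  draws <- vapply(1:200, function(s)
    simulate_lambda_trait(tree, 0, 0.5, 0, seed = s)[sib], numeric(2))
  expect_lt(abs(cor(draws[1, ], draws[2, ])), 0.2)
  expect_identical(simulate_lambda_trait(tree, 0.5, 0.1, 0, seed = 3),
                   simulate_lambda_trait(tree, 0.5, 0.1, 0, seed = 3))
  expect_error(simulate_lambda_trait(tree, 1.5, 1, 0, seed = 1),
               class = "abundicentre_invalid_argument")
})

test_that("full datasets are internally consistent and byte-reproducible", {
  cfg <- simulation_config(n_species = 20, n_obs_range = c(10, 60), seed = 99)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$observations, ds2$observations)
  expect_identical(ds1$tree, ds2$tree)
  expect_identical(ds1$traits, ds2$traits)
  expect_true(validate_dataset(ds1))
  # tampering breaks validation with a named species
  broken <- ds1
  broken$traits <- broken$traits[-1, ]
  expect_error(validate_dataset(broken), class = "abundicentre_missing_data",
               regexp = broken$observations$species[1])
  dir <- withr::local_tempdir()
  write_dataset(ds1, dir)
  expect_setequal(list.files(dir),
                  c("observations.csv", "traits.csv", "ranges.geojson",
                    "tree.nwk", "truth.csv", "config.json"))
  back <- read.csv(file.path(dir, "observations.csv"))
  expect_equal(nrow(back), nrow(ds1$observations))
  rngs <- read_ranges_geojson(file.path(dir, "ranges.geojson"))
  expect_setequal(names(rngs), ds1$traits$species)
})

test_that("the realised per-species correlations track the generator's truth", {
  cfg <- simulation_config(n_species = 25, n_obs_range = c(100, 400),
                           target_rs = -0.3, seed = 17)
  ds <- simulate_dataset(cfg)
  corr <- species_correlations(
    clean_and_filter(
      do.call(rbind, lapply(split(ds$observations, ds$observations$species),
                            function(o) distance_to_centroid(
                              o, range_summary(ds$ranges[[o$species[1]]])))))$observations)
  truth <- ds$truth[match(corr$species, ds$truth$species), ]
  expect_gt(cor(corr$rs, truth$target_rs), 0.6)
  expect_lt(mean(corr$rs) - mean(truth$target_rs), 0.1)
})
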