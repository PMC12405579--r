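test_that("weighted least squares reproduces weighted means and OLS limits", {
  d3 <- data.frame(fisher_z = c(1, 2, 3), weight = 1)
  expect_equal(unname(weighted_lm(d3, fisher_z ~ 1)$coefficients[1, 1]), 2)
  d2 <- data.frame(fisher_z = c(0, 4), weight = c(1, 3))
  expect_equal(unname(weighted_lm(d2, fisher_z ~ 1)$coefficients[1, 1]), 3)
  set.seed(8)
  d <- data.frame(fisher_z = rnorm(40), x = rnorm(40), weight = 1)
  wfit <- weighted_lm(d, fisher_z ~ x)
  ols <- lm(fisher_z ~ x, data = d)
  expect_equal(coef(wfit$fit), coef(ols), tolerance = 1e-10)
  expect_equal(wfit$coefficients[, 2], summary(ols)$coefficients[, 2],
               tolerance = 1e-10)
})

test_that("doubling a weight is equivalent to duplicating the row", {
  set.seed(15)
  d <- data.frame(fisher_z = rnorm(20), x = rnorm(20), weight = 1)
  d$weight[7] <- 2
  dup <- rbind(transform(d, weight = 1), transform(d[7, ], weight = 1))
  f1 <- weighted_lm(d, fisher_z ~ x)
  f2 <- weighted_lm(dup, fisher_z ~ x)
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-10)
})

test_that("the likelihood and AIC follow the weighted Gaussian ML convention", {
  set.seed(2)
  d <- data.frame(fisher_z = rnorm(30), x = rnorm(30),
                  weight = log(sample(5:500, 30, TRUE)))
  fit <- weighted_lm(d, fisher_z ~ x)
  n <- 30
  sigma2 <- fit$rss_w / n
  ll <- 0.5 * sum(log(fit$weights)) -
    0.5 * n * (log(2 * pi * sigma2) + 1)
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-10)
  expect_equal(fit$aic, -2 * ll + 2 * (2 + 1), tolerance = 1e-10)
  # aliased design raises a collinearity error naming the term
  d$x2 <- 2 * d$x
  expect_error(weighted_lm(d, fisher_z ~ x + x2),
               class = "abundicentre_collinearity")
})

test_that("grand mean flags significance by CI exclusion of zero and covers the truth", {
  zeros <- data.frame(fisher_z = rep(0, 10), weight = 1)
  gm0 <- grand_mean(zeros)
  expect_equal(gm0$mean_z, 0)
  expect_false(gm0$significant)
  expect_error(grand_mean(data.frame(fisher_z = 1, weight = 1)),
               class = "abundicentre_invalid_argument")
  hits <- vapply(1:100, function(s) {
    z <- withr::with_seed(s, rnorm(500, -0.1, 0.2))
    gm <- grand_mean(data.frame(fisher_z = z, weight = 1))
    abs(gm$mean_z - (-0.1)) <= 3 * gm$se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise keeps real effects, discards noise, and respects the alpha boundary", {
  # under the null, pure-noise predictors should mostly all be removed
  null_rate <- mean(vapply(1:50, function(s) {
    d <- make_effect_table(500, effect = 0, seed = s)
    sel <- stepwise_select(d, terms = c("x1", "x2", "x3", "x4", "x5"))
    length(sel$final_terms) == 0
  }, logical(1)))
  expect_gte(null_rate, 0.70)
  # a half-SD standardized effect at n = 500 is essentially always kept
  kept <- vapply(1:20, function(s) {
    d <- make_effect_table(500, effect = 0.5 * 0.2, seed = 100 + s)
    sel <- stepwise_select(d, terms = c("group", "x1"))
    "group" %in% sel$final_terms
  }, logical(1))
  expect_true(all(kept))
  # boundary: a term is retained iff its drop-test p <= alpha
  d <- make_effect_table(80, effect = 0.05, seed = 42)
  p_term <- drop1(weighted_lm(d, fisher_z ~ group)$fit, test = "F")["group", "Pr(>F)"]
  just_below <- stepwise_select(d, terms = "group", alpha = p_term + 1e-6)
  just_above <- stepwise_select(d, terms = "group", alpha = p_term - 1e-6)
  expect_identical(just_below$final_terms, "group")
  expect_identical(just_above$final_terms, character(0))
  expect_equal(just_above$trace$p, unname(p_term))
})

test_that("dredge enumerates marginality-respecting models and matches the closed-form counts", {
  expect_equal(length(enumerate_marginal_models(c("A", "B"))), 5)
  sets <- lapply(enumerate_marginal_models(c("A", "B")), sort)
  has_set <- function(s) any(vapply(sets, identical, logical(1), s))
  expect_true(has_set(character(0)))
  expect_true(has_set(c("A", "A:B", "B")))
  expect_false(any(vapply(sets, function(s) "A:B" %in% s && !"A" %in% s, logical(1))))
  expect_equal(count_marginal_models(5), 1450)
  expect_equal(count_marginal_models(6), 40069)
  expect_equal(length(enumerate_marginal_models(c("A", "B", "C"))),
               count_marginal_models(3))
  d <- make_effect_table(60, effect = 0, seed = 3)
  expect_error(dredge_interactions(d, main_terms = c("x1", "x2"), cap = 4),
               class = "abundicentre_invalid_argument")
})

test_that("dredge recovers a true interaction and keeps AIC ties in the best set", {
  hits <- vapply(1:15, function(s) {
    d <- withr::with_seed(s, {
      a <- rnorm(800); b <- rnorm(800)
      data.frame(fisher_z = rnorm(800, 0.1 * a * b, 0.2),
                 a = a, b = b, weight = 1)
    })
    dr <- dredge_interactions(d, main_terms = c("a", "b"))
    "a:b" %in% dr$final_terms
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  # an exact duplicate predictor produces a tied best AIC; both models stay
  d <- make_effect_table(100, effect = 0.3, seed = 5)
  d$g2 <- d$group
  dr <- suppressWarnings(dredge_interactions(d, main_terms = c("group", "g2")))
  expect_gte(min(dr$candidates$delta_aic), 0)
  expect_equal(dr$candidates$delta_aic[1], 0)
  tied <- dr$candidates$delta_aic < 1e-10
  expect_gte(sum(tied), 2)
  expect_true(all(which(tied) %in% dr$best_set))
})

test_that("marginal effects reduce to weighted group means and are coding-invariant", {
  set.seed(44)
  d <- data.frame(species = sprintf("s%02d", 1:40),
                  fisher_z = rnorm(40),
                  g = rep(c("u", "v"), 20),
                  weight = log(sample(5:400, 40, TRUE)))
  fit <- weighted_lm(d, fisher_z ~ g)
  me <- marginal_effects(fit, "g")
  for (lev in c("u", "v")) {
    sub <- d[d$g == lev, ]
    expect_equal(me$predicted_z[me$level_or_grid == lev],
                 weighted.mean(sub$fisher_z, sub$weight), tolerance = 1e-10)
  }
  # intercept-only: marginal prediction is the grand mean
  f0 <- weighted_lm(d, fisher_z ~ 1)
  me0 <- marginal_effects(f0, "g")
  expect_equal(me0$predicted_z, weighted.mean(d$fisher_z, d$weight),
               tolerance = 1e-10)
  # balanced design: recoding the reference level leaves marginal means alone
  d$g_rev <- factor(d$g, levels = c("v", "u"))
  fit2 <- weighted_lm(d, fisher_z ~ g_rev)
  me2 <- marginal_effects(fit2, "g_rev")
  expect_equal(sort(me2$predicted_z), sort(me$predicted_z), tolerance = 1e-10)
  # continuous predictor: grid spans the observed range
  d$x <- rnorm(40)
  fitx <- weighted_lm(d, fisher_z ~ x)
  mex <- marginal_effects(fitx, "x")
  expect_equal(nrow(mex), 10)
  grid <- as.numeric(mex$level_or_grid)
  expect_gte(min(grid), min(d$x) - 1e-9)
  expect_lte(max(grid), max(d$x) + 1e-9)
  expect_error(marginal_effects(fitx, "nope"),
               class = "abundicentre_invalid_argument")
})

test_that("the frequency-weighted average of marginal predictions equals the fitted mean", {
  set.seed(17)
  d <- data.frame(fisher_z = rnorm(60), g = sample(c("a", "b", "c"), 60, TRUE),
                  x = rnorm(60), weight = log(sample(5:900, 60, TRUE)))
  fit <- weighted_lm(d, fisher_z ~ g + x)
  me <- marginal_effects(fit, "g")
  freq <- vapply(levels(factor(d$g)), function(l)
    sum(d$weight[d$g == l]) / sum(d$weight), numeric(1))
  expect_equal(sum(me$predicted_z * freq),
               weighted.mean(fitted(fit$fit), d$weight), tolerance = 1e-10)
})

test_that("collinearity screen flags pairs at the 0.70 threshold", {
  set.seed(6)
  d <- data.frame(x = rnorm(100))
  d$y <- 2 * d$x + 1
  scr <- collinearity_screen(d, c("x", "y"))
  expect_true(scr$flagged)
  expect_equal(scr$r, 1, tolerance = 1e-12)
  ind <- data.frame(a = rnorm(10000), b = rnorm(10000))
  expect_false(any(collinearity_screen(ind, c("a", "b"))$flagged))
  lo <- make_exact_correlation(200, 0.69, seed = 1)
  hi <- make_exact_correlation(200, 0.71, seed = 1)
  expect_false(collinearity_screen(data.frame(lo), c("x", "y"))$flagged)
  expect_true(collinearity_screen(data.frame(hi), c("x", "y"))$flagged)
  expect_error(collinearity_screen(d, "x"), class = "abundicentre_invalid_argument")
})

test_that("selection results are nested and dredge never loses to stepwise on AIC", {
  for (s in 1:5) {
    d <- make_effect_table(150, effect = 0.15, seed = 900 + s)
    pool <- c("group", "x1", "x2")
    sw <- stepwise_select(d, terms = pool)
    expect_true(all(sw$final_terms %in% pool))
    dr <- dredge_interactions(d, main_terms = pool)
    expect_lte(dr$candidates$aic[1], sw$fit$aic + 1e-9)
  }
})
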