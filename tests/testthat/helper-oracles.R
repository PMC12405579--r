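# independent oracles used across the suite; deliberately naive
# implementations that share no code with the package internals

# O(n^3) convex hull: a pair (i, j) is a hull edge iff every other point
# lies on one side of the directed line i -> j
brute_force_hull_vertices <- function(x, y) {
  n <- length(x)
  on_hull <- rep(FALSE, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    cross <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
    others <- cross[-c(i, j)]
    if (all(others <= 1e-12) || all(others >= -1e-12))
      on_hull[c(i, j)] <- TRUE
  }
  which(on_hull)
}

# second haversine implementation, via geosphere on the same sphere radius
oracle_distance_km <- function(a, b) {
  geosphere::distHaversine(a, b, r = 6371.0088 * 1000) / 1000
}

# Brownian covariance by per-pair MRCA path walk over the raw edge matrix;
# does not use ape::vcv
oracle_vcv <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  ancestors <- function(node) {
    path <- node
    while (node != root) { node <- parent[node]; path <- c(path, node) }
    path
  }
  depth_to <- function(node) {   # branch length from root down to `node`
    d <- 0
    while (node != root) { d <- d + elen[node]; node <- parent[node] }
    d
  }
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in 1:ntip) for (j in i:ntip) {
    mrca <- intersect(ancestors(i), ancestors(j))[1]
    if (i == j) mrca <- i
    C[i, j] <- C[j, i] <- depth_to(mrca)
  }
  C
}

# small species-level table with a known binary effect on fisher_z
make_effect_table <- function(n, effect, seed, sd = 0.2) {
  withr::with_seed(seed, {
    g <- factor(rep(c("a", "b"), length.out = n))
    data.frame(species = sprintf("s%03d", 1:n),
               group = g,
               fisher_z = rnorm(n, mean = ifelse(g == "b", effect, 0), sd = sd),
               x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
               x4 = rnorm(n), x5 = rnorm(n),
               weight = log(sample(5:2000, n, replace = TRUE)))
  })
}

# construct two vectors with an exact target sample Pearson correlation
make_exact_correlation <- function(n, r, seed) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    e <- rnorm(n)
    e <- resid(lm(e ~ x))                    # orthogonal to x in-sample
    x_s <- (x - mean(x)) / sd(x)
    e_s <- (e - mean(e)) / sd(e)
    list(x = x_s, y = r * x_s + sqrt(1 - r^2) * e_s)
  })
}
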