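#' @title Per-species abundance-distance correlation statistics
#' @name abundance-correlation
#' @description
#' A species conforms to the abundant-centre pattern when the Spearman rank
#' correlation between log10(abundance) and log10(distance to the range
#' centroid) is negative. These functions implement the cleaning rules
#' (positive abundance and distance, at least five observations per
#' species), the correlation itself, Fisher's Z transformation and ln(n)
#' weights, and group-level conformity summaries.
NULL

#' Clean abundance observations and apply the minimum-sample filter
#'
#' Drops records with nonpositive or missing abundance or distance, then
#' drops species left with fewer than `min_n` observations. Both removals
#' are logged so audit counts satisfy input = used + excluded.
#'
#' @param observations data.frame with columns `species`, `abundance`, and
#'   `distance_km` (plus any others, preserved).
#' @param min_n minimum observations per species (default 5).
#' @return list with `observations` (cleaned), `excluded_records`
#'   (data.frame of dropped rows with a `reason` code),
#'   `excluded_species` (data.frame species/n/reason), and `audit`
#'   (named counts).
#' @export
clean_and_filter <- function(observations, min_n = 5) {
  min_n <- assert_count(min_n, "min_n", min = 1L)
  if (nrow(observations) == 0) {
    warnf("no observations supplied; returning empty result")
    return(list(observations = observations,
                excluded_records = observations,
                excluded_species = data.frame(species = character(),
                                              n = integer(),
                                              reason = character()),
                audit = c(input = 0L, used = 0L, excluded_records = 0L,
                          excluded_species = 0L)))
  }
  ab <- observations$abundance
  d <- observations$distance_km
  bad <- !is.finite(ab) | ab <= 0 | !is.finite(d) | d <= 0
  reason <- ifelse(!is.finite(ab) | ab <= 0, "nonpositive_abundance",
                   "nonpositive_distance")
  excluded_records <- cbind(observations[bad, , drop = FALSE],
                            reason = reason[bad])
  kept <- observations[!bad, , drop = FALSE]
  n_per <- table(kept$species)
  small <- names(n_per)[n_per < min_n]
  excluded_species <- data.frame(
    species = small,
    n = as.integer(n_per[small]),
    reason = rep(sprintf("fewer_than_%d_observations", min_n), length(small)),
    stringsAsFactors = FALSE)
  used <- kept[!(kept$species %in% small), , drop = FALSE]
  rownames(used) <- NULL
  list(observations = used,
       excluded_records = excluded_records,
       excluded_species = excluded_species,
       audit = c(input = nrow(observations),
                 used = nrow(used),
                 excluded_records = nrow(excluded_records),
                 excluded_species = length(small)))
}

#' Log10-transform abundance/distance pairs
#'
#' Cleaning guarantees strictly positive values; a nonpositive value
#' reaching this point signals a breached contract and raises an
#' invalid-state error rather than producing `-Inf`.
#'
#' @param observations cleaned data.frame with `abundance`, `distance_km`.
#' @return list of numeric vectors `log10_abundance`, `log10_distance`.
#' @export
log10_pairs <- function(observations) {
  ab <- observations$abundance
  d <- observations$distance_km
  if (any(!is.finite(ab) | ab <= 0) || any(!is.finite(d) | d <= 0))
    stopf("nonpositive abundance/distance after cleaning: run clean_and_filter() first",
          class = "abundicentre_invalid_state")
  list(log10_abundance = log10(ab), log10_distance = log10(d))
}

# exact two-sided permutation p for Spearman's rs, tie-free samples;
# enumerates the null distribution of rs over all n! rank permutations
# (cached per n)
spearman_exact_null <- local({
  cache <- list()
  all_perms <- function(n) {
    if (n == 1) return(matrix(1L))
    sub <- all_perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i)
      cbind(i, sub + (sub >= i))))
  }
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      P <- all_perms(n)
      r <- seq_len(n)
      # rs for ranks r vs permuted ranks: 1 - 6*S/(n(n^2-1))
      S <- rowSums((P - matrix(r, nrow(P), n, byrow = TRUE))^2)
      cache[[key]] <<- sort(1 - 6 * S / (n * (n^2 - 1)))
    }
    cache[[key]]
  }
})

#' Spearman rank correlation with p-value
#'
#' `rs` is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p-value uses the exact permutation null distribution for
#' tie-free samples with `n <= exact_max_n`, and otherwise the
#' t-approximation `t = rs * sqrt((n-2)/(1-rs^2))` on `n - 2` df. A
#' perfect correlation (`|rs| = 1`) gets the smallest representable
#' positive p and is flagged via the `"boundary"` attribute.
#'
#' @param x,y numeric vectors of equal length `n >= 5`.
#' @param exact_max_n largest tie-free n for which the exact permutation
#'   null is used (default 8).
#' @return list `rs`, `p_value`, `n`, `method`.
#' @export
spearman_rs <- function(x, y, exact_max_n = 8) {
  if (length(x) != length(y))
    stopf("x and y must have equal length", class = "abundicentre_invalid_argument")
  n <- length(x)
  if (n < 5)
    stopf("need at least 5 paired observations (got %d)", n,
          class = "abundicentre_invalid_argument")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("non-finite values in correlation input",
          class = "abundicentre_invalid_argument")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    stopf("constant vector: Spearman correlation undefined",
          class = "abundicentre_undefined_correlation")
  rs <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  boundary <- FALSE
  if (abs(rs) >= 1 - 1e-15) {
    rs <- sign(rs)
    p <- .Machine$double.xmin
    boundary <- TRUE
    method <- "boundary"
  } else if (!ties && n <= exact_max_n) {
    null_rs <- spearman_exact_null(n)
    p <- mean(abs(null_rs) >= abs(rs) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  structure(list(rs = rs, p_value = p, n = n, method = method),
            boundary = boundary)
}

#' Fisher's Z transformation of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * ln((1+r)/(1-r))`, the variance-stabilising
#' transform under which correlations can be averaged and modelled
#' approximately normally. `|r| = 1` is clamped to `1 - 1e-12` before the
#' transform (keeping `|Z|` near 14 rather than infinite); clamped entries
#' are flagged in the `"clamped"` attribute.
#'
#' @param rs correlation(s) in `[-1, 1]`.
#' @return Fisher's Z value(s).
#' @examples
#' fisher_z(0.5)   # 0.549306...
#' @export
fisher_z <- function(rs) {
  if (any(!is.finite(rs)) || any(abs(rs) > 1))
    stopf("correlations must be finite and within [-1, 1]",
          class = "abundicentre_invalid_argument")
  eps <- 1e-12
  clamped <- abs(rs) > 1 - eps
  z <- atanh(pmin(pmax(rs, -1 + eps), 1 - eps))
  if (any(clamped)) attr(z, "clamped") <- which(clamped)
  z
}

#' Per-species abundance-distance correlations
#'
#' For each species: Spearman `rs` between log10(abundance) and
#' log10(distance to the range centroid), its p-value, Fisher's Z, the
#' meta-analytic weight `ln(n)`, and the abundant-centre conformity flag
#' (`rs < 0`).
#'
#' @param observations cleaned data.frame with `species`, `abundance`,
#'   `distance_km` (run [clean_and_filter()] first).
#' @return data.frame of class `species_correlation` with columns
#'   `species`, `n_obs`, `rs`, `p_value`, `fisher_z`, `weight`,
#'   `conforms_abundant_centre`.
#' @export
species_correlations <- function(observations) {
  species <- unique(observations$species)
  rows <- lapply(species, function(sp) {
    obs <- observations[observations$species == sp, , drop = FALSE]
    lp <- log10_pairs(obs)
    ct <- spearman_rs(lp$log10_distance, lp$log10_abundance)
    data.frame(species = sp, n_obs = ct$n, rs = ct$rs, p_value = ct$p_value,
               fisher_z = as.numeric(fisher_z(ct$rs)), weight = log(ct$n),
               conforms_abundant_centre = ct$rs < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_correlation", "data.frame")
  out
}

#' Group-level conformity summaries
#'
#' Tallies, per group, how many species have negative abundance-distance
#' correlations (`rs < 0`, the abundant-centre pattern) versus `rs >= 0`,
#' and within each side the percentage with `p < 0.05`. Percentages are
#' rounded half-away-from-zero to one decimal, matching how such tables
#' are conventionally printed.
#'
#' @param correlations a `species_correlation` data.frame (or any
#'   data.frame with `species`, `rs`, `p_value`).
#' @param grouping named character vector (species -> label), or the name
#'   of a grouping column already present in `correlations`.
#' @param alpha significance threshold for the `% p < alpha` columns.
#' @return data.frame with one row per group: `group`, `n_species`,
#'   `n_negative`, `pct_negative`, `pct_negative_significant`,
#'   `n_nonnegative`, `pct_nonnegative_significant`.
#' @export
summarize_groups <- function(correlations, grouping, alpha = 0.05) {
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(correlations)) {
    labels <- as.character(correlations[[grouping]])
  } else {
    labels <- unname(grouping[as.character(correlations$species)])
  }
  missing <- is.na(labels)
  if (any(missing))
    stopf("no group label for species: %s",
          paste(head(correlations$species[missing], 10), collapse = ", "),
          class = "abundicentre_missing_data")
  rows <- lapply(sort(unique(labels)), function(g) {
    sub <- correlations[labels == g, , drop = FALSE]
    neg <- sub$rs < 0
    data.frame(
      group = g,
      n_species = nrow(sub),
      n_negative = sum(neg),
      pct_negative = round_half_up(100 * mean(neg), 1),
      pct_negative_significant =
        if (any(neg)) round_half_up(100 * mean(sub$p_value[neg] < alpha), 1) else NA_real_,
      n_nonnegative = sum(!neg),
      pct_nonnegative_significant =
        if (any(!neg)) round_half_up(100 * mean(sub$p_value[!neg] < alpha), 1) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
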