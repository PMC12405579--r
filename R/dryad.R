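#' Read a deposited per-species correlation table
#'
#' Loads a CSV of per-species abundance-distance correlation coefficients
#' (one row per species) such as the deposited tables accompanying
#' published compilations, normalising common column spellings: a species
#' identifier, the Spearman correlation (`rs`/`r_s`/`spearman`), the
#' per-species sample size (`n`/`n_obs`/`sample_size`), and optionally a
#' taxon/group column. Fisher's Z and the ln(n) weight are recomputed
#' from the loaded columns so downstream modelling never trusts derived
#' fields in the file.
#'
#' @param path CSV file path.
#' @return data.frame with columns `species`, `n_obs`, `rs`, `fisher_z`,
#'   `weight`, plus any group columns present.
#' @export
read_dryad_correlations <- function(path) {
  if (!file.exists(path))
    stopf("deposited correlation table not found at %s", path,
          class = "abundicentre_missing_data")
  raw <- read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(raw))
  pick <- function(cands) {
    hit <- match(cands, nm)
    hit <- hit[!is.na(hit)]
    if (!length(hit)) NA_integer_ else hit[1]
  }
  i_sp <- pick(c("species", "species_name", "sp", "taxon"))
  i_rs <- pick(c("rs", "r_s", "spearman", "spearman_rs", "cor", "r"))
  i_n <- pick(c("n", "n_obs", "nobs", "sample_size", "n_observations"))
  if (is.na(i_sp) || is.na(i_rs) || is.na(i_n))
    stopf("could not locate species / rs / n columns in %s (found: %s)",
          path, paste(names(raw), collapse = ", "),
          class = "abundicentre_invalid_argument")
  out <- data.frame(species = as.character(raw[[i_sp]]),
                    n_obs = as.integer(raw[[i_n]]),
                    rs = as.numeric(raw[[i_rs]]),
                    stringsAsFactors = FALSE)
  out <- out[is.finite(out$rs) & out$n_obs >= 5, ]
  out$fisher_z <- as.numeric(fisher_z(out$rs))
  out$weight <- log(out$n_obs)
  extra <- setdiff(seq_along(raw), c(i_sp, i_rs, i_n))
  for (j in extra) out[[names(raw)[j]]] <- raw[[j]][match(out$species, raw[[i_sp]])]
  out
}
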