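# internal helpers shared across modules

# mean Earth radius, km (WGS84 mean radius)
EARTH_RADIUS_KM <- 6371.0088

stopf <- function(fmt, ..., class = "abundicentre_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stopf("`%s` must be a single finite number", name,
          class = "abundicentre_invalid_argument")
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name)
  if (x != as.integer(x) || x < min)
    stopf("`%s` must be an integer >= %d (got %s)", name, min, format(x),
          class = "abundicentre_invalid_argument")
  invisible(as.integer(x))
}

# round half away from zero, for report parity with printed tables
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seeds derived from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
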