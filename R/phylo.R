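#' @title Phylogenetic signal in effect sizes: Pagel's lambda and PGLS
#' @name phylo-signal
#' @description
#' Species-level Fisher's Z values (or model residuals) are tested for
#' phylogenetic signal under Pagel's lambda model: the trait covariance is
#' `sigma2 * C(lambda)` where `C` is the Brownian (shared-path-length)
#' matrix of the tree and `lambda` in `[0, 1]` multiplies its
#' off-diagonal. `lambda = 0` means independence (no signal), `lambda = 1`
#' full Brownian signal. Lambda is estimated by maximum likelihood with
#' the mean and variance profiled analytically, and generalised
#' least-squares fits are compared by AIC at `lambda` fixed to 0 or 1 or
#' jointly fitted.
NULL

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) return(ape::read.tree(text = tree))
  stopf("`tree` must be an ape phylo object or a Newick string",
        class = "abundicentre_invalid_argument")
}

#' Brownian covariance matrix from a phylogeny
#'
#' `C[i, j]` is the shared branch length from the root to the most recent
#' common ancestor of tips i and j; `C[i, i]` is the root-to-tip depth.
#' Species requested but absent from the tree are dropped with a warning
#' listing them. Zero or negative branch lengths are padded to 1e-8
#' before the computation so the matrix stays positive definite.
#'
#' @param tree an `ape::phylo` or Newick string.
#' @param tips optional subset of tip labels (order of the result).
#' @return symmetric positive-semidefinite matrix indexed by tip labels.
#' @export
brownian_covariance <- function(tree, tips = NULL) {
  tree <- as_phylo(tree)
  if (any(tree$edge.length <= 0)) {
    tree$edge.length[tree$edge.length <= 0] <- 1e-8
    warnf("nonpositive branch lengths padded to 1e-8")
  }
  if (is.null(tips)) tips <- tree$tip.label
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) == length(tips))
    stopf("no overlap between requested tips and tree tip labels",
          class = "abundicentre_invalid_argument")
  if (length(missing))
    warnf("%d species absent from the tree were dropped: %s",
          length(missing), paste(head(missing, 10), collapse = ", "))
  tips <- setdiff(tips, missing)
  if (length(tips) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, tips)
  C <- ape::vcv(tree)
  C[tips, tips, drop = FALSE]
}

#' Pagel's lambda transformation of a covariance matrix
#'
#' Multiplies every off-diagonal entry by `lambda`, leaving the diagonal
#' unchanged. `lambda = 0` gives a diagonal (independence) matrix,
#' `lambda = 1` returns the matrix untouched.
#'
#' @param C covariance (or correlation) matrix.
#' @param lambda scalar in `[0, 1]`.
#' @export
lambda_transform <- function(C, lambda) {
  assert_scalar_number(lambda, "lambda")
  if (lambda < 0 || lambda > 1)
    stopf("lambda must be in [0, 1] (got %g)", lambda,
          class = "abundicentre_invalid_argument")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# correlation scale covariance for a given lambda, combined with optional
# observation weights: V = D^{1/2} corr(C)(lambda) D^{1/2}, D = diag(1/w)
build_v <- function(Cc, lambda, inv_w = NULL) {
  V <- lambda_transform(Cc, lambda)
  if (!is.null(inv_w)) {
    s <- sqrt(inv_w)
    V <- V * tcrossprod(s)
  }
  V
}

# profiled Gaussian log-likelihood of y ~ N(X beta, sigma2 V); returns
# beta, sigma2 (ML), logLik; jitters the diagonal if Cholesky fails
gls_profile <- function(y, X, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    ch <- tryCatch(chol(V + diag(1e-10, n)), error = function(e)
      stopf("phylogenetic covariance is numerically singular even after 1e-10 jitter",
            class = "abundicentre_numerical"))
  # whiten: solve L' z = y  with V = L'L (chol gives upper R, V = R'R)
  yt <- backsolve(ch, y, transpose = TRUE)
  Xt <- backsolve(ch, X, transpose = TRUE)
  qrX <- qr(Xt)
  beta <- qr.coef(qrX, yt)
  res <- yt - Xt %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  XtX_inv <- chol2inv(qr.R(qrX))
  list(beta = drop(beta), sigma2 = sigma2, log_likelihood = ll,
       cov_unscaled = XtX_inv, rss = rss)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximises the multivariate-normal likelihood of tip values with
#' covariance `sigma2 * V(lambda)`, where `V(lambda)` is the
#' lambda-transformed phylogenetic correlation matrix (the Brownian
#' covariance is converted to a correlation matrix first, making lambda
#' comparable across non-ultrametric trees), optionally combined with
#' per-tip observation weights as `V = D^{1/2} corr(C(lambda)) D^{1/2}`,
#' `D = diag(1/w)`. The mean and variance are profiled analytically;
#' lambda is optimised on `[0, 1]` by bounded search (tolerance 1e-6)
#' with both boundary values checked explicitly. A likelihood-ratio test
#' against `lambda = 0` uses the chi-square distribution with 1 df.
#'
#' @param values named numeric vector (names = tip labels).
#' @param tree an `ape::phylo` or Newick string.
#' @param weights optional named positive weights (larger = more precise).
#' @return A `lambda_fit` list: `lambda_hat`, `sigma2_hat`, `mu_hat`,
#'   `log_likelihood`, `loglik_lambda0`, `loglik_lambda1`,
#'   `lr_statistic`, `p_value`, `aic`, `aic_lambda0`, `aic_lambda1`,
#'   `n_tips`.
#' @export
ml_lambda <- function(values, tree, weights = NULL) {
  tree <- as_phylo(tree)
  common <- intersect(names(values), tree$tip.label)
  if (length(common) < 3)
    stopf("need >= 3 tips matched between values and tree",
          class = "abundicentre_invalid_argument")
  dropped <- setdiff(names(values), common)
  if (length(dropped))
    warnf("%d values without matching tips dropped", length(dropped))
  C <- brownian_covariance(tree, common)
  y <- as.numeric(values[common])
  n <- length(y)
  Cc <- stats::cov2cor(C)
  inv_w <- if (!is.null(weights)) 1 / as.numeric(weights[common])
  X <- matrix(1, n, 1)
  ll_at <- function(lam) gls_profile(y, X, build_v(Cc, lam, inv_w))$log_likelihood
  opt <- optimize(ll_at, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  cands <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll_at(0), ll_at(1))
  best <- which.max(lls)
  lambda_hat <- cands[best]
  prof <- gls_profile(y, X, build_v(Cc, lambda_hat, inv_w))
  lr <- max(0, 2 * (lls[best] - lls[2]))
  structure(list(
    lambda_hat = lambda_hat,
    sigma2_hat = prof$sigma2,
    mu_hat = unname(prof$beta[1]),
    log_likelihood = lls[best],
    loglik_lambda0 = lls[2],
    loglik_lambda1 = lls[3],
    lr_statistic = lr,
    p_value = pchisq(lr, df = 1, lower.tail = FALSE),
    aic = -2 * lls[best] + 2 * 3,          # mu, sigma2, lambda
    aic_lambda0 = -2 * lls[2] + 2 * 2,
    aic_lambda1 = -2 * lls[3] + 2 * 2,
    n_tips = n), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("<lambda_fit> lambda=%.4f sigma2=%.4g logLik=%.3f LR=%.3f p=%.3g (n=%d)\n",
              x$lambda_hat, x$sigma2_hat, x$log_likelihood,
              x$lr_statistic, x$p_value, x$n_tips))
  invisible(x)
}

#' Phylogenetic generalised least squares
#'
#' ML generalised least squares of a species-level response on predictor
#' terms with error covariance `sigma2 * V(lambda)` (see [ml_lambda()]
#' for the construction of `V`). `lambda` may be fixed at any value in
#' `[0, 1]` or jointly optimised (`"fit"`). `AIC = -2 logLik + 2k`,
#' counting the coefficients, the variance, and lambda when fitted. At
#' `lambda = 0` without weights the fit reduces to OLS; at `lambda = 0`
#' with weights, to weighted least squares.
#'
#' @param data data.frame with a `species` column matching tree tips.
#' @param formula model formula (e.g. `fisher_z ~ 1`).
#' @param tree an `ape::phylo` or Newick string.
#' @param lambda `"fit"`, or a number in `[0, 1]`.
#' @param weights optional positive weights: vector aligned with `data`
#'   rows, or a column name (default `NULL`, unweighted).
#' @return A `pgls_fit` list: `terms`, `coefficients` (estimate/se/t/p),
#'   `lambda_used`, `lambda_fitted`, `sigma2`, `log_likelihood`, `aic`,
#'   `weights_used`, `residuals`, `n`.
#' @export
pgls <- function(data, formula, tree, lambda = "fit", weights = NULL) {
  tree <- as_phylo(tree)
  data <- prepare_model_data(as.data.frame(data))
  if (!"species" %in% names(data))
    stopf("`data` must have a `species` column matching tree tips",
          class = "abundicentre_invalid_argument")
  if (is.character(weights) && length(weights) == 1) weights <- data[[weights]]
  common <- intersect(data$species, tree$tip.label)
  if (length(common) < 3)
    stopf("need >= 3 species matched between data and tree",
          class = "abundicentre_invalid_argument")
  if (length(common) < nrow(data))
    warnf("%d species absent from the tree were dropped",
          nrow(data) - length(common))
  idx <- match(common, data$species)
  data <- data[idx, , drop = FALSE]
  w <- if (!is.null(weights)) as.numeric(weights)[idx]
  C <- brownian_covariance(tree, common)
  Cc <- stats::cov2cor(C)
  inv_w <- if (!is.null(w)) 1 / w
  mf <- model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, data)
  fit_at <- function(lam) gls_profile(y, X, build_v(Cc, lam, inv_w))
  fitted_lambda <- identical(lambda, "fit")
  if (fitted_lambda) {
    opt <- optimize(function(l) fit_at(l)$log_likelihood,
                    interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    cands <- c(opt$maximum, 0, 1)
    lls <- vapply(cands, function(l) fit_at(l)$log_likelihood, numeric(1))
    lambda <- cands[which.max(lls)]
  } else {
    assert_scalar_number(lambda, "lambda")
    if (lambda < 0 || lambda > 1)
      stopf("lambda must be in [0,1] or \"fit\"",
            class = "abundicentre_invalid_argument")
  }
  prof <- fit_at(lambda)
  k <- ncol(X) + 1L + as.integer(fitted_lambda)
  se <- sqrt(prof$sigma2 * diag(prof$cov_unscaled))
  est <- prof$beta
  tval <- est / se
  n <- length(y)
  coefs <- cbind(Estimate = est, `Std. Error` = se, `t value` = tval,
                 `Pr(>|t|)` = 2 * pt(-abs(tval), df = n - ncol(X)))
  rownames(coefs) <- colnames(X)
  res <- setNames(drop(y - X %*% est), common)
  structure(list(
    terms = attr(terms(formula), "term.labels"),
    coefficients = coefs,
    lambda_used = lambda,
    lambda_fitted = fitted_lambda,
    sigma2 = prof$sigma2,
    log_likelihood = prof$log_likelihood,
    aic = -2 * prof$log_likelihood + 2 * k,
    weights_used = !is.null(w),
    residuals = res,
    species = common,
    n = n), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> lambda=%.4f%s logLik=%.3f AIC=%.2f n=%d weights=%s\n",
              x$lambda_used, if (x$lambda_fitted) " (fitted)" else "",
              x$log_likelihood, x$aic, x$n,
              if (x$weights_used) "yes" else "no"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Compare PGLS fits at lambda 0, 1 and fitted
#'
#' Fits the same model three times with lambda fixed at 0 (no signal),
#' fixed at 1 (full Brownian signal), and jointly optimised, and reports
#' the AIC of each — the comparison used to decide whether phylogeny
#' improves the model.
#'
#' @inheritParams pgls
#' @return data.frame with rows lambda0 / lambda1 / lambda_fit: `lambda`,
#'   `log_likelihood`, `aic`; fitted models attached as attribute
#'   `"fits"`.
#' @export
pgls_lambda_comparison <- function(data, formula, tree, weights = NULL) {
  fits <- list(lambda0 = pgls(data, formula, tree, lambda = 0, weights = weights),
               lambda1 = pgls(data, formula, tree, lambda = 1, weights = weights),
               lambda_fit = pgls(data, formula, tree, lambda = "fit", weights = weights))
  out <- data.frame(
    model = names(fits),
    lambda = vapply(fits, `[[`, numeric(1), "lambda_used"),
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Phylogenetic signal in the residuals of a weighted model
#'
#' Applies [ml_lambda()] to the (unweighted) residuals of a fitted
#' weighted linear model, testing whether what the predictors leave
#' unexplained is still structured by relatedness.
#'
#' @param fit a `wlm_fit` whose residuals are named by species.
#' @param tree an `ape::phylo` or Newick string.
#' @return A `lambda_fit` (see [ml_lambda()]).
#' @export
residual_signal <- function(fit, tree) {
  stopifnot(inherits(fit, "wlm_fit"))
  res <- fit$residuals
  if (is.null(names(res)) || !any(names(res) %in% as_phylo(tree)$tip.label))
    stopf("fit residuals are not named by species present in the tree",
          class = "abundicentre_invalid_argument")
  ml_lambda(res, tree, weights = NULL)
}
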