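#' @title Weighted meta-analytic models of Fisher's Z
#' @name meta-models
#' @description
#' Species-level Fisher's Z values are modelled by weighted least squares
#' with weights ln(n): intercept-only grand means, fixed-effect models,
#' backward stepwise selection by nested-model F-tests, all-subsets
#' enumeration of main effects plus two-way interactions ranked by AIC,
#' marginal effects, and a pairwise collinearity screen for the continuous
#' predictors.
NULL

# build a factor-coded model frame with deterministic treatment coding:
# character columns become factors with alphabetically sorted levels
prepare_model_data <- function(data) {
  for (nm in names(data)) {
    if (is.character(data[[nm]])) data[[nm]] <- factor(data[[nm]], levels = sort(unique(data[[nm]])))
    if (is.logical(data[[nm]])) data[[nm]] <- factor(data[[nm]], levels = c(FALSE, TRUE))
  }
  data
}

#' Weighted least-squares fit of Fisher's Z
#'
#' Thin wrapper over [stats::lm()] with case weights, returning the
#' quantities the meta-analysis needs: coefficients with standard errors
#' and t-based 95% CIs, weighted RSS, the Gaussian weighted log-likelihood
#' (which includes the `+0.5 * sum(log(w))` constant so AICs are
#' comparable across models on the same data), and `AIC = -2 logLik +
#' 2(k + 1)` counting the residual variance as a parameter. For the
#' intercept-only model the intercept is the weighted mean
#' `sum(w z) / sum(w)`.
#'
#' Categorical predictors are treatment-coded with the alphabetically
#' first level as reference. A rank-deficient design raises a collinearity
#' error naming the aliased coefficients.
#'
#' @param data data.frame of species-level rows (response + predictors).
#' @param formula model formula, e.g. `fisher_z ~ group + log10_body_size`.
#' @param weights numeric vector of positive weights (recycled if length
#'   1), or the name of a column in `data`; default the `weight` column.
#' @return A `wlm_fit` list: `fit` (the underlying `lm`), `terms`,
#'   `coefficients` (matrix with estimate/se/t/p), `ci_95`, `df_residual`,
#'   `rss_w`, `log_likelihood`, `aic`, `residuals`, `weights`, `species`.
#' @export
weighted_lm <- function(data, formula, weights = "weight") {
  data <- prepare_model_data(as.data.frame(data))
  w <- if (is.character(weights) && length(weights) == 1) data[[weights]] else weights
  if (is.null(w)) stopf("no weights found", class = "abundicentre_invalid_argument")
  w <- rep_len(as.numeric(w), nrow(data))
  if (any(!is.finite(w) | w <= 0))
    stopf("weights must be positive and finite",
          class = "abundicentre_invalid_argument")
  data$.w <- w
  fit <- lm(formula, data = data, weights = .w)
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stopf("rank-deficient design; aliased terms: %s",
          paste(aliased, collapse = ", "), class = "abundicentre_collinearity")
  }
  sm <- summary(fit)
  ll <- as.numeric(logLik(fit))
  res <- resid(fit)
  species <- if ("species" %in% names(data)) as.character(data$species) else rownames(data)
  names(res) <- species
  structure(list(
    fit = fit,
    formula = formula,
    terms = attr(terms(fit), "term.labels"),
    coefficients = sm$coefficients,
    ci_95 = confint(fit, level = 0.95),
    df_residual = fit$df.residual,
    rss_w = sum(w * res^2),
    log_likelihood = ll,
    aic = AIC(fit),
    residuals = res,
    weights = w,
    species = species,
    data = data), class = "wlm_fit")
}

#' @export
print.wlm_fit <- function(x, ...) {
  cat(sprintf("<wlm_fit> %s | n=%d, logLik=%.3f, AIC=%.2f\n",
              deparse(x$formula), length(x$residuals),
              x$log_likelihood, x$aic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Weighted grand mean Fisher's Z
#'
#' The grand mean effect is the intercept of a weighted intercept-only
#' model, i.e. the ln(n)-weighted average of the species-level Fisher's Z
#' values. It is called significant when the t-based 95% confidence
#' interval of the intercept excludes zero.
#'
#' @param data data.frame with a `fisher_z` column, or a numeric vector of
#'   Fisher's Z values.
#' @param weights positive weights (default the `weight` column, or equal
#'   weights for a bare vector).
#' @return list `mean_z`, `se`, `t`, `df`, `p`, `ci_95`, `significant`,
#'   `n`, and the underlying `fit`.
#' @export
grand_mean <- function(data, weights = "weight") {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- data.frame(fisher_z = data)
    if (identical(weights, "weight")) weights <- rep(1, nrow(data))
  }
  if (nrow(data) < 2)
    stopf("grand mean needs at least 2 species",
          class = "abundicentre_invalid_argument")
  fit <- weighted_lm(data, fisher_z ~ 1, weights = weights)
  est <- fit$coefficients[1, ]
  ci <- fit$ci_95[1, ]
  list(mean_z = unname(est["Estimate"]), se = unname(est["Std. Error"]),
       t = unname(est["t value"]), df = fit$df_residual,
       p = unname(est["Pr(>|t|)"]), ci_95 = unname(ci),
       significant = ci[1] > 0 || ci[2] < 0,
       n = length(fit$residuals), fit = fit)
}

#' Backward stepwise selection by nested-model F-tests
#'
#' Starting from the full model, each step computes the nested-model
#' F-test for dropping every currently droppable term (whole categorical
#' terms dropped as blocks, via [stats::drop1()]), removes the term with
#' the largest p-value if it exceeds `alpha`, and stops when every
#' remaining term has `p <= alpha`. Ties are broken by term name order.
#' Backward-only; dropped terms do not re-enter.
#'
#' @param data species-level data.frame.
#' @param response name of the response column (default `"fisher_z"`).
#' @param terms character vector of candidate predictor terms.
#' @param weights weights as in [weighted_lm()].
#' @param alpha retention threshold (default 0.05); a term with
#'   `p = alpha` exactly is retained.
#' @return A `model_selection` list: `final_terms`, `fit` (the final
#'   `wlm_fit`), and `trace` (data.frame of drops with F and p).
#' @export
stepwise_select <- function(data, response = "fisher_z", terms,
                            weights = "weight", alpha = 0.05) {
  current <- sort(terms)
  trace <- data.frame(step = integer(), dropped = character(),
                      F = numeric(), p = numeric(), stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    fml <- reformulate(if (length(current)) current else "1", response = response)
    fit <- weighted_lm(data, fml, weights = weights)
    if (!length(current)) break
    d1 <- drop1(fit$fit, test = "F")
    cand <- d1[-1, , drop = FALSE]          # skip the <none> row
    pvals <- cand[["Pr(>F)"]]
    names(pvals) <- rownames(cand)
    pvals <- pvals[order(-pvals, names(pvals))]  # largest p first, name tiebreak
    if (!length(pvals) || pvals[1] <= alpha) break
    worst <- names(pvals)[1]
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(
      step = step_i, dropped = worst,
      F = cand[worst, "F value"], p = pvals[[1]],
      stringsAsFactors = FALSE))
    current <- setdiff(current, worst)
  }
  structure(list(final_terms = current, fit = fit, trace = trace),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection>\n final terms:",
      if (length(x$final_terms)) paste(x$final_terms, collapse = " + ")
      else "(intercept only)", "\n")
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat(" dropped:\n"); print(x$trace)
  }
  if (!is.null(x$candidates))
    cat(sprintf(" %d candidate models, best set (dAIC<2): %d\n",
                nrow(x$candidates), length(x$best_set)))
  invisible(x)
}

# fit `response ~ terms`, dropping whole aliased terms until the design
# has full rank; interactions are pruned before main effects
prune_aliased_terms <- function(data, response, tms, weights) {
  repeat {
    fml <- reformulate(if (length(tms)) tms else "1", response = response)
    hit <- tryCatch(list(fit = weighted_lm(data, fml, weights = weights)),
                    abundicentre_collinearity = function(e) e)
    if (!inherits(hit, "condition")) return(list(fit = hit$fit, terms = tms))
    pdata <- prepare_model_data(as.data.frame(data))
    w <- if (is.character(weights) && length(weights) == 1) pdata[[weights]] else weights
    pdata$.w <- rep_len(as.numeric(w), nrow(pdata))
    raw <- lm(fml, data = pdata, weights = .w, singular.ok = TRUE)
    asn <- attr(model.matrix(raw), "assign")
    labels <- attr(terms(raw), "term.labels")
    aliased <- unique(labels[asn[is.na(coef(raw))]])
    drop_from <- if (any(grepl(":", aliased))) aliased[grepl(":", aliased)] else aliased
    if (!length(drop_from)) stop(hit)
    warnf("dropping aliased term(s) from the union model: %s",
          paste(drop_from, collapse = ", "))
    # terms() may reorder interaction components; match canonically
    canon <- function(t) vapply(strsplit(t, ":", fixed = TRUE),
                                function(p) paste(sort(p), collapse = ":"),
                                character(1))
    new_tms <- tms[!canon(tms) %in% canon(drop_from)]
    if (length(new_tms) == length(tms)) stop(hit)   # no progress: give up
    tms <- new_tms
  }
}

# all subsets of main effects and two-way interactions obeying marginality
enumerate_marginal_models <- function(main_terms, interactions = TRUE) {
  mains <- sort(main_terms)
  models <- list(character(0))
  for (k in seq_along(mains)) {
    for (S in combn(mains, k, simplify = FALSE)) {
      if (!interactions || length(S) < 2) { models <- c(models, list(S)); next }
      pairs <- combn(S, 2, FUN = function(p) paste(p, collapse = ":"))
      for (j in 0:length(pairs)) {
        if (j == 0) { models <- c(models, list(S)); next }
        for (I in combn(pairs, j, simplify = FALSE))
          models <- c(models, list(c(S, I)))
      }
    }
  }
  models
}

# closed-form count of the enumeration above, to enforce the cap cheaply
count_marginal_models <- function(n_mains, interactions = TRUE) {
  k <- 0:n_mains
  if (!interactions) return(sum(choose(n_mains, k)))
  sum(choose(n_mains, k) * 2^(choose(k, 2)))
}

#' All-subsets model enumeration with two-way interactions, ranked by AIC
#'
#' Enumerates every model containing any combination of the candidate main
#' effects and any subset of their two-way interactions, subject to
#' marginality (an interaction `A:B` only enters alongside both `A` and
#' `B`). Each candidate is fitted by [weighted_lm()] (maximum-likelihood
#' variance) and ranked by AIC. The best set contains every model with
#' `delta AIC < 2` from the minimum; the final interaction model is the
#' union of all fixed and interaction terms appearing in the best set.
#'
#' @param data species-level data.frame.
#' @param response response column name (default `"fisher_z"`).
#' @param main_terms candidate main-effect terms.
#' @param weights weights as in [weighted_lm()].
#' @param delta_aic inclusion threshold for the best set (default 2).
#' @param cap refuse enumeration above this many candidate models
#'   (default 100000).
#' @return A `model_selection` list: `candidates` (data.frame of terms,
#'   k, aic, delta_aic, ordered by AIC), `best_set` (row indices with
#'   `delta_aic < delta_aic` threshold), `final_terms`, `fit` (the final
#'   union model).
#' @export
dredge_interactions <- function(data, response = "fisher_z", main_terms,
                                weights = "weight", delta_aic = 2,
                                cap = 1e5) {
  n_models <- count_marginal_models(length(main_terms))
  if (n_models > cap)
    stopf(paste0("enumeration of %d candidate models exceeds cap %d; ",
                 "reduce the candidate term pool or raise `cap`"),
          n_models, cap, class = "abundicentre_invalid_argument")
  models <- enumerate_marginal_models(main_terms)
  rows <- lapply(models, function(tms) {
    fml <- reformulate(if (length(tms)) tms else "1", response = response)
    fit <- tryCatch(weighted_lm(data, fml, weights = weights),
                    abundicentre_collinearity = function(e) NULL)
    if (is.null(fit)) return(NULL)   # unestimable candidate: skip
    data.frame(terms = if (length(tms)) paste(tms, collapse = " + ") else "1",
               k = length(coef(fit$fit)), aic = fit$aic,
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (sum(!keep))
    warnf("%d candidate models were rank-deficient and skipped", sum(!keep))
  cand <- do.call(rbind, rows[keep])
  cand$term_list <- models[keep]
  cand <- cand[order(cand$aic, cand$k), ]
  cand$delta_aic <- cand$aic - cand$aic[1]
  rownames(cand) <- NULL
  best <- which(cand$delta_aic < delta_aic)
  final_terms <- sort(unique(unlist(cand$term_list[best])))
  # the union of best-set terms can be collinear even when each member
  # model is estimable; prune aliased terms (interactions first)
  pruned <- prune_aliased_terms(data, response, final_terms, weights)
  structure(list(candidates = cand[, c("terms", "k", "aic", "delta_aic")],
                 term_lists = cand$term_list,
                 best_set = best,
                 final_terms = pruned$terms,
                 fit = pruned$fit),
            class = "model_selection")
}

#' Marginal effects of one predictor from a weighted fit
#'
#' Model-predicted Fisher's Z for each level of a categorical predictor,
#' or over a 10-point grid spanning the observed range of a continuous
#' predictor. Predictions are counterfactual averages: the predictor is
#' set to the target level/value in every observed row, the design matrix
#' is rebuilt and averaged with the model weights — so continuous
#' covariates sit at their weighted means and other categorical predictors
#' are averaged with observed-frequency weights. CIs are delta-method
#' t-intervals from the coefficient covariance.
#'
#' @param fit a `wlm_fit`.
#' @param predictor name of a predictor appearing in the fit.
#' @param grid_n grid size for continuous predictors (default 10).
#' @return data.frame `predictor`, `level_or_grid`, `predicted_z`, `se`,
#'   `ci_lo`, `ci_hi`, of class `marginal_effects`.
#' @export
marginal_effects <- function(fit, predictor, grid_n = 10) {
  stopifnot(inherits(fit, "wlm_fit"))
  mf <- fit$data
  in_terms <- any(vapply(fit$terms, function(t)
    predictor %in% strsplit(t, ":", fixed = TRUE)[[1]], logical(1)))
  if (!in_terms && length(fit$terms))
    stopf("predictor `%s` is not in the fitted terms", predictor,
          class = "abundicentre_invalid_argument")
  if (!predictor %in% names(mf) && length(fit$terms))
    stopf("predictor `%s` not found in model data", predictor,
          class = "abundicentre_invalid_argument")
  w <- fit$weights / sum(fit$weights)
  beta <- coef(fit$fit)
  Vb <- vcov(fit$fit)
  tq <- qt(0.975, fit$df_residual)
  values <- if (!length(fit$terms) || !predictor %in% names(mf)) {
    list(grand = NA)
  } else if (is.factor(mf[[predictor]])) {
    setNames(as.list(levels(mf[[predictor]])), levels(mf[[predictor]]))
  } else {
    rng <- range(mf[[predictor]])
    grid <- seq(rng[1], rng[2], length.out = grid_n)
    setNames(as.list(grid), as.character(grid))
  }
  rows <- lapply(names(values), function(lab) {
    nd <- mf
    if (!is.na(values[[lab]][1]) && predictor %in% names(nd)) {
      nd[[predictor]] <- if (is.factor(mf[[predictor]]))
        factor(values[[lab]], levels = levels(mf[[predictor]]))
      else as.numeric(values[[lab]])
    }
    X <- model.matrix(terms(fit$fit), data = nd)
    xbar <- drop(crossprod(w, X))
    pred <- sum(xbar * beta)
    se <- sqrt(drop(t(xbar) %*% Vb %*% xbar))
    data.frame(predictor = predictor, level_or_grid = lab,
               predicted_z = pred, se = se,
               ci_lo = pred - tq * se, ci_hi = pred + tq * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("marginal_effects", "data.frame")
  out
}

#' Collinearity screen for continuous predictors
#'
#' Pairwise Pearson correlations among continuous predictors; pairs with
#' `|r| >= threshold` are flagged and should not enter the same model.
#'
#' @param data species-level data.frame.
#' @param vars names of continuous predictor columns; default every
#'   numeric column.
#' @param threshold flagging threshold (default 0.70).
#' @return data.frame of all pairs with `r` and `flagged`; the full
#'   correlation matrix is attached as attribute `"matrix"`.
#' @export
collinearity_screen <- function(data, vars = NULL, threshold = 0.70) {
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(vars) < 2)
    stopf("need at least two continuous predictors",
          class = "abundicentre_invalid_argument")
  M <- cor(as.matrix(data[, vars]))
  pairs <- combn(vars, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(p)
    data.frame(var1 = p[1], var2 = p[2], r = M[p[1], p[2]],
               flagged = abs(M[p[1], p[2]]) >= threshold,
               stringsAsFactors = FALSE)))
  attr(out, "matrix") <- M
  out
}

#' Standardize continuous predictors to unit variance
#'
#' Divides each named column by its (by default weight-aware) standard
#' deviation so fitted effects are per-SD and comparable across
#' predictors.
#'
#' @param data species-level data.frame.
#' @param vars columns to scale.
#' @param weights optional positive weights used in the variance
#'   (weighted variance about the weighted mean); `NULL` for unweighted.
#' @return `data` with scaled columns; scale factors in attribute
#'   `"scales"`.
#' @export
standardize_predictors <- function(data, vars, weights = NULL) {
  scales <- numeric(0)
  for (v in vars) {
    x <- data[[v]]
    s <- if (is.null(weights)) sd(x) else {
      wm <- weighted.mean(x, weights)
      sqrt(sum(weights * (x - wm)^2) / sum(weights))
    }
    if (!is.finite(s) || s == 0)
      stopf("cannot standardize constant predictor `%s`", v,
            class = "abundicentre_invalid_argument")
    data[[v]] <- x / s
    scales[v] <- s
  }
  attr(data, "scales") <- scales
  data
}
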