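#' Impute treatment costs by chained equations with predictive mean matching
#'
#' Multiple imputation of the adult treatment-cost column (and any other
#' incomplete numeric column) by chained equations. Each incomplete column
#' is visited in turn for `iterations` sweeps: a Bayesian linear model is
#' fitted on the currently-complete predictors (residual variance drawn from
#' its scaled inverse-chi-square posterior, coefficients from their normal
#' posterior), and each missing cell receives the observed value of a donor
#' drawn uniformly from the `k` observed rows with the closest predicted
#' means (PMM). `m` completed datasets are produced; the returned point
#' value is the across-imputation mean, because downstream costing consumes
#' a single completed table. Observed cells are never altered.
#'
#' @param records cohort data.frame.
#' @param target column to impute (default `"cost_treatment"`).
#' @param predictors predictor columns; factors are dummy-expanded.
#'   Zero-variance predictors are dropped with a warning.
#' @param m number of imputations.
#' @param iterations chained-equation sweeps per imputation.
#' @param k PMM donor-pool size.
#' @param seed integer RNG seed.
#' @return `records` with `target` completed; attribute `"imputations"`
#'   holds the n_missing x m matrix of per-imputation draws, and
#'   `"missing_rows"` the imputed row indices.
#' @export
impute_treatment <- function(records, target = "cost_treatment",
                             predictors = c("severity", "age_group",
                                            "employment", "cost_medical_services",
                                            "cost_associated", "days_missed"),
                             m = 5L, iterations = 10L, k = 5L, seed = 1L) {
  if (!target %in% names(records)) stopf("target column '%s' not found", target)
  miss <- which(is.na(records[[target]]))
  if (!length(miss)) {
    attr(records, "imputations") <- matrix(numeric(0), nrow = 0, ncol = m)
    attr(records, "missing_rows") <- integer(0)
    return(records)
  }
  if (length(miss) == nrow(records)) stopf("all values of '%s' are missing", target)

  predictors <- intersect(predictors, names(records))
  predictors <- predictors[vapply(predictors, function(v) {
    ok <- length(unique(records[[v]][!is.na(records[[v]])])) > 1
    if (!ok) warnf("dropping zero-variance predictor '%s'", v)
    ok
  }, logical(1))]
  if (!length(predictors)) stopf("no usable predictors")

  # predictors with their own missing cells join the chained visit sequence
  incomplete_preds <- predictors[vapply(predictors, function(v)
    anyNA(records[[v]]), logical(1))]
  visit <- c(incomplete_preds, target)

  set.seed(seed)
  draws <- matrix(NA_real_, nrow = length(miss), ncol = m)
  for (imp in seq_len(m)) {
    work <- records
    # initialize missing cells with random observed draws
    for (v in visit) {
      nas <- is.na(work[[v]])
      work[[v]][nas] <- sample(work[[v]][!nas], sum(nas), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in visit) {
        v_miss <- is.na(records[[v]])
        if (!any(v_miss)) next
        rhs <- setdiff(c(predictors, target), v)
        X <- stats::model.matrix(~ ., data = work[, rhs, drop = FALSE])
        y_obs <- work[[v]][!v_miss]
        work[[v]][v_miss] <- pmm_draw(X[!v_miss, , drop = FALSE], y_obs,
                                      X[v_miss, , drop = FALSE], k = k)
      }
    }
    draws[, imp] <- work[[target]][miss]
  }
  records[[target]][miss] <- rowMeans(draws)
  attr(records, "imputations") <- draws
  attr(records, "missing_rows") <- miss
  records
}

# One PMM draw: Bayesian lm posterior draw of (sigma2, beta), predicted means
# for observed rows under the ML fit and for missing rows under the drawn
# beta, then a uniform donor among the k nearest observed predictions.
pmm_draw <- function(X_obs, y_obs, X_mis, k = 5L) {
  qrX <- qr(X_obs)
  rank <- qrX$rank
  keep <- qrX$pivot[seq_len(rank)]
  Xo <- X_obs[, keep, drop = FALSE]
  Xm <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, y_obs)
  beta_hat <- fit$coefficients
  res <- fit$residuals
  df <- max(length(y_obs) - rank, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  XtX_inv <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
  beta_star <- beta_hat + drop(t(chol(sigma2 * XtX_inv + diag(1e-12, ncol(Xo)))) %*%
                                 stats::rnorm(ncol(Xo)))
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(Xm %*% beta_star)
  vapply(yhat_mis, function(yh) {
    pool <- order(abs(yhat_obs - yh))[seq_len(min(k, length(yhat_obs)))]
    y_obs[sample(pool, 1L)]
  }, numeric(1))
}
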