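#' Little-type MCAR chi-square test
#'
#' Groups rows by missingness pattern and compares each pattern's observed
#' variable means with the overall (available-case) means, weighting by the
#' pooled complete-case covariance. Under MCAR the statistic is
#' asymptotically chi-square with `sum(p_j) - p` degrees of freedom, where
#' `p_j` counts the observed variables in pattern j.
#'
#' @param data data.frame or matrix of numeric variables, NA = missing.
#' @return list with `statistic`, `df`, `p_value`, `n_patterns`.
#' @export
little_mcar_test <- function(data) {
  x <- as.matrix(as.data.frame(data))
  if (!is.numeric(x)) stopf("little_mcar_test needs numeric variables")
  p <- ncol(x)
  if (p < 2) stopf("need at least 2 variables")
  if (!anyNA(x)) {
    return(list(statistic = 0, df = 1L, p_value = 1, n_patterns = 1L))
  }
  if (all(is.na(x))) stopf("all values are missing")
  est <- em_norm(x)
  mu <- est$mu
  S <- est$sigma
  pat <- apply(is.na(x), 1L, function(r) paste(as.integer(r), collapse = ""))
  d2 <- 0
  df <- 0L
  for (pt in unique(pat)) {
    rows <- which(pat == pt)
    obs <- !is.na(x[rows[1], ])
    if (!any(obs)) next
    nj <- length(rows)
    dev <- colMeans(x[rows, obs, drop = FALSE]) - mu[obs]
    Sj <- S[obs, obs, drop = FALSE]
    Sj_inv <- tryCatch(solve(Sj), error = function(e) MASS_ginv(Sj))
    d2 <- d2 + nj * drop(t(dev) %*% Sj_inv %*% dev)
    df <- df + sum(obs)
  }
  df <- max(df - p, 1L)
  list(statistic = d2, df = df, p_value = stats::pchisq(d2, df, lower.tail = FALSE),
       n_patterns = length(unique(pat)))
}

# ML estimates of (mu, Sigma) for a multivariate normal with missing values,
# by EM over missingness patterns. Sufficient statistics accumulate the
# conditional means and covariances of the missing block given the observed
# block; ML (1/n) scaling throughout.
em_norm <- function(x, maxit = 100L, tol = 1e-8) {
  n <- nrow(x)
  p <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  xf <- x
  for (j in seq_len(p)) xf[is.na(xf[, j]), j] <- mu[j]
  S <- stats::cov(xf) * (n - 1) / n
  diag(S) <- pmax(diag(S), 1e-12)
  pat <- apply(is.na(x), 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  for (it in seq_len(maxit)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (rows in groups) {
      obs <- !is.na(x[rows[1], ])
      xo <- x[rows, obs, drop = FALSE]
      if (all(obs)) {
        T1 <- T1 + colSums(xo)
        T2 <- T2 + crossprod(xo)
        next
      }
      mis <- !obs
      Soo_inv <- tryCatch(solve(S[obs, obs, drop = FALSE]),
                          error = function(e) MASS_ginv(S[obs, obs, drop = FALSE]))
      B <- S[mis, obs, drop = FALSE] %*% Soo_inv
      cond_cov <- S[mis, mis, drop = FALSE] -
        B %*% S[obs, mis, drop = FALSE]
      xm_hat <- matrix(mu[mis], nrow = length(rows), ncol = sum(mis), byrow = TRUE) +
        sweep(xo, 2, mu[obs]) %*% t(B)
      xi <- matrix(0, nrow = length(rows), ncol = p)
      xi[, obs] <- xo
      xi[, mis] <- xm_hat
      T1 <- T1 + colSums(xi)
      T2 <- T2 + crossprod(xi)
      T2[mis, mis] <- T2[mis, mis] + length(rows) * cond_cov
    }
    mu_new <- T1 / n
    S_new <- T2 / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(S_new - S))
    mu <- mu_new
    S <- S_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = S)
}

# Moore-Penrose pseudoinverse via SVD (rank-deficient covariance guard).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Diagnose the missingness mechanism of a cost column
#'
#' Combines the Little-type MCAR chi-square over missingness patterns with a
#' logistic regression of the missingness indicator on the observed
#' covariates. MCAR survives if neither rejects at `alpha`; a significant
#' covariate makes the mechanism MAR-like; when MCAR is rejected but no
#' observed covariate explains the missingness, MNAR is assumed (the
#' mechanism depends on the unobserved value itself, which no test on
#' observed data can confirm directly).
#'
#' @param records cohort data.frame.
#' @param target name of the column with missing values
#'   (default `"cost_treatment"`).
#' @param covariates names of complete covariate columns; factors are
#'   expanded to dummies for the chi-square test.
#' @param alpha significance level for both instruments.
#' @return a `missingness_report` list: `mcar_statistic`, `mcar_df`,
#'   `mcar_p`, `mar_logit_coefficients` (data.frame with estimate and
#'   p-value per covariate term), `conclusion` in
#'   `{"MCAR", "MAR", "MNAR_assumed"}`.
#' @export
missingness_report <- function(records, target = "cost_treatment",
                               covariates = c("severity", "age_group",
                                              "employment", "cost_associated",
                                              "days_missed"),
                               alpha = 0.05) {
  if (!target %in% names(records)) stopf("target column '%s' not found", target)
  covariates <- intersect(covariates, names(records))
  if (length(covariates) < 2) stopf("need at least 2 complete covariates")
  y_missing <- is.na(records[[target]])

  if (!any(y_missing)) {
    return(structure(list(mcar_statistic = 0, mcar_df = 1L, mcar_p = 1,
                          mar_logit_coefficients = NULL, conclusion = "MCAR"),
                     class = "missingness_report"))
  }
  if (all(y_missing)) stopf("all values of '%s' are missing", target)

  keep <- vapply(covariates, function(v) length(unique(records[[v]])) > 1, logical(1))
  if (!all(keep)) {
    warnf("dropping constant covariate(s): %s",
          paste(covariates[!keep], collapse = ", "))
    covariates <- covariates[keep]
  }
  if (length(covariates) < 1) stopf("no non-constant covariates left")

  num <- stats::model.matrix(~ ., data = records[, covariates, drop = FALSE])
  num <- num[, -1, drop = FALSE]  # drop intercept; treatment coding keeps full rank
  lt <- little_mcar_test(cbind(num, target = records[[target]]))

  fit <- stats::glm(y_missing ~ ., family = stats::binomial(),
                    data = records[, covariates, drop = FALSE])
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  logit_tab <- data.frame(term = rownames(co), estimate = co[, 1],
                          p_value = co[, 4], row.names = NULL)

  conclusion <- if (lt$p_value >= alpha && all(logit_tab$p_value >= alpha)) {
    "MCAR"
  } else if (any(logit_tab$p_value < alpha)) {
    "MAR"
  } else {
    "MNAR_assumed"
  }
  structure(list(mcar_statistic = lt$statistic, mcar_df = lt$df,
                 mcar_p = lt$p_value, mar_logit_coefficients = logit_tab,
                 conclusion = conclusion),
            class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf("Missingness report: chi2 = %.3f (df %d), p = %.4f -> %s\n",
              x$mcar_statistic, x$mcar_df, x$mcar_p, x$conclusion))
  invisible(x)
}
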