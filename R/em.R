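# Expectation-maximization for a multivariate normal with arbitrary
# missingness, single deterministic imputation by conditional means, and
# Little's MCAR test built on the same ML estimates.

miss_patterns <- function(miss) {
  key <- apply(miss, 1, function(m) paste(as.integer(m), collapse = ""))
  split(seq_len(nrow(miss)), key)
}

obs_loglik <- function(Y, miss, mu, sigma) {
  ll <- 0
  for (rows in miss_patterns(miss)) {
    o <- which(!miss[rows[1], ])
    if (!length(o)) next
    S <- sigma[o, o, drop = FALSE]
    ch <- safe_chol(S, quiet = TRUE)$chol
    ld <- 2 * sum(log(diag(ch)))
    for (i in rows) {
      d <- Y[i, o] - mu[o]
      q <- sum(backsolve(ch, d, transpose = TRUE)^2)
      ll <- ll - 0.5 * (length(o) * log(2 * pi) + ld + q)
    }
  }
  ll
}

safe_chol <- function(S, ridge = 1e-8, quiet = FALSE) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  tries <- 0
  while (is.null(ch) && tries < 12) {
    tries <- tries + 1
    S <- S + ridge * mean(diag(S)) * diag(nrow(S))
    ridge <- ridge * 10
    ch <- tryCatch(chol(S), error = function(e) NULL)
  }
  if (is.null(ch)) stop("covariance block is numerically singular")
  if (tries > 0 && !quiet)
    warning("singular observed-block covariance; ridge added")
  list(chol = ch, S = S)
}

#' EM estimation and single imputation under a multivariate normal model
#'
#' Fits mean and covariance by expectation-maximization over the missingness
#' patterns and imputes each missing cell with its conditional mean given
#' the row's observed entries under the fitted parameters. Imputations are
#' NOT clipped to the observed range, so a bounded score (e.g. a 0-90
#' checklist count) can legitimately receive an out-of-range imputed value.
#' The covariance uses the maximum-likelihood (1/n) scaling.
#'
#' @param table Numeric matrix or data.frame with missing entries; every
#'   variable must be observed at least twice.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is flagged, and the last
#'   iterate returned.
#' @return A list of class `em_result`: `mean`, `cov`, `imputed` (data.frame
#'   matching the input), `iterations`, `converged`, `loglik` (trace).
#' @export
em_impute <- function(table, tol = 1e-6, max_iter = 500) {
  Y <- as.matrix(table)
  storage.mode(Y) <- "double"
  n <- nrow(Y); p <- ncol(Y)
  miss <- is.na(Y)
  if (any(colSums(!miss) < 2))
    stop("every variable must be observed at least twice")
  if (any(rowSums(!miss) == 0))
    stop("rows with no observed values cannot be used")
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2, var, na.rm = TRUE)
  v[v <= 0] <- mean(v[v > 0])
  sigma <- diag(v, p)
  patterns <- miss_patterns(miss)
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  if (!any(miss)) {
    mu <- colMeans(Y)
    sigma <- crossprod(sweep(Y, 2, mu)) / n
    ll_trace <- obs_loglik(Y, miss, mu, sigma)
    iter <- 1
    converged <- TRUE
  } else {
    for (iter in seq_len(max_iter)) {
      S1 <- numeric(p)
      S2 <- matrix(0, p, p)
      for (rows in patterns) {
        m <- which(miss[rows[1], ])
        o <- which(!miss[rows[1], ])
        Yo <- Y[rows, o, drop = FALSE]
        if (!length(m)) {
          S1[o] <- S1[o] + colSums(Yo)
          S2[o, o] <- S2[o, o] + crossprod(Yo)
          next
        }
        sc <- safe_chol(sigma[o, o, drop = FALSE])
        B <- sigma[m, o, drop = FALSE] %*% chol2inv(sc$chol)
        C <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
        dev <- sweep(Yo, 2, mu[o])
        Ym <- sweep(dev %*% t(B), 2, mu[m], FUN = "+")
        full <- matrix(0, length(rows), p)
        full[, o] <- Yo
        full[, m] <- Ym
        S1 <- S1 + colSums(full)
        cp <- crossprod(full)
        cp[m, m] <- cp[m, m] + length(rows) * C
        S2 <- S2 + cp
      }
      mu_new <- S1 / n
      sigma_new <- S2 / n - tcrossprod(mu_new)
      sigma_new <- (sigma_new + t(sigma_new)) / 2
      mu <- mu_new
      sigma <- sigma_new
      ll <- obs_loglik(Y, miss, mu, sigma)
      ll_trace <- c(ll_trace, ll)
      if (iter > 1) {
        prev <- ll_trace[iter - 1]
        if (abs(ll - prev) < tol * (abs(prev) + 1)) {
          converged <- TRUE
          break
        }
      }
    }
    if (!converged)
      warning("EM did not converge in ", max_iter,
              " iterations; returning last iterate")
  }
  imputed <- Y
  for (rows in patterns) {
    m <- which(miss[rows[1], ])
    if (!length(m)) next
    o <- which(!miss[rows[1], ])
    sc <- safe_chol(sigma[o, o, drop = FALSE])
    B <- sigma[m, o, drop = FALSE] %*% chol2inv(sc$chol)
    dev <- sweep(Y[rows, o, drop = FALSE], 2, mu[o])
    imputed[rows, m] <- sweep(dev %*% t(B), 2, mu[m], FUN = "+")
  }
  out <- as.data.frame(imputed)
  names(out) <- colnames(table)
  structure(list(mean = setNames(mu, colnames(table)),
                 cov = sigma, imputed = out, iterations = iter,
                 converged = converged, loglik = ll_trace),
            class = "em_result")
}

#' Little's test of missing completely at random
#'
#' Compares each missingness pattern's observed-variable means against the
#' EM estimates with the pattern-wise Mahalanobis statistic
#' `d2 = sum_j n_j (ybar_j - mu_oj)' Sigma_oj^-1 (ybar_j - mu_oj)`,
#' referred to a chi-square with `sum_j p_j - p` degrees of freedom.
#'
#' @param table Numeric matrix/data.frame with missing entries.
#' @return A list of class `mcar_test`: `d2`, `df`, `p`, `n_patterns`.
#' @export
little_mcar <- function(table) {
  Y <- as.matrix(table)
  storage.mode(Y) <- "double"
  miss <- is.na(Y)
  patterns <- miss_patterns(miss)
  if (length(patterns) < 2)
    stop("MCAR test not applicable: only one missingness pattern")
  fit <- em_impute(table)
  mu <- fit$mean
  sigma <- fit$cov
  d2 <- 0
  df <- 0
  p_tot <- ncol(Y)
  for (rows in patterns) {
    o <- which(!miss[rows[1], ])
    if (!length(o)) next
    ybar <- colMeans(Y[rows, o, drop = FALSE])
    dlt <- ybar - mu[o]
    sc <- safe_chol(sigma[o, o, drop = FALSE])
    d2 <- d2 + length(rows) *
      sum(backsolve(sc$chol, dlt, transpose = TRUE)^2)
    df <- df + length(o)
  }
  df <- df - p_tot
  structure(list(d2 = d2, df = df, p = pchisq(d2, df, lower.tail = FALSE),
                 n_patterns = length(patterns)), class = "mcar_test")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("EM fit: %d variables, %d iterations, converged: %s\n",
              length(x$mean), x$iterations, x$converged))
  invisible(x)
}

#' @export
print.mcar_test <- function(x, ...) {
  cat(sprintf("Little's MCAR test: d2 = %.2f, df = %d, p = %.3f (%d patterns)\n",
              x$d2, x$df, x$p, x$n_patterns))
  invisible(x)
}
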