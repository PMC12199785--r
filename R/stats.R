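# Descriptives, rank correlations (zero-order and partial), paired tests,
# the reading-habits composite, CDI inclusion, and the sensitivity analysis.

#' Descriptive statistics for one outcome measure
#'
#' Median, SD (n-1 denominator), adjusted Fisher-Pearson skewness (G1) and
#' sample excess kurtosis (G2) — the conventions of mainstream statistics
#' packages, so rows are comparable with published descriptive tables.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param label Row label.
#' @return One-row data.frame: `measure`, `n`, `median`, `sd`, `skewness`,
#'   `kurtosis`. Skewness/kurtosis are `NA` below the minimal n (3 and 4)
#'   or for constant data.
#' @export
descriptives <- function(values, label = "measure") {
  x <- values[!is.na(values)]
  n <- length(x)
  s <- if (n >= 2) sd(x) else NA_real_
  skew <- if (n >= 3 && isTRUE(s > 0)) e1071::skewness(x, type = 2) else NA_real_
  kurt <- if (n >= 4 && isTRUE(s > 0)) e1071::kurtosis(x, type = 2) else NA_real_
  data.frame(measure = label, n = n,
             median = if (n) median(x) else NA_real_,
             sd = s, skewness = skew, kurtosis = kurt,
             stringsAsFactors = FALSE)
}

mid_rank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation
#'
#' Tie-aware Spearman's rho: the Pearson correlation of mid-ranks, with a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors; pairs with any `NA` are dropped.
#' @return A list: `rho`, `p`, `n`. `rho` is `NA` when either rank vector is
#'   constant or `n < 4`.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || var(mid_rank(x)) == 0 || var(mid_rank(y)) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(mid_rank(x), mid_rank(y))
  p <- rho_p_value(rho, df = n - 2)
  list(rho = rho, p = p, n = n)
}

rho_p_value <- function(rho, df) {
  if (is.na(rho) || df < 1) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * pt(-abs(tstat), df)
}

#' Partial Spearman correlation
#'
#' The nonparametric-partial convention: rank-transform the continuous
#' variables (binary 0/1 covariates are left as they are), residualize the
#' ranked `x` and `y` on the covariate matrix by least squares, and
#' correlate the residuals. The p-value uses `df = n - k - 2` where `k` is
#' the number of (retained) covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates data.frame/matrix of covariates; `NULL` or zero columns
#'   reduces to [spearman()].
#' @return A list: `rho`, `p`, `n`, `n_covariates`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    out <- spearman(x, y)
    out$n_covariates <- 0L
    return(out)
  }
  z <- as.data.frame(covariates)
  ok <- is.finite(x) & is.finite(y) & complete.cases(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x)
  zr <- vapply(z, function(col) {
    if (is.logical(col) || length(unique(col)) <= 2) as.numeric(col)
    else mid_rank(col)
  }, numeric(n))
  zr <- as.matrix(zr)
  # drop collinear covariate columns
  q <- qr(cbind(1, zr))
  if (q$rank < ncol(zr) + 1) {
    keep <- q$pivot[seq_len(q$rank)]
    keep <- setdiff(keep, 1L) - 1L
    warning("dropping collinear covariates: ",
            paste(colnames(zr)[setdiff(seq_len(ncol(zr)), keep)],
                  collapse = ", "))
    zr <- zr[, keep, drop = FALSE]
    q <- qr(cbind(1, zr))
  }
  k <- ncol(zr)
  if (n <= k + 3) stop("need n > number of covariates + 3")
  rx <- qr.resid(q, mid_rank(x))
  ry <- qr.resid(q, mid_rank(y))
  if (var(rx) == 0 || var(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, n_covariates = k))
  rho <- cor(rx, ry)
  list(rho = rho, p = rho_p_value(rho, df = n - k - 2), n = n,
       n_covariates = k)
}

#' Paired t-test
#'
#' Thin wrapper over [stats::t.test()] returning the pieces the reports use;
#' zero-variance differences are flagged rather than tested.
#'
#' @param a,b Paired numeric vectors; incomplete pairs are dropped.
#' @return A list: `t`, `df`, `p`, `mean_diff` (mean of `a - b`),
#'   `degenerate`.
#' @export
paired_t <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("need at least 2 complete pairs")
  d <- a - b
  if (var(d) == 0)
    return(list(t = NA_real_, df = length(a) - 1, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Reading-habits composite
#'
#' Standardizes each questionnaire item (reading frequency and length of
#' reading, both ordinal 0-3) across the sample and averages the two
#' z-scores. The composite is not re-standardized, so its sample mean is 0
#' by construction while its SD is below 1 unless the items correlate
#' perfectly. A missing item yields a composite from the observed item
#' alone, flagged in the `partial` attribute.
#'
#' @param freq_level,duration_level Integer item codes 0-3.
#' @return Numeric composite vector with attribute `partial` (logical).
#' @export
reading_composite <- function(freq_level, duration_level) {
  stopifnot(length(freq_level) == length(duration_level))
  chk <- function(v) if (any(!is.na(v) & (v < 0 | v > 3)))
    stop("item levels must be coded 0-3")
  chk(freq_level); chk(duration_level)
  zf <- scale(freq_level)[, 1]
  zd <- scale(duration_level)[, 1]
  comp <- rowMeans(cbind(zf, zd), na.rm = TRUE)
  comp[is.na(zf) & is.na(zd)] <- NA_real_
  attr(comp, "partial") <- xor(is.na(zf), is.na(zd))
  comp
}

#' CDI questionnaire inclusion rule
#'
#' A parent-report checklist is usable only when at least 90% of its items
#' were answered (81 of 90 on the standard form).
#'
#' @param item_responses Vector of item responses with `NA` for unanswered.
#' @param min_fraction Minimal answered fraction.
#' @return Logical flag.
#' @export
cdi_inclusion <- function(item_responses, min_fraction = 0.9) {
  n_items <- length(item_responses)
  sum(!is.na(item_responses)) >= ceiling(min_fraction * n_items)
}

# --- sensitivity analysis -------------------------------------------------

# log of the Gauss hypergeometric series 2F1(a, b; c; z), 0 <= z < 1,
# convergent here because c - a - b > 0
log_hyp2f1 <- function(a, b, cc, z) {
  term <- 1; s <- 1
  for (k in 1:10000) {
    term <- term * (a + k - 1) * (b + k - 1) / ((cc + k - 1) * k) * z
    s <- s + term
    if (abs(term) < 1e-15 * abs(s)) break
  }
  log(s)
}

# exact density of the sample correlation r under a bivariate normal with
# population correlation rho and sample size n
dcorr_exact <- function(r, rho, n) {
  vapply(r, function(ri) {
    lc <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
      ((n - 4) / 2) * log1p(-ri^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
      (n - 1.5) * log1p(-rho * ri)
    exp(lc + log_hyp2f1(0.5, 0.5, n - 0.5, (rho * ri + 1) / 2))
  }, numeric(1))
}

#' Power of the test of zero correlation
#'
#' Exact bivariate-normal power (via the exact sampling distribution of the
#' correlation coefficient, with the exact critical value of the t-form
#' statistic) or the Fisher-z approximation.
#'
#' @param rho Population correlation under the alternative.
#' @param n Sample size (> 4).
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @param method `"exact"` or `"fisher-z"`.
#' @return Power in (0, 1).
#' @export
correlation_power <- function(rho, n, alpha = 0.05, tails = 2,
                              method = c("exact", "fisher-z")) {
  method <- match.arg(method)
  stopifnot(n > 4, alpha > 0, alpha < 1, tails %in% c(1, 2), abs(rho) < 1)
  if (method == "fisher-z") {
    se <- 1 / sqrt(n - 3)
    zc <- qnorm(1 - alpha / tails)
    zr <- atanh(rho) / se
    pw <- pnorm(zr - zc)
    if (tails == 2) pw <- pw + pnorm(-zr - zc)
    return(pw)
  }
  tc <- qt(1 - alpha / tails, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  hi <- integrate(dcorr_exact, rc, 1, rho = rho, n = n,
                  rel.tol = 1e-10)$value
  if (tails == 1) return(hi)
  lo <- integrate(dcorr_exact, -1, -rc, rho = rho, n = n,
                  rel.tol = 1e-10)$value
  hi + lo
}

#' Minimum detectable correlation (sensitivity analysis)
#'
#' Root-finds the smallest population correlation whose power for the test
#' of zero correlation reaches `power` at the given `n`, `alpha` and
#' tailedness.
#'
#' @param n Sample size (> 4).
#' @param alpha Significance level.
#' @param power Target power, in (`alpha`, 1).
#' @param tails 1 or 2.
#' @param method `"exact"` bivariate-normal or `"fisher-z"`.
#' @param tol Root tolerance.
#' @return The minimum detectable `rho`.
#' @export
#' @examples
#' min_detectable_r(70, 0.05, 0.80)
min_detectable_r <- function(n, alpha = 0.05, power = 0.80, tails = 2,
                             method = c("exact", "fisher-z"), tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(n > 4, alpha > 0, alpha < 1, power > alpha, power < 1)
  # above |rho| ~ 0.999 the exact density is too concentrated for reliable
  # quadrature; any practical sensitivity analysis solves far below that
  uniroot(function(r) correlation_power(r, n, alpha, tails, method) - power,
          interval = c(1e-6, 0.999), tol = tol)$root
}

# --- correlation matrices -------------------------------------------------

#' Matrix of (partial) Spearman correlations
#'
#' Builds the full rho/p/n matrices over a set of outcome columns, either
#' zero-order or partialling out a covariate set.
#'
#' @param table data.frame holding the outcome columns (and covariates).
#' @param vars Character vector of outcome column names.
#' @param covariates Character vector of covariate column names (or `NULL`
#'   for zero-order correlations).
#' @param labels Optional display labels for `vars`.
#' @return A `corr_report` list: `labels`, `rho`, `p`, `n` (matrices),
#'   `method`, `covariates`, and a `note` on multiplicity.
#' @export
correlation_report <- function(table, vars, covariates = NULL,
                               labels = vars) {
  k <- length(vars)
  rho <- p <- nn <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(rho) <- 1
  diag(p) <- 0
  covdf <- if (length(covariates)) table[covariates] else NULL
  for (i in seq_len(k)) {
    nn[i, i] <- sum(is.finite(table[[vars[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      res <- partial_spearman(table[[vars[i]]], table[[vars[j]]], covdf)
      rho[i, j] <- rho[j, i] <- res$rho
      p[i, j] <- p[j, i] <- res$p
      nn[i, j] <- nn[j, i] <- res$n
    }
  }
  structure(list(labels = labels, rho = rho, p = p, n = nn,
                 method = if (length(covariates)) "partial" else "zero-order",
                 covariates = covariates,
                 note = paste("p-values are two-sided and uncorrected for",
                              "multiple comparisons")),
            class = "corr_report")
}

#' @export
print.corr_report <- function(x, digits = 2, ...) {
  cat(sprintf("%s Spearman correlation matrix (%d variables)\n",
              x$method, ncol(x$rho)))
  if (length(x$covariates))
    cat("controlling for:", paste(x$covariates, collapse = ", "), "\n")
  print(round(x$rho, digits))
  cat(x$note, "\n")
  invisible(x)
}
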