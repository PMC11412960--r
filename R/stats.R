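#' Two-sample pooled-variance t-test from summary statistics
#'
#' Student's t-test with pooled variance, computed directly from group
#' means, SDs and sizes. This is the form that lets every published
#' group-comparison p-value be recomputed from a table's printed
#' mean +/- SD columns without the raw data. With `welch = TRUE` the
#' Welch-Satterthwaite unequal-variance form is used instead.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @param variable label carried into the result.
#' @param welch logical; use the Welch unequal-variance test.
#' @return a `test_result` list: variable, method, statistic, df, p,
#'   group summaries.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                  variable = NA_character_, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2)
      return(test_result(variable, "student_t_pooled", statistic = 0,
                         df = n1 + n2 - 2, p = 1,
                         summary1 = c(mean = m1, sd = s1, n = n1),
                         summary2 = c(mean = m2, sd = s2, n = n2)))
    stop("zero pooled variance with unequal means: t is infinite")
  }
  if (welch) {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    tstat <- (m2 - m1) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "welch_t"
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    tstat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "student_t_pooled"
  }
  test_result(variable, method, statistic = tstat, df = df,
              p = 2 * stats::pt(-abs(tstat), df),
              summary1 = c(mean = m1, sd = s1, n = n1),
              summary2 = c(mean = m2, sd = s2, n = n2))
}

test_result <- function(variable, method, statistic, df = NA_real_, p,
                        summary1 = NULL, summary2 = NULL) {
  stopifnot(p >= 0, p <= 1)
  structure(list(variable = variable, method = method, statistic = statistic,
                 df = df, p = p, summary1 = summary1, summary2 = summary2),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: %s statistic = %.4g, df = %.4g, p = %.4g\n",
              x$variable, x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' Two-sample pooled t-test on raw samples
#'
#' Identical by construction to [pooled_t_from_summary()] applied to the
#' samples' own means, SDs and sizes.
#'
#' @param x,y numeric samples (each n >= 2).
#' @inheritParams pooled_t_from_summary
#' @return a `test_result`.
#' @export
two_sample_t <- function(x, y, variable = NA_character_, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("two_sample_t needs at least 2 observations per group")
  pooled_t_from_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y),
                        variable = variable, welch = welch)
}

#' Mann-Whitney U test
#'
#' U statistic via midranks. For n1 + n2 <= 12 (or `exact = TRUE`) the
#' two-sided p-value is computed by exhaustive enumeration of all
#' choose(n1+n2, n1) group labelings of the pooled sample — valid under
#' ties, where the U null distribution remains symmetric about n1*n2/2 —
#' as P(|U - n1 n2/2| >= |u - n1 n2/2|). Otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact force (TRUE) or forbid (FALSE) enumeration; NULL = automatic.
#' @param variable label carried into the result.
#' @return a `test_result` with `statistic` = U (number of (x, y) pairs with
#'   x > y, counting ties as 1/2).
#' @export
mann_whitney_u <- function(x, y, exact = NULL, variable = NA_character_) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("mann_whitney_u needs non-empty samples")
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- (n1 + n2) <= 12L
  if (exact) {
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2L, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
    dev <- abs(us - n1 * n2 / 2)
    p <- mean(dev >= abs(u - n1 * n2 / 2) - 1e-9)
    method <- "mann_whitney_u_exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(0, z)))
    }
    method <- "mann_whitney_u"
  }
  test_result(variable, method, statistic = u, df = NA_real_, p = p,
              summary1 = c(median = stats::median(x), n = n1),
              summary2 = c(median = stats::median(y), n = n2))
}

#' Normality-routed two-sample comparison
#'
#' The routing rule of the study's analysis plan: Shapiro-Wilk is applied
#' to each group and the pooled t-test is used only when both groups are
#' compatible with normality (p >= `alpha_normality`); otherwise the
#' Mann-Whitney U test. Groups smaller than 3 (Shapiro-Wilk undefined)
#' fall back to Mann-Whitney with a warning. Constant samples (Shapiro-Wilk
#' undefined) are treated as non-normal.
#'
#' @param x,y numeric samples.
#' @param alpha_normality Shapiro-Wilk significance level (default 0.05).
#' @param variable label carried into the result.
#' @param welch use Welch's t for the parametric branch.
#' @return a `test_result`; `method` records which branch ran.
#' @export
route_two_sample <- function(x, y, alpha_normality = 0.05,
                             variable = NA_character_, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    warning("group too small for Shapiro-Wilk; routing to Mann-Whitney")
    return(mann_whitney_u(x, y, variable = variable))
  }
  sw_p <- function(v) {
    if (length(unique(v)) < 2) return(0)  # constant: not normal
    stats::shapiro.test(v)$p.value
  }
  if (sw_p(x) >= alpha_normality && sw_p(y) >= alpha_normality)
    two_sample_t(x, y, variable = variable, welch = welch)
  else
    mann_whitney_u(x, y, variable = variable)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (df = 1), as used for the sex-by-group
#' comparison.
#'
#' @param counts 2x2 numeric matrix of non-negative counts with positive
#'   margins.
#' @param variable label carried into the result.
#' @return a `test_result`.
#' @export
chi_square_2x2 <- function(counts, variable = NA_character_) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)))
  if (any(counts < 0)) stop("chi-square counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi-square table has a zero margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  test_result(variable, "chi_square", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p = ct$p.value,
              summary1 = counts[, 1L], summary2 = counts[, 2L])
}

#' Covariate-adjusted (partial) correlation
#'
#' x and y are each residualized on an intercept plus the covariate columns
#' by least squares (after a rank transform when `method = "spearman"`);
#' the partial correlation is the Pearson correlation of the residuals,
#' with df = n - 2 - k and the p-value from the t transform
#' t = r sqrt(df) / sqrt(1 - r^2).
#'
#' @param x,y numeric vectors of length n.
#' @param covariates n x k numeric matrix (k = 0 allowed: plain correlation).
#' @param method `"pearson"` or `"spearman"`.
#' @param pair label carried into the result.
#' @return a `correlation_result` list: pair, method, r, n, k, df, p.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                method = c("pearson", "spearman"),
                                pair = NA_character_) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & rowSums(is.na(covariates)) == 0L
    covariates <- covariates[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 2) stop("partial correlation needs n > k + 2")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    if (k > 0) covariates <- apply(covariates, 2L, rank)
  }
  ssx0 <- sum((x - mean(x))^2)
  ssy0 <- sum((y - mean(y))^2)
  if (k > 0) {
    Z <- cbind(1, covariates)
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      dep <- setdiff(seq_len(ncol(Z)), qz$pivot[seq_len(qz$rank)]) - 1L
      stop("rank-deficient covariates: column(s) ",
           paste(dep, collapse = ", "), " linearly dependent")
    }
    x <- qr.resid(qz, x)
    y <- qr.resid(qz, y)
  } else {
    x <- x - mean(x); y <- y - mean(y)
  }
  # a variable fully explained by the covariates has no residual variation
  # left to correlate: r = 0, not roundoff noise
  r <- if (sum(x^2) <= 1e-20 * ssx0 || sum(y^2) <= 1e-20 * ssy0) 0
       else sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  structure(list(pair = pair, method = method, r = r, n = n, k = k,
                 df = n - 2L - k, p = p_from_r(r, n, k)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: %s r = %.3f (n = %d, k = %d, df = %d), p = %.4g\n",
              x$pair, x$method, x$r, x$n, x$k, x$df, x$p))
  invisible(x)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Uses the t transform t = |r| sqrt(n - 2 - k) / sqrt(1 - r^2) with
#' df = n - 2 - k, the convention for a correlation adjusted for k
#' covariates (k = 0 gives the ordinary test).
#'
#' @param r correlation in \[-1, 1\].
#' @param n sample size.
#' @param k number of covariates adjusted for (default 0).
#' @return two-sided p-value; |r| = 1 returns 0 by convention.
#' @export
p_from_r <- function(r, n, k = 0L) {
  df <- n - 2 - k
  stopifnot(df >= 1, abs(r) <= 1)
  if (abs(r) == 1) return(0)
  tstat <- abs(r) * sqrt(df) / sqrt(1 - r^2)
  2 * stats::pt(-tstat, df)
}

#' Bonferroni adjustment
#'
#' adjusted_i = min(1, m p_i) with m the family size (the list length),
#' preserving order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Round half away from zero to a fixed number of decimals
#'
#' The rounding convention of the published tables (so 0.0005 prints as
#' 0.001, not banker's-rounded to 0).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 3L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
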