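test_that("pooled t from summaries reproduces published-style p-values", {
  # auditory verbal memory comparison, n = 50 per group
  avlt <- pooled_t_from_summary(32.68, 7.13, 50, 35.78, 7.19, 50, "avlt")
  expect_equal(round_half_up(avlt$p, 3), 0.033)
  expect_equal(avlt$df, 98)
  # equal means give t = 0, p = 1
  eq <- pooled_t_from_summary(10, 2, 20, 10, 3, 20)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # large standardized group difference rounds to 0.000 at three decimals
  alps <- pooled_t_from_summary(1.51839, 0.11933, 50, 1.61730, 0.14277, 50)
  expect_lt(alps$p, 0.0005)
  expect_equal(round_half_up(alps$p, 3), 0)
  # degenerate variance handling
  expect_equal(pooled_t_from_summary(5, 0, 10, 5, 0, 10)$p, 1)
  expect_error(pooled_t_from_summary(5, 0, 10, 6, 0, 10), "infinite")
})

test_that("raw-sample t equals the summary form exactly", {
  set.seed(41)
  for (i in 1:10) {
    x <- stats::rnorm(15, 10, 3)
    y <- stats::rnorm(22, 11, 2)
    a <- two_sample_t(x, y)
    b <- pooled_t_from_summary(mean(x), stats::sd(x), length(x),
                               mean(y), stats::sd(y), length(y))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    # and matches the standard implementation
    tt <- stats::t.test(y, x, var.equal = TRUE)
    expect_equal(a$p, tt$p.value, tolerance = 1e-12)
  }
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("Welch variant matches the standard implementation", {
  set.seed(42)
  x <- stats::rnorm(20, 0, 1)
  y <- stats::rnorm(30, 0.5, 3)
  w <- two_sample_t(x, y, welch = TRUE)
  tt <- stats::t.test(y, x)
  expect_equal(w$p, tt$p.value, tolerance = 1e-12)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-9)
})

test_that("Mann-Whitney U: separation, identity, and enumeration oracle", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  ident <- mann_whitney_u(c(2, 5, 5, 9), c(2, 5, 5, 9))
  expect_equal(ident$p, 1)
  set.seed(43)
  for (i in 1:8) {
    x <- stats::rnorm(5)
    y <- stats::rnorm(6, 0.8)
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "mann_whitney_u_exact")
    expect_equal(got$p, enumerate_mw_p(x, y), tolerance = 1e-12)
    # tie-free small-sample case also agrees with the standard implementation
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p, wt$p.value, tolerance = 1e-12)
  }
  # enumeration handles ties through midranks
  xt <- c(1, 2, 2, 3)
  yt <- c(2, 3, 3, 4)
  expect_equal(mann_whitney_u(xt, yt)$p, enumerate_mw_p(xt, yt),
               tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation tracks enumeration in the rejection region", {
  # exhaustive over all 924 rank configurations at n1 = n2 = 6
  r <- 1:12
  combs <- utils::combn(12, 6)
  us <- apply(combs, 2, function(i) sum(r[i])) - 21
  worst_tail <- 0
  worst_all <- 0
  for (u in 0:36) {
    x_ranks <- combs[, match(u + 21, apply(combs, 2, function(i) sum(r[i])))]
    x <- r[x_ranks]; y <- r[-x_ranks]
    p_exact <- mann_whitney_u(x, y, exact = TRUE)$p
    p_approx <- mann_whitney_u(x, y, exact = FALSE)$p
    d <- abs(p_exact - p_approx)
    worst_all <- max(worst_all, d)
    if (p_exact <= 0.10) worst_tail <- max(worst_tail, d)
  }
  expect_lt(worst_tail, 0.01)
  expect_lt(worst_all, 0.02)
})

test_that("normality routing picks the branch the data supports", {
  set.seed(44)
  xn <- stats::rnorm(50); yn <- stats::rnorm(50)
  stopifnot(stats::shapiro.test(xn)$p.value >= 0.05,
            stats::shapiro.test(yn)$p.value >= 0.05)
  expect_equal(route_two_sample(xn, yn)$method, "student_t_pooled")
  set.seed(45)
  xl <- exp(stats::rnorm(50, 0, 1.5))  # heavy right skew
  stopifnot(stats::shapiro.test(xl)$p.value < 0.05)
  expect_equal(route_two_sample(xl, yn)$method, "mann_whitney_u")
  expect_warning(res <- route_two_sample(c(1, 2), c(3, 4)), "Shapiro")
  expect_match(res$method, "mann_whitney")
})

test_that("routed test holds its type-I error under a normal null", {
  set.seed(46)
  rej <- mean(replicate(2000, {
    suppressWarnings(route_two_sample(stats::rnorm(50),
                                      stats::rnorm(50))$p) < 0.05
  }))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("chi-square on 2x2 tables matches the direct formula", {
  bal <- chi_square_2x2(matrix(c(23, 27, 23, 27), 2), "gender")
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)
  expect_equal(bal$df, 1)
  full <- chi_square_2x2(matrix(c(50, 0, 0, 50), 2))
  expect_equal(full$statistic, 100)
  set.seed(47)
  counts <- matrix(stats::rpois(4, 10) + 1, 2)
  got <- chi_square_2x2(counts)
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(got$statistic, sum((counts - E)^2 / E), tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("partial correlation: reduction, orthogonality, invariance", {
  set.seed(48)
  n <- 60
  x <- stats::rnorm(n); y <- 0.5 * x + stats::rnorm(n)
  # k = 0 reduces to plain Pearson
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$r, stats::cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$df, n - 2)
  # y an exact linear function of covariates: partial r vanishes
  Z <- matrix(stats::rnorm(n * 3), n)
  ylin <- 2 + Z %*% c(1, -2, 0.5)
  expect_lt(abs(partial_correlation(x, as.vector(ylin), Z)$r), 1e-10)
  # invariance under invertible affine maps of the covariates
  pc1 <- partial_correlation(x, y, Z)
  A <- matrix(c(2, 1, 0, -1, 3, 0, 0.5, 0, 1), 3)
  Zt <- sweep(Z %*% A, 2, c(10, -5, 2), "+")
  pc2 <- partial_correlation(x, y, Zt)
  expect_equal(pc1$r, pc2$r, tolerance = 1e-10)
  expect_equal(pc1$df, n - 2 - 3)
  # p consistent with the t transform
  expect_equal(pc1$p, p_from_r(pc1$r, n, 3), tolerance = 1e-10)
  # duplicated covariate column is named in the error
  expect_error(partial_correlation(x, y, cbind(Z, Z[, 1])), "rank-deficient")
  # spearman branch equals Pearson on ranks
  pcs <- partial_correlation(x, y, Z, method = "spearman")
  pcr <- partial_correlation(rank(x), rank(y), apply(Z, 2, rank))
  expect_equal(pcs$r, pcr$r, tolerance = 1e-12)
})

test_that("correlation p-values follow the adjusted-df t transform", {
  expect_equal(round_half_up(p_from_r(-0.309, 50, 5), 3), 0.039)
  expect_equal(round_half_up(p_from_r(-0.413, 50, 5), 3), 0.005)
  expect_equal(p_from_r(0, 30, 2), 1)
  expect_equal(p_from_r(1, 30, 0), 0)
  # strictly decreasing in |r| at fixed (n, k)
  rs <- seq(0.05, 0.95, by = 0.05)
  ps <- vapply(rs, p_from_r, 1, n = 40, k = 3)
  expect_true(all(diff(ps) < 0))
  # strictly decreasing in n at fixed (r, k)
  ns <- seq(10, 200, by = 10)
  pn <- vapply(ns, function(n) p_from_r(0.3, n, 2), 1)
  expect_true(all(diff(pn) < 0))
})

test_that("Bonferroni adjustment is m * p capped at 1, order preserved", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(rep(0.004, 10))[1], 0.04)
  set.seed(49)
  p <- stats::runif(10)
  adj <- bonferroni_adjust(p)
  expect_equal(adj, pmin(1, 10 * p))
  expect_true(all(adj >= p))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("half-away-from-zero rounding matches table formatting", {
  expect_equal(round_half_up(0.0005, 3), 0.001)
  expect_equal(round_half_up(0.0004999, 3), 0)
  expect_equal(round_half_up(-0.0345, 3), -0.035)
  expect_equal(round_half_up(0.189328, 2), 0.19)
})
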