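test_that("noiseless log-linear fit recovers the tensor exactly", {
  gt <- default_gradient_table()
  d6 <- c(0.00060, 0.00042, 0.00111, 0, 0, 0)  # projection-fiber diagonal
  s <- voxel_signals(d6, gt, s0 = 800)
  dwi <- array(s, c(1, 1, 1, length(s)))
  f <- fit_tensor_loglinear(dwi, gt)
  expect_equal(as.vector(f$D[1, 1, 1, ]), d6, tolerance = 1e-8 * max(d6))
  expect_equal(f$s0[1, 1, 1], 800, tolerance = 1e-8)
  expect_true(f$valid[1, 1, 1])
  # relative error of the diagonal under 1e-8
  rel <- abs(as.vector(f$D[1, 1, 1, 1:3]) - d6[1:3]) / d6[1:3]
  expect_true(all(rel < 1e-8))
})

test_that("isotropic signals give equal diagonals and null off-diagonals", {
  gt <- default_gradient_table()
  d <- 8e-4
  s <- voxel_signals(c(d, d, d, 0, 0, 0), gt)
  f <- fit_tensor_loglinear(array(s, c(1, 1, 1, length(s))), gt)
  v <- as.vector(f$D[1, 1, 1, ])
  expect_equal(v[1], v[2], tolerance = 1e-12)
  expect_equal(v[2], v[3], tolerance = 1e-12)
  expect_true(all(abs(v[4:6]) < 1e-12))
})

test_that("log-linear fit matches a brute-force nonlinear LS oracle", {
  gt <- default_gradient_table()
  set.seed(31)
  n_vox <- 40L
  worst <- 0
  for (i in seq_len(n_vox)) {
    # random SPD tensor near brain-tissue scale
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    lam <- sort(stats::runif(3, 3e-4, 15e-4), decreasing = TRUE)
    M <- R %*% diag(lam) %*% t(R)
    d6 <- c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
    s <- voxel_signals(d6, gt, s0 = 500)
    fit <- fit_tensor_loglinear(array(s, c(1, 1, 1, length(s))), gt)
    # independent oracle: Levenberg-Marquardt least squares on the signal
    # equation itself from a generic isotropic start, with diffusivities in
    # 1e-3 mm^2/s units so all parameters are O(1)
    resid_fn <- function(th)
      s - voxel_signals(th[1:6] * 1e-3, gt, s0 = exp(th[7]))
    th0 <- c(0.7, 0.7, 0.7, 0, 0, 0, log(mean(s[gt$bvals == 0])))
    opt <- minpack.lm::nls.lm(th0, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ftol = 1e-15, ptol = 1e-15))
    expect_lt(sum(resid_fn(opt$par)^2), 1e-12)  # oracle converged
    rel <- max(abs(as.vector(fit$D[1, 1, 1, ]) - opt$par[1:6] * 1e-3)) /
      max(lam)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.005)
})

test_that("rotation consistency: fitting a rotated tensor recovers R D R'", {
  gt <- default_gradient_table()
  D0 <- diag(c(0.00111, 0.00042, 0.00060))
  th <- 25 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3,
              byrow = TRUE)
  M <- R %*% D0 %*% t(R)
  d6 <- c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
  s <- voxel_signals(d6, gt)
  f <- fit_tensor_loglinear(array(s, c(1, 1, 1, length(s))), gt)
  expect_equal(as.vector(f$D[1, 1, 1, ]), d6, tolerance = 1e-6 * max(abs(d6)))
})

test_that("scale equivariance: scaling signals scales s0 and leaves D fixed", {
  gt <- default_gradient_table()
  d6 <- c(9e-4, 5e-4, 7e-4, 1e-4, 0, -5e-5)
  s <- voxel_signals(d6, gt, s0 = 100)
  f1 <- fit_tensor_loglinear(array(s, c(1, 1, 1, length(s))), gt)
  f2 <- fit_tensor_loglinear(array(3.7 * s, c(1, 1, 1, length(s))), gt)
  expect_equal(f1$D, f2$D, tolerance = 1e-10)
  expect_equal(f2$s0[1, 1, 1] / f1$s0[1, 1, 1], 3.7, tolerance = 1e-10)
})

test_that("Rician noise at SNR 30 keeps the median fit within 5% of truth", {
  gt <- default_gradient_table()
  geom <- small_geom()
  truth <- draw_subject_truth(exact_params(), 1)
  field <- build_tensor_field(truth, geom)
  dwi <- simulate_dwi(field, gt, s0 = 1000, sigma = 1000 / 30, seed = 17)
  m <- roi_mask(geom)
  f <- fit_tensor_loglinear(dwi, gt, mask = m > 0)
  sel <- which(m %in% 1:2 & f$valid)  # projection ROI voxels
  nvox <- prod(geom$dim)
  dzz <- matrix(f$D, nvox, 6)[sel, 3]
  expect_lt(abs(stats::median(dzz) - truth$Dzzproj) / truth$Dzzproj, 0.05)
})

test_that("degenerate inputs are flagged or rejected, not silently fitted", {
  gt <- default_gradient_table()
  s <- voxel_signals(c(8e-4, 8e-4, 8e-4, 0, 0, 0), gt)
  dwi <- array(rep(s, 2), c(2, 1, 1, length(s)))
  expect_error(fit_tensor_loglinear(dwi, gt, mask = array(FALSE, c(2, 1, 1))),
               "mask")
  # a near-zero signal is clamped and the voxel flagged invalid
  dwi2 <- dwi
  dwi2[2, 1, 1, 5] <- 0
  f <- fit_tensor_loglinear(dwi2, gt)
  expect_true(f$valid[1, 1, 1])
  expect_false(f$valid[2, 1, 1])
  # coplanar directions cannot determine all six elements
  flat <- sphere_directions(12)
  flat[, 3] <- 0
  flat <- flat / sqrt(rowSums(flat^2))
  gflat <- gradient_table(c(0, rep(1000, 12)), rbind(0, flat))
  sflat <- voxel_signals(c(8e-4, 8e-4, 8e-4, 0, 0, 0), gflat)
  expect_error(fit_tensor_loglinear(array(sflat, c(1, 1, 1, 13)), gflat),
               "rank-deficient")
})

test_that("weighted refit agrees with OLS on noiseless data", {
  gt <- default_gradient_table()
  d6 <- c(0.00110, 0.00051, 0.00089, 5e-5, -2e-5, 1e-5)
  s <- voxel_signals(d6, gt)
  dwi <- array(s, c(1, 1, 1, length(s)))
  f_ols <- fit_tensor_loglinear(dwi, gt)
  f_wls <- fit_tensor_loglinear(dwi, gt, weighted = TRUE)
  expect_equal(f_ols$D, f_wls$D, tolerance = 1e-9)
})

test_that("eigenstructure: ordering, principal axis, FA", {
  # x-dominant diagonal tensor has an x-aligned principal eigenvector
  f <- one_voxel_field(c(0.00111, 0.00042, 0.00060, 0, 0, 0))
  e <- tensor_eigen(f)
  expect_equal(as.vector(e$eigenvalues[1, 1, 1, ]),
               c(0.00111, 0.00060, 0.00042))
  expect_equal(abs(as.vector(e$principal[1, 1, 1, ])), c(1, 0, 0))
  expect_gte(e$principal[1, 1, 1, 1], 0)  # deterministic sign convention
  # isotropic tensor: FA = 0
  fi <- one_voxel_field(c(8e-4, 8e-4, 8e-4, 0, 0, 0))
  expect_equal(tensor_eigen(fi)$fa[1, 1, 1], 0)
  # subcortical-fiber reference diagonal: closed-form FA
  lam <- c(0.00110, 0.00051, 0.00089)
  md <- mean(lam)
  fa_closed <- sqrt(3 / 2) * sqrt(sum((lam - md)^2) / sum(lam^2))
  fs <- one_voxel_field(c(lam, 0, 0, 0))
  expect_equal(tensor_eigen(fs)$fa[1, 1, 1], fa_closed, tolerance = 1e-12)
  expect_equal(fa_closed, 0.34439, tolerance = 1e-4)
  # FA bounded in [0, 1] for random SPD tensors
  set.seed(2)
  for (i in 1:10) {
    lam <- stats::runif(3, 1e-4, 2e-3)
    expect_gte(fa_from_eigenvalues(lam), 0)
    expect_lte(fa_from_eigenvalues(lam), 1)
  }
})
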