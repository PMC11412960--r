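# Small geometries and degenerate (SD = 0) parameter sets used across tests.

small_geom <- function() phantom_geometry(dim = c(24L, 24L, 12L))

# group parameters with all diffusivity SDs forced to zero: every subject's
# truth equals the group means exactly
exact_params <- function(group = "tinnitus") {
  zero <- stats::setNames(rep(0, 9), diffusivity_names())
  group_params(group, diffusivity_sd = zero)
}

# reference tinnitus ROI means as a plain named vector
tinnitus_means <- function() cohort_reference_params()$tinnitus$diffusivity_mean

# symmetric 3x3 tensor from a 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_matrix <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L)
}

# single-voxel tensor field
one_voxel_field <- function(d6) {
  tensor_field(array(d6, c(1L, 1L, 1L, 6L)))
}

# noiseless signals for one voxel under a gradient table
voxel_signals <- function(d6, gtab, s0 = 1000) {
  D <- tensor_matrix(d6)
  b <- gtab$bvals
  g <- gtab$bvecs
  s0 * exp(-b * rowSums((g %*% D) * g))
}

# brute-force exact two-sided Mann-Whitney p over all group labelings,
# independent of the package implementation
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mean(abs(us - n1 * n2 / 2) >= abs(u_obs - n1 * n2 / 2) - 1e-9)
}
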