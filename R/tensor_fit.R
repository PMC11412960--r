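#' Per-voxel diffusion tensor field
#'
#' Container for a voxelwise symmetric diffusion tensor in the image
#' coordinate frame — the frame whose diagonal elements (Dxx, Dyy, Dzz) the
#' ALPS index reads. Only the 6 unique elements are stored, in the order
#' Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#'
#' @param D numeric 4D array (nx, ny, nz, 6).
#' @param s0 optional 3D array of estimated non-weighted signal.
#' @param valid optional logical 3D array flagging voxels whose fit is
#'   trustworthy; defaults to all TRUE.
#' @return object of class `tensor_field` with elements `dim`, `D`, `s0`,
#'   `valid`.
#' @export
tensor_field <- function(D, s0 = NULL, valid = NULL) {
  stopifnot(is.array(D), length(dim(D)) == 4L, dim(D)[4] == 6L)
  d3 <- dim(D)[1:3]
  if (is.null(valid)) valid <- array(TRUE, d3)
  stopifnot(identical(dim(valid), as.integer(d3)) || identical(dim(valid), d3))
  structure(list(dim = d3, D = D, s0 = s0, valid = valid),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %s grid, %d/%d voxels valid\n",
              paste(x$dim, collapse = " x "), sum(x$valid), prod(x$dim)))
  invisible(x)
}

#' Fit the diffusion tensor per voxel by log-linear least squares
#'
#' Ordinary least squares of ln(signal) on the 7-column design of
#' [design_matrix()] estimates the 6 tensor elements and ln s0 jointly in
#' one linear model per voxel. On noiseless single-tensor signals the
#' estimate is exact. With `weighted = TRUE` a one-pass weighted LS is used
#' instead, with weights equal to the squared predicted signals from the
#' OLS pass (the usual WLS correction for the log transform's
#' heteroscedasticity).
#'
#' Signals are clamped below at `1e-6 * max(signal in voxel)` before the
#' log; voxels that needed clamping, or with any non-finite signal, are
#' flagged invalid in the output rather than dropped.
#'
#' @param dwi 4D signal array (nx, ny, nz, N), e.g. from [simulate_dwi()]
#'   or [read_dwi()].
#' @param gtab a [gradient_table()] with N entries.
#' @param mask optional logical 3D array restricting the fit.
#' @param weighted logical; use the WLS second pass (default FALSE = OLS).
#' @return a [tensor_field()] with `s0` filled in and `valid` flags set.
#' @export
fit_tensor_loglinear <- function(dwi, gtab, mask = NULL, weighted = FALSE) {
  stopifnot(is.array(dwi), length(dim(dwi)) == 4L,
            inherits(gtab, "gradient_table"))
  d3 <- dim(dwi)[1:3]
  nvol <- dim(dwi)[4]
  if (nvol != length(gtab$bvals))
    stop(sprintf("DWI has %d volumes but the gradient table %d entries",
                 nvol, length(gtab$bvals)))
  if (is.null(mask)) mask <- array(TRUE, d3)
  if (!any(mask)) stop("mask is empty: no voxels to fit")
  X <- design_matrix(gtab)
  qx <- qr(X)
  if (qx$rank < 7L)
    stop("rank-deficient design: the gradient table does not determine a tensor")
  nvox <- prod(d3)
  S <- matrix(dwi, nvox, nvol)[which(mask), , drop = FALSE]
  finite_ok <- rowSums(!is.finite(S) | is.na(S)) == 0L
  S[!finite_ok, ] <- 1  # placeholder; flagged invalid below
  floor_vals <- 1e-6 * apply(S, 1L, max)
  clamped <- S < floor_vals
  S <- pmax(S, floor_vals)
  B <- qr.coef(qx, t(log(S)))          # 7 x nmask
  if (weighted) {
    W <- exp(X %*% B)^2                # predicted signals squared, N x nmask
    for (j in seq_len(ncol(B))) {
      w <- W[, j]
      B[, j] <- qr.coef(qr(X * sqrt(w)), sqrt(w) * log(S[j, ]))
    }
  }
  D <- array(0, c(d3, 6L))
  s0 <- array(NA_real_, d3)
  valid <- array(FALSE, d3)
  sel <- which(mask)
  for (k in 1:6) {
    plane <- array(0, d3)
    plane[sel] <- B[k, ]
    D[, , , k] <- plane
  }
  s0[sel] <- exp(B[7L, ])
  valid[sel] <- finite_ok & (rowSums(clamped) == 0L)
  # a valid voxel must also be positive-definite
  ev <- tensor_eigenvalues(matrix(aperm(D, c(4, 1, 2, 3)), 6L)[, sel, drop = FALSE])
  valid[sel] <- valid[sel] & (ev[3L, ] > 0)
  tensor_field(D, s0 = s0, valid = valid)
}

# eigenvalues (descending) of symmetric tensors given as 6 x n matrix
tensor_eigenvalues <- function(d6) {
  apply(d6, 2L, function(v) {
    if (any(!is.finite(v))) return(rep(NA_real_, 3L))
    M <- matrix(c(v[1], v[4], v[5],
                  v[4], v[2], v[6],
                  v[5], v[6], v[3]), 3L)
    eigen(M, symmetric = TRUE, only.values = TRUE)$values
  })
}

#' Eigen-decomposition and fractional anisotropy of a tensor field
#'
#' Eigenvalues are sorted descending. The eigenvector of the leading
#' eigenvalue has its sign fixed by making its largest-magnitude component
#' positive, so outputs are deterministic. FA uses the standard normalized
#' eigenvalue-dispersion formula and lies in \[0, 1\] for positive-definite
#' tensors (0 for isotropic).
#'
#' @param field a [tensor_field()].
#' @return list with `eigenvalues` (nx, ny, nz, 3 array, descending),
#'   `principal` (nx, ny, nz, 3 array, leading eigenvector), and `fa`
#'   (3D array). Voxels with non-finite tensors yield NA.
#' @export
tensor_eigen <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  d3 <- field$dim
  nvox <- prod(d3)
  d6 <- t(matrix(field$D, nvox, 6L))  # 6 x nvox
  evals <- matrix(NA_real_, 3L, nvox)
  evecs <- matrix(NA_real_, 3L, nvox)
  for (j in seq_len(nvox)) {
    v <- d6[, j]
    if (any(!is.finite(v))) next
    M <- matrix(c(v[1], v[4], v[5],
                  v[4], v[2], v[6],
                  v[5], v[6], v[3]), 3L)
    e <- eigen(M, symmetric = TRUE)
    evals[, j] <- e$values
    p <- e$vectors[, 1L]
    if (p[which.max(abs(p))] < 0) p <- -p
    evecs[, j] <- p
  }
  md <- colMeans(evals)
  num <- colSums(sweep(evals, 2L, md)^2)
  den <- colSums(evals^2)
  fa <- sqrt(1.5) * sqrt(num / den)
  list(eigenvalues = array(t(evals), c(d3, 3L)),
       principal   = array(t(evecs), c(d3, 3L)),
       fa          = array(fa, d3))
}

#' Fractional anisotropy from three eigenvalues
#'
#' @param lambda numeric length-3 vector of eigenvalues.
#' @return FA scalar in \[0, 1\] for non-negative eigenvalues.
#' @export
fa_from_eigenvalues <- function(lambda) {
  stopifnot(length(lambda) == 3L)
  md <- mean(lambda)
  sqrt(1.5) * sqrt(sum((lambda - md)^2) / sum(lambda^2))
}
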