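#' Diffusion gradient table
#'
#' A gradient table pairs each diffusion-weighted volume with its b-value
#' (s/mm^2) and unit sensitization direction. The default acquisition mirrors
#' a single-shell clinical protocol: one b = 0 volume plus 32 directions at
#' b = 1000 s/mm^2.
#'
#' @param bvals numeric vector of b-values, s/mm^2.
#' @param bvecs numeric matrix of gradient directions, either 3 x N (FSL
#'   convention) or N x 3. Directions for non-zero b must be unit norm.
#' @return an object of class `gradient_table` with elements `bvals`
#'   (length-N numeric) and `bvecs` (N x 3 matrix, rows unit-norm for b > 0).
#' @examples
#' gt <- default_gradient_table()
#' nrow(gt$bvecs)  # 33 volumes
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must be a 3 x N or N x 3 matrix of directions")
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("gradient table mismatch: %d b-values but %d directions",
                 length(bvals), nrow(bvecs)))
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  dwi <- bvals > 0
  if (sum(!dwi) < 1L)
    stop("gradient table needs at least one b = 0 volume")
  if (sum(dwi) < 6L)
    stop("gradient table needs at least 6 non-zero-b directions for a tensor fit")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[dwi] - 1) > 1e-6))
    stop("non-unit gradient direction: |g| deviates from 1 by more than 1e-6")
  dimnames(bvecs) <- NULL
  structure(list(bvals = unname(bvals), bvecs = bvecs),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("gradient_table: %d volumes (%d b=0, %d diffusion-weighted), b max = %g s/mm^2\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0), max(x$bvals)))
  invisible(x)
}

#' Evenly spread unit directions on the sphere
#'
#' Deterministic golden-angle (Fibonacci) spiral placement, a standard
#' stand-in for electrostatic-repulsion direction schemes: directions are
#' near-uniform on the sphere and reproducible without optimization.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default single-shell acquisition: 1 b=0 + 32 directions at b = 1000
#'
#' @param n_dirs number of diffusion-weighted directions (default 32).
#' @param b b-value of the shell, s/mm^2 (default 1000).
#' @return a [gradient_table()].
#' @export
default_gradient_table <- function(n_dirs = 32L, b = 1000) {
  gradient_table(c(0, rep(b, n_dirs)),
                 rbind(c(0, 0, 0), sphere_directions(n_dirs)))
}

#' Design matrix for the log-linearized tensor signal model
#'
#' Linearizing ln S = ln s0 - b g' D g gives, per volume, the row
#' \[-b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz, 1\]
#' against the coefficient vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, ln s0).
#'
#' @param gtab a [gradient_table()].
#' @return N x 7 numeric matrix.
#' @export
design_matrix <- function(gtab) {
  stopifnot(inherits(gtab, "gradient_table"))
  b <- gtab$bvals
  g <- gtab$bvecs
  X <- cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3], 1)
  colnames(X) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz", "log_s0")
  if (nrow(X) < 7L) stop("underdetermined design: fewer than 7 volumes")
  X
}
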