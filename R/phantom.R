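#' Phantom geometry for the ALPS ROI layout
#'
#' A small voxel grid holding six rectangular ROI blocks — projection,
#' association and subcortical fiber regions on each side — embedded in an
#' isotropic background. At the level of the lateral ventricles the three
#' fiber systems run mainly along the image z, y and x axes respectively;
#' the phantom realizes that geometry directly so the ALPS diagonal-read
#' logic can be validated exactly.
#'
#' ROI labels follow the mask convention 1:proj-L, 2:proj-R, 3:assoc-L,
#' 4:assoc-R, 5:sub-L, 6:sub-R; 0 is background.
#'
#' @param dim integer grid shape (nx, ny, nz).
#' @param voxel_mm voxel edge length, mm.
#' @param background_diffusivity isotropic background diffusivity, mm^2/s.
#' @param roi_blocks optional named list of 3 x 2 integer matrices giving
#'   inclusive voxel index ranges per label name (`proj_L`, `proj_R`,
#'   `assoc_L`, `assoc_R`, `sub_L`, `sub_R`). Defaults place six disjoint
#'   2 x 2 x 2 blocks flanking the grid midline.
#' @return object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(dim = c(40L, 40L, 20L), voxel_mm = 2,
                             background_diffusivity = 0.0008,
                             roi_blocks = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 4L), voxel_mm > 0,
            background_diffusivity > 0)
  if (is.null(roi_blocks)) {
    cx <- dim[1] %/% 2; cy <- dim[2] %/% 2; cz <- dim[3] %/% 2
    blk <- function(x0, y0, z0)
      rbind(c(x0, x0 + 1L), c(y0, y0 + 1L), c(z0, z0 + 1L))
    roi_blocks <- list(
      proj_L  = blk(cx - 6L, cy, cz),
      proj_R  = blk(cx + 4L, cy, cz),
      assoc_L = blk(cx - 6L, cy - 4L, cz),
      assoc_R = blk(cx + 4L, cy - 4L, cz),
      sub_L   = blk(cx - 6L, cy + 4L, cz),
      sub_R   = blk(cx + 4L, cy + 4L, cz)
    )
  }
  need <- c("proj_L", "proj_R", "assoc_L", "assoc_R", "sub_L", "sub_R")
  if (!setequal(names(roi_blocks), need))
    stop("roi_blocks must name exactly: ", paste(need, collapse = ", "))
  roi_blocks <- roi_blocks[need]
  occupied <- array(FALSE, dim)
  for (nm in need) {
    b <- roi_blocks[[nm]]
    if (any(b[, 1] < 1L) || any(b[, 2] > dim) || any(b[, 2] < b[, 1]))
      stop("ROI block ", nm, " falls outside the grid")
    idx <- expand_block(b)
    if (nrow(idx) < 4L) stop("ROI block ", nm, " has fewer than 4 voxels")
    if (any(occupied[idx])) stop("ROI block ", nm, " overlaps another block")
    occupied[idx] <- TRUE
  }
  structure(list(dim = dim, voxel_mm = voxel_mm,
                 background_diffusivity = background_diffusivity,
                 roi_blocks = roi_blocks),
            class = "phantom_geometry")
}

expand_block <- function(b) {
  as.matrix(expand.grid(x = b[1, 1]:b[1, 2], y = b[2, 1]:b[2, 2],
                        z = b[3, 1]:b[3, 2]))
}

#' ROI label volume for a phantom geometry
#'
#' @param geom a [phantom_geometry()].
#' @return integer 3D array with labels 1:proj-L ... 6:sub-R, 0 background.
#' @export
roi_mask <- function(geom) {
  stopifnot(inherits(geom, "phantom_geometry"))
  m <- array(0L, geom$dim)
  for (i in seq_along(geom$roi_blocks))
    m[expand_block(geom$roi_blocks[[i]])] <- i
  m
}

#' Mapping from ROI labels to fiber type, side and expected fiber axis
#'
#' Projection fibers run inferior-superior (z), association fibers
#' anterior-posterior (y), subcortical fibers left-right (x) at the ALPS
#' ROI level under the radiological frame convention.
#'
#' @return data.frame with columns label, name, fiber, side, axis.
#' @export
roi_label_table <- function() {
  data.frame(
    label = 1:6,
    name  = c("proj_L", "proj_R", "assoc_L", "assoc_R", "sub_L", "sub_R"),
    fiber = rep(c("projection", "association", "subcortical"), each = 2),
    side  = rep(c("L", "R"), 3),
    axis  = rep(c("z", "y", "x"), each = 2),
    stringsAsFactors = FALSE
  )
}

#' Build a voxelwise tensor field from one subject's true diffusivities
#'
#' Every voxel inside a fiber-type ROI (both sides) receives a diagonal
#' tensor whose (Dxx, Dyy, Dzz) are that subject's true diffusivities for
#' that fiber type; background voxels are isotropic at the geometry's
#' background diffusivity. All tensors are therefore symmetric
#' positive-definite by construction.
#'
#' @param truth a `subject_truth` from [draw_subject_truth()], or any list
#'   with the nine named diffusivities (mm^2/s).
#' @param geom a [phantom_geometry()].
#' @return a `tensor_field` (see [fit_tensor_loglinear()] for the layout).
#' @export
build_tensor_field <- function(truth, geom) {
  stopifnot(inherits(geom, "phantom_geometry"))
  dvals <- unlist(truth[diffusivity_names()])
  if (length(dvals) != 9L || any(!is.finite(dvals)))
    stop("truth must carry the nine finite ROI diffusivities")
  if (any(dvals <= 0)) stop("requested diagonal diffusivity <= 0")
  D <- array(0, c(geom$dim, 6L))
  bg <- geom$background_diffusivity
  D[, , , 1] <- bg; D[, , , 2] <- bg; D[, , , 3] <- bg
  lab <- roi_label_table()
  nvox <- prod(geom$dim)
  for (i in seq_len(nrow(lab))) {
    idx <- expand_block(geom$roi_blocks[[lab$name[i]]])
    flat <- idx[, 1] + geom$dim[1] * (idx[, 2] - 1L) +
      geom$dim[1] * geom$dim[2] * (idx[, 3] - 1L)
    pre <- c("Dxx", "Dyy", "Dzz")
    suf <- c(projection = "proj", association = "assoc",
             subcortical = "sub")[[lab$fiber[i]]]
    for (k in 1:3) D[flat + (k - 1L) * nvox] <- dvals[[paste0(pre[k], suf)]]
  }
  tensor_field(D, valid = array(TRUE, geom$dim))
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' The noiseless signal per voxel and volume follows the monoexponential
#' tensor model S = s0 exp(-b g' D g). With `sigma > 0`, Rician noise is
#' applied as sqrt((S + e1)^2 + e2^2) with e1, e2 independent zero-mean
#' normals of SD `sigma`, the standard model for magnitude MR data; its
#' second moment satisfies E\[S_noisy^2\] = S^2 + 2 sigma^2.
#'
#' @param field a `tensor_field`.
#' @param gtab a [gradient_table()].
#' @param s0 non-diffusion-weighted signal amplitude (> 0).
#' @param sigma Rician noise SD (>= 0); the default SNR convention is
#'   sigma = s0 / snr with snr = 30.
#' @param seed optional integer seed for the noise draw.
#' @return 4D array (nx, ny, nz, N volumes) of signals, with the gradient
#'   table attached as attribute `gradient_table`.
#' @export
simulate_dwi <- function(field, gtab, s0 = 1000, sigma = 0, seed = NULL) {
  stopifnot(inherits(field, "tensor_field"), inherits(gtab, "gradient_table"),
            s0 > 0, sigma >= 0)
  X <- design_matrix(gtab)[, 1:6, drop = FALSE]
  nvox <- prod(field$dim)
  Dmat <- matrix(field$D, nvox, 6L)   # voxels x 6
  logS <- Dmat %*% t(X)               # voxels x N, equals -b g'Dg
  S <- s0 * exp(logS)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    e1 <- matrix(stats::rnorm(length(S), 0, sigma), nrow(S))
    e2 <- matrix(stats::rnorm(length(S), 0, sigma), nrow(S))
    S <- sqrt((S + e1)^2 + e2^2)
  }
  out <- array(S, c(field$dim, length(gtab$bvals)))
  attr(out, "gradient_table") <- gtab
  out
}
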