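#' ALPS ratio from its four constituent diffusivities
#'
#' ALPS = mean(Dxxproj, Dxxassoc) / mean(Dyyproj, Dzzassoc): x-axis
#' diffusivity in the projection and association ROIs — the direction of
#' the perivascular space at the lateral-ventricle level, perpendicular to
#' both fiber systems — over the diffusivity perpendicular to both the
#' x-axis and each ROI's dominant fiber direction.
#'
#' @param dxxproj,dxxassoc,dyyproj,dzzassoc diffusivities, mm^2/s.
#' @return dimensionless ALPS index.
#' @export
alps_ratio <- function(dxxproj, dxxassoc, dyyproj, dzzassoc) {
  den <- (dyyproj + dzzassoc) / 2
  if (any(den <= 0)) stop("ALPS denominator mean(Dyyproj, Dzzassoc) <= 0")
  ((dxxproj + dxxassoc) / 2) / den
}

#' Construct a per-subject diffusivity profile
#'
#' @param values named numeric vector or list holding the nine diffusivities
#'   of [diffusivity_names()], mm^2/s, all finite and > 0.
#' @param subject_id subject identifier.
#' @return object of class `diffusivity_profile`.
#' @export
diffusivity_profile <- function(values, subject_id = NA_character_) {
  v <- unlist(values)[diffusivity_names()]
  if (any(is.na(v)) || any(!is.finite(v)))
    stop("diffusivity profile must contain all nine finite diffusivities")
  if (any(v <= 0)) stop("diffusivity profile values must be > 0")
  structure(c(as.list(v), list(subject_id = subject_id)),
            class = "diffusivity_profile")
}

#' Extract fiber-type ROI diffusivities from a fitted tensor field
#'
#' For each fiber type the diagonal tensor elements Dxx, Dyy, Dzz are
#' averaged over all fit-valid voxels of the left and right ROI blocks
#' jointly (equal weight per voxel), yielding one nine-value profile per
#' subject. ROIs in which fewer than half the voxels carry a valid fit
#' trigger a warning; an ROI with no valid voxel is an error.
#'
#' @param field a [tensor_field()].
#' @param roi integer 3D label array (1:proj-L ... 6:sub-R, 0 background).
#' @param subject_id subject identifier carried into the profile.
#' @return a [diffusivity_profile()].
#' @export
extract_roi_diffusivities <- function(field, roi, subject_id = NA_character_) {
  stopifnot(inherits(field, "tensor_field"))
  roi <- as.array(roi)
  if (!identical(as.integer(dim(roi)), as.integer(field$dim)))
    stop("ROI mask dimensions do not match the tensor field")
  lab <- roi_label_table()
  nvox <- prod(field$dim)
  Dmat <- matrix(field$D, nvox, 6L)
  out <- list()
  for (fib in unique(lab$fiber)) {
    labels <- lab$label[lab$fiber == fib]
    sel <- which(roi %in% labels)
    if (!length(sel)) stop("ROI labels for ", fib, " fibers missing from mask")
    ok <- sel[field$valid[sel]]
    if (!length(ok)) stop("all voxels invalid in the ", fib, " fiber ROI")
    if (length(ok) < 0.5 * length(sel))
      warning(sprintf("fewer than 50%% valid voxels in the %s fiber ROI (%d/%d)",
                      fib, length(ok), length(sel)))
    suf <- c(projection = "proj", association = "assoc",
             subcortical = "sub")[[fib]]
    out[[paste0("Dxx", suf)]] <- mean(Dmat[ok, 1L])
    out[[paste0("Dyy", suf)]] <- mean(Dmat[ok, 2L])
    out[[paste0("Dzz", suf)]] <- mean(Dmat[ok, 3L])
  }
  diffusivity_profile(out, subject_id = subject_id)
}

#' DTI-ALPS index from a diffusivity profile
#'
#' Applies the ALPS formula mean(Dxxproj, Dxxassoc) / mean(Dyyproj,
#' Dzzassoc). Subcortical diffusivities are carried in the profile for
#' reporting but never enter the index.
#'
#' @param profile a [diffusivity_profile()].
#' @return object of class `alps_result`: `subject_id`, `alps_index`,
#'   `numerator`, `denominator` (mm^2/s).
#' @export
alps_index <- function(profile) {
  stopifnot(inherits(profile, "diffusivity_profile"))
  num <- (profile$Dxxproj + profile$Dxxassoc) / 2
  den <- (profile$Dyyproj + profile$Dzzassoc) / 2
  if (den <= 0) stop("ALPS denominator <= 0")
  structure(list(subject_id = profile$subject_id, alps_index = num / den,
                 numerator = num, denominator = den),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("ALPS index %s: %.5f (num %.3g / den %.3g mm^2/s)\n",
              x$subject_id, x$alps_index, x$numerator, x$denominator))
  invisible(x)
}

#' Automated ROI orientation validation
#'
#' Stands in for a radiologist's review of ROI placement: for each of the
#' six ROI blocks the principal eigenvector of the ROI-mean tensor (valid
#' voxels only) is compared with the fiber system's expected axis —
#' projection along z, association along y, subcortical along x. An ROI
#' passes when the angle is within `max_angle_deg`.
#'
#' @param field a [tensor_field()].
#' @param roi integer 3D label array.
#' @param max_angle_deg pass threshold in degrees (default 20).
#' @return data.frame with one row per ROI: name, fiber, side, expected
#'   axis, angle_deg, n_valid, pass.
#' @export
validate_roi_orientation <- function(field, roi, max_angle_deg = 20) {
  stopifnot(inherits(field, "tensor_field"))
  roi <- as.array(roi)
  lab <- roi_label_table()
  nvox <- prod(field$dim)
  Dmat <- matrix(field$D, nvox, 6L)
  axes <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  res <- lab
  res$angle_deg <- NA_real_
  res$n_valid <- 0L
  res$pass <- FALSE
  for (i in seq_len(nrow(lab))) {
    sel <- which(roi == lab$label[i])
    ok <- sel[field$valid[sel]]
    res$n_valid[i] <- length(ok)
    if (!length(ok)) next
    v <- colMeans(Dmat[ok, , drop = FALSE])
    M <- matrix(c(v[1], v[4], v[5],
                  v[4], v[2], v[6],
                  v[5], v[6], v[3]), 3L)
    p <- eigen(M, symmetric = TRUE)$vectors[, 1L]
    cosang <- abs(sum(p * axes[[lab$axis[i]]]))
    res$angle_deg[i] <- acos(min(1, cosang)) * 180 / pi
    res$pass[i] <- res$angle_deg[i] <= max_angle_deg
  }
  res
}

#' Fit, extract and compute the ALPS index for one subject's DWI
#'
#' Convenience wrapper chaining [fit_tensor_loglinear()],
#' [extract_roi_diffusivities()], [alps_index()] and
#' [validate_roi_orientation()].
#'
#' @param dwi 4D signal array.
#' @param gtab a [gradient_table()].
#' @param roi integer 3D label array.
#' @param subject_id subject identifier.
#' @param weighted passed to [fit_tensor_loglinear()].
#' @return list with `profile`, `alps`, `orientation`.
#' @export
subject_alps <- function(dwi, gtab, roi, subject_id = NA_character_,
                         weighted = FALSE) {
  roi <- as.array(roi)
  field <- fit_tensor_loglinear(dwi, gtab, mask = roi > 0, weighted = weighted)
  profile <- extract_roi_diffusivities(field, roi, subject_id = subject_id)
  list(profile = profile, alps = alps_index(profile),
       orientation = validate_roi_orientation(field, roi))
}
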