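#' Read FSL-style bval/bvec files into a gradient table
#'
#' bval: one whitespace-separated row of b-values; bvec: 3 rows by N
#' columns of direction components.
#'
#' @param bval_path,bvec_path file paths.
#' @return a [gradient_table()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bvals <- scan(bval_path, quiet = TRUE)
  lines <- readLines(bvec_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3L)
    stop("malformed bvec file (expected 3 rows): ", bvec_path)
  rows <- lapply(lines, function(l) scan(text = l, quiet = TRUE))
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged bvec file: ", bvec_path)
  bvecs <- do.call(rbind, rows)
  if (ncol(bvecs) != length(bvals))
    stop(sprintf("bval/bvec mismatch: %d b-values vs %d directions (%s)",
                 length(bvals), ncol(bvecs), bvec_path))
  gradient_table(bvals, bvecs)
}

#' Write a gradient table as FSL-style bval/bvec files
#'
#' @param gtab a [gradient_table()].
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_bval_bvec <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, trim = TRUE, digits = 17),
                   collapse = " "), bval_path)
  writeLines(apply(t(gtab$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

bval_bvec_paths <- function(nii_path) {
  stem <- sub("\\.nii(\\.gz)?$", "", nii_path)
  c(bval = paste0(stem, ".bval"), bvec = paste0(stem, ".bvec"))
}

#' Write a 4D DWI volume with bval/bvec sidecars
#'
#' @param dwi 4D array (nx, ny, nz, N).
#' @param gtab a [gradient_table()] with N entries, volume order matching
#'   the 4th dimension.
#' @param path output NIfTI path (`.nii` or `.nii.gz`); sidecar `.bval` and
#'   `.bvec` files are written next to it.
#' @param voxel_mm voxel size recorded in the header.
#' @return invisibly, the NIfTI path.
#' @export
write_dwi <- function(dwi, gtab, path, voxel_mm = 2) {
  stopifnot(length(dim(dwi)) == 4L)
  if (dim(dwi)[4] != length(gtab$bvals))
    stop(sprintf("DWI has %d volumes but the gradient table %d entries",
                 dim(dwi)[4], length(gtab$bvals)))
  img <- RNifti::asNifti(unclass(dwi), pixdim = c(rep(voxel_mm, 3), 1))
  RNifti::writeNifti(img, path)
  sp <- bval_bvec_paths(path)
  write_bval_bvec(gtab, sp[["bval"]], sp[["bvec"]])
  invisible(path)
}

#' Read a 4D DWI volume and its bval/bvec sidecars
#'
#' @param path NIfTI path; sidecars found by replacing the extension.
#' @return list with `dwi` (4D array) and `gtab` ([gradient_table()]).
#' @export
read_dwi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dwi <- array(as.numeric(img), dim(img))
  if (length(dim(dwi)) != 4L) stop("not a 4D DWI volume: ", path)
  sp <- bval_bvec_paths(path)
  gtab <- read_bval_bvec(sp[["bval"]], sp[["bvec"]])
  if (length(gtab$bvals) != dim(dwi)[4])
    stop(sprintf("DWI %s has %d volumes but bval lists %d entries",
                 path, dim(dwi)[4], length(gtab$bvals)))
  list(dwi = dwi, gtab = gtab)
}

#' Write a tensor field as NIfTI maps
#'
#' Writes the 6 unique tensor elements as a 4D volume (order Dxx, Dyy,
#' Dzz, Dxy, Dxz, Dyz) plus s0 and valid-flag maps alongside.
#'
#' @param field a [tensor_field()].
#' @param path output path for the tensor volume; `_s0` / `_valid` maps are
#'   derived from it.
#' @param voxel_mm voxel size recorded in the header.
#' @return invisibly, the tensor path.
#' @export
write_tensor_field <- function(field, path, voxel_mm = 2) {
  stopifnot(inherits(field, "tensor_field"))
  pd <- c(rep(voxel_mm, 3), 1)
  RNifti::writeNifti(RNifti::asNifti(unclass(field$D), pixdim = pd), path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  ext <- sub("^.*?(\\.nii(\\.gz)?)$", "\\1", path)
  if (!is.null(field$s0))
    RNifti::writeNifti(RNifti::asNifti(unclass(field$s0), pixdim = pd),
                       paste0(stem, "_s0", ext))
  RNifti::writeNifti(RNifti::asNifti(field$valid + 0, pixdim = pd),
                     paste0(stem, "_valid", ext))
  invisible(path)
}

#' Read a tensor field written by [write_tensor_field()]
#'
#' @param path tensor NIfTI path.
#' @return a [tensor_field()].
#' @export
read_tensor_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  D <- array(as.numeric(img), dim(img))
  if (length(dim(D)) != 4L || dim(D)[4] != 6L)
    stop("not a 6-volume tensor NIfTI: ", path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  ext <- sub("^.*?(\\.nii(\\.gz)?)$", "\\1", path)
  s0 <- NULL
  if (file.exists(paste0(stem, "_s0", ext))) {
    s0img <- RNifti::readNifti(paste0(stem, "_s0", ext))
    s0 <- array(as.numeric(s0img), dim(s0img))
  }
  valid <- NULL
  if (file.exists(paste0(stem, "_valid", ext))) {
    vimg <- RNifti::readNifti(paste0(stem, "_valid", ext))
    valid <- array(as.numeric(vimg) > 0.5, dim(vimg))
  }
  tensor_field(D, s0 = s0, valid = valid)
}

#' Read an ROI label mask NIfTI
#'
#' @param path NIfTI path with integer labels 1:proj-L ... 6:sub-R.
#' @return integer 3D array.
#' @export
read_roi_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  m <- array(as.integer(round(as.numeric(img))), dim(img))
  if (length(dim(m)) != 3L) stop("ROI mask must be 3D: ", path)
  if (!all(1:6 %in% m))
    stop("ROI mask is missing label(s): ",
         paste(setdiff(1:6, unique(as.vector(m))), collapse = ", "))
  m
}

#' Read a cohort CSV, checking the column schema
#'
#' @param path CSV path with the columns of [cohort_columns()].
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols))
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Write analysis results as JSON
#'
#' @param x list or data.frame of results.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
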