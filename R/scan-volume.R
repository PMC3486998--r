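#' CT scan volume container
#'
#' A `scan_volume` bundles a 3D grid of attenuation values in Hounsfield units
#' (HU) with its voxel spacing in millimetres and, optionally, a binary lung
#' mask of the same shape. It is the carrier type for every densitometric
#' operation in the package.
#'
#' @param voxels 3D numeric array of HU values; must lie within
#'   \eqn{[-1024, 3071]}, the representable range of 12-bit CT.
#' @param spacing numeric length-3, voxel size in mm along each axis.
#' @param lung_mask optional logical (or 0/1) array with the same dimensions
#'   as `voxels`.
#' @param meta named list of free-form labels (subject, visit, phase, ...).
#'
#' @return An object of class `scan_volume`: a list with elements `voxels`,
#'   `spacing`, `lung_mask` and `meta`.
#' @export
#' @examples
#' v <- scan_volume(array(-900, c(4, 4, 4)), spacing = c(1, 1, 1))
#' lung_volume(array(TRUE, c(4, 4, 4)), v$spacing)
scan_volume <- function(voxels, spacing, lung_mask = NULL, meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array of HU values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop("HU values must lie within [-1024, 3071]")
  if (!is.null(lung_mask)) {
    if (!identical(dim(lung_mask), dim(voxels)))
      stop("`lung_mask` must have the same shape as `voxels`")
    storage.mode(lung_mask) <- "logical"
  }
  structure(list(voxels = voxels, spacing = spacing,
                 lung_mask = lung_mask, meta = meta),
            class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<scan_volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]; mask: %s\n",
              min(x$voxels), max(x$voxels),
              if (is.null(x$lung_mask)) "none"
              else sprintf("%d voxels", sum(x$lung_mask))))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Paired inspiratory/expiratory scans for one subject-visit
#'
#' @param insp,exp `scan_volume` objects for the inspiratory and expiratory
#'   acquisitions of the same visit.
#' @param subject_id subject identifier.
#' @param visit visit index (1 = baseline CT, 2 = repeat CT).
#' @return An object of class `visit_pair`.
#' @export
visit_pair <- function(insp, exp, subject_id, visit) {
  stopifnot(inherits(insp, "scan_volume"), inherits(exp, "scan_volume"))
  structure(list(insp = insp, exp = exp,
                 subject_id = subject_id, visit = as.integer(visit)),
            class = "visit_pair")
}

#' @export
print.visit_pair <- function(x, ...) {
  cat(sprintf("<visit_pair> subject %s, visit %d\n", x$subject_id, x$visit))
  invisible(x)
}

#' Read and write scan volumes as NIfTI
#'
#' Volumes are stored one file per phase per visit as compressed NIfTI
#' (`.nii.gz`), with voxel spacing carried in the header `pixdim`. Masks are
#' written as 0/1 integer volumes.
#'
#' @param vol a `scan_volume`.
#' @param file path ending in `.nii` or `.nii.gz`.
#' @param mask_file optional path for the lung mask; omitted if `NULL`.
#' @return `write_scan` invisibly returns `file`; `read_scan` returns a
#'   `scan_volume`.
#' @export
write_scan <- function(vol, file, mask_file = NULL) {
  stopifnot(inherits(vol, "scan_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, file)
  if (!is.null(mask_file)) {
    if (is.null(vol$lung_mask)) stop("volume carries no lung mask to write")
    m <- array(as.integer(vol$lung_mask), dim = dim(vol$lung_mask))
    mimg <- RNifti::asNifti(m)
    RNifti::pixdim(mimg) <- vol$spacing
    RNifti::writeNifti(mimg, mask_file)
  }
  invisible(file)
}

#' @rdname write_scan
#' @param meta named list attached to the returned volume.
#' @export
read_scan <- function(file, mask_file = NULL, meta = list()) {
  img <- RNifti::readNifti(file)
  spacing <- RNifti::pixdim(img)[1:3]
  vox <- array(as.numeric(img), dim = dim(img)[1:3])
  mask <- NULL
  if (!is.null(mask_file)) {
    mimg <- RNifti::readNifti(mask_file)
    mask <- array(as.numeric(mimg) > 0.5, dim = dim(mimg)[1:3])
  }
  scan_volume(vox, spacing, lung_mask = mask, meta = meta)
}
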