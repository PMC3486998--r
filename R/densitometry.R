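#' Gaussian noise-reduction filter in physical units
#'
#' Smooths the voxel grid with a separable Gaussian kernel whose sd is given
#' in millimetres, so anisotropic voxel spacing is handled per axis. The lung
#' mask is left untouched. A kernel sd of 0 returns the input unchanged.
#'
#' @param vol a [scan_volume()].
#' @param kernel_sd_mm Gaussian sd in mm; `>= 0`.
#' @return A `scan_volume` with smoothed voxels.
#' @export
smooth_volume <- function(vol, kernel_sd_mm) {
  stopifnot(inherits(vol, "scan_volume"), kernel_sd_mm >= 0)
  if (kernel_sd_mm == 0) return(vol)
  sigma_vox <- kernel_sd_mm / vol$spacing
  vol$voxels <- smooth_array3d(vol$voxels, sigma_vox)
  vol
}

#' Threshold-based lung segmentation (stand-in)
#'
#' A deliberately simple segmenter: voxels below `hu_threshold` are foreground,
#' 3D 6-connected components are labelled, components touching the grid border
#' (ambient air) are discarded, and the two largest internal components are
#' retained as the lungs. Clinical-grade segmentation software is out of scope;
#' pipelines on synthetic data normally bypass this via the generator's
#' ground-truth masks.
#'
#' @param vol a [scan_volume()].
#' @param hu_threshold HU threshold below which a voxel is lung candidate.
#' @param bypass if `TRUE`, return the volume's own `lung_mask` verbatim.
#' @return Logical mask array.
#' @export
segment_lungs <- function(vol, hu_threshold = -300, bypass = FALSE) {
  stopifnot(inherits(vol, "scan_volume"))
  if (bypass) {
    if (is.null(vol$lung_mask))
      stop("bypass requested but the volume carries no lung mask")
    return(vol$lung_mask)
  }
  fg <- vol$voxels < hu_threshold
  if (!any(fg))
    stop("segmentation failure: no voxels below the threshold")
  d <- dim(fg)
  n <- prod(d)
  idx <- which(fg)
  id <- integer(n)
  id[idx] <- seq_along(idx)
  lin <- array(seq_len(n), d)
  edges <- list()
  # 6-connectivity: forward neighbour along each axis
  b1 <- fg[-d[1], , , drop = FALSE] & fg[-1, , , drop = FALSE]
  edges[[1]] <- cbind(id[lin[-d[1], , ][b1]], id[lin[-1, , ][b1]])
  b2 <- fg[, -d[2], , drop = FALSE] & fg[, -1, , drop = FALSE]
  edges[[2]] <- cbind(id[lin[, -d[2], ][b2]], id[lin[, -1, ][b2]])
  b3 <- fg[, , -d[3], drop = FALSE] & fg[, , -1, drop = FALSE]
  edges[[3]] <- cbind(id[lin[, , -d[3]][b3]], id[lin[, , -1][b3]])
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e) > 0) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)
  # drop components that touch the grid border (ambient air)
  ai <- arrayInd(idx, d)
  on_border <- ai[, 1] %in% c(1L, d[1]) | ai[, 2] %in% c(1L, d[2]) |
    ai[, 3] %in% c(1L, d[3])
  border_comps <- unique(comp$membership[on_border])
  keep <- setdiff(order(comp$csize, decreasing = TRUE), border_comps)
  if (length(keep) < 1)
    stop("segmentation failure: no internal connected component found")
  keep <- keep[seq_len(min(2L, length(keep)))]
  mask <- array(FALSE, d)
  mask[idx[comp$membership %in% keep]] <- TRUE
  mask
}

masked_values <- function(vol, mask = NULL) {
  if (inherits(vol, "scan_volume")) {
    if (is.null(mask)) mask <- vol$lung_mask
    vox <- vol$voxels
  } else {
    vox <- vol
  }
  if (is.null(mask)) stop("a lung mask is required")
  if (!identical(dim(mask), dim(vox)))
    stop("mask shape must equal voxel shape")
  v <- vox[as.logical(mask)]
  if (length(v) == 0) stop("empty lung mask")
  v
}

#' Lung volume from a mask
#'
#' Voxel count times voxel volume, in litres.
#'
#' @param mask logical mask array (or a `scan_volume` whose `lung_mask` is
#'   used).
#' @param spacing voxel spacing in mm (taken from the volume if one is given).
#' @return Volume in litres.
#' @export
#' @examples
#' lung_volume(array(TRUE, c(10, 10, 10)), c(1, 1, 1)) # 0.001 L
lung_volume <- function(mask, spacing = NULL) {
  if (inherits(mask, "scan_volume")) {
    spacing <- mask$spacing
    mask <- mask$lung_mask
  }
  if (is.null(mask) || !any(mask)) stop("empty lung mask")
  if (is.null(spacing)) stop("`spacing` required when passing a bare mask")
  sum(as.logical(mask)) * prod(spacing) / 1e6
}

#' Mean lung density (MLD)
#'
#' Arithmetic mean attenuation over the masked voxels, HU.
#'
#' @inheritParams exp856
#' @return MLD in HU.
#' @export
mean_lung_density <- function(vol, mask = NULL) {
  mean(masked_values(vol, mask))
}

#' Expiratory low-attenuation fraction (air trapping score)
#'
#' Percentage of masked voxels with attenuation strictly below the threshold
#' (default \eqn{-856} HU), computed on the expiratory scan. Ties at exactly
#' the threshold are not counted.
#'
#' @param vol a [scan_volume()] or bare 3D HU array.
#' @param mask logical mask; defaults to the volume's `lung_mask`.
#' @param threshold HU cut, default `-856`.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' a <- array(c(-900, -856, -855, -1000), c(4, 1, 1))
#' exp856(a, array(TRUE, c(4, 1, 1))) # 50
exp856 <- function(vol, mask = NULL, threshold = -856) {
  v <- masked_values(vol, mask)
  100 * mean(v < threshold)
}

#' Expiratory-to-inspiratory ratio of mean lung density
#'
#' \eqn{100 \times MLD_{exp} / MLD_{insp}}, in percent. Higher values mean the
#' lung empties less (more trapping). The ratio may exceed 100.
#'
#' @param mld_exp,mld_insp mean lung densities in HU; physiological lungs are
#'   negative. A zero inspiratory MLD is an error; positive MLDs raise a
#'   warning.
#' @return Ratio in percent.
#' @export
#' @examples
#' ei_ratio(-800, -880) # 90.9...
ei_ratio <- function(mld_exp, mld_insp) {
  if (any(mld_insp == 0)) stop("undefined ratio: inspiratory MLD is zero")
  if (any(mld_insp > 0) || any(mld_exp > 0))
    warning("positive mean lung density is non-physiological")
  100 * mld_exp / mld_insp
}

#' Lung density histogram
#'
#' Histogram of masked attenuation values on integer-aligned HU bins, the
#' summary from which thresholded air-trapping measures and percentiles can
#' be read off.
#'
#' @inheritParams exp856
#' @param binwidth bin width in HU.
#' @return Object of class `hu_histogram`: `breaks`, `counts`, `total`.
#' @export
density_histogram <- function(vol, mask = NULL, binwidth = 1) {
  v <- masked_values(vol, mask)
  lo <- floor(min(v) / binwidth) * binwidth
  hi <- ceiling(max(v) / binwidth) * binwidth
  breaks <- seq(lo, hi + binwidth, by = binwidth)
  counts <- tabulate(findInterval(v, breaks, left.open = FALSE),
                     nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts, total = length(v)),
            class = "hu_histogram")
}

#' @rdname density_histogram
#' @param h a `hu_histogram`.
#' @param threshold HU value; must align with a bin edge for an exact answer.
#' @return `hist_percent_below`: percentage of voxels in bins entirely below
#'   `threshold`.
#' @export
hist_percent_below <- function(h, threshold = -856) {
  stopifnot(inherits(h, "hu_histogram"))
  100 * sum(h$counts[h$breaks[-1] <= threshold]) / h$total
}

#' Mean attenuation in a circular phantom ROI
#'
#' Mimics the observer protocol for the QC phantom: a circular region of
#' interest of given diameter placed in one axial slice at a fixed location;
#' a voxel belongs to the ROI if its in-plane centre lies within the circle.
#'
#' @param vol a [scan_volume()] (typically a phantom session).
#' @param center length-3 position in mm relative to the grid centre; the
#'   slice nearest `center[3]` is used.
#' @param diameter ROI diameter in mm (default 20).
#' @return Mean HU over the ROI voxels.
#' @export
phantom_roi_mean <- function(vol, center = c(0, 0, 0), diameter = 20) {
  stopifnot(inherits(vol, "scan_volume"), diameter > 0)
  d <- dim(vol$voxels)
  co <- grid_coords(d, vol$spacing)
  r <- diameter / 2
  ext <- d * vol$spacing
  if (abs(center[1]) + r > ext[1] / 2 || abs(center[2]) + r > ext[2] / 2 ||
      abs(center[3]) > ext[3] / 2)
    stop("ROI extends outside the image grid")
  zi <- which.min(abs(co$axis[[3]] - center[3]))
  sl <- vol$voxels[, , zi]
  x <- rep(co$axis[[1]], times = d[2])
  y <- rep(co$axis[[2]], each = d[1])
  sel <- (x - center[1])^2 + (y - center[2])^2 <= r^2
  if (!any(sel)) stop("ROI contains no voxel centres; enlarge the diameter")
  mean(sl[sel])
}

#' Densitometric measures for one subject-visit
#'
#' Applies the (optional) noise-reduction filter to both phases, obtains lung
#' masks (ground truth by default, threshold segmentation on request), and
#' computes volumes, mean lung densities, the expiratory low-attenuation
#' fraction and the E/I density ratio. Both air-trapping measures see the
#' identically preprocessed volumes.
#'
#' @param pair a [visit_pair()].
#' @param smooth_sd_mm Gaussian noise-filter sd in mm (0 disables).
#' @param segmentation `"mask"` uses the volumes' own masks; `"threshold"`
#'   runs [segment_lungs()].
#' @param hu_threshold threshold for the stand-in segmenter.
#' @return One-row data frame with fixed column names: `subject_id`, `visit`,
#'   `v_insp_L`, `v_exp_L`, `v_exhaled_L`, `mld_insp_hu`, `mld_exp_hu`,
#'   `exp856_pct`, `ei_ratio_pct`, `flags`.
#' @export
measure_visit <- function(pair, smooth_sd_mm = 0,
                          segmentation = c("mask", "threshold"),
                          hu_threshold = -300) {
  stopifnot(inherits(pair, "visit_pair"))
  segmentation <- match.arg(segmentation)
  vi <- smooth_volume(pair$insp, smooth_sd_mm)
  ve <- smooth_volume(pair$exp, smooth_sd_mm)
  mi <- if (segmentation == "mask") segment_lungs(vi, bypass = TRUE)
        else segment_lungs(vi, hu_threshold)
  me <- if (segmentation == "mask") segment_lungs(ve, bypass = TRUE)
        else segment_lungs(ve, hu_threshold)
  flags <- character(0)
  v_insp <- lung_volume(mi, vi$spacing)
  v_exp <- lung_volume(me, ve$spacing)
  v_exhaled <- v_insp - v_exp
  if (v_exhaled <= 0) flags <- c(flags, "non_positive_exhaled_volume")
  mld_i <- mean_lung_density(vi, mi)
  mld_e <- mean_lung_density(ve, me)
  ei <- withCallingHandlers(
    ei_ratio(mld_e, mld_i),
    warning = function(w) {
      flags <<- c(flags, "positive_mld")
      invokeRestart("muffleWarning")
    })
  data.frame(subject_id = pair$subject_id, visit = pair$visit,
             v_insp_L = v_insp, v_exp_L = v_exp, v_exhaled_L = v_exhaled,
             mld_insp_hu = mld_i, mld_exp_hu = mld_e,
             exp856_pct = exp856(ve, me),
             ei_ratio_pct = ei,
             flags = paste(flags, collapse = ";"))
}

#' Densitometric measures for a whole cohort
#'
#' Runs [measure_visit()] on every subject-visit. Subjects whose segmentation
#' fails are excluded (all their visits) and recorded, mirroring how clinical
#' studies drop scan pairs with segmentation errors rather than abort.
#'
#' @param cohort a `ct_cohort`.
#' @inheritParams measure_visit
#' @return Data frame of per-visit measures; excluded subjects are listed in
#'   `attr(, "excluded")` as a data frame of `subject_id`, `reason`.
#' @export
measure_cohort <- function(cohort, smooth_sd_mm = 0,
                           segmentation = c("mask", "threshold"),
                           hu_threshold = -300) {
  stopifnot(inherits(cohort, "ct_cohort"))
  segmentation <- match.arg(segmentation)
  rows <- list()
  excluded <- list()
  for (s in cohort$subjects) {
    res <- tryCatch(
      lapply(s$visits, measure_visit, smooth_sd_mm = smooth_sd_mm,
             segmentation = segmentation, hu_threshold = hu_threshold),
      error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        subject_id = s$truth$subject_id, reason = conditionMessage(res))
    } else {
      rows <- c(rows, res)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
    else data.frame(subject_id = character(0), reason = character(0))
  out
}
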