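# Small, fast cohort configurations used across the unit tests. These are test
# fixtures (coarse grids, small lungs), not the package's default study
# conditions.

tiny_config <- function(...) {
  args <- list(n_subjects = 3, grid_shape = c(20L, 20L, 20L),
               voxel_spacing = c(8, 8, 8), insp_volume_dist = c(1.6, 0.15),
               seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

small_config <- function(...) {
  args <- list(n_subjects = 12, grid_shape = c(24L, 24L, 24L),
               voxel_spacing = c(8, 8, 8), insp_volume_dist = c(1.7, 0.15),
               seed = 4242)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# Interior voxels of a lung mask: those untouched by boundary partial-volume
# mixing at the given smoothing scale (mask smoothed, then thresholded).
interior_mask <- function(vol, kernel_sd_mm) {
  m <- scan_volume(array(as.numeric(vol$lung_mask), dim(vol$lung_mask)) * 100 - 50,
                   vol$spacing)
  sm <- smooth_volume(m, kernel_sd_mm)$voxels
  vol$lung_mask & (sm > 49.9)
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Frozen outputs of run_pipeline(small_config()); regenerate by rerunning the
# pipeline and pasting the printed values if the generator is intentionally
# changed.
golden_report_values <- function() {
  c(exp856_mean_diff = -1.72654082201528,
    exp856_loa_high = 5.74780241927069,
    ei_ccc = 0.852085488016871)
}
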