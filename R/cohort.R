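#' Configuration for a synthetic paired-CT cohort
#'
#' Defines the study conditions emulated by the generator: a cohort of heavy
#' smokers imaged twice in inspiration and expiration, with per-subject air
#' trapping, between-visit breath-hold variability and scanner noise. The
#' defaults describe a 45-subject cohort with inspiratory volumes around
#' 5--7 L, expiratory volumes around 2.5--4.5 L and trapped-lung fractions
#' spanning roughly half a percent to tens of percent of expiratory volume.
#'
#' @param n_subjects number of subjects.
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing mm per axis.
#' @param insp_volume_dist `c(mean, sd)` of the true inspiratory lung volume, L.
#' @param exp_to_insp_ratio_dist `c(mean, sd)` of the normal-tissue emptying
#'   factor \eqn{r_0 \in (0,1)}; the realized expiratory-to-inspiratory volume
#'   ratio is \eqn{f + (1-f) r_0} for trapped fraction \eqn{f}, so trapped
#'   subjects exhale less and feasibility (`exp_ratio > f_trapped`) always
#'   holds.
#' @param trapped_fraction_dist `c(alpha, beta)` of a Beta law for the fraction
#'   of inspiratory lung volume that is trapped.
#' @param mu_tissue_insp mean inspiratory lung attenuation, HU.
#' @param mu_tissue_sd between-subject sd of inspiratory lung attenuation, HU.
#' @param sigma_texture HU sd of parenchymal texture.
#' @param sigma_noise HU sd of additive scanner noise.
#' @param hu_drift_sd HU sd of a per-scan global calibration offset (scanner CT
#'   numbers vary by a few HU between sessions even with phantom QC in place).
#' @param breath_hold_sd log-scale sd of the multiplicative visit-2 expiratory
#'   volume factor (breath-hold variability).
#' @param insp_repro_sd log-scale sd of the visit-2 inspiratory volume factor;
#'   inspiratory breath holds reproduce better than expiratory ones.
#' @param share_visit_noise if `TRUE`, visit 2 replays visit 1's noise stream
#'   (the zero-variation identity mode used for pipeline verification).
#' @param round_hu round voxel values to integer HU.
#' @param seed integer RNG seed; the entire cohort is a pure function of the
#'   configuration including this seed.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_subjects = 45L,
                          grid_shape = c(48L, 48L, 48L),
                          voxel_spacing = c(5.5, 5.5, 5.5),
                          insp_volume_dist = c(mean = 6.0, sd = 0.5),
                          exp_to_insp_ratio_dist = c(mean = 0.45, sd = 0.08),
                          trapped_fraction_dist = c(alpha = 1.2, beta = 4.5),
                          mu_tissue_insp = -880,
                          mu_tissue_sd = 10,
                          sigma_texture = 30,
                          sigma_noise = 25,
                          hu_drift_sd = 0,
                          breath_hold_sd = 0.08,
                          insp_repro_sd = 0.035,
                          share_visit_noise = FALSE,
                          round_hu = FALSE,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              insp_volume_dist = unname(as.numeric(insp_volume_dist)),
              exp_to_insp_ratio_dist = unname(as.numeric(exp_to_insp_ratio_dist)),
              trapped_fraction_dist = unname(as.numeric(trapped_fraction_dist)),
              mu_tissue_insp = as.numeric(mu_tissue_insp),
              mu_tissue_sd = as.numeric(mu_tissue_sd),
              sigma_texture = as.numeric(sigma_texture),
              sigma_noise = as.numeric(sigma_noise),
              hu_drift_sd = as.numeric(hu_drift_sd),
              breath_hold_sd = as.numeric(breath_hold_sd),
              insp_repro_sd = as.numeric(insp_repro_sd),
              share_visit_noise = isTRUE(share_visit_noise),
              round_hu = isTRUE(round_hu),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L,
            length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 4L),
            length(cfg$voxel_spacing) == 3L, all(cfg$voxel_spacing > 0))
  if (cfg$insp_volume_dist[1] <= 0 || cfg$insp_volume_dist[2] < 0)
    stop("insp_volume_dist must be (mean > 0, sd >= 0)")
  r <- cfg$exp_to_insp_ratio_dist
  if (r[1] <= 0 || r[1] >= 1 || r[2] < 0)
    stop("exp_to_insp_ratio_dist mean must lie in (0,1), sd >= 0")
  if (any(cfg$trapped_fraction_dist <= 0))
    stop("trapped_fraction_dist Beta parameters must be positive")
  sds <- c(cfg$mu_tissue_sd, cfg$sigma_texture, cfg$sigma_noise,
           cfg$hu_drift_sd, cfg$breath_hold_sd, cfg$insp_repro_sd)
  if (any(sds < 0)) stop("all sd parameters must be >= 0")
  grid_l <- prod(cfg$grid_shape) * prod(cfg$voxel_spacing) / 1e6
  if (cfg$insp_volume_dist[1] > 0.5 * grid_l)
    stop(sprintf(paste("infeasible geometry: mean inspiratory volume %.2f L",
                       "exceeds half the grid physical volume (%.2f L)"),
                 cfg$insp_volume_dist[1], grid_l))
  invisible(cfg)
}

#' Trapped-share algebra for the expiratory lung
#'
#' With a fraction `f_trapped` of the inspiratory lung volume trapped (it
#' retains its inspiratory volume and attenuation at expiration) and an
#' expiratory-to-inspiratory volume ratio `exp_ratio`, volume closure
#' \eqn{V_{exp} = f V_{insp} + k (1-f) V_{insp}} gives the shrink factor of
#' the normally emptying tissue, \eqn{k = (r - f)/(1 - f)}, and the trapped
#' fraction of the *expiratory* volume, \eqn{f_{exp} = f / r}.
#'
#' @param f_trapped fraction of inspiratory volume that is trapped, in
#'   `[0, exp_ratio)`.
#' @param exp_ratio expiratory-to-inspiratory volume ratio, in `(f_trapped, 1]`.
#' @return A list with `k` (normal-tissue shrink factor) and `f_exp` (trapped
#'   fraction of expiratory volume), both in `(0, 1]` (with `f_exp = 0` when
#'   there is no trapping).
#' @export
#' @examples
#' trapped_share_expiratory(0.2, 0.6) # k = 0.5, f_exp = 1/3
trapped_share_expiratory <- function(f_trapped, exp_ratio) {
  stopifnot(is.numeric(f_trapped), is.numeric(exp_ratio))
  if (any(f_trapped < 0) || any(f_trapped >= 1))
    stop("f_trapped must lie in [0, 1)")
  if (any(exp_ratio > 1))
    stop("exp_ratio must lie in (0, 1]")
  if (any(exp_ratio <= f_trapped))
    stop("infeasible: exp_ratio must exceed f_trapped (trapped tissue cannot shrink)")
  list(k = (exp_ratio - f_trapped) / (1 - f_trapped),
       f_exp = ifelse(f_trapped == 0, 0, f_trapped / exp_ratio))
}

#' Sponge-model attenuation under regional volume change
#'
#' Lung attenuation above \eqn{-1000} HU is proportional to tissue content per
#' unit volume. If a region's volume scales by factor `k` while its tissue
#' mass is conserved, its attenuation becomes
#' \eqn{-1000 + (1000 + HU_{insp}) / k}.
#'
#' @param hu_insp attenuation at the reference (inspiratory) volume, HU;
#'   at or above \eqn{-1000}.
#' @param k volume scale factor, positive; `k < 1` is shrink (densification),
#'   `k > 1` is expansion.
#' @return Attenuation in HU; results above +100 HU (non-physical for lung
#'   parenchyma) are clipped with a warning.
#' @export
#' @examples
#' sponge_hu(-880, 0.5) # -760
sponge_hu <- function(hu_insp, k) {
  if (any(hu_insp < -1000)) stop("hu_insp below -1000 HU is non-physical")
  if (any(k <= 0)) stop("volume scale factor k must be positive")
  out <- -1000 + (1000 + hu_insp) / k
  if (any(out > 100)) {
    warning("sponge attenuation above +100 HU clipped (non-physical for lung)")
    out[out > 100] <- 100
  }
  out
}

#' Analytic expectation of the expiratory low-attenuation fraction
#'
#' For an expiratory lung whose voxel HU follow a two-component Gaussian
#' mixture (trapped vs normally emptied tissue, common sd), the expected
#' percentage of voxels below \eqn{-856} HU is
#' \deqn{100 [ f_{exp} \Phi((-856-\mu_t)/\sigma) +
#'             (1-f_{exp}) \Phi((-856-\mu_n)/\sigma) ].}
#' Used as the independent oracle for the rendered measure.
#'
#' @param f_exp trapped fraction of the expiratory volume, in `[0, 1]`.
#' @param mu_trapped,mu_normal component means, HU.
#' @param sigma common component sd, HU; must be positive.
#' @param threshold attenuation threshold, HU.
#' @return Expected measure in percent.
#' @export
#' @examples
#' expected_exp856(0.3, -900, -750, 40) # ~26.2
expected_exp856 <- function(f_exp, mu_trapped, mu_normal, sigma,
                            threshold = -856) {
  stopifnot(f_exp >= 0, f_exp <= 1)
  if (sigma <= 0) stop("sigma must be positive")
  100 * (f_exp * stats::pnorm((threshold - mu_trapped) / sigma) +
           (1 - f_exp) * stats::pnorm((threshold - mu_normal) / sigma))
}

# ---- internal geometry -----------------------------------------------------

# Precompute, once per grid, the voxel ordering that grows each ellipsoidal
# lung from its centre outwards. A mask of any target volume is then the first
# N voxels of that ordering, so realized volumes are exact to half a voxel.
lung_geometry <- function(grid_shape, spacing) {
  co <- grid_coords(grid_shape, spacing)
  ext <- grid_shape * spacing
  semi <- c(ext[1] / 4, ext[2] / 3, ext[3] / 2.2)   # lung-like aspect
  r2 <- function(cx) ((co$x - cx) / semi[1])^2 + (co$y / semi[2])^2 +
    (co$z / semi[3])^2
  left_idx <- which(co$x < 0)
  right_idx <- which(co$x > 0)
  r2l <- r2(-ext[1] / 4)[left_idx]
  r2r <- r2(ext[1] / 4)[right_idx]
  list(left_order = left_idx[order(r2l, left_idx)],
       right_order = right_idx[order(r2r, right_idx)],
       voxvol = prod(spacing),
       grid_shape = grid_shape, spacing = spacing)
}

# Linear voxel indices of a two-lung mask of target volume (litres).
mask_indices <- function(geom, v_litres, label = "volume") {
  n_total <- round(v_litres * 1e6 / geom$voxvol)
  n_left <- n_total %/% 2L
  n_right <- n_total - n_left
  if (n_left > length(geom$left_order) || n_right > length(geom$right_order))
    stop(sprintf("infeasible geometry: %s of %.2f L does not fit the grid",
                 label, v_litres))
  realized <- n_total * geom$voxvol / 1e6
  if (abs(realized - v_litres) / v_litres > 0.02)
    stop(sprintf("generation error: realized %s %.3f L deviates >2%% from target %.3f L",
                 label, realized, v_litres))
  list(idx = c(geom$left_order[seq_len(n_left)],
               geom$right_order[seq_len(n_right)]),
       realized = realized)
}

index_mask <- function(idx, grid_shape) {
  m <- array(FALSE, grid_shape)
  m[idx] <- TRUE
  m
}

# Spatially smooth random field used to carve contiguous trapped blobs.
blob_field <- function(grid_shape, corr_vox = 2.5) {
  smooth_array3d(array(stats::rnorm(prod(grid_shape)), grid_shape),
                 rep(corr_vox, 3))
}

#' Render a single expiratory-style lung scan
#'
#' Low-level renderer used by [generate_cohort()] and directly useful for
#' verifying the densitometry against the analytic oracle
#' [expected_exp856()]. Voxels inside the two-ellipsoid lung mask are drawn
#' from a two-component Gaussian mixture: a fraction `f_exp` of the lung,
#' arranged as contiguous blobs, has mean `mu_trapped`; the remainder has mean
#' `mu_normal`. Background is soft tissue around +50 HU.
#'
#' @param grid_shape,spacing grid geometry (voxels / mm).
#' @param lung_volume_l total lung volume to render, litres.
#' @param f_exp trapped (low-attenuation) blob fraction of the lung volume.
#' @param mu_trapped,mu_normal,sigma mixture means and common sd, HU.
#' @param blob_corr_vox correlation length of the blob-carving field, voxels.
#' @return A `scan_volume` with `lung_mask` set.
#' @export
render_expiratory_scan <- function(grid_shape, spacing, lung_volume_l,
                                   f_exp, mu_trapped, mu_normal, sigma,
                                   blob_corr_vox = 2.5) {
  stopifnot(f_exp >= 0, f_exp <= 1, sigma > 0)
  geom <- lung_geometry(as.integer(grid_shape), as.numeric(spacing))
  mi <- mask_indices(geom, lung_volume_l, "lung volume")
  n <- prod(grid_shape)
  vox <- stats::rnorm(n, mean = 50, sd = sigma / 2)
  n_lung <- length(mi$idx)
  n_trap <- round(f_exp * n_lung)
  trap_idx <- integer(0)
  if (n_trap > 0) {
    fld <- blob_field(as.integer(grid_shape), blob_corr_vox)
    ord <- mi$idx[order(-fld[mi$idx], mi$idx)]
    trap_idx <- ord[seq_len(n_trap)]
  }
  norm_idx <- setdiff(mi$idx, trap_idx)
  vox[norm_idx] <- stats::rnorm(length(norm_idx), mu_normal, sigma)
  if (n_trap > 0) vox[trap_idx] <- stats::rnorm(n_trap, mu_trapped, sigma)
  scan_volume(array(clamp_hu(vox), grid_shape), spacing,
              lung_mask = index_mask(mi$idx, grid_shape),
              meta = list(phase = "expiratory", f_exp = f_exp))
}

# Render one visit (inspiratory + expiratory scan) for one subject.
# Consumes the current RNG stream; callers control seeding/sharing.
#
# The trapped compartment is a disease property, fixed across visits: it
# occupies f_trapped of the subject's *reference* inspiratory volume and
# retains the reference inspiratory attenuation. The expiratory scan is
# therefore a function of expiratory volume alone (tissue-mass conservation),
# while the inspiratory scan tracks the realized breath depth.
render_visit <- function(truth, visit, cfg, geom) {
  v_insp <- truth$v_insp_visit[visit]
  v_exp <- truth$v_exp_visit[visit]
  r <- v_exp / truth$v_insp_true
  f <- truth$f_trapped
  sh <- trapped_share_expiratory(f, r)
  # Inspiratory attenuation tracks the realized breath depth (sponge model).
  mu_i <- sponge_hu(truth$mu_tissue_insp, v_insp / truth$v_insp_true)
  mu_norm <- sponge_hu(truth$mu_tissue_insp, sh$k)
  sig <- sqrt(cfg$sigma_texture^2 + cfg$sigma_noise^2)
  gs <- cfg$grid_shape
  n <- prod(gs)

  drift_i <- stats::rnorm(1, 0, cfg$hu_drift_sd)
  drift_e <- stats::rnorm(1, 0, cfg$hu_drift_sd)

  ins <- mask_indices(geom, v_insp,
                      sprintf("inspiratory volume (subject %s)", truth$subject_id))
  exp_ <- mask_indices(geom, v_exp,
                       sprintf("expiratory volume (subject %s)", truth$subject_id))

  vox_i <- stats::rnorm(n, 50, cfg$sigma_noise)
  vox_i[ins$idx] <- stats::rnorm(length(ins$idx), mu_i, sig)
  vox_i <- clamp_hu(vox_i + drift_i)

  n_lung <- length(exp_$idx)
  n_trap <- round(sh$f_exp * n_lung)
  trap_idx <- integer(0)
  if (n_trap > 0) {
    fld <- blob_field(gs)
    ord <- exp_$idx[order(-fld[exp_$idx], exp_$idx)]
    trap_idx <- ord[seq_len(n_trap)]
  }
  norm_idx <- setdiff(exp_$idx, trap_idx)
  vox_e <- stats::rnorm(n, 50, cfg$sigma_noise)
  vox_e[norm_idx] <- stats::rnorm(length(norm_idx), mu_norm, sig)
  if (n_trap > 0)
    vox_e[trap_idx] <- stats::rnorm(n_trap, truth$mu_tissue_insp, sig)
  vox_e <- clamp_hu(vox_e + drift_e)

  if (cfg$round_hu) {
    vox_i <- round(vox_i)
    vox_e <- round(vox_e)
  }

  mk <- function(vox, idx, phase) scan_volume(
    array(vox, gs), cfg$voxel_spacing, lung_mask = index_mask(idx, gs),
    meta = list(subject = truth$subject_id, visit = visit, phase = phase))
  visit_pair(mk(vox_i, ins$idx, "inspiratory"),
             mk(vox_e, exp_$idx, "expiratory"),
             truth$subject_id, visit)
}

#' Generate a synthetic paired two-visit CT cohort
#'
#' Draws per-subject ground truth (inspiratory volume, emptying factor,
#' trapped fraction, tissue attenuation), then renders both visits of both
#' phases on a shared grid. Visit 1 realizes the true volumes; visit 2
#' perturbs the expiratory volume by a log-normal breath-hold factor
#' (`breath_hold_sd`) and the inspiratory volume by an independent, smaller
#' factor (`insp_repro_sd`). The trapped fraction is constant across visits
#' (small airways disease assumed stable over the short follow-up). In the
#' rare event that the perturbed visit-2 volumes are infeasible
#' (`exp_ratio <= f_trapped`), the perturbation pair is re-drawn
#' deterministically.
#'
#' The whole cohort is a pure function of the configuration, including its
#' seed: the same `cohort_config` yields bit-identical voxel grids.
#'
#' @param config a [cohort_config()].
#' @return An object of class `ct_cohort`: list with `config` and `subjects`,
#'   each subject holding `truth` (ground-truth list) and `visits` (two
#'   [visit_pair()]s).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  with_seed(config$seed, {
    geom <- lung_geometry(config$grid_shape, config$voxel_spacing)
    grid_l <- prod(config$grid_shape) * geom$voxvol / 1e6
    subjects <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      sid <- sprintf("S%03d", s)
      v_true <- 0
      while (v_true < 0.2) # reject non-physical tiny/negative draws
        v_true <- stats::rnorm(1, config$insp_volume_dist[1],
                               config$insp_volume_dist[2])
      if (v_true > 0.5 * grid_l)
        stop(sprintf("infeasible geometry for subject %s: %.2f L > half grid volume",
                     sid, v_true))
      r0 <- Inf
      while (r0 <= 0.05 || r0 >= 0.95)
        r0 <- stats::rnorm(1, config$exp_to_insp_ratio_dist[1],
                           config$exp_to_insp_ratio_dist[2])
      f <- 1
      while (f <= 1e-3 || f >= 0.95)
        f <- stats::rbeta(1, config$trapped_fraction_dist[1],
                          config$trapped_fraction_dist[2])
      exp_ratio <- f + (1 - f) * r0
      mu_t <- stats::rnorm(1, config$mu_tissue_insp, config$mu_tissue_sd)
      v_exp1 <- v_true * exp_ratio
      # visit-2 perturbation, re-drawn if it breaks volume closure
      # (normal tissue must keep a physical shrink factor, k >= ~0.12)
      for (try in 1:1000) {
        v_insp2 <- v_true * exp(stats::rnorm(1, 0, config$insp_repro_sd))
        v_exp2 <- v_exp1 * exp(stats::rnorm(1, 0, config$breath_hold_sd))
        r2 <- v_exp2 / v_true
        if (r2 > f + 0.12 * (1 - f) && r2 <= 0.98 &&
            v_exp2 <= 0.98 * v_insp2 && v_insp2 <= 0.5 * grid_l) break
        if (try == 1000)
          stop(sprintf("infeasible geometry for subject %s: no feasible visit-2 volumes", sid))
      }
      truth <- list(subject_id = sid,
                    v_insp_true = v_true,
                    exp_ratio_true = exp_ratio,
                    f_trapped = f,
                    mu_tissue_insp = mu_t,
                    v_insp_visit = c(v_true, v_insp2),
                    v_exp_visit = c(v_exp1, v_exp2))
      if (config$share_visit_noise) saved <- .Random.seed
      p1 <- render_visit(truth, 1L, config, geom)
      if (config$share_visit_noise) .Random.seed <<- saved
      p2 <- render_visit(truth, 2L, config, geom)
      subjects[[s]] <- list(truth = truth, visits = list(p1, p2))
    }
    structure(list(config = config, subjects = subjects), class = "ct_cohort")
  })
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat(sprintf("<ct_cohort> %d subjects, grid %s @ %s mm, seed %d\n",
              length(x$subjects),
              paste(x$config$grid_shape, collapse = "x"),
              paste(x$config$voxel_spacing, collapse = "x"),
              x$config$seed))
  invisible(x)
}

#' Ground-truth table of a synthetic cohort
#'
#' @param cohort a `ct_cohort`.
#' @return Data frame with one row per subject: true volumes, expiratory
#'   ratio, trapped fraction, tissue attenuation, and the realized per-visit
#'   volumes.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "ct_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    t <- s$truth
    data.frame(subject_id = t$subject_id,
               v_insp_true = t$v_insp_true,
               exp_ratio_true = t$exp_ratio_true,
               f_trapped = t$f_trapped,
               mu_tissue_insp = t$mu_tissue_insp,
               v_insp_v1 = t$v_insp_visit[1], v_insp_v2 = t$v_insp_visit[2],
               v_exp_v1 = t$v_exp_visit[1], v_exp_v2 = t$v_exp_visit[2])
  }))
}

# ---- digital QC phantom ----------------------------------------------------

#' Specification of the digital QC phantom
#'
#' A cylindrical foam body mimicking emphysematous lung parenchyma, with two
#' embedded cylinders filled with air and plastic. Imaged repeatedly, it
#' monitors the stability of CT numbers over data-acquisition sessions.
#'
#' @param body_diameter foam body diameter, mm.
#' @param foam_mean,air_cyl_mean,plastic_cyl_mean nominal attenuations, HU.
#' @param cyl_radius,cyl_offset cylinder radius and in-plane centre offset
#'   from the body axis, mm (air cylinder at `+cyl_offset` on x, plastic at
#'   `-cyl_offset`).
#' @param noise_sd additive Gaussian noise per session, HU.
#' @param drift_per_session optional linear HU drift across sessions (for
#'   exercising QC alarms); default 0.
#' @param grid_shape,voxel_spacing phantom image geometry.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_diameter = 320,
                         foam_mean = -966,
                         air_cyl_mean = -1000,
                         plastic_cyl_mean = 100,
                         cyl_radius = 25,
                         cyl_offset = 80,
                         noise_sd = 2,
                         drift_per_session = 0,
                         grid_shape = c(96L, 96L, 8L),
                         voxel_spacing = c(4, 4, 6)) {
  spec <- list(body_diameter = body_diameter, foam_mean = foam_mean,
               air_cyl_mean = air_cyl_mean, plastic_cyl_mean = plastic_cyl_mean,
               cyl_radius = cyl_radius, cyl_offset = cyl_offset,
               noise_sd = noise_sd, drift_per_session = drift_per_session,
               grid_shape = as.integer(grid_shape),
               voxel_spacing = as.numeric(voxel_spacing))
  if (spec$foam_mean >= -800) stop("foam_mean must be below -800 HU")
  if (spec$cyl_offset + spec$cyl_radius > spec$body_diameter / 2)
    stop("cylinders must lie fully inside the foam body")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  ext <- spec$grid_shape[1:2] * spec$voxel_spacing[1:2]
  if (any(spec$body_diameter > ext))
    stop("phantom body does not fit the image grid")
  structure(spec, class = "phantom_spec")
}

#' Generate repeated acquisitions of the QC phantom
#'
#' @param spec a [phantom_spec()].
#' @param n_sessions number of acquisition sessions to simulate.
#' @param seed optional RNG seed.
#' @return List of `scan_volume`s, one per session; session-to-session
#'   variation comes only from noise (plus the configured drift, if any).
#' @export
generate_phantom <- function(spec, n_sessions = 1L, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), n_sessions >= 1)
  with_seed(seed, {
    gs <- spec$grid_shape
    co <- grid_coords(gs, spec$voxel_spacing)
    base <- rep(-1000, prod(gs))
    in_body <- co$x^2 + co$y^2 <= (spec$body_diameter / 2)^2
    base[in_body] <- spec$foam_mean
    in_air <- (co$x - spec$cyl_offset)^2 + co$y^2 <= spec$cyl_radius^2
    in_plastic <- (co$x + spec$cyl_offset)^2 + co$y^2 <= spec$cyl_radius^2
    base[in_air] <- spec$air_cyl_mean
    base[in_plastic] <- spec$plastic_cyl_mean
    lapply(seq_len(n_sessions), function(i) {
      vox <- base + spec$drift_per_session * (i - 1)
      if (spec$noise_sd > 0)
        vox <- vox + stats::rnorm(length(vox), 0, spec$noise_sd)
      scan_volume(array(clamp_hu(vox), gs), spec$voxel_spacing,
                  meta = list(session = i))
    })
  })
}

# ---- cohort file interchange ----------------------------------------------

#' Write and read a cohort as NIfTI volumes plus a CSV manifest
#'
#' One `.nii.gz` per phase per visit (and its mask), with a manifest CSV
#' linking files to subjects, visits, phases and ground-truth columns.
#'
#' @param cohort a `ct_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort` invisibly returns the manifest path; `read_cohort`
#'   returns a `ct_cohort` (config restored from the stored YAML).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ct_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- cohort_truth(cohort)
  rows <- list()
  for (s in cohort$subjects) {
    for (pair in s$visits) {
      for (phase in c("insp", "exp")) {
        vol <- pair[[phase]]
        stem <- sprintf("%s_v%d_%s", pair$subject_id, pair$visit, phase)
        write_scan(vol, file.path(dir, paste0(stem, ".nii.gz")),
                   file.path(dir, paste0(stem, "_mask.nii.gz")))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = pair$subject_id, visit = pair$visit, phase = phase,
          file = paste0(stem, ".nii.gz"),
          mask_file = paste0(stem, "_mask.nii.gz"))
      }
    }
  }
  manifest <- merge(do.call(rbind, rows), truth, by = "subject_id", sort = FALSE)
  manifest <- manifest[order(manifest$subject_id, manifest$visit,
                             manifest$phase), ]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  write_cohort_config(cohort$config, file.path(dir, "cohort_config.yaml"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  config <- read_cohort_config(file.path(dir, "cohort_config.yaml"))
  sids <- unique(manifest$subject_id)
  subjects <- lapply(sids, function(sid) {
    rows <- manifest[manifest$subject_id == sid, ]
    t1 <- rows[1, ]
    truth <- list(subject_id = sid,
                  v_insp_true = t1$v_insp_true,
                  exp_ratio_true = t1$exp_ratio_true,
                  f_trapped = t1$f_trapped,
                  mu_tissue_insp = t1$mu_tissue_insp,
                  v_insp_visit = c(t1$v_insp_v1, t1$v_insp_v2),
                  v_exp_visit = c(t1$v_exp_v1, t1$v_exp_v2))
    visits <- lapply(1:2, function(v) {
      get_phase <- function(phase) {
        r <- rows[rows$visit == v & rows$phase == phase, ]
        read_scan(file.path(dir, r$file), file.path(dir, r$mask_file),
                  meta = list(subject = sid, visit = v, phase = phase))
      }
      visit_pair(get_phase("insp"), get_phase("exp"), sid, v)
    })
    list(truth = truth, visits = visits)
  })
  structure(list(config = config, subjects = subjects), class = "ct_cohort")
}

#' Read and write cohort configurations as YAML
#'
#' Keys mirror the [cohort_config()] fields.
#'
#' @param config a `cohort_config`.
#' @param path YAML file path.
#' @return `read_cohort_config` returns a validated `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}
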